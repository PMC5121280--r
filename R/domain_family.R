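# Family identification: membership requires one QLQ and one WRC domain hit.
# The domains are found with a position-specific scoring matrix (PSSM) built
# from a packaged seed alignment; the scan threshold defaults to 60% of the
# maximum attainable bit score and an E-value is attached from an
# extreme-value (Gumbel) fit to a random-window null computed at build time.

#' Build a PSSM from a seed alignment
#'
#' Log-odds (bits) against a uniform 1/20 background with an additive
#' pseudocount. Columns containing gaps are dropped (all-gap columns with a
#' warning), so the matrix width equals the seed's ungapped column count.
#'
#' @param seed_aln named character vector of aligned amino-acid sequences
#'   (>= 3 sequences, >= 5 ungapped columns).
#' @param domain_name label, e.g. `"QLQ"` or `"WRC"`.
#' @param pseudocount additive pseudocount (spread over the 20 residues).
#' @param threshold_frac score threshold as a fraction of the maximum
#'   attainable score.
#' @param n_null random windows used for the Gumbel E-value fit.
#' @param seed RNG seed for the null sample (fit is stored with the PSSM, so
#'   scanning itself is deterministic).
#' @return An object of class `fam_pssm`.
#' @export
build_pssm <- function(seed_aln, domain_name = "domain", pseudocount = 0.5,
                       threshold_frac = 0.6, n_null = 10000, seed = 1L) {
  if (length(seed_aln) < 3) stopf("need >= 3 seed sequences, got %d", length(seed_aln))
  m <- seq_to_matrix(seed_aln)
  gap <- m == "-" | m == "."
  all_gap <- colSums(gap) == nrow(m)
  if (any(all_gap)) warnf("dropping %d all-gap seed column(s)", sum(all_gap))
  keep <- colSums(gap) == 0 & !all_gap
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 5) stopf("need >= 5 ungapped seed columns, got %d", ncol(m))
  counts <- apply(m, 2, function(col) table(factor(col, levels = AA_ALPHABET)))
  probs <- sweep(counts + pseudocount / 20, 2, colSums(counts) + pseudocount, "/")
  scores <- log2(probs / (1 / 20)) # bits vs uniform background
  max_score <- sum(apply(scores, 2, max))
  pssm <- structure(
    list(domain_name = domain_name, width = ncol(m), scores = scores,
         probs = probs, max_score = max_score,
         threshold = threshold_frac * max_score),
    class = "fam_pssm"
  )
  # Gumbel null: scores of random uniform-composition windows (moment fit)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  null_windows <- matrix(sample.int(20, n_null * pssm$width, replace = TRUE),
                         nrow = n_null)
  null_scores <- pssm_window_scores_idx(pssm, null_windows)
  beta <- stats::sd(null_scores) * sqrt(6) / pi
  mu <- mean(null_scores) - 0.5772156649 * beta
  pssm$gumbel <- c(mu = mu, beta = beta)
  pssm
}

#' @export
print.fam_pssm <- function(x, ...) {
  cat(sprintf("<fam_pssm> %s: width %d, max score %.1f bits, threshold %.1f bits\n",
              x$domain_name, x$width, x$max_score, x$threshold))
  invisible(x)
}

# score a matrix of integer-encoded windows (rows) against the PSSM
pssm_window_scores_idx <- function(pssm, idx_matrix) {
  w <- pssm$width
  sc <- pssm$scores
  out <- numeric(nrow(idx_matrix))
  for (j in seq_len(w)) out <- out + sc[idx_matrix[, j] + (j - 1L) * 20L]
  out
}

#' Consensus sequence of a PSSM
#' @param pssm a `fam_pssm`.
#' @return The argmax residue per column, as a string.
#' @export
pssm_consensus <- function(pssm) {
  paste0(AA_ALPHABET[apply(pssm$scores, 2, which.max)], collapse = "")
}

#' Scan a protein for domain hits
#'
#' Every window scoring at or above the PSSM threshold is reported;
#' overlapping hits are resolved greedily to the best-scoring non-overlapping
#' set (ties broken leftmost). E-values use the stored Gumbel null times the
#' number of windows scanned.
#'
#' @param protein_seq amino-acid string.
#' @param pssm a `fam_pssm`.
#' @param gene_id optional id carried into the result.
#' @return Tibble with columns gene_id, domain_name, start, end (1-based
#'   protein coordinates), score (bits), evalue. Empty when the sequence is
#'   shorter than the PSSM width.
#' @export
scan_protein <- function(protein_seq, pssm, gene_id = NA_character_) {
  w <- pssm$width
  L <- nchar(protein_seq)
  empty <- tibble::tibble(gene_id = character(), domain_name = character(),
                          start = integer(), end = integer(),
                          score = numeric(), evalue = numeric())
  if (L < w) return(empty)
  idx <- match(strsplit(protein_seq, "")[[1]], AA_ALPHABET)
  idx[is.na(idx)] <- 1L # unknown residues scored as 'A' (conservative)
  n_win <- L - w + 1L
  starts <- seq_len(n_win)
  windows <- vapply(seq_len(w), function(j) idx[starts + j - 1L], integer(n_win))
  if (n_win == 1L) windows <- matrix(windows, nrow = 1L)
  sc <- pssm_window_scores_idx(pssm, windows)
  hit <- which(sc >= pssm$threshold)
  if (!length(hit)) return(empty)
  ord <- hit[order(-sc[hit], hit)] # best score first, ties leftmost
  chosen <- integer(0)
  for (h in ord) {
    if (!any(abs(h - chosen) < w)) chosen <- c(chosen, h)
  }
  chosen <- sort(chosen)
  z <- (sc[chosen] - pssm$gumbel[["mu"]]) / pssm$gumbel[["beta"]]
  pval <- -expm1(-exp(-z)) # P(window score >= s) under the Gumbel null
  tibble::tibble(
    gene_id = gene_id, domain_name = pssm$domain_name,
    start = as.integer(chosen), end = as.integer(chosen + w - 1L),
    score = sc[chosen], evalue = pmax(n_win * pval, 0)
  )
}

#' Call family members across genomes
#'
#' A gene is a family member iff its protein has at least one QLQ hit and at
#' least one WRC hit. Members are named `<prefix><NN>` ordered by chromosome
#' then start position within each species.
#'
#' @param genomes a `fam_genome` or list of them (proteins attached).
#' @param pssms list with elements `QLQ` and `WRC` (class `fam_pssm`).
#' @return Tibble: member_id, gene_id, species, chrom, start, end, strand,
#'   n_QLQ, n_WRC, qlq_score, wrc_score.
#' @export
call_family <- function(genomes, pssms) {
  stopifnot(all(c("QLQ", "WRC") %in% names(pssms)))
  if (inherits(genomes, "fam_genome")) genomes <- list(genomes)
  purrr::map_dfr(genomes, function(g) {
    if (is.null(g$protein)) stopf("genome %s has no protein sequences attached", g$species)
    hits <- purrr::map_dfr(g$genes$gene_id, function(id) {
      p <- g$protein[[id]]
      if (is.null(p) || is.na(p)) return(NULL)
      dplyr::bind_rows(
        scan_protein(p, pssms$QLQ, gene_id = id),
        scan_protein(p, pssms$WRC, gene_id = id)
      )
    })
    if (nrow(hits) == 0L) return(empty_members())
    per_gene <- hits |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        n_QLQ = sum(.data$domain_name == "QLQ"),
        n_WRC = sum(.data$domain_name == "WRC"),
        qlq_score = max(c(.data$score[.data$domain_name == "QLQ"], -Inf)),
        wrc_score = max(c(.data$score[.data$domain_name == "WRC"], -Inf)),
        .groups = "drop"
      ) |>
      dplyr::filter(.data$n_QLQ >= 1, .data$n_WRC >= 1)
    if (nrow(per_gene) == 0L) return(empty_members())
    out <- genes_by_id(g, per_gene$gene_id) |>
      dplyr::select("gene_id", "chrom", "start", "end", "strand") |>
      dplyr::left_join(per_gene, by = "gene_id") |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::mutate(species = g$species,
                    member_id = sprintf("%s%02d", g$prefix, dplyr::row_number()))
    dplyr::select(out, "member_id", "gene_id", "species", "chrom", "start",
                  "end", "strand", "n_QLQ", "n_WRC", "qlq_score", "wrc_score")
  })
}

empty_members <- function() {
  tibble::tibble(member_id = character(), gene_id = character(),
                 species = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 n_QLQ = integer(), n_WRC = integer(),
                 qlq_score = numeric(), wrc_score = numeric())
}

#' Packaged synthetic seed alignments for the QLQ and WRC domains
#'
#' Constructed seed alignments (eight sequences each) emulating the conserved
#' Gln-Leu-Gln protein-interaction domain and the Trp-Arg-Cys zinc-finger
#' DNA-binding domain that jointly define the family. They are synthetic
#' stand-ins written for this package, not Pfam records.
#'
#' @param domain `"QLQ"` or `"WRC"`.
#' @return Named character vector of aligned sequences.
#' @export
seed_alignment <- function(domain = c("QLQ", "WRC")) {
  domain <- match.arg(domain)
  f <- system.file("extdata",
                   sprintf("%s_seed_synthetic.fasta", tolower(domain)),
                   package = "famsynt", mustWork = TRUE)
  read_fasta(f)
}

#' Default family PSSM pair built from the packaged seeds
#' @param ... passed to [build_pssm()].
#' @return List with elements `QLQ` and `WRC`.
#' @export
default_pssms <- function(...) {
  list(QLQ = build_pssm(seed_alignment("QLQ"), "QLQ", ...),
       WRC = build_pssm(seed_alignment("WRC"), "WRC", ...))
}
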