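# Nei-Gojobori (1986) Ka/Ks with codon back-translation alignment and the
# 150 bp / 9 bp sliding-window selection scan. Site counts use the fraction
# of synonymous single-nucleotide changes at each codon position (stop-codon
# mutations excluded); multi-nucleotide codon differences are averaged over
# all minimal substitution pathways with stop-crossing pathways dropped.
# Rates are Jukes-Cantor corrected: d = -(3/4) ln(1 - (4/3) p).

#' Back-translate a protein alignment pair to a codon alignment
#'
#' Each protein gap column becomes a `---` codon gap, so gaps occur only in
#' whole triplets and ungapping either sequence recovers its CDS exactly
#' (trailing stop codons are trimmed first).
#'
#' @param prot_a,prot_b aligned protein sequences (equal length, `-` gaps).
#' @param cds_a,cds_b the corresponding coding sequences; each must translate
#'   to its ungapped protein (error naming the first discordant residue).
#' @return Object of class `codon_alignment`: list with `a`, `b` (gap-aligned
#'   CDS strings) and `protein_columns` (source protein-alignment column per
#'   codon column).
#' @export
backtranslate <- function(prot_a, prot_b, cds_a, cds_b) {
  stopifnot(nchar(prot_a) == nchar(prot_b))
  expand <- function(prot, cds, label) {
    cds <- trim_stop(cds)
    aa <- translate_cds(cds)
    bare <- gsub("-", "", prot, fixed = TRUE)
    if (nchar(aa) != nchar(bare)) {
      stopf("%s: CDS translates to %d residues but protein has %d",
            label, nchar(aa), nchar(bare))
    }
    mism <- which(strsplit(aa, "")[[1]] != strsplit(bare, "")[[1]])
    if (length(mism)) {
      stopf("%s: translation mismatch at residue %d (%s vs %s)", label, mism[1],
            substr(aa, mism[1], mism[1]), substr(bare, mism[1], mism[1]))
    }
    codons <- codon_split(cds)
    cols <- strsplit(prot, "")[[1]]
    out <- character(length(cols))
    k <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- codons[k] }
    }
    out
  }
  a <- expand(prot_a, cds_a, "sequence a")
  b <- expand(prot_b, cds_b, "sequence b")
  structure(list(a = paste0(a, collapse = ""), b = paste0(b, collapse = ""),
                 protein_columns = seq_along(a)),
            class = "codon_alignment")
}

trim_stop <- function(cds) {
  codons <- codon_split(cds)
  if (length(codons) && genetic_code()[codons[length(codons)]] == "*") {
    cds <- substr(cds, 1, nchar(cds) - 3)
  }
  cds
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d codon columns\n", nchar(x$a) / 3))
  invisible(x)
}

# core NG86 on two codon vectors (gap-containing columns already removed)
ng86_core <- function(cod_a, cod_b) {
  syn <- codon_syn_sites()
  tabs <- codon_diff_tables()
  sa <- syn[cod_a]; sb <- syn[cod_b]
  if (anyNA(sa) || anyNA(sb)) stopf("stop or invalid codon in alignment")
  S <- (sum(sa) + sum(sb)) / 2
  N <- 3 * length(cod_a) - S
  idx <- cbind(match(cod_a, rownames(tabs$sd)), match(cod_b, colnames(tabs$sd)))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_) # correction undefined, flagged
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  classification <- if (is.na(ratio)) NA_character_
    else if (ratio < 1) "purifying" else if (ratio > 1) "positive" else "neutral"
  tibble::tibble(n_codons = length(cod_a), S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, Ks = Ks, Ka = Ka, ka_ks = ratio,
                 classification = classification)
}

codon_columns <- function(codon_aln) {
  a <- codon_split(codon_aln$a)
  b <- codon_split(codon_aln$b)
  gap <- grepl("-", a, fixed = TRUE) | grepl("-", b, fixed = TRUE)
  list(a = a, b = b, gap = gap)
}

#' NG86 Ka/Ks for a codon alignment
#'
#' @param codon_aln a `codon_alignment` (or list with `a`, `b` strings).
#' @return One-row tibble: n_codons (gap-free columns), S, N, Sd, Nd, pS, pN,
#'   Ks, Ka, ka_ks, classification. `ka_ks` is `NA` (undefined flag) when
#'   `Ks = 0` or a Jukes-Cantor correction is invalid; identical sequences
#'   give Ka = Ks = 0 with an undefined ratio.
#' @export
ng86 <- function(codon_aln) {
  cc <- codon_columns(codon_aln)
  keep <- !cc$gap
  if (!any(keep)) stopf("alignment has no gap-free codon columns")
  ng86_core(cc$a[keep], cc$b[keep])
}

#' Sliding-window NG86 scan
#'
#' NG86 on every fully contained window of `window` bp moved by `step` bp
#' along the alignment; `n_windows = floor((L - window)/step) + 1`. Windows
#' where the ratio is undefined carry `NA`, never a fabricated value.
#'
#' @param codon_aln a `codon_alignment`.
#' @param window window size in alignment bp (divisible by 3; default
#'   150).
#' @param step step size in bp (default 9).
#' @return Tibble with `win_start` (1-based alignment bp) plus the [ng86()]
#'   columns per window; zero rows (with a warning) when the alignment is
#'   shorter than `window`.
#' @export
sliding_window_kaks <- function(codon_aln, window = 150, step = 9) {
  stopifnot(window %% 3 == 0, step >= 1)
  cc <- codon_columns(codon_aln)
  L <- length(cc$a) * 3
  if (L < window) {
    warnf("alignment length %d bp is shorter than the window (%d bp); empty series", L, window)
    return(dplyr::mutate(ng86_empty(), win_start = integer(), .before = 1))
  }
  starts_bp <- seq(1, L - window + 1, by = step)
  purrr::map_dfr(starts_bp, function(s) {
    cols <- ((s - 1) %/% 3 + 1):((s + window - 2) %/% 3 + 1)
    # windows aligned to bp may straddle codons; use the codon columns whose
    # first bp lies inside the window so each window covers window/3 codons
    cols <- cols[(cols - 1) * 3 + 1 >= s & (cols - 1) * 3 + 1 <= s + window - 3]
    keep <- cols[!cc$gap[cols]]
    res <- if (length(keep)) ng86_core(cc$a[keep], cc$b[keep]) else ng86_empty()[0, ]
    dplyr::mutate(res, win_start = as.integer(s), .before = 1)
  })
}

ng86_empty <- function() {
  tibble::tibble(n_codons = integer(), S = numeric(), N = numeric(),
                 Sd = numeric(), Nd = numeric(), pS = numeric(), pN = numeric(),
                 Ks = numeric(), Ka = numeric(), ka_ks = numeric(),
                 classification = character())
}

#' Ka/Ks report for a list of gene pairs
#'
#' Aligns each pair's proteins, back-translates with the CDS, and runs NG86
#' plus (optionally) the sliding-window scan. Pairs with missing sequences
#' are flagged and the pipeline continues.
#'
#' @param pairs tibble with columns `gene_a`, `gene_b`.
#' @param cds,proteins named character vectors keyed by gene id.
#' @param window,step sliding-window settings; `windows = FALSE` skips the
#'   scan.
#' @param windows logical; also compute per-pair window series.
#' @return List with `pairs` (one row per pair: NG86 columns + `ok`/`note`)
#'   and `windows` (long tibble keyed by gene_a/gene_b) when requested.
#' @export
kaks_report <- function(pairs, cds, proteins, window = 150, step = 9,
                        windows = TRUE) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0L) {
    return(list(pairs = dplyr::mutate(ng86_empty(),
                                      gene_a = character(), gene_b = character(),
                                      ok = logical(), note = character(),
                                      .before = 1),
                windows = NULL))
  }
  win_acc <- list()
  rows <- purrr::pmap_dfr(pairs[, c("gene_a", "gene_b")], function(gene_a, gene_b) {
    base <- tibble::tibble(gene_a = gene_a, gene_b = gene_b)
    miss <- c(gene_a, gene_b)[!(c(gene_a, gene_b) %in% names(cds)) |
                                !(c(gene_a, gene_b) %in% names(proteins))]
    if (length(miss)) {
      return(dplyr::mutate(base, ok = FALSE,
                           note = sprintf("missing CDS/protein for %s", miss[1])))
    }
    pa <- proteins[[gene_a]]; pb <- proteins[[gene_b]]
    aln <- align_proteins(c(a = pa, b = pb))
    ca <- backtranslate(aln[["a"]], aln[["b"]], cds[[gene_a]], cds[[gene_b]])
    res <- ng86(ca)
    if (windows) {
      ws <- suppressWarnings(sliding_window_kaks(ca, window = window, step = step))
      win_acc[[paste(gene_a, gene_b)]] <<- dplyr::mutate(ws, gene_a = gene_a,
                                                         gene_b = gene_b, .before = 1)
    }
    dplyr::bind_cols(base, res, tibble::tibble(ok = TRUE, note = NA_character_))
  })
  list(pairs = rows,
       windows = if (windows) dplyr::bind_rows(win_acc) else NULL)
}
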