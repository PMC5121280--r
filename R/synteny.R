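# Anchor-centered microsynteny and duplication-mode classification.
# Flank proteins are compared with BLASTP (one search over the union of flank
# proteins per genome pair, memoised); E-values are recomputed from bit
# scores with the flank-set search space, E = m * n * 2^(-bit), where m is
# the query length and n the opposing flank set's total residues. A flanking
# pair is conserved iff it is the best non-self hit in both directions
# (reciprocal best hit) with E below the threshold, and pairing is one-to-one
# (greedy by score, ties to the smaller gene id).

#' Extract the flanking genes around an anchor
#'
#' Genes whose span intersects `[anchor.start - radius, anchor.end + radius]`
#' on the anchor's chromosome, anchor excluded; windows are clipped at
#' chromosome ends (an anchor at the start simply has an empty upstream
#' side).
#'
#' @param genome a `fam_genome`.
#' @param anchor_id anchor gene id (error if unknown).
#' @param radius_bp flank radius in bp (default 100 kb, the standard microsynteny window).
#' @return List of class `flank_set`: `anchor` (gene row), `window`
#'   (chrom/start/end), `genes` (tibble of flanking genes in position order).
#' @export
extract_flanks <- function(genome, anchor_id, radius_bp = 100000) {
  anchor <- genes_by_id(genome, anchor_id)
  lo <- max(1, anchor$start - radius_bp)
  hi <- anchor$end + radius_bp
  g <- genome$genes
  sel <- g$chrom == anchor$chrom & g$end >= lo & g$start <= hi &
    g$gene_id != anchor_id
  structure(
    list(anchor = anchor, species = genome$species,
         window = list(chrom = anchor$chrom, start = lo, end = hi),
         genes = g[sel, , drop = FALSE]),
    class = "flank_set"
  )
}

#' @export
print.flank_set <- function(x, ...) {
  cat(sprintf("<flank_set> anchor %s (%s:%d-%d), %d flanking genes\n",
              x$anchor$gene_id, x$window$chrom, x$window$start, x$window$end,
              nrow(x$genes)))
  invisible(x)
}

# run blastp of set a (queries) vs set b (database); returns tibble
# qid, sid, bit (max HSP bit score per pair). Deterministic.
blast_scores <- function(seqs_a, seqs_b) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    stopf("blastp/makeblastdb not found on PATH")
  }
  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "q.fa"); sf <- file.path(td, "s.fa")
  write_fasta(seqs_a, qf)
  write_fasta(seqs_b, sf)
  db <- file.path(td, "db")
  out <- file.path(td, "hits.tsv")
  sys_quiet("makeblastdb", c("-in", sf, "-dbtype", "prot", "-out", db))
  sys_quiet("blastp", c("-query", qf, "-db", db, "-outfmt", shQuote("6 qseqid sseqid bitscore"),
                        "-evalue", "10", "-max_target_seqs", "500",
                        "-seg", "no", "-num_threads", "1", "-out", out))
  if (!file.exists(out) || file.size(out) == 0) {
    return(tibble::tibble(qid = character(), sid = character(), bit = numeric()))
  }
  hits <- readr::read_tsv(out, col_names = c("qid", "sid", "bit"),
                          col_types = "ccd", progress = FALSE)
  dplyr::summarise(dplyr::group_by(hits, .data$qid, .data$sid),
                   bit = max(.data$bit), .groups = "drop")
}

sys_quiet <- function(cmd, args) {
  status <- system2(cmd, args, stdout = FALSE, stderr = FALSE)
  if (status != 0) stopf("%s failed with status %d", cmd, status)
}

# score table cache for a genome pair: environment keyed by sorted species
# pair holding the blast hit tibble over the union of family-flank proteins
synteny_score_cache <- function(genome_a, genome_b, members_a, members_b,
                                radius_bp) {
  flank_ids <- function(genome, members) {
    ids <- unique(unlist(lapply(members, function(a) {
      fs <- extract_flanks(genome, a, radius_bp)
      c(fs$genes$gene_id, a)
    })))
    ids[ids %in% names(genome$protein)]
  }
  ids_a <- flank_ids(genome_a, members_a)
  ids_b <- flank_ids(genome_b, members_b)
  if (!length(ids_a) || !length(ids_b)) {
    return(tibble::tibble(qid = character(), sid = character(), bit = numeric()))
  }
  blast_scores(genome_a$protein[ids_a], genome_b$protein[ids_b])
}

#' Conserved (reciprocal-best, one-to-one) matches between two flank sets
#'
#' For each gene in `flanks_a` its highest-scoring non-self protein match in
#' `flanks_b` is found, and vice versa; a pair is conserved iff it is the
#' best hit in both directions with `E <= evalue_max`, and the final pairing
#' is one-to-one (greedy by score, ties to the smaller gene id).
#'
#' @param flanks_a,flanks_b `flank_set` objects with protein sequences
#'   available (`proteins_a/b` vectors).
#' @param proteins_a,proteins_b named protein vectors covering the flank
#'   genes.
#' @param evalue_max E-value threshold (default 1e-10).
#' @param scores optional precomputed blast score tibble (qid in a, sid in b);
#'   computed on the fly when `NULL`.
#' @return Tibble: gene_a, gene_b, bit, evalue.
#' @export
best_nonself_matches <- function(flanks_a, flanks_b, proteins_a, proteins_b,
                                 evalue_max = 1e-10, scores = NULL) {
  ids_a <- intersect(flanks_a$genes$gene_id, names(proteins_a))
  ids_b <- intersect(flanks_b$genes$gene_id, names(proteins_b))
  empty <- tibble::tibble(gene_a = character(), gene_b = character(),
                          bit = numeric(), evalue = numeric())
  if (!length(ids_a) || !length(ids_b)) return(empty)
  if (is.null(scores)) scores <- blast_scores(proteins_a[ids_a], proteins_b[ids_b])
  hits <- scores[scores$qid %in% ids_a & scores$sid %in% ids_b &
                   scores$qid != scores$sid, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  m_len <- nchar(proteins_a[hits$qid])
  n_res <- sum(nchar(proteins_b[ids_b]))
  hits$evalue <- unname(m_len) * n_res * 2^(-hits$bit)
  # best non-self match per direction (ties to smaller partner id)
  hits <- hits[order(-hits$bit, hits$qid, hits$sid), ]
  best_ab <- hits[!duplicated(hits$qid), ]
  best_ba <- hits[!duplicated(hits$sid), ]
  rbh <- dplyr::inner_join(
    best_ab[, c("qid", "sid", "bit", "evalue")],
    best_ba[, c("qid", "sid")],
    by = c("qid", "sid")
  )
  rbh <- rbh[rbh$evalue <= evalue_max, , drop = FALSE]
  if (nrow(rbh) == 0L) return(empty)
  # greedy one-to-one by score (reciprocal best is already near one-to-one)
  rbh <- rbh[order(-rbh$bit, pmin(rbh$qid, rbh$sid)), ]
  used_a <- character(0); used_b <- character(0); keep <- logical(nrow(rbh))
  for (i in seq_len(nrow(rbh))) {
    if (!(rbh$qid[i] %in% used_a) && !(rbh$sid[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, rbh$qid[i]); used_b <- c(used_b, rbh$sid[i])
    }
  }
  rbh <- rbh[keep, ]
  tibble::tibble(gene_a = rbh$qid, gene_b = rbh$sid,
                 bit = rbh$bit, evalue = rbh$evalue)
}

count_intervening <- function(genome, anchor_a, anchor_b) {
  ga <- genes_by_id(genome, anchor_a)
  gb <- genes_by_id(genome, anchor_b)
  if (ga$chrom != gb$chrom) return(NA_integer_)
  g <- genome$genes[genome$genes$chrom == ga$chrom, ]
  ra <- which(g$gene_id == anchor_a)
  rb <- which(g$gene_id == anchor_b)
  abs(ra - rb) - 1L
}

#' Classify the duplication mode of an anchor pair
#'
#' Tandem if the anchors sit on one chromosome with at most `max_intervening`
#' genes between them (tandem takes precedence); otherwise `large_scale` when
#' four or more conserved flanking pairs support the block, `relaxed` for two
#' or three, and `none` below that.
#'
#' @param genome_a,genome_b `fam_genome`s (the same object for intra-species
#'   calls).
#' @param anchor_a,anchor_b anchor gene ids (family members).
#' @param radius_bp,evalue_max,min_pairs,max_intervening thresholds; defaults
#'   100 kb, 1e-10, 4 pairs, and adjacency (1 intervening gene allowed).
#' @param scores optional precomputed blast scores for the genome pair.
#' @return One-row tibble of class rows: anchor_a, anchor_b, scope,
#'   chrom_a, chrom_b, n_intervening, n_pairs, classification, pairs (list
#'   column of the conserved pair tibble).
#' @export
classify_duplication <- function(genome_a, genome_b, anchor_a, anchor_b,
                                 radius_bp = 100000, evalue_max = 1e-10,
                                 min_pairs = 4, max_intervening = 1,
                                 scores = NULL) {
  intra <- identical(genome_a$species, genome_b$species)
  fa <- extract_flanks(genome_a, anchor_a, radius_bp)
  fb <- extract_flanks(genome_b, anchor_b, radius_bp)
  # both anchors are excluded from both flank windows before matching
  fa$genes <- fa$genes[!(fa$genes$gene_id %in% c(anchor_a, anchor_b)), ]
  fb$genes <- fb$genes[!(fb$genes$gene_id %in% c(anchor_a, anchor_b)), ]
  pairs <- best_nonself_matches(fa, fb, genome_a$protein, genome_b$protein,
                                evalue_max = evalue_max, scores = scores)
  n_pairs <- nrow(pairs)
  n_int <- if (intra) count_intervening(genome_a, anchor_a, anchor_b) else NA_integer_
  tandem <- intra && !is.na(n_int) && n_int <= max_intervening
  classification <- if (tandem) "tandem"
    else if (n_pairs >= min_pairs) "large_scale"
    else if (n_pairs >= 2) "relaxed"
    else "none"
  tibble::tibble(
    anchor_a = anchor_a, anchor_b = anchor_b,
    scope = if (intra) "intra" else "inter",
    species_a = genome_a$species, species_b = genome_b$species,
    chrom_a = fa$anchor$chrom, chrom_b = fb$anchor$chrom,
    n_intervening = n_int, n_pairs = n_pairs,
    classification = classification, pairs = list(pairs)
  )
}

#' Intra-species duplication scan over all member pairs
#'
#' Runs [classify_duplication()] for every unordered pair of family members
#' of one species, with the BLAST search memoised across anchors.
#'
#' @param genome a `fam_genome`.
#' @param members member tibble (rows of this species; `gene_id` column used).
#' @param ... thresholds passed to [classify_duplication()].
#' @param radius_bp flank radius in bp.
#' @return Tibble of classification rows (one per pair).
#' @export
intraspecies_duplications <- function(genome, members, radius_bp = 100000, ...) {
  ids <- members$gene_id[members$species == genome$species]
  if (length(ids) < 2) return(NULL)
  scores <- synteny_score_cache(genome, genome, ids, ids, radius_bp)
  combos <- utils::combn(sort(ids), 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    classify_duplication(genome, genome, combos[1, k], combos[2, k],
                         radius_bp = radius_bp, scores = scores, ...)
  })
}

#' Inter-species microsynteny between two genomes
#'
#' Evaluates every member-by-member anchor pair with the same flank/match
#' rules; blocks with at least `min_report_pairs` conserved pairs are
#' reported (classification per the usual thresholds) and members appearing
#' in no block are listed as non-syntenic.
#'
#' @param genome_a,genome_b distinct `fam_genome`s.
#' @param members member tibble covering both species.
#' @param radius_bp,evalue_max,min_pairs thresholds as in
#'   [classify_duplication()].
#' @param min_report_pairs minimum conserved pairs for a block to be reported.
#' @return List: `blocks` (tibble), `non_syntenic` (tibble member_id/species).
#' @export
interspecies_synteny <- function(genome_a, genome_b, members,
                                 radius_bp = 100000, evalue_max = 1e-10,
                                 min_pairs = 4, min_report_pairs = 2) {
  stopifnot(!identical(genome_a$species, genome_b$species))
  ids_a <- members$gene_id[members$species == genome_a$species]
  ids_b <- members$gene_id[members$species == genome_b$species]
  scores <- synteny_score_cache(genome_a, genome_b, ids_a, ids_b, radius_bp)
  rows <- purrr::map_dfr(ids_a, function(a) {
    purrr::map_dfr(ids_b, function(b) {
      classify_duplication(genome_a, genome_b, a, b, radius_bp = radius_bp,
                           evalue_max = evalue_max, min_pairs = min_pairs,
                           scores = scores)
    })
  })
  blocks <- rows[rows$n_pairs >= min_report_pairs, , drop = FALSE]
  in_block <- c(blocks$anchor_a, blocks$anchor_b)
  ns <- members[members$species %in% c(genome_a$species, genome_b$species) &
                  !(members$gene_id %in% in_block), c("member_id", "gene_id", "species")]
  list(blocks = blocks, non_syntenic = ns)
}
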