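# Shared fixtures. Simulations are cached per seed within the test session so
# several test files (and the acceptance blocks) reuse the same objects.

.fixture_cache <- new.env(parent = emptyenv())

# compact simulation used by unit tests (fast: ~2 s)
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(n_chroms = 3, genes_per_chrom = 30, n_family_genes = 6,
                   n_subfamilies = 3, n_tandem_events = 1,
                   n_segmental_events = 1, segment_size_genes = 8,
                   family_codons = 160, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_sim <- function(seed = 1L) {
  key <- paste0("tiny", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_genomes(tiny_config(seed))
  }
  .fixture_cache[[key]]
}

# full-size study-condition simulation (defaults), cached by seed
default_sim <- function(seed = 1L) {
  key <- paste0("def", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_genomes(sim_config(seed = seed))
  }
  .fixture_cache[[key]]
}

cached_pssms <- function() {
  if (is.null(.fixture_cache$pssms)) .fixture_cache$pssms <- default_pssms()
  .fixture_cache$pssms
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# member proteins keyed by member_id
member_proteins <- function(sim, members) {
  prot <- unlist(unname(lapply(sim$genomes, function(g) g$protein)))
  setNames(prot[members$gene_id], members$member_id)
}

# independent oracle: pathway-averaged Sd/Nd by explicit enumeration of all
# orderings of the differing positions (permutations), skipping pathways that
# cross a stop codon
oracle_path_counts <- function(c1, c2) {
  code <- setNames(as.character(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE))
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  pos <- which(ch1 != ch2)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  walk <- function(order) {
    cur <- ch1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- ch2[p]
      aa_cur <- code[paste0(cur, collapse = "")]
      aa_nxt <- code[paste0(nxt, collapse = "")]
      if (aa_nxt == "*" && !identical(nxt, ch2)) return(NULL)
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms(pos), walk))
  if (!length(res)) { # all pathways blocked: re-admit stop-crossing paths
    res <- lapply(perms(pos), function(o) {
      cur <- ch1; sd <- 0; nd <- 0
      for (p in o) {
        nxt <- cur; nxt[p] <- ch2[p]
        if (code[paste0(cur, collapse = "")] == code[paste0(nxt, collapse = "")]) {
          sd <- sd + 1
        } else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, res))
}

# exhaustive least-squares topology search oracle for small additive matrices
ls_best_topology <- function(D) {
  taxa <- rownames(D)
  n <- length(taxa)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  pair_idx <- t(utils::combn(n, 2))
  sse <- vapply(trees, function(tr) {
    ne <- nrow(tr$edge)
    A <- matrix(0, nrow(pair_idx), ne)
    for (e in seq_len(ne)) {
      tips <- unlist(phangorn::Descendants(tr, tr$edge[e, 2], "tips"))
      inside <- seq_len(n) %in% tips
      A[, e] <- xor(inside[pair_idx[, 1]], inside[pair_idx[, 2]])
    }
    dvec <- D[pair_idx]
    fit <- stats::lm.fit(A, dvec)
    sum(fit$residuals^2)
  }, numeric(1))
  trees[[which.min(sse)]]
}

rf_zero <- function(t1, t2) {
  isTRUE(all.equal(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0))
}
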