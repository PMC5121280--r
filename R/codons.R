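# Genetic-code machinery shared by the simulator (codon substitution process)
# and the Ka/Ks estimator (NG86 site and pathway counting). All tables are
# built lazily once per session and cached.

genetic_code <- function() {
  if (is.null(.famsynt_cache$code)) {
    code <- Biostrings::GENETIC_CODE # standard code, table 1
    .famsynt_cache$code <- setNames(as.character(code), names(code))
  }
  .famsynt_cache$code
}

all_codons <- function() names(genetic_code())

#' Sense codons of the standard genetic code
#' @return Character vector of the 61 non-stop codons.
#' @keywords internal
sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

#' Translate a coding sequence
#'
#' Standard genetic code; the final stop codon (if present) is trimmed.
#' Internal stops translate to `*`.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  stopifnot(is_string(cds))
  if (nchar(cds) %% 3 != 0) stopf("CDS length %d not divisible by 3", nchar(cds))
  codons <- codon_split(cds)
  aa <- unname(genetic_code()[codons])
  if (anyNA(aa)) stopf("non-ACGT codon at position %d", which(is.na(aa))[1])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste0(aa, collapse = "")
}

codon_split <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

# per-codon synonymous site count: at each position, the fraction of non-stop
# single-nucleotide alternatives that are synonymous. Mutations to stop codons
# are excluded from numerator and denominator, so s + n = 3 per codon.
codon_syn_sites <- function() {
  if (!is.null(.famsynt_cache$syn_sites)) return(.famsynt_cache$syn_sites)
  code <- genetic_code()
  nts <- c("A", "C", "G", "T")
  sense <- sense_codons()
  s <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    chars <- strsplit(cod, "")[[1]]
    tot <- 0
    for (pos in 1:3) {
      alts <- nts[nts != chars[pos]]
      neigh <- vapply(alts, function(nt) {
        x <- chars; x[pos] <- nt; paste0(x, collapse = "")
      }, character(1))
      keep <- code[neigh] != "*"
      if (!any(keep)) next
      tot <- tot + sum(code[neigh[keep]] == code[cod]) / sum(keep)
    }
    s[cod] <- tot
  }
  .famsynt_cache$syn_sites <- s
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons (NG86). All minimal single-step pathways are weighted equally;
# pathways passing through a stop codon are dropped and the weights
# renormalised. If every pathway is blocked, stop-crossing paths are
# re-admitted (does not occur between sense codons closer than 3 steps in
# practice, kept as a guard).
codon_path_counts <- function(c1, c2, allow_stop = FALSE) {
  code <- genetic_code()
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  diffs <- which(ch1 != ch2)
  if (length(diffs) == 0L) return(c(sd = 0, nd = 0, npaths = 1))
  acc_sd <- 0; acc_nd <- 0; npaths <- 0
  for (pos in diffs) {
    mid_ch <- ch1
    mid_ch[pos] <- ch2[pos]
    mid <- paste0(mid_ch, collapse = "")
    if (!allow_stop && unname(code[mid]) == "*" && mid != c2) next
    step_syn <- unname(code[c1] == code[mid])
    sub <- codon_path_counts(mid, c2, allow_stop)
    if (sub[["npaths"]] == 0) next
    acc_sd <- acc_sd + sub[["sd"]] + step_syn * sub[["npaths"]]
    acc_nd <- acc_nd + sub[["nd"]] + (!step_syn) * sub[["npaths"]]
    npaths <- npaths + sub[["npaths"]]
  }
  c(sd = acc_sd, nd = acc_nd, npaths = npaths)
}

# 61 x 61 matrices of pathway-averaged Sd and Nd, cached
codon_diff_tables <- function() {
  if (!is.null(.famsynt_cache$diff_tables)) return(.famsynt_cache$diff_tables)
  sense <- sense_codons()
  n <- length(sense)
  sd_m <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_m <- sd_m
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      pc <- codon_path_counts(sense[i], sense[j])
      if (pc[["npaths"]] == 0) pc <- codon_path_counts(sense[i], sense[j], allow_stop = TRUE)
      sd_m[i, j] <- sd_m[j, i] <- pc[["sd"]] / pc[["npaths"]]
      nd_m[i, j] <- nd_m[j, i] <- pc[["nd"]] / pc[["npaths"]]
    }
  }
  .famsynt_cache$diff_tables <- list(sd = sd_m, nd = nd_m)
  .famsynt_cache$diff_tables
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# neighbor table for the codon substitution process: for every sense codon,
# its single-nucleotide sense neighbors with transition and synonymy flags
codon_neighbors <- function() {
  if (!is.null(.famsynt_cache$neighbors)) return(.famsynt_cache$neighbors)
  code <- genetic_code()
  nts <- c("A", "C", "G", "T")
  out <- lapply(sense_codons(), function(cod) {
    chars <- strsplit(cod, "")[[1]]
    rows <- list()
    for (pos in 1:3) {
      for (nt in nts[nts != chars[pos]]) {
        x <- chars; x[pos] <- nt
        target <- paste0(x, collapse = "")
        if (code[target] == "*") next # substitutions to stops rejected
        rows[[length(rows) + 1L]] <- list(
          target = target,
          ts = is_transition(chars[pos], nt),
          syn = code[target] == code[cod]
        )
      }
    }
    list(
      target = vapply(rows, `[[`, character(1), "target"),
      ts = vapply(rows, `[[`, logical(1), "ts"),
      syn = vapply(rows, `[[`, logical(1), "syn")
    )
  })
  names(out) <- sense_codons()
  .famsynt_cache$neighbors <- out
  out
}

# total leaving rate per codon for given omega/kappa, plus normalisation so
# that time is measured in expected substitutions per codon under uniform
# codon frequencies
codon_rate_scale <- function(omega, kappa) {
  nb <- codon_neighbors()
  tot <- vapply(nb, function(x) sum(ifelse(x$ts, kappa, 1) * ifelse(x$syn, 1, omega)),
                numeric(1))
  mean(tot)
}

# per-state jump table for a given (omega, kappa): normalised leaving rate
# (substitutions per unit scaled time) and target probabilities; cached
codon_jump_table <- function(omega, kappa) {
  key <- sprintf("jump_%.10g_%.10g", omega, kappa)
  if (!is.null(.famsynt_cache[[key]])) return(.famsynt_cache[[key]])
  nb <- codon_neighbors()
  scl <- codon_rate_scale(omega, kappa)
  jt <- lapply(nb, function(x) {
    r <- ifelse(x$ts, kappa, 1) * ifelse(x$syn, 1, omega)
    tot <- sum(r)
    list(targets = x$target, probs = if (tot > 0) r / tot else r,
         lambda = tot / scl)
  })
  .famsynt_cache[[key]] <- jt
  jt
}

#' Evolve a coding sequence under a codon substitution model
#'
#' Continuous-time Markov codon process in the Goldman–Yang style: single
#' nucleotide changes only, rate multiplied by `kappa` for transitions and by
#' `omega` for nonsynonymous changes; substitutions to stop codons are
#' rejected. Codon frequencies are uniform and time is scaled so that `t` is
#' the expected number of substitutions per codon (computed at the scalar
#' `omega`, or at each site's own `omega` when a vector is given).
#'
#' @param cds coding sequence (no internal stops; trailing stop allowed and
#'   preserved untouched).
#' @param t branch length in expected substitutions per codon; `t = 0` returns
#'   the input unchanged.
#' @param omega dN/dS; scalar or per-codon vector.
#' @param kappa transition/transversion rate ratio.
#' @param seed optional integer; when supplied the RNG state is set (and
#'   restored afterwards), otherwise the current stream is used.
#' @return The evolved coding sequence (same length).
#' @export
evolve_cds <- function(cds, t, omega = 0.2, kappa = 2, seed = NULL) {
  stopifnot(is_string(cds), t >= 0, all(omega > 0) || all(omega == 0), kappa > 0)
  codons <- codon_split(cds)
  code <- genetic_code()
  trailing_stop <- length(codons) && code[codons[length(codons)]] == "*"
  body <- if (trailing_stop) codons[-length(codons)] else codons
  if (any(code[body] == "*")) {
    stopf("internal stop codon at codon %d", which(code[body] == "*")[1])
  }
  if (length(omega) == 1L) omega <- rep(omega, length(body))
  if (length(omega) != length(body)) stopf("omega must be scalar or one per codon")
  if (t == 0) return(cds)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  jts <- lapply(unique(omega), codon_jump_table, kappa = kappa)
  names(jts) <- as.character(unique(omega))
  out <- body
  # first waiting time drawn for all sites at once; most sites never jump
  lam0 <- vapply(seq_along(body), function(i) jts[[as.character(omega[i])]][[body[i]]]$lambda,
                 numeric(1))
  first_wait <- rexp(length(body), pmax(lam0, 1e-300))
  active <- which(first_wait <= t & lam0 > 0)
  for (i in active) {
    jt <- jts[[as.character(omega[i])]]
    state <- body[i]
    t_left <- t - first_wait[i]
    repeat {
      x <- jt[[state]]
      state <- x$targets[sample.int(length(x$targets), 1, prob = x$probs)]
      x <- jt[[state]]
      if (x$lambda <= 0) break
      wait <- rexp(1, x$lambda)
      if (wait > t_left) break
      t_left <- t_left - wait
    }
    out[i] <- state
  }
  paste0(c(out, if (trailing_stop) codons[length(codons)]), collapse = "")
}

#' Generate a random coding sequence
#'
#' Independent uniform draws from the 61 sense codons (so no internal stops).
#'
#' @param n_codons number of codons.
#' @return Nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  paste0(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# pick, for each amino acid, a fixed representative codon (used when a protein
# motif has to be back-translated into the simulated CDS)
codon_for_aa <- function() {
  if (!is.null(.famsynt_cache$aa2codon)) return(.famsynt_cache$aa2codon)
  code <- genetic_code()
  sense <- sense_codons()
  m <- vapply(AA_ALPHABET, function(a) sense[code[sense] == a][1], character(1))
  .famsynt_cache$aa2codon <- m
  m
}
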