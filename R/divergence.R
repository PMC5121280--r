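# Gu-style functional divergence between subfamily clusters.
# Type I: two-state Poisson-gamma mixture ML (shared vs cluster-independent
# site rates), with per-site posteriors, SE from observed Fisher information
# and a chi-squared(1) LRT against theta = 0.
# Type II: moments estimator over a radical/conservative amino-acid property
# partition -- the excess of radical between-cluster fixed differences over
# the within-cluster baseline.

# amino-acid property classes (charge/polarity); a change across classes is
# radical, within a class conservative
AA_PROPERTY_CLASS <- c(
  K = "basic", R = "basic", H = "basic",
  D = "acidic", E = "acidic",
  S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
  Y = "polar", W = "polar", G = "polar",
  A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
  M = "nonpolar", F = "nonpolar", P = "nonpolar"
)

#' Per-site substitution counts within two clusters
#'
#' For every alignment column, the minimum number of substitutions within
#' each cluster by Fitch parsimony on the cluster's own NJ subtree (built
#' from Poisson-corrected distances). Columns where gaps are the majority
#' state in either cluster are excluded; original column indices are kept.
#'
#' @param alignment named character vector of aligned proteins.
#' @param cluster1,cluster2 disjoint taxon sets, each of size >= 4.
#' @return Tibble: site (original column), x1, x2.
#' @export
site_substitution_counts <- function(alignment, cluster1, cluster2) {
  if (length(intersect(cluster1, cluster2))) stopf("clusters overlap")
  for (cl in list(cluster1, cluster2)) {
    if (length(cl) < 4) {
      stopf("cluster of size %d: functional divergence needs >= 4 sequences per cluster",
            length(cl))
    }
  }
  stopifnot(all(c(cluster1, cluster2) %in% names(alignment)))
  m <- seq_to_matrix(alignment)
  counts <- lapply(list(cluster1, cluster2), function(cl) {
    sub <- m[cl, , drop = FALSE]
    tree <- build_nj(pairwise_distance(sub)$d)
    fitch_counts(tree, sub)
  })
  gaps_major <- function(cl) {
    colMeans(m[cl, , drop = FALSE] == "-" | m[cl, , drop = FALSE] == ".") > 0.5
  }
  keep <- !(gaps_major(cluster1) | gaps_major(cluster2))
  tibble::tibble(site = which(keep),
                 x1 = counts[[1]][keep], x2 = counts[[2]][keep])
}

# vectorised Fitch parsimony over all columns of a character matrix
# (rows = taxa matching tree tip labels); gaps treated as missing (full
# state set). Multifurcations (the unrooted NJ root) are folded in child by
# child, which is the standard generalisation of the binary Fitch count.
fitch_counts <- function(tree, m) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- ncol(m)
  sets <- array(FALSE, dim = c(nnode, L, 20))
  for (i in seq_len(ntip)) {
    idx <- match(m[tree$tip.label[i], ], AA_ALPHABET)
    known <- which(!is.na(idx))
    if (length(known)) {
      sets[cbind(i, known, idx[known])] <- TRUE
    }
    unknown <- which(is.na(idx))
    if (length(unknown)) sets[i, unknown, ] <- TRUE
  }
  counts <- numeric(L)
  parents <- tree$edge[, 1]
  children <- tree$edge[, 2]
  done <- rep(FALSE, nnode)
  done[seq_len(ntip)] <- TRUE
  remaining <- sort(unique(parents))
  while (length(remaining)) {
    progressed <- FALSE
    for (nd in remaining) {
      kids <- children[parents == nd]
      if (!all(done[kids])) next
      cur <- sets[kids[1], , , drop = TRUE]
      if (is.null(dim(cur))) cur <- matrix(cur, nrow = L)
      for (k in kids[-1]) {
        nxt <- sets[k, , , drop = TRUE]
        if (is.null(dim(nxt))) nxt <- matrix(nxt, nrow = L)
        both <- cur & nxt
        miss <- rowSums(both) == 0
        counts <- counts + miss
        cur[miss, ] <- cur[miss, , drop = FALSE] | nxt[miss, , drop = FALSE]
        cur[!miss, ] <- both[!miss, , drop = FALSE]
      }
      sets[nd, , ] <- cur
      done[nd] <- TRUE
      progressed <- TRUE
    }
    remaining <- remaining[!done[remaining]]
    if (length(remaining) && !progressed) stopf("tree traversal failed")
  }
  counts
}

# log-likelihood of the two-state Poisson-gamma mixture, vectorised over
# sites. theta in [0,1), alpha > 0, d1, d2 > 0; gamma rates have mean 1.
theta1_loglik <- function(par, x1, x2) {
  theta <- par[1]; alpha <- par[2]; d1 <- par[3]; d2 <- par[4]
  lp0 <- lgamma(x1 + x2 + alpha) - lgamma(alpha) - lfactorial(x1) -
    lfactorial(x2) + x1 * log(d1) + x2 * log(d2) + alpha * log(alpha) -
    (x1 + x2 + alpha) * log(d1 + d2 + alpha)
  nb <- function(x, d) {
    lgamma(x + alpha) - lgamma(alpha) - lfactorial(x) + x * log(d) +
      alpha * log(alpha) - (x + alpha) * log(d + alpha)
  }
  lp1 <- nb(x1, d1) + nb(x2, d2)
  mx <- pmax(lp0, lp1)
  ll <- sum(mx + log((1 - theta) * exp(lp0 - mx) + theta * exp(lp1 - mx)))
  list(ll = ll, lp0 = lp0, lp1 = lp1)
}

#' Type-I functional divergence (rate-shift mixture ML)
#'
#' Fits the two-state mixture: with probability `1 - theta` a site's
#' substitution rate is shared between the clusters (F0), with probability
#' `theta` the rates are independent (F1). Rates are gamma-distributed
#' (mean 1), counts Poisson given rate times a per-cluster tree-length
#' scalar; theta, the gamma shape and the two scalars are estimated by
#' bounded quasi-Newton ML with multiple starts. The SE comes from the
#' observed Fisher information, the LRT compares against theta = 0 with a
#' chi-squared(1) p-value, and per-site posteriors `qk = P(F1 | x1, x2)`
#' flag critical sites above `qk_threshold`.
#'
#' @param counts tibble from [site_substitution_counts()] (or
#'   [simulate_site_counts()]): columns site, x1, x2; >= 50 usable sites.
#' @param qk_threshold posterior cutoff for critical sites (default 0.9, the conventional cutoff).
#' @param starts theta multi-start grid.
#' @param reltol convergence tolerance on the log-likelihood.
#' @return Object of class `divergence_fit` (type "I") with theta, se, lrt,
#'   p_value, qk, critical_sites, loglik, at_boundary flag.
#' @export
estimate_theta1 <- function(counts, qk_threshold = 0.9,
                            starts = c(0.05, 0.25, 0.45, 0.65, 0.85),
                            reltol = 1e-8) {
  x1 <- counts$x1; x2 <- counts$x2
  sites <- counts$site %||% seq_along(x1)
  if (length(x1) < 50) stopf("need >= 50 usable sites, got %d", length(x1))
  lower <- c(0, 1e-3, 1e-4, 1e-4)
  upper <- c(1 - 1e-6, 1e3, 1e3, 1e3)
  obj <- function(par) -theta1_loglik(par, x1, x2)$ll
  run <- function(par0, fix_theta0 = FALSE) {
    if (fix_theta0) {
      o <- stats::optim(par0[-1], function(p) obj(c(0, p)), method = "L-BFGS-B",
                        lower = lower[-1], upper = upper[-1],
                        control = list(factr = reltol / .Machine$double.eps))
      list(par = c(0, o$par), value = o$value, conv = o$convergence)
    } else {
      o <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                        upper = upper,
                        control = list(factr = reltol / .Machine$double.eps))
      list(par = o$par, value = o$value, conv = o$convergence)
    }
  }
  d0 <- c(mean(x1), mean(x2))
  fits <- lapply(starts, function(th) {
    tryCatch(run(c(th, 1, pmax(d0, 0.05))), error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits) || all(vapply(fits, function(f) f$conv != 0, logical(1)))) {
    ok <- fits[vapply(fits, function(f) is.finite(f$value), logical(1))]
    if (!length(ok)) stopf("theta estimation failed to converge from all starts")
    fits <- ok
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  null <- run(c(0, 1, pmax(d0, 0.05)), fix_theta0 = TRUE)
  ll1 <- -best$value
  ll0 <- -null$value
  if (ll0 > ll1) { # theta = 0 is the MLE (boundary)
    best <- null
    ll1 <- ll0
  }
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  theta_hat <- best$par[1]
  se <- tryCatch({
    H <- stats::optimHess(best$par, obj)
    v <- solve(H)[1, 1]
    if (is.finite(v) && v > 0) sqrt(v) else NA_real_
  }, error = function(e) NA_real_)
  parts <- theta1_loglik(best$par, x1, x2)
  qk <- theta_hat * exp(parts$lp1) /
    ((1 - theta_hat) * exp(parts$lp0) + theta_hat * exp(parts$lp1))
  qk[!is.finite(qk)] <- 0
  structure(
    list(type = "I", theta = theta_hat, se = se, lrt = lrt, p_value = p,
         alpha = best$par[2], d1 = best$par[3], d2 = best$par[4],
         loglik = ll1, loglik_null = ll0,
         qk = tibble::tibble(site = sites, qk = qk),
         qk_threshold = qk_threshold,
         critical_sites = sites[qk > qk_threshold],
         at_boundary = theta_hat <= lower[1] + 1e-9,
         n_sites = length(x1)),
    class = "divergence_fit"
  )
}

#' Type-II functional divergence (radical fixed-difference moments)
#'
#' Sites are classified by cluster consensus: a between-cluster fixed
#' difference is a site monomorphic within each cluster with different
#' residues, radical when the residues fall in different property classes
#' (charge/polarity partition). `theta2` is the excess of radical changes
#' among fixed differences over the within-cluster baseline,
#' `(rF - rW) / (1 - rW)`, with a delta-method SE; negative estimates are
#' reported as-is. Per-site posteriors assign `qk` to radical fixed
#' differences via Bayes' rule against the baseline radical rate.
#'
#' @param alignment named character vector of aligned proteins.
#' @param cluster1,cluster2 disjoint taxon sets (>= 4 sequences each).
#' @param qk_threshold posterior cutoff for critical sites.
#' @return Object of class `divergence_fit` (type "II") with theta, se, qk,
#'   critical_sites and the component rates.
#' @export
estimate_theta2 <- function(alignment, cluster1, cluster2, qk_threshold = 0.9) {
  if (length(intersect(cluster1, cluster2))) stopf("clusters overlap")
  for (cl in list(cluster1, cluster2)) {
    if (length(cl) < 4) {
      stopf("cluster of size %d: functional divergence needs >= 4 sequences per cluster",
            length(cl))
    }
  }
  m <- seq_to_matrix(alignment)
  L <- ncol(m)
  res1 <- m[cluster1, , drop = FALSE]
  res2 <- m[cluster2, , drop = FALSE]
  col_states <- function(sub, j) unique(sub[, j][sub[, j] %in% AA_ALPHABET])
  is_radical <- function(a, b) AA_PROPERTY_CLASS[[a]] != AA_PROPERTY_CLASS[[b]]
  fixed_diff <- logical(L); radical <- logical(L)
  within_events <- 0L; within_radical <- 0L
  for (j in seq_len(L)) {
    s1 <- col_states(res1, j); s2 <- col_states(res2, j)
    if (!length(s1) || !length(s2)) next
    if (length(s1) == 1 && length(s2) == 1) {
      if (s1 != s2) {
        fixed_diff[j] <- TRUE
        radical[j] <- is_radical(s1, s2)
      }
    }
    for (s in list(s1, s2)) {
      if (length(s) >= 2) {
        # one within-cluster change event per polymorphic site: the two most
        # frequent residues
        within_events <- within_events + 1L
        within_radical <- within_radical + is_radical(s[1], s[2])
      }
    }
  }
  n_f <- sum(fixed_diff)
  if (n_f == 0) {
    warnf("no between-cluster fixed differences; theta2 = 0")
    return(structure(
      list(type = "II", theta = 0, se = NA_real_, lrt = NA_real_,
           p_value = NA_real_, r_fixed = NA_real_, r_within = NA_real_,
           n_fixed = 0L, n_within = within_events,
           qk = tibble::tibble(site = seq_len(L), qk = 0),
           qk_threshold = qk_threshold, critical_sites = integer(0),
           at_boundary = TRUE, n_sites = L),
      class = "divergence_fit"))
  }
  r_f <- mean(radical[fixed_diff])
  r_w <- if (within_events > 0) within_radical / within_events else 0.25
  # guard the degenerate all-radical baseline
  r_w <- min(max(r_w, 1e-6), 1 - 1e-6)
  theta <- (r_f - r_w) / (1 - r_w)
  var_rf <- r_f * (1 - r_f) / n_f
  var_rw <- r_w * (1 - r_w) / max(within_events, 1)
  se <- sqrt(var_rf / (1 - r_w)^2 + var_rw * ((r_f - 1) / (1 - r_w)^2)^2)
  pi_div <- max(theta, 0)
  qk <- numeric(L)
  denom <- pi_div + (1 - pi_div) * r_w
  qk[fixed_diff & radical] <- if (denom > 0) pi_div / denom else 0
  structure(
    list(type = "II", theta = theta, se = se, lrt = NA_real_,
         p_value = NA_real_, r_fixed = r_f, r_within = r_w,
         n_fixed = n_f, n_within = within_events,
         qk = tibble::tibble(site = seq_len(L), qk = qk),
         qk_threshold = qk_threshold,
         critical_sites = which(qk > qk_threshold),
         at_boundary = theta <= 0, n_sites = L),
    class = "divergence_fit"
  )
}

#' @export
print.divergence_fit <- function(x, ...) {
  cat(sprintf("<divergence_fit> type %s: theta = %.6f (SE %.6f)%s, %d critical site(s)\n",
              x$type, x$theta, x$se,
              if (x$type == "I") sprintf(", LRT = %.4f (p = %.3g)", x$lrt, x$p_value) else "",
              length(x$critical_sites)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy divergence_fit
#' @export
tidy.divergence_fit <- function(x, ...) x$qk

#' @method glance divergence_fit
#' @export
glance.divergence_fit <- function(x, ...) {
  tibble::tibble(type = x$type, theta = x$theta, se = x$se, lrt = x$lrt,
                 p_value = x$p_value, n_sites = x$n_sites,
                 n_critical = length(x$critical_sites),
                 at_boundary = x$at_boundary)
}

#' All-pairs functional divergence report
#'
#' Runs type-I and type-II estimation for every unordered pair of
#' subfamilies with at least `min_cluster` members; smaller subfamilies are
#' skipped with a reason (the classic DIVERGE rule of four sequences).
#'
#' @param alignment named character vector of aligned member proteins.
#' @param subfamilies tibble with columns member_id, subfamily.
#' @param qk_threshold posterior cutoff for critical sites.
#' @param min_cluster minimum cluster size.
#' @return List: `results` tibble (pair, type, theta, se, lrt, p_value,
#'   n_critical, critical_sites list column), `fits` (named list of
#'   `divergence_fit`), `skipped` tibble with reasons.
#' @export
divergence_report <- function(alignment, subfamilies, qk_threshold = 0.9,
                              min_cluster = 4) {
  groups <- split(subfamilies$member_id, subfamilies$subfamily)
  sizes <- lengths(groups)
  eligible <- names(groups)[sizes >= min_cluster]
  skipped <- tibble::tibble(
    subfamily = names(groups)[sizes < min_cluster],
    reason = sprintf("only %d member(s); need >= %d", sizes[sizes < min_cluster],
                     min_cluster))
  if (length(eligible) < 2) {
    return(list(results = tibble::tibble(), fits = list(), skipped = skipped))
  }
  combos <- utils::combn(sort(eligible), 2)
  fits <- list(); rows <- list()
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    pair <- sprintf("%s vs %s", a, b)
    counts <- site_substitution_counts(alignment, groups[[a]], groups[[b]])
    f1 <- estimate_theta1(counts, qk_threshold = qk_threshold)
    f2 <- estimate_theta2(alignment, groups[[a]], groups[[b]],
                          qk_threshold = qk_threshold)
    fits[[paste0(pair, " [I]")]] <- f1
    fits[[paste0(pair, " [II]")]] <- f2
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      dplyr::mutate(glance(f1), pair = pair,
                    critical_sites = list(f1$critical_sites), .before = 1),
      dplyr::mutate(glance(f2), pair = pair,
                    critical_sites = list(f2$critical_sites), .before = 1)
    )
  }
  list(results = dplyr::bind_rows(rows), fits = fits, skipped = skipped)
}
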