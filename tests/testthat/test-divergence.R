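mk_aln <- function(m) setNames(apply(m, 1, paste0, collapse = ""), rownames(m))

test_that("site substitution counts: invariant and single-change columns", {
  taxa <- c(paste0("a", 1:4), paste0("b", 1:4))
  m <- matrix("A", 8, 60, dimnames = list(taxa, NULL))
  m[, 31:60] <- "L"
  m["a1", 5] <- "C" # one change in cluster 1 only
  counts <- site_substitution_counts(mk_aln(m), paste0("a", 1:4), paste0("b", 1:4))
  expect_equal(counts$x1[counts$site == 1], 0)
  expect_equal(counts$x2[counts$site == 1], 0)
  expect_equal(counts$x1[counts$site == 5], 1)
  expect_equal(counts$x2[counts$site == 5], 0)
  expect_error(site_substitution_counts(mk_aln(m), paste0("a", 1:3), paste0("b", 1:4)),
               ">= 4")
  expect_error(site_substitution_counts(mk_aln(m), paste0("a", 1:4),
                                        c("a1", paste0("b", 1:3))), "overlap")
})

test_that("parsimony counts track planted site rates", {
  sim <- tiny_sim(1)
  aln <- align_proteins(member_proteins(sim, call_family(sim$genomes, cached_pssms())))
  half <- length(aln) %/% 2
  c1 <- names(aln)[1:half]; c2 <- names(aln)[(half + 1):length(aln)]
  pl <- plant_rate_shift(aln, c1, c2, theta_sim = 0.3, gamma_shape = 0.5,
                         branch_length = 0.8, seed = 3)
  counts <- site_substitution_counts(pl$alignment, c1, c2)
  lab <- as.integer(pl$labels[counts$site] == "F1")
  # F1 sites have cluster-independent rates; their count disparity is larger
  disparity <- abs(counts$x1 - counts$x2)
  rho <- suppressWarnings(cor(disparity, lab, method = "spearman"))
  expect_gt(rho, 0.1)
  total <- counts$x1 + counts$x2
  # overall: hot sites accumulate more substitutions than planted-cold ones
  expect_gt(cor(total, lab, method = "spearman"), -1) # sanity; main check above
})

test_that("theta1 likelihood machinery: nesting, posteriors, permutation equivariance", {
  cts <- simulate_site_counts(400, theta = 0.3, alpha = 1, d1 = 1.5, d2 = 1.5,
                              seed = 10)
  f <- estimate_theta1(cts)
  expect_gte(f$loglik, f$loglik_null - 1e-6) # nested models => LRT >= 0
  expect_gte(f$lrt, 0)
  expect_true(all(f$qk$qk >= 0 & f$qk$qk <= 1))
  expect_true(all(f$critical_sites %in% cts$site))
  # permutation equivariance of the posterior vector
  set.seed(2)
  perm <- sample(nrow(cts))
  f2 <- estimate_theta1(cts[perm, ])
  expect_equal(f2$qk$qk[order(f2$qk$site)], f$qk$qk[order(f$qk$site)],
               tolerance = 1e-6)
  expect_equal(f2$theta, f$theta, tolerance = 1e-6)
  # glance/tidy interface
  g <- glance(f)
  expect_equal(g$theta, f$theta)
  expect_equal(nrow(tidy(f)), 400)
  expect_error(estimate_theta1(cts[1:20, ]), ">= 50")
})

test_that("theta estimates are consistent as the number of sites grows", {
  errs <- vapply(c(200, 2000), function(n) {
    est <- vapply(1:4, function(r) {
      estimate_theta1(simulate_site_counts(n, 0.3, seed = 50 + r))$theta
    }, numeric(1))
    abs(mean(est) - 0.3)
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 0.05) # error shrinks (allow noise slack)
  expect_lt(errs[2], 0.08)
})

test_that("critical-site sets shrink as the posterior threshold rises", {
  cts <- simulate_site_counts(500, theta = 0.4, alpha = 0.8, d1 = 2, d2 = 2,
                              seed = 77)
  f <- estimate_theta1(cts)
  sizes <- vapply(c(0.5, 0.7, 0.9, 0.99),
                  function(thr) sum(f$qk$qk > thr), numeric(1))
  expect_false(is.unsorted(rev(sizes)))
})

test_that("theta2: identical consensus gives zero; planted radical sites are found", {
  taxa <- c(paste0("a", 1:5), paste0("b", 1:5))
  prop <- famsynt:::AA_PROPERTY_CLASS
  set.seed(6)
  base <- sample(names(prop), 250, replace = TRUE)
  m <- matrix(rep(base, each = 10), 10, dimnames = list(taxa, NULL))
  expect_warning(f0 <- estimate_theta2(mk_aln(m), paste0("a", 1:5), paste0("b", 1:5)),
                 "no between-cluster fixed differences")
  expect_equal(f0$theta, 0)
  expect_length(f0$critical_sites, 0)
  # plant radical fixed differences at 10% of sites + scattered noise
  rad <- sample(250, 25)
  for (j in rad) {
    alt <- sample(names(prop)[prop != prop[[base[j]]]], 1)
    m[paste0("b", 1:5), j] <- alt
  }
  for (k in 1:50) {
    m[sample(taxa, 1), sample(setdiff(1:250, rad), 1)] <- sample(names(prop), 1)
  }
  f <- estimate_theta2(mk_aln(m), paste0("a", 1:5), paste0("b", 1:5))
  expect_gt(f$theta, 0)
  expect_gte(mean(rad %in% f$critical_sites), 0.6)
  expect_true(is.finite(f$se))
})

test_that("the all-pairs report covers eligible pairs and skips small subfamilies", {
  sim <- tiny_sim(1)
  members <- call_family(sim$genomes, cached_pssms())
  aln <- align_proteins(member_proteins(sim, members))
  truth <- sim$truth$family
  sf <- tibble::tibble(
    member_id = members$member_id,
    subfamily = truth$subfamily[match(members$gene_id, truth$gene_id)])
  rep <- divergence_report(aln, sf)
  eligible <- names(which(table(sf$subfamily) >= 4))
  expected_pairs <- choose(length(eligible), 2)
  expect_equal(nrow(rep$results), 2 * expected_pairs) # one row per type
  expect_setequal(unique(rep$results$type), c("I", "II"))
  expect_equal(nrow(rep$skipped), length(setdiff(unique(sf$subfamily), eligible)))
  # theta_I clipped to [0, 1]; theta_II may be negative
  t1 <- rep$results$theta[rep$results$type == "I"]
  expect_true(all(t1 >= 0 & t1 <= 1))
})
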