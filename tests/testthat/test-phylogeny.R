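test_that("Poisson-corrected distances: closed forms and pairwise deletion", {
  # p = 0.1 -> d = -ln(0.9)
  d <- pairwise_distance(c(x = strrep("A", 10), y = paste0(strrep("A", 9), "C")))
  expect_equal(d$p[1, 2], 0.1)
  expect_equal(d$d[1, 2], 0.105360516, tolerance = 1e-8)
  # identical sequences
  d0 <- pairwise_distance(c(x = "MKLV", y = "MKLV"))
  expect_equal(d0$p[1, 2], 0)
  expect_equal(d0$d[1, 2], 0)
  # hand-counted pairwise deletion: compared sites {1,4}, zero mismatches
  dh <- pairwise_distance(c(a = "AC-A", b = "A-GA"))
  expect_equal(dh$p[1, 2], 0)
  # saturated pair flagged, error in strict mode
  ds <- pairwise_distance(c(a = "AAAA", b = "CCCC"))
  expect_true(is.na(ds$d[1, 2]))
  expect_error(pairwise_distance(c(a = "A-", b = "-A"), strict = TRUE),
               "no comparable sites")
})

test_that("distances are permutation-equivariant", {
  sim <- tiny_sim(1)
  prot <- head(sim$genomes$alpha$protein, 6)
  aln <- align_proteins(prot)
  d1 <- pairwise_distance(aln)
  set.seed(3)
  perm <- sample(length(aln))
  d2 <- pairwise_distance(aln[perm])
  expect_equal(d2$d[names(aln), names(aln)], d1$d)
})

test_that("NJ is exact on additive matrices (exhaustive LS oracle)", {
  set.seed(17)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
    D <- cophenetic(tr)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    mine <- build_nj(D)
    expect_true(rf_zero(mine, tr), label = sprintf("rep %d vs truth", i))
    expect_true(rf_zero(mine, ls_best_topology(D)),
                label = sprintf("rep %d vs LS oracle", i))
    # branch-length recovery on the additive input
    expect_equal(sum(mine$edge.length), sum(tr$edge.length), tolerance = 1e-6)
  }
})

test_that("NJ closed forms and deterministic tie-breaking", {
  # three taxa: unique unrooted topology, three-point branch lengths
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_nj(D)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))
  # ultrametric ((A,B),(C,D)): A and B join first
  D4 <- matrix(0.8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D4[cbind(c("A", "B"), c("B", "A"))] <- 0.2
  D4[cbind(c("C", "D"), c("D", "C"))] <- 0.2
  diag(D4) <- 0
  tr4 <- build_nj(D4)
  bp <- famsynt:::tree_bipartitions(tr4)
  expect_equal(bp$key, "C|D") # the {A,B} | {C,D} split
  # missing distances are an error naming the pair
  Dna <- D4; Dna["A", "C"] <- Dna["C", "A"] <- NA
  expect_error(build_nj(Dna), "A and C")
})

test_that("bootstrap supports behave: determinism, identical sequences, clean splits", {
  # identical sequences: a resolved star; every bipartition at full support
  aln_id <- setNames(rep("MKLVHG", 5), paste0("t", 1:5))
  b <- bootstrap_nj(aln_id, n_reps = 50, seed = 1)
  if (nrow(b$supports)) expect_true(all(b$supports$support == 50))
  # two clearly separated clades get near-maximal support
  sim <- tiny_sim(1)
  members <- call_family(sim$genomes, cached_pssms())
  prot <- member_proteins(sim, members)
  aln <- align_proteins(prot)
  b1 <- bootstrap_nj(aln, n_reps = 100, seed = 9)
  b2 <- bootstrap_nj(aln, n_reps = 100, seed = 9)
  expect_identical(b1$supports$support, b2$supports$support)
  expect_true(all(b1$supports$support <= 100))
  # deep subfamily splits are strongly supported
  truth <- sim$truth$family
  for (sf in unique(truth$subfamily)) {
    tips <- members$member_id[members$gene_id %in% truth$gene_id[truth$subfamily == sf]]
    key <- famsynt:::bipartition_key(tips, b1$tree$tip.label)
    row <- b1$supports[b1$supports$key == key, ]
    if (nrow(row)) expect_gte(row$support, 90)
  }
})

test_that("subfamily assignment cuts supported branches and orders labels by size", {
  sim <- tiny_sim(1)
  members <- call_family(sim$genomes, cached_pssms())
  aln <- align_proteins(member_proteins(sim, members))
  ph <- bootstrap_nj(aln, n_reps = 100, seed = 2)
  sf <- assign_subfamilies(ph, k = 3, min_support = 50)
  expect_setequal(sf$member_id, names(aln))
  expect_equal(length(unique(sf$subfamily)), 3)
  sizes <- table(sf$subfamily)[as.character(utils::as.roman(1:3))]
  expect_true(all(diff(as.integer(sizes)) <= 0)) # I is the largest
  # partition matches planted subfamilies
  truth <- sim$truth$family
  mm <- dplyr::inner_join(dplyr::inner_join(sf, members, by = "member_id"),
                          truth[, c("gene_id", "subfamily")],
                          by = "gene_id", suffix = c("_called", "_true"))
  expect_equal(adjusted_rand_index(mm$subfamily_called, mm$subfamily_true), 1)
  # k = 1: everything in one subfamily
  sf1 <- assign_subfamilies(ph, k = 1)
  expect_true(all(sf1$subfamily == "I"))
  # impossible support threshold is a helpful error
  expect_error(assign_subfamilies(ph, k = 3, min_support = 101), "min_support")
  # k = 2 on a 4-leaf tree with one long supported internal branch: cherries
  tr <- ape::read.tree(text = "((A:0.1,B:0.1)100:1.0,(C:0.1,D:0.1):0.0);")
  ph4 <- structure(list(tree = tr, n_reps = 100L), class = "fam_phylo")
  sf2 <- assign_subfamilies(ph4, k = 2, min_support = 50)
  grp <- split(sf2$member_id, sf2$subfamily)
  expect_true(setequal(grp[[1]], c("A", "B")) || setequal(grp[[1]], c("C", "D")))
})

test_that("bootstrap support multiset is stable under column shuffling", {
  sim <- tiny_sim(1)
  aln <- align_proteins(member_proteins(sim, call_family(sim$genomes, cached_pssms())))
  m <- famsynt:::seq_to_matrix(aln)
  set.seed(4)
  shuf <- m[, sample(ncol(m))]
  b1 <- bootstrap_nj(m, n_reps = 100, seed = 5)
  b2 <- bootstrap_nj(shuf, n_reps = 100, seed = 5)
  # same tree (distances identical), supports equal up to resampling noise
  expect_identical(sort(b1$supports$key), sort(b2$supports$key))
  s1 <- b1$supports$support[order(b1$supports$key)]
  s2 <- b2$supports$support[order(b2$supports$key)]
  expect_true(all(abs(s1 - s2) <= 25))
})
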