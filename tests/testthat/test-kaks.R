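codon_aln <- function(a, b) structure(list(a = a, b = b), class = "codon_alignment")

test_that("NG86 single-codon site and difference counting", {
  # TTT vs TTC: only the third-position change is synonymous
  res <- ng86(codon_aln("TTT", "TTC"))
  expect_equal(res$Sd, 1)
  expect_equal(res$Nd, 0)
  expect_equal(res$S, 1 / 3)
  expect_equal(res$N, 8 / 3)
  syn <- famsynt:::codon_syn_sites()
  expect_equal(unname(syn["TTT"]), 1 / 3)
  # identical pair: zero rates, undefined ratio flag
  res0 <- ng86(codon_aln("ATGAAA", "ATGAAA"))
  expect_equal(res0$Sd + res0$Nd, 0)
  expect_equal(res0$Ka, 0)
  expect_equal(res0$Ks, 0)
  expect_true(is.na(res0$ka_ks))
})

test_that("pathway averaging matches exhaustive enumeration on random codon pairs", {
  tabs <- famsynt:::codon_diff_tables()
  sense <- famsynt:::sense_codons()
  set.seed(12)
  for (i in 1:200) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    oracle <- oracle_path_counts(c1, c2)
    expect_equal(tabs$sd[c1, c2], unname(oracle["sd"]), tolerance = 1e-12,
                 label = paste(c1, c2))
    expect_equal(tabs$nd[c1, c2], unname(oracle["nd"]), tolerance = 1e-12,
                 label = paste(c1, c2))
  }
})

test_that("site counts conserve S + N = 3 x codons and ng86 is symmetric", {
  set.seed(21)
  for (i in 1:10) {
    a <- random_cds(60)
    b <- evolve_cds(a, 0.4, omega = 0.5, kappa = 2)
    r1 <- ng86(codon_aln(a, b))
    r2 <- ng86(codon_aln(b, a))
    expect_equal(r1$S + r1$N, 3 * r1$n_codons, tolerance = 1e-6)
    expect_equal(r1[, c("S", "N", "Sd", "Nd", "Ka", "Ks")],
                 r2[, c("S", "N", "Sd", "Nd", "Ka", "Ks")])
  }
})

test_that("backtranslation preserves codons under protein gaps and round-trips", {
  bt <- backtranslate("M-KL", "MAKL", "ATGAAACTT", "ATGGCTAAGCTG")
  expect_equal(bt$a, "ATG---AAACTT")
  expect_equal(bt$b, "ATGGCTAAGCTG")
  expect_equal(gsub("-", "", bt$a), "ATGAAACTT")
  # gapless alignment: CDS pass through unchanged (stop trimmed)
  bt2 <- backtranslate("MK", "MR", "ATGAAATGA", "ATGAGA")
  expect_equal(bt2$a, "ATGAAA")
  expect_equal(bt2$b, "ATGAGA")
  # simulator pair round-trips exactly
  sim <- tiny_sim(1)
  ev <- sim$truth$events[1, ]
  g <- sim$genomes[[ev$species]]
  pa <- g$protein[[ev$gene_a]]; pb <- g$protein[[ev$gene_b]]
  aln <- align_proteins(c(a = pa, b = pb))
  bt3 <- backtranslate(aln[["a"]], aln[["b"]], g$cds[[ev$gene_a]], g$cds[[ev$gene_b]])
  expect_equal(gsub("-", "", bt3$a), famsynt:::trim_stop(g$cds[[ev$gene_a]]))
  # translation mismatch is reported with the first discordant residue
  expect_error(backtranslate("MK", "MK", "ATGAAA", "ATGCGT"), "residue 2")
})

test_that("sliding windows follow the count formula and flag undefined ratios", {
  set.seed(33)
  a <- random_cds(100)
  b <- evolve_cds(a, 0.3, omega = 0.3, kappa = 2)
  ws <- sliding_window_kaks(codon_aln(a, b), window = 150, step = 9)
  expect_equal(nrow(ws), floor((300 - 150) / 9) + 1) # 17
  expect_equal(ws$win_start, as.integer(seq(1, 151, by = 9)))
  # aligned length equal to the window: exactly one window
  a50 <- random_cds(50)
  expect_equal(nrow(sliding_window_kaks(codon_aln(a50, a50), 150, 9)), 1)
  # identical window content: NA ratio, never a fabricated number
  expect_true(all(is.na(sliding_window_kaks(codon_aln(a50, a50), 150, 9)$ka_ks)))
  # shorter than the window: empty series with a warning
  expect_warning(out <- sliding_window_kaks(codon_aln("ATG", "ATG")), "shorter")
  expect_equal(nrow(out), 0)
  expect_error(sliding_window_kaks(codon_aln(a, b), window = 100), "window")
})

test_that("the report runs per pair, flags missing sequences, and keeps going", {
  sim <- tiny_sim(1)
  g <- sim$genomes$alpha
  ev <- sim$truth$events[sim$truth$events$species == "alpha", ]
  all_cds <- g$cds; all_prot <- g$protein
  pairs <- dplyr::bind_rows(ev[, c("gene_a", "gene_b")],
                            tibble::tibble(gene_a = "missing", gene_b = ev$gene_a[1]))
  rep <- kaks_report(pairs, all_cds, all_prot)
  expect_equal(nrow(rep$pairs), nrow(pairs))
  expect_true(all(rep$pairs$ok[seq_len(nrow(ev))]))
  expect_false(rep$pairs$ok[nrow(pairs)])
  expect_match(rep$pairs$note[nrow(pairs)], "missing")
  # duplicates evolved under purifying selection classify as purifying
  expect_true(all(rep$pairs$classification[rep$pairs$ok] == "purifying"))
  # empty pair list: header-only result
  rep0 <- kaks_report(pairs[0, ], all_cds, all_prot)
  expect_equal(nrow(rep0$pairs), 0)
})

test_that("estimated Ka/Ks is monotone in the simulated omega", {
  set.seed(44)
  grid <- c(0.1, 0.5, 2)
  means <- vapply(grid, function(w) {
    mean(vapply(1:25, function(i) {
      a <- random_cds(300)
      b <- evolve_cds(a, 0.3, omega = w, kappa = 2)
      ng86(codon_aln(a, b))$ka_ks
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_false(is.unsorted(means))
})
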