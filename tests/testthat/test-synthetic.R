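test_that("equal seeds give byte-identical simulation output", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_genomes(tiny_config(7)), d1, genome_fa = TRUE)
  write_simulation(simulate_genomes(tiny_config(7)), d2, genome_fa = TRUE)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("planted event counts and placement match the configuration", {
  sim0 <- simulate_genomes(tiny_config(3, n_tandem_events = 0,
                                       n_segmental_events = 0))
  expect_equal(nrow(sim0$truth$events), 0)

  sim3 <- simulate_genomes(tiny_config(4, n_tandem_events = 3,
                                       n_segmental_events = 0))
  tr <- sim3$truth$events
  expect_equal(sum(tr$type == "tandem" & tr$species == "alpha"), 3)
  # each tandem pair lies on one chromosome, adjacent
  for (i in which(tr$type == "tandem")) {
    g <- sim3$genomes[[tr$species[i]]]
    ga <- genes_by_id(g, tr$gene_a[i]); gb <- genes_by_id(g, tr$gene_b[i])
    expect_identical(ga$chrom, gb$chrom)
    expect_lte(famsynt:::count_intervening(g, tr$gene_a[i], tr$gene_b[i]), 1)
  }
})

test_that("segmental copies preserve source-block gene order and strand", {
  sim <- tiny_sim(2)
  tr <- sim$truth$events
  seg <- tr[tr$type == "segmental", ]
  expect_gt(nrow(seg), 0)
  for (sp in unique(seg$species)) {
    g <- sim$genomes[[sp]]
    rows <- seg[seg$species == sp, ]
    src <- genes_by_id(g, rows$gene_a)
    cp <- genes_by_id(g, rows$gene_b)
    # copies land on a different chromosome than their source
    expect_true(all(src$chrom != cp$chrom))
    expect_identical(src$strand, cp$strand)
    # order preserved: ranks of sources and of copies agree within one event
    if (nrow(rows) > 1 && length(unique(cp$chrom)) == 1) {
      expect_identical(order(src$start), order(cp$start))
    }
  }
})

test_that("truth tables are referentially intact over many random configs", {
  set.seed(99)
  for (rep in 1:25) {
    cfg <- tiny_config(seed = 1000 + rep,
                       n_tandem_events = sample(0:2, 1),
                       n_segmental_events = sample(0:2, 1),
                       n_family_genes = sample(5:6, 1))
    sim <- simulate_genomes(cfg)
    all_ids <- unlist(lapply(sim$genomes, function(g) g$genes$gene_id))
    tr <- sim$truth
    expect_true(all(c(tr$events$gene_a, tr$events$gene_b) %in% all_ids))
    expect_true(all(tr$family$gene_id %in% all_ids))
    expect_true(all(c(tr$orthologs$gene_a, tr$orthologs$gene_b) %in% all_ids))
    # family genes present per species and subfamily labels complete
    expect_equal(sum(tr$family$species == "alpha" & !grepl("_d", tr$family$gene_id)),
                 cfg$n_family_genes)
  }
})

test_that("evolve_cds respects branch length, omega and the stop-codon rule", {
  set.seed(11)
  cds <- random_cds(200)
  expect_identical(evolve_cds(cds, 0), cds)
  # omega = 0: essentially all differences synonymous under NG86 counting
  # (rare multi-step jumps between synonymous codon islands can look
  # nonsynonymous at the endpoint level)
  e <- evolve_cds(cds, 0.6, omega = 0, kappa = 1, seed = 5)
  res <- ng86(structure(list(a = cds, b = e), class = "codon_alignment"))
  expect_lte(res$Nd / (res$Sd + res$Nd), 0.02)
  # no stop codons ever appear
  expect_false(grepl("\\*", translate_cds(e)))
  expect_error(evolve_cds(paste0("ATG", "TAA", "AAA"), 0.1), "internal stop")
})

test_that("plant_rate_shift labels sites at the requested theta", {
  sim <- tiny_sim(1)
  aln <- member_proteins(sim, call_family(sim$genomes, cached_pssms()))
  aln <- align_proteins(aln)
  half <- length(aln) %/% 2
  c1 <- names(aln)[1:half]; c2 <- names(aln)[(half + 1):length(aln)]
  r0 <- plant_rate_shift(aln, c1, c2, theta_sim = 0, seed = 1)
  expect_true(all(r0$labels == "F0"))
  r1 <- plant_rate_shift(aln, c1, c2, theta_sim = 1, seed = 1)
  expect_true(all(r1$labels == "F1"))
  n_sites <- nchar(aln[[1]])
  r25 <- plant_rate_shift(aln, c1, c2, theta_sim = 0.25, seed = 2)
  k <- sum(r25$labels == "F1")
  expect_gt(k, qbinom(0.001, n_sites, 0.25))
  expect_lt(k, qbinom(0.999, n_sites, 0.25))
  expect_error(plant_rate_shift(aln, c1, c(c1[1], c2), 0.5), "overlap")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(segment_size_genes = 80, genes_per_chrom = 60),
               "exceeds")
  expect_error(sim_config(segment_size_genes = 3), ">= 5")
  expect_error(sim_config(n_tandem_events = 6, n_segmental_events = 6,
                          n_family_genes = 10), "more duplication events")
  # YAML config round-trip with defaults for unset keys
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_family_genes: 6", "seed: 42"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$n_family_genes, 6)
  expect_equal(cfg$seed, 42)
  expect_equal(cfg$omega, sim_config()$omega)
  writeLines("not_a_key: 1", f)
  expect_error(read_sim_config(f), "unknown config key")
})
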