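# Genome simulator with planted gene-family history. Generates multi-species,
# multi-chromosome genomes in which family genes carry QLQ+WRC domains, with
# tandem and segmental (block) duplications, subfamily structure on a known
# family tree, and coding sequences evolved under a codon model with
# specified omega -- so every downstream stage can be benchmarked against
# ground truth.

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the package's
#' benchmarks: two species, three chromosomes of 40 genes with ~10 kb mean
#' spacing, ten family genes in five subfamilies of two, two tandem and two
#' segmental duplication events per species with blocks of eight genes
#' centered on the family anchor and per-gene retention 0.9, background
#' omega 0.2 with strong purifying selection (omega 0.02) inside the planted
#' domains, and kappa 2.
#'
#' @param n_species number of species (2-5).
#' @param n_chroms chromosomes per species.
#' @param genes_per_chrom gene slots per chromosome.
#' @param n_family_genes family genes per species (before duplications).
#' @param n_subfamilies planted subfamily clades.
#' @param n_tandem_events,n_segmental_events duplication events planted in
#'   each species.
#' @param segment_size_genes genes per segmental block (>= 5), anchored on
#'   the family gene at its center.
#' @param omega,domain_omega,kappa codon-model parameters (dN/dS outside and
#'   inside domains; transition/transversion ratio).
#' @param theta_sim fraction of sites with cluster-independent rates, used by
#'   [plant_rate_shift()].
#' @param intergenic_bp mean intergenic spacing.
#' @param retention_prob probability a non-anchor block gene survives a
#'   segmental duplication as a recognisable copy.
#' @param t_deep,t_within,t_species,t_dup branch lengths (expected
#'   substitutions per codon): subfamily radiation, within-subfamily, species
#'   terminal branches, and duplicate divergence.
#' @param family_codons family CDS length in codons.
#' @param bg_codon_range min/max background CDS length in codons.
#' @param exon_max maximum planted exon count (exon numbers drawn 1..max).
#' @param exon_change_prob probability a duplicate copy gains or loses one
#'   exon.
#' @param family_min_sep minimum separation (gene slots) between family genes
#'   on one chromosome, so members sit outside each other's flank windows as
#'   in real gene-family layouts.
#' @param copy_min_dist minimum distance (gene slots) between a segmental
#'   copy's insertion point and any family gene on the target chromosome.
#' @param seed RNG seed; the whole simulation runs off one stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 2, n_chroms = 4, genes_per_chrom = 60,
                       n_family_genes = 10, n_subfamilies = 5,
                       n_tandem_events = 2, n_segmental_events = 2,
                       segment_size_genes = 8, omega = 0.2,
                       domain_omega = 0.02, kappa = 2, theta_sim = 0.25,
                       intergenic_bp = 10000, retention_prob = 0.9,
                       t_deep = 0.5, t_within = 0.08, t_species = 0.05,
                       t_dup = 0.1, family_codons = 200,
                       bg_codon_range = c(100, 200), exon_max = 6,
                       exon_change_prob = 0.3, family_min_sep = 18,
                       copy_min_dist = 14, seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_species >= 1, n_species <= 5, n_chroms >= 1,
              genes_per_chrom >= 1, n_family_genes >= 0, n_subfamilies >= 1,
              n_tandem_events >= 0, n_segmental_events >= 0,
              omega > 0, domain_omega > 0, kappa > 0,
              theta_sim >= 0, theta_sim <= 1, retention_prob >= 0,
              retention_prob <= 1, exon_max >= 1)
    if (segment_size_genes < 5) stopf("segment_size_genes must be >= 5")
    if (segment_size_genes > genes_per_chrom) {
      stopf("segment_size_genes (%d) exceeds genes_per_chrom (%d)",
            segment_size_genes, genes_per_chrom)
    }
    if (n_tandem_events + n_segmental_events > n_family_genes) {
      stopf("more duplication events than family genes to anchor them")
    }
  })
  cfg$species <- c("alpha", "beta", "gamma", "delta", "epsilon")[seq_len(n_species)]
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML key-value file
#' @param path YAML file; every key has a default from [sim_config()].
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path) %||% list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stopf("unknown config key: %s", unknown[1])
  do.call(sim_config, vals)
}

# place family genes with a minimum same-chromosome separation: counts are
# spread over chromosomes, then positions drawn uniformly among the
# separation-respecting configurations (classic stars-and-bars shift)
place_family_slots <- function(config) {
  L <- config$genes_per_chrom
  g <- config$family_min_sep
  n <- config$n_family_genes
  if (n == 0) return(integer(0))
  cap <- floor((L - 1) / g) + 1
  base <- n %/% config$n_chroms
  counts <- rep(base, config$n_chroms)
  extra <- n %% config$n_chroms
  if (extra > 0) {
    bump <- sample.int(config$n_chroms, extra)
    counts[bump] <- counts[bump] + 1L
  }
  if (any(counts > cap)) {
    stopf("cannot place %d family genes on %d chromosomes of %d slots with separation %d",
          n, config$n_chroms, L, g)
  }
  slots <- integer(0)
  for (cn in seq_len(config$n_chroms)) {
    k <- counts[cn]
    if (k == 0) next
    ymax <- L - (k - 1) * g
    y <- sort(sample.int(ymax, k))
    x <- y + (seq_len(k) - 1L) * g
    slots <- c(slots, (cn - 1L) * L + x)
  }
  sort(slots)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

consensus_of_alignment <- function(aln) {
  m <- seq_to_matrix(aln)
  apply(m, 2, function(col) {
    tab <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    AA_ALPHABET[which.max(tab)]
  })
}

# back-translate a domain motif into codons: per column the seed consensus,
# substituted with probability `noise` by another residue observed in that
# seed column (uniform over the alphabet when the column is invariant) --
# point noise that mimics within-family domain variation
plant_domain_cds <- function(seed_aln, noise = 0.1) {
  m <- seq_to_matrix(seed_aln)
  code <- genetic_code()
  sense <- sense_codons()
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j][m[, j] %in% AA_ALPHABET]
    tab <- table(factor(col, levels = AA_ALPHABET))
    a <- AA_ALPHABET[which.max(tab)]
    if (runif(1) < noise) {
      alt <- setdiff(unique(col), a)
      a <- if (length(alt)) sample(alt, 1) else sample(setdiff(AA_ALPHABET, a), 1)
    }
    syn <- sense[code[sense] == a]
    sample(syn, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate genomes with a planted gene-family history
#'
#' @param config a [sim_config()].
#' @return Object of class `fam_simulation`: list with `genomes` (named list
#'   of `fam_genome`), `truth` (list of tibbles: `events`, `family`,
#'   `orthologs`, `genes`) and `config`. Deterministic given `config$seed`.
#' @export
simulate_genomes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  qlq_seed <- seed_alignment("QLQ")
  wrc_seed <- seed_alignment("WRC")
  qlq_w <- nchar(qlq_seed[[1]])
  wrc_w <- nchar(wrc_seed[[1]])
  n_slots <- config$n_chroms * config$genes_per_chrom

  # ---- family root CDS with planted domains and per-codon omega ----
  root <- sample(sense_codons(), config$family_codons, replace = TRUE)
  qlq_start <- 11L
  wrc_start <- qlq_start + qlq_w + 30L
  stopifnot(wrc_start + wrc_w - 1 <= config$family_codons)
  qlq_cols <- qlq_start:(qlq_start + qlq_w - 1)
  wrc_cols <- wrc_start:(wrc_start + wrc_w - 1)
  root[qlq_cols] <- plant_domain_cds(qlq_seed)
  root[wrc_cols] <- plant_domain_cds(wrc_seed)
  root <- paste0(root, collapse = "")
  omega_vec <- rep(config$omega, config$family_codons)
  omega_vec[c(qlq_cols, wrc_cols)] <- config$domain_omega

  # ---- family tree: star of subfamily ancestors, then members ----
  subfam_of <- rep(seq_len(config$n_subfamilies),
                   length.out = config$n_family_genes)
  sub_anc <- lapply(seq_len(config$n_subfamilies), function(s) {
    evolve_cds(root, config$t_deep, omega_vec, config$kappa)
  })
  mem_anc <- lapply(seq_len(config$n_family_genes), function(m) {
    evolve_cds(sub_anc[[subfam_of[m]]], config$t_within, omega_vec, config$kappa)
  })

  # ---- ancestral genome layout shared by all species ----
  fam_slots <- place_family_slots(config)
  slot_chrom <- rep(seq_len(config$n_chroms), each = config$genes_per_chrom)
  bg_idx_of_slot <- rep(NA_integer_, n_slots)
  bg_idx_of_slot[setdiff(seq_len(n_slots), fam_slots)] <-
    seq_len(n_slots - config$n_family_genes)
  n_bg <- n_slots - config$n_family_genes
  bg_anc <- replicate(n_bg, random_cds(sample(seq(config$bg_codon_range[1],
                                                  config$bg_codon_range[2]), 1)))
  anc_exons <- sample.int(config$exon_max, n_slots, replace = TRUE)
  anc_strand <- sample(c("+", "-"), n_slots, replace = TRUE)

  genomes <- list()
  events <- list(); family <- list(); gene_rows <- list()
  gene_anc_id <- list() # species -> named vector gene_id -> ancestral slot key

  for (sp in config$species) {
    fam_leaf <- vapply(mem_anc, function(x) {
      evolve_cds(x, config$t_species, omega_vec, config$kappa)
    }, character(1))
    bg_leaf <- vapply(bg_anc, function(x) {
      evolve_cds(x, config$t_species, config$omega, config$kappa)
    }, character(1))

    # per-chromosome ordered gene records
    recs <- lapply(seq_len(n_slots), function(s) {
      if (s %in% fam_slots) {
        m <- match(s, fam_slots)
        list(gene_id = sprintf("%s_f%02d", sp, m), cds = fam_leaf[m],
             n_exons = anc_exons[s], strand = anc_strand[s],
             chrom = slot_chrom[s], is_family = TRUE, member = m,
             anc = sprintf("slot%03d", s))
      } else {
        b <- bg_idx_of_slot[s]
        list(gene_id = sprintf("%s_b%03d", sp, b), cds = bg_leaf[b],
             n_exons = anc_exons[s], strand = anc_strand[s],
             chrom = slot_chrom[s], is_family = FALSE, member = NA_integer_,
             anc = sprintf("slot%03d", s))
      }
    })
    chrom_recs <- split(recs, vapply(recs, `[[`, integer(1), "chrom"))
    names(chrom_recs) <- paste0("chr", names(chrom_recs))

    dup_counter <- 0L
    new_copy <- function(src, type) {
      dup_counter <<- dup_counter + 1L
      ne <- src$n_exons
      if (runif(1) < config$exon_change_prob) {
        ne <- max(1L, min(config$exon_max, ne + sample(c(-1L, 1L), 1)))
      }
      fam <- isTRUE(src$is_family)
      cds <- evolve_cds(src$cds, config$t_dup,
                        if (fam) omega_vec else config$omega, config$kappa)
      list(gene_id = sprintf("%s_d%03d", sp, dup_counter), cds = cds,
           n_exons = ne, strand = src$strand, chrom = NA_integer_,
           is_family = fam, member = src$member, anc = src$anc)
    }

    # pick distinct family anchors for the planted events
    n_ev <- config$n_tandem_events + config$n_segmental_events
    anchors <- if (n_ev > 0) sample(config$n_family_genes, n_ev) else integer(0)
    tandem_src <- head(anchors, config$n_tandem_events)
    seg_src <- tail(anchors, config$n_segmental_events)

    find_member <- function(m) {
      for (cn in names(chrom_recs)) {
        k <- which(vapply(chrom_recs[[cn]], function(r) identical(r$member, m), logical(1)))
        if (length(k)) return(list(chrom = cn, pos = k[1]))
      }
      stopf("member %d not found", m)
    }

    for (m in tandem_src) {
      loc <- find_member(m)
      src <- chrom_recs[[loc$chrom]][[loc$pos]]
      cp <- new_copy(src, "tandem")
      chrom_recs[[loc$chrom]] <- append(chrom_recs[[loc$chrom]], list(cp), after = loc$pos)
      events[[length(events) + 1L]] <- tibble::tibble(
        species = sp, gene_a = src$gene_id, gene_b = cp$gene_id,
        type = "tandem", omega = config$omega, is_anchor = TRUE)
    }

    for (m in seg_src) {
      loc <- find_member(m)
      src_list <- chrom_recs[[loc$chrom]]
      half <- (config$segment_size_genes - 1) %/% 2
      lo <- max(1, loc$pos - half)
      hi <- min(length(src_list), lo + config$segment_size_genes - 1)
      lo <- max(1, hi - config$segment_size_genes + 1)
      block <- src_list[lo:hi]
      copies <- lapply(block, function(r) {
        if (isTRUE(r$is_family) || runif(1) < config$retention_prob) {
          new_copy(r, "segmental")
        } else {
          dup_counter <<- dup_counter + 1L
          n_cod <- sample(seq(config$bg_codon_range[1], config$bg_codon_range[2]), 1)
          list(gene_id = sprintf("%s_d%03d", sp, dup_counter),
               cds = random_cds(n_cod),
               n_exons = sample.int(config$exon_max, 1),
               strand = r$strand, chrom = NA_integer_, is_family = FALSE,
               member = NA_integer_, anc = NA_character_)
        }
      })
      other <- setdiff(names(chrom_recs), loc$chrom)
      if (!length(other)) stopf("segmental events need >= 2 chromosomes")
      # keep the copied block clear of existing family-gene windows
      cand <- purrr::map_dfr(other, function(cn) {
        fpos <- which(vapply(chrom_recs[[cn]], function(r) isTRUE(r$is_family),
                             logical(1)))
        at <- 0:length(chrom_recs[[cn]])
        mind <- if (length(fpos)) {
          vapply(at, function(a) min(abs(fpos - a)), numeric(1))
        } else rep(Inf, length(at))
        tibble::tibble(chrom = cn, at = at, mind = mind)
      })
      ok <- cand[cand$mind >= config$copy_min_dist, ]
      pick <- if (nrow(ok)) ok[sample.int(nrow(ok), 1), ] else
        cand[which.max(cand$mind), ]
      target <- pick$chrom
      at <- pick$at
      chrom_recs[[target]] <- append(chrom_recs[[target]], copies, after = at)
      # every family gene carried by the block is a planted segmental pair
      for (i in seq_along(block)) {
        if (isTRUE(block[[i]]$is_family)) {
          events[[length(events) + 1L]] <- tibble::tibble(
            species = sp, gene_a = block[[i]]$gene_id,
            gene_b = copies[[i]]$gene_id,
            type = "segmental", omega = config$omega,
            is_anchor = identical(block[[i]]$member, m))
        }
      }
    }

    # ---- coordinates, exon structures, sequences ----
    rows <- list(); cds_vec <- character(0); prot_vec <- character(0)
    anc_map <- character(0)
    for (cn in names(chrom_recs)) {
      cur <- 0L
      for (r in chrom_recs[[cn]]) {
        gap <- as.integer(round(config$intergenic_bp * runif(1, 0.6, 1.4)))
        start <- cur + gap + 1L
        cds_len <- nchar(r$cds)
        ne <- min(r$n_exons, cds_len %/% 3) # at least one bp per exon
        cuts <- if (ne > 1) sort(sample(cds_len - 1L, ne - 1L)) else integer(0)
        exon_lens <- diff(c(0L, cuts, cds_len))
        intron_lens <- if (ne > 1) sample(80:600, ne - 1L, replace = TRUE) else integer(0)
        genomic_lens <- if (r$strand == "+") exon_lens else rev(exon_lens)
        ex_start <- integer(ne); ex_end <- integer(ne)
        pos <- start
        for (j in seq_len(ne)) {
          ex_start[j] <- pos
          ex_end[j] <- pos + genomic_lens[j] - 1L
          pos <- ex_end[j] + (if (j < ne) intron_lens[j] else 0L) + 1L
        }
        end <- ex_end[ne]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = r$gene_id, chrom = cn, start = start, end = end,
          strand = r$strand, exons = list(cbind(start = ex_start, end = ex_end)),
          n_exons = ne)
        cds_vec[r$gene_id] <- r$cds
        prot_vec[r$gene_id] <- translate_cds(r$cds)
        anc_map[r$gene_id] <- r$anc %||% NA_character_
        gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
          species = sp, gene_id = r$gene_id, chrom = cn, n_exons = ne,
          is_family = r$is_family)
        if (r$is_family) {
          family[[length(family) + 1L]] <- tibble::tibble(
            species = sp, gene_id = r$gene_id,
            subfamily = sprintf("SF%d", subfam_of[r$member]),
            member_index = r$member)
        }
        cur <- end
      }
    }
    g <- genome(sp, dplyr::bind_rows(rows), cds = cds_vec, protein = prot_vec)
    genomes[[sp]] <- g
    gene_anc_id[[sp]] <- anc_map
  }

  # ---- ortholog truth: genes sharing an ancestral slot across species ----
  orthologs <- list()
  if (length(config$species) >= 2) {
    combos <- utils::combn(config$species, 2)
    for (k in seq_len(ncol(combos))) {
      a <- combos[1, k]; b <- combos[2, k]
      ma <- gene_anc_id[[a]]; mb <- gene_anc_id[[b]]
      ma <- ma[!is.na(ma)]; mb <- mb[!is.na(mb)]
      shared <- intersect(ma, mb)
      # original (non-duplicate) representative per slot: the _f/_b gene
      rep_of <- function(mv, slot) {
        ids <- names(mv)[mv == slot]
        ids[order(grepl("_d", ids), ids)][1]
      }
      orthologs[[length(orthologs) + 1L]] <- tibble::tibble(
        species_a = a, species_b = b,
        gene_a = vapply(shared, rep_of, character(1), mv = ma),
        gene_b = vapply(shared, rep_of, character(1), mv = mb),
        slot = shared,
        is_family = shared %in% sprintf("slot%03d", fam_slots)
      )
    }
  }

  truth <- list(
    events = dplyr::bind_rows(events) %||% tibble::tibble(),
    family = dplyr::bind_rows(family),
    orthologs = dplyr::bind_rows(orthologs),
    genes = dplyr::bind_rows(gene_rows)
  )
  if (nrow(truth$events) == 0L) {
    truth$events <- tibble::tibble(species = character(), gene_a = character(),
                                   gene_b = character(), type = character(),
                                   omega = numeric(), is_anchor = logical())
  }
  structure(list(genomes = genomes, truth = truth, config = config),
            class = "fam_simulation")
}

#' @export
print.fam_simulation <- function(x, ...) {
  cat(sprintf("<fam_simulation> %d species, %d genes, %d planted events\n",
              length(x$genomes),
              sum(vapply(x$genomes, function(g) nrow(g$genes), integer(1))),
              nrow(x$truth$events)))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits, per species, `<sp>.genes.gff3`, `<sp>.cds.fa`, `<sp>.proteins.fa`
#' (and `<sp>.genome.fa` on request), plus `truth_events.tsv`,
#' `truth_family.tsv`, `truth_genes.tsv`, `truth_orthologs.tsv`.
#' Byte-identical across runs with the same config (seed included).
#'
#' @param sim a `fam_simulation`.
#' @param dir output directory (created).
#' @param genome_fa also emit chromosome sequences (random intergenic spacer
#'   around the genic sequence).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, genome_fa = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]
    write_gff3(g, file.path(dir, paste0(sp, ".genes.gff3")))
    write_fasta(g$cds, file.path(dir, paste0(sp, ".cds.fa")))
    write_fasta(g$protein, file.path(dir, paste0(sp, ".proteins.fa")))
    if (genome_fa) {
      write_fasta(chromosome_sequences(g, seed = sim$config$seed),
                  file.path(dir, paste0(sp, ".genome.fa")))
    }
  }
  tr <- sim$truth
  readr::write_tsv(tr$events, file.path(dir, "truth_events.tsv"))
  readr::write_tsv(tr$family, file.path(dir, "truth_family.tsv"))
  readr::write_tsv(tr$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(tr$orthologs, file.path(dir, "truth_orthologs.tsv"))
  invisible(dir)
}

# chromosome sequences consistent with the gene models: exon bp carry the
# CDS (reverse-complemented on '-'), intron/intergenic bp are random
chromosome_sequences <- function(g, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  nts <- c("A", "C", "G", "T")
  out <- character(0)
  for (cn in unique(g$genes$chrom)) {
    rows <- g$genes[g$genes$chrom == cn, ]
    L <- max(rows$end) + 200L
    chrom <- sample(nts, L, replace = TRUE)
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      cds <- g$cds[[r$gene_id]]
      genic <- if (r$strand == "+") cds else revcomp(cds)
      ex <- r$exons[[1]]
      pos <- 1L
      for (j in seq_len(nrow(ex))) {
        len <- ex[j, 2] - ex[j, 1] + 1L
        chrom[ex[j, 1]:ex[j, 2]] <- strsplit(substr(genic, pos, pos + len - 1L), "")[[1]]
        pos <- pos + len
      }
    }
    out[cn] <- paste0(chrom, collapse = "")
  }
  out
}

#' Plant a subfamily rate shift into a protein alignment
#'
#' Re-simulates each alignment column from its consensus under a two-state
#' site model: with probability `theta_sim` the site is F1 (independent
#' gamma rates in the two clusters), otherwise F0 (one shared rate). Each
#' sequence accumulates a Poisson number of substitutions (rate x branch
#' length) toward random residues. Per-site labels are returned as truth.
#'
#' @param alignment named character vector of equal-length protein sequences.
#' @param cluster1,cluster2 disjoint taxon name sets.
#' @param theta_sim fraction of F1 sites in \[0, 1\].
#' @param gamma_shape shape of the gamma rate distribution (mean 1).
#' @param branch_length expected substitutions per site at rate 1.
#' @param seed RNG seed.
#' @return List: `alignment` (modified), `labels` (factor F0/F1 per column).
#' @export
plant_rate_shift <- function(alignment, cluster1, cluster2, theta_sim,
                             gamma_shape = 1, branch_length = 0.5, seed = 1L) {
  stopifnot(theta_sim >= 0, theta_sim <= 1)
  if (length(intersect(cluster1, cluster2))) stopf("clusters overlap")
  stopifnot(all(c(cluster1, cluster2) %in% names(alignment)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  m <- seq_to_matrix(alignment)
  L <- ncol(m)
  labels <- factor(ifelse(runif(L) < theta_sim, "F1", "F0"), levels = c("F0", "F1"))
  clusters <- list(cluster1, cluster2)
  for (j in seq_len(L)) {
    anc <- names(sort(table(m[, j][m[, j] %in% AA_ALPHABET]), decreasing = TRUE))[1]
    if (is.null(anc) || is.na(anc)) next
    shared <- rgamma(1, gamma_shape, gamma_shape)
    for (ci in 1:2) {
      rate <- if (labels[j] == "F1") rgamma(1, gamma_shape, gamma_shape) else shared
      for (taxon in clusters[[ci]]) {
        res <- anc
        nsub <- rpois(1, rate * branch_length)
        if (nsub > 0) for (k in seq_len(nsub)) res <- sample(setdiff(AA_ALPHABET, res), 1)
        m[taxon, j] <- res
      }
    }
  }
  list(alignment = matrix_to_seq(m), labels = labels)
}

#' Simulate per-site substitution counts under the two-state rate model
#'
#' Draws (x1, x2) site counts from the Poisson-gamma mixture that
#' [estimate_theta1()] fits: with probability `theta` a site's rates are
#' independent between clusters (F1), otherwise shared (F0); rates are
#' gamma(`alpha`, `alpha`) (mean 1) and counts Poisson(rate x d).
#'
#' @param n_sites number of sites.
#' @param theta true fraction of F1 sites.
#' @param alpha gamma shape.
#' @param d1,d2 cluster tree lengths (expected substitutions per site at
#'   rate 1).
#' @param seed RNG seed.
#' @return Tibble: site, x1, x2, label (F0/F1).
#' @export
simulate_site_counts <- function(n_sites, theta, alpha = 1, d1 = 1.5,
                                 d2 = 1.5, seed = 1L) {
  stopifnot(theta >= 0, theta <= 1, alpha > 0, d1 > 0, d2 > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  f1 <- runif(n_sites) < theta
  r1 <- rgamma(n_sites, alpha, alpha)
  r2 <- ifelse(f1, rgamma(n_sites, alpha, alpha), r1)
  tibble::tibble(
    site = seq_len(n_sites),
    x1 = rpois(n_sites, r1 * d1),
    x2 = rpois(n_sites, r2 * d2),
    label = factor(ifelse(f1, "F1", "F0"), levels = c("F0", "F1"))
  )
}
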