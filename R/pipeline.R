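# End-to-end orchestration: simulate -> identify -> phylo -> structure ->
# synteny -> kaks -> diverge, with a manifest and deterministic outputs
# (no timestamps in any report file, so equal-seed runs are byte-identical).

#' Pipeline configuration
#'
#' Defaults are the analysis settings the pipeline is built around: 100 kb
#' flank radius, E-value 1e-10, >= 4 conserved pairs for a large-scale call,
#' 150 bp / 9 bp sliding windows, Qk > 0.9 critical sites, 1000 bootstrap
#' replicates and five subfamilies.
#'
#' @param sim a [sim_config()] (used when `stages` includes "simulate");
#'   its seed drives every stage.
#' @param stages character vector of stages to run, in dependency order.
#' @param radius_bp,evalue_max,min_pairs,max_intervening synteny settings.
#' @param window,step sliding-window settings (bp).
#' @param qk_threshold critical-site posterior cutoff.
#' @param n_bootstrap bootstrap replicates.
#' @param k_subfamilies clades to cut.
#' @param min_support minimum bootstrap count for a cuttable branch
#'   (default half the replicates).
#' @param input_dir directory with pre-existing inputs when "simulate" is
#'   not among the stages (expects the [write_simulation()] layout).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "identify", "phylo",
                                       "structure", "synteny", "kaks",
                                       "diverge"),
                            radius_bp = 100000, evalue_max = 1e-10,
                            min_pairs = 4, max_intervening = 1,
                            window = 150, step = 9, qk_threshold = 0.9,
                            n_bootstrap = 1000, k_subfamilies = 5,
                            min_support = NULL, input_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages run in dependency order; a missing prerequisite is an error before
#' any stage runs. Every output TSV is written under `out_dir` together with
#' a `manifest.json` recording parameters, input hashes and per-stage seeds
#' (no timestamps: two runs with the same config are byte-identical).
#' Failures on an individual pair/anchor are logged to `run.log` and the
#' pair is skipped, never silently dropped.
#'
#' @param config a [pipeline_config()].
#' @param out_dir report directory (created; must be empty or absent).
#' @return `out_dir`, invisibly. Side effects: report files.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  known <- c("simulate", "identify", "phylo", "structure", "synteny",
             "kaks", "diverge")
  if (length(setdiff(stages, known))) {
    stopf("unknown stage: %s", setdiff(stages, known)[1])
  }
  # dry-run validation before any stage runs
  if (!("simulate" %in% stages) && length(setdiff(stages, "simulate"))) {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir)) {
      stopf("stages %s need input_dir when the simulate stage is disabled",
            paste(setdiff(stages, "simulate"), collapse = ","))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  seed <- config$sim$seed
  note("pipeline start (seed %d)", seed)

  genomes <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_genomes(config$sim)
    write_simulation(sim, file.path(out_dir, "inputs"))
    genomes <- sim$genomes
    note("simulate: %d species, %d genes, %d planted events",
         length(sim$genomes), nrow(sim$truth$genes), nrow(sim$truth$events))
  } else if (length(setdiff(stages, "simulate"))) {
    sp_files <- list.files(config$input_dir, pattern = "\\.genes\\.gff3$")
    genomes <- lapply(sub("\\.genes\\.gff3$", "", sp_files), function(sp) {
      read_gff3(file.path(config$input_dir, paste0(sp, ".genes.gff3")),
                species = sp,
                cds_fasta = file.path(config$input_dir, paste0(sp, ".cds.fa")),
                protein_fasta = file.path(config$input_dir, paste0(sp, ".proteins.fa")))
    })
    names(genomes) <- sub("\\.genes\\.gff3$", "", sp_files)
    note("loaded %d genomes from %s", length(genomes), config$input_dir)
  }

  members <- NULL
  if ("identify" %in% stages) {
    pssms <- default_pssms()
    members <- call_family(genomes, pssms)
    readr::write_tsv(members, file.path(out_dir, "members.tsv"))
    note("identify: %d members", nrow(members))
  }

  member_proteins <- NULL
  if (!is.null(members) && nrow(members) > 0) {
    all_prot <- unlist(lapply(genomes, function(g) g$protein))
    names(all_prot) <- unlist(lapply(genomes, function(g) names(g$protein)))
    member_proteins <- setNames(all_prot[members$gene_id], members$member_id)
  }

  phylo <- NULL; subfam <- NULL
  if ("phylo" %in% stages) {
    if (is.null(member_proteins) || length(member_proteins) < 4) {
      note("phylo: skipped (fewer than 4 members)")
    } else {
      aln <- align_proteins(member_proteins)
      phylo <- bootstrap_nj(aln, n_reps = config$n_bootstrap, seed = seed)
      write_newick(phylo$tree, file.path(out_dir, "tree.nwk"))
      subfam <- tryCatch(
        assign_subfamilies(phylo, k = config$k_subfamilies,
                           min_support = config$min_support),
        error = function(e) {
          note("phylo: subfamily cut failed (%s)", conditionMessage(e))
          NULL
        })
      if (!is.null(subfam)) {
        readr::write_tsv(subfam, file.path(out_dir, "subfamilies.tsv"))
      }
      note("phylo: %d tips, %d bootstrap replicates",
           length(phylo$tree$tip.label), config$n_bootstrap)
    }
  }

  if ("structure" %in% stages && !is.null(members)) {
    st <- structure_table(genomes, members)
    readr::write_tsv(
      dplyr::mutate(st, exon_lengths = vapply(.data$exon_lengths, paste,
                                              character(1), collapse = ";")),
      file.path(out_dir, "structure.tsv"))
    readr::write_tsv(exon_count_distribution(st),
                     file.path(out_dir, "exon_distribution.tsv"))
    note("structure: %d records", nrow(st))
  }

  blocks_intra <- NULL
  if ("synteny" %in% stages && !is.null(members)) {
    blocks_intra <- purrr::map_dfr(genomes, function(g) {
      intraspecies_duplications(g, members, radius_bp = config$radius_bp,
                                evalue_max = config$evalue_max,
                                min_pairs = config$min_pairs,
                                max_intervening = config$max_intervening)
    })
    if (!is.null(blocks_intra) && nrow(blocks_intra)) {
      readr::write_tsv(flatten_blocks(blocks_intra),
                       file.path(out_dir, "blocks_intra.tsv"))
    }
    if (length(genomes) >= 2) {
      combos <- utils::combn(names(genomes), 2)
      inter <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
        r <- interspecies_synteny(genomes[[combos[1, k]]], genomes[[combos[2, k]]],
                                  members, radius_bp = config$radius_bp,
                                  evalue_max = config$evalue_max,
                                  min_pairs = config$min_pairs)
        r$blocks
      })
      if (nrow(inter)) {
        readr::write_tsv(flatten_blocks(inter),
                         file.path(out_dir, "blocks_inter.tsv"))
      }
      note("synteny: %d intra calls, %d inter blocks",
           if (is.null(blocks_intra)) 0L else nrow(blocks_intra), nrow(inter))
    } else {
      note("synteny: %d intra calls",
           if (is.null(blocks_intra)) 0L else nrow(blocks_intra))
    }
  }

  if ("kaks" %in% stages && !is.null(blocks_intra) && nrow(blocks_intra)) {
    dup_pairs <- blocks_intra[blocks_intra$classification != "none",
                              c("anchor_a", "anchor_b")]
    names(dup_pairs) <- c("gene_a", "gene_b")
    all_cds <- unlist(lapply(genomes, function(g) g$cds))
    names(all_cds) <- unlist(lapply(genomes, function(g) names(g$cds)))
    all_prot <- unlist(lapply(genomes, function(g) g$protein))
    names(all_prot) <- unlist(lapply(genomes, function(g) names(g$protein)))
    kk <- kaks_report(dup_pairs, all_cds, all_prot, window = config$window,
                      step = config$step)
    readr::write_tsv(kk$pairs, file.path(out_dir, "kaks.tsv"))
    if (!is.null(kk$windows) && nrow(kk$windows)) {
      readr::write_tsv(kk$windows, file.path(out_dir, "kaks_windows.tsv"))
    }
    note("kaks: %d pairs", nrow(kk$pairs))
  }

  if ("diverge" %in% stages && !is.null(subfam) && !is.null(member_proteins)) {
    aln <- align_proteins(member_proteins)
    dv <- divergence_report(aln, subfam, qk_threshold = config$qk_threshold)
    if (nrow(dv$results)) {
      out <- dplyr::mutate(dv$results,
                           critical_sites = vapply(.data$critical_sites, paste,
                                                   character(1), collapse = ";"))
      readr::write_tsv(out, file.path(out_dir, "divergence.tsv"))
    }
    if (nrow(dv$skipped)) {
      readr::write_tsv(dv$skipped, file.path(out_dir, "divergence_skipped.tsv"))
    }
    note("diverge: %d rows, %d subfamilies skipped",
         nrow(dv$results), nrow(dv$skipped))
  }

  manifest <- list(
    package = "famsynt",
    version = as.character(utils::packageVersion("famsynt")),
    stages = stages,
    seed = seed,
    parameters = config[c("radius_bp", "evalue_max", "min_pairs",
                          "max_intervening", "window", "step", "qk_threshold",
                          "n_bootstrap", "k_subfamilies")],
    sim = unclass(config$sim)[setdiff(names(config$sim), "species")],
    input_hashes = manifest_hashes(file.path(out_dir, "inputs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

flatten_blocks <- function(blocks) {
  dplyr::mutate(blocks, pairs = vapply(.data$pairs, function(p) {
    paste(sprintf("%s:%s", p$gene_a, p$gene_b), collapse = ";")
  }, character(1)))
}

manifest_hashes <- function(dir) {
  if (!dir.exists(dir)) return(list())
  files <- sort(list.files(dir, full.names = TRUE))
  as.list(setNames(unname(tools::md5sum(files)), basename(files)))
}

#' Summarise a completed pipeline run
#'
#' Per-species member counts, duplication-class tallies, and the fraction of
#' members found in duplicated regions (members appearing in at least one
#' non-`none` intra-species call over all members).
#'
#' @param report_dir directory written by [run_pipeline()].
#' @return List of tibbles: `members_per_species`, `duplication_classes`,
#'   `members_in_duplications`.
#' @export
summarize_run <- function(report_dir) {
  need <- file.path(report_dir, "members.tsv")
  if (!file.exists(need)) stopf("incomplete run: missing %s", need)
  members <- readr::read_tsv(need, show_col_types = FALSE)
  if (nrow(members) == 0L) {
    return(list(members_per_species = tibble::tibble(),
                duplication_classes = tibble::tibble(),
                members_in_duplications = tibble::tibble()))
  }
  per_species <- dplyr::count(members, .data$species, name = "n_members")
  bi_path <- file.path(report_dir, "blocks_intra.tsv")
  classes <- c("tandem", "large_scale", "relaxed", "none")
  if (file.exists(bi_path)) {
    blocks <- readr::read_tsv(bi_path, show_col_types = FALSE)
    tallies <- dplyr::count(blocks, .data$classification, name = "n_pairs_called") |>
      tidyr::complete(classification = classes,
                      fill = list(n_pairs_called = 0L))
    in_dup <- unique(unlist(blocks[blocks$classification != "none",
                                   c("anchor_a", "anchor_b")]))
    frac <- members |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(
        n_members = dplyr::n(),
        n_in_duplication = sum(.data$gene_id %in% in_dup),
        fraction = .data$n_in_duplication / .data$n_members)
  } else {
    tallies <- tibble::tibble(classification = classes, n_pairs_called = 0L)
    frac <- dplyr::mutate(per_species, n_in_duplication = 0L, fraction = 0)
  }
  list(members_per_species = per_species,
       duplication_classes = tallies,
       members_in_duplications = frac)
}
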