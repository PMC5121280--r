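# Exon-intron statistics and gain/loss calls between paralog/ortholog pairs.

#' Exon-intron structure table for family members
#'
#' One record per member: exon count, intron count and exon lengths (bp,
#' genomic order). Exon counts use exon features (not CDS segments), so
#' UTR-bearing models are handled if the annotation provides them. Members
#' without exon annotation are excluded with a warning.
#'
#' @param genomes a `fam_genome` or list of them.
#' @param members tibble from [call_family()] (or any tibble with `gene_id`
#'   and `species`); `NULL` means every gene.
#' @return Tibble: gene_id, species, n_exons, n_introns, exon_lengths (list
#'   column).
#' @export
structure_table <- function(genomes, members = NULL) {
  if (inherits(genomes, "fam_genome")) genomes <- list(genomes)
  purrr::map_dfr(genomes, function(g) {
    ids <- if (is.null(members)) g$genes$gene_id else {
      members$gene_id[members$species == g$species]
    }
    if (!length(ids)) return(NULL)
    rows <- genes_by_id(g, ids)
    no_exons <- vapply(rows$exons, function(e) is.null(e) || nrow(e) == 0, logical(1))
    if (any(no_exons)) {
      warnf("excluding %d gene(s) without exon annotation (e.g. %s)",
            sum(no_exons), rows$gene_id[no_exons][1])
      rows <- rows[!no_exons, ]
    }
    tibble::tibble(
      gene_id = rows$gene_id,
      species = g$species,
      n_exons = vapply(rows$exons, nrow, integer(1)),
      n_introns = pmax(vapply(rows$exons, nrow, integer(1)) - 1L, 0L),
      exon_lengths = lapply(rows$exons, function(e) as.integer(e[, 2] - e[, 1] + 1))
    )
  })
}

#' Distribution of members over exon-number classes
#' @param table output of [structure_table()].
#' @return Tibble: n_exons, n_genes (classes partition the member set).
#' @export
exon_count_distribution <- function(table) {
  dplyr::count(table, .data$n_exons, name = "n_genes")
}

#' Exon gain/loss calls for gene pairs
#'
#' The call is relative to `gene_a`: `delta = n_exons(b) - n_exons(a)`;
#' a positive delta is a `gain`, negative a `loss`, zero `equal`.
#'
#' @param pairs tibble/data frame with columns `gene_a`, `gene_b`.
#' @param table output of [structure_table()] covering both genes of every
#'   pair (a missing gene is an error naming it).
#' @return `pairs` with added columns n_exons_a, n_exons_b, delta, call.
#' @export
gain_loss <- function(pairs, table) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  lookup <- setNames(table$n_exons, table$gene_id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(lookup))
  if (length(missing)) stopf("gene missing from structure table: %s", missing[1])
  pairs |>
    dplyr::mutate(
      n_exons_a = unname(lookup[.data$gene_a]),
      n_exons_b = unname(lookup[.data$gene_b]),
      delta = .data$n_exons_b - .data$n_exons_a,
      call = dplyr::case_when(delta > 0 ~ "gain", delta < 0 ~ "loss", TRUE ~ "equal")
    )
}
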