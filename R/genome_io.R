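# Genome container and the standard-format IO every stage touches.
# Coordinates are GFF3-native: 1-based, inclusive, everywhere.

#' Construct a genome object
#'
#' The coordinate substrate for every downstream stage: one gene model per
#' gene (one transcript each), plus optional CDS and protein sequence sets.
#'
#' @param species species name.
#' @param genes tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `exons` (list column of 2-column start/end matrices in genomic
#'   order).
#' @param cds,protein named character vectors keyed by `gene_id` (optional).
#' @param prefix species prefix used when naming family members
#'   (default: capitalised first two letters of `species`).
#' @return An object of class `fam_genome`.
#' @export
genome <- function(species, genes, cds = NULL, protein = NULL, prefix = NULL) {
  stopifnot(is_string(species), is.data.frame(genes))
  need <- c("gene_id", "chrom", "start", "end", "strand", "exons")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols)) stopf("genes is missing columns: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) {
    stopf("duplicate gene_id: %s", genes$gene_id[duplicated(genes$gene_id)][1])
  }
  bad <- genes$start > genes$end
  if (any(bad)) stopf("gene %s has start > end", genes$gene_id[bad][1])
  genes <- dplyr::arrange(tibble::as_tibble(genes), .data$chrom, .data$start)
  if (!"n_exons" %in% names(genes)) {
    genes$n_exons <- vapply(genes$exons, nrow, integer(1))
  }
  structure(
    list(species = species, prefix = prefix %||% default_prefix(species),
         genes = genes, cds = cds, protein = protein),
    class = "fam_genome"
  )
}

default_prefix <- function(species) {
  paste0(toupper(substr(species, 1, 1)), substr(species, 2, 2))
}

#' @export
print.fam_genome <- function(x, ...) {
  cat(sprintf(
    "<fam_genome> %s: %d genes on %d chromosome(s)%s\n",
    x$species, nrow(x$genes), length(unique(x$genes$chrom)),
    if (!is.null(x$cds)) sprintf(", %d CDS", length(x$cds)) else ""
  ))
  invisible(x)
}

#' Look up genes by id
#' @param genome a `fam_genome`.
#' @param gene_ids character vector.
#' @return Tibble of the matching gene rows (error if any id is unknown).
#' @export
genes_by_id <- function(genome, gene_ids) {
  idx <- match(gene_ids, genome$genes$gene_id)
  if (anyNA(idx)) stopf("unknown gene id: %s", gene_ids[is.na(idx)][1])
  genome$genes[idx, ]
}

#' Read a GFF3 file into a genome object
#'
#' Expects gene/mRNA/exon/CDS features; one gene model is kept per gene (the
#' transcript with the longest total CDS when several are annotated).
#' Coordinates are preserved as 1-based inclusive. Genes whose CDS length is
#' not divisible by 3 are flagged (`codon_ok = FALSE`) with a warning and are
#' excluded from codon-level analyses downstream.
#'
#' @param path GFF3 file.
#' @param species species name (default: file stem).
#' @param cds_fasta,protein_fasta optional FASTA paths; sequences are attached
#'   by gene id.
#' @return A `fam_genome`.
#' @export
read_gff3 <- function(path, species = NULL, cds_fasta = NULL, protein_fasta = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    stopf("malformed GFF3 line %d in %s: expected 9 tab-separated fields, got %d",
          body[nfield != 9L][1], path, nfield[nfield != 9L][1])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID),
    parent = vapply(as.list(gr$Parent), function(p) if (length(p)) as.character(p[1]) else NA_character_, character(1))
  )
  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  exons <- df[df$type == "exon", ]
  cdss <- df[df$type == "CDS", ]
  pick <- vapply(genes$id, function(g) {
    tx <- mrnas[!is.na(mrnas$parent) & mrnas$parent == g, ]
    if (nrow(tx) == 0L) return(NA_character_)
    cds_len <- vapply(tx$id, function(tid) {
      sum(cdss$end[cdss$parent == tid] - cdss$start[cdss$parent == tid] + 1)
    }, numeric(1))
    tx$id[which.max(cds_len)]
  }, character(1))
  keep <- !is.na(pick)
  genes <- genes[keep, ]
  pick <- pick[keep]
  exon_list <- lapply(pick, function(tid) {
    ex <- exons[!is.na(exons$parent) & exons$parent == tid, c("start", "end")]
    ex <- ex[order(ex$start), , drop = FALSE]
    as.matrix(ex)
  })
  tbl <- tibble::tibble(
    gene_id = genes$id, chrom = genes$chrom, start = genes$start,
    end = genes$end, strand = genes$strand, exons = exon_list
  )
  g <- genome(species %||% sub("\\.gff3?$", "", basename(path)), tbl)
  if (!is.null(cds_fasta)) g <- attach_sequences(g, cds = read_fasta(cds_fasta))
  if (!is.null(protein_fasta)) g <- attach_sequences(g, protein = read_fasta(protein_fasta))
  g
}

#' Attach CDS / protein sequences to a genome
#'
#' Checks that each CDS translates to the attached protein (stop trimmed) and
#' that CDS lengths are divisible by 3; offenders are flagged in a
#' `codon_ok` column with a warning.
#'
#' @param genome a `fam_genome`.
#' @param cds,protein named character vectors keyed by gene id.
#' @return The updated genome.
#' @export
attach_sequences <- function(genome, cds = NULL, protein = NULL) {
  if (!is.null(cds)) genome$cds <- cds
  if (!is.null(protein)) genome$protein <- protein
  if (!is.null(genome$cds)) {
    len_ok <- nchar(genome$cds) %% 3 == 0
    if (any(!len_ok)) {
      warnf("%d CDS with length not divisible by 3 (e.g. %s); flagged and excluded from codon analyses",
            sum(!len_ok), names(genome$cds)[!len_ok][1])
    }
    genome$genes$codon_ok <- unname(len_ok[genome$genes$gene_id]) %in% TRUE
  }
  genome
}

#' Transcript-orientation exon order
#'
#' Exons are stored in genomic order; on the `-` strand the transcript reads
#' them in reverse.
#'
#' @param genome a `fam_genome`.
#' @param gene_id single gene id.
#' @return Matrix of exon (start, end) rows in transcript orientation.
#' @export
transcript_exons <- function(genome, gene_id) {
  row <- genes_by_id(genome, gene_id)
  ex <- row$exons[[1]]
  if (row$strand == "-") ex[rev(seq_len(nrow(ex))), , drop = FALSE] else ex
}

#' Read a FASTA file
#'
#' @param path FASTA file (amino acid or nucleotide).
#' @return Named character vector (empty for an empty file). Duplicate ids are
#'   an error naming the id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1])
  setNames(as.character(x), ids)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s)) {
      starts <- seq(1, nchar(s), 60)
      writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over \pkg{ape} so that round-trips preserve topology, branch
#' lengths and integer bootstrap labels.
#'
#' @param tree an `ape::phylo` object.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a genome's gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features (UTR-less models: exon and CDS
#' segments coincide), 1-based inclusive, with a `##gff-version 3` directive.
#'
#' @param genome a `fam_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  src <- "famsynt"
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    ex <- g$exons[[1]]
    gid <- g$gene_id
    tid <- paste0(gid, ".t1")
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, src, g$start, g$end, g$strand, gid), con)
    writeLines(sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, src, g$start, g$end, g$strand, tid, gid), con)
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$chrom, src, ex[j, 1], ex[j, 2], g$strand, tid, j, tid), con)
      writeLines(sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
                         g$chrom, src, ex[j, 1], ex[j, 2], g$strand, tid, j, tid), con)
    }
  }
  invisible(path)
}
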