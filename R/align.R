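# Protein multiple alignment used upstream of distances, Ka/Ks
# back-translation and divergence. The alignment is a means, not a result:
# equal-length inputs (the simulator is indel-free) are treated as already
# aligned; anything else is aligned with MAFFT.

#' Align a set of protein sequences
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param method `"auto"` (default: pass through when all sequences have equal
#'   length, otherwise MAFFT), `"mafft"`, or `"none"` (error if lengths
#'   differ).
#' @return Named character vector of aligned sequences (equal lengths, `-`
#'   gaps), in the input order.
#' @export
align_proteins <- function(seqs, method = c("auto", "mafft", "none")) {
  method <- match.arg(method)
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  equal_len <- length(unique(nchar(seqs))) == 1L
  if (method == "none" || (method == "auto" && equal_len)) {
    if (!equal_len) stopf("method='none' requires equal-length sequences")
    return(seqs)
  }
  if (Sys.which("mafft") == "") stopf("mafft not found on PATH")
  tmp_in <- tempfile(fileext = ".fa")
  tmp_out <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  write_fasta(seqs, tmp_in)
  status <- system2("mafft", c("--auto", "--anysymbol", "--thread", "1", "--quiet", tmp_in),
                    stdout = tmp_out, stderr = FALSE)
  if (status != 0) stopf("mafft failed with status %d", status)
  aln <- read_fasta(tmp_out)
  aln <- toupper(aln)
  aln[names(seqs)]
}
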