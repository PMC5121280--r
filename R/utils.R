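#' @importFrom rlang %||% abort warn
#' @importFrom stats optim optimHess pchisq rbinom rgamma rpois runif rexp setNames
#' @importFrom utils head tail
NULL

`%||%` <- rlang::`%||%`

# package-level cache for lazily built lookup tables (codon tables, PSSM nulls)
.famsynt_cache <- new.env(parent = emptyenv())

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Adjusted Rand index between two labelings
#'
#' Used to compare an inferred subfamily partition with the simulator's truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# split a vector of sequences (strings) into a character matrix of residues
seq_to_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) {
    stopf("sequences have unequal lengths (%s)", paste(unique(n), collapse = ", "))
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

matrix_to_seq <- function(m) {
  setNames(apply(m, 1, paste0, collapse = ""), rownames(m))
}
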