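#' Multiple sequence alignments
#'
#' A light container for an aligned set of sequences (equal widths, gap
#' character `-`) with a designated target row.
#'
#' @param sequences Character vector of aligned rows.
#' @param target Index of the target sequence (default 1).
#' @return An object of class `msa`.
#' @export
msa <- function(sequences, target = 1L) {
  if (!length(sequences)) stop("an alignment needs at least one row")
  w <- nchar(sequences)
  if (length(unique(w)) != 1L)
    stop("all alignment rows must have equal width")
  structure(list(sequences = toupper(sequences), n = length(sequences),
                 width = w[1], target = as.integer(target)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", x$n, x$width))
  invisible(x)
}

#' Read an alignment from aligned FASTA or A3M
#'
#' A3M insert states (lower-case letters and `.` columns) are removed on
#' read, per the A3M convention, leaving rows of equal match-state width.
#' Parsing is delegated to Biostrings.
#'
#' @param path File path.
#' @return An [msa()].
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  rows <- as.character(aa)
  rows <- gsub("[a-z.]", "", rows)   # drop A3M insert states
  msa(unname(rows))
}

#' Pairwise sequence identity between aligned rows
#'
#' Matches divided by the number of columns where at least one row is
#' non-gap; columns gapped in both rows are ignored.  (CD-HIT's exact
#' denominator convention differs; this transparent definition is the
#' package's contract.)
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned rows must have equal length")
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  use <- !(x == "-" & y == "-")
  if (!any(use)) return(0)
  sum(x[use] == y[use] & x[use] != "-") / sum(use)
}

# greedy leader clustering in input order; returns leader index per row
leader_clusters <- function(msa, threshold) {
  leaders <- integer(0)
  assign <- integer(msa$n)
  for (r in seq_len(msa$n)) {
    hit <- 0L
    for (ld in leaders) {
      if (pairwise_identity(msa$sequences[r], msa$sequences[ld]) >=
          threshold) { hit <- ld; break }
    }
    if (hit == 0L) { leaders <- c(leaders, r); hit <- r }
    assign[r] <- hit
  }
  assign
}

#' Effective sequence count of an alignment
#'
#' Sequences are clustered by greedy leader clustering in input order: a
#' row joins the first existing cluster whose leader it matches at
#' `threshold` identity or better, otherwise it founds a new cluster.
#' The effective sequence count Neff is the number of clusters at 62%
#' identity.
#'
#' @param msa An [msa()].
#' @param threshold Identity threshold (default 0.62).
#' @return Integer cluster count.
#' @export
neff <- function(msa, threshold = 0.62) {
  stopifnot(inherits(msa, "msa"))
  length(unique(leader_clusters(msa, threshold)))
}

#' Nf-style effective sequence count
#'
#' Cluster count at 80% identity, optionally normalized by the square
#' root of the alignment length (the normalization used by some related
#' depth measures is not settled, hence the explicit flag).
#'
#' @param msa An [msa()].
#' @param threshold Identity threshold (default 0.80).
#' @param normalize_by_sqrt_length Divide by sqrt(alignment width)?
#' @return Numeric value.
#' @export
nf <- function(msa, threshold = 0.80, normalize_by_sqrt_length = FALSE) {
  k <- neff(msa, threshold)
  if (normalize_by_sqrt_length) k / sqrt(msa$width) else as.numeric(k)
}

#' Write an alignment as aligned FASTA
#'
#' @param msa An [msa()].
#' @param path Output file.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  writeLines(as.vector(rbind(sprintf(">seq%d", seq_len(msa$n)),
                             msa$sequences)), path)
  invisible(path)
}
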