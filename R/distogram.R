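#' Distance bin schemes
#'
#' A bin scheme partitions the Cβ–Cβ distance axis into 20 half-open
#' intervals `[lo, hi)`.  The default scheme is the one used by the
#' distance predictor's 20-channel softmax head: a first bin 3.5–4.5 Å,
#' seven 0.5-Å bins from 4.5 to 8 Å, eleven 1-Å bins from 8 to 19 Å, and a
#' final unbounded bin for everything at or beyond 19 Å.  Bin centers are
#' interval midpoints; the unbounded last bin carries a sentinel center
#' (default 20 Å) used only for filtering, never for error arithmetic.
#'
#' @param edges Numeric vector of 21 strictly increasing boundaries in Å;
#'   the last must be `Inf`.
#' @param last_center Sentinel center for the unbounded final bin, in Å.
#' @return An object of class `bin_scheme` with elements `edges` (length
#'   21), `centers` (length 20), `n_bins` (20).
#' @examples
#' sc <- default_bin_scheme()
#' sc$edges[1:3]          # 3.5 4.5 5.0
#' bin_index(sc, 8.3)     # the [8, 9) bin
#' @export
bin_scheme <- function(edges, last_center = 20) {
  edges <- as.numeric(edges)
  if (length(edges) != 21L)
    stop("a bin scheme needs exactly 21 edges (20 intervals)")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (!is.infinite(edges[21L])) stop("the final edge must be +Inf")
  centers <- (edges[-21L] + edges[-1L]) / 2
  centers[20L] <- last_center
  structure(list(edges = edges, centers = centers, n_bins = 20L),
            class = "bin_scheme")
}

#' @rdname bin_scheme
#' @export
default_bin_scheme <- function() {
  bin_scheme(c(3.5, seq(4.5, 8, by = 0.5), seq(9, 19, by = 1), Inf))
}

#' @rdname bin_scheme
#' @param scheme A `bin_scheme`.
#' @param d Distances in Å (vectorized).  Distances below the first edge
#'   are clamped into the first bin.
#' @export
bin_index <- function(scheme, d) {
  stopifnot(inherits(scheme, "bin_scheme"))
  idx <- findInterval(d, scheme$edges, rightmost.closed = FALSE)
  pmin(pmax(idx, 1L), scheme$n_bins)
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("Distance bin scheme: %d bins, %.1f Å to %.1f Å then unbounded\n",
              x$n_bins, x$edges[1], x$edges[x$n_bins]))
  invisible(x)
}

#' Distogram objects
#'
#' A distogram stores, for every residue pair, a likelihood distribution
#' over the 20 distance bins of a [bin_scheme()].  Likelihoods are held in
#' an `L x L x 20` array; every off-diagonal pair's 20 values are
#' non-negative and sum to one.
#'
#' @param likelihoods `L x L x 20` array of per-pair bin likelihoods.
#' @param scheme A [bin_scheme()]; defaults to [default_bin_scheme()].
#' @param check Validate normalization and symmetry-compatible shape.
#' @return An object of class `distogram` with elements `length`,
#'   `likelihoods`, `scheme`.
#' @export
distogram <- function(likelihoods, scheme = default_bin_scheme(),
                      check = TRUE) {
  dm <- dim(likelihoods)
  if (length(dm) != 3L || dm[1] != dm[2] || dm[3] != scheme$n_bins)
    stop("likelihoods must be an L x L x 20 array")
  L <- dm[1]
  if (check && L > 1) {
    off <- which(upper.tri(matrix(0, L, L)) | lower.tri(matrix(0, L, L)))
    sums <- apply(likelihoods, c(1, 2), sum)[off]
    if (any(likelihoods < -1e-12))
      stop("likelihoods must be non-negative")
    if (any(abs(sums - 1) > 1e-6))
      stop("off-diagonal pair likelihoods must sum to 1 (tolerance 1e-6)")
  }
  structure(list(length = L, likelihoods = likelihoods, scheme = scheme),
            class = "distogram")
}

#' @export
print.distogram <- function(x, ...) {
  cat(sprintf("Distogram: L = %d residues, %d distance bins\n",
              x$length, x$scheme$n_bins))
  invisible(x)
}

#' Symmetrize raw distance-predictor scores into a distogram
#'
#' The distance predictor emits independent raw (pre-softmax) scores for
#' the upper and lower triangles.  The canonical distogram applies, per
#' pair, a softmax over the 20 channels of the sum of the raw-score tensor
#' and its transpose, which both enforces symmetry of the output and
#' ensembles the two independent triangle predictions.
#'
#' @param logits `L x L x 20` array of finite raw scores.
#' @param scheme A [bin_scheme()].
#' @return A symmetric [distogram()].
#' @examples
#' lg <- array(0, c(4, 4, 20))
#' d <- symmetrize(lg)              # uniform 1/20 everywhere
#' @export
symmetrize <- function(logits, scheme = default_bin_scheme()) {
  if (!all(is.finite(logits))) stop("logits must be finite")
  dm <- dim(logits)
  if (length(dm) != 3L || dm[1] != dm[2] || dm[3] != scheme$n_bins)
    stop("logits must be an L x L x 20 array")
  s <- logits + aperm(logits, c(2, 1, 3))
  # per-pair softmax over channel axis, stabilized
  mx <- apply(s, c(1, 2), max)
  e <- exp(s - array(mx, dm))
  tot <- apply(e, c(1, 2), sum)
  lik <- e / array(tot, dm)
  distogram(lik, scheme, check = FALSE)
}

#' Convert a distogram to a contact map
#'
#' The contact probability of a pair is the sum of its likelihoods over
#' all bins wholly below the cutoff (8 Å by default, i.e. the first 8
#' bins of the default scheme).  A contact is conventionally called
#' present when this probability reaches 0.5.
#'
#' @param d A [distogram()].
#' @param cutoff Contact cutoff in Å; must coincide with a bin edge.
#' @return An object of class `contact_map`: `length`, `prob` (L x L,
#'   symmetric, zero diagonal), `cutoff`.
#' @export
distogram_to_contacts <- function(d, cutoff = 8) {
  stopifnot(inherits(d, "distogram"))
  edges <- d$scheme$edges
  k <- match(cutoff, edges)
  if (is.na(k)) stop("cutoff must coincide with a bin edge")
  n_below <- k - 1L                      # bins wholly below the cutoff
  if (n_below < 1L) stop("cutoff leaves no bins below it")
  prob <- apply(d$likelihoods[, , seq_len(n_below), drop = FALSE],
                c(1, 2), sum)
  diag(prob) <- 0
  prob <- pmin(pmax((prob + t(prob)) / 2, 0), 1)
  structure(list(length = d$length, prob = prob, cutoff = cutoff),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: L = %d, cutoff %.1f Å, %d pairs at p >= 0.5\n",
              x$length, x$cutoff,
              sum(x$prob[upper.tri(x$prob)] >= 0.5)))
  invisible(x)
}

#' Rank predicted contacts
#'
#' Returns the `n` highest-probability residue pairs, excluding
#' short-range pairs closer in sequence than `min_separation`.  Ties are
#' broken lexicographically by `(i, j)` so ranking is deterministic.
#'
#' @param cm A `contact_map`.
#' @param n Number of pairs requested (the customary choice is the
#'   sequence length L).
#' @param min_separation Minimum |i - j| for a pair to be ranked.
#' @return A data.frame with columns `i`, `j` (1-based, `i < j`), `prob`,
#'   sorted by probability descending.
#' @export
top_contacts <- function(cm, n, min_separation = 5) {
  stopifnot(inherits(cm, "contact_map"), n >= 1)
  L <- cm$length
  idx <- which(upper.tri(cm$prob), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= min_separation
  idx <- idx[keep, , drop = FALSE]
  p <- cm$prob[idx]
  ord <- order(-p, idx[, 1], idx[, 2])
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(i = idx[ord, 1], j = idx[ord, 2], prob = p[ord],
             row.names = NULL)
}

#' Distance-prediction error statistics
#'
#' For every pair whose maximum-likelihood bin center lies below
#' `max_pred` (15 Å by default), the prediction error is the absolute
#' difference between that bin's center and the native Cβ–Cβ distance.
#' Pairs whose maximum-likelihood bin is at or beyond the threshold
#' (including the unbounded final bin, via its sentinel center) are
#' excluded.
#'
#' @param d A [distogram()].
#' @param native A `fold_model` of the same length (see [make_toy_fold()]
#'   or [read_pdb_model()]).
#' @param max_pred Exclusion threshold on the predicted (max-likelihood
#'   bin center) distance, Å.
#' @param min_separation Minimum |i - j| for inclusion.
#' @return A list: `mean`, `median` of absolute errors (NA when empty)
#'   and `count` of contributing pairs.
#' @export
distance_error_stats <- function(d, native, max_pred = 15,
                                 min_separation = 2) {
  stopifnot(inherits(d, "distogram"))
  if (native$length != d$length)
    stop("native structure length does not match the distogram")
  L <- d$length
  cbm <- cb_distance_matrix(native)
  maxbin <- apply(d$likelihoods, c(1, 2), which.max)
  centers <- d$scheme$centers
  idx <- which(upper.tri(maxbin), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= min_separation, , drop = FALSE]
  pred <- centers[maxbin[idx]]
  keep <- pred < max_pred
  err <- abs(pred[keep] - cbm[idx[keep, , drop = FALSE]])
  list(mean = if (length(err)) mean(err) else NA_real_,
       median = if (length(err)) stats::median(err) else NA_real_,
       count = length(err))
}

#' Distogram serialization
#'
#' Two on-disk variants share a header carrying `L` and the 21 bin edges.
#' The text variant is TSV: header lines starting `#`, then one row per
#' ordered pair `i j` (1-based) with 20 likelihood columns.  The binary
#' variant stores the same content as doubles after a short magic string.
#' [read_distogram()] detects the variant automatically.
#'
#' @param d A [distogram()].
#' @param path Output file.
#' @param format `"tsv"` or `"bin"`.
#' @export
write_distogram <- function(d, path, format = c("tsv", "bin")) {
  format <- match.arg(format)
  stopifnot(inherits(d, "distogram"))
  L <- d$length
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("#distogram\tL=%d", L),
                 paste0("#edges\t", paste(d$scheme$edges, collapse = "\t"))),
               con)
    idx <- expand.grid(j = seq_len(L), i = seq_len(L))[, c("i", "j")]
    mat <- matrix(aperm(d$likelihoods, c(3, 2, 1)), ncol = 20, byrow = TRUE)
    utils::write.table(cbind(idx, signif(mat, 9)), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("DGRAM1", con, eos = NULL)
    writeBin(as.integer(L), con, size = 4L)
    writeBin(as.double(d$scheme$edges), con, size = 8L)
    writeBin(as.double(aperm(d$likelihoods, c(3, 2, 1))), con, size = 8L)
  }
  invisible(path)
}

#' @rdname write_distogram
#' @export
read_distogram <- function(path) {
  con <- file(path, "rb")
  magic <- suppressWarnings(rawToChar(readBin(con, "raw", 6L)))
  if (identical(magic, "DGRAM1")) {
    L <- readBin(con, "integer", 1L, size = 4L)
    edges <- readBin(con, "double", 21L, size = 8L)
    vals <- readBin(con, "double", L * L * 20L, size = 8L)
    close(con)
    lik <- aperm(array(vals, c(20L, L, L)), c(3, 2, 1))
    return(distogram(lik, bin_scheme(edges), check = FALSE))
  }
  close(con)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  L <- as.integer(sub(".*L=", "", hdr[1]))
  edges <- as.numeric(strsplit(hdr[2], "\t")[[1]][-1])
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            sep = "\t")
  lik <- array(0, c(L, L, 20L))
  ij <- as.matrix(body[, 1:2])
  for (k in 1:20) lik[cbind(ij, k)] <- body[[k + 2]]
  distogram(lik, bin_scheme(edges), check = FALSE)
}

#' Export a contact map in CASP RR dialect
#'
#' Writes lines `i j 0 8 p` (1-based indices, probability descending).
#'
#' @param cm A `contact_map`.
#' @param path Output file.
#' @param n Number of top contacts to write (default: all eligible).
#' @param min_separation Minimum sequence separation.
#' @export
write_casp_rr <- function(cm, path, n = Inf, min_separation = 5) {
  tc <- top_contacts(cm, n = min(n, cm$length^2), min_separation)
  writeLines(sprintf("%d %d 0 %g %.6f", tc$i, tc$j, cm$cutoff, tc$prob),
             path)
  invisible(path)
}
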