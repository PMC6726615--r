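#' Accrete distance bins into a bound interval
#'
#' Bound derivation starts from the maximum-likelihood bin and repeatedly
#' extends the contiguous bin interval by whichever adjacent bin (left or
#' right) carries the higher likelihood, until the cumulative likelihood
#' reaches the threshold.  The unbounded final bin never participates: no
#' bound is emitted when it is the maximum-likelihood bin, and accretion
#' never extends into it, so every emitted upper bound stays at or below
#' the last finite edge (19 Å in the default scheme).  Wider intervals
#' for flatter distributions mean that less confident predictions yield
#' looser bounds.  When left and right neighbours tie, the interval
#' extends left, toward shorter distances.
#'
#' @param p Numeric vector of 20 bin likelihoods summing to 1.
#' @param scheme A [bin_scheme()].
#' @param threshold Cumulative likelihood target in (0, 1]; 0.4 by
#'   default.
#' @return `NULL` when the maximum-likelihood bin is the final bin,
#'   otherwise a list `lower`, `upper` (Å) and `cum_likelihood`.
#' @examples
#' p <- numeric(20); p[9] <- 1            # all mass in [8, 9)
#' accrete_bounds(p, default_bin_scheme())
#' @export
accrete_bounds <- function(p, scheme = default_bin_scheme(),
                           threshold = 0.4) {
  if (length(p) != scheme$n_bins) stop("p must have one entry per bin")
  if (abs(sum(p) - 1) > 1e-6) stop("bin likelihoods must sum to 1")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  nb <- scheme$n_bins
  k <- which.max(p)
  if (k == nb) return(NULL)
  lo <- hi <- k
  cum <- p[k]
  threshold <- threshold - 1e-9      # exact-sum cases meet the threshold
  while (cum < threshold) {
    left <- if (lo > 1L) p[lo - 1L] else -Inf
    right <- if (hi < nb - 1L) p[hi + 1L] else -Inf   # final bin excluded
    if (is.infinite(left) && is.infinite(right)) break
    if (left >= right) { lo <- lo - 1L; cum <- cum + p[lo] }
    else { hi <- hi + 1L; cum <- cum + p[hi] }
  }
  # threshold unreachable without the unbounded final bin: no usable bound
  if (cum < threshold) return(NULL)
  list(lower = scheme$edges[lo], upper = scheme$edges[hi + 1L],
       cum_likelihood = cum)
}

#' Derive distance bounds from a distogram
#'
#' Applies [accrete_bounds()] to every unordered residue pair at sequence
#' separation `min_separation` or more.  Bounds reference Cβ atoms, or Cα
#' for glycine.
#'
#' @param d A symmetric [distogram()].
#' @param threshold Cumulative likelihood threshold (default 0.4).
#' @param min_separation Minimum |i - j|.
#' @return A data.frame of class `distance_bounds` with columns `i`, `j`
#'   (1-based, `i < j`), `lower`, `upper` (Å), `cum_likelihood`.
#' @export
distogram_to_bounds <- function(d, threshold = 0.4, min_separation = 2) {
  stopifnot(inherits(d, "distogram"))
  L <- d$length
  out <- vector("list", L * (L - 1L) / 2L)
  n <- 0L
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      if (j - i < min_separation) next
      b <- accrete_bounds(d$likelihoods[i, j, ], d$scheme, threshold)
      if (is.null(b)) next
      n <- n + 1L
      out[[n]] <- c(i, j, b$lower, b$upper, b$cum_likelihood)
    }
  }
  res <- if (n) as.data.frame(do.call(rbind, out[seq_len(n)]))
         else data.frame(matrix(numeric(0), ncol = 5))
  names(res) <- c("i", "j", "lower", "upper", "cum_likelihood")
  class(res) <- c("distance_bounds", "data.frame")
  res
}

#' Derive hydrogen-bond restraints from a donor/acceptor likelihood map
#'
#' The H-bond map is directional: rows index backbone amide-N donors,
#' columns carbonyl-O acceptors, and the map is not expected to be
#' symmetric.  Every cell at or above the likelihood threshold (0.85 by
#' default) becomes one restraint; the restraint geometry is a
#' flat-bottom well on the donor-N to acceptor-O distance, with default
#' limits 2.7–3.2 Å as observed in highly resolved crystal structures.
#'
#' @param map L x L likelihood matrix in \[0, 1\].
#' @param threshold Emission threshold (default 0.85).
#' @param target N–O flat-bottom limits in Å, length 2.
#' @param min_separation Minimum |donor - acceptor| sequence separation.
#' @return A data.frame of class `hbond_restraints` with columns `donor`,
#'   `acceptor`, `likelihood`, `no_lower`, `no_upper`.
#' @export
hbond_map_to_restraints <- function(map, threshold = 0.85,
                                    target = c(2.7, 3.2),
                                    min_separation = 2) {
  if (any(map < 0 | map > 1)) stop("map values must lie in [0, 1]")
  idx <- which(map >= threshold, arr.ind = TRUE)
  if (nrow(idx))
    idx <- idx[abs(idx[, 1] - idx[, 2]) >= min_separation, , drop = FALSE]
  res <- data.frame(donor = as.integer(idx[, 1]),
                    acceptor = as.integer(idx[, 2]),
                    likelihood = map[idx],
                    no_lower = rep(target[1], nrow(idx)),
                    no_upper = rep(target[2], nrow(idx)))
  res <- res[order(res$donor, res$acceptor), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("hbond_restraints", "data.frame")
  res
}

#' Derive dihedral restraints from torsion predictions
#'
#' Keeps φ and ψ; ω predictions are discarded (the upstream predictors
#' show no skill on rare cis-peptides, so ω carries no usable restraint
#' information).  Each restraint's deviation is the predictor's error
#' estimate, floored at `floor` radians.
#'
#' @param torsions A data.frame/list with elements `phi`, `psi` (radians,
#'   per residue; NA allowed at chain termini) and matching `phi_err`,
#'   `psi_err` error estimates.  `omega`/`omega_err` are ignored.
#' @param floor Minimum deviation in radians (default 0.087, i.e. 5°).
#' @return A data.frame of class `torsion_restraints` with columns
#'   `residue`, `angle` ("phi"/"psi"), `target`, `deviation` (radians).
#' @export
torsions_to_restraints <- function(torsions, floor = 0.087) {
  rows <- list()
  for (ang in c("phi", "psi")) {
    v <- torsions[[ang]]
    if (is.null(v)) next
    err <- torsions[[paste0(ang, "_err")]]
    if (is.null(err)) err <- rep(0, length(v))
    ok <- which(!is.na(v))
    if (length(ok))
      rows[[ang]] <- data.frame(residue = ok, angle = ang,
                                target = v[ok],
                                deviation = pmax(err[ok], floor))
  }
  res <- if (length(rows)) do.call(rbind, rows)
         else data.frame(residue = integer(0), angle = character(0),
                         target = numeric(0), deviation = numeric(0))
  res <- res[order(res$residue, res$angle), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("torsion_restraints", "data.frame")
  res
}

#' Bundle restraints into a restraint set
#'
#' @param bounds A `distance_bounds` data.frame ([distogram_to_bounds()]).
#' @param hbonds An `hbond_restraints` data.frame.
#' @param torsions A `torsion_restraints` data.frame.
#' @param sequence One-letter amino-acid sequence string (drives the
#'   Cβ/Cα choice for glycine).
#' @param meta Named list of provenance metadata (thresholds, iteration).
#' @return An object of class `restraint_set`.
#' @export
restraint_set <- function(bounds = NULL, hbonds = NULL, torsions = NULL,
                          sequence, meta = list()) {
  L <- nchar(sequence)
  empty_b <- structure(data.frame(i = numeric(0), j = numeric(0),
                                  lower = numeric(0), upper = numeric(0),
                                  cum_likelihood = numeric(0)),
                       class = c("distance_bounds", "data.frame"))
  if (is.null(bounds)) bounds <- empty_b
  if (is.null(hbonds))
    hbonds <- hbond_map_to_restraints(matrix(0, max(L, 1), max(L, 1)))
  if (is.null(torsions)) torsions <- torsions_to_restraints(list())
  for (v in list(bounds$i, bounds$j, hbonds$donor, hbonds$acceptor,
                 torsions$residue))
    if (length(v) && (any(v < 1) || any(v > L)))
      stop("restraint residue indices must lie in 1..L")
  structure(list(bounds = bounds, hbonds = hbonds, torsions = torsions,
                 sequence = sequence, length = L, meta = meta),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf(
    "Restraint set (L = %d): %d distance bounds, %d H-bonds, %d torsions\n",
    x$length, nrow(x$bounds), nrow(x$hbonds), nrow(x$torsions)))
  invisible(x)
}

# circular difference a - b wrapped to (-pi, pi]
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Count restraints satisfied by a model
#'
#' A distance bound is satisfied when the model's Cβ–Cβ (Cα for glycine)
#' distance lies within `[lower, upper]`; an H-bond when the donor N to
#' acceptor O distance is at most 3.5 Å; a torsion when the absolute
#' circular difference between the model angle and the target is at most
#' the restraint's deviation.
#'
#' @param rs A [restraint_set()].
#' @param model A `fold_model` of matching length.
#' @param hbond_cutoff N–O satisfaction cutoff in Å.
#' @return A data.frame with rows `bounds`, `hbonds`, `torsions` and
#'   columns `satisfied`, `total`, `fraction` (NA for empty categories).
#' @export
count_satisfied <- function(rs, model, hbond_cutoff = 3.5) {
  stopifnot(inherits(rs, "restraint_set"))
  if (model$length != rs$length)
    stop("model length does not match the restraint set")
  cbm <- cb_distance_matrix(model)
  b <- rs$bounds
  d <- cbm[cbind(b$i, b$j)]
  b_sat <- sum(d >= b$lower & d <= b$upper)
  h <- rs$hbonds
  h_sat <- if (nrow(h)) {
    dn <- sqrt(rowSums((model$xyz$N[h$donor, , drop = FALSE] -
                        model$xyz$O[h$acceptor, , drop = FALSE])^2))
    sum(dn <= hbond_cutoff)
  } else 0L
  t <- rs$torsions
  t_sat <- if (nrow(t)) {
    ang <- backbone_torsions(model)
    mv <- ifelse(t$angle == "phi", ang$phi[t$residue], ang$psi[t$residue])
    sum(abs(circ_diff(mv, t$target)) <= t$deviation, na.rm = TRUE)
  } else 0L
  tot <- c(nrow(b), nrow(h), nrow(t))
  sat <- c(b_sat, h_sat, t_sat)
  data.frame(row.names = c("bounds", "hbonds", "torsions"),
             satisfied = sat, total = tot,
             fraction = ifelse(tot > 0, sat / tot, NA_real_))
}

#' Serialize a restraint set
#'
#' Two dialects: `"cns-tbl"` writes NOE-style distance lines
#' `assign (resid i and name X) (resid j and name Y) d dminus dplus`
#' with `d = (lower+upper)/2` and the flat-bottom half-widths, plus an
#' H-bond NOE section and CNS dihedral-syntax torsion restraints;
#' `"native-json"` is a lossless round-trip format read back by
#' [read_restraints()].  Atom names are CB, or CA for glycine.  All
#' residue indices are 1-based.
#'
#' @param rs A [restraint_set()].
#' @param path Output file, or NULL to return the text.
#' @param dialect `"cns-tbl"` or `"native-json"`.
#' @return The serialized text, invisibly when written to a file.
#' @export
write_restraints <- function(rs, path = NULL,
                             dialect = c("cns-tbl", "native-json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rs, "restraint_set"))
  if (dialect == "cns-tbl") {
    aa <- strsplit(rs$sequence, "")[[1]]
    atom <- ifelse(aa == "G", "CA", "CB")
    b <- rs$bounds
    lines <- c("! distance restraints (NOE-like flat-bottom bounds)")
    if (nrow(b)) {
      d <- (b$lower + b$upper) / 2
      lines <- c(lines, sprintf(
        "assign (resid %d and name %s) (resid %d and name %s) %.2f %.2f %.2f",
        b$i, atom[b$i], b$j, atom[b$j], d, d - b$lower, b$upper - d))
    }
    h <- rs$hbonds
    lines <- c(lines, "! hydrogen-bond restraints (donor N to acceptor O)")
    if (nrow(h)) {
      d <- (h$no_lower + h$no_upper) / 2
      lines <- c(lines, sprintf(
        "assign (resid %d and name N) (resid %d and name O) %.2f %.2f %.2f",
        h$donor, h$acceptor, d, d - h$no_lower, h$no_upper - d))
    }
    t <- rs$torsions
    lines <- c(lines, "! dihedral restraints")
    if (nrow(t)) {
      sel <- function(r, a) {
        if (a == "phi") sprintf(
          "(resid %d and name c) (resid %d and name n) (resid %d and name ca) (resid %d and name c)",
          r - 1L, r, r, r)
        else sprintf(
          "(resid %d and name n) (resid %d and name ca) (resid %d and name c) (resid %d and name n)",
          r, r, r, r + 1L)
      }
      lines <- c(lines, vapply(seq_len(nrow(t)), function(k) sprintf(
        "assign %s 1.0 %.2f %.2f 2",
        sel(t$residue[k], t$angle[k]),
        t$target[k] * 180 / pi, t$deviation[k] * 180 / pi),
        character(1)))
    }
    txt <- paste(lines, collapse = "\n")
  } else {
    txt <- jsonlite::toJSON(
      list(sequence = rs$sequence, meta = rs$meta,
           bounds = as.data.frame(unclass(rs$bounds)),
           hbonds = as.data.frame(unclass(rs$hbonds)),
           torsions = as.data.frame(unclass(rs$torsions))),
      dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  x <- jsonlite::fromJSON(path)
  tor <- as.data.frame(x$torsions)
  if (!nrow(tor)) tor <- NULL
  restraint_set(bounds = if (length(x$bounds$i)) as.data.frame(x$bounds),
                hbonds = if (length(x$hbonds$donor)) {
                  h <- as.data.frame(x$hbonds)
                  class(h) <- c("hbond_restraints", "data.frame")
                  h
                },
                torsions = if (!is.null(tor)) {
                  class(tor) <- c("torsion_restraints", "data.frame")
                  tor
                },
                sequence = x$sequence, meta = as.list(x$meta))
}
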