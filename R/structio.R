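#' Backbone fold models
#'
#' A `fold_model` stores per-residue backbone coordinates (N, CA, C, O and
#' CB; CB is absent for glycine) together with the one-letter sequence.
#'
#' @param sequence One-letter amino-acid sequence string.
#' @param N,CA,C,O,CB L x 3 coordinate matrices in Å; glycine CB rows are
#'   set to NA.
#' @param energy Optional energy breakdown attached by the refiner.
#' @return An object of class `fold_model`.
#' @export
fold_model <- function(sequence, N, CA, C, O, CB, energy = NULL) {
  L <- nchar(sequence)
  xyz <- list(N = N, CA = CA, C = C, O = O, CB = CB)
  for (nm in names(xyz)) {
    if (!is.matrix(xyz[[nm]]) || nrow(xyz[[nm]]) != L ||
        ncol(xyz[[nm]]) != 3)
      stop(sprintf("%s must be an L x 3 matrix", nm))
  }
  gly <- strsplit(sequence, "")[[1]] == "G"
  xyz$CB[gly, ] <- NA_real_
  structure(list(sequence = sequence, length = L, xyz = xyz,
                 energy = energy),
            class = "fold_model")
}

#' @export
print.fold_model <- function(x, ...) {
  cat(sprintf("Fold model: %d residues", x$length))
  if (!is.null(x$energy))
    cat(sprintf(", total energy %.2f%s", x$energy$total,
                if (isTRUE(x$energy$unconverged)) " (unconverged)" else ""))
  cat("\n")
  invisible(x)
}

#' Cβ–Cβ distance matrix of a model
#'
#' Uses the Cα position for glycine.  The matrix is symmetric with a zero
#' diagonal and is invariant to rigid motion of the model.
#'
#' @param m A [fold_model()].
#' @return An L x L matrix of distances in Å.
#' @export
cb_distance_matrix <- function(m) {
  cb <- m$xyz$CB
  miss <- is.na(cb[, 1])
  cb[miss, ] <- m$xyz$CA[miss, ]
  out <- as.matrix(stats::dist(cb))
  dimnames(out) <- NULL
  out
}

#' Read and write models as PDB
#'
#' Models are written as standard ATOM records (chain A, 1-based resSeq,
#' occupancy 1.00); the B-factor column carries an optional per-residue
#' score.  Reading accepts any single-chain PDB with N, CA, C and O
#' atoms; CB is taken when present and synthesized from ideal geometry
#' otherwise, and residues missing CA are dropped with a warning.  I/O is
#' delegated to the bio3d package.
#'
#' @param path PDB file path.
#' @return [read_pdb_model()]: a [fold_model()]. [write_pdb_model()]: the
#'   path, invisibly.
#' @export
read_pdb_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (!nrow(at)) stop("no ATOM records found")
  at <- at[at$chain == at$chain[1], ]
  res_ids <- unique(at$resno)
  aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  keep <- logical(length(res_ids))
  seqc <- character(length(res_ids))
  coords <- list()
  for (nm in c("N", "CA", "C", "O", "CB"))
    coords[[nm]] <- matrix(NA_real_, length(res_ids), 3)
  for (k in seq_along(res_ids)) {
    rr <- at[at$resno == res_ids[k], ]
    if (!"CA" %in% rr$elety) next
    keep[k] <- TRUE
    a1 <- aa3to1[rr$resid[1]]
    seqc[k] <- if (is.na(a1)) "X" else a1
    for (nm in c("N", "CA", "C", "O", "CB")) {
      hit <- which(rr$elety == nm)[1]
      if (!is.na(hit))
        coords[[nm]][k, ] <- as.numeric(rr[hit, c("x", "y", "z")])
    }
  }
  if (any(!keep))
    warning(sprintf("%d residue(s) without CA dropped", sum(!keep)))
  if (!any(keep)) stop("no usable residues (empty chain)")
  for (nm in names(coords)) coords[[nm]] <- coords[[nm]][keep, , drop = FALSE]
  sq <- paste(seqc[keep], collapse = "")
  m <- fold_model(sq, coords$N, coords$CA, coords$C, coords$O,
                  ifelse_matrix(coords$CB, coords$CA))
  # restore genuine CB where the file had them; synthesize the rest
  have_cb <- !is.na(coords$CB[, 1])
  synth <- synth_cb(m)
  cb <- synth
  cb[have_cb, ] <- coords$CB[have_cb, ]
  fold_model(sq, coords$N, coords$CA, coords$C, coords$O, cb)
}

# placeholder-fill NA rows of a with rows of b (internal)
ifelse_matrix <- function(a, b) {
  miss <- is.na(a[, 1])
  a[miss, ] <- b[miss, ]
  a
}

# ideal-geometry CB positions for every residue of a model (internal)
synth_cb <- function(m) {
  L <- m$length
  cb <- matrix(NA_real_, L, 3)
  for (i in seq_len(L))
    cb[i, ] <- place_atom(m$xyz$C[i, ], m$xyz$N[i, ], m$xyz$CA[i, ],
                          IDEAL$b_ca_cb, IDEAL$a_n_ca_cb,
                          IDEAL$t_c_n_ca_cb)
  cb
}

#' @rdname read_pdb_model
#' @param m A [fold_model()].
#' @param b_factor Optional numeric vector (length L) written to the
#'   B-factor column, e.g. a per-residue restraint-violation score.
#' @export
write_pdb_model <- function(m, path, b_factor = NULL) {
  stopifnot(inherits(m, "fold_model"))
  L <- m$length
  if (is.null(b_factor)) b_factor <- rep(0, L)
  aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
              X = "UNK")
  aa <- strsplit(m$sequence, "")[[1]]
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(L)) {
    for (nm in c("N", "CA", "C", "O", "CB")) {
      xyz <- m$xyz[[nm]][i, ]
      if (any(is.na(xyz))) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, nm, aa1to3[aa[i]], i, xyz[1], xyz[2], xyz[3], 1.00,
        b_factor[i], substr(nm, 1, 1)))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Optimal superposition of paired coordinate sets
#'
#' Least-squares rigid superposition (Kabsch algorithm) of `a` onto `b`
#' using a proper rotation only (determinant +1, never a reflection).
#'
#' @param a,b n x 3 matrices of paired coordinates, n >= 3.
#' @return A list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `a %*% rotation + translation`), `rmsd` in Å and `n`.
#' @export
kabsch <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || nrow(a) != nrow(b) || nrow(a) < 3)
    stop("kabsch needs matched coordinate sets with at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(a0, b0))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  if (det(rot) < 0) stop("degenerate configuration: no proper rotation")
  fit <- a0 %*% rot
  rmsd <- sqrt(mean(rowSums((fit - b0)^2)))
  list(rotation = rot, translation = cb - as.numeric(ca %*% rot),
       rmsd = rmsd, n = nrow(a))
}

#' TM-score between two models of equal length
#'
#' Standard length-normalized structural similarity on Cα atoms with a
#' fixed 1:1 residue correspondence: `d0 = 1.24 (L - 15)^(1/3) - 1.8`,
#' floored at 0.5 for short chains, and the score maximized over rigid
#' superpositions found by fragment-seeded iterative Kabsch refinement.
#' The score is 1 for identical structures, is invariant to rigid motion
#' of either argument, and (because only proper rotations are used) drops
#' below 1 for mirror images of chiral structures.
#'
#' @param model,reference `fold_model`s of equal length (the score is
#'   normalized by the reference length).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference) {
  a <- model$xyz$CA; b <- reference$xyz$CA
  if (nrow(a) != nrow(b))
    stop("tm_score requires equal-length models (no structural alignment)")
  L <- nrow(b)
  d0 <- max(0.5, 1.24 * max(L - 15, 0)^(1 / 3) - 1.8)
  tm_of <- function(rot, tra) {
    d <- sqrt(rowSums((sweep(a %*% rot, 2, tra, "+") - b)^2))
    sum(1 / (1 + (d / d0)^2)) / L
  }
  best <- 0
  frags <- unique(pmax(3, c(L, ceiling(L / 2), ceiling(L / 4), 4)))
  seeds <- list()
  for (fl in frags) {
    starts <- unique(c(seq(1, max(1, L - fl + 1), by = max(1, fl %/% 2)),
                       L - fl + 1))
    for (s in starts) seeds[[length(seeds) + 1]] <- s:(s + fl - 1)
  }
  if (L <= 10)   # short chains: seed every residue triple as well
    seeds <- c(seeds, utils::combn(L, 3, simplify = FALSE))
  for (sel in seeds) {
    for (iter in 1:20) {
      k <- tryCatch(kabsch(a[sel, , drop = FALSE], b[sel, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(k)) break
      tm <- tm_of(k$rotation, k$translation)
      best <- max(best, tm)
      d <- sqrt(rowSums((sweep(a %*% k$rotation, 2, k$translation, "+") -
                           b)^2))
      cut <- d0
      repeat {
        new_sel <- which(d < cut)
        if (length(new_sel) >= 3) break
        cut <- cut + 0.5
      }
      if (identical(new_sel, sel)) break
      sel <- new_sel
    }
  }
  best
}

#' Geometric backbone hydrogen-bond detection
#'
#' A hydrogen bond is called between residues i (donor) and j (acceptor)
#' when the donor amide N of residue i lies within `cutoff` of the
#' carbonyl O of residue j and the two residues are at least
#' `min_separation` apart in sequence.  The output is directional: (i, j)
#' and (j, i) are distinct.
#'
#' @param m A [fold_model()].
#' @param cutoff N–O distance cutoff in Å (default 3.5).
#' @param min_separation Minimum |i - j|.
#' @return A data.frame with columns `donor`, `acceptor`, `distance`.
#' @export
detect_hbonds <- function(m, cutoff = 3.5, min_separation = 2) {
  L <- m$length
  N <- m$xyz$N; O <- m$xyz$O
  d2 <- outer(rowSums(N^2), rowSums(O^2), "+") - 2 * N %*% t(O)
  d <- sqrt(pmax(d2, 0))
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  idx <- which(d <= cutoff & sep >= min_separation, arr.ind = TRUE)
  out <- data.frame(donor = as.integer(idx[, 1]),
                    acceptor = as.integer(idx[, 2]),
                    distance = d[idx])
  out <- out[order(out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision of predicted hydrogen bonds against a structure
#'
#' Fraction of predicted donor-to-acceptor pairs that are geometrically
#' present in the model according to [detect_hbonds()].
#'
#' @param hbonds An `hbond_restraints` data.frame (or any data.frame with
#'   `donor` and `acceptor` columns).
#' @param m A [fold_model()].
#' @param cutoff,min_separation Passed to [detect_hbonds()].
#' @return Fraction in \[0, 1\], or NA when no H-bonds were predicted.
#' @export
hbond_precision <- function(hbonds, m, cutoff = 3.5, min_separation = 2) {
  if (!nrow(hbonds)) return(NA_real_)
  det <- detect_hbonds(m, cutoff, min_separation)
  pred <- paste(hbonds$donor, hbonds$acceptor)
  mean(pred %in% paste(det$donor, det$acceptor))
}
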