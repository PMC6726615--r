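#' Builder configuration
#'
#' Controls the restrained model builder: the simulated-annealing
#' schedule (geometric cooling from `temp_start` to `temp_end` over
#' `n_stages` stages, each running up to `moves_per_stage` minimizer
#' iterations), the relative weights of the energy terms, and the
#' ensemble size.
#'
#' @param temp_start,temp_end Annealing temperatures (arbitrary energy
#'   units).
#' @param n_stages Number of temperature stages (>= 1).
#' @param moves_per_stage Minimizer iteration budget per stage.
#' @param w_distance,w_hbond,w_torsion,w_geometry,w_chirality,w_clash
#'   Non-negative term weights.
#' @param center_pull Relative weight of a weak quadratic pull toward
#'   each restraint well's centre (lifts flat-bottom plateau degeneracy
#'   during minimization; 0 disables it).
#' @param clash_floor Non-bonded atom-pair distance floor in Å.
#' @param mirror_mode `"both"` refines each embedding in both hands and
#'   keeps the lower-energy one; `"single"` refines only the unmirrored
#'   embedding.
#' @param ensemble_size Models per ensemble (default 20).
#' @param energy_ceiling Total energy above which a refined model is
#'   flagged unconverged.
#' @param rng_seed Integer seed.
#' @return An object of class `builder_config`.
#' @export
builder_config <- function(temp_start = 2.0, temp_end = 0.02,
                           n_stages = 12L, moves_per_stage = 60L,
                           w_distance = 1, w_hbond = 1, w_torsion = 0.5,
                           w_geometry = 10, w_chirality = 2, w_clash = 2,
                           center_pull = 0.02,
                           clash_floor = 2.2,
                           mirror_mode = c("both", "single"),
                           ensemble_size = 20L,
                           energy_ceiling = 500, rng_seed = 1L) {
  mirror_mode <- match.arg(mirror_mode)
  stopifnot(n_stages >= 1, moves_per_stage >= 1, ensemble_size >= 1,
            temp_start > 0, temp_end > 0,
            w_distance >= 0, w_hbond >= 0, w_torsion >= 0,
            w_geometry >= 0, w_chirality >= 0, w_clash >= 0)
  structure(list(temp_start = temp_start, temp_end = temp_end,
                 n_stages = as.integer(n_stages),
                 moves_per_stage = as.integer(moves_per_stage),
                 w_distance = w_distance, w_hbond = w_hbond,
                 w_torsion = w_torsion, w_geometry = w_geometry,
                 w_chirality = w_chirality, w_clash = w_clash,
                 center_pull = center_pull, clash_floor = clash_floor,
                 mirror_mode = mirror_mode,
                 ensemble_size = as.integer(ensemble_size),
                 energy_ceiling = energy_ceiling,
                 rng_seed = as.integer(rng_seed)),
            class = "builder_config")
}

#' Distance-geometry bound smoothing
#'
#' Completes sparse pairwise Cβ-referenced bounds into full L x L
#' lower/upper matrices: sequential-neighbour ladder bounds (the Cβ–Cβ
#' chain-step range, 3.5–6.2 Å, around the 3.8 Å Cα ladder with Cβ
#' offsets) are inserted, upper bounds are tightened by the triangle
#' inequality (shortest paths, Floyd–Warshall), lower bounds are floored
#' at 3.5 Å for non-bonded pairs and lifted by the inverse triangle
#' inequality.  Contradictory bounds surviving smoothing (upper < lower)
#' are reported and relaxed.
#'
#' @param bounds A `distance_bounds` data.frame (may be empty).
#' @param L Residue count.
#' @return A list with `lower` and `upper` L x L matrices (Å).
#' @export
smooth_bounds <- function(bounds, L) {
  up <- matrix(Inf, L, L); diag(up) <- 0
  lo <- matrix(0, L, L)
  idx <- seq_len(L - 1)
  up[cbind(idx, idx + 1)] <- up[cbind(idx + 1, idx)] <- 6.2
  lo[cbind(idx, idx + 1)] <- lo[cbind(idx + 1, idx)] <- 3.5
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  lo[sep >= 2] <- pmax(lo[sep >= 2], 3.5)
  if (nrow(bounds)) {
    if (any(bounds$lower > bounds$upper))
      stop("inconsistent input bounds (lower > upper)")
    ij <- cbind(bounds$i, bounds$j)
    up[ij] <- pmin(up[ij], bounds$upper)
    lo[ij] <- pmax(lo[ij], bounds$lower)
    up[ij[, 2:1, drop = FALSE]] <- up[ij]
    lo[ij[, 2:1, drop = FALSE]] <- lo[ij]
  }
  for (k in seq_len(L))                  # shortest-path upper smoothing
    up <- pmin(up, outer(up[, k], up[k, ], "+"))
  for (k in seq_len(L))                  # inverse-triangle lower lifting
    lo <- pmax(lo, outer(lo[, k], -up[k, ], "+"),
               outer(-up[, k], lo[k, ], "+"))
  bad <- lo > up + 1e-9
  if (any(bad)) {
    warning(sprintf("%g contradictory bound(s) relaxed after smoothing",
                    sum(bad) / 2))
    lo[bad] <- up[bad]
  }
  diag(lo) <- diag(up) <- 0
  list(lower = lo, upper = up)
}

#' Metric-matrix embedding of smoothed bounds
#'
#' Samples a distance matrix uniformly within the smoothed bounds
#' (seeded), double-centres its squared entries and takes the top three
#' eigen-axes as coordinates (classical multidimensional scaling).  With
#' `mirror = TRUE` one axis is negated, giving the reflected embedding.
#' Exact input distances (lower = upper) reproduce the generating
#' structure up to rigid motion and reflection.
#'
#' @param sm Output of [smooth_bounds()].
#' @param rng_seed Integer seed for distance sampling.
#' @param mirror Negate one coordinate axis?
#' @param projection_rounds Bound-projection re-embedding rounds: after
#'   the first embedding, distances measured on the embedded coordinates
#'   are clamped back into the bounds and re-embedded, which pulls the
#'   metric matrix toward a consistent 3-D configuration.
#' @param polish_rounds Basin-hopping rounds of the trace-level
#'   bound-violation minimizer that follows the eigen-embedding (0 for
#'   the bare metric-matrix embedding).
#' @return An L x 3 matrix of trace coordinates (Cβ-referenced).
#' @export
embed_initial <- function(sm, rng_seed = 1L, mirror = FALSE,
                          projection_rounds = 4L, polish_rounds = 8L) {
  L <- nrow(sm$lower)
  mds3 <- function(D) {
    B <- -0.5 * scale(t(scale(t(D^2), scale = FALSE)), scale = FALSE)
    e <- eigen(B, symmetric = TRUE)
    if (sum(e$values > 1e-8) < 3) return(NULL)
    unname(e$vectors[, 1:3] %*% diag(sqrt(pmax(e$values[1:3], 0))))
  }
  with_seed(rng_seed, {
    for (attempt in 1:3) {
      u <- matrix(stats::runif(L * L), L, L)
      u[lower.tri(u)] <- t(u)[lower.tri(u)]
      D <- sm$lower + u * (sm$upper - sm$lower)
      D[!is.finite(D)] <- 25
      D <- (D + t(D)) / 2; diag(D) <- 0
      xyz <- mds3(D)
      if (!is.null(xyz)) {
        for (r in seq_len(projection_rounds)) {
          D <- as.matrix(stats::dist(xyz))
          D <- pmin(pmax(D, sm$lower), sm$upper)
          D[!is.finite(D)] <- 25
          nxt <- mds3(D)
          if (is.null(nxt)) break
          xyz <- nxt
        }
        if (polish_rounds > 0)
          xyz <- polish_trace(xyz, sm, mds3, polish_rounds)
        if (mirror) xyz[, 3] <- -xyz[, 3]
        return(xyz)
      }
      # degenerate spectrum: widen the sampling window and retry
      sm$lower <- pmax(sm$lower - 0.05, 0)
      sm$upper <- sm$upper + 0.05
    }
  })
  stop("embedding degenerate: bound matrix has rank < 3")
}

# trace-level bound-violation minimization: the trace is lifted into a
# fourth spatial dimension (where the chain can pass through itself and
# escape topological traps), the summed squared bound violations are
# minimized by L-BFGS while the fourth coordinate is squeezed away by a
# harmonic penalty of increasing weight, and leftover violations are
# attacked by jittered 3-D restarts
polish_trace <- function(xyz, sm, mds3, rounds) {
  L <- nrow(xyz)
  pr <- which(upper.tri(sm$lower), arr.ind = TRUE)
  lo <- sm$lower[pr]; up <- sm$upper[pr]
  up[!is.finite(up)] <- 1e6
  a <- pr[, 1]; b <- pr[, 2]
  viol_fn <- function(X, dim, w4) {
    dv <- X[a, , drop = FALSE] - X[b, , drop = FALSE]
    dd <- sqrt(rowSums(dv * dv))
    vv <- pmax(dd - up, 0) + pmax(lo - dd, 0)
    vq <- pmin(vv, 1)                     # soft-square beyond 1 A
    v <- sum(vq^2 + 2 * (vv - vq))
    if (dim == 4L) v <- v + w4 * sum(X[, 4]^2)
    v
  }
  viol_gr <- function(X, dim, w4) {
    dv <- X[a, , drop = FALSE] - X[b, , drop = FALSE]
    dd <- pmax(sqrt(rowSums(dv * dv)), 1e-9)
    vv <- pmax(dd - up, 0) + pmax(lo - dd, 0)
    sgn <- sign(dd - pmin(pmax(dd, lo), up))
    gv <- dv * (2 * pmin(vv, 1) * sgn / dd)
    G <- matrix(0, L, dim)
    s1 <- rowsum(gv, a)
    G[as.integer(rownames(s1)), ] <- G[as.integer(rownames(s1)), ,
                                       drop = FALSE] + s1
    s2 <- rowsum(-gv, b)
    G[as.integer(rownames(s2)), ] <- G[as.integer(rownames(s2)), ,
                                       drop = FALSE] + s2
    if (dim == 4L) G[, 4] <- G[, 4] + 2 * w4 * X[, 4]
    G
  }
  minimize <- function(X, w4 = 0) {
    dim <- ncol(X)
    opt <- stats::optim(as.numeric(X),
                        function(x) viol_fn(matrix(x, L, dim), dim, w4),
                        function(x) as.numeric(
                          viol_gr(matrix(x, L, dim), dim, w4)),
                        method = "L-BFGS-B", control = list(maxit = 150))
    list(X = matrix(opt$par, L, dim), v = opt$value)
  }
  # 4-D squeeze from the 3-D embedding plus a small 4th coordinate
  X4 <- cbind(xyz, stats::rnorm(L, sd = 1))
  for (w4 in c(0.01, 0.05, 0.2, 1, 5, 25, 1e3)) X4 <- minimize(X4, w4)$X
  best <- minimize(X4[, 1:3])
  for (r in seq_len(rounds)) {
    if (best$v < 1e-6) break
    cand <- minimize(best$X + matrix(stats::rnorm(L * 3, sd = 0.8), L, 3))
    if (cand$v < best$v) best <- cand
  }
  best$X
}

# ---- energy machinery (internal) -------------------------------------

# flatten a fold_model into an atom table + coordinate matrix
model_atoms <- function(m) {
  L <- m$length
  types <- c("N", "CA", "C", "O", "CB")
  aidx <- matrix(NA_integer_, L, 5, dimnames = list(NULL, types))
  coords <- matrix(0, 0, 3)
  n <- 0L
  for (i in seq_len(L)) for (t in 1:5) {
    xyz <- m$xyz[[types[t]]][i, ]
    if (any(is.na(xyz))) next
    n <- n + 1L
    aidx[i, t] <- n
    coords <- rbind(coords, xyz)
  }
  list(aidx = aidx, coords = coords, res = {
    r <- integer(n)
    for (i in seq_len(L)) for (t in 1:5)
      if (!is.na(aidx[i, t])) r[aidx[i, t]] <- i
    r
  })
}

atoms_to_model <- function(X, aidx, sequence, energy = NULL) {
  L <- nrow(aidx)
  g <- function(t) {
    out <- matrix(NA_real_, L, 3)
    ok <- !is.na(aidx[, t])
    out[ok, ] <- X[aidx[ok, t], , drop = FALSE]
    out
  }
  fold_model(sequence, g("N"), g("CA"), g("C"), g("O"), g("CB"),
             energy = energy)
}

# ideal 1-3 distance from two bond lengths and the included angle
d13 <- function(b1, b2, ang) sqrt(b1^2 + b2^2 - 2 * b1 * b2 * cos(ang))

# precompute all energy term tables for a restraint set + atom layout
energy_terms <- function(rs, aidx, cfg) {
  L <- nrow(aidx)
  A <- function(i, t) aidx[cbind(i, match(t, colnames(aidx)))]
  pair <- function(i1, t1, i2, t2, r0) {
    a <- A(i1, t1); b <- A(i2, t2)
    ok <- !is.na(a) & !is.na(b)
    cbind(a[ok], b[ok], r0[ok])
  }
  i <- seq_len(L); ip <- seq_len(L - 1)
  r <- function(v, n) rep(v, length.out = n)
  geom <- rbind(
    pair(i, "N", i, "CA", r(IDEAL$b_n_ca, L)),
    pair(i, "CA", i, "C", r(IDEAL$b_ca_c, L)),
    pair(i, "C", i, "O", r(IDEAL$b_c_o, L)),
    pair(i, "CA", i, "CB", r(IDEAL$b_ca_cb, L)),
    pair(ip, "C", ip + 1, "N", r(IDEAL$b_c_n, L - 1)),
    pair(i, "N", i, "C", r(d13(IDEAL$b_n_ca, IDEAL$b_ca_c,
                               IDEAL$a_n_ca_c), L)),
    pair(i, "CA", i, "O", r(d13(IDEAL$b_ca_c, IDEAL$b_c_o,
                                IDEAL$a_ca_c_o), L)),
    pair(i, "N", i, "CB", r(d13(IDEAL$b_n_ca, IDEAL$b_ca_cb,
                                IDEAL$a_n_ca_cb), L)),
    pair(i, "C", i, "CB", r(d13(IDEAL$b_ca_c, IDEAL$b_ca_cb,
                                110.5 * pi / 180), L)),
    pair(ip, "CA", ip + 1, "N", r(d13(IDEAL$b_ca_c, IDEAL$b_c_n,
                                      IDEAL$a_ca_c_n), L - 1)),
    pair(ip, "O", ip + 1, "N", r(d13(IDEAL$b_c_o, IDEAL$b_c_n,
                                     122.6 * pi / 180), L - 1)),
    pair(ip, "C", ip + 1, "CA", r(d13(IDEAL$b_c_n, IDEAL$b_n_ca,
                                      IDEAL$a_c_n_ca), L - 1)),
    pair(ip, "CA", ip + 1, "CA", r(3.80, L - 1))   # trans peptide
  )
  gly <- is.na(aidx[, "CB"])
  b <- rs$bounds
  cb_atom <- ifelse(gly, aidx[, "CA"], aidx[, "CB"])
  bound_tab <- if (nrow(b))
    cbind(cb_atom[b$i], cb_atom[b$j], b$lower, b$upper) else
    matrix(0, 0, 4)
  h <- rs$hbonds
  hb_tab <- if (nrow(h))
    cbind(A(h$donor, "N"), A(h$acceptor, "O"), h$no_lower, h$no_upper) else
    matrix(0, 0, 4)
  tor <- rs$torsions
  tor_tab <- if (nrow(tor)) {
    rows <- lapply(seq_len(nrow(tor)), function(k) {
      rr <- tor$residue[k]
      if (tor$angle[k] == "phi") {
        if (rr < 2) return(NULL)
        ats <- c(A(rr - 1L, "C"), A(rr, "N"), A(rr, "CA"), A(rr, "C"))
      } else {
        if (rr >= L) return(NULL)
        ats <- c(A(rr, "N"), A(rr, "CA"), A(rr, "C"), A(rr + 1L, "N"))
      }
      if (any(is.na(ats))) return(NULL)
      c(ats, tor$target[k], tor$deviation[k])
    })
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  } else matrix(0, 0, 6)
  if (is.null(tor_tab)) tor_tab <- matrix(0, 0, 6)
  # L-chirality impropers: dihedral(C, N, CA, CB) at +122.6 deg
  ok <- !gly
  chir_tab <- cbind(A(i, "C"), A(i, "N"), A(i, "CA"), aidx[, "CB"])[ok, ,
                                                                    drop = FALSE]
  # helix handedness: CA quadruplets, gated at run time on i,i+3 distance
  helix_tab <- if (L >= 4)
    cbind(aidx[1:(L - 3), "CA"], aidx[2:(L - 2), "CA"],
          aidx[3:(L - 1), "CA"], aidx[4:L, "CA"]) else matrix(0, 0, 4)
  # clash pairs: atoms from residues >= 2 apart in sequence
  res_of <- integer(max(aidx, na.rm = TRUE))
  for (ii in seq_len(L)) for (t in 1:5)
    if (!is.na(aidx[ii, t])) res_of[aidx[ii, t]] <- ii
  M <- length(res_of)
  cp <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
  keep <- abs(res_of[cp[, 1]] - res_of[cp[, 2]]) >= 2
  clash_tab <- cp[keep, , drop = FALSE]
  # positions of the kept pairs in the condensed dist() vector
  ii <- clash_tab[, 1]; jj <- clash_tab[, 2]
  clash_pos <- M * (ii - 1) - ii * (ii - 1) / 2 + (jj - ii)
  list(geom = geom, bounds = bound_tab, hbonds = hb_tab,
       torsions = tor_tab, chir = chir_tab, helix = helix_tab,
       clash = clash_tab, clash_pos = clash_pos, n_atoms = M, cfg = cfg)
}

# energy + gradient of the full restraint/geometry functional.
# Returns list(total, terms, grad) with grad an M x 3 matrix.
energy_eval <- function(X, tm, grad = TRUE) {
  cfg <- tm$cfg
  M <- nrow(X)
  G <- if (grad) matrix(0, M, 3) else NULL
  add_grad <- function(gv, idx) {
    s <- rowsum(gv, idx)
    rows <- as.integer(rownames(s))
    G[rows, ] <<- G[rows, , drop = FALSE] + s
  }
  acc_pair <- function(tab, elo, ehi, w, soft_delta = Inf) {
    # flat-bottom well [elo, ehi] on distances of atom pairs in tab.
    # With a finite soft_delta the penalty is soft-square: quadratic up
    # to delta, linear beyond, so a few irreconcilable restraints can
    # never dominate the whole energy surface.
    if (!nrow(tab)) return(0)
    a <- tab[, 1]; b <- tab[, 2]
    dv <- X[a, , drop = FALSE] - X[b, , drop = FALSE]
    d <- pmax(sqrt(rowSums(dv * dv)), 1e-9)
    v <- pmax(d - ehi, 0) + pmax(elo - d, 0)
    sgn <- sign(d - pmin(pmax(d, elo), ehi))
    vq <- pmin(v, soft_delta)
    e <- if (is.finite(soft_delta))
      w * sum(vq^2 + 2 * soft_delta * (v - vq))
    else w * sum(v^2)
    if (grad && e > 0) {
      hit <- which(v > 0)
      coef <- 2 * w * vq[hit] * sgn[hit] / d[hit]
      gv <- dv[hit, , drop = FALSE] * coef
      add_grad(gv, a[hit])
      add_grad(-gv, b[hit])
    }
    e
  }
  acc_center <- function(tab, elo, ehi, w) {
    # weak quadratic pull toward the well centre: lifts the flat-bottom
    # plateau degeneracy so minimization settles inside the bounds
    if (!nrow(tab) || w <= 0) return(0)
    a <- tab[, 1]; b <- tab[, 2]
    dv <- X[a, , drop = FALSE] - X[b, , drop = FALSE]
    d <- pmax(sqrt(rowSums(dv * dv)), 1e-9)
    hi <- pmin(ehi, elo + 50)
    mid <- (elo + hi) / 2
    halfw <- (hi - elo) / 2
    # capped at the well edge so the pull never pushes other restraints
    # out of their own wells
    e <- w * sum(pmin((d - mid)^2, halfw^2))
    if (grad) {
      inside <- which((d - mid)^2 < halfw^2)
      gv <- dv[inside, , drop = FALSE] *
        (2 * w * (d[inside] - mid[inside]) / d[inside])
      add_grad(gv, a[inside])
      add_grad(-gv, b[inside])
    }
    e
  }
  acc_dihedral <- function(tab, target, halfwidth, w) {
    if (!nrow(tab)) return(0)
    p <- lapply(1:4, function(k) X[tab[, k], , drop = FALSE])
    ang <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    dd <- circ_diff(ang, target)
    v <- pmax(abs(dd) - halfwidth, 0)
    e <- w * sum(v^2)
    if (grad && e > 0) {
      hit <- which(v > 0)
      dEda <- 2 * w * v[hit] * sign(dd[hit])
      ph <- lapply(p, function(pk) pk[hit, , drop = FALSE])
      gs <- dihedral_grad(ph[[1]], ph[[2]], ph[[3]], ph[[4]])
      for (k in 1:4) add_grad(gs[[k]] * dEda, tab[hit, k])
    }
    e
  }
  e_geom <- acc_pair(tm$geom, tm$geom[, 3], tm$geom[, 3], cfg$w_geometry)
  e_dist <- acc_pair(tm$bounds, tm$bounds[, 3], tm$bounds[, 4],
                     cfg$w_distance, soft_delta = 1)
  e_hb <- acc_pair(tm$hbonds, tm$hbonds[, 3], tm$hbonds[, 4], cfg$w_hbond,
                   soft_delta = 1)
  e_cen <- acc_center(tm$bounds, tm$bounds[, 3], tm$bounds[, 4],
                      cfg$w_distance * cfg$center_pull) +
    acc_center(tm$hbonds, tm$hbonds[, 3], tm$hbonds[, 4],
               cfg$w_hbond * cfg$center_pull)
  e_tor <- acc_dihedral(tm$torsions, tm$torsions[, 5], tm$torsions[, 6],
                        cfg$w_torsion)
  e_chir <- acc_dihedral(tm$chir, IDEAL$t_c_n_ca_cb, 10 * pi / 180,
                         cfg$w_chirality)
  if (nrow(tm$helix)) {
    # left-handed helical stretches: the CA(i)..CA(i+3) virtual dihedral
    # is pushed positive wherever three consecutive i,i+3 spans are
    # helix-like (< 6.5 A) - i.e. in helix cores, never isolated turns
    a <- tm$helix[, 1]; d4 <- tm$helix[, 4]
    span <- sqrt(rowSums((X[a, , drop = FALSE] - X[d4, , drop = FALSE])^2))
    g <- span < 6.5
    n <- length(g)
    gate <- g & c(FALSE, g[-n]) & c(g[-1], FALSE)
    if (any(gate)) {
      sub <- tm$helix[gate, , drop = FALSE]
      e_chir <- e_chir + acc_dihedral(sub, 0.9, 0.73, cfg$w_chirality)
    }
  }
  e_clash <- 0
  if (nrow(tm$clash)) {
    dd <- stats::dist(X)[tm$clash_pos]
    hit <- which(dd < cfg$clash_floor)
    if (length(hit))   # lower-only flat-bottom at the clash floor
      e_clash <- acc_pair(tm$clash[hit, , drop = FALSE],
                          cfg$clash_floor, Inf, cfg$w_clash)
  }
  terms <- c(distance = e_dist, hbond = e_hb, torsion = e_tor,
             geometry = e_geom, chirality = e_chir, clash = e_clash,
             center = e_cen)
  list(total = sum(terms), terms = terms, grad = G)
}

#' Energy breakdown of a model under a restraint set
#'
#' Evaluates the builder's energy functional — flat-bottom distance
#' wells, H-bond wells, torsion wells, ideal-geometry terms, chirality
#' (Cα-L impropers plus left-handed-helix penalty) and soft clashes —
#' without refining.  Distance terms are reflection-invariant; the
#' chirality term is not, which is what discriminates a model from its
#' topological mirror.
#'
#' @param m A [fold_model()].
#' @param rs A [restraint_set()].
#' @param cfg A [builder_config()].
#' @return A named list of term energies plus `total`.  The `center`
#'   entry (the plateau-lifting pull used during search) is reported for
#'   transparency but excluded from `total`, which is the physical
#'   restraint + geometry energy.
#' @export
energy_breakdown <- function(m, rs, cfg = builder_config()) {
  at <- model_atoms(m)
  tm <- energy_terms(rs, at$aidx, cfg)
  ev <- energy_eval(at$coords, tm, grad = FALSE)
  c(as.list(ev$terms), list(total = ev$total - ev$terms[["center"]]))
}

# stage minimization: limited-memory BFGS with monotone line search;
# never returns a state worse than its input.  fn/gr share one
# evaluation via a same-point memo.
descend <- function(X, tm, maxit) {
  M <- nrow(X)
  memo_x <- NULL; memo <- NULL
  at <- function(x) {
    if (is.null(memo_x) || !identical(x, memo_x)) {
      memo_x <<- x
      memo <<- energy_eval(matrix(x, M, 3), tm)
    }
    memo
  }
  fn <- function(x) at(x)$total
  gr <- function(x) as.numeric(at(x)$grad)
  e0 <- fn(as.numeric(X))
  opt <- stats::optim(as.numeric(X), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  if (opt$value <= e0) X <- matrix(opt$par, M, 3)
  list(X = X, ev = energy_eval(X, tm, grad = FALSE))
}

#' Refine a model against a restraint set
#'
#' Builds a full backbone around the start (a coarse Cα trace from
#' [embed_initial()] or an existing [fold_model()]) and minimizes the
#' total energy by simulated annealing: geometric cooling over
#' `cfg$n_stages` stages, each stage jittering the coordinates in
#' proportion to the temperature, re-minimizing monotonically, and
#' applying a Metropolis accept/reject against the previous state.  The
#' best state ever seen is returned, with its energy breakdown and the
#' per-stage energy trace.  Models whose final energy exceeds
#' `cfg$energy_ceiling` are flagged unconverged rather than rejected.
#'
#' @param start An L x 3 Cα matrix or a [fold_model()].
#' @param rs A [restraint_set()].
#' @param cfg A [builder_config()].
#' @return A [fold_model()] with an `energy` element (term breakdown,
#'   `total`, `unconverged` flag and `trace` of per-stage start/end
#'   energies).
#' @export
refine <- function(start, rs, cfg = builder_config()) {
  m0 <- if (inherits(start, "fold_model")) start
        else backbone_from_ca_trace(start, rs$sequence)
  if (m0$length != rs$length)
    stop("start model length does not match the restraint set")
  at <- model_atoms(m0)
  tm <- energy_terms(rs, at$aidx, cfg)
  base_of <- function(ev) ev$total - ev$terms[["center"]]
  with_seed(cfg$rng_seed, {
    cur <- descend(at$coords, tm, cfg$moves_per_stage)
    best <- cur
    temps <- cfg$temp_start *
      (cfg$temp_end / cfg$temp_start)^(seq(0, 1, length.out = cfg$n_stages))
    trace <- matrix(NA_real_, cfg$n_stages, 2,
                    dimnames = list(NULL, c("start", "end")))
    for (s in seq_len(cfg$n_stages)) {
      Tc <- temps[s]
      Xj <- cur$X + matrix(stats::rnorm(length(cur$X),
                                        sd = 0.25 * sqrt(Tc)),
                           nrow(cur$X), 3)
      ev0 <- energy_eval(Xj, tm, grad = FALSE)
      cand <- descend(Xj, tm, cfg$moves_per_stage)
      trace[s, ] <- c(ev0$total, cand$ev$total)
      dE <- cand$ev$total - cur$ev$total
      if (dE <= 0 || stats::runif(1) < exp(-dE / Tc)) cur <- cand
      # the centre pull is a search heuristic: the retained optimum is
      # judged on the physical restraint + geometry energy alone
      if (base_of(cand$ev) < base_of(best$ev)) best <- cand
    }
    # final quench: long zero-temperature minimization of the best
    # state, with the restraint wells up-weighted (and the centre pull
    # off) so satisfied-to-the-edge restraints settle inside bounds
    qcfg <- cfg
    qcfg$w_distance <- 8 * cfg$w_distance
    qcfg$w_hbond <- 8 * cfg$w_hbond
    qcfg$w_torsion <- 8 * cfg$w_torsion
    qcfg$center_pull <- 0
    tmq <- tm; tmq$cfg <- qcfg
    quench <- descend(best$X, tmq, 5L * cfg$moves_per_stage)
    quench$ev <- energy_eval(quench$X, tm, grad = FALSE)
    if (base_of(quench$ev) <= base_of(best$ev)) best <- quench
    energy <- c(as.list(best$ev$terms),
                list(total = base_of(best$ev),
                     unconverged = base_of(best$ev) > cfg$energy_ceiling,
                     trace = trace))
    atoms_to_model(best$X, at$aidx, rs$sequence, energy = energy)
  })
}

#' Build an ensemble of models from a restraint set
#'
#' Runs `cfg$ensemble_size` independent seeded embed-and-refine builds.
#' Each run embeds once, refines both the embedding and its mirror
#' image, and keeps the lower-energy hand; the returned ensemble is
#' sorted by total energy.
#'
#' @param rs A [restraint_set()].
#' @param cfg A [builder_config()].
#' @return An object of class `ensemble`: list of [fold_model()]s plus
#'   the smoothed bounds used.
#' @export
build_ensemble <- function(rs, cfg = builder_config()) {
  sm <- smooth_bounds(rs$bounds, rs$length)
  models <- vector("list", cfg$ensemble_size)
  mirrors <- if (identical(cfg$mirror_mode, "single")) FALSE
             else c(FALSE, TRUE)
  for (k in seq_len(cfg$ensemble_size)) {
    seed_k <- cfg$rng_seed + 1000L * k
    hands <- lapply(mirrors, function(mir) {
      ca <- embed_initial(sm, rng_seed = seed_k, mirror = mir)
      cfg_k <- cfg; cfg_k$rng_seed <- seed_k
      refine(ca, rs, cfg_k)
    })
    models[[k]] <- hands[[which.min(vapply(hands,
                                           function(m) m$energy$total,
                                           0))]]
  }
  ord <- order(vapply(models, function(m) m$energy$total, 0))
  structure(list(models = models[ord], smoothed = sm, config = cfg),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  en <- vapply(x$models, function(m) m$energy$total, 0)
  cat(sprintf("Ensemble of %d models; energy range %.2f to %.2f\n",
              length(x$models), min(en), max(en)))
  invisible(x)
}
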