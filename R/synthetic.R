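#' Synthetic prediction oracle configuration
#'
#' The oracle stands in for the trained distance/H-bond/torsion
#' predictors: it derives noisy predictions from a known reference
#' structure so every downstream stage runs offline.  `distance_sigma`
#' blurs bin mass around the true Cβ–Cβ distance; `corruption_rate`
#' replaces a random fraction of pairs with uninformative (uniform)
#' distributions; `seed_coupling` controls how strongly a seed model from
#' a previous iteration sharpens the next prediction.
#'
#' @param distance_sigma Gaussian blur of bin mass, Å (> 0).
#' @param corruption_rate Fraction of pairs replaced by uniform mass.
#' @param hbond_true_likelihood,hbond_false_likelihood Emitted likelihood
#'   for geometrically true / false H-bond cells.
#' @param torsion_sigma Wrapped-Gaussian torsion noise, radians.
#' @param seed_coupling In \[0, 1\]: for pairs whose seed-model distance is
#'   within 2 Å of the truth, the effective blur shrinks by the factor
#'   `(1 - seed_coupling)`.
#' @param rng_seed Integer seed; all oracle outputs are deterministic
#'   functions of (inputs, seed).
#' @return An object of class `oracle_config`.
#' @export
oracle_config <- function(distance_sigma = 1.0, corruption_rate = 0.1,
                          hbond_true_likelihood = 0.95,
                          hbond_false_likelihood = 0.05,
                          torsion_sigma = 0.2, seed_coupling = 0.5,
                          rng_seed = 1L) {
  stopifnot(distance_sigma > 0,
            corruption_rate >= 0, corruption_rate <= 1,
            hbond_true_likelihood >= 0, hbond_true_likelihood <= 1,
            hbond_false_likelihood >= 0, hbond_false_likelihood <= 1,
            torsion_sigma >= 0, seed_coupling >= 0, seed_coupling <= 1)
  structure(list(distance_sigma = distance_sigma,
                 corruption_rate = corruption_rate,
                 hbond_true_likelihood = hbond_true_likelihood,
                 hbond_false_likelihood = hbond_false_likelihood,
                 torsion_sigma = torsion_sigma,
                 seed_coupling = seed_coupling,
                 rng_seed = as.integer(rng_seed)),
            class = "oracle_config")
}

#' Toy fold specifications and reference structures
#'
#' A toy fold is described by a per-residue secondary-structure string
#' (H = helix, E = strand, C = coil).  [make_toy_fold()] realizes it as
#' an ideal-geometry backbone: helix residues get φ/ψ ≈ (−57°, −47°),
#' strand residues (−120°, 120°), and coil residues seeded random angles;
#' an optional Gaussian perturbation then jitters the coordinates toward
#' a target RMSD.
#'
#' @param ss Secondary-structure string over \{H, E, C\}.
#' @param sequence Optional sequence string of the same length (default:
#'   all alanine).
#' @param perturb Coordinate perturbation target RMSD in Å (default 0).
#' @return `toy_fold_spec`: an object of class `toy_fold_spec`.
#' @export
toy_fold_spec <- function(ss, sequence = NULL, perturb = 0) {
  if (grepl("[^HEC]", ss)) stop("unknown secondary-structure character")
  if (is.null(sequence))
    sequence <- paste(rep("A", nchar(ss)), collapse = "")
  if (nchar(sequence) != nchar(ss))
    stop("sequence and secondary-structure lengths differ")
  structure(list(ss = ss, sequence = sequence, perturb = perturb),
            class = "toy_fold_spec")
}

#' @rdname toy_fold_spec
#' @param spec A `toy_fold_spec`.
#' @param rng_seed Integer seed (coil angles and perturbation).
#' @param n_steps Hill-climbing steps over the coil dihedrals: starting
#'   from seeded random coil angles, single-residue moves that make the
#'   chain more compact (more long-range contacts, no self-clashes) are
#'   accepted, so toys acquire genuine long-range structure instead of
#'   staying extended.
#' @return `make_toy_fold`: a [fold_model()].
#' @export
make_toy_fold <- function(spec, rng_seed = 1L, n_steps = 400L) {
  stopifnot(inherits(spec, "toy_fold_spec"))
  L <- nchar(spec$ss)
  if (L < 10) stop("toy folds need at least 10 residues")
  st <- strsplit(spec$ss, "")[[1]]
  coil_idx <- which(st == "C")
  phi <- psi <- numeric(L)
  phi[st == "H"] <- -57; psi[st == "H"] <- -47
  phi[st == "E"] <- -120; psi[st == "E"] <- 120
  # coil basins: alpha, beta and left-handed-alpha (turn) regions
  basins <- matrix(c(-70, -30, -110, 130, 62, 35), 2)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  score_of <- function(m) {
    d <- as.matrix(stats::dist(m$xyz$CA))
    cb <- m$xyz$CB; miss <- is.na(cb[, 1]); cb[miss, ] <- m$xyz$CA[miss, ]
    dcb <- as.matrix(stats::dist(cb))
    # steric sanity: keep CA and CB pseudo-atoms of distant residues
    # apart so derived restraints stay consistent with the bin floor
    nclash <- (sum(d[sep >= 2] < 3.8) + sum(dcb[sep >= 2] < 3.8)) / 2
    all_atoms <- rbind(m$xyz$N, m$xyz$CA, m$xyz$C, m$xyz$O,
                       cb)
    res_id <- rep(seq_len(L), 5)
    da <- as.matrix(stats::dist(all_atoms))
    sepa <- abs(outer(res_id, res_id, "-"))
    nclash <- nclash + sum(da[sepa >= 2] < 2.7) / 2
    sum(d < 8 & sep > 8) / 2 - 25 * nclash - 0.2 * max(d)
  }
  draw <- function(n) {
    bas <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.3, 0.4))
    rbind(basins[1, bas] + stats::rnorm(n, 0, 15),
          basins[2, bas] + stats::rnorm(n, 0, 15))
  }
  with_seed(rng_seed, {
    if (length(coil_idx)) {
      ang <- draw(length(coil_idx))
      phi[coil_idx] <- ang[1, ]; psi[coil_idx] <- ang[2, ]
    }
    best <- backbone_from_torsions(phi * pi / 180, psi * pi / 180,
                                   spec$sequence)
    best_score <- score_of(best)
    if (length(coil_idx)) {
      for (step in seq_len(n_steps)) {
        cand_phi <- phi; cand_psi <- psi
        k <- sample(coil_idx, 1)
        ang <- draw(1)
        cand_phi[k] <- ang[1, 1]; cand_psi[k] <- ang[2, 1]
        m <- backbone_from_torsions(cand_phi * pi / 180,
                                    cand_psi * pi / 180, spec$sequence)
        sc <- score_of(m)
        if (sc > best_score) {
          best <- m; best_score <- sc
          phi <- cand_phi; psi <- cand_psi
        }
      }
    }
    if (spec$perturb > 0) {
      for (nm in names(best$xyz)) {
        jit <- matrix(stats::rnorm(3 * L, sd = spec$perturb), L, 3)
        best$xyz[[nm]] <- best$xyz[[nm]] + jit
      }
    }
    best
  })
}

#' Oracle distogram from a reference structure
#'
#' Per pair, bin mass is the Gaussian probability mass over each bin
#' interval centred on the true Cβ–Cβ distance with standard deviation
#' `distance_sigma` (the unbounded final bin receives the upper tail;
#' mass below the first edge is clamped into the first bin).  A seeded
#' `corruption_rate` fraction of pairs is replaced by uniform mass.  When
#' a `seed_model` is supplied, pairs whose seed distance lies within 2 Å
#' of the truth are re-blurred with sigma shrunk by `(1 - seed_coupling)`
#' — the mechanism by which iteration can improve information.
#'
#' @param native Reference [fold_model()].
#' @param cfg An [oracle_config()].
#' @param seed_model Optional [fold_model()] of the same length.
#' @param scheme A [bin_scheme()].
#' @return A symmetric [distogram()].
#' @export
oracle_distogram <- function(native, cfg, seed_model = NULL,
                             scheme = default_bin_scheme()) {
  stopifnot(inherits(cfg, "oracle_config"))
  L <- native$length
  if (!is.null(seed_model) && seed_model$length != L)
    stop("seed model length does not match the reference")
  truth <- cb_distance_matrix(native)
  sigma <- matrix(cfg$distance_sigma, L, L)
  if (!is.null(seed_model)) {
    sd_seed <- cb_distance_matrix(seed_model)
    close_enough <- abs(sd_seed - truth) <= 2
    sigma[close_enough] <- sigma[close_enough] * (1 - cfg$seed_coupling)
    sigma <- pmax(sigma, 1e-4)
  }
  edges <- scheme$edges
  lik <- array(0, c(L, L, scheme$n_bins))
  # integrated Gaussian mass per bin; first bin absorbs the lower tail
  cums <- vapply(seq_len(20L), function(k) {
    hi <- edges[k + 1L]
    if (is.infinite(hi)) matrix(1, L, L)
    else stats::pnorm((hi - truth) / sigma)
  }, matrix(0, L, L))
  lik[, , 1L] <- cums[, , 1L]    # lower tail clamped into the first bin
  for (k in 2:20) lik[, , k] <- cums[, , k] - cums[, , k - 1L]
  with_seed(cfg$rng_seed, {
    if (cfg$corruption_rate > 0 && L > 1) {
      pairs <- which(upper.tri(truth), arr.ind = TRUE)
      n_bad <- round(cfg$corruption_rate * nrow(pairs))
      if (n_bad > 0) {
        bad <- pairs[sample.int(nrow(pairs), n_bad), , drop = FALSE]
        for (r in seq_len(n_bad)) {
          lik[bad[r, 1], bad[r, 2], ] <- 1 / 20
          lik[bad[r, 2], bad[r, 1], ] <- 1 / 20
        }
      }
    }
  })
  tot <- apply(lik, c(1, 2), sum)
  lik <- lik / array(pmax(tot, 1e-12), dim(lik))
  distogram(lik, scheme, check = FALSE)
}

#' Oracle hydrogen-bond donor/acceptor map
#'
#' Cells that are geometrically true H-bonds in the reference (donor N
#' within 3.5 Å of acceptor O, per [detect_hbonds()]) receive
#' `hbond_true_likelihood`; all other cells receive
#' `hbond_false_likelihood`.  Seeded flip noise scales with
#' `corruption_rate`: each true cell is missed (dropped to the false
#' level) with that probability, and a matching budget of false cells —
#' twice `corruption_rate` times the true count, mimicking the
#' false-discovery level of a realistic predictor rather than a uniform
#' per-cell flip — is raised to the true level.  The map is directional
#' (rows = donors) and not symmetric in general.
#'
#' @inheritParams oracle_distogram
#' @return An L x L likelihood matrix.
#' @export
oracle_hbonds <- function(native, cfg) {
  stopifnot(inherits(cfg, "oracle_config"))
  L <- native$length
  hb <- detect_hbonds(native)
  tl <- cfg$hbond_true_likelihood; fl <- cfg$hbond_false_likelihood
  map <- matrix(fl, L, L)
  if (nrow(hb)) map[cbind(hb$donor, hb$acceptor)] <- tl
  with_seed(cfg$rng_seed + 1L, {
    if (cfg$corruption_rate > 0 && nrow(hb)) {
      true_cells <- cbind(hb$donor, hb$acceptor)
      miss <- stats::runif(nrow(hb)) < cfg$corruption_rate
      map[true_cells[miss, , drop = FALSE]] <- fl
      n_fp <- round(2 * cfg$corruption_rate * nrow(hb))
      if (n_fp > 0) {
        false_cells <- which(map < tl & row(map) != col(map))
        pick <- sample(false_cells, min(n_fp, length(false_cells)))
        map[pick] <- tl
      }
    }
  })
  diag(map) <- fl
  map
}

#' Oracle torsion predictions
#'
#' True backbone φ/ψ (and trans ω) plus wrapped-Gaussian noise of width
#' `torsion_sigma`; the reported per-angle error estimate is
#' `torsion_sigma` itself.  Angles stay in (−π, π].
#'
#' @inheritParams oracle_distogram
#' @return A data.frame with columns `phi`, `psi`, `omega` and matching
#'   `*_err` error estimates (radians); NA at undefined termini.
#' @export
oracle_torsions <- function(native, cfg) {
  stopifnot(inherits(cfg, "oracle_config"))
  tor <- backbone_torsions(native)
  L <- native$length
  wrap <- function(a) ifelse(is.na(a), NA_real_,
                             ((a + pi) %% (2 * pi)) - pi)
  with_seed(cfg$rng_seed + 2L, {
    phi <- wrap(tor$phi + stats::rnorm(L, sd = cfg$torsion_sigma))
    psi <- wrap(tor$psi + stats::rnorm(L, sd = cfg$torsion_sigma))
  })
  data.frame(phi = phi, psi = psi, omega = rep(pi, L),
             phi_err = rep(cfg$torsion_sigma, L),
             psi_err = rep(cfg$torsion_sigma, L),
             omega_err = rep(cfg$torsion_sigma, L))
}

#' Bundle the oracle into a predictor function
#'
#' Returns a closure with the predictor interface used by
#' [run_pipeline()]: called with an optional seed model, it returns a
#' list with elements `distogram`, `hbond_map` and `torsions`.
#'
#' @inheritParams oracle_distogram
#' @return A function `function(seed_model = NULL)`.
#' @export
oracle_predictor <- function(native, cfg, scheme = default_bin_scheme()) {
  force(native); force(cfg); force(scheme)
  function(seed_model = NULL) {
    list(distogram = oracle_distogram(native, cfg, seed_model, scheme),
         hbond_map = oracle_hbonds(native, cfg),
         torsions = oracle_torsions(native, cfg))
  }
}

#' Generate a synthetic multiple sequence alignment
#'
#' A seeded random root sequence plus `n_seqs - 1` copies mutated
#' independently at each site with probability `mutation_rate`
#' (substitutions drawn uniformly from the 19 alternatives), so the
#' expected pairwise identity to the root is `1 - mutation_rate`.
#'
#' @param n_seqs Number of sequences (>= 1).
#' @param length Alignment length in columns.
#' @param mutation_rate Per-site substitution probability.
#' @param rng_seed Integer seed.
#' @return An object of class `msa`: list with `sequences` (character
#'   vector, equal widths) and `target` (index of the root row).
#' @export
make_msa <- function(n_seqs, length, mutation_rate, rng_seed = 1L) {
  stopifnot(n_seqs >= 1, length >= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  alph <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(rng_seed, {
    root <- sample(alph, length, replace = TRUE)
    seqs <- character(n_seqs)
    seqs[1] <- paste(root, collapse = "")
    for (s in seq_len(n_seqs - 1L)) {
      row <- root
      mut <- which(stats::runif(length) < mutation_rate)
      for (p in mut) row[p] <- sample(setdiff(alph, row[p]), 1)
      seqs[s + 1L] <- paste(row, collapse = "")
    }
    msa(seqs, target = 1L)
  })
}
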