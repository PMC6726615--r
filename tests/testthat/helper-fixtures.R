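# shared fixtures: tiny deterministic structures and random distograms

helix_model <- function(L = 20, seq_str = NULL) {
  spec <- toy_fold_spec(paste(rep("H", L), collapse = ""),
                        sequence = seq_str)
  make_toy_fold(spec, rng_seed = 1)
}

strand_model <- function(L = 20) {
  make_toy_fold(toy_fold_spec(paste(rep("E", L), collapse = "")),
                rng_seed = 1)
}

# compact mixed-topology toy used for build/pipeline tests
compact_spec <- function() {
  toy_fold_spec(paste(c(rep("H", 14), rep("C", 4), rep("E", 7),
                        rep("C", 4), rep("E", 7), rep("C", 4),
                        rep("H", 8)), collapse = ""))
}

# random normalized 20-bin likelihood vector (Dirichlet via gamma draws)
random_bin_vector <- function(alpha = 1) {
  x <- stats::rgamma(20, shape = alpha)
  x / sum(x)
}

# random symmetric distogram with normalized channels
random_distogram <- function(L, seed = 1) {
  set.seed(seed)
  lik <- array(stats::rgamma(L * L * 20, 1), c(L, L, 20))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j < i) lik[i, j, ] <- lik[j, i, ]
    lik[i, j, ] <- lik[i, j, ] / sum(lik[i, j, ])
  }
  distogram(lik, check = FALSE)
}

# zero-noise oracle configuration (deterministic predictions)
zero_noise_config <- function(seed = 1) {
  oracle_config(distance_sigma = 1e-3, corruption_rate = 0,
                torsion_sigma = 0, rng_seed = seed)
}

zero_noise_restraints <- function(native, seed = 1) {
  cfg <- zero_noise_config(seed)
  restraint_set(
    distogram_to_bounds(oracle_distogram(native, cfg)),
    hbond_map_to_restraints(oracle_hbonds(native, cfg)),
    torsions_to_restraints(oracle_torsions(native, cfg)),
    native$sequence)
}

# rigid-motion helper
transform_model <- function(m, rot = diag(3), shift = c(0, 0, 0)) {
  for (nm in names(m$xyz)) m$xyz[[nm]] <- m$xyz[[nm]] %*% rot +
      matrix(shift, m$length, 3, byrow = TRUE)
  m
}

rotation_z <- function(theta)
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)

mirror_model <- function(m) {
  for (nm in names(m$xyz)) m$xyz[[nm]][, 3] <- -m$xyz[[nm]][, 3]
  m
}
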