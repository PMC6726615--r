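test_that("toy folds have ideal local geometry and are deterministic", {
  m <- helix_model(20)
  ca <- m$xyz$CA
  steps <- sqrt(rowSums((ca[-1, ] - ca[-20, ])^2))
  expect_true(all(abs(steps - 3.8) < 0.05))
  # i -> i+4 CA distance diagnostic of an alpha helix
  d4 <- sqrt(rowSums((ca[5:20, ] - ca[1:16, ])^2))
  expect_true(all(abs(d4 - 6.2) < 0.5))
  m2 <- helix_model(20)
  expect_identical(m$xyz, m2$xyz)
  expect_error(toy_fold_spec("HHXHHHHHHH"), "unknown")
  expect_error(make_toy_fold(toy_fold_spec("HHHH")), "at least 10")
})

test_that("compact toys fold back on themselves without steric clashes", {
  m <- make_toy_fold(compact_spec(), 2, n_steps = 150)
  L <- m$length
  d <- as.matrix(dist(m$xyz$CA))
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  expect_gt(sum(d < 8 & sep > 8) / 2, 5)   # genuine long-range contacts
  expect_gt(min(d[sep >= 2]), 3.5)
})

test_that("oracle distogram concentrates on the true bin at zero noise", {
  m <- helix_model(15)
  cfg <- zero_noise_config()
  d <- oracle_distogram(m, cfg)
  truth <- cb_distance_matrix(m)
  sc <- d$scheme
  for (pair in list(c(1, 5), c(2, 9), c(3, 14))) {
    k <- bin_index(sc, truth[pair[1], pair[2]])
    expect_equal(d$likelihoods[pair[1], pair[2], k], 1, tolerance = 1e-6)
  }
  sums <- apply(d$likelihoods, c(1, 2), sum)
  expect_equal(as.numeric(sums), rep(1, 225), tolerance = 1e-9)
  expect_identical(d$likelihoods,
                   oracle_distogram(m, cfg)$likelihoods)   # determinism
  expect_true(all(d$likelihoods == aperm(d$likelihoods, c(2, 1, 3))))
})

test_that("corrupted pairs are uniform and seeding sharpens true pairs", {
  m <- make_toy_fold(compact_spec(), 1, n_steps = 100)
  cfg <- oracle_config(distance_sigma = 1.2, corruption_rate = 1,
                       rng_seed = 5)
  d <- oracle_distogram(m, cfg)
  expect_equal(d$likelihoods[1, 10, ], rep(1 / 20, 20))
  # accretion over a uniform distribution needs 8 bins for 0.4
  b <- accrete_bounds(d$likelihoods[1, 10, ])
  expect_equal(b$cum_likelihood, 0.4)
  # ties resolve to the first bin, so the interval is the 8 lowest bins
  expect_equal(c(b$lower, b$upper), c(3.5, 8))
  # seed conditioning: a truthful seed halves the blur on matching pairs
  cfg2 <- oracle_config(distance_sigma = 1.2, corruption_rate = 0,
                        seed_coupling = 0.75, rng_seed = 5)
  d_un <- oracle_distogram(m, cfg2)
  d_se <- oracle_distogram(m, cfg2, seed_model = m)
  truth <- cb_distance_matrix(m)
  k <- bin_index(d_se$scheme, truth[2, 12])
  expect_gt(d_se$likelihoods[2, 12, k], d_un$likelihoods[2, 12, k])
  expect_error(oracle_distogram(m, cfg2, seed_model = helix_model(10)),
               "length")
})

test_that("information degrades monotonically with noise", {
  m <- make_toy_fold(compact_spec(), 1, n_steps = 100)
  truth <- cb_distance_matrix(m)
  sc <- default_bin_scheme()
  tb <- matrix(bin_index(sc, truth), nrow(truth))
  frac_correct <- function(sigma, corr) {
    vals <- sapply(1:3, function(s) {
      d <- oracle_distogram(m, oracle_config(distance_sigma = sigma,
                                             corruption_rate = corr,
                                             rng_seed = s))
      mb <- apply(d$likelihoods, c(1, 2), which.max)
      mean((mb == tb)[upper.tri(tb)])
    })
    mean(vals)
  }
  by_sigma <- sapply(c(0.2, 1, 3), frac_correct, corr = 0)
  expect_true(all(diff(by_sigma) <= 1e-9))
  by_corr <- sapply(c(0, 0.3, 0.8), function(cc) frac_correct(0.5, cc))
  expect_true(all(diff(by_corr) <= 1e-9))
})

test_that("oracle hbond maps reflect helix geometry and stay asymmetric", {
  m <- helix_model(20)
  cfg <- zero_noise_config()
  mp <- oracle_hbonds(m, cfg)
  hits <- which(mp >= 0.5, arr.ind = TRUE)
  # every i -> i-4 helical H-bond is present; offsets stay local
  off <- hits[, 1] - hits[, 2]
  expect_equal(sum(off == 4), m$length - 4)
  expect_true(all(off >= 2 & off <= 4))
  expect_false(isSymmetric(mp))
  # fully extended chain: no N-O pair within 3.5 A
  ext <- strand_model(20)
  expect_true(all(oracle_hbonds(ext, cfg) <= cfg$hbond_false_likelihood))
})

test_that("oracle torsions wrap correctly and scale with sigma", {
  m <- helix_model(15)
  t0 <- oracle_torsions(m, zero_noise_config())
  ref <- distfold:::backbone_torsions(m)
  expect_equal(t0$phi[-1], ref$phi[-1], tolerance = 1e-9)
  expect_equal(t0$psi[-15], ref$psi[-15], tolerance = 1e-9)
  cfg <- oracle_config(torsion_sigma = 0.3, rng_seed = 8)
  tn <- oracle_torsions(m, cfg)
  expect_true(all(tn$phi > -pi & tn$phi <= pi, na.rm = TRUE))
  expect_equal(tn$phi_err, rep(0.3, 15))
  # mean absolute circular error over many residues ~ sigma * sqrt(2/pi)
  big <- helix_model(500)
  bt <- oracle_torsions(big, oracle_config(torsion_sigma = 0.2,
                                           rng_seed = 3))
  bref <- distfold:::backbone_torsions(big)
  err <- abs(distfold:::circ_diff(bt$phi[-1], bref$phi[-1]))
  expect_equal(mean(err), 0.2 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("synthetic MSAs follow the independent-site mutation model", {
  a <- make_msa(5, 30, 0, rng_seed = 2)
  expect_true(all(a$sequences == a$sequences[1]))
  expect_equal(make_msa(1, 10, 0.5)$n, 1L)
  big <- make_msa(40, 400, 0.3, rng_seed = 4)
  ids <- sapply(2:40, function(k)
    pairwise_identity(big$sequences[1], big$sequences[k]))
  expect_equal(mean(ids), 0.7, tolerance = 0.03)
  expect_identical(make_msa(6, 50, 0.2, rng_seed = 9)$sequences,
                   make_msa(6, 50, 0.2, rng_seed = 9)$sequences)
})
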