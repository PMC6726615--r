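test_that("bound smoothing applies triangle inequalities without breaking inputs", {
  empty <- data.frame(i = numeric(0), j = numeric(0), lower = numeric(0),
                      upper = numeric(0), cum_likelihood = numeric(0))
  sm <- smooth_bounds(empty, 3)
  expect_lte(sm$upper[1, 3], sm$upper[1, 2] + sm$upper[2, 3] + 1e-9)
  # loose input upper tightened by the chain path
  b <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                  lower = c(3.8, 3.8, 3.5), upper = c(4, 4, 100),
                  cum_likelihood = 1)
  sm <- smooth_bounds(b, 3)
  expect_lte(sm$upper[1, 3], 8)
  # an already-tight input bound is preserved
  b2 <- data.frame(i = 1, j = 3, lower = 6, upper = 6.5,
                   cum_likelihood = 1)
  sm2 <- smooth_bounds(b2, 4)
  expect_equal(sm2$lower[1, 3], 6)
  expect_equal(sm2$upper[1, 3], 6.5)
  # contradictions are reported and relaxed
  bad <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                    lower = c(4, 4, 15), upper = c(4.2, 4.2, 16),
                    cum_likelihood = 1)
  expect_warning(smu <- smooth_bounds(bad, 3), "contradictory")
  expect_true(all(smu$lower <= smu$upper + 1e-9))
})

test_that("metric-matrix embedding reproduces exact distances up to a rigid motion", {
  m <- make_toy_fold(compact_spec(), 1, n_steps = 100)
  ca <- m$xyz$CA
  D <- as.matrix(dist(ca))
  sm <- list(lower = D, upper = D)
  xyz <- embed_initial(sm, rng_seed = 1, polish_rounds = 0,
                       projection_rounds = 0)
  fit <- kabsch(xyz, ca)
  mfit <- kabsch(cbind(xyz[, 1:2], -xyz[, 3]), ca)
  expect_lt(min(fit$rmsd, mfit$rmsd), 0.1)
  # mirror flag gives the reflected embedding
  x2 <- embed_initial(sm, rng_seed = 1, mirror = TRUE,
                      polish_rounds = 0, projection_rounds = 0)
  expect_equal(x2[, 3], -xyz[, 3])
  expect_identical(embed_initial(sm, rng_seed = 4),
                   embed_initial(sm, rng_seed = 4))
})

test_that("refinement keeps a native start and prices violations quadratically", {
  m <- make_toy_fold(compact_spec(), 1, n_steps = 100)
  rs <- zero_noise_restraints(m)
  cfg <- builder_config(rng_seed = 1, n_stages = 4, moves_per_stage = 40)
  mod <- refine(m, rs, cfg)
  expect_lt(mod$energy$distance, 0.1)
  disp <- kabsch(mod$xyz$CA, m$xyz$CA)$rmsd
  expect_lt(disp, 0.5)
  # a single bound violated by exactly 1 A costs w * 1^2
  b <- data.frame(i = 2, j = 12, lower = 3.5, upper = 6,
                  cum_likelihood = 1)
  m2 <- helix_model(15)
  m2$xyz$CB[12, ] <- m2$xyz$CB[2, ] + c(7, 0, 0)
  rs2 <- restraint_set(b, sequence = m2$sequence)
  for (w in c(1, 2.5)) {
    eb <- energy_breakdown(m2, rs2, builder_config(w_distance = w))
    expect_equal(eb$distance, w * 1^2, tolerance = 1e-9)
  }
})

test_that("stage energies never rise within a stage", {
  m <- make_toy_fold(compact_spec(), 2, n_steps = 100)
  rs <- zero_noise_restraints(m, seed = 2)
  sm <- smooth_bounds(rs$bounds, rs$length)
  ca <- embed_initial(sm, 3)
  mod <- refine(ca, rs, builder_config(rng_seed = 3, n_stages = 6,
                                       moves_per_stage = 30))
  trace <- mod$energy$trace
  expect_true(all(trace[, "end"] <= trace[, "start"] + 1e-9))
})

test_that("mirror images tie on distance energy but lose on chirality", {
  m <- make_toy_fold(compact_spec(), 1, n_steps = 100)
  rs <- zero_noise_restraints(m)
  sm <- smooth_bounds(rs$bounds, rs$length)
  ca <- embed_initial(sm, 5)
  cfg <- builder_config(rng_seed = 5, n_stages = 3, moves_per_stage = 30)
  mod <- refine(ca, rs, cfg)
  mir <- mirror_model(mod)
  e_true <- energy_breakdown(mod, rs, cfg)
  e_mir <- energy_breakdown(mir, rs, cfg)
  expect_equal(e_mir$distance, e_true$distance, tolerance = 1e-9)
  expect_gt(e_mir$chirality, e_true$chirality)
})

test_that("ensembles are deterministic and reach high restraint satisfaction", {
  m <- make_toy_fold(compact_spec(), 1, n_steps = 100)
  rs <- zero_noise_restraints(m)
  cfg <- builder_config(rng_seed = 7, ensemble_size = 2, n_stages = 4,
                        moves_per_stage = 40)
  e1 <- build_ensemble(rs, cfg)
  expect_length(e1$models, 2L)
  e2 <- build_ensemble(rs, cfg)
  expect_identical(e1$models[[1]]$xyz, e2$models[[1]]$xyz)
  en <- vapply(e1$models, function(mm) mm$energy$total, 0)
  expect_true(all(diff(en) >= 0))          # sorted by energy
  # zero-noise closure: the best member satisfies nearly everything
  cs <- count_satisfied(rs, e1$models[[1]])
  expect_gte(sum(cs$satisfied) / sum(cs$total), 0.95)
  expect_gte(tm_score(e1$models[[1]], m), 0.9)
  # chain geometry survives refinement
  ca <- e1$models[[1]]$xyz$CA
  steps <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(steps >= 2.8 & steps <= 4.2))
  single <- build_ensemble(rs, builder_config(rng_seed = 2,
                                              ensemble_size = 1,
                                              n_stages = 2,
                                              moves_per_stage = 20))
  expect_length(single$models, 1L)
})

test_that("analytic energy gradients match finite differences", {
  m <- make_toy_fold(compact_spec(), 3, n_steps = 80)
  cfg <- oracle_config(distance_sigma = 0.8, corruption_rate = 0.1,
                       rng_seed = 5)
  rs <- restraint_set(
    distogram_to_bounds(oracle_distogram(m, cfg)),
    hbond_map_to_restraints(oracle_hbonds(m, cfg)),
    torsions_to_restraints(oracle_torsions(m, cfg)), m$sequence)
  at <- distfold:::model_atoms(m)
  tm <- distfold:::energy_terms(rs, at$aidx, builder_config())
  set.seed(8)
  X <- at$coords + matrix(rnorm(length(at$coords), sd = 0.8),
                          nrow(at$coords), 3)
  ev <- distfold:::energy_eval(X, tm)
  for (t in 1:20) {
    i <- sample(nrow(X), 1); k <- sample(3, 1); eps <- 1e-6
    X2 <- X; X2[i, k] <- X2[i, k] + eps
    num <- (distfold:::energy_eval(X2, tm, grad = FALSE)$total -
              ev$total) / eps
    expect_equal(num, ev$grad[i, k], tolerance = 1e-3)
  }
})
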