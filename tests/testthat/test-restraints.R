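# independent oracle: search all contiguous bin intervals containing the
# max-likelihood bin, replaying the greedy neighbour order, and return
# the first interval reaching the threshold
brute_accrete <- function(p, scheme, threshold = 0.4) {
  k <- which.max(p)
  if (k == 20) return(NULL)
  lo <- hi <- k; cum <- p[k]
  threshold <- threshold - 1e-9          # shared numeric tolerance
  while (cum < threshold) {
    left <- if (lo > 1) p[lo - 1] else -Inf
    right <- if (hi < 19) p[hi + 1] else -Inf
    if (left == -Inf && right == -Inf) break
    if (left >= right) { lo <- lo - 1; cum <- cum + p[lo] }
    else { hi <- hi + 1; cum <- cum + p[hi] }
  }
  if (cum < threshold) return(NULL)
  list(lower = scheme$edges[lo], upper = scheme$edges[hi + 1],
       cum_likelihood = cum)
}

test_that("bound accretion grows greedily from the max-likelihood bin", {
  sc <- default_bin_scheme()
  p <- numeric(20); p[9] <- 1               # all mass in [8, 9)
  b <- accrete_bounds(p, sc)
  expect_equal(c(b$lower, b$upper, b$cum_likelihood), c(8, 9, 1))
  # max-likelihood bin unbounded: nothing emitted
  p <- numeric(20); p[20] <- 0.9; p[1] <- 0.1
  expect_null(accrete_bounds(p, sc))
  # hand-simulated accretion: 0.20 @ [6,6.5), 0.30 @ [6.5,7), 0.25 @ [7,7.5)
  p <- numeric(20)
  p[c(5, 6, 7)] <- c(0.20, 0.30, 0.25)   # bins [6,6.5), [6.5,7), [7,7.5)
  p[-c(5, 6, 7)] <- 0.25 / 17
  b <- accrete_bounds(p, sc)
  expect_equal(c(b$lower, b$upper), c(6.5, 7.5))
  expect_equal(b$cum_likelihood, 0.55)
  expect_error(accrete_bounds(rep(1, 20), sc), "sum to 1")
})

test_that("accretion equals brute-force contiguous-interval search", {
  sc <- default_bin_scheme()
  set.seed(19)
  for (rep in 1:400) {
    p <- random_bin_vector(alpha = runif(1, 0.2, 3))
    got <- accrete_bounds(p, sc)
    want <- brute_accrete(p, sc)
    expect_equal(got, want)
    if (!is.null(got)) {
      expect_gte(got$cum_likelihood, 0.4)
      expect_lte(got$upper, 19)
      expect_gte(got$lower, 3.5)
    }
  }
  # gridded vectors on a 0.05 lattice
  for (rep in 1:200) {
    raw <- stats::rmultinom(1, 20, random_bin_vector())[, 1] / 20
    if (abs(sum(raw) - 1) > 1e-9) next
    expect_equal(accrete_bounds(raw, sc), brute_accrete(raw, sc))
  }
})

test_that("distogram_to_bounds honours thresholds and emits Cb-consistent bounds", {
  # all mass in the final bin everywhere: empty set
  L <- 8
  lik <- array(0, c(L, L, 20)); lik[, , 20] <- 1
  b <- distogram_to_bounds(distogram(lik, check = FALSE))
  expect_equal(nrow(b), 0L)
  # zero-noise oracle bounds are all satisfied by the generating model
  m <- make_toy_fold(compact_spec(), 1)
  rs <- zero_noise_restraints(m)
  cs <- count_satisfied(rs, m)
  expect_equal(cs["bounds", "fraction"], 1)
  expect_true(all(rs$bounds$upper <= 19))
  expect_true(all(rs$bounds$cum_likelihood >= 0.4))
  # flatter distributions give wider bounds for the same max bin
  sharp <- numeric(20); sharp[9] <- 0.8; sharp[10] <- 0.2
  flat <- numeric(20); flat[9] <- 0.15
  flat[c(5:8, 10:13)] <- (1 - 0.15) / 8
  sc <- default_bin_scheme()
  w_sharp <- with(accrete_bounds(sharp, sc), upper - lower)
  w_flat <- with(accrete_bounds(flat, sc), upper - lower)
  expect_gt(w_flat, w_sharp)
})

test_that("hbond restraint emission respects the likelihood threshold", {
  expect_equal(nrow(hbond_map_to_restraints(matrix(0, 6, 6))), 0L)
  mp <- matrix(0, 10, 10); mp[3, 7] <- 0.90
  h <- hbond_map_to_restraints(mp)
  expect_equal(h$donor, 3L)
  expect_equal(h$acceptor, 7L)
  mp <- matrix(0, 10, 10)
  mp[2, 6] <- 0.84; mp[3, 7] <- 0.85; mp[4, 8] <- 0.86
  h <- hbond_map_to_restraints(mp)
  expect_equal(nrow(h), 2L)
  expect_true(all(h$likelihood >= 0.85))
  expect_error(hbond_map_to_restraints(matrix(2, 3, 3)), "0, 1")
})

test_that("torsion restraints keep phi/psi, drop omega and floor deviations", {
  t0 <- torsions_to_restraints(list(omega = rep(pi, 5),
                                    omega_err = rep(0.1, 5)))
  expect_equal(nrow(t0), 0L)
  t1 <- torsions_to_restraints(list(phi = c(NA, -1.047),
                                    phi_err = c(NA, 0.2)))
  expect_equal(t1$target, -1.047)
  expect_equal(t1$deviation, 0.2)
  t2 <- torsions_to_restraints(list(psi = 1.0, psi_err = 0))
  expect_equal(t2$deviation, 0.087)
})

test_that("count_satisfied applies the per-category geometric rules", {
  m <- helix_model(12)
  empty <- restraint_set(sequence = m$sequence)
  cs <- count_satisfied(empty, m)
  expect_equal(cs$total, c(0L, 0L, 0L))
  expect_true(all(is.na(cs$fraction)))
  # single bound (5, 6) on a pair engineered to sit at 7.2 A
  m2 <- m
  m2$xyz$CB[10, ] <- m2$xyz$CB[2, ] + c(7.2, 0, 0)
  b <- data.frame(i = 2, j = 10, lower = 5, upper = 6,
                  cum_likelihood = 0.5)
  rs <- restraint_set(b, sequence = m$sequence)
  cs <- count_satisfied(rs, m2)
  expect_equal(cs["bounds", "satisfied"], 0)
  expect_equal(cs["bounds", "total"], 1)
  expect_error(count_satisfied(rs, helix_model(13)), "length")
})

test_that("restraint serialization: CNS-style midpoints, glycine CA, json round-trip", {
  sq <- paste(c("A", "A", "G", rep("A", 47)), collapse = "")
  b <- data.frame(i = c(3, 5), j = c(40, 30), lower = c(6.5, 4.5),
                  upper = c(7.5, 5.0), cum_likelihood = c(0.6, 0.9))
  h <- hbond_map_to_restraints({m <- matrix(0, 50, 50); m[4, 9] <- 0.9; m})
  tt <- torsions_to_restraints(list(phi = c(NA, -1.0, 0.5),
                                    phi_err = c(NA, 0.3, 0.1)))
  rs <- restraint_set(b, h, tt, sq, meta = list(iteration = 1))
  txt <- write_restraints(rs, dialect = "cns-tbl")
  lines <- strsplit(txt, "\n")[[1]]
  # midpoint arithmetic: (6.5, 7.5) -> 7.00 0.50 0.50
  expect_match(txt, "7\\.00 0\\.50 0\\.50", all = FALSE)
  # glycine at position 3 selects CA
  expect_match(grep("resid 3 ", lines, value = TRUE)[1], "name CA")
  expect_match(grep("resid 5 ", lines, value = TRUE)[1], "name CB")
  # empty set still yields a valid headed file
  etxt <- write_restraints(restraint_set(sequence = "AAAAAAAAAA"),
                           dialect = "cns-tbl")
  expect_match(etxt, "! distance restraints")
  expect_error(write_restraints(rs, dialect = "nonsense"))
  # native JSON round trip is lossless
  path <- tempfile(fileext = ".json")
  write_restraints(rs, path, dialect = "native-json")
  rs2 <- read_restraints(path)
  expect_equal(as.data.frame(unclass(rs2$bounds)),
               as.data.frame(unclass(rs$bounds)))
  expect_equal(rs2$hbonds$donor, rs$hbonds$donor)
  expect_equal(rs2$torsions$target, rs$torsions$target)
  expect_equal(rs2$sequence, rs$sequence)
  unlink(path)
})
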