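test_that("default bin scheme matches the 20-channel layout", {
  sc <- default_bin_scheme()
  expect_equal(sc$n_bins, 20L)
  expect_length(sc$edges, 21L)
  expect_equal(sc$edges[1:2], c(3.5, 4.5))     # first interval
  expect_equal(sc$edges[20], 19)
  expect_true(is.infinite(sc$edges[21]))       # last interval unbounded
  expect_equal(diff(sc$edges[2:9]), rep(0.5, 7))
  expect_equal(diff(sc$edges[9:20]), rep(1, 11))
  # 8.3 A falls in [8, 9)
  k <- bin_index(sc, 8.3)
  expect_equal(unname(c(sc$edges[k], sc$edges[k + 1])), c(8, 9))
  # sub-3.5 distances clamp into the first bin
  expect_equal(bin_index(sc, 2.0), 1L)
  expect_equal(bin_index(sc, 100), 20L)
})

test_that("symmetrization softmaxes the summed raw scores per pair", {
  L <- 4
  lg <- array(0, c(L, L, 20))
  d <- symmetrize(lg)
  expect_equal(d$likelihoods[1, 2, ], rep(1 / 20, 20))
  # asymmetric raw scores: both directions equal softmax(a + b)
  a <- rnorm(20); b <- rnorm(20)
  lg[1, 3, ] <- a; lg[3, 1, ] <- b
  d <- symmetrize(lg)
  expect_equal(d$likelihoods[1, 3, ], d$likelihoods[3, 1, ])
  expect_equal(d$likelihoods[1, 3, ], exp(a + b) / sum(exp(a + b)))
  # (ln 2, 0, ...) one way, zeros the other: 2/21 then 1/21 each
  lg <- array(0, c(L, L, 20))
  lg[2, 4, 1] <- log(2)
  d <- symmetrize(lg)
  expect_equal(d$likelihoods[2, 4, ], c(2 / 21, rep(1 / 21, 19)))
  expect_error(symmetrize(array(NaN, c(2, 2, 20))), "finite")
})

test_that("symmetrization is idempotent on symmetric logits and conserves mass", {
  set.seed(42)
  for (rep in 1:5) {
    L <- sample(3:8, 1)
    lg <- array(rnorm(L * L * 20), c(L, L, 20))
    lg <- lg + aperm(lg, c(2, 1, 3))        # symmetric raw scores
    d1 <- symmetrize(lg)
    # applying the construction to logs of the output keeps the result
    d2 <- symmetrize(log(d1$likelihoods) / 2)
    expect_equal(d1$likelihoods, d2$likelihoods, tolerance = 1e-9)
    sums <- apply(d1$likelihoods, c(1, 2), sum)
    expect_equal(as.numeric(sums), rep(1, L * L), tolerance = 1e-9)
  }
})

test_that("contact conversion sums the bins wholly below the cutoff", {
  L <- 5
  lik <- array(0, c(L, L, 20))
  lik[, , 1] <- 1                         # all mass in [3.5, 4.5)
  d <- distogram(lik, check = FALSE)
  cm <- distogram_to_contacts(d)
  expect_equal(cm$prob[1, 2], 1.0)
  expect_equal(diag(cm$prob), rep(0, L))
  u <- distogram(array(1 / 20, c(L, L, 20)), check = FALSE)
  expect_equal(distogram_to_contacts(u)$prob[1, 2], 8 / 20)  # 8 bins < 8 A
  expect_error(distogram_to_contacts(d, cutoff = 8.3), "bin edge")
})

test_that("contact probability is monotone in the cutoff", {
  d <- random_distogram(8, seed = 7)
  cuts <- c(4.5, 6, 8, 12, 19)
  probs <- sapply(cuts, function(cc) distogram_to_contacts(d, cc)$prob[2, 7])
  expect_true(all(diff(probs) >= -1e-12))
})

test_that("top_contacts ranks deterministically and matches brute force", {
  set.seed(11)
  for (rep in 1:5) {
    L <- sample(8:20, 1)
    p <- matrix(runif(L * L), L, L); p <- (p + t(p)) / 2; diag(p) <- 0
    cm <- structure(list(length = L, prob = p, cutoff = 8),
                    class = "contact_map")
    tc <- top_contacts(cm, n = L, min_separation = 5)
    # brute force: enumerate, sort by prob then lexicographic
    idx <- which(upper.tri(p) & abs(row(p) - col(p)) >= 5, arr.ind = TRUE)
    ord <- order(-p[idx], idx[, 1], idx[, 2])
    take <- head(ord, L)
    expect_equal(tc$i, unname(idx[take, 1]))
    expect_equal(tc$j, unname(idx[take, 2]))
  }
  # explicit tie: two equal probabilities, lower (i, j) first
  p <- matrix(0, 10, 10)
  p[1, 8] <- p[8, 1] <- 0.7
  p[2, 9] <- p[9, 2] <- 0.7
  cm <- structure(list(length = 10, prob = p, cutoff = 8),
                  class = "contact_map")
  tc <- top_contacts(cm, 2)
  expect_equal(tc$i, c(1, 2))
  # n beyond the available pairs returns everything ranked
  expect_equal(nrow(top_contacts(cm, 1e6)), sum(upper.tri(p) &
                                                  abs(row(p) - col(p)) >= 5))
})

test_that("distance-error statistics exclude long predictions and use bin centers", {
  m <- helix_model(12)
  # craft a distogram whose every pair has mass on the true bin
  cfg <- zero_noise_config()
  d <- oracle_distogram(m, cfg)
  st <- distance_error_stats(d, m)
  expect_true(st$mean <= 0.5)             # within half the bin width
  # single off pair: mass on [8, 9), truth forced to 10
  L <- m$length
  lik <- array(rep(1 / 20, L * L * 20), c(L, L, 20))
  lik[1, 5, ] <- lik[5, 1, ] <- c(rep(0, 8), 1, rep(0, 11))  # bin [8,9)
  lik[1, 5, 9] <- lik[5, 1, 9] <- 1
  d2 <- distogram(lik, check = FALSE)
  m2 <- m
  # place residue 5 CB exactly 10 A from residue 1 CB
  dir <- c(1, 0, 0)
  m2$xyz$CB[5, ] <- m2$xyz$CB[1, ] + 10 * dir
  # all other pairs get uniform mass -> max bin center is 4.0 (< 15, kept)
  st2 <- distance_error_stats(d2, m2, min_separation = 4)
  # the crafted pair contributes |8.5 - 10| = 1.5
  lik3 <- array(0, c(L, L, 20)); lik3[, , 20] <- 1
  lik3[1, 5, ] <- lik3[5, 1, ] <- c(rep(0, 8), 1, rep(0, 11))
  d3 <- distogram(lik3, check = FALSE)
  st3 <- distance_error_stats(d3, m2)
  expect_equal(st3$count, 1L)
  expect_equal(st3$mean, 1.5)
  # every max bin at or beyond 15 A: empty summary
  lik4 <- array(0, c(L, L, 20)); lik4[, , 20] <- 1
  d4 <- distogram(lik4, check = FALSE)
  st4 <- distance_error_stats(d4, m)
  expect_equal(st4$count, 0L)
  expect_true(is.na(st4$mean))
  expect_error(distance_error_stats(d, helix_model(13)), "length")
})

test_that("distogram serialization round-trips in both variants", {
  d <- random_distogram(5, seed = 3)
  for (fmt in c("tsv", "bin")) {
    path <- tempfile(fileext = if (fmt == "tsv") ".tsv" else ".bin")
    write_distogram(d, path, format = fmt)
    d2 <- read_distogram(path)
    expect_equal(d2$length, d$length)
    expect_equal(d2$scheme$edges, d$scheme$edges)
    expect_equal(d2$likelihoods, d$likelihoods,
                 tolerance = if (fmt == "tsv") 1e-7 else 1e-12)
    unlink(path)
  }
})

test_that("contact maps export in CASP RR dialect", {
  d <- random_distogram(12, seed = 5)
  cm <- distogram_to_contacts(d)
  path <- tempfile()
  write_casp_rr(cm, path, n = 10)
  lines <- readLines(path)
  expect_length(lines, 10)
  f <- read.table(text = lines)
  expect_true(all(f$V3 == 0) && all(f$V4 == 8))
  expect_true(all(diff(f$V5) <= 0))            # descending probability
  expect_true(all(f$V1 >= 1 & f$V2 <= 12))
  unlink(path)
})
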