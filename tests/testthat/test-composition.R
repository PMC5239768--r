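test_that("proportion standardization normalizes rows", {
  expect_equal(unname(standardize_proportions(rbind(c(2, 2)))[1, ]),
               c(0.5, 0.5))
  expect_equal(unname(standardize_proportions(rbind(c(7, 0, 0)))[1, ]),
               c(1, 0, 0))
  set.seed(1)
  m <- matrix(rpois(60, 4), 6, 10)
  m[1, ] <- m[1, ] + 1
  p <- suppressWarnings(standardize_proportions(m))
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  z <- rbind(c(1, 2), c(0, 0))
  expect_warning(pz <- standardize_proportions(z), "dropped")
  expect_equal(nrow(pz), 1)
})

test_that("Bray-Curtis matches hand arithmetic and boundary cases", {
  expect_equal(bray_curtis(c(6, 2, 0), c(2, 2, 4)), 0.5)
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("Bray-Curtis equals the vegan implementation on random data", {
  set.seed(7)
  for (r in 1:5) {
    m <- matrix(rpois(48, 5), 6, 8) + matrix(rbinom(48, 1, 0.5), 6, 8)
    mine <- bray_curtis_matrix(m)
    ref <- as.matrix(vegan::vegdist(m, method = "bray"))
    expect_lt(max(abs(mine - ref)), 1e-10)
  }
})

test_that("proportion standardization makes Bray-Curtis scale-invariant", {
  set.seed(9)
  m <- matrix(rpois(40, 6) + 1, 4, 10)
  m2 <- m
  m2[2, ] <- m2[2, ] * 17          # inflate one class's total catch
  p1 <- standardize_proportions(m)
  p2 <- standardize_proportions(m2)
  expect_equal(bray_curtis_matrix(p1), bray_curtis_matrix(p2),
               tolerance = 1e-12)
})

test_that("NMDS recovers planar configurations with near-zero stress", {
  set.seed(11)
  pts <- matrix(runif(16), 8, 2)
  d <- as.matrix(dist(pts))
  fit <- nmds(d, k = 2, n_restarts = 10, seed = 4)
  expect_lt(fit$stress, 1e-3)
})

test_that("NMDS stress cannot rise with dimension and ranks are preserved", {
  set.seed(13)
  m <- matrix(runif(36), 6, 6)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  s2 <- nmds(d, k = 2, n_restarts = 10, seed = 1)$stress
  s5 <- nmds(d, k = 5, n_restarts = 10, seed = 1)$stress
  expect_lte(s5, s2 + 1e-8)

  # 3-point metric: recovered distance ranks match input ranks
  d3 <- matrix(0, 3, 3)
  d3[1, 2] <- d3[2, 1] <- 0.2
  d3[1, 3] <- d3[3, 1] <- 0.4
  d3[2, 3] <- d3[3, 2] <- 0.5
  fit <- nmds(d3, k = 2, n_restarts = 20, seed = 2)
  rec <- as.matrix(dist(fit$points))
  expect_equal(order(c(rec[1, 2], rec[1, 3], rec[2, 3])), c(1, 2, 3))
})

test_that("NMDS is reproducible for a fixed seed and validates input", {
  set.seed(15)
  m <- matrix(runif(25), 5, 5)
  d <- (m + t(m)) / 2; diag(d) <- 0
  f1 <- nmds(d, seed = 8)
  f2 <- nmds(d, seed = 8)
  expect_identical(f1$points, f2$points)
  bad <- d; bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(nmds(bad), "symmetric")
})

test_that("multivariate edge statistic is invariant to species order", {
  set.seed(17)
  y <- matrix(rnbinom(20 * 6, mu = 5, size = 1), 20, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  g <- rep(c("edge", "interior"), each = 10)
  s1 <- multivariate_edge_test(y, g, n_boot = 5, seed = 1)$statistic
  s2 <- multivariate_edge_test(y[, 6:1], g, n_boot = 5, seed = 1)$statistic
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("multivariate edge test drops empty species and validates groups", {
  set.seed(19)
  y <- cbind(matrix(rpois(30, 4), 10, 3), 0)
  colnames(y) <- paste0("s", 1:4)
  g <- rep(c("a", "b"), each = 5)
  expect_warning(r <- multivariate_edge_test(y, g, n_boot = 19, seed = 2),
                 "all-zero")
  expect_equal(r$dropped_species, "s4")
  expect_error(multivariate_edge_test(y[, 1:3], rep("a", 10), n_boot = 9),
               "2 levels")
})

test_that("multivariate edge test controls type-I error under the null", {
  set.seed(23)
  n_rep <- 1000
  rej <- 0; pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    y <- matrix(rnbinom(20 * 8, mu = 6, size = 1.5), 20, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
    g <- rep(c("edge", "interior"), each = 10)
    p <- suppressWarnings(
      multivariate_edge_test(y, g, n_boot = 199)$p_value)
    pvals[r] <- p
  }
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  expect_gt(median(pvals), 0.4)
  expect_lt(median(pvals), 0.6)
})

test_that("multivariate edge test detects a strong composition shift", {
  set.seed(29)
  n_rep <- 40
  hits <- replicate(n_rep, {
    mu <- rep(6, 8)
    mu_edge <- mu * rep(c(2, 0.5), each = 4)   # half the species shifted 2x
    y <- rbind(
      matrix(rnbinom(15 * 8, mu = rep(mu_edge, each = 15), size = 1.5), 15, 8),
      matrix(rnbinom(15 * 8, mu = rep(mu, each = 15), size = 1.5), 15, 8))
    colnames(y) <- paste0("s", 1:8)
    g <- rep(c("edge", "interior"), each = 15)
    suppressWarnings(
      multivariate_edge_test(y, g, n_boot = 999)$p_value) <= 0.005
  })
  expect_gte(mean(hits), 0.95)
})
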