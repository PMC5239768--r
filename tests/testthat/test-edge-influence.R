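test_that("MEI matches its closed form on known cases", {
  expect_equal(mei(c(10, 10), c(10, 10)), 0)
  # means 48.6 and 129.3 (the case-study abundance contrast)
  expect_equal(round(mei(c(48.6, 48.6), c(129.3, 129.3)), 4), -0.4536)
  expect_equal(mei(c(0, 0, 0), c(5, 7)), -1)
  expect_error(mei(c(0, 0), c(0, 0)), "undefined")
  expect_error(mei(numeric(0), 1), "non-empty")
  expect_error(mei(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("MEI is antisymmetric and scale-invariant", {
  set.seed(101)
  for (r in 1:50) {
    e <- rpois(sample(2:10, 1), 8)
    i <- rpois(sample(2:10, 1), 3) + 1
    expect_equal(mei(e, i), -mei(i, e))
    c0 <- runif(1, 0.1, 50)
    expect_equal(mei(e * c0, i * c0), mei(e, i))
    expect_lte(abs(mei(e, i)), 1)
  }
})

test_that("RTEI handles degenerate pools and tiny n_rand", {
  expect_warning(r <- rtei(c(5, 5, 5), c(5, 5, 5), n_rand = 100, seed = 1),
                 "degenerate")
  expect_equal(r$mei, 0)
  expect_equal(r$p_value, 1)

  r1 <- rtei(c(1, 2), c(8, 9), n_rand = 1, seed = 1)
  expect_true(r1$p_value %in% c(0.5, 1))
  expect_gte(r1$p_value, 1 / (r1$n_rand + 1))
})

test_that("seeded RTEI p-values agree with exhaustive enumeration", {
  cases <- list(list(e = c(0, 1, 0), i = c(9, 10, 11)),
                list(e = c(2, 4, 1), i = c(3, 5, 2, 6, 1)),
                list(e = c(7, 9), i = c(1, 2, 3, 4)))
  for (cs in cases) {
    exact <- rtei_exact_p(cs$e, cs$i)
    r <- rtei(cs$e, cs$i, n_rand = 4000, seed = 99)
    mc_se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(r$p_value - exact), 2 * mc_se + 1e-3)
  }
})

test_that("RTEI null p-values are approximately uniform", {
  set.seed(2024)
  pvals <- replicate(400, {
    rtei(rnbinom(24, mu = 10, size = 2), rnbinom(24, mu = 10, size = 2),
         n_rand = 199)$p_value
  })
  expect_gt(mean(pvals <= 0.05), 0.02)
  expect_lt(mean(pvals <= 0.05), 0.09)
  expect_gt(mean(pvals <= 0.25), 0.19)
  expect_lt(mean(pvals <= 0.25), 0.31)
})

test_that("DEI follows its contiguous-significance definition", {
  d <- c(0, 6, 12, 25, 50, 100)
  r <- dei(data.frame(distance_m = d,
                      significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)))
  expect_equal(r$range, c(0, 50))
  expect_false(r$empty)

  # a later isolated significant distance does not extend the DEI
  r2 <- dei(data.frame(distance_m = d,
                       significant = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)))
  expect_equal(r2$range, c(0, 6))

  r3 <- dei(data.frame(distance_m = d, significant = rep(FALSE, 6)))
  expect_true(r3$empty)

  expect_error(dei(data.frame(distance_m = c(6, 0), significant = c(TRUE, TRUE))),
               "ordered")
})

test_that("DEI recovers a known 25 m edge zone in most replicates", {
  d <- c(0, 6, 12, 25, 50, 100)
  hits <- 0
  n_rep <- 200
  set.seed(77)
  for (r in seq_len(n_rep)) {
    interior <- rnbinom(58, mu = 10, size = 2)
    tab <- data.frame(distance_m = d, significant = NA)
    for (j in seq_along(d)) {
      mu <- if (d[j] <= 25) 2.5 else 10   # strong effect vanishing beyond 25 m
      edge <- rnbinom(24, mu = mu, size = 2)
      tab$significant[j] <- rtei(edge, interior, n_rand = 299)$significant
    }
    out <- dei(tab)
    if (!out$empty && identical(out$range, c(0, 25))) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("rtei_profile ties distances, interior reference and DEI together", {
  set.seed(5)
  d <- rep(c(0, 6, 12, 25, 50, 100), each = 24)
  vals <- rnbinom(length(d), mu = ifelse(d <= 12, 2, 10), size = 2)
  interior <- rnbinom(58, mu = 10, size = 2)
  prof <- rtei_profile(c(vals, interior),
                       c(d, rep(NA, 58)),
                       c(rep(FALSE, length(d)), rep(TRUE, 58)),
                       n_rand = 499, seed = 12, variable = "abundance")
  expect_equal(prof$table$distance_m, c(0, 6, 12, 25, 50, 100))
  expect_true(all(prof$table$significant[1:3]))
  expect_identical(prof$dei$range, c(0, prof$dei$range[2]))
  # deterministic under the same seed
  prof2 <- rtei_profile(c(vals, interior), c(d, rep(NA, 58)),
                        c(rep(FALSE, length(d)), rep(TRUE, 58)),
                        n_rand = 499, seed = 12, variable = "abundance")
  expect_identical(prof$table, prof2$table)
})
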