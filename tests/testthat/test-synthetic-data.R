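test_that("default design lays out the full trap complement", {
  locs <- generate_design(study_design())
  expect_equal(sum(locs$habitat == "road_edge"), 144)
  expect_equal(sum(locs$habitat == "interior"), 58)
  expect_equal(sum(locs$habitat == "primary"), 60)
  expect_equal(nrow(locs), 262)
  expect_false(anyDuplicated(locs$trap_id) > 0)
})

test_that("degenerate and invalid designs behave as specified", {
  one <- generate_design(study_design(n_edge_plots = 1,
                                      edge_distances_m = 0,
                                      n_interior_transects = 0,
                                      n_primary_transects = 0))
  expect_equal(nrow(one), 1)
  expect_equal(one$distance_m, 0)

  expect_error(study_design(edge_distances_m = c(12, 6, 0)), "increasing")
  expect_error(study_design(edge_distances_m = c(-5, 0, 10)), "non-negative")
})

test_that("within-plot trap spacing respects the minimum", {
  locs <- generate_design(study_design())
  edge <- locs[locs$habitat == "road_edge", ]
  for (p in unique(edge$plot_id)) {
    sub <- edge[edge$plot_id == p, c("x", "y")]
    expect_gte(min(dist(sub)), 50)
  }
})

test_that("generated tables are bit-identical for a fixed seed", {
  locs <- generate_design(study_design())
  m <- community_model()
  expect_identical(generate_counts(locs, m, seed = 42),
                   generate_counts(locs, m, seed = 42))
  expect_identical(generate_vegetation(locs, seed = 42),
                   generate_vegetation(locs, seed = 42))
  expect_false(identical(generate_counts(locs, m, seed = 42),
                         generate_counts(locs, m, seed = 43)))
})

test_that("counts are non-negative integers at design distances only", {
  locs <- generate_design(study_design())
  s <- generate_counts(locs, community_model(), seed = 3)
  expect_true(all(s$count > 0))                 # zeros are implicit
  expect_true(all(s$count == round(s$count)))
  expect_true(all(s$distance_m[s$habitat == "road_edge"] %in%
                    c(0, 6, 12, 25, 50, 100)))
})

test_that("flat community with no plot noise converges to its target mean", {
  # beta1 = 0 by making edge and interior group targets equal
  g <- data.frame(
    guild = rep(c("tunneller", "roller"), c(4, 3)),
    diel = c("diurnal", "nocturnal", "diurnal", "nocturnal",
             "diurnal", "nocturnal", "diurnal"),
    size_class = c("large", "large", "small", "small", "large", "large", "small"),
    interior_mean = c(13, 11.3, 55.6, 6.4, 20.4, 1.5, 21),
    edge_mean = c(13, 11.3, 55.6, 6.4, 20.4, 1.5, 21))
  m <- community_model(plot_random_sd = 0, groups = g,
                       total_interior_mean = 129.3)
  expect_true(all(abs(m$groups$beta1) < 1e-12))

  n <- 4000
  locs <- generate_design(study_design(n_edge_plots = n, edge_distances_m = 0,
                                       n_interior_transects = 0,
                                       n_primary_transects = 0))
  s <- generate_counts(locs, m, seed = 11)
  per_trap <- tapply(s$count, factor(s$trap_id, levels = locs$trap_id), sum)
  per_trap[is.na(per_trap)] <- 0
  mc_se <- sd(per_trap) / sqrt(n)
  expect_lt(abs(mean(per_trap) - 129.3), 3 * mc_se)
})

test_that("very large dispersion approaches the Poisson limit", {
  g <- data.frame(guild = rep(c("tunneller", "roller"), c(4, 3)),
                  diel = c("diurnal", "nocturnal", "diurnal", "nocturnal",
                           "diurnal", "nocturnal", "diurnal"),
                  size_class = c("large", "large", "small", "small",
                                 "large", "large", "small"),
                  interior_mean = rep(10, 7), edge_mean = rep(10, 7))
  m <- community_model(theta = 1e7, plot_random_sd = 0, groups = g,
                       total_interior_mean = 70)
  locs <- generate_design(study_design(n_edge_plots = 3000,
                                       edge_distances_m = 0,
                                       n_interior_transects = 0,
                                       n_primary_transects = 0))
  s <- generate_counts(locs, m, seed = 5)
  per_trap <- tapply(s$count, factor(s$trap_id, levels = locs$trap_id), sum)
  per_trap[is.na(per_trap)] <- 0
  # sum of independent Poissons is Poisson: variance/mean near 1
  expect_lt(abs(var(per_trap) / mean(per_trap) - 1), 0.1)
})

test_that("NB dispersion is recoverable from generated single-species counts", {
  m <- community_model(theta = 1.5, plot_random_sd = 0)
  locs <- generate_design(study_design(n_edge_plots = 500,
                                       edge_distances_m = 0,
                                       n_interior_transects = 0,
                                       n_primary_transects = 0))
  s <- generate_counts(locs, m, seed = 8)
  sp <- m$species$species[which.max(m$species$interior_mean)]
  y <- integer(nrow(locs))
  names(y) <- locs$trap_id
  rows <- s[s$species == sp, ]
  y[rows$trap_id] <- rows$count
  fit <- suppressWarnings(MASS::glm.nb(y ~ 1))
  expect_lt(abs(fit$theta - 1.5) / 1.5, 0.2)
})

test_that("theta must be positive", {
  expect_error(community_model(theta = 0), "theta")
  expect_error(community_model(theta = -2), "theta")
})

test_that("group mean orderings implied by the slopes are realized", {
  locs <- generate_design(study_design())
  m <- community_model()
  tr <- default_traits(m)
  pooled <- do.call(rbind, lapply(1:5, function(s)
    trap_metrics(generate_counts(locs, m, seed = s), tr, locs)))
  gcols <- grep("^abund_", names(pooled), value = TRUE)
  edge0 <- colMeans(pooled[pooled$habitat == "road_edge" &
                             pooled$distance_m == 0, gcols])
  interior <- colMeans(pooled[pooled$habitat == "interior", gcols])
  key <- sub("abund_", "", gcols)
  b1 <- m$groups$beta1[match(key, m$groups$group)]
  strong <- b1 * m$psi_m > 0.5   # groups with a substantial edge decline
  expect_true(all(interior[strong] > edge0[strong]))
})

test_that("vegetation is deterministic, signed, and breakpoint-recoverable", {
  locs <- generate_design(study_design())
  v0 <- generate_vegetation(locs, noise_sd = 0, seed = 1)
  same_d <- v0[v0$distance_m %in% 50 & v0$habitat == "road_edge", ]
  expect_true(all(abs(same_d$canopy_cover - same_d$canopy_cover[1]) < 1e-12))

  v <- generate_vegetation(locs, seed = 2)
  e <- v[v$habitat == "road_edge", ]
  expect_gt(mean(e$successional_vegetation[e$distance_m == 0]),
            mean(e$successional_vegetation[e$distance_m == 100]))

  # noiseless piecewise fit recovers the vegetation breakpoint exactly
  e0 <- v0[v0$habitat == "road_edge", ]
  fit <- suppressWarnings(fit_piecewise(e0$canopy_cover, e0$distance_m,
                                        gaussian = TRUE))
  expect_equal(fit$psi, 34)
})
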