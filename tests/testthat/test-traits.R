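test_that("body size is the length-width product", {
  expect_equal(body_size(10, 5), 50)
  expect_equal(body_size(1, 1), 1)
  expect_equal(body_size(2 * 3, 2 * 4), 4 * body_size(3, 4))
  expect_error(body_size(0, 5), "positive")
  expect_error(body_size(3, -1), "positive")
})

test_that("allometric extrapolation recovers an exact power law", {
  set.seed(1)
  n <- 12
  traits <- data.frame(
    species = sprintf("sp%02d", 1:n),
    length_mm = runif(n, 5, 25),
    width_mm = runif(n, 3, 12))
  size <- traits$length_mm * traits$width_mm
  true_mass <- 0.001 * size^1.5
  traits$mean_mass_g <- true_mass
  traits$mean_mass_g[c(3, 7, 10, 11)] <- NA

  out <- extrapolate_mass(traits)
  expect_false(anyNA(out$mean_mass_g))
  expect_equal(out$mean_mass_g[c(3, 7, 10, 11)], true_mass[c(3, 7, 10, 11)],
               tolerance = 1e-6)
  expect_equal(out$mean_mass_g[1], true_mass[1])        # measured: unchanged
  expect_true(all(out$mass_imputed == is.na(traits$mean_mass_g)))
  expect_gt(attr(out, "allometry")["b"], 0)
  expect_equal(unname(attr(out, "r_squared")), 1, tolerance = 1e-12)
})

test_that("extrapolation refuses an inadequate calibration set", {
  traits <- data.frame(species = paste0("s", 1:6), length_mm = 1:6 + 3,
                       width_mm = 1:6 + 1,
                       mean_mass_g = c(0.1, 0.2, NA, NA, NA, NA))
  expect_error(extrapolate_mass(traits), "too few calibration")
})

test_that("trap metrics match hand arithmetic", {
  traits <- data.frame(
    species = c("A", "B"), guild = c("tunneller", "roller"),
    diel = c("diurnal", "nocturnal"), size_class = c("large", "small"),
    length_mm = c(10, 5), width_mm = c(5, 3), mean_mass_g = c(0.1, 0.2))
  samples <- data.frame(
    trap_id = c("t1", "t1"), plot_id = "p1", habitat = "road_edge",
    distance_m = 0, x = 0, y = 0, species = c("A", "B"), count = c(2L, 3L))
  m <- trap_metrics(samples, traits)
  expect_equal(m$richness, 2)
  expect_equal(m$abundance, 5)
  expect_equal(m$biomass_g, 0.8)
  expect_equal(m$abund_large_diurnal_tunneller, 2)
  expect_equal(m$abund_small_nocturnal_roller, 3)
})

test_that("capture-free traps appear as zero rows when locations are given", {
  traits <- data.frame(
    species = "A", guild = "tunneller", diel = "diurnal",
    size_class = "large", length_mm = 10, width_mm = 5, mean_mass_g = 0.1)
  samples <- data.frame(trap_id = "t1", plot_id = "p1", habitat = "road_edge",
                        distance_m = 0, x = 0, y = 0, species = "A",
                        count = 4L)
  locs <- data.frame(trap_id = c("t1", "t2"), plot_id = "p1",
                     habitat = "road_edge", distance_m = c(0, 6),
                     x = c(0, 60), y = c(0, 6))
  m <- trap_metrics(samples, traits, locs)
  expect_equal(nrow(m), 2)
  empty <- m[m$trap_id == "t2", ]
  expect_equal(empty$richness, 0)
  expect_equal(empty$abundance, 0)
  expect_equal(empty$biomass_g, 0)
})

test_that("missing trait rows are reported by species", {
  traits <- data.frame(species = "A", guild = "tunneller", diel = "diurnal",
                       size_class = "large", length_mm = 10, width_mm = 5,
                       mean_mass_g = 0.1)
  samples <- data.frame(trap_id = "t1", plot_id = "p1", habitat = "road_edge",
                        distance_m = 0, x = 0, y = 0,
                        species = c("A", "ghost"), count = c(1L, 1L))
  expect_error(trap_metrics(samples, traits), "ghost")
})

test_that("group abundances partition total abundance on synthetic data", {
  locs <- generate_design(study_design())
  model <- community_model()
  tm <- trap_metrics(generate_counts(locs, model, seed = 4),
                     default_traits(model), locs)
  gcols <- grep("^abund_", names(tm), value = TRUE)
  expect_equal(rowSums(tm[, gcols]), tm$abundance, tolerance = 1e-12,
               ignore_attr = TRUE)
  # biomass additive over traps
  expect_equal(sum(tm$biomass_g),
               sum(trap_metrics(generate_counts(locs, model, seed = 4),
                                default_traits(model))$biomass_g),
               tolerance = 1e-9)
})
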