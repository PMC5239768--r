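HABITATS <- c("road_edge", "interior", "primary")

#' Read and validate a long-format trap sample table
#'
#' @param path CSV with columns `trap_id`, `plot_id`, `habitat`,
#'   `distance_m`, `x`, `y`, `species`, `count`.
#' @return Validated data.frame; counts are integer, habitat levels checked.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("trap_id", "plot_id", "habitat", "distance_m", "x", "y",
           "species", "count")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(x$count) | x$count < 0 |
                 abs(x$count - round(x$count)) > 1e-8)
  if (length(bad) > 0)
    stop("invalid count at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  x$count <- as.integer(round(x$count))
  unknown <- setdiff(unique(x$habitat), HABITATS)
  if (length(unknown) > 0)
    stop("unknown habitat level(s): ", paste(unknown, collapse = ", "))
  if (any(!is.na(x$distance_m) & x$distance_m < 0))
    stop("negative distance_m")
  x
}

#' Write a trap sample table
#' @param x Sample table.
#' @param path Output CSV path.
#' @export
write_samples <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a species trait table
#' @param path CSV with `species`, `guild`, `diel`, `size_class`,
#'   `length_mm`, `width_mm`, `mean_mass_g` (may contain NA).
#' @return Validated data.frame.
#' @export
read_traits <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "guild", "diel", "size_class", "length_mm", "width_mm",
           "mean_mass_g")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(x$guild %in% c("tunneller", "roller")) ||
      !all(x$diel %in% c("diurnal", "nocturnal")) ||
      !all(x$size_class %in% c("large", "small")))
    stop("invalid trait level(s)")
  if (any(stats::na.omit(x$mean_mass_g) <= 0))
    stop("measured masses must be positive")
  x
}

#' Read a per-trap vegetation table
#' @param path CSV from [generate_vegetation()] (or the same layout).
#' @return data.frame.
#' @export
read_vegetation <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"trap_id" %in% names(x)) stop("missing column: trap_id")
  x
}

#' Widen a long sample table to a trap x species count matrix
#'
#' @param samples Long-format sample table.
#' @param locations Optional trap table; when given, capture-free traps
#'   appear as all-zero rows.
#' @param species Optional species vector fixing the column set and order.
#' @return Integer matrix, rows named by trap, columns by species.
#' @export
widen_counts <- function(samples, locations = NULL, species = NULL) {
  traps <- if (is.null(locations)) unique(samples$trap_id) else locations$trap_id
  if (is.null(species)) species <- sort(unique(samples$species))
  m <- matrix(0L, length(traps), length(species),
              dimnames = list(traps, species))
  ri <- match(samples$trap_id, traps)
  ci <- match(samples$species, species)
  keep <- !is.na(ri) & !is.na(ci)
  for (k in which(keep)) m[ri[k], ci[k]] <- m[ri[k], ci[k]] + samples$count[k]
  m
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline consumes a seed derived
#' deterministically from the single master seed and the stage name, so no
#' stage depends on hidden global random state.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return Integer seed in \[0, 2^31).
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(as.character(stage)) *
             (31^(seq_along(utf8ToInt(as.character(stage))) %% 7)))
  as.integer((as.numeric(master) * 1009 + h) %% 2147483647)
}

#' Pipeline run configuration
#'
#' Bundles and validates every tunable of the end-to-end run: Monte Carlo
#' sizes, significance level, and the landscape accounting inputs. Defaults
#' reproduce the emulated study's settings (10,000 RTEI randomizations, 1000
#' bootstrap and permutation resamples, alpha 0.05, 170 m edge limit, 2403 km
#' of road in a 9078 km^2 logged landscape).
#'
#' @param seed Master seed.
#' @param n_rand RTEI randomizations.
#' @param n_boot Composition-test bootstrap resamples.
#' @param n_perm Moran's I permutations.
#' @param alpha Significance level.
#' @param edge_limit_m Edge-effect penetration distance (m).
#' @param road_length_km Total road length (km).
#' @param logged_area_km2 Logged-landscape area (km^2).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_rand = 10000, n_boot = 1000, n_perm = 1000,
                       alpha = 0.05, edge_limit_m = 170,
                       road_length_km = 2403, logged_area_km2 = 9078) {
  if (n_rand < 1 || n_boot < 1 || n_perm < 1)
    stop("resample counts must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (edge_limit_m < 0 || road_length_km < 0 || logged_area_km2 <= 0)
    stop("landscape inputs must be non-negative (area positive)")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains every stage end to end: synthetic data generation, per-trap
#' metrics, RTEI edge-influence profiles with DEI, piecewise gradient fits,
#' community composition (NMDS + multivariate edge test), the vegetation
#' GLMM with its Moran's I residual diagnostic, and landscape accounting.
#' All stage seeds derive from the master seed. Any stage failure aborts
#' with an error naming the stage.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, each stage's table is
#'   written there as CSV.
#' @param design,model Study design and community model (defaults emulate
#'   the case-study conditions).
#' @param variables Metric columns to profile with RTEI and the piecewise
#'   fits.
#' @return Named list with each stage's results.
#' @export
run_all <- function(config = run_config(), out_dir = NULL,
                    design = study_design(), model = community_model(),
                    variables = c("abundance", "richness", "biomass_g")) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  out <- list(config = config)

  out$data <- stage("synthetic_data", {
    locations <- generate_design(design)
    samples <- generate_counts(locations, model,
                               seed = derive_seed(config$seed, "counts"))
    vegetation <- generate_vegetation(
      locations, seed = derive_seed(config$seed, "vegetation"))
    traits <- extrapolate_mass(model$species[, c("species", "guild", "diel",
                                                 "size_class", "length_mm",
                                                 "width_mm", "mean_mass_g")])
    list(locations = locations, samples = samples, vegetation = vegetation,
         traits = traits)
  })

  out$metrics <- stage("trap_metrics",
    trap_metrics(out$data$samples, out$data$traits, out$data$locations))

  out$edge_influence <- stage("edge_influence", {
    met <- out$metrics
    is_int <- met$habitat == "interior"
    on_edge <- met$habitat == "road_edge"
    sub <- met[is_int | on_edge, ]
    lapply(stats::setNames(variables, variables), function(v)
      rtei_profile(sub[[v]], sub$distance_m, sub$habitat == "interior",
                   n_rand = config$n_rand, alpha = config$alpha,
                   seed = derive_seed(config$seed, paste0("rtei_", v)),
                   variable = v))
  })

  out$gradients <- stage("gradient_models", {
    met <- out$metrics
    sub <- met[met$habitat != "primary", ]
    # biomass is continuous; round to the nearest gram for the count model
    lapply(stats::setNames(variables, variables), function(v)
      fit_piecewise(round(sub[[v]]), sub$distance_m))
  })

  out$composition <- stage("community_composition", {
    met <- out$metrics
    keep <- met$habitat == "road_edge" |
      (met$habitat == "interior" & met$distance_m >= 170)
    locs <- out$data$locations[out$data$locations$trap_id %in%
                                 met$trap_id[keep], ]
    counts <- widen_counts(out$data$samples, locs)
    grp <- ifelse(locs$habitat == "road_edge", "edge", "interior")
    # distance-class composition for the ordination
    cls <- ifelse(locs$habitat == "interior", "interior",
                  paste0("d", locs$distance_m))
    cls_counts <- rowsum(counts, cls)
    prop <- standardize_proportions(cls_counts)
    ord <- nmds(bray_curtis_matrix(prop), k = 2,
                seed = derive_seed(config$seed, "nmds"))
    test <- multivariate_edge_test(counts, grp, n_boot = config$n_boot,
                                   seed = derive_seed(config$seed, "mvtest"))
    list(class_proportions = prop, nmds = ord, test = test, group = grp)
  })

  out$vegetation_glmm <- stage("vegetation_glmm", {
    met <- out$metrics
    veg <- out$data$vegetation
    keep <- met$habitat != "primary"
    met <- met[keep, ]
    veg <- veg[match(met$trap_id, veg$trap_id), ]
    veg_cols <- setdiff(names(veg), c("trap_id", "plot_id", "habitat",
                                      "distance_m"))
    preds <- as.data.frame(lapply(stats::setNames(veg_cols, veg_cols),
                                  function(v) standardize(veg[[v]], v)))
    fit <- fit_nb_glmm(met$abundance, preds, met$plot_id)
    res <- stats::residuals(fit$model, type = "pearson")
    agg <- stats::aggregate(cbind(res = res, x = met$x, y = met$y),
                            by = list(plot = met$plot_id), FUN = mean)
    moran <- morans_i_test(agg$res, agg[, c("x", "y")],
                           n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "moran"))
    list(fit = fit, moran = moran)
  })

  out$landscape <- stage("landscape_accounting", {
    met <- out$metrics
    edge_m <- colMeans(met[met$habitat == "road_edge", variables, drop = FALSE])
    int_m <- colMeans(met[met$habitat == "interior", variables, drop = FALSE])
    prim_m <- colMeans(met[met$habitat == "primary", variables, drop = FALSE])
    sim <- data.frame(metric = variables, primary_mean = prim_m,
                      interior_mean = int_m, edge_mean = edge_m,
                      combined_mean = NA_real_, row.names = NULL)
    sim$combined_mean <- round(combined_metric(
      sim$interior_mean, sim$edge_mean,
      road_edge_area(config$road_length_km, config$edge_limit_m / 1000) /
        config$logged_area_km2), 1)
    list(simulated = landscape_summary(config$road_length_km,
                                       config$edge_limit_m,
                                       config$logged_area_km2, sim),
         case_study = landscape_summary(config$road_length_km,
                                        config$edge_limit_m,
                                        config$logged_area_km2))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$metrics, file.path(out_dir, "trap_metrics.csv"),
                     row.names = FALSE)
    ei <- do.call(rbind, lapply(out$edge_influence, `[[`, "table"))
    utils::write.csv(ei, file.path(out_dir, "edge_influence.csv"),
                     row.names = FALSE)
    gr <- do.call(rbind, lapply(names(out$gradients), function(v) {
      f <- out$gradients[[v]]
      data.frame(variable = v, psi = f$psi, beta1 = f$beta1, beta2 = f$beta2,
                 theta = f$theta, aic_linear = f$aic_linear,
                 aic_piecewise = f$aic_piecewise,
                 choice = select_model(f)$choice)
    }))
    utils::write.csv(gr, file.path(out_dir, "gradient_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(out$composition$nmds$points,
                                stress = out$composition$nmds$stress),
                     file.path(out_dir, "nmds_coordinates.csv"))
    utils::write.csv(out$vegetation_glmm$fit$coefficients,
                     file.path(out_dir, "glmm_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(out$landscape$case_study$metrics,
                     file.path(out_dir, "landscape_case_study.csv"),
                     row.names = FALSE)
  }
  out
}
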