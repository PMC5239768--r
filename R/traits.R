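#' Body size from linear dimensions
#'
#' Body size is length times width (mm^2), the quantity used to extrapolate
#' dry mass for species that were never weighed.
#'
#' @param length_mm,width_mm Positive body dimensions (mm); vectorized.
#' @return Body size in mm^2.
#' @export
body_size <- function(length_mm, width_mm) {
  if (anyNA(length_mm) || anyNA(width_mm) ||
      any(length_mm <= 0) || any(width_mm <= 0))
    stop("length and width must be positive")
  length_mm * width_mm
}

#' Fill missing species masses by allometric extrapolation
#'
#' Fits `log(mass) = a + b * log(size)` on the species with both a measured
#' mean dry mass and body dimensions, then predicts the missing masses on
#' the natural scale (plain exponential back-transform; no smearing
#' correction, so predictions are slightly conservative for noisy
#' calibrations but exact when the allometry is exact).
#'
#' @param traits data.frame with columns `species`, `mean_mass_g` (may hold
#'   `NA`), `length_mm`, `width_mm`.
#' @param min_calibration Minimum number of weighed species required.
#' @return The traits table with `mean_mass_g` filled and a logical
#'   `mass_imputed` column; attributes `allometry` (coefficients a, b) and
#'   `r_squared` describe the calibration fit.
#' @export
extrapolate_mass <- function(traits, min_calibration = 5) {
  req <- c("species", "mean_mass_g", "length_mm", "width_mm")
  if (!all(req %in% names(traits)))
    stop("traits must have columns: ", paste(req, collapse = ", "))
  size <- body_size(traits$length_mm, traits$width_mm)
  have <- !is.na(traits$mean_mass_g)
  if (any(traits$mean_mass_g[have] <= 0))
    stop("measured masses must be positive")
  if (sum(have) < min_calibration)
    stop("too few calibration species (", sum(have), " < ", min_calibration, ")")

  fit <- stats::lm(log(traits$mean_mass_g[have]) ~ log(size[have]))
  out <- traits
  out$mass_imputed <- !have
  if (any(!have)) {
    pred <- stats::coef(fit)[1] + stats::coef(fit)[2] * log(size[!have])
    out$mean_mass_g[!have] <- exp(unname(pred))
  }
  attr(out, "allometry") <- c(a = unname(stats::coef(fit)[1]),
                              b = unname(stats::coef(fit)[2]))
  attr(out, "r_squared") <- summary(fit)$r.squared
  out
}

#' Per-trap community metrics
#'
#' Collapses the long-format sample table to one row per trap carrying
#' species richness, total abundance, biomass (grams: species mean mass times
#' count, summed over species) and the abundance of each functional group
#' (size class x diel activity x guild) present in the trait table. The
#' group columns partition total abundance.
#'
#' @param samples Long-format sample table (see [read_samples()]).
#' @param traits Trait table with `species`, `guild`, `diel`, `size_class`
#'   and a complete `mean_mass_g` (run [extrapolate_mass()] first).
#' @param locations Optional trap table from [generate_design()]; when given,
#'   traps with no captures appear as all-zero rows and trap metadata
#'   (habitat, distance, coordinates) is taken from it.
#' @return data.frame, one row per trap: `trap_id`, `plot_id`, `habitat`,
#'   `distance_m`, `x`, `y`, `richness`, `abundance`, `biomass_g`, and one
#'   `abund_<group>` column per functional group.
#' @export
trap_metrics <- function(samples, traits, locations = NULL) {
  missing_sp <- setdiff(unique(samples$species), traits$species)
  if (length(missing_sp) > 0)
    stop("species missing from traits: ", paste(missing_sp, collapse = ", "))
  if (anyNA(traits$mean_mass_g))
    stop("traits has missing masses; run extrapolate_mass() first")

  ti <- match(samples$species, traits$species)
  grp <- paste(traits$size_class, traits$diel, traits$guild, sep = "_")[ti]
  mass <- traits$mean_mass_g[ti]

  meta_cols <- c("trap_id", "plot_id", "habitat", "distance_m", "x", "y")
  meta <- if (is.null(locations)) {
    unique(samples[, intersect(meta_cols, names(samples)), drop = FALSE])
  } else {
    locations[, intersect(meta_cols, names(locations)), drop = FALSE]
  }
  if (anyDuplicated(meta$trap_id)) stop("inconsistent trap metadata")
  ids <- meta$trap_id
  orphan <- setdiff(unique(samples$trap_id), ids)
  if (length(orphan) > 0)
    stop("samples reference traps absent from locations: ",
         paste(orphan, collapse = ", "))

  zero <- stats::setNames(numeric(length(ids)), ids)
  acc <- function(v, by) {
    s <- tapply(v, by, sum)
    out <- zero
    out[names(s)] <- s
    out
  }
  out <- meta
  out$richness <- as.vector(acc(as.numeric(samples$count > 0), samples$trap_id))
  out$abundance <- as.vector(acc(samples$count, samples$trap_id))
  out$biomass_g <- as.vector(acc(samples$count * mass, samples$trap_id))
  all_groups <- sort(unique(paste(traits$size_class, traits$diel,
                                  traits$guild, sep = "_")))
  for (g in all_groups) {
    sel <- grp == g
    out[[paste0("abund_", g)]] <-
      as.vector(acc(samples$count[sel], samples$trap_id[sel]))
  }
  rownames(out) <- NULL
  out
}
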