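#' Sampling design for a road-edge pitfall-trap survey
#'
#' Encodes the three strata of the field layout: road-edge plots with a fixed
#' ladder of trap distances from the road, interior transects in logged forest
#' well beyond the expected edge zone, and primary-forest reference transects.
#' The defaults reproduce the study design the package emulates: 24 edge plots
#' with traps at 0, 6, 12, 25, 50 and 100 m (144 traps), 14 interior transects
#' holding 58 traps at 170-550 m from the nearest road, and 12 primary-forest
#' transects of 5 traps each (60 traps); 262 traps in total.
#'
#' @param n_edge_plots Number of road-edge plots.
#' @param edge_distances_m Sorted, non-negative trap distances (m) from the
#'   road edge within each plot.
#' @param n_interior_transects Number of interior (logged-forest) transects.
#' @param interior_distances_m List with one sorted distance vector per
#'   interior transect, or `NULL` for the default layout: 4 traps at
#'   170, 270, 370, 470 m on most transects and 5 traps (adding 550 m) on the
#'   last two, totalling 58 traps under the default transect count.
#' @param n_primary_transects Number of primary-forest transects.
#' @param primary_traps_per_transect Traps per primary transect.
#' @param min_trap_spacing_m Minimum pairwise trap spacing within a plot (m).
#' @return An object of class `study_design` (a validated list of the above).
#' @examples
#' d <- study_design()
#' sum(lengths(d$interior_distances_m))  # 58
#' @export
study_design <- function(n_edge_plots = 24,
                         edge_distances_m = c(0, 6, 12, 25, 50, 100),
                         n_interior_transects = 14,
                         interior_distances_m = NULL,
                         n_primary_transects = 12,
                         primary_traps_per_transect = 5,
                         min_trap_spacing_m = 50) {
  if (n_edge_plots < 1 || n_interior_transects < 0 || n_primary_transects < 0)
    stop("design error: stratum counts must be positive")
  if (length(edge_distances_m) < 1 || anyNA(edge_distances_m))
    stop("design error: edge distance list is empty or has missing values")
  if (any(edge_distances_m < 0))
    stop("design error: edge distances must be non-negative")
  if (is.unsorted(edge_distances_m, strictly = TRUE))
    stop("design error: edge distances must be strictly increasing")

  if (is.null(interior_distances_m)) {
    interior_distances_m <- rep(list(c(170, 270, 370, 470)), n_interior_transects)
    # last two transects carry a fifth trap so the default totals 58
    if (n_interior_transects >= 2) {
      idx <- seq(n_interior_transects - 1, n_interior_transects)
      interior_distances_m[idx] <- list(c(170, 270, 370, 470, 550))
    }
  }
  if (length(interior_distances_m) != n_interior_transects)
    stop("design error: one interior distance vector is needed per transect")
  for (v in interior_distances_m) {
    if (any(v < 0) || is.unsorted(v, strictly = TRUE))
      stop("design error: interior distances must be sorted and non-negative")
  }

  structure(list(
    n_edge_plots = n_edge_plots,
    edge_distances_m = edge_distances_m,
    n_interior_transects = n_interior_transects,
    interior_distances_m = interior_distances_m,
    n_primary_transects = n_primary_transects,
    primary_traps_per_transect = primary_traps_per_transect,
    min_trap_spacing_m = min_trap_spacing_m
  ), class = "study_design")
}

#' Lay out trap locations for a study design
#'
#' Places every trap of a [study_design()] in a common coordinate frame
#' (metres). Edge plots sit along the road (the x axis) with traps staggered
#' laterally on alternating sides of the perpendicular so that all within-plot
#' pairwise spacings respect `min_trap_spacing_m`; the y coordinate of an edge
#' or interior trap equals its distance from the road edge. Primary-forest
#' traps have no road-distance (`distance_m` is `NA`) and occupy a separate
#' region of the frame. The layout is fully deterministic.
#'
#' @param design A [study_design()].
#' @param seed Accepted for interface symmetry with the stochastic generators;
#'   the layout does not use randomness.
#' @return A data.frame with columns `trap_id`, `plot_id`, `habitat`
#'   (`road_edge`, `interior` or `primary`), `distance_m`, `x`, `y`.
#' @examples
#' locs <- generate_design(study_design())
#' table(locs$habitat)  # 144 road_edge, 58 interior, 60 primary
#' @export
generate_design <- function(design = study_design(), seed = NULL) {
  stopifnot(inherits(design, "study_design"))

  # lateral stagger: 0, +s, -s, +2s, -2s, ... with step >= the minimum spacing
  step <- max(60, design$min_trap_spacing_m)
  k <- seq_along(design$edge_distances_m)
  lateral <- step * floor(k / 2) * (-1)^(k + 1)

  edge <- do.call(rbind, lapply(seq_len(design$n_edge_plots), function(p) {
    data.frame(
      trap_id = sprintf("E%02d_T%d", p, k),
      plot_id = sprintf("edge_%02d", p),
      habitat = "road_edge",
      distance_m = design$edge_distances_m,
      x = (p - 1) * 5900 + lateral,
      y = design$edge_distances_m
    )
  }))

  interior <- NULL
  if (design$n_interior_transects > 0) {
    interior <- do.call(rbind, lapply(seq_len(design$n_interior_transects), function(t) {
      dd <- design$interior_distances_m[[t]]
      data.frame(
        trap_id = sprintf("I%02d_T%d", t, seq_along(dd)),
        plot_id = sprintf("int_%02d", t),
        habitat = "interior",
        distance_m = dd,
        x = 200000 + (t - 1) * 11900,
        y = dd
      )
    }))
  }

  primary <- NULL
  if (design$n_primary_transects > 0) {
    np <- design$primary_traps_per_transect
    primary <- do.call(rbind, lapply(seq_len(design$n_primary_transects), function(t) {
      data.frame(
        trap_id = sprintf("P%02d_T%d", t, seq_len(np)),
        plot_id = sprintf("pri_%02d", t),
        habitat = "primary",
        distance_m = NA_real_,
        x = 600000 + (t - 1) * 4500,
        y = (seq_len(np) - 1) * 100
      )
    }))
  }

  out <- rbind(edge, interior, primary)
  rownames(out) <- NULL

  # within-plot spacing audit for the edge stratum
  for (p in unique(edge$plot_id)) {
    sub <- edge[edge$plot_id == p, c("x", "y")]
    if (nrow(sub) > 1 && min(stats::dist(sub)) < design$min_trap_spacing_m - 1e-9)
      stop("design error: staggered layout violates the minimum trap spacing")
  }
  out
}
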