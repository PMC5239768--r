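#' Forest area affected by road edges
#'
#' The area of forest under road-edge influence, beyond the road surface
#' itself: total road length times the limit of edge effects, doubled for the
#' two road sides.
#'
#' @param road_length_km Total road length (km).
#' @param edge_limit_km Penetration depth of edge effects (km), e.g. 0.170
#'   for a 170 m edge zone.
#' @return Affected area (km^2).
#' @examples
#' road_edge_area(2403, 0.170)  # 817.02 km^2
#' @export
road_edge_area <- function(road_length_km, edge_limit_km) {
  if (road_length_km < 0 || edge_limit_km < 0)
    stop("road length and edge limit must be non-negative")
  road_length_km * edge_limit_km * 2
}

#' Area-weighted landscape mean of a community metric
#'
#' Combines the interior and road-edge means of a metric in proportion to
#' the fraction of the logged landscape lying within the road-edge zone.
#'
#' @param interior_mean,edge_mean Per-trap metric means in interior and
#'   road-edge forest; vectorized.
#' @param w_edge Proportion of the logged landscape that is road-edge forest,
#'   in \[0, 1\].
#' @return `w_edge * edge_mean + (1 - w_edge) * interior_mean`.
#' @export
combined_metric <- function(interior_mean, edge_mean, w_edge) {
  if (any(w_edge < 0) || any(w_edge > 1)) stop("w_edge must be in [0, 1]")
  w_edge * edge_mean + (1 - w_edge) * interior_mean
}

#' Percentage decline of a metric relative to a reference
#'
#' @param reference_mean Positive reference value (e.g. the interior or
#'   primary-forest mean); vectorized.
#' @param comparison_mean Value compared against the reference.
#' @return `100 * (reference - comparison) / reference` (percent).
#' @export
percent_decline <- function(reference_mean, comparison_mean) {
  if (any(reference_mean <= 0)) stop("reference mean must be positive")
  100 * (reference_mean - comparison_mean) / reference_mean
}

#' Audit published combined means against the weighting rule
#'
#' Recomputes the area-weighted combined value for every metric row and flags
#' rows whose printed combined value disagrees with the weighting beyond
#' rounding. The shipped case-study table (see [case_study_metrics()])
#' contains several internally inconsistent printed rows; this audit reports
#' them rather than silently correcting or reproducing them.
#'
#' @param metrics data.frame with columns `metric`, `interior_mean`,
#'   `edge_mean`, `combined_mean` (the printed value). A `primary_mean`
#'   column, if present, is carried through.
#' @param w_edge Road-edge area fraction of the logged landscape.
#' @param tol Agreement tolerance; the default 0.05 matches values printed to
#'   one decimal place.
#' @return The input with `recomputed`, `difference` and `consistent` columns.
#' @export
audit_combined <- function(metrics, w_edge, tol = 0.05) {
  req <- c("metric", "interior_mean", "edge_mean", "combined_mean")
  if (!all(req %in% names(metrics)))
    stop("metrics must have columns: ", paste(req, collapse = ", "))
  out <- metrics
  out$recomputed <- combined_metric(metrics$interior_mean, metrics$edge_mean,
                                    w_edge)
  out$difference <- out$recomputed - metrics$combined_mean
  out$consistent <- abs(round(out$recomputed, 1) - metrics$combined_mean) <= tol
  out
}

#' Case-study landscape metrics table
#'
#' Published per-trap community metric means (primary forest, interior logged
#' forest, road-edge forest, and the area-weighted combined logged landscape)
#' from the Bornean logging-road case study the package emulates. Shipped as
#' a plain-text input for the landscape accounting audit.
#'
#' @return data.frame with columns `metric`, `primary_mean`, `interior_mean`,
#'   `edge_mean`, `combined_mean`.
#' @export
case_study_metrics <- function() {
  utils::read.csv(system.file("extdata", "case_study_metrics.csv",
                              package = "roadedge"),
                  stringsAsFactors = FALSE)
}

#' Landscape-scale accounting summary
#'
#' Chains the edge-area computation, the area weighting and the decline
#' percentages: computes the road-edge area, its share of the logged
#' landscape, the combined mean of every metric, and percentage declines of
#' the combined landscape relative to interior logged forest and (when a
#' `primary_mean` column is present) to primary forest.
#'
#' @param road_length_km Total road length (km).
#' @param edge_limit_m Edge-effect penetration distance (m).
#' @param logged_area_km2 Total logged-forest area (km^2).
#' @param metrics Metric table as in [audit_combined()]; defaults to the
#'   shipped case-study table.
#' @return Object of class `landscape_summary`: `road_length_km`,
#'   `edge_limit_km`, `road_edge_area_km2`, `w_edge`, and `metrics` (with
#'   recomputed combined means and decline columns).
#' @export
landscape_summary <- function(road_length_km, edge_limit_m, logged_area_km2,
                              metrics = case_study_metrics()) {
  if (logged_area_km2 <= 0) stop("logged area must be positive")
  area <- road_edge_area(road_length_km, edge_limit_m / 1000)
  w <- area / logged_area_km2
  if (w > 1) stop("road-edge area exceeds the logged landscape")
  m <- audit_combined(metrics, w)
  m$decline_vs_interior_pct <- percent_decline(m$interior_mean, m$recomputed)
  if ("primary_mean" %in% names(m))
    m$decline_vs_primary_pct <- percent_decline(m$primary_mean, m$recomputed)
  structure(list(road_length_km = road_length_km,
                 edge_limit_km = edge_limit_m / 1000,
                 road_edge_area_km2 = area, w_edge = w, metrics = m),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf("road-edge area: %.1f km^2 (%.1f km of road, %g m edge zone)\n",
              x$road_edge_area_km2, x$road_length_km,
              x$edge_limit_km * 1000))
  cat(sprintf("edge fraction of logged landscape: %.1f%%\n", 100 * x$w_edge))
  print(x$metrics, digits = 4)
  invisible(x)
}
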