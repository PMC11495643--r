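select_region <- function(workmap, region) {
  region <- match.arg(region, c("LV", "septum", "LV free wall", "all"))
  if (region %in% c("LV", "all")) return(workmap)  # whole LV incl. septum
  workmap[workmap$region == region, , drop = FALSE]
}

weighted_mean_sd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  s <- sqrt(sum(w * (x - m)^2) / sum(w))  # population convention
  c(mean = m, sd = s)
}

# Weighted quantile, lower interpolation on the cumulative weight function:
# the smallest x whose cumulative weight fraction reaches q.
weighted_quantile <- function(x, w, q) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= q - 1e-12)[1]]
}

#' Coefficient of variation of regional work (COVW)
#'
#' Heterogeneity of the regional work distribution: weighted population
#' standard deviation divided by the weighted mean of the work densities in
#' the chosen region. Invariant under uniform positive scaling of the work
#' values. Undefined (NA, warning) when the region mean is zero.
#'
#' @param workmap a [compute_work_map()] result.
#' @param region `"LV"` (whole LV including septum; default), `"septum"`,
#'   `"LV free wall"` or `"all"`.
#' @param weighted logical; use the map's area/volume weights (default).
#' @return COVW, unitless.
#' @export
covw <- function(workmap, region = "LV", weighted = TRUE) {
  m <- select_region(workmap, region)
  w <- if (weighted) m$weight else rep(1, nrow(m))
  ms <- weighted_mean_sd(m$work, w)
  if (abs(ms["mean"]) < 1e-300) {
    warning("zero mean work; COVW undefined")
    return(NA_real_)
  }
  unname(ms["sd"] / ms["mean"])
}

#' Fraction of a region performing negative work
#'
#' Weighted fraction of the region's myocardium with strictly negative net
#' loop area. With endocardial-area weights this is the surface fraction
#' (S_f); with wall-volume weights the volume fraction (V_f).
#'
#' @inheritParams covw
#' @return Fraction in `[0, 1]`.
#' @export
negative_work_fraction <- function(workmap, region = "LV") {
  m <- select_region(workmap, region)
  if (!nrow(m)) stop("empty region")
  sum(m$weight[m$work < 0]) / sum(m$weight)
}

#' Fraction of a region performing high work
#'
#' Weighted fraction of the region with work density strictly above the
#' weighted `quantile` of that same patient-state map's distribution (per
#' patient, per state). With `quantile = 0.75` this is the upper-quartile
#' high-work fraction (V_f_LVHW with volume weights).
#'
#' @inheritParams covw
#' @param quantile probability of the threshold quantile (default 0.75).
#' @return Fraction in `[0, 1]`.
#' @export
high_work_fraction <- function(workmap, region = "LV", quantile = 0.75) {
  m <- select_region(workmap, region)
  if (!nrow(m)) stop("empty region")
  thr <- weighted_quantile(m$work, m$weight, quantile)
  sum(m$weight[m$work > thr]) / sum(m$weight)
}

#' Full regional work metric set for one work map
#'
#' COVW over the LV, negative-work fractions for LV and septum, and the
#' upper-quartile high-work fraction for the LV. Metric names carry the
#' `S_f` prefix for area-weighted maps and `V_f` for volume-weighted maps.
#'
#' @param workmap a [compute_work_map()] result.
#' @return One-row data frame: `covw`, `f_lvnw`, `f_stnw`, `f_lvhw`, plus
#'   `method`, `state`, `weight_type` columns.
#' @export
regional_work_metrics <- function(workmap) {
  data.frame(method = attr(workmap, "method"),
             state = attr(workmap, "state"),
             weight_type = attr(workmap, "weight_type"),
             covw = covw(workmap, "LV"),
             f_lvnw = negative_work_fraction(workmap, "LV"),
             f_stnw = negative_work_fraction(workmap, "septum"),
             f_lvhw = high_work_fraction(workmap, "LV"),
             stringsAsFactors = FALSE)
}

#' Change in regional metrics from baseline to post-therapy
#'
#' Baseline-minus-post differences, so a positive delta means the metric
#' was reduced by therapy (e.g. `delta_f_stnw = f_stnw(LBBB) -
#' f_stnw(CRT)` is positive when CRT reduced septal negative work).
#' Both inputs must come from the same stress surrogate method.
#'
#' @param baseline,post one-row data frames from [regional_work_metrics()].
#' @return Named numeric vector of deltas over the shared numeric metrics.
#' @export
delta_metric <- function(baseline, post) {
  if (!identical(baseline$method, post$method))
    stop("cannot difference metrics from different methods")
  cols <- c("covw", "f_lvnw", "f_stnw", "f_lvhw")
  out <- unlist(baseline[1, cols]) - unlist(post[1, cols])
  names(out) <- paste0("delta_", cols)
  out
}
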