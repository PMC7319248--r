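#' Response-curve primitives for simulated species
#'
#' Named building blocks for the log-intensity of the simulated group
#' process: `resp_monotone` adds `slope * x`, `resp_unimodal` adds a
#' Gaussian bump `-((x - opt) / width)^2 / 2`, and `resp_threshold` adds
#' `delta` where `x > cut`.
#'
#' @param var Covariate name (one of sst, sst_sd, ssh, ssh_sd, mld, depth,
#'   lat, lon, year).
#' @param slope,opt,width,cut,delta Curve parameters.
#' @param ref Reference value at which a monotone term contributes zero
#'   (so `lambda0` is the intensity at `x = ref`).
#' @return A response-term object used by [species_truth()].
#' @export
resp_monotone <- function(var, slope, ref = 0) {
  structure(list(var = var, type = "monotone", slope = slope, ref = ref),
            class = "resp_term")
}

#' @rdname resp_monotone
#' @export
resp_unimodal <- function(var, opt, width) {
  if (width <= 0) stop("width must be positive")
  structure(list(var = var, type = "unimodal", opt = opt, width = width),
            class = "resp_term")
}

#' @rdname resp_monotone
#' @export
resp_threshold <- function(var, cut, delta) {
  structure(list(var = var, type = "threshold", cut = cut, delta = delta),
            class = "resp_term")
}

#' Define a simulated species ("truth")
#'
#' The species is an inhomogeneous Poisson group process with intensity
#' `lambda(x) = lambda0 * exp(sum of response terms) * year-trend`, in
#' groups per km^2, optionally restricted to a range polygon. Group sizes
#' are lognormal with a location (meanlog) that may vary linearly with
#' latitude, floored at 1 after rounding.
#'
#' @param name Species name.
#' @param lambda0 Baseline intensity (groups / km^2) where all response
#'   terms are zero.
#' @param terms List of response terms from [resp_monotone()] and friends.
#' @param group_meanlog Baseline meanlog of group size.
#' @param group_meanlog_lat Slope of meanlog per degree latitude (centered
#'   on `lat_ref`).
#' @param group_sdlog sdlog of group size.
#' @param lat_ref Latitude at which `group_meanlog` applies.
#' @param range_mask Optional polygon (two-column lon/lat matrix); intensity
#'   is zero outside.
#' @param year_trend Optional named numeric vector of per-year multipliers
#'   (> 0) on the group intensity; unlisted years get 1.
#' @param group_size_trend Optional named numeric vector of per-year
#'   multipliers (> 0) on expected group size (a concentration year has
#'   intensity multiplier < 1 and size multiplier > 1: fewer, larger
#'   groups).
#' @return Object of class `species_truth`.
#' @export
species_truth <- function(name, lambda0, terms = list(),
                          group_meanlog = log(5), group_meanlog_lat = 0,
                          group_sdlog = 0.5, lat_ref = 35,
                          range_mask = NULL, year_trend = NULL,
                          group_size_trend = NULL) {
  if (lambda0 < 0) stop("lambda0 must be non-negative")
  if (!is.null(year_trend) && any(year_trend <= 0))
    stop("year trend multipliers must be positive")
  if (!is.null(group_size_trend) && any(group_size_trend <= 0))
    stop("group size trend multipliers must be positive")
  structure(list(name = name, lambda0 = lambda0, terms = terms,
                 group_meanlog = group_meanlog,
                 group_meanlog_lat = group_meanlog_lat,
                 group_sdlog = group_sdlog, lat_ref = lat_ref,
                 range_mask = range_mask, year_trend = year_trend,
                 group_size_trend = group_size_trend),
            class = "species_truth")
}

#' True group intensity at covariate values
#'
#' @param truth A [species_truth()].
#' @param covars data.frame of covariates (needs each term's variable, plus
#'   lon/lat if a range mask is set and year if a trend is set).
#' @return Intensity in groups per km^2 (>= 0).
#' @export
truth_intensity <- function(truth, covars) {
  eta <- rep(log(truth$lambda0 + .Machine$double.xmin), nrow(covars))
  for (tm in truth$terms) {
    x <- covars[[tm$var]]
    if (is.null(x)) stop("covariate missing for response term: ", tm$var)
    eta <- eta + switch(tm$type,
      monotone = tm$slope * (x - tm$ref),
      unimodal = -((x - tm$opt) / tm$width)^2 / 2,
      threshold = tm$delta * (x > tm$cut))
  }
  lam <- exp(eta)
  if (!is.null(truth$year_trend) && !is.null(covars$year)) {
    mult <- truth$year_trend[as.character(covars$year)]
    mult[is.na(mult)] <- 1
    lam <- lam * as.numeric(mult)
  }
  if (!is.null(truth$range_mask))
    lam <- lam * point_in_polygon(covars$lon, covars$lat, truth$range_mask)
  lam
}

# meanlog of the group-size law at a latitude (and survey year)
truth_group_meanlog <- function(truth, lat, year = NULL) {
  m <- truth$group_meanlog + truth$group_meanlog_lat * (lat - truth$lat_ref)
  if (!is.null(truth$group_size_trend) && !is.null(year)) {
    mult <- truth$group_size_trend[as.character(year)]
    mult[is.na(mult)] <- 1
    m <- m + log(as.numeric(mult))
  }
  m
}
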