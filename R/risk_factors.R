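#' Comparative number: normalized species abundance
#'
#' Each species' total observed individuals divided by the largest such
#' total in the community. The most abundant species scores 1; ties share
#' the maximum. Stored on the 0-1 scale; the x100 rescaling happens once,
#' in [strike_severity()].
#'
#' @param profiles Species profile tibble from [aggregate_profiles()].
#' @return Named numeric vector (species -> value in \[0,1\]).
#' @export
comparative_number <- function(profiles) {
  if (nrow(profiles) == 0 || all(profiles$total_count == 0)) {
    stop("no individuals observed: comparative number undefined", call. = FALSE)
  }
  stats::setNames(profiles$total_count / max(profiles$total_count),
                  profiles$species)
}

#' Comparative weight: normalized species biomass
#'
#' Each species' total observed biomass (total count x mean individual
#' mass) divided by the largest species total biomass. With
#' `weight_basis = "individual"` the mean individual mass is normalized
#' instead.
#'
#' @inheritParams comparative_number
#' @param weight_basis `"total"` (default) or `"individual"`.
#' @return Named numeric vector (species -> value in \[0,1\]).
#' @export
comparative_weight <- function(profiles, weight_basis = c("total", "individual")) {
  weight_basis <- match.arg(weight_basis)
  w <- if (weight_basis == "total") profiles$total_biomass_g else profiles$mass_g
  if (length(w) == 0 || all(w == 0)) {
    stop("no biomass observed: comparative weight undefined", call. = FALSE)
  }
  stats::setNames(w / max(w), profiles$species)
}

#' Flight-height risk coefficient
#'
#' Step function over the representative flight height H (metres), peaked
#' at the 30-50 m band around the 40 m critical approach/landing altitude:
#' H > 100 -> 0.1; 100 >= H > 50 -> 0.5; 50 >= H > 30 -> 1;
#' 30 >= H > 5 -> 0.5; H <= 5 -> 0.1. Upper boundaries are inclusive.
#'
#' @param height_m Non-negative flight height(s) in metres.
#' @return Numeric vector with values in `{0.1, 0.5, 1}`.
#' @examples
#' flight_height_coeff(c(3, 20, 40, 80, 150))
#' @export
flight_height_coeff <- function(height_m) {
  if (!is.numeric(height_m) || anyNA(height_m) || any(height_m < 0)) {
    stop("flight height must be non-negative and numeric", call. = FALSE)
  }
  dplyr::case_when(
    height_m > 100 ~ 0.1,
    height_m > 50 ~ 0.5,
    height_m > 30 ~ 1,
    height_m > 5 ~ 0.5,
    TRUE ~ 0.1
  )
}

#' Cluster (flocking) risk coefficient
#'
#' Step function over the species' typical flock size N:
#' N >= 100 -> 1; 100 > N >= 20 -> 0.5; 20 > N >= 3 -> 0.2;
#' 3 > N >= 1 -> 0. The published table leaves N = 100 unassigned
#' (N > 100 vs 100 > N); it is closed risk-conservatively into the top
#' band.
#'
#' @param n Positive integer flock size(s).
#' @return Numeric vector with values in `{0, 0.2, 0.5, 1}`.
#' @examples
#' cluster_coeff(c(1, 3, 20, 100, 500))
#' @export
cluster_coeff <- function(n) {
  if (!is.numeric(n) || anyNA(n) || any(n < 1)) {
    stop("cluster size must be a positive integer", call. = FALSE)
  }
  dplyr::case_when(
    n >= 100 ~ 1,
    n >= 20 ~ 0.5,
    n >= 3 ~ 0.2,
    TRUE ~ 0
  )
}

#' Activity-range risk coefficient
#'
#' Weight by the activity zone nearest to the flight area: A (airport
#' grounds) -> 0.9, B (within 4 km, excluding A) -> 0.6, C (4-8 km) -> 0.3.
#'
#' @param zone Character vector of zones in `{"A", "B", "C"}`.
#' @return Numeric vector with values in `{0.9, 0.6, 0.3}`.
#' @export
activity_coeff <- function(zone) {
  if (!all(zone %in% c("A", "B", "C"))) {
    stop("unknown zone: ",
         paste(setdiff(unique(zone), c("A", "B", "C")), collapse = ", "),
         call. = FALSE)
  }
  unname(c(A = 0.9, B = 0.6, C = 0.3)[zone])
}

#' Assign all five risk factors to every species
#'
#' Applies [comparative_number()], [comparative_weight()],
#' [flight_height_coeff()] (to the representative flight height),
#' [cluster_coeff()] (to the aggregated flock size) and [activity_coeff()]
#' (to the nearest zone).
#'
#' @inheritParams comparative_number
#' @param config A [risk_config()]; `weight_basis` is honoured.
#' @return Tibble `(species, cn, cw, height_coeff, cluster_coeff,
#'   activity_coeff)`, one row per species.
#' @export
assign_factors <- function(profiles, config = risk_config()) {
  validate_risk_config(config)
  tibble::tibble(
    species = profiles$species,
    cn = unname(comparative_number(profiles)),
    cw = unname(comparative_weight(profiles, config$weight_basis)),
    height_coeff = flight_height_coeff(profiles$height_m),
    cluster_coeff = cluster_coeff(profiles$max_cluster),
    activity_coeff = activity_coeff(profiles$nearest_zone)
  )
}
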