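COEFF_SETS <- list(
  cluster = c(0, 0.2, 0.5, 1),
  height = c(0.1, 0.5, 1),
  activity = c(0.3, 0.6, 0.9)
)

#' Birdstrike likelihood score
#'
#' Likelihood = (cluster coefficient + flight-height coefficient +
#' activity-range coefficient) x 100 / 3, on a 0-100 scale. With the
#' step-function coefficient sets the attainable range is
#' \[13.33, 96.67\].
#'
#' @param cluster_coeff Value(s) in `{0, 0.2, 0.5, 1}`.
#' @param height_coeff Value(s) in `{0.1, 0.5, 1}`.
#' @param activity_coeff Value(s) in `{0.3, 0.6, 0.9}`.
#' @return Numeric likelihood score(s).
#' @examples
#' strike_likelihood(1, 1, 0.9)  # 96.67, the attainable maximum
#' @export
strike_likelihood <- function(cluster_coeff, height_coeff, activity_coeff) {
  check_in_set(cluster_coeff, COEFF_SETS$cluster, "cluster coefficient")
  check_in_set(height_coeff, COEFF_SETS$height, "flight-height coefficient")
  check_in_set(activity_coeff, COEFF_SETS$activity, "activity coefficient")
  (cluster_coeff + height_coeff + activity_coeff) * 100 / 3
}

#' Birdstrike severity score
#'
#' Severity = (comparative number + comparative weight) x 100 / 2 on a
#' 0-100 scale, with both inputs as fractions in \[0,1\]. The single x100
#' rescaling here keeps severity on the 0-100 scale the banding table
#' expects.
#'
#' @param cn,cw Comparative number and comparative weight in \[0,1\].
#' @return Numeric severity score(s).
#' @examples
#' strike_severity(1, 1)       # 100
#' strike_severity(0.25, 0.05) # 15
#' @export
strike_severity <- function(cn, cw) {
  for (v in list(cn, cw)) {
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 1)) {
      stop("comparative number/weight must lie in [0, 1]", call. = FALSE)
    }
  }
  (cn + cw) * 100 / 2
}

check_in_set <- function(x, set, what) {
  ok <- vapply(x, function(v) any(abs(v - set) < 1e-9), logical(1))
  if (!all(ok)) {
    stop(what, " outside its lookup set {",
         paste(set, collapse = ", "), "}: ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Band a 0-100 score into five ordinal classes
#'
#' Continuous half-open intervals with the top band closed at 100:
#' with bounds `c(b1,b2,b3,b4)` the bands are \[0,b1) very_low,
#' \[b1,b2) low, \[b2,b3) moderate, \[b3,b4) high, \[b4,100\] very_high.
#' The published integer ranges (e.g. likelihood 0-14, 15-29, ...) leave
#' non-integer scores unassigned; the half-open reading covers them while
#' agreeing with the table on every integer.
#'
#' @param score Score(s) in \[0, 100\].
#' @param bounds Four strictly increasing thresholds (lower edges of bands
#'   2-5), e.g. `risk_config()$likelihood_bounds`.
#' @return Factor with ordered levels `RISK_BANDS`.
#' @examples
#' score_band(c(0, 14.5, 70), risk_config()$likelihood_bounds)
#' @export
score_band <- function(score, bounds) {
  if (!is.numeric(score) || anyNA(score) || any(score < 0 | score > 100)) {
    stop("score must lie in [0, 100]", call. = FALSE)
  }
  idx <- findInterval(score, bounds) + 1L
  factor(RISK_BANDS[idx], levels = RISK_BANDS, ordered = TRUE)
}

#' Classify a likelihood band x severity band pair into a danger level
#'
#' Looks the pair up in the configured 5x5 matrix. The matrix is validated
#' monotone: improving neither band can ever lower the level.
#'
#' @param likelihood_band,severity_band Band labels (character or factor
#'   with levels `RISK_BANDS`), recycled to a common length.
#' @param config A [risk_config()].
#' @return Integer danger level(s) in `{1, 2, 3}`.
#' @export
classify_risk <- function(likelihood_band, severity_band,
                          config = risk_config()) {
  validate_risk_config(config)
  lb <- as.character(likelihood_band)
  sb <- as.character(severity_band)
  if (!all(lb %in% RISK_BANDS) || !all(sb %in% RISK_BANDS)) {
    stop("bands must be one of: ", paste(RISK_BANDS, collapse = ", "),
         call. = FALSE)
  }
  config$matrix[cbind(lb, sb)]
}

#' Apply the rule-based danger-level adjustments
#'
#' Two independent +1 bumps, each capped at level 3: one for birds of prey
#' (fast, hard-hitting, under-weighted by the biomass-driven severity
#' score), one for species observed crossing or overflying the runway at
#' least `crossing_threshold` times. Both rules may stack.
#'
#' @param base_level Integer level(s) in `{1,2,3}` from [classify_risk()].
#' @param is_raptor Logical vector.
#' @param runway_crossings Non-negative integer vector.
#' @param config A [risk_config()].
#' @return Tibble `(adjusted_level, adjustments)`, `adjustments` a
#'   comma-separated rule list (`""` when none applied).
#' @examples
#' adjust_level(2, is_raptor = TRUE, runway_crossings = 0)
#' @export
adjust_level <- function(base_level, is_raptor, runway_crossings,
                         config = risk_config()) {
  if (!all(base_level %in% 1:3)) {
    stop("base_level must be in {1, 2, 3}", call. = FALSE)
  }
  n <- max(length(base_level), length(is_raptor), length(runway_crossings))
  base_level <- rep_len(as.integer(base_level), n)
  is_raptor <- rep_len(is_raptor, n)
  runway_crossings <- rep_len(runway_crossings, n)

  raptor_rule <- config$raptor_bump & is_raptor
  crossing_rule <- runway_crossings >= config$crossing_threshold
  adjusted <- pmin(3L, base_level + raptor_rule + crossing_rule)
  # name a rule only when it was applicable, even if the cap absorbed it
  adjustments <- mapply(function(r, x) {
    paste(c(if (r) "raptor", if (x) "runway_crossing"), collapse = ",")
  }, raptor_rule, crossing_rule)
  tibble::tibble(adjusted_level = adjusted,
                 adjustments = unname(adjustments))
}

#' Score every species: likelihood, severity, bands, levels
#'
#' Composes the whole matrix stage: computes likelihood and severity from
#' the assigned factors, bands both scores, looks up the base danger level
#' in the matrix, and applies the raptor and runway-crossing adjustments
#' from the species profiles.
#'
#' @param factors Factor tibble from [assign_factors()].
#' @param profiles Profile tibble from [aggregate_profiles()] (same
#'   species set; matched by name).
#' @param config A [risk_config()].
#' @return Tibble `(species, likelihood, severity, l_band, s_band,
#'   base_level, adjusted_level, adjustments)`.
#' @export
score_species <- function(factors, profiles, config = risk_config()) {
  validate_risk_config(config)
  if (!setequal(factors$species, profiles$species)) {
    stop("factors and profiles must cover the same species", call. = FALSE)
  }
  prof <- profiles[match(factors$species, profiles$species), ]
  likelihood <- strike_likelihood(factors$cluster_coeff,
                                  factors$height_coeff,
                                  factors$activity_coeff)
  severity <- strike_severity(factors$cn, factors$cw)
  l_band <- score_band(likelihood, config$likelihood_bounds)
  s_band <- score_band(severity, config$severity_bounds)
  base <- classify_risk(l_band, s_band, config)
  adj <- adjust_level(base, prof$is_raptor, prof$runway_crossings, config)
  tibble::tibble(
    species = factors$species,
    likelihood = likelihood,
    severity = severity,
    l_band = l_band,
    s_band = s_band,
    base_level = base,
    adjusted_level = adj$adjusted_level,
    adjustments = adj$adjustments
  )
}

#' Run the full risk assessment on sighting records
#'
#' Convenience wrapper: aggregates profiles, assigns the five factors,
#' scores and classifies every species, and bundles the result with the
#' configuration used.
#'
#' @param records Sighting tibble from [read_survey()].
#' @param traits Trait tibble from [read_traits()].
#' @param config A [risk_config()].
#' @return A `risk_assessment` list: `profiles`, `factors`, `scores`,
#'   `config`.
#' @export
assess_risk <- function(records, traits, config = risk_config()) {
  profiles <- aggregate_profiles(records, traits, config)
  factors <- assign_factors(profiles, config)
  scores <- score_species(factors, profiles, config)
  structure(list(profiles = profiles, factors = factors,
                 scores = scores, config = config),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  lv <- table(factor(x$scores$adjusted_level, levels = 1:3))
  cat("<risk_assessment>", nrow(x$profiles), "species:",
      lv[["3"]], "high (3),", lv[["2"]], "moderate (2),",
      lv[["1"]], "low (1)\n")
  invisible(x)
}
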