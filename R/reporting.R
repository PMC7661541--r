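#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the printed percentage
#' style (e.g. 27.1, 55.9), rather than R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Danger-level percentages
#'
#' 100 x count / total per level, rounded half-up to one decimal.
#'
#' @param counts Named integer vector of species counts per danger level.
#' @return Named numeric vector of percentages.
#' @examples
#' level_percentages(c(`1` = 66, `2` = 32, `3` = 20))
#' @export
level_percentages <- function(counts) {
  if (length(counts) == 0 || sum(counts) == 0) {
    stop("cannot compute percentages of an empty classification", call. = FALSE)
  }
  round_half_up(100 * counts / sum(counts), 1)
}

#' Species counts per season and danger level
#'
#' For each season, the number of species present in that season (at least
#' one record) at each adjusted danger level. A species present year-round
#' is counted in all four seasons, so rows can sum to more than the number
#' of species.
#'
#' @param profiles Profile tibble from [aggregate_profiles()].
#' @param scores Score tibble from [score_species()].
#' @return Tibble `(season, level, n_species)` covering all 4 x 3 cells.
#' @export
seasonal_summary <- function(profiles, scores) {
  all_seasons <- c("spring", "summer", "autumn", "winter")
  grid <- tidyr::expand_grid(season = all_seasons, level = 1:3)
  if (nrow(profiles) == 0) {
    return(dplyr::mutate(grid, n_species = 0L))
  }
  level <- scores$adjusted_level[match(profiles$species, scores$species)]
  long <- tibble::tibble(
    species = rep(profiles$species, lengths(profiles$seasons)),
    season = unlist(profiles$seasons),
    level = rep(level, lengths(profiles$seasons))
  )
  counts <- dplyr::count(long, .data$season, .data$level, name = "n_species")
  grid |>
    dplyr::left_join(counts, by = c("season", "level")) |>
    dplyr::mutate(n_species = tidyr::replace_na(.data$n_species, 0L),
                  season = factor(.data$season, levels = all_seasons)) |>
    dplyr::arrange(.data$season, .data$level) |>
    dplyr::mutate(season = as.character(.data$season))
}

#' Build a full risk report
#'
#' One table row per species (factors, scores, bands, levels), danger-level
#' counts and percentages, and the season x level presence table.
#'
#' @param assessment A `risk_assessment` from [assess_risk()], or `NULL`
#'   if `profiles`/`factors`/`scores`/`config` are given separately.
#' @param profiles,factors,scores,config Components, if not passing an
#'   assessment.
#' @return A `risk_report` list: `species_rows` (tibble), `level_counts`
#'   (named integer, levels "1","2","3"), `level_percentages`,
#'   `seasonal_counts` (tibble), `config`.
#' @export
risk_report <- function(assessment = NULL, profiles = assessment$profiles,
                        factors = assessment$factors,
                        scores = assessment$scores,
                        config = assessment$config) {
  rows <- profiles |>
    dplyr::select("species", "family", "order") |>
    dplyr::left_join(factors, by = "species") |>
    dplyr::left_join(
      dplyr::mutate(scores,
                    l_band = as.character(.data$l_band),
                    s_band = as.character(.data$s_band)),
      by = "species") |>
    dplyr::arrange(dplyr::desc(.data$adjusted_level),
                   dplyr::desc(.data$likelihood + .data$severity))
  counts <- table(factor(scores$adjusted_level, levels = 1:3))
  counts <- stats::setNames(as.integer(counts), names(counts))
  pct <- if (sum(counts) > 0) level_percentages(counts) else counts * NA_real_
  structure(
    list(
      species_rows = rows,
      level_counts = counts,
      level_percentages = pct,
      seasonal_counts = seasonal_summary(profiles, scores),
      config = config
    ),
    class = "risk_report"
  )
}

#' @export
print.risk_report <- function(x, ...) {
  n <- sum(x$level_counts)
  cat("<risk_report>", n, "species\n")
  for (lv in c("3", "2", "1")) {
    cat(sprintf("  level %s: %d species (%.1f%%)\n", lv,
                x$level_counts[[lv]],
                if (n > 0) x$level_percentages[[lv]] else NA_real_))
  }
  invisible(x)
}

#' Write a risk report to CSV or JSON
#'
#' CSV holds the per-species table (one row per species). JSON holds the
#' whole report — species rows, level counts and percentages, seasonal
#' table — plus an echo of the configuration used, for provenance, and
#' round-trips through [read_report()].
#'
#' @param report A `risk_report`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(report$species_rows, path, progress = FALSE)
  } else {
    payload <- list(
      species_rows = report$species_rows,
      level_counts = as.list(report$level_counts),
      level_percentages = as.list(report$level_percentages),
      seasonal_counts = report$seasonal_counts,
      config = config_as_list(report$config)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a JSON risk report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A `risk_report` (config restored as a `risk_config`).
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_raw <- raw$config
  m <- matrix(as.integer(unlist(cfg_raw$matrix)), nrow = 5, byrow = TRUE,
              dimnames = list(likelihood = RISK_BANDS, severity = RISK_BANDS))
  config <- risk_config(
    likelihood_bounds = cfg_raw$likelihood_bounds,
    severity_bounds = cfg_raw$severity_bounds,
    matrix = m,
    crossing_threshold = cfg_raw$crossing_threshold,
    raptor_bump = cfg_raw$raptor_bump,
    height_stat = cfg_raw$height_stat,
    cluster_stat = cfg_raw$cluster_stat,
    weight_basis = cfg_raw$weight_basis,
    season_months = cfg_raw$season_months
  )
  rows <- tibble::as_tibble(raw$species_rows)
  structure(
    list(
      species_rows = rows,
      level_counts = stats::setNames(as.integer(unlist(raw$level_counts)),
                                     names(raw$level_counts)),
      level_percentages = stats::setNames(as.numeric(unlist(raw$level_percentages)),
                                          names(raw$level_percentages)),
      seasonal_counts = tibble::as_tibble(raw$seasonal_counts),
      config = config
    ),
    class = "risk_report"
  )
}
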