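#' Default survey CSV column mapping
#'
#' Names are the internal record fields, values the CSV header names.
#' Override individual entries to read survey tables with other headers.
#' @return Named character vector.
#' @export
survey_schema <- function() {
  c(species = "species", family = "family", order = "order",
    unit = "unit", date = "date", zone = "zone", count = "count",
    height_m = "height_m", group_size = "group_size",
    crossed_runway = "crossed_runway")
}

#' Read and validate a survey observation table
#'
#' One row per sighting of one species: taxonomic identity, survey unit,
#' date, activity zone (A = airport flight area, B = within 4 km excluding
#' A, C = within 8 km excluding A and B), number of individuals, estimated
#' flight height in metres, observed group size, and whether the sighting
#' crossed or overflew the runway.
#'
#' A missing required column is a hard error naming the column. Rows that
#' fail validation (unknown zone, unparseable date or number, negative
#' count or height, group size below 1 or exceeding the count) are dropped
#' individually and collected, with reasons, in the `"rejected"` attribute
#' of the result (see [rejected_rows()]).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Column mapping as produced by [survey_schema()].
#' @return A tibble of validated sighting records with columns
#'   `species, family, order, unit, date (Date), zone, count, height_m,
#'   group_size, crossed_runway`, and attribute `rejected`: a tibble
#'   `(row, reason)` of dropped input rows (row numbers count data rows,
#'   header excluded).
#' @export
read_survey <- function(path, schema = survey_schema()) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing) > 0) {
    stop("survey file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, unname(schema)]
  names(raw) <- names(schema)
  if (nrow(raw) == 0) {
    out <- empty_survey()
    attr(out, "rejected") <- tibble::tibble(row = integer(), reason = character())
    return(out)
  }

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  zone <- toupper(trimws(raw$zone))
  count <- suppressWarnings(as.numeric(raw$count))
  height <- suppressWarnings(as.numeric(raw$height_m))
  gsize <- suppressWarnings(as.numeric(raw$group_size))
  crossed <- parse_flag(raw$crossed_runway)

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) {
    reason[is.na(reason) & bad] <<- why
  }
  flag(!zone %in% c("A", "B", "C"), "unknown zone")
  flag(is.na(date), "unparseable date")
  flag(is.na(count) | count < 0 | count != round(count),
       "count must be a non-negative integer")
  flag(is.na(height) | height < 0, "flight height must be non-negative")
  flag(is.na(gsize) | gsize < 1 | gsize != round(gsize),
       "group size must be a positive integer")
  flag(!is.na(gsize) & !is.na(count) & gsize > count,
       "group size exceeds count")
  flag(is.na(crossed), "unparseable crossed_runway flag")
  flag(is.na(raw$species) | trimws(raw$species) == "", "missing species name")

  keep <- is.na(reason)
  out <- tibble::tibble(
    species = trimws(raw$species[keep]),
    family = trimws(raw$family[keep]),
    order = trimws(raw$order[keep]),
    unit = raw$unit[keep],
    date = date[keep],
    zone = zone[keep],
    count = as.integer(count[keep]),
    height_m = height[keep],
    group_size = as.integer(gsize[keep]),
    crossed_runway = crossed[keep]
  )
  attr(out, "rejected") <- tibble::tibble(row = which(!keep),
                                          reason = reason[!keep])
  out
}

#' Rows rejected while reading a survey table
#'
#' @param records Result of [read_survey()].
#' @return Tibble `(row, reason)`; zero rows if everything parsed.
#' @export
rejected_rows <- function(records) {
  rej <- attr(records, "rejected")
  if (is.null(rej)) tibble::tibble(row = integer(), reason = character()) else rej
}

empty_survey <- function() {
  tibble::tibble(
    species = character(), family = character(), order = character(),
    unit = character(), date = as.Date(character()), zone = character(),
    count = integer(), height_m = numeric(), group_size = integer(),
    crossed_runway = logical()
  )
}

parse_flag <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Read a species trait table
#'
#' @param path CSV with columns `species, mass_g, is_raptor`: mean
#'   individual body mass in grams and a bird-of-prey flag.
#' @return Tibble `(species, mass_g, is_raptor)`.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("species", "mass_g", "is_raptor")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("trait file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    species = trimws(raw$species),
    mass_g = suppressWarnings(as.numeric(raw$mass_g)),
    is_raptor = parse_flag(raw$is_raptor)
  )
  if (anyNA(out$mass_g) || any(out$mass_g <= 0)) {
    stop("mass_g must be a positive number for every species", call. = FALSE)
  }
  if (anyNA(out$is_raptor)) {
    stop("is_raptor must be TRUE/FALSE for every species", call. = FALSE)
  }
  if (anyDuplicated(out$species)) {
    stop("duplicated species in trait table: ",
         paste(unique(out$species[duplicated(out$species)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Map calendar dates to seasons
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts).
#' @param season_months Twelve season names, one per month Jan-Dec; the
#'   default is the calendar-quarter scheme Mar-May spring, Jun-Aug summer,
#'   Sep-Nov autumn, Dec-Feb winter.
#' @return Character vector of seasons.
#' @examples
#' assign_season(as.Date("2019-04-15"))  # "spring"
#' @export
assign_season <- function(date, season_months = default_season_months()) {
  date <- as.Date(date)
  if (anyNA(date)) stop("invalid date", call. = FALSE)
  stopifnot(length(season_months) == 12)
  season_months[as.integer(format(date, "%m"))]
}

#' Aggregate sighting records into per-species profiles
#'
#' Collapses all sightings of each species over the survey period into the
#' quantities the risk model consumes: total individuals, total biomass
#' (total count x mean individual mass), one representative flight height
#' (count-weighted median by default), the largest observed group size, the
#' activity zone nearest to the flight area (A < B < C), the number of
#' runway crossings, and the set of seasons with at least one record.
#'
#' @param records Sighting tibble from [read_survey()] (or equivalently
#'   shaped data).
#' @param traits Trait tibble from [read_traits()]; every species in
#'   `records` must appear (hard error listing any that do not).
#' @param config A [risk_config()]; `height_stat`, `cluster_stat` and
#'   `season_months` control the aggregation.
#' @return Tibble with one row per species: `species, family, order,
#'   total_count, mass_g, total_biomass_g, height_m, max_cluster,
#'   nearest_zone, is_raptor, runway_crossings, seasons` (list-column of
#'   season names).
#' @export
aggregate_profiles <- function(records, traits, config = risk_config()) {
  validate_risk_config(config)
  missing <- setdiff(unique(records$species), traits$species)
  if (length(missing) > 0) {
    stop("species missing from trait table: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(
      species = character(), family = character(), order = character(),
      total_count = integer(), mass_g = numeric(), total_biomass_g = numeric(),
      height_m = numeric(), max_cluster = integer(), nearest_zone = character(),
      is_raptor = logical(), runway_crossings = integer(), seasons = list()
    ))
  }
  records$season <- assign_season(records$date, config$season_months)

  cluster_agg <- if (identical(config$cluster_stat, "max")) {
    function(g) max(g)
  } else {
    function(g) stats::quantile(g, probs = config$cluster_stat,
                                names = FALSE, type = 1)
  }
  height_agg <- if (config$height_stat == "median") {
    weighted_median
  } else {
    function(x, w) sum(x * w) / sum(w)
  }

  prof <- records |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      family = .data$family[1],
      order = .data$order[1],
      total_count = sum(.data$count),
      height_m = height_agg(.data$height_m, .data$count),
      max_cluster = as.integer(cluster_agg(.data$group_size)),
      nearest_zone = min(.data$zone),
      runway_crossings = sum(.data$crossed_runway),
      seasons = list(intersect(c("spring", "summer", "autumn", "winter"),
                               unique(.data$season))),
      .groups = "drop"
    ) |>
    dplyr::left_join(traits, by = "species") |>
    dplyr::mutate(total_biomass_g = .data$total_count * .data$mass_g) |>
    dplyr::select("species", "family", "order", "total_count", "mass_g",
                  "total_biomass_g", "height_m", "max_cluster",
                  "nearest_zone", "is_raptor", "runway_crossings", "seasons")
  prof
}

# Lower weighted median: smallest x whose cumulative weight reaches half the
# total. Deterministic under ties and robust to outlier sightings.
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}
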