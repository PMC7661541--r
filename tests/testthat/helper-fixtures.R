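# Tiny in-code fixtures shared across test files.

rec <- function(species, zone = "B", count = 1L, height = 10, group = 1L,
                date = "2019-05-10", crossed = FALSE,
                family = "Famidae", order = "Ordiformes", unit = "B01") {
  tibble::tibble(
    species = species, family = family, order = order, unit = unit,
    date = as.Date(date), zone = zone, count = as.integer(count),
    height_m = height, group_size = as.integer(group),
    crossed_runway = crossed
  )
}

make_records <- function(...) dplyr::bind_rows(...)

make_traits <- function(species, mass_g = 100, is_raptor = FALSE) {
  tibble::tibble(species = species,
                 mass_g = rep_len(mass_g, length(species)),
                 is_raptor = rep_len(is_raptor, length(species)))
}

write_survey_csv <- function(records, path = withr::local_tempfile(
                               fileext = ".csv", .local_envir = parent.frame())) {
  readr::write_csv(records, path, progress = FALSE)
  path
}

write_traits_csv <- function(traits, path = withr::local_tempfile(
                               fileext = ".csv", .local_envir = parent.frame())) {
  readr::write_csv(traits, path, progress = FALSE)
  path
}

# Independent transcriptions of the printed coefficient tables, kept as
# literal if-chains so they cannot share a defect with the vectorized
# implementation.
oracle_height <- function(H) {
  if (H > 100) return(0.1)
  if (100 >= H && H > 50) return(0.5)
  if (50 >= H && H > 30) return(1)
  if (30 >= H && H > 5) return(0.5)
  0.1
}

oracle_cluster <- function(N) {
  if (N >= 100) return(1)
  if (100 > N && N >= 20) return(0.5)
  if (20 > N && N >= 3) return(0.2)
  0
}

oracle_band <- function(score, bounds) {
  labels <- c("very_low", "low", "moderate", "high", "very_high")
  edges <- c(0, bounds, 100)
  for (i in 1:4) {
    if (score >= edges[i] && score < edges[i + 1]) return(labels[i])
  }
  labels[5]
}
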