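#' Read a historical strike-record table
#'
#' @param path CSV with columns `species, family`; `species` may be blank
#'   when only the family of the strike-causing bird is known. Every entry
#'   must at least name a family.
#' @return Tibble `(species, family)` with `NA` for blank species.
#' @export
read_strike_records <- function(path) {
  if (!file.exists(path)) stop("strike-record file not found: ", path,
                               call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(c("species", "family"), names(raw))
  if (length(missing) > 0) {
    stop("strike-record file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    species = dplyr::na_if(trimws(raw$species), ""),
    family = trimws(raw$family)
  )
  if (anyNA(out$family) || any(out$family == "")) {
    stop("every strike record must name at least a family", call. = FALSE)
  }
  out
}

normalize_name <- function(x, synonyms = NULL) {
  x <- tolower(trimws(gsub("\\s+", " ", x)))
  if (!is.null(synonyms)) {
    key <- tolower(trimws(gsub("\\s+", " ", synonyms$name)))
    hit <- match(x, key)
    x[!is.na(hit)] <- tolower(trimws(synonyms$canonical[hit[!is.na(hit)]]))
  }
  x
}

#' Cross-check high-danger species against historical strike records
#'
#' For each species classified as high danger, looks for a match in a
#' strike-record list: first by normalized species name (case-folded,
#' whitespace-squashed, optional synonym table), then — for species not
#' matched by name — by family. The two match sets are disjoint by
#' construction and the two fractions (over the high-danger list) sum to
#' at most 1.
#'
#' @param high_danger Profile tibble (needs `species` and `family`
#'   columns), typically the level-3 subset of an assessment.
#' @param strikes Strike-record tibble from [read_strike_records()].
#' @param synonyms Optional synonym tibble `(name, canonical)` applied to
#'   species names on both sides before matching.
#' @return A list: `species_matches`, `family_matches` (character vectors
#'   of high-danger species names), `species_fraction`, `family_fraction`.
#' @export
strike_overlap <- function(high_danger, strikes, synonyms = NULL) {
  if (nrow(high_danger) == 0) {
    stop("high-danger species list is empty", call. = FALSE)
  }
  if (nrow(strikes) == 0) {
    warning("strike-record list is empty: no overlap computable")
    return(list(species_matches = character(), family_matches = character(),
                species_fraction = 0, family_fraction = 0))
  }
  hd_species <- normalize_name(high_danger$species, synonyms)
  hd_family <- normalize_name(high_danger$family)
  st_species <- normalize_name(strikes$species[!is.na(strikes$species)], synonyms)
  st_family <- normalize_name(strikes$family)

  by_species <- hd_species %in% st_species
  by_family <- !by_species & hd_family %in% st_family
  n <- nrow(high_danger)
  list(
    species_matches = high_danger$species[by_species],
    family_matches = high_danger$species[by_family],
    species_fraction = sum(by_species) / n,
    family_fraction = sum(by_family) / n
  )
}
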