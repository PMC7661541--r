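#' @importFrom rlang .data
NULL

#' Ordered band labels used throughout the model
#'
#' Five ordinal bands shared by the likelihood and severity scales.
#' @export
RISK_BANDS <- c("very_low", "low", "moderate", "high", "very_high")

#' Build a risk-model configuration
#'
#' Collects every tunable of the scoring pipeline in one validated object:
#' band thresholds, the 5x5 likelihood x severity matrix, the adjustment
#' rules, and the aggregation choices used when collapsing many sightings of
#' a species into one profile.
#'
#' @param likelihood_bounds Lower edges of bands 2-5 on the 0-100 likelihood
#'   scale. Defaults `c(15, 30, 50, 70)`, i.e. bands
#'   \[0,15) \[15,30) \[30,50) \[50,70) \[70,100\].
#' @param severity_bounds Lower edges of bands 2-5 on the 0-100 severity
#'   scale. Defaults `c(4, 7, 14, 40)`.
#' @param matrix 5x5 integer matrix of danger levels in `{1,2,3}`, rows =
#'   likelihood bands, columns = severity bands, dimnames `RISK_BANDS`.
#'   Must be monotone non-decreasing along both axes. The default is an
#'   ordinal-sum reconstruction: level 3 where the band ordinals (1-5) sum
#'   to 8 or more, level 2 for sums 5-7, level 1 otherwise.
#' @param crossing_threshold Number of observed runway crossings (or
#'   overflights of the runway) at which a species' level is raised by one.
#'   Default 3.
#' @param raptor_bump Should birds of prey get a +1 level adjustment?
#'   Default `TRUE`.
#' @param height_stat How to pick one representative flight height per
#'   species from many sightings: `"median"` (count-weighted median,
#'   default, robust to outlier sightings) or `"mean"` (count-weighted).
#' @param cluster_stat Aggregation for observed group sizes: `"max"`
#'   (default, risk-conservative) or a quantile in (0,1).
#' @param weight_basis Basis of comparative weight: `"total"` (total
#'   biomass = count x mean individual mass, default) or `"individual"`
#'   (mean individual mass only).
#' @param season_months Character vector of 12 season names, one per
#'   calendar month Jan-Dec. Default: Mar-May spring, Jun-Aug summer,
#'   Sep-Nov autumn, Dec-Feb winter.
#'
#' @return A list with class `"risk_config"`.
#' @examples
#' cfg <- risk_config()
#' cfg$matrix["high", "high"]  # danger level for the high/high cell
#' @export
risk_config <- function(likelihood_bounds = c(15, 30, 50, 70),
                        severity_bounds = c(4, 7, 14, 40),
                        matrix = default_risk_matrix(),
                        crossing_threshold = 3,
                        raptor_bump = TRUE,
                        height_stat = c("median", "mean"),
                        cluster_stat = "max",
                        weight_basis = c("total", "individual"),
                        season_months = default_season_months()) {
  height_stat <- match.arg(height_stat)
  weight_basis <- match.arg(weight_basis)
  cfg <- structure(
    list(
      likelihood_bounds = as.numeric(likelihood_bounds),
      severity_bounds = as.numeric(severity_bounds),
      matrix = matrix,
      crossing_threshold = crossing_threshold,
      raptor_bump = isTRUE(raptor_bump),
      height_stat = height_stat,
      cluster_stat = cluster_stat,
      weight_basis = weight_basis,
      season_months = season_months
    ),
    class = "risk_config"
  )
  validate_risk_config(cfg)
}

#' Default 5x5 danger-level matrix (ordinal-sum reconstruction)
#'
#' Level 3 where likelihood ordinal + severity ordinal >= 8, level 2 for
#' sums 5-7, level 1 otherwise. Both extreme corners land on the extreme
#' levels and the grid is monotone along both axes.
#'
#' @return Integer 5x5 matrix with `RISK_BANDS` dimnames.
#' @export
default_risk_matrix <- function() {
  s <- outer(seq_len(5), seq_len(5), `+`)
  m <- ifelse(s >= 8, 3L, ifelse(s >= 5, 2L, 1L))
  dimnames(m) <- list(likelihood = RISK_BANDS, severity = RISK_BANDS)
  m
}

#' @rdname risk_config
#' @export
default_season_months <- function() {
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")
}

#' Validate a risk-model configuration
#'
#' Checks band thresholds (strictly increasing, inside (0,100)), matrix
#' shape, cell values and monotonicity, and the adjustment parameters.
#' Called by [risk_config()] and again before scoring.
#'
#' @param cfg A `risk_config` object.
#' @return `cfg`, invisibly unchanged, or an error.
#' @export
validate_risk_config <- function(cfg) {
  for (nm in c("likelihood_bounds", "severity_bounds")) {
    b <- cfg[[nm]]
    if (length(b) != 4 || anyNA(b) || any(diff(b) <= 0) ||
        b[1] <= 0 || b[4] >= 100) {
      stop(nm, " must be 4 strictly increasing thresholds inside (0, 100)",
           call. = FALSE)
    }
  }
  m <- cfg$matrix
  if (!is.matrix(m) || !identical(dim(m), c(5L, 5L))) {
    stop("risk matrix must be 5x5", call. = FALSE)
  }
  if (!all(m %in% 1:3)) {
    stop("risk matrix cells must be danger levels 1, 2 or 3", call. = FALSE)
  }
  row_ok <- all(apply(m, 1, function(r) all(diff(r) >= 0)))
  col_ok <- all(apply(m, 2, function(r) all(diff(r) >= 0)))
  if (!row_ok || !col_ok) {
    stop("risk matrix must be monotone non-decreasing along both band axes",
         call. = FALSE)
  }
  if (!is.numeric(cfg$crossing_threshold) || cfg$crossing_threshold < 1) {
    stop("crossing_threshold must be a positive number", call. = FALSE)
  }
  if (!(identical(cfg$cluster_stat, "max") ||
        (is.numeric(cfg$cluster_stat) && cfg$cluster_stat > 0 &&
         cfg$cluster_stat < 1))) {
    stop("cluster_stat must be \"max\" or a quantile in (0, 1)", call. = FALSE)
  }
  if (length(cfg$season_months) != 12 ||
      !all(cfg$season_months %in% c("spring", "summer", "autumn", "winter"))) {
    stop("season_months must name a season for each of the 12 months",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read a risk-model configuration from YAML or JSON
#'
#' Keys absent from the file keep their defaults. The `matrix` key, if
#' present, is a list of 5 rows (likelihood very_low..very_high), each a
#' vector of 5 levels (severity very_low..very_high).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `risk_config`.
#' @export
read_risk_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  for (nm in c("likelihood_bounds", "severity_bounds", "crossing_threshold",
               "raptor_bump", "height_stat", "cluster_stat", "weight_basis",
               "season_months")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$matrix)) {
    m <- raw$matrix
    if (is.list(m)) m <- do.call(rbind, m)
    m <- matrix(as.integer(m), nrow = 5, ncol = 5,
                dimnames = list(likelihood = RISK_BANDS,
                                severity = RISK_BANDS))
    args$matrix <- m
  }
  do.call(risk_config, args)
}

#' Serialize a risk-model configuration to a plain list
#'
#' Used when echoing the configuration into JSON reports for provenance.
#' @param cfg A `risk_config`.
#' @return A list of plain vectors (matrix as a list of rows).
#' @export
config_as_list <- function(cfg) {
  list(
    likelihood_bounds = cfg$likelihood_bounds,
    severity_bounds = cfg$severity_bounds,
    matrix = apply(cfg$matrix, 1, identity, simplify = FALSE),
    crossing_threshold = cfg$crossing_threshold,
    raptor_bump = cfg$raptor_bump,
    height_stat = cfg$height_stat,
    cluster_stat = cfg$cluster_stat,
    weight_basis = cfg$weight_basis,
    season_months = cfg$season_months
  )
}

#' @export
print.risk_config <- function(x, ...) {
  cat("<risk_config>\n")
  cat("  likelihood bounds:", paste(x$likelihood_bounds, collapse = "/"), "\n")
  cat("  severity bounds:  ", paste(x$severity_bounds, collapse = "/"), "\n")
  cat("  matrix (rows = likelihood, cols = severity):\n")
  print(x$matrix)
  cat("  raptor bump:", x$raptor_bump,
      " crossing threshold:", x$crossing_threshold, "\n")
  cat("  height stat:", x$height_stat,
      " cluster stat:", format(x$cluster_stat),
      " weight basis:", x$weight_basis, "\n")
  invisible(x)
}
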