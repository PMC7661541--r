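# Guild parameter table: lognormal body mass and modal flight height, plus
# weights over four band-safe flock-size classes (solitary 1-2, small 4-16,
# flock 25-80, mass 130-400). Class ranges deliberately avoid the cluster
# band edges (3, 20, 100) so a species' flock-size band is well defined
# under modest per-sighting variation.
GUILDS <- list(
  songbird    = list(w = 0.40, mass = c(log(30), 0.6),  height = c(log(10), 0.7),
                     flock = c(0.20, 0.40, 0.30, 0.10), zone_a = 0.40,
                     families = c("Passeridae", "Corvidae", "Alaudidae",
                                  "Motacillidae"), order = "Passeriformes"),
  waterfowl   = list(w = 0.15, mass = c(log(1500), 0.6), height = c(log(60), 0.4),
                     flock = c(0.05, 0.25, 0.45, 0.25), zone_a = 0.15,
                     families = c("Anatidae", "Ardeidae", "Rallidae"),
                     order = "Anseriformes"),
  terrestrial = list(w = 0.15, mass = c(log(400), 0.6), height = c(log(4), 0.6),
                     flock = c(0.40, 0.40, 0.20, 0.00), zone_a = 0.50,
                     families = c("Phasianidae", "Columbidae"),
                     order = "Galliformes"),
  aerial      = list(w = 0.08, mass = c(log(40), 0.4),  height = c(log(80), 0.4),
                     flock = c(0.10, 0.30, 0.40, 0.20), zone_a = 0.40,
                     families = c("Apodidae", "Hirundinidae"),
                     order = "Apodiformes"),
  wader       = list(w = 0.17, mass = c(log(200), 0.6), height = c(log(25), 0.5),
                     flock = c(0.30, 0.40, 0.30, 0.00), zone_a = 0.30,
                     families = c("Charadriidae", "Scolopacidae"),
                     order = "Charadriiformes"),
  raptor      = list(w = NA,   mass = c(log(700), 0.5), height = c(log(45), 0.3),
                     flock = c(0.80, 0.20, 0.00, 0.00), zone_a = 0.50,
                     families = c("Accipitridae", "Falconidae", "Strigidae"),
                     order = "Accipitriformes")
)

FLOCK_CLASSES <- list(c(1L, 2L), c(4L, 16L), c(25L, 80L), c(130L, 400L))

#' Specify a synthetic bird community
#'
#' Parameters of the community generator, which emulates a year of monthly
#' transect/point-count surveys of an airport bird community across three
#' activity zones (A: airport grounds, 7 units; B: within 4 km, 20 units;
#' C: 4-8 km, 12 units — 39 units, 468 unit-visits over 12 months).
#'
#' Species are drawn from six guilds (songbirds, waterfowl, terrestrial
#' birds, aerial foragers, waders, raptors) with guild-specific body-mass
#' and flight-height distributions and flock-size classes; abundance is
#' lognormal across species; each species occupies a subset of zones
#' (nearest zone dominant in sampling) and a seasonal pattern (resident,
#' summer visitor, passage migrant, winter visitor).
#'
#' @param n_species Number of species. Default 118.
#' @param seed Integer seed; the community and its latent truth are fully
#'   determined by it.
#' @param abundance Lognormal abundance model, `list(meanlog, sdlog)`
#'   across species.
#' @param raptor_fraction Expected fraction of raptor species. Default
#'   0.05.
#' @param zone_units Named integer vector of survey units per zone.
#' @param year Calendar year stamped on generated survey dates.
#' @param height_sd Lognormal sd of per-sighting flight-height variation
#'   around the species' modal height.
#' @param plant_maximal,plant_minimal Replace the first (resp. second)
#'   species with a planted extreme: a maximal-risk species (most
#'   abundant, heaviest total biomass, 40 m flight height, flocks of 150,
#'   zone A only) or a minimal-risk one (rare, 15 g, 200 m, solitary,
#'   zone C only, summer only, non-raptor). Used for end-to-end
#'   classification checks.
#' @param season_months Month-to-season mapping (see
#'   [default_season_months()]).
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_species = 118, seed = 1,
                           abundance = list(meanlog = 2, sdlog = 1.2),
                           raptor_fraction = 0.05,
                           zone_units = c(A = 7L, B = 20L, C = 12L),
                           year = 2019,
                           height_sd = 0.2,
                           plant_maximal = FALSE,
                           plant_minimal = FALSE,
                           season_months = default_season_months()) {
  stopifnot(n_species >= 1, raptor_fraction >= 0, raptor_fraction <= 1,
            all(zone_units >= 1), setequal(names(zone_units), c("A", "B", "C")),
            abundance$sdlog > 0, height_sd >= 0)
  structure(
    list(n_species = as.integer(n_species), seed = as.integer(seed),
         abundance = abundance, raptor_fraction = raptor_fraction,
         zone_units = zone_units, year = year, height_sd = height_sd,
         plant_maximal = isTRUE(plant_maximal),
         plant_minimal = isTRUE(plant_minimal),
         season_months = season_months),
    class = "community_spec"
  )
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic bird community
#'
#' Draws species traits (guild, mass, raptor flag) and the latent
#' per-species truth the survey simulator samples from: true abundance,
#' modal flight height, characteristic flock size, occupied zones with the
#' nearest-zone-dominant sampling weights, seasonal pattern, and the risk
#' coefficients those latent values imply (for recovery tests).
#'
#' @param spec A [community_spec()].
#' @return A `bird_community` list: `traits` (tibble
#'   `species, mass_g, is_raptor`), `truth` (tibble of latent values),
#'   `spec`.
#' @export
generate_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    n <- spec$n_species
    guild_names <- names(GUILDS)
    base_w <- vapply(GUILDS[setdiff(guild_names, "raptor")], `[[`,
                     numeric(1), "w")
    probs <- c(base_w / sum(base_w) * (1 - spec$raptor_fraction),
               raptor = spec$raptor_fraction)
    guild <- sample(names(probs), n, replace = TRUE, prob = probs)

    species <- sprintf("Species %03d", seq_len(n))
    family <- character(n)
    order <- character(n)
    mass <- numeric(n)
    h0 <- numeric(n)
    g0 <- integer(n)
    for (i in seq_len(n)) {
      g <- GUILDS[[guild[i]]]
      family[i] <- sample(g$families, 1)
      order[i] <- g$order
      mass[i] <- min(12000, max(10, stats::rlnorm(1, g$mass[1], g$mass[2])))
      h0[i] <- stats::rlnorm(1, g$height[1], g$height[2])
      cls <- FLOCK_CLASSES[[sample.int(4, 1, prob = g$flock)]]
      g0[i] <- sample(cls[1]:cls[2], 1)
    }
    is_raptor <- guild == "raptor"

    lambda <- stats::rlnorm(n, spec$abundance$meanlog, spec$abundance$sdlog)

    # occupied zones; the zone nearest the flight area dominates sampling
    zones <- vector("list", n)
    zone_probs <- vector("list", n)
    for (i in seq_len(n)) {
      inc <- c(A = stats::runif(1) < GUILDS[[guild[i]]]$zone_a,
               B = stats::runif(1) < 0.7,
               C = stats::runif(1) < 0.7)
      if (!any(inc)) inc["C"] <- TRUE
      zz <- names(inc)[inc]
      zones[[i]] <- zz
      p <- if (length(zz) == 1) 1 else c(0.6, rep(0.4 / (length(zz) - 1),
                                                  length(zz) - 1))
      zone_probs[[i]] <- stats::setNames(p, zz)  # zz sorted A<B<C; first = nearest
    }
    nearest <- vapply(zones, min, character(1))

    season_sets <- list(resident = c("spring", "summer", "autumn", "winter"),
                        summer_visitor = c("spring", "summer", "autumn"),
                        passage = c("spring", "autumn"),
                        winter_visitor = c("autumn", "winter"))
    pattern <- sample(names(season_sets), n, replace = TRUE,
                      prob = c(0.40, 0.25, 0.25, 0.10))
    seasons <- season_sets[pattern]

    cross_prob <- ifelse(vapply(zones, function(z) "A" %in% z, logical(1)),
                         stats::rbeta(n, 1.5, 4), 0)
    height_sd <- rep(spec$height_sd, n)

    if (spec$plant_maximal) {
      i <- 1L
      species[i] <- "Planted maximal-risk"
      guild[i] <- "waterfowl"; family[i] <- "Anatidae"; order[i] <- "Anseriformes"
      mass[i] <- 10000; h0[i] <- 40; g0[i] <- 150L
      lambda[i] <- 3 * max(lambda[-i])
      zones[[i]] <- "A"; zone_probs[[i]] <- c(A = 1); nearest[i] <- "A"
      seasons[[i]] <- season_sets$resident
      is_raptor[i] <- FALSE; cross_prob[i] <- 0.3; height_sd[i] <- 0
    }
    if (spec$plant_minimal) {
      i <- 2L
      species[i] <- "Planted minimal-risk"
      guild[i] <- "songbird"; family[i] <- "Sylviidae"; order[i] <- "Passeriformes"
      mass[i] <- 15; h0[i] <- 200; g0[i] <- 1L
      lambda[i] <- min(lambda) / 10
      zones[[i]] <- "C"; zone_probs[[i]] <- c(C = 1); nearest[i] <- "C"
      seasons[[i]] <- "summer"
      is_raptor[i] <- FALSE; cross_prob[i] <- 0; height_sd[i] <- 0
    }

    rel <- lambda / max(lambda)
    monthly_rate <- pmin(12, 2 + 8 * rel)  # expected sightings per active month
    if (spec$plant_maximal) monthly_rate[1] <- 12
    if (spec$plant_minimal) monthly_rate[2] <- 1.5

    truth <- tibble::tibble(
      species = species, guild = guild, family = family, order = order,
      mass_g = mass, is_raptor = is_raptor,
      abundance = lambda, rel_abundance = rel, monthly_rate = monthly_rate,
      modal_height_m = h0, height_sd = height_sd, flock_size = g0,
      zones = zones, zone_probs = zone_probs, nearest_zone = nearest,
      seasons = seasons, cross_prob = cross_prob,
      height_coeff_true = flight_height_coeff(h0),
      cluster_coeff_true = cluster_coeff(g0),
      activity_coeff_true = activity_coeff(nearest)
    )
    traits <- tibble::tibble(species = species, mass_g = mass,
                             is_raptor = is_raptor)
    structure(list(traits = traits, truth = truth, spec = spec),
              class = "bird_community")
  })
}

#' Simulate a year of survey records from a community
#'
#' For each species and each month of its seasonal pattern, draws a
#' Poisson number of sightings (rate = the species' latent monthly
#' encounter rate), assigns each to a survey unit within an occupied zone
#' (nearest zone dominant), and draws the sighting's group size
#' (characteristic flock size with +/-15% variation), count (= group
#' size), flight height (lognormal around the modal height), and runway
#' crossing flag (zone A only). A planted species that would otherwise go
#' unrecorded is guaranteed one mid-season record.
#'
#' @param community A `bird_community` from [generate_community()].
#' @param n_months Number of consecutive survey months, starting in
#'   January. Default 12 (the full design: 39 units x 12 months = 468
#'   unit-visits).
#' @param seed Integer seed for the sampling stage; defaults to the
#'   community seed + 1.
#' @return A sighting tibble shaped exactly like [read_survey()] output,
#'   with attribute `n_unit_visits`.
#' @export
generate_surveys <- function(community, n_months = 12,
                             seed = community$spec$seed + 1) {
  stopifnot(inherits(community, "bird_community"),
            n_months >= 1, n_months <= 12)
  spec <- community$spec
  truth <- community$truth
  units <- lapply(names(spec$zone_units), function(z) {
    sprintf("%s%02d", z, seq_len(spec$zone_units[[z]]))
  })
  names(units) <- names(spec$zone_units)
  months <- seq_len(n_months)
  month_season <- spec$season_months

  with_seed(seed, {
    per_species <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      active <- months[month_season[months] %in% tr$seasons[[1]]]
      if (length(active) == 0) return(NULL)
      k_m <- stats::rpois(length(active), tr$monthly_rate)
      planted <- grepl("^Planted", tr$species)
      if (planted && sum(k_m) == 0) k_m[ceiling(length(active) / 2)] <- 1L
      k <- sum(k_m)
      if (k == 0) return(NULL)
      month <- rep(active, k_m)
      zp <- tr$zone_probs[[1]]
      zone <- if (length(zp) == 1) rep(names(zp), k) else {
        sample(names(zp), k, replace = TRUE, prob = zp)
      }
      unit <- vapply(zone, function(z) sample(units[[z]], 1), character(1))
      g <- pmax(1L, as.integer(round(tr$flock_size *
                                       stats::runif(k, 0.85, 1.15))))
      height <- tr$modal_height_m * exp(stats::rnorm(k, 0, tr$height_sd))
      crossed <- zone == "A" & stats::runif(k) < tr$cross_prob
      tibble::tibble(
        species = tr$species, family = tr$family, order = tr$order,
        unit = unit,
        date = as.Date(sprintf("%d-%02d-%02d", spec$year, month,
                               sample.int(28, k, replace = TRUE))),
        zone = zone, count = g, height_m = height, group_size = g,
        crossed_runway = crossed
      )
    })
    out <- dplyr::bind_rows(per_species)
    out <- out[order(out$date, out$unit, out$species), ]
    attr(out, "n_unit_visits") <- sum(spec$zone_units) * n_months
    out
  })
}

#' Write a simulated dataset to CSV files plus a truth sidecar
#'
#' Emits `survey.csv` and `traits.csv` in the dialects [read_survey()] and
#' [read_traits()] consume, and `truth.json` recording the generator seed,
#' spec parameters and latent per-species truth.
#'
#' @param community A `bird_community`.
#' @param records Sightings from [generate_surveys()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(community, records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(records, file.path(dir, "survey.csv"), progress = FALSE)
  traits_out <- community$traits
  traits_out$is_raptor <- ifelse(traits_out$is_raptor, "true", "false")
  readr::write_csv(traits_out, file.path(dir, "traits.csv"), progress = FALSE)
  truth <- community$truth
  truth$zones <- vapply(truth$zones, paste, character(1), collapse = ",")
  truth$seasons <- vapply(truth$seasons, paste, character(1), collapse = ",")
  truth$zone_probs <- NULL
  sidecar <- list(
    seed = community$spec$seed,
    spec = unclass(community$spec)[c("n_species", "seed", "abundance",
                                     "raptor_fraction", "year", "height_sd",
                                     "plant_maximal", "plant_minimal")],
    zone_units = as.list(community$spec$zone_units),
    truth = truth
  )
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
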