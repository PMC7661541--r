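test_that("likelihood is (c + f + a) x 100/3 with validated inputs", {
  expect_equal(strike_likelihood(1, 1, 0.9), 96.667, tolerance = 1e-4)
  expect_equal(strike_likelihood(0, 0.1, 0.3), 13.333, tolerance = 1e-4)
  expect_equal(strike_likelihood(0.5, 1, 0.9), 80)
  expect_error(strike_likelihood(0.7, 1, 0.9), "cluster")
  expect_error(strike_likelihood(1, 0.2, 0.9), "height")
  expect_error(strike_likelihood(1, 1, 0.5), "activity")
})

test_that("severity is (cn + cw) x 100/2 on the [0,1] factor scale", {
  expect_equal(strike_severity(1, 1), 100)
  expect_equal(strike_severity(0.25, 0.05), 15)
  expect_equal(strike_severity(0, 0), 0)
  expect_error(strike_severity(1.2, 0.5), "\\[0, 1\\]")
  expect_error(strike_severity(0.5, -0.1), "\\[0, 1\\]")
})

test_that("banding uses half-open intervals matching the printed tables", {
  cfg <- risk_config()
  expect_equal(as.character(score_band(70, cfg$likelihood_bounds)), "very_high")
  expect_equal(as.character(score_band(14, cfg$severity_bounds)), "high")
  expect_equal(as.character(score_band(0, cfg$likelihood_bounds)), "very_low")
  expect_equal(as.character(score_band(c(14.9, 15, 29.9, 30, 49.9, 50, 69.9),
                                       cfg$likelihood_bounds)),
               c("very_low", "low", "low", "moderate", "moderate",
                 "high", "high"))
  expect_equal(as.character(score_band(c(3.9, 4, 6.9, 7, 13.9, 39.9, 40, 100),
                                       cfg$severity_bounds)),
               c("very_low", "low", "low", "moderate", "moderate",
                 "high", "very_high", "very_high"))
  expect_error(score_band(101, cfg$likelihood_bounds), "\\[0, 100\\]")
  expect_error(score_band(-0.5, cfg$severity_bounds), "\\[0, 100\\]")
})

test_that("banding agrees with a brute-force scan over 10,001 scores", {
  cfg <- risk_config()
  scores <- seq(0, 100, length.out = 10001)
  for (bounds in list(cfg$likelihood_bounds, cfg$severity_bounds)) {
    expect_equal(as.character(score_band(scores, bounds)),
                 vapply(scores, oracle_band, character(1), bounds = bounds))
  }
})

test_that("default matrix hits the extreme corners and is monotone", {
  cfg <- risk_config()
  expect_equal(classify_risk("very_high", "very_high", cfg), 3L)
  expect_equal(classify_risk("very_low", "very_low", cfg), 1L)
  expect_equal(classify_risk("high", "high", cfg), 3L)  # ordinal sum 8
  # monotone over all 25 cells and every dominance pair
  m <- cfg$matrix
  for (i in 1:5) for (j in 1:5) for (k in i:5) for (l in j:5) {
    expect_gte(m[k, l], m[i, j])
  }
})

test_that("a non-monotone configured matrix is refused", {
  m <- default_risk_matrix()
  m[5, 5] <- 1L
  expect_error(risk_config(matrix = m), "monotone")
  m2 <- default_risk_matrix()
  m2[1, 1] <- 4L
  expect_error(risk_config(matrix = m2), "levels 1, 2 or 3")
})

test_that("adjustment rules bump, stack, cap at 3 and are idempotent", {
  prof_adj <- function(base, raptor, crossings, cfg = risk_config()) {
    adjust_level(base, raptor, crossings, cfg)
  }
  expect_equal(prof_adj(2, TRUE, 0)$adjusted_level, 3L)
  expect_equal(prof_adj(3, TRUE, 10)$adjusted_level, 3L)     # capped
  expect_equal(prof_adj(1, TRUE, 5)$adjusted_level, 3L)      # two bumps stack
  expect_equal(prof_adj(1, FALSE, 2)$adjusted_level, 1L)     # below threshold
  expect_equal(prof_adj(1, FALSE, 3)$adjusted_level, 2L)     # trigger at >= 3
  expect_equal(prof_adj(1, TRUE, 3)$adjustments, "raptor,runway_crossing")
  expect_equal(prof_adj(2, FALSE, 0)$adjustments, "")
  # raptor bump can be disabled; crossing threshold is configurable
  cfg2 <- risk_config(raptor_bump = FALSE, crossing_threshold = 5)
  expect_equal(prof_adj(2, TRUE, 4, cfg2)$adjusted_level, 2L)
  expect_equal(prof_adj(2, TRUE, 5, cfg2)$adjusted_level, 3L)
  # idempotence on the cap: re-adjusting an adjusted level changes nothing
  once <- prof_adj(2:3, TRUE, 4)
  twice <- adjust_level(once$adjusted_level, TRUE, 4)
  expect_equal(twice$adjusted_level, once$adjusted_level)
})

test_that("score_species fills every field consistently", {
  prof <- tibble::tibble(
    species = c("big", "small"), family = "Famidae", order = "Ordiformes",
    total_count = c(1000L, 1L), mass_g = c(1000, 10),
    total_biomass_g = c(1e6, 10), height_m = c(40, 200),
    max_cluster = c(150L, 1L), nearest_zone = c("A", "C"),
    is_raptor = FALSE, runway_crossings = 0L,
    seasons = list("spring", "spring")
  )
  factors <- assign_factors(prof)
  sc <- score_species(factors, prof)
  big <- sc[sc$species == "big", ]
  expect_equal(big$likelihood, (1 + 1 + 0.9) * 100 / 3)
  expect_equal(big$severity, 100)
  expect_equal(as.character(big$l_band), "very_high")
  expect_equal(as.character(big$s_band), "very_high")
  expect_equal(big$base_level, 3L)
  expect_equal(big$adjusted_level, 3L)
  small <- sc[sc$species == "small", ]
  expect_equal(small$likelihood, (0 + 0.1 + 0.3) * 100 / 3)
  expect_equal(as.character(small$l_band), "very_low")
  expect_equal(small$base_level, 1L)
  expect_true(all(sc$adjusted_level >= sc$base_level))
})

test_that("likelihood stays within the attainable [13.33, 96.67] envelope", {
  grid <- expand.grid(c = c(0, 0.2, 0.5, 1), f = c(0.1, 0.5, 1),
                      a = c(0.3, 0.6, 0.9))
  lik <- strike_likelihood(grid$c, grid$f, grid$a)
  expect_true(all(lik >= 13.333 - 1e-9 & lik <= 96.667 + 1e-6))
  expect_equal(lik, (grid$c + grid$f + grid$a) * 100 / 3)
})

test_that("raising one species' count never lowers its danger level", {
  base_records <- make_records(
    rec("focal", zone = "B", count = 10, group = 10, height = 10),
    rec("other", zone = "A", count = 500, group = 50, height = 40,
        date = "2019-06-01")
  )
  traits <- make_traits(c("focal", "other"), mass_g = c(800, 50))
  levels_seen <- vapply(c(10L, 100L, 1000L, 10000L), function(k) {
    recs <- base_records
    recs$count[1] <- k
    a <- assess_risk(recs, traits)
    a$scores$adjusted_level[a$scores$species == "focal"]
  }, integer(1))
  expect_true(all(diff(levels_seen) >= 0))
  expect_equal(levels_seen[4], 3L)  # dominant in number and biomass
})
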