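#' Synthetic trawl-survey scenario configuration
#'
#' Describes a seeded synthetic multi-species bottom-trawl survey with the
#' statistical structure the indicator pipeline assumes: depth-structured
#' species niches, phase-wise regime dynamics driven by a common driver,
#' zero-inflated lognormal catches and a mid-series size-dependent
#' catchability (gear) shift.
#'
#' The regional log-biomass of species `s` in year `t` is
#' `log B[s,t] = baseline_s + gamma_s * D_t + delta[s,t]`, where `D_t` is the
#' common driver accumulated from the per-phase slopes and `delta` is
#' species-year noise. Per trawl in polygon `p`, the local density is
#' `B[s,t] * exp(-(depth_p - mu_s)^2 / (2 w_s^2))`, multiplied post-1995 by a
#' species gear factor `exp(k (Lbar - L_s)/Lbar)` clamped to `[1, 10]`;
#' presence is Bernoulli(`plogis(detection_slope * log density)`) and the
#' positive catch is lognormal with median equal to the density.
#'
#' @param n_species number of species (default 30).
#' @param n_polygons number of Voronoi cells (default 150).
#' @param years inclusive survey interval (default 1981-2013).
#' @param trawls_per_year_mean,trawls_per_year_sd annual trawl count drawn as
#'   a rounded normal (defaults 421, 62), truncated at >= 50.
#' @param phases list of `list(years = c(a, b), kind, slope)` tiling `years`;
#'   `kind` one of `stable`, `synchronous_decline`, `shifted_regime`,
#'   `compositional_recovery`, `biomass_growth`; `slope` is the common-driver
#'   increment per year.
#' @param species_params data frame with columns `species`,
#'   `baseline_log_biomass`, `gamma` (driver loading, >= 0), `depth_mu` (m),
#'   `depth_w` (m), `detection_slope`; `NULL` draws defaults.
#' @param traits a [species_traits()] table aligned with `species_params`;
#'   `NULL` draws random traits (categorical levels uniform over 4-5 level
#'   sets, numeric traits lognormal).
#' @param gear_k strength of the size-dependent gear effect (default 0.8).
#' @param sd_species_year sd of the species-year log deviations (default
#'   0.15).
#' @param sd_trawl sd of the trawl-level lognormal catch noise (default 0.8).
#' @param lon_range,lat_range survey domain rectangle (decimal degrees).
#' @param depth_gradient,depth_base,depth_noise_sd polygon depth model:
#'   `depth = depth_base + depth_gradient * latitude fraction + noise`,
#'   clamped to >= 30 m, so depth and geography are partially confounded as
#'   on a real shelf.
#' @param seed integer seed; all randomness flows through it.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_species = 30L,
                            n_polygons = 150L,
                            years = c(1981L, 2013L),
                            trawls_per_year_mean = 421,
                            trawls_per_year_sd = 62,
                            phases = default_phases(),
                            species_params = NULL,
                            traits = NULL,
                            gear_k = 0.8,
                            sd_species_year = 0.15,
                            sd_trawl = 0.8,
                            lon_range = c(-55, -48),
                            lat_range = c(46, 55),
                            depth_gradient = 400,
                            depth_base = 100,
                            depth_noise_sd = 30,
                            seed = 1L) {
  stopifnot(n_species >= 1L, n_polygons >= 3L,
            sd_species_year >= 0, sd_trawl >= 0, gear_k >= 0)
  check_phase_tiling(phases, years)
  structure(list(n_species = as.integer(n_species),
                 n_polygons = as.integer(n_polygons),
                 years = as.integer(years),
                 trawls_per_year_mean = trawls_per_year_mean,
                 trawls_per_year_sd = trawls_per_year_sd,
                 phases = phases,
                 species_params = species_params,
                 traits = traits,
                 gear_k = gear_k,
                 sd_species_year = sd_species_year,
                 sd_trawl = sd_trawl,
                 lon_range = lon_range, lat_range = lat_range,
                 depth_gradient = depth_gradient, depth_base = depth_base,
                 depth_noise_sd = depth_noise_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

default_phases <- function() {
  list(list(years = c(1981L, 1986L), kind = "stable", slope = 0),
       list(years = c(1987L, 1994L), kind = "synchronous_decline",
            slope = -0.45),
       list(years = c(1995L, 2004L), kind = "shifted_regime", slope = 0),
       list(years = c(2005L, 2009L), kind = "compositional_recovery",
            slope = 0.2),
       list(years = c(2010L, 2013L), kind = "biomass_growth", slope = 0.1))
}

check_phase_tiling <- function(phases, years) {
  spans <- t(vapply(phases, function(p) as.numeric(p$years), numeric(2)))
  if (spans[1L, 1L] != years[1L] || spans[nrow(spans), 2L] != years[2L] ||
      (nrow(spans) > 1L &&
       any(spans[-1L, 1L] != spans[-nrow(spans), 2L] + 1))) {
    stop("phase intervals must tile the year range exactly")
  }
  kinds <- c("stable", "synchronous_decline", "shifted_regime",
             "compositional_recovery", "biomass_growth")
  bad <- setdiff(vapply(phases, `[[`, character(1), "kind"), kinds)
  if (length(bad) > 0L) stop("unknown phase kind: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Ready-made four-phase collapse-and-recovery scenario
#'
#' A scenario with four dominant "commercial" species and 26 others: a stable
#' early period, a synchronous collapse (1987-1994) driven by a common
#' declining driver that all species load on, a shifted regime (1995-2004) in
#' which dominance transfers from species `sp01` (large, schooling,
#' cod-like, high driver loading) to species `sp02` (halibut-like, nearly
#' driver-insensitive and deliberately central in trait space, so the
#' dominance shift depresses functional dispersion), then slow compositional
#' recovery (2005-2009) and slow biomass growth (2010-2013) as the driver
#' partially returns.
#'
#' @param seed integer seed.
#' @return a [scenario_config()].
#' @export
default_collapse_scenario <- function(seed = 1L) {
  n_species <- 30L
  species <- sprintf("sp%02d", seq_len(n_species))
  rng <- local_rng(seed + 101L)
  on.exit(rng$restore())
  baseline <- c(4.6, 3.2, 3.0, 2.8, runif(26L, log(0.3), log(5)))
  gamma <- c(1.1, 0.05, 0.8, 0.6, runif(26L, 0.4, 1.0))
  depth_mu <- c(250, 450, 120, 420, runif(26L, 80, 550))
  depth_w <- c(180, 160, 140, 150, runif(26L, 100, 250))
  body_length <- c(130, 90, 60, 45,
                   exp(rnorm(26L, log(35), 0.5)))
  traits <- data.frame(
    species = species,
    vertical_position = sample(c("benthic", "demersal", "benthopelagic",
                                 "bathydemersal"), n_species, replace = TRUE),
    body_length_cm = body_length,
    doubling_time = exp(rnorm(n_species, log(4.5), 0.5)),
    trophic_level = pmax(1, 3.4 * exp(rnorm(n_species, 0, 0.12))),
    aggregation = sample(c("schooling", "shoaling", "solitary", "irregular"),
                         n_species, replace = TRUE),
    food_niche = sample(c("piscivore", "planktivore", "benthivore",
                          "generalist", "mixed"), n_species, replace = TRUE),
    stringsAsFactors = FALSE)
  # cod-like: large schooling piscivore; halibut-like: central in trait space
  traits$aggregation[1L] <- "schooling"
  traits$food_niche[1L] <- "piscivore"
  traits$body_length_cm[2L] <- median(traits$body_length_cm)
  traits$doubling_time[2L] <- median(traits$doubling_time)
  traits$trophic_level[2L] <- median(traits$trophic_level)
  traits$vertical_position[2L] <- mode_level(traits$vertical_position)
  traits$aggregation[2L] <- mode_level(traits$aggregation)
  traits$food_niche[2L] <- mode_level(traits$food_niche)
  params <- data.frame(species = species,
                       baseline_log_biomass = baseline,
                       gamma = gamma,
                       depth_mu = depth_mu,
                       depth_w = depth_w,
                       detection_slope = rep(1.5, n_species),
                       stringsAsFactors = FALSE)
  scenario_config(species_params = params,
                  traits = species_traits(traits),
                  seed = seed)
}

mode_level <- function(x) names(which.max(table(x)))[1L]

# seeded RNG scope that restores the caller's stream on exit
local_rng <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  list(restore = function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
}

#' Simulate a synthetic trawl survey
#'
#' Draws a complete survey from a [scenario_config()]: the Voronoi polygon
#' set with depth structure, annual trawl allocations, per-trawl
#' zero-inflated lognormal catches for every species, the species trait
#' table, and the generating ground truth needed for recovery tests. Fully
#' reproducible from the config seed; the caller's RNG stream is left
#' untouched.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `"synthetic_survey"` with elements `table`
#'   ([trawl_table()]), `traits` ([species_traits()]), `polygons`
#'   ([polygon_set()] with `years_present` populated) and `truth` (list: the
#'   driver path, noiseless and realized expected log-biomass per
#'   species-year, the estimator-target expected biomass per species-year,
#'   per-window synchrony of the noiseless community, designed trough years,
#'   depth-structuring strength, per species-year presence probabilities).
#' @export
simulate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  check_phase_tiling(cfg$phases, cfg$years)
  rng <- local_rng(cfg$seed)
  on.exit(rng$restore())

  years <- seq.int(cfg$years[1L], cfg$years[2L])
  n_years <- length(years)
  params <- cfg$species_params
  traits <- cfg$traits
  if (is.null(params)) params <- draw_species_params(cfg$n_species)
  if (is.null(traits)) traits <- draw_traits(params$species)
  n_species <- nrow(params)

  # --- domain: Voronoi cells over a rectangle, depth from a smooth
  #     latitudinal gradient plus noise (depth and geography confounded)
  seeds <- cbind(lon = runif(cfg$n_polygons, cfg$lon_range[1L], cfg$lon_range[2L]),
                 lat = runif(cfg$n_polygons, cfg$lat_range[1L], cfg$lat_range[2L]))
  boundary <- rbind(c(cfg$lon_range[1L], cfg$lat_range[1L]),
                    c(cfg$lon_range[2L], cfg$lat_range[1L]),
                    c(cfg$lon_range[2L], cfg$lat_range[2L]),
                    c(cfg$lon_range[1L], cfg$lat_range[2L]))
  latfrac <- (seeds[, "lat"] - cfg$lat_range[1L]) / diff(cfg$lat_range)
  depth <- pmax(30, cfg$depth_base + cfg$depth_gradient * latfrac +
                  rnorm(cfg$n_polygons, 0, cfg$depth_noise_sd))
  polys <- build_voronoi_polygons(seeds, boundary, mean_depth = depth)

  # --- common driver and species-year log biomass
  driver <- driver_path(cfg$phases, years)
  delta <- matrix(rnorm(n_years * n_species, 0, cfg$sd_species_year),
                  n_years, n_species)
  noiseless <- outer(driver, params$gamma) +
    matrix(params$baseline_log_biomass, n_years, n_species, byrow = TRUE)
  logB <- noiseless + delta
  dimnames(logB) <- dimnames(noiseless) <- list(years, params$species)

  gear_mult <- gear_multiplier(traits$body_length_cm, cfg$gear_k)

  # --- depth niche kernel per polygon x species
  kern <- exp(-outer(depth, params$depth_mu, "-")^2 /
                (2 * matrix(params$depth_w^2, cfg$n_polygons, n_species,
                            byrow = TRUE)))

  # --- trawl allocation and catches
  n_trawls <- pmax(50L, as.integer(round(
    rnorm(n_years, cfg$trawls_per_year_mean, cfg$trawls_per_year_sd))))
  rec <- vector("list", n_years)
  for (ti in seq_len(n_years)) {
    nt <- n_trawls[ti]
    poly_i <- sample.int(cfg$n_polygons, nt, replace = TRUE)
    pts <- sample_points_in_cells(polys, poly_i)
    # log density per trawl x species
    ld <- matrix(logB[ti, ], nt, n_species, byrow = TRUE) +
      log(kern[poly_i, , drop = FALSE])
    if (years[ti] >= GEAR_CHANGE_YEAR) {
      ld <- ld + matrix(log(gear_mult), nt, n_species, byrow = TRUE)
    }
    slope <- matrix(params$detection_slope, nt, n_species, byrow = TRUE)
    present <- matrix(rbinom(nt * n_species, 1L,
                             plogis(slope * ld)) == 1L, nt, n_species)
    catch <- matrix(0, nt, n_species)
    npos <- sum(present)
    if (npos > 0L) {
      catch[present] <- exp(ld[present] + rnorm(npos, 0, cfg$sd_trawl))
    }
    idx <- which(present, arr.ind = TRUE)
    rec[[ti]] <- data.frame(
      trawl_id = sprintf("T%d_%04d", years[ti], idx[, 1L]),
      year = years[ti],
      lat = pts[idx[, 1L], 2L],
      lon = pts[idx[, 1L], 1L],
      depth_m = depth[poly_i[idx[, 1L]]],
      species = params$species[idx[, 2L]],
      biomass_kg = catch[present],
      stringsAsFactors = FALSE)
    # keep empty trawls in the roster via zero-species sentinel rows? no:
    # trawls with no catch at all still exist; record them with the most
    # common species at biomass 0 so the trawl roster (n) is complete
    empty <- setdiff(seq_len(nt), unique(idx[, 1L]))
    if (length(empty) > 0L) {
      rec[[ti]] <- rbind(rec[[ti]], data.frame(
        trawl_id = sprintf("T%d_%04d", years[ti], empty),
        year = years[ti],
        lat = pts[empty, 2L], lon = pts[empty, 1L],
        depth_m = depth[poly_i[empty]],
        species = params$species[1L],
        biomass_kg = 0,
        stringsAsFactors = FALSE))
    }
  }
  table <- trawl_table(do.call(rbind, rec))

  assigned <- suppressWarnings(assign_trawls(table, polys))
  polys$years_present <- polygon_years_present(assigned)

  truth <- ground_truth(cfg, years, driver, noiseless, logB, kern, depth,
                        params, gear_mult)
  structure(list(table = table, traits = traits, polygons = polys,
                 truth = truth, config = cfg),
            class = "synthetic_survey")
}

driver_path <- function(phases, years) {
  slope_of_year <- numeric(length(years))
  for (p in phases) {
    slope_of_year[years >= p$years[1L] & years <= p$years[2L]] <- p$slope
  }
  # D starts at 0 in the first year and accumulates the per-year slopes
  cumsum(c(0, slope_of_year[-1L]))
}

gear_multiplier <- function(body_length, k) {
  lbar <- mean(body_length)
  pmin(10, pmax(1, exp(k * (lbar - body_length) / lbar)))
}

draw_species_params <- function(n_species) {
  species <- sprintf("sp%02d", seq_len(n_species))
  data.frame(species = species,
             baseline_log_biomass = runif(n_species, log(0.5), log(20)),
             gamma = runif(n_species, 0.4, 1.0),
             depth_mu = runif(n_species, 80, 550),
             depth_w = runif(n_species, 100, 250),
             detection_slope = rep(1.5, n_species),
             stringsAsFactors = FALSE)
}

draw_traits <- function(species) {
  n <- length(species)
  species_traits(data.frame(
    species = species,
    vertical_position = sample(c("benthic", "demersal", "benthopelagic",
                                 "bathydemersal"), n, replace = TRUE),
    body_length_cm = exp(rnorm(n, log(45), 0.6)),
    doubling_time = exp(rnorm(n, log(4.5), 0.5)),
    trophic_level = pmax(1, 3.4 * exp(rnorm(n, 0, 0.12))),
    aggregation = sample(c("schooling", "shoaling", "solitary", "irregular"),
                         n, replace = TRUE),
    food_niche = sample(c("piscivore", "planktivore", "benthivore",
                          "generalist", "mixed"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# uniform point inside each (convex) Voronoi cell by bounding-box rejection
sample_points_in_cells <- function(polys, poly_i) {
  out <- matrix(NA_real_, length(poly_i), 2L)
  for (i in unique(poly_i)) {
    v <- polys$vertices[[i]]
    rows <- which(poly_i == i)
    need <- length(rows)
    got <- matrix(numeric(0), 0L, 2L)
    bb <- rbind(range(v[, 1L]), range(v[, 2L]))
    while (nrow(got) < need) {
      cand <- cbind(runif(2L * need + 8L, bb[1L, 1L], bb[1L, 2L]),
                    runif(2L * need + 8L, bb[2L, 1L], bb[2L, 2L]))
      ok <- mgcv::in.out(v, cand)
      got <- rbind(got, cand[ok, , drop = FALSE])
    }
    out[rows, ] <- got[seq_len(need), ]
  }
  out
}

# deterministic generating quantities: the estimator's large-sample target is
# mean presence probability times the geometric mean of density over the
# polygon pool, presence-weighted
ground_truth <- function(cfg, years, driver, noiseless, logB, kern, depth,
                         params, gear_mult) {
  n_years <- length(years)
  n_species <- nrow(params)
  target <- matrix(NA_real_, n_years, n_species,
                   dimnames = list(years, params$species))
  presence <- array(NA_real_, c(n_years, n_species),
                    dimnames = list(years, params$species))
  for (ti in seq_len(n_years)) {
    ld <- matrix(logB[ti, ], nrow(kern), n_species, byrow = TRUE) + log(kern)
    if (years[ti] >= GEAR_CHANGE_YEAR) {
      ld <- ld + matrix(log(gear_mult), nrow(kern), n_species, byrow = TRUE)
    }
    pi_p <- plogis(matrix(params$detection_slope, nrow(kern), n_species,
                          byrow = TRUE) * ld)
    pbar <- colMeans(pi_p)
    wlog <- colSums(pi_p * ld) / pmax(colSums(pi_p), .Machine$double.eps)
    target[ti, ] <- pbar * exp(wlog)
    presence[ti, ] <- pbar
  }
  phases_of_year <- rep(NA_character_, n_years)
  for (p in cfg$phases) {
    phases_of_year[years >= p$years[1L] & years <= p$years[2L]] <- p$kind
  }
  B_noiseless <- exp(noiseless)
  window <- 5L
  sync <- if (n_years >= window) {
    ends <- seq.int(window, n_years)
    setNames(vapply(ends, function(e) {
      as.numeric(community_synchrony(
        B_noiseless[(e - window + 1L):e, , drop = FALSE]))
    }, numeric(1)), years[ends])
  } else numeric(0)
  list(years = years,
       driver = setNames(driver, years),
       phase = setNames(phases_of_year, years),
       noiseless_log_biomass = noiseless,
       realized_log_biomass = logB,
       expected_biomass = target,
       presence_prob = presence,
       true_synchrony = sync,
       trough_years = years[driver <= min(driver) + 1e-12],
       depth_structuring = depth_structuring_r2(kern, depth))
}

# unadjusted R^2 of logit Bray-Curtis between noiseless polygon compositions
# on log absolute depth difference (first survey year, equal species biomass)
depth_structuring_r2 <- function(kern, depth) {
  comp <- kern / rowSums(kern)
  keep <- seq_len(min(nrow(comp), 80L))  # cap the pair count
  bc <- as.matrix(vegan::vegdist(comp[keep, , drop = FALSE], method = "bray"))
  y <- bc[lower.tri(bc)]
  y <- pmin(pmax(y, 1e-4), 1 - 1e-4)
  y <- log(y / (1 - y))
  dd <- abs(outer(depth[keep], depth[keep], "-"))[lower.tri(bc)]
  x <- log(dd + 1e-3)
  fit <- lm(y ~ x)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat("synthetic_survey (seed ", x$config$seed, ")\n", sep = "")
  print(x$table)
  print(x$polygons)
  invisible(x)
}

#' Write a synthetic survey to disk
#'
#' Emits `trawls.csv`, `traits.csv`, `polygons.geojson` and `truth.json`
#' under `out_dir`.
#'
#' @param survey a `"synthetic_survey"` from [simulate_survey()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_survey <- function(survey, out_dir) {
  stopifnot(inherits(survey, "synthetic_survey"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trawl_table(survey$table, file.path(out_dir, "trawls.csv"))
  write.csv(as.data.frame(survey$traits), file.path(out_dir, "traits.csv"),
            row.names = FALSE, quote = FALSE)
  write_polygons_geojson(survey$polygons, file.path(out_dir, "polygons.geojson"))
  tr <- survey$truth
  tr$noiseless_log_biomass <- as.data.frame(tr$noiseless_log_biomass)
  tr$realized_log_biomass <- as.data.frame(tr$realized_log_biomass)
  tr$expected_biomass <- as.data.frame(tr$expected_biomass)
  tr$presence_prob <- as.data.frame(tr$presence_prob)
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
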