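#' Run the full community-indicator pipeline
#'
#' Orchestrates every analysis stage on a survey — synthetic (pass a
#' [scenario_config()]) or read from files — for both community subsets (the
#' whole community and the community excluding the commercially dominant
#' species): gear-sensitivity screening, annual biomass estimation with
#' jackknife SEs, moving-window synchrony with its randomization null,
#' Bray-Curtis/NMDS compositional trajectories, biomass-weighted functional
#' dispersion and trait means, polygon-period community-type clustering,
#' per-year depth/distance variance partitioning, alpha/beta diversity
#' diagnostics, and the 0-100 relative-change recovery series. Every
#' randomized stage is seeded from `config$rng_seed`, so two runs with the
#' same inputs and config are identical.
#'
#' @param config an [analysis_config()].
#' @param inputs a [scenario_config()], an already-simulated
#'   `"synthetic_survey"`, or a named list of file paths with elements
#'   `trawls`, `traits` and optionally `polygons`, `effort`, `climate`.
#' @param commercial_species character vector of the commercially dominant
#'   species to exclude in the `noncommercial` subset; `NULL` (default) takes
#'   the four species with the highest summed annual biomass estimates.
#' @param verbose print one structured line per stage.
#' @return list of class `"pipeline_report"`; see the elements documented in
#'   Details. Every component table carries the run's `config_hash`.
#' @details Report elements: `biomass` (indicator series: total, per focal
#'   species, non-commercial total), `synchrony` (per subset), `nmds` (per
#'   subset), `fdis` (per subset), `trait_means`, `clusters` +
#'   `cluster_profiles`, `variance_partition` (per subset),
#'   `diversity` diagnostics, `recovery` (scaled 0-100 series), `drivers`,
#'   `screening`, `provenance`.
#' @export
run_pipeline <- function(config = analysis_config(), inputs,
                         commercial_species = NULL, verbose = FALSE) {
  t_start <- Sys.time()
  log_stage <- function(stage, detail) {
    if (verbose) {
      cat(sprintf("[%s] %s: %s (%.1fs elapsed)\n",
                  format(Sys.time(), "%H:%M:%S"), stage, detail,
                  as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- acquire ---------------------------------------------------------
  survey <- run_stage("acquire", {
    if (inherits(inputs, "scenario_config")) {
      simulate_survey(inputs)
    } else if (inherits(inputs, "synthetic_survey")) {
      inputs
    } else {
      table <- read_trawl_table(inputs$trawls)
      traits <- read_species_traits(inputs$traits)
      polys <- if (!is.null(inputs$polygons)) {
        read_polygons_geojson(inputs$polygons)
      } else {
        default_polygons_from_trawls(table, seed = config$rng_seed)
      }
      list(table = table, traits = traits, polygons = polys, truth = NULL)
    }
  })
  log_stage("acquire", sprintf("%d records", nrow(survey$table)))

  # --- screen ----------------------------------------------------------
  screening <- run_stage("screen", screen_gear_sensitive_species(
    survey$table, threshold = config$gear_ratio_threshold))
  table <- screening$table
  log_stage("screen", sprintf("excluded %d species, %d retained",
                              length(screening$excluded),
                              length(attr(table, "species_list"))))

  # --- spatial assignment ---------------------------------------------
  assigned <- run_stage("assign", {
    a <- suppressWarnings(assign_trawls(table, survey$polygons))
    survey$polygons$years_present <- polygon_years_present(a)
    a
  })

  # --- focal species ---------------------------------------------------
  annual_all <- run_stage("annual_estimates",
                          build_community_matrix(table, "year",
                                                 jackknife = TRUE))
  if (is.null(commercial_species)) {
    totals <- colSums(annual_all)
    commercial_species <- names(sort(totals, decreasing = TRUE))[
      seq_len(min(4L, length(totals)))]
  }
  noncommercial <- setdiff(attr(table, "species_list"), commercial_species)
  log_stage("focal", paste(commercial_species, collapse = ", "))

  # --- per-subset indicator stages ------------------------------------
  subsets <- list(
    all = table,
    noncommercial = subset_trawl_table(table, noncommercial))
  stage_out <- lapply(names(subsets), function(nm) {
    out <- indicator_stage(subsets[[nm]], survey$traits, survey$polygons,
                           config, nm)
    log_stage(paste0("indicators[", nm, "]"),
              sprintf("%d species", ncol(out$annual)))
    out
  })
  names(stage_out) <- names(subsets)

  # --- recovery scaling ------------------------------------------------
  recovery <- run_stage("recovery", {
    all_s <- stage_out$all
    years <- attr(all_s$annual, "years")
    focal1 <- intersect(commercial_species, colnames(all_s$annual))[1L]
    series <- list(
      focal_biomass = if (!is.na(focal1))
        setNames(all_s$annual[, focal1], years),
      total_biomass = setNames(rowSums(all_s$annual), years),
      composition_similarity = setNames(all_s$composition$similarity,
                                        all_s$composition$years),
      fdis = setNames(all_s$fdis$values, all_s$fdis$years))
    series <- Filter(Negate(is.null), series)
    out <- lapply(names(series), function(nm) {
      tryCatch(relative_change_series(series[[nm]],
                                      reference_year = config$reference_year),
               error = function(e) {
                 warning("recovery series '", nm, "' skipped: ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
    })
    names(out) <- names(series)
    Filter(Negate(is.null), out)
  })

  # --- drivers ---------------------------------------------------------
  drivers <- run_stage("drivers", {
    out <- list()
    if (!inherits(inputs, "scenario_config") &&
        !inherits(inputs, "synthetic_survey")) {
      if (!is.null(inputs$effort)) {
        eff <- fishing_effort(read_effort_table(inputs$effort),
                              target_filter = "benthic")
        out$effort_tonne_days <- eff
        out$effort_smoothed <- moving_average(eff, config$window_length)
      }
      if (!is.null(inputs$climate)) {
        cl <- read.csv(inputs$climate, stringsAsFactors = FALSE)
        comps <- lapply(cl[setdiff(names(cl), "year")],
                        function(x) setNames(x, cl$year))
        ci <- climate_index(comps)
        out$climate_index <- ci$index
        out$climate_smoothed <- moving_average(ci$index, config$window_length)
      }
    } else if (!is.null(survey$truth)) {
      out$common_driver <- survey$truth$driver
      out$driver_smoothed <- moving_average(survey$truth$driver,
                                            config$window_length)
    }
    out
  })

  hash <- config_hash(config, commercial_species)
  report <- structure(list(
    biomass = c(
      list(total = indicator_series("total_biomass",
                                    attr(stage_out$all$annual, "years"),
                                    rowSums(stage_out$all$annual)),
           noncommercial_total = indicator_series(
             "total_biomass", attr(stage_out$noncommercial$annual, "years"),
             rowSums(stage_out$noncommercial$annual),
             subset = "noncommercial")),
      local({
        present <- intersect(commercial_species,
                             colnames(stage_out$all$annual))
        setNames(lapply(present, function(sp) {
          indicator_series(paste0("biomass_", sp),
                           attr(stage_out$all$annual, "years"),
                           stage_out$all$annual[, sp],
                           ses = attr(stage_out$all$annual, "se")[, sp])
        }), present)
      })),
    annual = lapply(stage_out, `[[`, "annual"),
    synchrony = lapply(stage_out, `[[`, "synchrony"),
    nmds = lapply(stage_out, `[[`, "nmds"),
    fdis = lapply(stage_out, `[[`, "fdis"),
    composition = lapply(stage_out, `[[`, "composition"),
    trait_means = stage_out$all$trait_means,
    clusters = lapply(stage_out, `[[`, "clusters"),
    cluster_profiles = lapply(stage_out, `[[`, "cluster_profiles"),
    variance_partition = lapply(stage_out, `[[`, "variance_partition"),
    diversity = stage_out$all$diversity,
    recovery = recovery,
    drivers = drivers,
    screening = screening[c("excluded", "ratios")],
    commercial_species = commercial_species,
    truth = survey$truth,
    provenance = list(config = config, config_hash = hash,
                      seed = config$rng_seed,
                      package_version =
                        as.character(utils::packageVersion("trawlshift")),
                      r_version = R.version.string)),
    class = "pipeline_report")
  for (nm in setdiff(names(report), "provenance")) {
    attr(report[[nm]], "config_hash") <- hash
  }
  log_stage("done", sprintf("%d output families", length(report) - 1L))
  report
}

# per-subset indicator computations on an already-screened table
indicator_stage <- function(table, traits, polys, config, subset_name) {
  annual <- build_community_matrix(table, "year", jackknife = TRUE)
  sync <- moving_window_synchrony(annual, window = config$window_length,
                                  R = config$n_randomizations,
                                  seed = config$rng_seed)
  norm_annual <- normalize_rows(annual)
  ord <- nmds(bray_curtis(norm_annual), k = config$nmds_dimensions,
              seed = config$rng_seed)
  fd <- annual_fdis(annual, traits)
  fd$subset <- subset_name
  comp <- composition_trajectory(annual, config$reference_year)
  comp$subset <- subset_name
  tmeans <- community_weighted_trait_means(annual, traits)

  assigned <- suppressWarnings(assign_trawls(table, polys))
  at <- structure(assigned, class = c("trawl_table", "data.frame"),
                  species_list = attr(table, "species_list"),
                  year_range = attr(table, "year_range"))
  pp <- build_community_matrix(at, "polygon-period",
                               periods = config$period_breaks)
  cl <- cluster_polygon_periods(pp, K = config$n_clusters)
  focal <- names(sort(colSums(annual), decreasing = TRUE))
  prof <- cluster_profiles(cl, pp, focal[seq_len(min(4L, length(focal)))])
  py <- build_community_matrix(at, "polygon-year")
  total_years <- diff(attr(table, "year_range")) + 1L
  retained <- retain_consistent_polygons(
    polys, min_years = min(config$min_years_present, total_years),
    years_present = polygon_years_present(assigned))
  vp <- do.call(rbind, lapply(sort(unique(at$year)), function(yr) {
    tryCatch(variance_partition_by_year(py, retained, yr),
             error = function(e) NULL)
  }))
  div <- diversity_diagnostics(py, table)
  list(annual = annual, synchrony = sync, nmds = ord, fdis = fd,
       composition = comp, trait_means = tmeans, clusters = cl,
       cluster_profiles = prof, variance_partition = vp, diversity = div)
}

subset_trawl_table <- function(table, species) {
  df <- as.data.frame(table)
  # keep the full trawl roster: trawls whose only catches were focal species
  # must still contribute zeros, so retain one zero-biomass row for them
  keep <- df$species %in% species
  lost <- setdiff(df$trawl_id, df$trawl_id[keep])
  out <- df[keep, TRAWL_COLUMNS]
  if (length(lost) > 0L) {
    sent <- df[match(lost, df$trawl_id), TRAWL_COLUMNS]
    sent$species <- species[1L]
    sent$biomass_kg <- 0
    out <- rbind(out, sent)
  }
  trawl_table(out)
}

default_polygons_from_trawls <- function(table, n_polygons = 150L, seed = 1L) {
  rng <- local_rng(seed + 7L)
  on.exit(rng$restore())
  pts <- unique(as.data.frame(table)[c("lon", "lat")])
  k <- min(n_polygons, nrow(pts) - 1L)
  km <- kmeans(pts, centers = k, nstart = 5L, iter.max = 50L)
  pad_lon <- diff(range(pts$lon)) * 0.05 + 1e-6
  pad_lat <- diff(range(pts$lat)) * 0.05 + 1e-6
  boundary <- rbind(c(min(pts$lon) - pad_lon, min(pts$lat) - pad_lat),
                    c(max(pts$lon) + pad_lon, min(pts$lat) - pad_lat),
                    c(max(pts$lon) + pad_lon, max(pts$lat) + pad_lat),
                    c(min(pts$lon) - pad_lon, max(pts$lat) + pad_lat))
  polys <- build_voronoi_polygons(as.matrix(km$centers), boundary)
  # mean observed depth per cell from the trawls themselves
  a <- suppressWarnings(assign_trawls(table, polys))
  depth <- tapply(a$depth_m, a$polygon_id, mean)
  polys$mean_depth <- as.numeric(depth[polys$id])
  polys
}

config_hash <- function(config, commercial_species) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(vapply(unclass(config), function(x)
    paste(format(x, digits = 17), collapse = ","), character(1)),
    paste(commercial_species, collapse = ",")), f)
  unname(tools::md5sum(f))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (config", substr(x$provenance$config_hash, 1, 8),
      ", seed", x$provenance$seed, ")\n")
  cat(sprintf("  species: %d commercial + %d retained total\n",
              length(x$commercial_species),
              ncol(x$annual$all)))
  cat(sprintf("  years: %d-%d\n", min(x$biomass$total$years),
              max(x$biomass$total$years)))
  cat(sprintf("  synchrony windows: %d; NMDS stress: %.3f; clusters: %d\n",
              nrow(x$synchrony$all), x$nmds$all$stress,
              x$clusters$all$K))
  invisible(x)
}

#' Percentage recovered per scaled indicator at a given year
#'
#' Reads the 0-100 relative-change series of the report (focal-species
#' biomass, total community biomass, composition similarity to the reference
#' year, functional dispersion) at `as_of_year`: 100 means the reference-year
#' level, 0 the maximum observed departure from it.
#'
#' @param report a `"pipeline_report"`.
#' @param as_of_year year at which to read the scaled series (default: last
#'   survey year).
#' @return named numeric vector of percentages.
#' @export
recovery_summary <- function(report, as_of_year = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  if (is.null(as_of_year)) {
    as_of_year <- max(report$biomass$total$years)
  }
  vapply(report$recovery, function(s) {
    v <- s[as.character(as_of_year)]
    if (is.na(v)) stop("year ", as_of_year, " not in scaled series")
    unname(v)
  }, numeric(1))
}

#' Write a pipeline report as CSV/JSON tables
#'
#' Emits one tidy file per output family plus a `manifest.json` with the
#' provenance (config, hash, seed, versions).
#'
#' @param report a `"pipeline_report"`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(do.call(rbind, lapply(report$biomass, as.data.frame)), "biomass.csv")
  w(do.call(rbind, lapply(names(report$synchrony), function(nm) {
    cbind(subset = nm, as.data.frame(report$synchrony[[nm]]))
  })), "synchrony.csv")
  w(do.call(rbind, lapply(names(report$nmds), function(nm) {
    co <- report$nmds[[nm]]$coordinates
    cbind(subset = nm, label = rownames(co), as.data.frame(co),
          stress = report$nmds[[nm]]$stress)
  })), "nmds.csv")
  w(do.call(rbind, lapply(report$fdis, as.data.frame)), "fdis.csv")
  w(do.call(rbind, lapply(report$composition, as.data.frame)),
    "composition.csv")
  w(report$trait_means, "trait_means.csv")
  w(do.call(rbind, lapply(names(report$clusters), function(nm) {
    cbind(subset = nm, report$clusters[[nm]]$assignment)
  })), "cluster_assignments.csv")
  w(do.call(rbind, lapply(names(report$cluster_profiles), function(nm) {
    p <- report$cluster_profiles[[nm]]
    sp_cols <- setdiff(names(p), c("cluster", "n_units"))
    do.call(rbind, lapply(sp_cols, function(sp) {
      data.frame(subset = nm, cluster = p$cluster, n_units = p$n_units,
                 species = sp, share = p[[sp]], stringsAsFactors = FALSE)
    }))
  })), "cluster_profiles.csv")
  w(do.call(rbind, lapply(names(report$variance_partition), function(nm) {
    cbind(subset = nm, report$variance_partition[[nm]])
  })), "variance_partition.csv")
  w(report$diversity, "diversity.csv")
  w(do.call(rbind, lapply(names(report$recovery), function(nm) {
    data.frame(series = nm, year = as.integer(names(report$recovery[[nm]])),
               scaled = as.numeric(report$recovery[[nm]]))
  })), "recovery.csv")
  jsonlite::write_json(
    list(config = unclass(report$provenance$config),
         config_hash = report$provenance$config_hash,
         seed = report$provenance$seed,
         commercial_species = report$commercial_species,
         package_version = report$provenance$package_version,
         r_version = report$provenance$r_version),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
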