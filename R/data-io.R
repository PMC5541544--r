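#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor dist hclust cutree lm kmeans median plogis
#'   quantile rbinom rlnorm rnorm runif sd setNames var isoreg cmdscale
#'   weighted.mean
#' @importFrom utils read.csv write.csv head
NULL

TRAWL_COLUMNS <- c("trawl_id", "year", "lat", "lon", "depth_m", "species",
                   "biomass_kg")
TRAIT_COLUMNS <- c("species", "vertical_position", "body_length_cm",
                   "doubling_time", "trophic_level", "aggregation",
                   "food_niche")
GEAR_CHANGE_YEAR <- 1995L

#' Construct a validated trawl table
#'
#' The atomic survey container: one row per species-per-trawl, with biomass in
#' kg per tow and space/time/gear metadata. The gear-era flag is derived from
#' the survey year (pre1995 for years <= 1994). Species absent from a trawl
#' carry no row; absences become explicit zeros when a community matrix is
#' built.
#'
#' @param df data frame with columns `trawl_id`, `year`, `lat`, `lon`,
#'   `depth_m`, `species`, `biomass_kg`.
#' @return An object of class `"trawl_table"`: the validated data frame with a
#'   `gear_era` column and attributes `species_list` (ordered unique species
#'   codes) and `year_range`.
#' @export
trawl_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(TRAWL_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("trawl table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[TRAWL_COLUMNS]
  for (col in c("year", "lat", "lon", "depth_m", "biomass_kg")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[col]])))))
      stop(sprintf("column '%s': unparseable numeric value at data row(s) %s",
                   col, paste(head(bad, 5L), collapse = ", ")))
    }
  }
  bad <- which(df$biomass_kg < 0)
  if (length(bad) > 0L) {
    stop(sprintf("negative biomass at data row(s) %s",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  bad <- which(!(df$depth_m > 0))
  if (length(bad) > 0L) {
    stop(sprintf("non-positive depth at data row(s) %s",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  df$year <- as.integer(df$year)
  for (col in c("lat", "lon", "depth_m", "biomass_kg")) {
    df[[col]] <- as.double(df[[col]])
  }
  df$species <- as.character(df$species)
  df$trawl_id <- as.character(df$trawl_id)
  df$gear_era <- ifelse(df$year <= GEAR_CHANGE_YEAR - 1L, "pre1995", "post1995")
  structure(df,
            species_list = sort(unique(df$species)),
            year_range = range(df$year),
            class = c("trawl_table", "data.frame"))
}

#' Read a trawl survey table from CSV
#'
#' Comma-separated, UTF-8, `.` decimal, header row required, with columns
#' `trawl_id, year, lat, lon, depth_m, species, biomass_kg`. Rows with
#' negative biomass or non-positive depth are rejected with a row-level error;
#' a missing column is a schema error naming the column.
#'
#' @param path path to the CSV file.
#' @return A [trawl_table()].
#' @export
read_trawl_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  trawl_table(df)
}

#' Write a trawl table to CSV
#'
#' Inverse of [read_trawl_table()]: full-precision round trip (values written
#' with 17 significant digits).
#'
#' @param table a [trawl_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trawl_table <- function(table, path) {
  stopifnot(inherits(table, "trawl_table"))
  df <- as.data.frame(table)[TRAWL_COLUMNS]
  for (col in c("lat", "lon", "depth_m", "biomass_kg")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.trawl_table <- function(x, ...) {
  yr <- attr(x, "year_range")
  cat(sprintf("trawl_table: %d records, %d species, years %d-%d, %d trawls\n",
              nrow(x), length(attr(x, "species_list")), yr[1], yr[2],
              length(unique(x$trawl_id))))
  invisible(x)
}

#' Read a species trait table from CSV
#'
#' Six functional traits per species: vertical position (categorical), maximum
#' body length (cm), population doubling time, trophic level, aggregation
#' class and food-niche class. Numeric traits must be strictly positive and
#' trophic level >= 1; no missing values are allowed for retained species.
#'
#' @param path path to the CSV file with columns
#'   `species, vertical_position, body_length_cm, doubling_time,
#'   trophic_level, aggregation, food_niche`.
#' @return data frame of class `"species_traits"`, one row per species.
#' @export
read_species_traits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  species_traits(df)
}

#' @rdname read_species_traits
#' @param df data frame with the trait columns (used directly).
#' @export
species_traits <- function(df) {
  missing_cols <- setdiff(TRAIT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("trait table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[TRAIT_COLUMNS]
  if (anyNA(df)) stop("trait table contains missing values")
  if (any(df$body_length_cm <= 0) || any(df$doubling_time <= 0)) {
    stop("numeric traits must be strictly positive")
  }
  if (any(df$trophic_level < 1)) stop("trophic level must be >= 1")
  if (anyDuplicated(df$species)) stop("duplicate species in trait table")
  df$species <- as.character(df$species)
  structure(df, class = c("species_traits", "data.frame"))
}

#' Screen out gear-sensitive and rarely-caught species
#'
#' Removes, ahead of all analyses, species whose biomass estimates are
#' confounded by a mid-series gear change: (i) species whose mean biomass over
#' the post-change window (default 1995-2000) exceeds `threshold` times their
#' pre-change mean (strict inequality), and (ii) species captured infrequently
#' before the change (present in fewer than `min_pre_trawls` pre-change
#' trawls). Era means use the zero-inflated geometric-mean estimator pooled
#' over all trawls of the era (zeros for trawls where the species is absent).
#'
#' @param table a [trawl_table()] spanning both eras.
#' @param threshold ratio above which a species is excluded (default 7).
#' @param post_window inclusive year interval for the post-change mean
#'   (default `c(1995, 2000)`).
#' @param min_pre_trawls species present in fewer pre-change trawls than this
#'   are excluded (default 1: only never-captured species).
#' @return list with `table` (screened [trawl_table()]), `excluded` (character
#'   vector) and `ratios` (named post/pre ratios, `Inf` when the pre-change
#'   mean is zero).
#' @export
screen_gear_sensitive_species <- function(table, threshold = 7,
                                          post_window = c(1995L, 2000L),
                                          min_pre_trawls = 1L) {
  stopifnot(inherits(table, "trawl_table"))
  if (nrow(table) == 0L) stop("empty trawl table")
  yr <- attr(table, "year_range")
  if (yr[1] >= GEAR_CHANGE_YEAR || yr[2] < post_window[1]) {
    stop("table must span years before 1995 and cover the post window")
  }
  species <- attr(table, "species_list")
  pre_ids <- unique(table$trawl_id[table$year < GEAR_CHANGE_YEAR])
  post_keep <- table$year >= post_window[1] & table$year <= post_window[2]
  post_ids <- unique(table$trawl_id[post_keep])
  n_pre <- length(pre_ids)
  n_post <- length(post_ids)

  excluded <- character(0)
  ratios <- setNames(rep(NA_real_, length(species)), species)
  for (sp in species) {
    rows <- table$species == sp
    pre_b <- table$biomass_kg[rows & table$year < GEAR_CHANGE_YEAR]
    pre_b <- pre_b[pre_b > 0]
    m_pre <- length(pre_b)
    if (m_pre < min_pre_trawls) {
      excluded <- c(excluded, sp)
      ratios[sp] <- Inf
      next
    }
    post_b <- table$biomass_kg[rows & post_keep]
    post_b <- post_b[post_b > 0]
    pre_mean <- (m_pre / n_pre) * exp(mean(log(pre_b)))
    post_mean <- if (length(post_b) == 0L) 0 else
      (length(post_b) / n_post) * exp(mean(log(post_b)))
    ratios[sp] <- post_mean / pre_mean
    if (ratios[sp] > threshold) excluded <- c(excluded, sp)
  }
  kept <- table[!(table$species %in% excluded), , drop = FALSE]
  list(table = trawl_table(as.data.frame(kept)[TRAWL_COLUMNS]),
       excluded = sort(excluded),
       ratios = ratios)
}

#' Build a community abundance matrix from a trawl table
#'
#' Aggregates per-trawl biomasses into a groups x species matrix, where a
#' group is a survey year, a polygon-year, or a polygon-period. Each cell is
#' the chosen estimator applied to *all* trawls of the group, with explicit
#' zeros for trawls in which the species is absent (so the zero-inflated
#' estimator sees `n` = all trawls in the group, `m` = trawls with the species
#' present).
#'
#' @param table a [trawl_table()].
#' @param group_by one of `"year"`, `"polygon-year"`, `"polygon-period"`.
#' @param polygons a [polygon_set()] (required for polygon groupings). Trawls
#'   must already carry a `polygon_id` column (see [assign_trawls()]).
#' @param periods list of inclusive year intervals for `"polygon-period"`.
#' @param estimator function of a biomass vector; default
#'   [zinf_geometric_mean()].
#' @param jackknife if `TRUE`, also return a matrix of leave-one-trawl-out
#'   jackknife SEs (only for the default estimator).
#' @return A `"community_matrix"`: numeric matrix (groups x species) with
#'   attributes `normalized` (FALSE), `group_by`, and for year groupings a
#'   `years` integer vector; with `jackknife = TRUE`, an `se` attribute.
#' @export
build_community_matrix <- function(table,
                                   group_by = c("year", "polygon-year",
                                                "polygon-period"),
                                   polygons = NULL, periods = NULL,
                                   estimator = zinf_geometric_mean,
                                   jackknife = FALSE) {
  stopifnot(inherits(table, "trawl_table"))
  group_by <- match.arg(group_by)
  df <- as.data.frame(table)
  if (group_by != "year") {
    if (is.null(df$polygon_id)) {
      if (is.null(polygons)) stop("polygon grouping requires assigned polygons")
      df <- assign_trawls(table, polygons)
    }
    df <- df[!is.na(df$polygon_id), , drop = FALSE]
  }
  group <- switch(group_by,
    "year" = as.character(df$year),
    "polygon-year" = paste(df$polygon_id, df$year, sep = ":"),
    "polygon-period" = {
      if (is.null(periods)) stop("polygon-period grouping requires 'periods'")
      pid <- period_of_year(df$year, periods)
      keep <- !is.na(pid)
      df <- df[keep, , drop = FALSE]
      paste(df$polygon_id[keep], pid[keep], sep = ":")
    })
  species <- attr(table, "species_list")
  # trawl roster per group: a trawl contributes a zero for every absent species
  trawl_group <- unique(data.frame(trawl_id = df$trawl_id, group = group,
                                   stringsAsFactors = FALSE))
  n_per_group <- table(trawl_group$group)
  groups <- sort(names(n_per_group))
  mat <- matrix(0, nrow = length(groups), ncol = length(species),
                dimnames = list(groups, species))
  se <- if (jackknife) mat else NULL
  pos <- df[df$biomass_kg > 0, , drop = FALSE]
  pos_group <- group[df$biomass_kg > 0]
  key <- paste(pos_group, pos$species, sep = "\r")
  default_est <- identical(estimator, zinf_geometric_mean)
  if (default_est && !jackknife) {
    # vectorized: cell = (m/n) * exp(mean log positives)
    sums <- rowsum(log(pos$biomass_kg), key)
    counts <- rowsum(rep(1L, length(key)), key)
    gk <- sub("\r.*$", "", rownames(sums))
    sk <- sub("^.*\r", "", rownames(sums))
    n <- as.numeric(n_per_group[gk])
    mat[cbind(match(gk, groups), match(sk, species))] <-
      (counts[, 1L] / n) * exp(sums[, 1L] / counts[, 1L])
  } else {
    split_b <- split(pos$biomass_kg, key)
    for (k in names(split_b)) {
      gk <- sub("\r.*$", "", k)
      sk <- sub("^.*\r", "", k)
      b_pos <- split_b[[k]]
      n <- as.integer(n_per_group[[gk]])
      b_full <- c(b_pos, rep(0, n - length(b_pos)))
      mat[gk, sk] <- if (default_est) {
        (length(b_pos) / n) * exp(mean(log(b_pos)))
      } else {
        estimator(b_full)
      }
      if (jackknife) se[gk, sk] <- zinf_jackknife_se(b_full)
    }
  }
  if (group_by == "year") {
    ord <- order(as.integer(groups))
    mat <- mat[ord, , drop = FALSE]
    if (jackknife) se <- se[ord, , drop = FALSE]
    attr(mat, "years") <- as.integer(rownames(mat))
  }
  attr(mat, "normalized") <- FALSE
  attr(mat, "group_by") <- group_by
  attr(mat, "n_trawls") <- as.integer(n_per_group[rownames(mat)])
  if (jackknife) attr(mat, "se") <- se
  class(mat) <- c("community_matrix", class(matrix()))
  mat
}

period_of_year <- function(year, periods) {
  out <- rep(NA_character_, length(year))
  for (p in periods) {
    lab <- sprintf("%d-%d", p[1], p[2])
    out[year >= p[1] & year <= p[2]] <- lab
  }
  out
}

#' Normalize community-matrix rows to relative biomass
#'
#' Divides each row with a positive total by its sum, so rows represent
#' relative biomass (summing to 1). All-zero rows are left as zeros and
#' recorded in the `zero_rows` attribute.
#'
#' @param m a `"community_matrix"` (or plain numeric matrix).
#' @return The normalized matrix with `normalized = TRUE` and `zero_rows`
#'   attributes.
#' @export
normalize_rows <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  rs <- rowSums(m)
  zero <- rs <= 0
  out <- m
  out[!zero, ] <- m[!zero, , drop = FALSE] / rs[!zero]
  attr(out, "normalized") <- TRUE
  attr(out, "zero_rows") <- rownames(m)[zero]
  out
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the indicator pipeline with their
#' defaults: the 5-year moving window, 999 randomization replicates, 7 spatial
#' community clusters, 2 ordination dimensions, the 7x gear-screening ratio,
#' the 30-year polygon consistency rule, the 1981 reference year and the six
#' polygon-period intervals.
#'
#' @param window_length synchrony/smoothing window in years.
#' @param n_randomizations Monte-Carlo replicates for the synchrony null.
#' @param n_clusters number of spatial community-type clusters.
#' @param nmds_dimensions ordination dimensions.
#' @param gear_ratio_threshold post/pre screening ratio.
#' @param min_years_present polygon consistency threshold (years present).
#' @param reference_year baseline year for relative-change scaling.
#' @param period_breaks list of inclusive year intervals (polygon-periods).
#' @param rng_seed integer seed controlling all randomized stages.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(window_length = 5L,
                            n_randomizations = 999L,
                            n_clusters = 7L,
                            nmds_dimensions = 2L,
                            gear_ratio_threshold = 7,
                            min_years_present = 30L,
                            reference_year = 1981L,
                            period_breaks = list(c(1981L, 1984L), c(1985L, 1989L),
                                                 c(1990L, 1994L), c(1995L, 2001L),
                                                 c(2002L, 2006L), c(2007L, 2013L)),
                            rng_seed = 1L) {
  counts <- c(window_length, n_randomizations, n_clusters, nmds_dimensions,
              min_years_present)
  if (any(counts < 1)) stop("all counts must be >= 1")
  starts <- vapply(period_breaks, `[`, numeric(1), 1L)
  ends <- vapply(period_breaks, `[`, numeric(1), 2L)
  if (any(diff(starts) <= 0) || any(ends < starts) ||
      any(starts[-1] <= ends[-length(ends)])) {
    stop("period intervals must be disjoint and ordered")
  }
  structure(list(window_length = as.integer(window_length),
                 n_randomizations = as.integer(n_randomizations),
                 n_clusters = as.integer(n_clusters),
                 nmds_dimensions = as.integer(nmds_dimensions),
                 gear_ratio_threshold = gear_ratio_threshold,
                 min_years_present = as.integer(min_years_present),
                 reference_year = as.integer(reference_year),
                 period_breaks = period_breaks,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' Read / write an analysis configuration as JSON
#' @param path JSON file path.
#' @return [analysis_config()] (reader); `path` invisibly (writer).
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$period_breaks)) {
    pb <- raw$period_breaks
    if (is.matrix(pb)) pb <- lapply(seq_len(nrow(pb)), function(i) pb[i, ])
    raw$period_breaks <- lapply(pb, as.integer)
  }
  do.call(analysis_config, raw)
}

#' @rdname read_analysis_config
#' @param config an [analysis_config()].
#' @export
write_analysis_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
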