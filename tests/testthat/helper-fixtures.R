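# shared fixtures and independent oracles, built in code at test time

# tiny trawl table: 2 polygons-worth of trawls, hand-enumerable
toy_trawl_df <- function() {
  data.frame(
    trawl_id = c("t1", "t1", "t2", "t3", "t3", "t4"),
    year = c(1981L, 1981L, 1981L, 1982L, 1982L, 1982L),
    lat = c(47, 47, 48, 47, 47, 48),
    lon = c(-52, -52, -51, -52, -52, -51),
    depth_m = c(100, 100, 200, 100, 100, 200),
    species = c("cod", "plaice", "cod", "cod", "plaice", "plaice"),
    biomass_kg = c(4, 1, 9, 1, 2, 8),
    stringsAsFactors = FALSE)
}

toy_traits_df <- function(species = c("a", "b", "c")) {
  data.frame(
    species = species,
    vertical_position = c("benthic", "demersal", "benthic")[seq_along(species)],
    body_length_cm = c(10, 30, 50)[seq_along(species)],
    doubling_time = c(2, 4, 8)[seq_along(species)],
    trophic_level = c(3, 3.5, 4)[seq_along(species)],
    aggregation = c("schooling", "solitary", "schooling")[seq_along(species)],
    food_niche = c("piscivore", "benthivore", "piscivore")[seq_along(species)],
    stringsAsFactors = FALSE)
}

# small fast synthetic scenario for pipeline-level tests
small_scenario <- function(seed = 1L, n_species = 10L, n_polygons = 25L) {
  scenario_config(
    n_species = n_species, n_polygons = n_polygons,
    years = c(1981L, 1996L),
    trawls_per_year_mean = 80, trawls_per_year_sd = 8,
    phases = list(
      list(years = c(1981L, 1986L), kind = "stable", slope = 0),
      list(years = c(1987L, 1993L), kind = "synchronous_decline",
           slope = -0.4),
      list(years = c(1994L, 1996L), kind = "shifted_regime", slope = 0)),
    seed = seed)
}

small_analysis_config <- function(seed = 1L) {
  analysis_config(
    n_randomizations = 99L, n_clusters = 4L, min_years_present = 12L,
    period_breaks = list(c(1981L, 1984L), c(1985L, 1989L),
                         c(1990L, 1993L), c(1994L, 1996L)),
    rng_seed = seed)
}

# O(n^3) complete-linkage oracle: returns merge heights and the partition
# (canonical set of sorted member vectors) after every merge
complete_linkage_oracle <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(dm[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    partitions[[length(partitions) + 1L]] <-
      canonical_partition(clusters)
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(clusters) {
  sets <- lapply(clusters, sort)
  sets[order(vapply(sets, `[`, numeric(1), 1L))]
}

# partitions after each hclust merge, canonicalized like the oracle
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", nrow(hc$merge))
  out <- vector("list", nrow(hc$merge))
  current <- as.list(seq_len(n))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) -x else members[[x]]
    mem <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
    members[[i]] <- mem
    current <- Filter(function(s) !any(s %in% mem), current)
    current <- c(current, list(mem))
    out[[i]] <- canonical_partition(current)
  }
  out
}

# brute-force even-odd ray casting point-in-polygon
raycast_inside <- function(p, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > p[2]) != (v[j, 2] > p[2])) {
      xint <- v[i, 1] + (p[2] - v[i, 2]) * (v[j, 1] - v[i, 1]) /
        (v[j, 2] - v[i, 2])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# direct FDis evaluation with explicit loops (independent of fdis())
fdis_bruteforce <- function(coords, w) {
  w <- w / sum(w)
  centroid <- numeric(ncol(coords))
  for (j in seq_len(nrow(coords))) centroid <- centroid + w[j] * coords[j, ]
  total <- 0
  for (j in seq_len(nrow(coords))) {
    total <- total + w[j] * sqrt(sum((coords[j, ] - centroid)^2))
  }
  total
}
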