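square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

test_that("Voronoi cells partition the boundary and contain their seeds", {
  seeds <- rbind(c(0.25, 0.25), c(0.75, 0.25), c(0.25, 0.75), c(0.75, 0.75))
  vp <- build_voronoi_polygons(seeds, square)
  areas <- vapply(vp$vertices, function(v) abs(trawlshift:::polygon_area(v)),
                  numeric(1))
  expect_equal(areas, rep(0.25, 4), tolerance = 1e-9)  # congruent by symmetry
  expect_equal(sum(areas), 1, tolerance = 1e-6)
  for (i in 1:4) {
    expect_true(raycast_inside(seeds[i, ], vp$vertices[[i]]))
  }
  expect_error(build_voronoi_polygons(rbind(seeds, seeds[1, ]), square),
               "duplicate")
  # random seeds: partition property still holds
  set.seed(2)
  seeds2 <- cbind(runif(12), runif(12))
  vp2 <- build_voronoi_polygons(seeds2, square)
  areas2 <- vapply(vp2$vertices, function(v) abs(trawlshift:::polygon_area(v)),
                   numeric(1))
  expect_equal(sum(areas2), 1, tolerance = 1e-6)
  for (i in 1:12) expect_true(raycast_inside(seeds2[i, ], vp2$vertices[[i]]))
})

test_that("polygon GeoJSON round-trips ids, rings and depths", {
  seeds <- rbind(c(0.2, 0.3), c(0.7, 0.6), c(0.4, 0.9))
  vp <- build_voronoi_polygons(seeds, square, mean_depth = c(120, 340, 90))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_polygons_geojson(vp, f)
  back <- read_polygons_geojson(f)
  expect_identical(back$id, vp$id)
  expect_equal(back$mean_depth, vp$mean_depth)
  for (i in 1:3) expect_equal(back$vertices[[i]], vp$vertices[[i]],
                              ignore_attr = TRUE)
})

test_that("trawl assignment matches a brute-force containment scan", {
  set.seed(33)
  seeds <- cbind(runif(8), runif(8))
  vp <- build_voronoi_polygons(seeds, square, mean_depth = runif(8, 50, 300))
  pts <- cbind(runif(60), runif(60))
  df <- data.frame(trawl_id = sprintf("t%02d", 1:60), year = 1990L,
                   lat = pts[, 2], lon = pts[, 1], depth_m = 100,
                   species = "cod", biomass_kg = 1, stringsAsFactors = FALSE)
  a <- assign_trawls(trawl_table(df), vp)
  brute <- vapply(seq_len(60), function(i) {
    hit <- which(vapply(vp$vertices, function(v)
      raycast_inside(pts[i, ], v), logical(1)))
    if (length(hit) == 0) NA_character_ else vp$id[min(hit)]
  }, character(1))
  expect_identical(a$polygon_id, brute)
  # a trawl at a seed lands in that seed's cell; one outside is dropped
  df2 <- df[1:2, ]
  df2$lon <- c(seeds[3, 1], 5); df2$lat <- c(seeds[3, 2], 5)
  expect_warning(a2 <- assign_trawls(trawl_table(df2), vp), "outside")
  expect_identical(a2$polygon_id, c(vp$id[3], NA_character_))
  expect_error(assign_trawls(trawl_table(df2), vp, unmatched = "error"),
               "outside")
})

test_that("complete-linkage clustering reproduces an O(n^3) brute-force tree", {
  set.seed(55)
  for (i in 1:50) {
    m <- matrix(rlnorm(10 * 4), 10, 4)
    d <- bray_curtis(normalize_rows(m))
    hc <- hclust(d, method = "complete")
    oracle <- complete_linkage_oracle(d)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    got <- hclust_partitions(hc)
    for (s in seq_along(got)) {
      expect_identical(got[[s]], oracle$partitions[[s]])
    }
  }
})

test_that("linkage heights are monotone and cluster output ignores row order", {
  set.seed(66)
  m <- matrix(rlnorm(12 * 5), 12, 5,
              dimnames = list(sprintf("u%02d", 1:12), letters[1:5]))
  cl <- cluster_polygon_periods(m, K = 3)
  expect_true(all(diff(cl$tree$height) >= -1e-12))
  expect_equal(sort(unique(cl$assignment$cluster)), 1:3)
  perm <- sample(12)
  cl2 <- cluster_polygon_periods(m[perm, ], K = 3)
  a1 <- setNames(cl$assignment$cluster, cl$assignment$unit)
  a2 <- setNames(cl2$assignment$cluster, cl2$assignment$unit)
  expect_identical(a1[sort(names(a1))], a2[sort(names(a2))])
  # two tight blobs separate perfectly; K = n gives singletons
  blobs <- rbind(matrix(rep(c(10, 0, 0), each = 4), 4) + runif(12, 0, 0.01),
                 matrix(rep(c(0, 10, 0), each = 4), 4) + runif(12, 0, 0.01))
  rownames(blobs) <- sprintf("b%d", 1:8)
  cb <- cluster_polygon_periods(blobs, K = 2)
  expect_equal(length(unique(cb$assignment$cluster[1:4])), 1L)
  expect_equal(length(unique(cb$assignment$cluster[5:8])), 1L)
  expect_equal(sort(unique(cluster_polygon_periods(blobs, 8)$assignment$cluster)),
               1:8)
  expect_error(cluster_polygon_periods(blobs, 9), "exceeds")
})

test_that("cluster profiles average member compositions and close to 1", {
  m <- rbind(u1 = c(0.8, 0.1, 0.1), u2 = c(0.6, 0.3, 0.1),
             u3 = c(0.05, 0.05, 0.9))
  colnames(m) <- c("cod", "halibut", "plaice")
  attr(m, "normalized") <- TRUE
  cl <- cluster_polygon_periods(m, K = 2)
  prof <- cluster_profiles(cl, m, focal_species = c("cod", "halibut"))
  pair <- prof[prof$n_units == 2, ]
  expect_equal(pair$cod, 0.7)
  expect_equal(pair$halibut, 0.2)
  expect_equal(pair$cod + pair$halibut + pair$other, 1, tolerance = 1e-12)
  single <- prof[prof$n_units == 1, ]
  expect_equal(single$cod, 0.05)
})

test_that("polygon consistency filter keeps well-sampled cells", {
  seeds <- rbind(c(0.2, 0.2), c(0.8, 0.2), c(0.5, 0.8))
  vp <- build_voronoi_polygons(seeds, square, mean_depth = c(100, 200, 300))
  vp$years_present <- list(`1` = 1981:2013, `2` = 1981:1990,
                           `3` = c(1981:2005, 2007:2013))
  kept <- retain_consistent_polygons(vp, min_years = 30)
  expect_setequal(kept$id, c("1", "3"))
  expect_equal(retain_consistent_polygons(vp, min_years = 5)$id, vp$id)
})

test_that("great-circle distance honours spherical limits and metric axioms", {
  expect_equal(great_circle_km(c(-52, 47), c(-52, 47)), 0)
  expect_equal(great_circle_km(c(0, 0), c(180, 0)), pi * 6371.0088,
               tolerance = 1e-6)
  set.seed(3)
  for (i in 1:20) {
    p <- matrix(c(runif(3, -180, 180), runif(3, -89, 89)), 3, 2)
    d12 <- great_circle_km(p[1, ], p[2, ])
    d13 <- great_circle_km(p[1, ], p[3, ])
    d23 <- great_circle_km(p[2, ], p[3, ])
    expect_equal(d12, great_circle_km(p[2, ], p[1, ]), tolerance = 1e-9)
    expect_lte(d12, d13 + d23 + 1e-6)
  }
})

test_that("variance partitioning isolates a constructed depth-only signal", {
  set.seed(44)
  n_poly <- 20
  seeds <- cbind(runif(n_poly), runif(n_poly))
  depth <- runif(n_poly, 50, 500)  # independent of position
  vp <- build_voronoi_polygons(seeds, square, mean_depth = depth)
  # two species trading off smoothly along depth: Bray-Curtis between
  # polygons is an exact monotone function of |depth difference|
  p1 <- (depth - min(depth)) / diff(range(depth)) * 0.8 + 0.1
  m <- cbind(sp1 = p1, sp2 = 1 - p1)
  rownames(m) <- paste0(vp$id, ":1990")
  attr(m, "normalized") <- TRUE
  res <- variance_partition_by_year(m, vp, 1990, eps_depth = 1e-6)
  expect_gt(res$r2_depth, 0.95)
  expect_lt(res$r2_distance, 0.05)
  expect_equal(res$n_pairs, n_poly * (n_poly - 1) / 2)
})

test_that("variance partitioning is centred on zero under a permuted null", {
  set.seed(91)
  n_poly <- 20
  seeds <- cbind(runif(n_poly), runif(n_poly))
  vp <- build_voronoi_polygons(seeds, square,
                               mean_depth = runif(n_poly, 50, 500))
  vals <- replicate(100, {
    m <- matrix(rlnorm(n_poly * 6), n_poly)
    m <- m / rowSums(m)
    rownames(m) <- paste0(vp$id, ":1990")[sample(n_poly)]  # break any link
    attr(m, "normalized") <- TRUE
    r <- variance_partition_by_year(m, vp, 1990)
    r$r2_full
  })
  expect_lt(mean(abs(vals)), 0.02)
})

test_that("variance-partition components follow their adjusted-R2 definition", {
  set.seed(17)
  n_poly <- 12
  seeds <- cbind(runif(n_poly), runif(n_poly))
  depth <- runif(n_poly, 50, 500)
  vp <- build_voronoi_polygons(seeds, square, mean_depth = depth)
  m <- matrix(rlnorm(n_poly * 5), n_poly)
  m <- m / rowSums(m)
  rownames(m) <- paste0(vp$id, ":1985")
  attr(m, "normalized") <- TRUE
  res <- variance_partition_by_year(m, vp, 1985)
  # recompute the partials from scratch with the same transforms
  bc <- as.matrix(vegan::vegdist(m, method = "bray"))
  y <- bc[lower.tri(bc)]
  y <- pmin(pmax(y, 1e-4), 1 - 1e-4); y <- log(y / (1 - y))
  pr <- which(lower.tri(bc), arr.ind = TRUE)
  dd <- log(abs(depth[pr[, 1]] - depth[pr[, 2]]) + 1e-3)
  gd <- log(great_circle_km(vp$centroid[pr[, 1], ], vp$centroid[pr[, 2], ]) +
              1e-3)
  adj <- function(fit) summary(fit)$adj.r.squared
  full <- adj(lm(y ~ dd + gd))
  expect_equal(res$r2_full, full, tolerance = 1e-10)
  expect_equal(res$r2_depth, full - adj(lm(y ~ gd)), tolerance = 1e-10)
  expect_equal(res$r2_distance, full - adj(lm(y ~ dd)), tolerance = 1e-10)
  # unadjusted R2 is monotone under predictor addition
  r2 <- function(fit) summary(fit)$r.squared
  expect_gte(r2(lm(y ~ dd + gd)), r2(lm(y ~ dd)) - 1e-12)
  expect_gte(r2(lm(y ~ dd + gd)), r2(lm(y ~ gd)) - 1e-12)
})

test_that("diversity diagnostics match hand-computed alpha and dissimilarity moments", {
  df <- toy_trawl_df()
  tab <- trawl_table(df)
  m <- rbind(`p1:1981` = c(0.8, 0.2), `p2:1981` = c(0.5, 0.5),
             `p3:1981` = c(0.1, 0.9))
  colnames(m) <- c("cod", "plaice")
  attr(m, "normalized") <- TRUE
  dd <- diversity_diagnostics(m, tab)
  # trawls in 1981: t1 catches 2 species, t2 catches 1 -> alpha 1.5
  expect_equal(dd$alpha[dd$year == 1981], 1.5)
  bc <- as.numeric(vegan::vegdist(m, method = "bray"))
  expect_equal(dd$mean_dissimilarity[dd$year == 1981], mean(bc))
  expect_equal(dd$var_dissimilarity[dd$year == 1981], var(bc))
  # identical compositions -> zero mean and variance
  m2 <- rbind(`p1:1982` = c(0.5, 0.5), `p2:1982` = c(0.5, 0.5),
              `p3:1982` = c(0.5, 0.5))
  colnames(m2) <- c("cod", "plaice")
  attr(m2, "normalized") <- TRUE
  dd2 <- diversity_diagnostics(m2, tab)
  expect_equal(dd2$mean_dissimilarity[dd2$year == 1982], 0)
  expect_equal(dd2$var_dissimilarity[dd2$year == 1982], 0)
})
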