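test_that("Gower dissimilarity matches hand-computed mixed-trait values", {
  tr <- species_traits(toy_traits_df())
  d <- as.matrix(gower_dissimilarity(tr))
  # ranges: length 40, doubling 6, trophic 1; six traits averaged
  ab <- (1 + 20 / 40 + 2 / 6 + 0.5 / 1 + 1 + 1) / 6
  ac <- (0 + 40 / 40 + 6 / 6 + 1 / 1 + 0 + 0) / 6
  bc <- (1 + 20 / 40 + 4 / 6 + 0.5 / 1 + 1 + 1) / 6
  expect_equal(d["a", "b"], ab, tolerance = 1e-12)
  expect_equal(d["a", "c"], ac, tolerance = 1e-12)
  expect_equal(d["b", "c"], bc, tolerance = 1e-12)
  # identical rows -> 0; all traits maximally different -> 1
  tr2 <- toy_traits_df(c("a", "b"))
  tr2[2, ] <- tr2[1, ]; tr2$species[2] <- "b"
  expect_equal(as.numeric(gower_dissimilarity(species_traits(tr2))), 0)
  expect_equal(d["a", "c"], ac)
  expect_warning(
    gower_dissimilarity(species_traits(transform(toy_traits_df(),
                                                 trophic_level = 3))),
    "zero range")
})

test_that("Gower agrees with the cluster::daisy reference", {
  skip_if_not_installed("cluster")
  set.seed(14)
  df <- data.frame(
    species = sprintf("s%d", 1:7),
    vertical_position = sample(c("benthic", "demersal", "pelagic"), 7, TRUE),
    body_length_cm = rlnorm(7, 3, 0.5),
    doubling_time = rlnorm(7, 1.5, 0.4),
    trophic_level = runif(7, 2.5, 4.5),
    aggregation = sample(c("schooling", "solitary"), 7, TRUE),
    food_niche = sample(c("piscivore", "benthivore", "mixed"), 7, TRUE),
    stringsAsFactors = FALSE)
  ours <- gower_dissimilarity(species_traits(df))
  dd <- df[-1]
  for (col in c("vertical_position", "aggregation", "food_niche")) {
    dd[[col]] <- factor(dd[[col]])
  }
  ref <- cluster::daisy(dd, metric = "gower")
  expect_equal(as.numeric(ours), as.numeric(ref), tolerance = 1e-10)
})

test_that("PCoA embeddings reproduce their (corrected) input distances", {
  # points on a line: one dominant axis, distances recovered exactly
  x <- c(0, 1, 3, 7)
  sp <- pcoa_embed(as.matrix(dist(x)))
  expect_equal(sp$correction, "none")
  expect_equal(as.matrix(dist(sp$coordinates)), as.matrix(dist(x)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(sp$eigenvalues > 1e-8), 1L)
  # random mixed-trait Gower matrices: embedded distances match the
  # (possibly Cailliez-corrected) distances within 1e-8
  set.seed(6)
  for (i in 1:5) {
    df <- data.frame(
      species = sprintf("s%d", 1:6),
      vertical_position = sample(c("x", "y", "z"), 6, TRUE),
      body_length_cm = rlnorm(6, 3, 0.4),
      doubling_time = rlnorm(6, 1, 0.4),
      trophic_level = runif(6, 2, 5),
      aggregation = sample(c("p", "q"), 6, TRUE),
      food_niche = sample(c("u", "v", "w"), 6, TRUE),
      stringsAsFactors = FALSE)
    g <- gower_dissimilarity(species_traits(df))
    sp <- pcoa_embed(g)
    expect_equal(as.matrix(dist(sp$coordinates)), as.matrix(sp$distances),
                 tolerance = 1e-8, ignore_attr = TRUE)
    if (sp$correction == "cailliez") {
      off <- as.matrix(g) + sp$cailliez_constant
      diag(off) <- 0
      expect_equal(as.matrix(sp$distances), off, tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("Cailliez constant agrees with the ape reference implementation", {
  skip_if_not_installed("ape")
  # the classic non-Euclidean 4-point configuration: two long diagonals
  dm <- matrix(1, 4, 4) - diag(4)
  dm[1, 2] <- dm[2, 1] <- 2
  dm[3, 4] <- dm[4, 3] <- 2
  d <- as.dist(dm)
  ev0 <- trawlshift:::pcoa_eigen(dm)$values
  expect_lt(min(ev0), -1e-8)  # fixture really is non-Euclidean
  ours <- pcoa_embed(d, correction = "cailliez")
  ref <- ape::pcoa(d, correction = "cailliez")
  # both corrections embed to the same corrected distance matrix
  expect_equal(as.matrix(dist(ref$vectors.cor)), as.matrix(ours$distances),
               tolerance = 1e-6, ignore_attr = TRUE)
  # and the corrected distances are Euclidean (no remaining negative mass)
  ev <- trawlshift:::pcoa_eigen(as.matrix(ours$distances))$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("FDis matches closed forms and a brute-force oracle", {
  two <- structure(list(coordinates = matrix(c(0, 1), 2, 1,
                                             dimnames = list(c("a", "b"),
                                                             NULL))),
                   class = "trait_space")
  expect_equal(fdis(two, c(a = 1, b = 1)), 0.5)
  expect_equal(fdis(two, c(a = 0.75, b = 0.25)), 0.375)
  expect_equal(fdis(two, c(a = 1, b = 0)), 0)
  set.seed(12)
  for (i in 1:20) {
    coords <- matrix(rnorm(8 * 3), 8, 3)
    w <- runif(8)
    expect_equal(fdis(coords, w), fdis_bruteforce(coords, w),
                 tolerance = 1e-10)
  }
})

test_that("FDis invariances: weight scale, rotation, zero-weight species", {
  set.seed(15)
  coords <- matrix(rnorm(12), 6, 2)
  w <- runif(6)
  base <- fdis(coords, w)
  expect_equal(fdis(coords, 17 * w), base, tolerance = 1e-12)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(fdis(coords %*% rot, w), base, tolerance = 1e-12)
  expect_equal(fdis(rbind(coords, c(99, 99)), c(w, 0)), base,
               tolerance = 1e-12)
  expect_error(fdis(coords, rep(0, 6)), "positive sum")
})

test_that("annual FDis responds to dominance shifts toward trait-central species", {
  tr <- toy_traits_df()
  tr$body_length_cm <- c(10, 30, 50)  # b central on every numeric trait
  tr$vertical_position <- c("benthic", "demersal", "pelagic")
  m <- rbind(`1981` = c(1, 1, 1), `1982` = c(0.05, 2.5, 0.05),
             `1983` = c(1, 1, 1))
  colnames(m) <- tr$species
  fd <- annual_fdis(m, species_traits(tr))
  expect_equal(fd$years, 1981:1983)
  expect_lt(fd$values[2], fd$values[1])  # dominance at the centroid
  expect_equal(fd$values[1], fd$values[3], tolerance = 1e-12)
  # one species holding all weight -> 0
  m1 <- rbind(`1981` = c(0, 5, 0))
  colnames(m1) <- tr$species
  expect_equal(annual_fdis(m1, species_traits(tr))$values, 0,
               tolerance = 1e-12)
})

test_that("community-weighted trait means and categorical shares are exact", {
  tr <- species_traits(toy_traits_df())
  m <- rbind(`1981` = c(1, 1, 0), `1982` = c(2, 0, 0))
  colnames(m) <- tr$species
  cwm <- community_weighted_trait_means(m, tr)
  bl <- cwm[cwm$trait == "body_length_cm", ]
  expect_equal(bl$value[bl$year == 1981], 20)  # equal weights on 10, 30
  expect_equal(bl$value[bl$year == 1982], 10)  # single species
  shares <- cwm[!is.na(cwm$level), ]
  sums <- tapply(shares$value, list(shares$year, shares$trait), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  agg81 <- shares[shares$trait == "aggregation" & shares$year == 1981, ]
  expect_equal(agg81$value[agg81$level == "schooling"], 0.5)
})
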