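test_that("trawl CSV round-trips at full precision", {
  df <- toy_trawl_df()
  df$biomass_kg <- df$biomass_kg + pi * 1e-7  # exercise full-precision writing
  tab <- trawl_table(df)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trawl_table(tab, f)
  back <- read_trawl_table(f)
  expect_identical(back$biomass_kg, tab$biomass_kg)
  expect_identical(back$depth_m, tab$depth_m)
  expect_identical(back$trawl_id, tab$trawl_id)
  expect_identical(attr(back, "species_list"), attr(tab, "species_list"))
  expect_identical(back$gear_era, rep("pre1995", nrow(df)))
})

test_that("trawl table schema and row validation errors are specific", {
  df <- toy_trawl_df()
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[setdiff(names(df), "depth_m")], f, row.names = FALSE)
  expect_error(read_trawl_table(f), "depth_m")
  df_bad <- df; df_bad$biomass_kg[2] <- -1
  expect_error(trawl_table(df_bad), "negative biomass.*2")
  df_bad <- df; df_bad$depth_m[3] <- 0
  expect_error(trawl_table(df_bad), "depth.*3")
  expect_error(trawl_table(transform(df, year = "eighty")), "unparseable")
})

test_that("species screening applies the strict 7x rule and the rare-capture rule", {
  # one trawl per year, 1990..2000; species biomasses chosen so era-pooled
  # zero-inflated means are exact
  years <- 1990:2000
  mk <- function(sp, pre, post) {
    data.frame(trawl_id = paste0("t", years), year = years, lat = 47,
               lon = -52, depth_m = 100, species = sp,
               biomass_kg = c(rep(pre, 5), rep(post, 6)),
               stringsAsFactors = FALSE)
  }
  df <- rbind(mk("ratio8", 1, 8), mk("ratio7", 1, 7), mk("stable", 2, 2))
  # never caught before the gear change
  post_only <- data.frame(trawl_id = paste0("t", 1995:2000), year = 1995:2000,
                          lat = 47, lon = -52, depth_m = 100,
                          species = "newcomer", biomass_kg = 5,
                          stringsAsFactors = FALSE)
  tab <- trawl_table(rbind(df, post_only))
  scr <- screen_gear_sensitive_species(tab, threshold = 7,
                                       post_window = c(1995L, 2000L))
  expect_setequal(scr$excluded, c("ratio8", "newcomer"))
  expect_setequal(attr(scr$table, "species_list"), c("ratio7", "stable"))
  expect_equal(unname(scr$ratios["ratio8"]), 8)
  expect_equal(unname(scr$ratios["ratio7"]), 7)
  # idempotent: screening the screened table changes nothing
  scr2 <- screen_gear_sensitive_species(scr$table, threshold = 7,
                                        post_window = c(1995L, 2000L))
  expect_identical(attr(scr2$table, "species_list"),
                   attr(scr$table, "species_list"))
  expect_length(scr2$excluded, 0)
  expect_error(screen_gear_sensitive_species(tab[0, ]), "empty|span")
})

test_that("community matrix cells equal per-group hand evaluation with implicit zeros", {
  tab <- trawl_table(toy_trawl_df())
  m <- build_community_matrix(tab, "year")
  # 1981: trawls t1 (cod 4, plaice 1), t2 (cod 9): cod n=2 m=2 -> 6; plaice
  # n=2 m=1 -> 0.5 * 1
  expect_equal(m["1981", "cod"], sqrt(36))
  expect_equal(m["1981", "plaice"], 0.5 * 1)
  # 1982: t3 (cod 1, plaice 2), t4 (plaice 8): cod (1/2)*1, plaice sqrt(16)
  expect_equal(m["1982", "cod"], 0.5)
  expect_equal(m["1982", "plaice"], 4)
  expect_identical(attr(m, "years"), c(1981L, 1982L))
  # species absent from a group -> 0 cell
  df <- toy_trawl_df()
  df$species[df$trawl_id %in% c("t3", "t4")] <- "cod"
  m2 <- build_community_matrix(trawl_table(df), "year")
  expect_equal(m2["1982", "plaice"], 0)
})

test_that("community matrix is invariant to record order and agrees with brute force", {
  set.seed(9)
  s <- simulate_survey(small_scenario(seed = 3, n_species = 6,
                                      n_polygons = 12))
  tab <- s$table
  m1 <- build_community_matrix(tab, "year")
  shuffled <- as.data.frame(tab)[sample(nrow(tab)), ]
  m2 <- build_community_matrix(trawl_table(shuffled[
    trawlshift:::TRAWL_COLUMNS]), "year")
  expect_equal(m1, m2, ignore_attr = TRUE)
  # brute-force re-aggregation for a handful of cells
  df <- as.data.frame(tab)
  n_trawls <- tapply(df$trawl_id, df$year, function(x) length(unique(x)))
  for (yr in c("1981", "1990")) {
    for (sp in colnames(m1)[1:3]) {
      b <- df$biomass_kg[df$year == as.integer(yr) & df$species == sp]
      b <- b[b > 0]
      expected <- if (length(b) == 0) 0 else
        (length(b) / n_trawls[[yr]]) * exp(mean(log(b)))
      expect_equal(m1[yr, sp], expected, tolerance = 1e-12)
    }
  }
})

test_that("row normalization divides positive rows and flags zero rows", {
  m <- matrix(c(2, 2, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("a", "b")))
  nm <- normalize_rows(m)
  expect_equal(nm["r1", ], c(a = 0.5, b = 0.5))
  expect_equal(nm["r2", ], c(a = 0, b = 0))
  expect_identical(attr(nm, "zero_rows"), "r2")
  set.seed(2)
  r <- matrix(rlnorm(50), 5)
  expect_equal(rowSums(normalize_rows(r)), rep(1, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("analysis config validates counts and period ordering; JSON round-trips", {
  expect_error(analysis_config(window_length = 0), "counts")
  expect_error(analysis_config(period_breaks = list(c(1981L, 1990L),
                                                    c(1988L, 1995L))),
               "disjoint")
  cfg <- analysis_config(rng_seed = 42L)
  f <- withr::local_tempfile(fileext = ".json")
  write_analysis_config(cfg, f)
  expect_equal(read_analysis_config(f), cfg)
})
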