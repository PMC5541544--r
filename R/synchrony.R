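#' Loreau-de Mazancourt community synchrony
#'
#' The variance-ratio synchrony statistic
#' \deqn{\varphi = \mathrm{var}(\sum_s x_s) \, / \, (\sum_s \mathrm{sd}(x_s))^2}
#' computed with the population (divide-by-N) variance convention. It equals 1
#' when all species fluctuate in perfect proportion (including the
#' single-species case) and 0 when fluctuations cancel exactly so the
#' community total is constant. Species with zero variance contribute nothing
#' to the denominator; when *all* species are constant the statistic is
#' undefined and `NA` is returned with attribute `degenerate = TRUE`.
#'
#' @param series numeric matrix, years x species, no missing cells.
#' @return \eqn{\varphi \in [0, 1]} (or flagged `NA`).
#' @export
community_synchrony <- function(series) {
  stopifnot(is.matrix(series))
  if (anyNA(series)) stop("missing cells in abundance matrix")
  if (nrow(series) < 2L) stop("need at least 2 years")
  if (ncol(series) < 1L) stop("need at least 1 species")
  n <- nrow(series)
  pvar <- function(x) sum((x - mean(x))^2) / n
  denom <- sum(apply(series, 2L, function(x) sqrt(pvar(x))))^2
  if (denom == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  pvar(rowSums(series)) / denom
}

#' Moving-window community synchrony with a randomization null
#'
#' Computes the synchrony statistic in a running window of `window` years
#' ending in each feasible year, with significance from a one-sided
#' Monte-Carlo randomization test: each species' values are independently
#' permuted within the window, `R` replicates, and
#' \eqn{p = (1 + \#\{\varphi_{null} \ge \varphi_{obs}\})/(R + 1)} (never 0).
#' Each window is classified as `increasing` or `declining` by the sign of the
#' least-squares slope of the community-total series within the window, and
#' flagged when it straddles the 1994/1995 gear change.
#'
#' @param annual numeric matrix of annual abundance estimates, years x
#'   species, with years as `attr(annual, "years")` or rownames.
#' @param window window length in years (default 5).
#' @param R randomization replicates (default 999).
#' @param seed integer seed for the permutation null.
#' @return data frame of class `"synchrony_result"`: one row per window with
#'   `window_end_year`, `phi`, `p_value`, `direction`, `n_species`,
#'   `straddles_gear_change`.
#' @export
moving_window_synchrony <- function(annual, window = 5L, R = 999L, seed = 1L) {
  stopifnot(is.matrix(annual))
  years <- attr(annual, "years")
  if (is.null(years)) years <- as.integer(rownames(annual))
  if (anyNA(years)) stop("annual matrix must carry years")
  n_years <- nrow(annual)
  if (window > n_years) {
    warning("window longer than series; no feasible windows")
    return(empty_synchrony_result())
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  ends <- seq.int(window, n_years)
  res <- lapply(ends, function(e) {
    idx <- (e - window + 1L):e
    w <- annual[idx, , drop = FALSE]
    phi <- community_synchrony(w)
    if (is.na(phi)) {
      p <- NA_real_
    } else {
      exceed <- 0L
      for (r in seq_len(R)) {
        perm <- apply(w, 2L, sample)
        phi_r <- community_synchrony(perm)
        if (!is.na(phi_r) && phi_r >= phi) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (R + 1)
    }
    tot <- rowSums(w)
    slope <- coef(lm(tot ~ seq_along(tot)))[2L]
    data.frame(window_end_year = years[e],
               phi = as.numeric(phi),
               p_value = p,
               direction = if (slope > 0) "increasing" else "declining",
               n_species = ncol(w),
               straddles_gear_change =
                 years[idx[1L]] <= 1994L && years[e] >= 1995L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("synchrony_result", "data.frame")
  out
}

empty_synchrony_result <- function() {
  out <- data.frame(window_end_year = integer(0), phi = numeric(0),
                    p_value = numeric(0), direction = character(0),
                    n_species = integer(0),
                    straddles_gear_change = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("synchrony_result", "data.frame")
  out
}
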