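#' Bray-Curtis dissimilarity between community-matrix rows
#'
#' \eqn{BC(x, y) = \sum_s |x_s - y_s| / \sum_s (x_s + y_s)}. Computed with
#' \code{vegan::vegdist}. All-zero rows are excluded with a warning (the
#' dissimilarity is undefined for them).
#'
#' @param m non-negative matrix, rows = communities.
#' @return A `dist` object of class `"dissimilarity_matrix"` in `[0, 1]`.
#' @export
bray_curtis <- function(m) {
  stopifnot(is.matrix(m))
  if (any(m < 0)) stop("negative abundances")
  zero <- rowSums(m) <= 0
  if (any(zero)) {
    warning(sprintf("excluding %d all-zero row(s)", sum(zero)))
    m <- m[!zero, , drop = FALSE]
  }
  d <- vegan::vegdist(m, method = "bray")
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

#' Quantitative Sorensen similarity
#'
#' The complement of the Bray-Curtis dissimilarity between two abundance
#' vectors: 1 for identical compositions, 0 for disjoint supports.
#'
#' @param x,y non-negative abundance vectors of equal length, each with at
#'   least one positive entry.
#' @return similarity in `[0, 1]`.
#' @export
sorensen_similarity <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) <= 0 || sum(y) <= 0) stop("all-zero composition")
  1 - sum(abs(x - y)) / sum(x + y)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimizing Kruskal's
#' stress-1 over monotone transformations of the dissimilarities. Each start
#' alternates isotonic regression of configuration distances on the
#' dissimilarity order (weak/primary tie rule) with a Guttman majorization
#' step; a step that would increase stress is replaced by backtracking toward
#' the previous configuration, so the per-iteration stress sequence is
#' non-increasing. The best of `n_starts` random initializations plus one
#' classical-scaling (metric) initialization is returned, centred and rotated
#' to its principal axes.
#'
#' @param d symmetric dissimilarity matrix or `dist`.
#' @param k embedding dimensions (default 2).
#' @param n_starts random restarts (default 20).
#' @param seed integer seed.
#' @param max_iter iteration cap per start (default 300).
#' @param tol relative stress-change convergence tolerance (default 1e-7).
#' @return list of class `"nmds_result"`: `coordinates` (n x k, centred,
#'   principal axes), `stress` (Kruskal stress-1), `converged`, `n_starts`,
#'   `seed`, `stress_trace` (per-iteration stress of the best start).
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, seed = 1L, max_iter = 300L,
                 tol = 1e-7) {
  dm <- as.matrix(d)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12))) {
    stop("dissimilarity matrix must be symmetric")
  }
  n <- nrow(dm)
  if (n < k + 2L) stop("need at least k + 2 points")
  delta <- dm[lower.tri(dm)]
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  inits <- c(list(metric_init(dm, k)),
             replicate(n_starts, matrix(rnorm(n * k), n, k), simplify = FALSE))
  for (X0 in inits) {
    run <- nmds_single(X0, delta, n, k, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  X <- scale(best$X, center = TRUE, scale = FALSE)
  X <- X %*% svd(X)$v  # principal-axis rotation
  dimnames(X) <- list(rownames(dm), paste0("NMDS", seq_len(k)))
  structure(list(coordinates = X, stress = best$stress,
                 converged = best$converged, n_starts = n_starts + 1L,
                 seed = seed, stress_trace = best$trace),
            class = "nmds_result")
}

metric_init <- function(dm, k) {
  X <- suppressWarnings(cmdscale(dm, k = k))
  if (ncol(X) < k) X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
  X
}

kruskal_stress <- function(dvec, dhat) {
  sqrt(sum((dvec - dhat)^2) / sum(dvec^2))
}

# one NMDS start: alternate isotonic fit and Guttman transform with
# backtracking so reported stress never increases
nmds_single <- function(X, delta, n, k, max_iter, tol) {
  lt <- lower.tri(matrix(0, n, n))
  conf_dist <- function(X) as.matrix(dist(X))[lt]
  dvec <- conf_dist(X)
  dhat <- isoreg_fit(dvec, delta)
  stress <- kruskal_stress(dvec, dhat)
  trace <- stress
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Xn <- guttman_step(X, dhat, n, k, lt)
    dvec_n <- conf_dist(Xn)
    dhat_n <- isoreg_fit(dvec_n, delta)
    stress_n <- kruskal_stress(dvec_n, dhat_n)
    halvings <- 0L
    while (stress_n > stress && halvings < 8L) {
      Xn <- (Xn + X) / 2
      dvec_n <- conf_dist(Xn)
      dhat_n <- isoreg_fit(dvec_n, delta)
      stress_n <- kruskal_stress(dvec_n, dhat_n)
      halvings <- halvings + 1L
    }
    if (stress_n > stress) { converged <- TRUE; break }
    improved <- (stress - stress_n) > tol * max(stress, .Machine$double.eps)
    X <- Xn; dvec <- dvec_n; dhat <- dhat_n; stress <- stress_n
    trace <- c(trace, stress)
    if (!improved) { converged <- TRUE; break }
  }
  list(X = X, stress = stress, trace = trace, converged = converged)
}

# isotonic (weakly increasing) fit of configuration distances against the
# dissimilarity order; ties in the dissimilarities follow the primary rule
# (within a tie block, distances are taken in their current ascending order)
isoreg_fit <- function(dvec, delta) {
  ord <- order(delta, dvec)
  fit <- isoreg(dvec[ord])$yf
  out <- numeric(length(dvec))
  out[ord] <- fit
  pmax(out, 0)
}

guttman_step <- function(X, dhat, n, k, lt) {
  D <- matrix(0, n, n)
  D[lt] <- dhat
  D <- D + t(D)
  cd <- as.matrix(dist(X))
  ratio <- ifelse(cd > 0, D / cd, 0)
  B <- -ratio
  diag(B) <- rowSums(ratio)
  (B %*% X) / n
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress-1 = %.5f (%s, %d starts)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "iteration cap", x$n_starts))
  invisible(x)
}

#' Rescale an annual series to 0-100 relative change
#'
#' Anchors a series at 0 for its observed minimum (maximum departure from the
#' reference state) and 100 for the reference-year value:
#' \deqn{s_t = 100\,(x_t - \min x) / (x_{ref} - \min x).}
#' Invariant to positive affine transformations of the input.
#'
#' @param x numeric series with names (or `years` given) identifying years.
#' @param reference_year year whose value maps to 100.
#' @param years optional integer vector of years (defaults to `names(x)`).
#' @return named numeric series on the 0-100 scale.
#' @export
relative_change_series <- function(x, reference_year, years = NULL) {
  if (is.null(years)) years <- as.integer(names(x))
  if (length(years) != length(x) || anyNA(years)) {
    stop("series must carry years (names or 'years')")
  }
  i <- match(as.integer(reference_year), years)
  if (is.na(i)) stop("reference year not in series")
  lo <- min(x)
  if (x[i] == lo) stop("degenerate scaling: reference value equals the minimum")
  out <- 100 * (x - lo) / (x[i] - lo)
  names(out) <- years
  out
}

#' Compositional similarity trajectory relative to a reference year
#'
#' For each year, the quantitative Sorensen similarity (1 - Bray-Curtis) of
#' that year's relative-biomass composition to the reference year's, then
#' rescaled to the 0-100 relative-change scale (100 = reference composition,
#' 0 = maximum observed departure).
#'
#' @param m year x species community matrix (rows normalized, or normalized
#'   here if not).
#' @param reference_year baseline year.
#' @return list of class `"indicator_series"` with `years`, `values` (scaled),
#'   `similarity` (raw Sorensen values) and `name`.
#' @export
composition_trajectory <- function(m, reference_year) {
  years <- attr(m, "years")
  if (is.null(years)) years <- as.integer(rownames(m))
  if (!isTRUE(attr(m, "normalized"))) m <- normalize_rows(m)
  i <- match(as.integer(reference_year), years)
  if (is.na(i)) stop("reference year not in matrix")
  sim <- apply(m, 1L, function(row) sorensen_similarity(row, m[i, ]))
  scaled <- relative_change_series(sim, reference_year, years = years)
  indicator_series("composition_similarity", years, as.numeric(scaled),
                   extra = list(similarity = as.numeric(sim)))
}

indicator_series <- function(name, years, values, ses = NULL, subset = "all",
                             extra = NULL) {
  stopifnot(length(years) == length(values),
            all(diff(years) > 0))
  out <- c(list(name = name, years = as.integer(years),
                values = as.numeric(values),
                ses = if (is.null(ses)) rep(NA_real_, length(values)) else ses,
                subset = subset), extra)
  class(out) <- "indicator_series"
  out
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("indicator_series '%s' (%s): %d years [%d-%d], range %.4g..%.4g\n",
              x$name, x$subset, length(x$years), min(x$years), max(x$years),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.indicator_series <- function(x, ...) {
  data.frame(name = x$name, subset = x$subset, year = x$years,
             value = x$values, se = x$ses, stringsAsFactors = FALSE)
}
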