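#' Gower dissimilarity on mixed species traits
#'
#' Mixed-type trait distance: for each trait pair-wise distance is
#' `|x - y| / range` for numeric traits and 0/1 mismatch for categorical
#' traits; the overall dissimilarity is the unweighted mean over traits.
#' Numeric ranges are computed once over the full species pool so distances
#' (and downstream dispersion values) are comparable across subsets and
#' years. A numeric trait with zero range carries no information and is
#' dropped with a warning.
#'
#' Numeric traits: body length, doubling time, trophic level. Categorical:
#' vertical position, aggregation, food niche.
#'
#' @param traits a [species_traits()] table (no missing values).
#' @return symmetric `dist` of class `"dissimilarity_matrix"` in `[0, 1]`,
#'   labelled by species.
#' @export
gower_dissimilarity <- function(traits) {
  stopifnot(inherits(traits, "species_traits") || is.data.frame(traits))
  numeric_traits <- c("body_length_cm", "doubling_time", "trophic_level")
  categorical_traits <- c("vertical_position", "aggregation", "food_niche")
  n <- nrow(traits)
  acc <- matrix(0, n, n)
  used <- 0L
  for (tr in numeric_traits) {
    x <- traits[[tr]]
    rng <- diff(range(x))
    if (rng <= 0) {
      warning(sprintf("numeric trait '%s' has zero range; dropped", tr))
      next
    }
    acc <- acc + abs(outer(x, x, "-")) / rng
    used <- used + 1L
  }
  for (tr in categorical_traits) {
    x <- as.character(traits[[tr]])
    acc <- acc + outer(x, x, "!=")
    used <- used + 1L
  }
  if (used == 0L) stop("no informative traits")
  acc <- acc / used
  dimnames(acc) <- list(traits$species, traits$species)
  d <- stats::as.dist(acc)
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

#' Principal-coordinates embedding of a dissimilarity matrix
#'
#' Double-centred eigendecomposition (Gower's PCoA) returning real
#' coordinates whose pairwise Euclidean distances reproduce the (corrected)
#' input distances. When the input is non-Euclidean (negative eigenvalue mass
#' above `threshold` of the total absolute mass), the Cailliez correction is
#' applied: the smallest constant `c` such that adding `c` to all
#' off-diagonal dissimilarities yields a Euclidean configuration.
#'
#' @param d symmetric dissimilarity matrix or `dist` with zero diagonal.
#' @param correction `"auto"` (Cailliez when needed), `"cailliez"`, or
#'   `"none"`.
#' @param threshold relative negative-eigenvalue mass above which `"auto"`
#'   triggers the correction (default 1e-8).
#' @return list of class `"trait_space"`: `coordinates` (species x axes),
#'   `eigenvalues`, `correction` applied, `cailliez_constant`,
#'   `negative_eigenvalue_mass`, and `distances` (the corrected distances the
#'   coordinates reproduce).
#' @export
pcoa_embed <- function(d, correction = c("auto", "cailliez", "none"),
                       threshold = 1e-8) {
  correction <- match.arg(correction)
  dm <- as.matrix(d)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-10)) ||
      any(abs(diag(dm)) > 1e-12)) {
    stop("need a symmetric dissimilarity matrix with zero diagonal")
  }
  n <- nrow(dm)
  eig <- pcoa_eigen(dm)
  neg_mass <- sum(abs(eig$values[eig$values < 0])) / sum(abs(eig$values))
  applied <- "none"
  ccst <- 0
  if (correction == "cailliez" ||
      (correction == "auto" && neg_mass > threshold)) {
    ccst <- cailliez_constant(dm)
    dm_c <- dm + ccst
    diag(dm_c) <- 0
    dm <- dm_c
    eig <- pcoa_eigen(dm)
    applied <- "cailliez"
  }
  keep <- eig$values > max(eig$values) * 1e-10
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), nrow = sum(keep))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = eig$values,
                 correction = applied,
                 cailliez_constant = ccst,
                 negative_eigenvalue_mass = neg_mass,
                 distances = stats::as.dist(dm)),
            class = "trait_space")
}

pcoa_eigen <- function(dm) {
  n <- nrow(dm)
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  eigen((G + t(G)) / 2, symmetric = TRUE)
}

# smallest constant c such that d_ij + c (i != j) is Euclidean: the largest
# real eigenvalue of the 2n x 2n block matrix of Cailliez & Pages
cailliez_constant <- function(dm) {
  n <- nrow(dm)
  A <- -0.5 * dm^2
  B <- -0.5 * dm
  J <- diag(n) - matrix(1 / n, n, n)
  A <- J %*% A %*% J
  B <- J %*% B %*% J
  M <- rbind(cbind(matrix(0, n, n), 2 * A),
             cbind(-diag(n), -4 * B))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf(
    "trait_space: %d species, %d axes, correction = %s (neg. eigenvalue mass %.2g)\n",
    nrow(x$coordinates), ncol(x$coordinates), x$correction,
    x$negative_eigenvalue_mass))
  invisible(x)
}

#' Abundance-weighted functional dispersion (FDis)
#'
#' The abundance-weighted mean distance of species to the abundance-weighted
#' centroid in trait space:
#' \deqn{c = \sum_j a_j x_j / \sum_j a_j, \qquad
#'       FDis = \sum_j a_j \|x_j - c\| / \sum_j a_j.}
#' Zero iff all weight rests on species with identical coordinates; invariant
#' to rescaling the weights and to rigid rotation of the coordinates.
#'
#' @param space a `"trait_space"` from [pcoa_embed()] (or a bare coordinate
#'   matrix).
#' @param weights non-negative per-species weights (relative biomass), summing
#'   to a positive value; names, if present, are matched to species.
#' @return FDis (single non-negative number).
#' @export
fdis <- function(space, weights) {
  coords <- if (inherits(space, "trait_space")) space$coordinates else space
  stopifnot(is.matrix(coords))
  if (!is.null(names(weights)) && !is.null(rownames(coords))) {
    weights <- weights[rownames(coords)]
    if (anyNA(weights)) stop("weights missing for some species")
  }
  if (length(weights) != nrow(coords)) stop("one weight per species required")
  if (any(weights < 0)) stop("negative weights")
  s <- sum(weights)
  if (s <= 0) stop("weights must have a positive sum")
  a <- weights / s
  centroid <- colSums(coords * a)
  dists <- sqrt(rowSums(sweep(coords, 2L, centroid)^2))
  sum(a * dists)
}

#' Annual biomass-weighted functional dispersion series
#'
#' For each year, species biomasses are normalized to relative weights and
#' functional dispersion is evaluated in the shared trait space (Gower
#' dissimilarity over the full species pool, PCoA-embedded once).
#'
#' @param m year x species community matrix of biomass estimates.
#' @param traits a [species_traits()] table covering every matrix species.
#' @param subset optional character vector of species to restrict to (e.g.
#'   the non-commercial community); the trait space is rebuilt on the subset
#'   pool but numeric trait ranges still span the given trait table.
#' @return an `indicator_series` of annual FDis values.
#' @export
annual_fdis <- function(m, traits, subset = NULL) {
  stopifnot(is.matrix(m))
  years <- attr(m, "years")
  if (is.null(years)) years <- as.integer(rownames(m))
  sp <- colnames(m)
  if (!all(sp %in% traits$species)) {
    stop("traits missing for species: ",
         paste(setdiff(sp, traits$species), collapse = ", "))
  }
  # Gower ranges span the full matrix species pool so dispersion values are
  # comparable between the whole-community and subset series
  tr_pool <- traits[match(sp, traits$species), , drop = FALSE]
  gd <- as.matrix(gower_dissimilarity(species_traits(as.data.frame(tr_pool))))
  if (!is.null(subset)) {
    sp <- intersect(sp, subset)
    if (length(sp) < 2L) stop("subset leaves fewer than 2 species")
    m <- m[, sp, drop = FALSE]
    gd <- gd[sp, sp]
  }
  space <- pcoa_embed(stats::as.dist(gd))
  keep <- rowSums(m) > 0
  vals <- vapply(which(keep), function(i) fdis(space, m[i, ]), numeric(1))
  indicator_series("fdis", years[keep], vals,
                   subset = if (is.null(subset)) "all" else "subset")
}

#' Community-weighted trait means and categorical shares
#'
#' Per year: biomass-weighted mean of each numeric trait and the biomass
#' share of each level of each categorical trait (shares sum to 1).
#'
#' @param m year x species community matrix.
#' @param traits a [species_traits()] table covering every matrix species.
#' @return data frame with columns `year`, `trait`, `level` (`NA` for numeric
#'   traits) and `value`.
#' @export
community_weighted_trait_means <- function(m, traits) {
  stopifnot(is.matrix(m))
  years <- attr(m, "years")
  if (is.null(years)) years <- as.integer(rownames(m))
  sp <- colnames(m)
  tr <- traits[match(sp, traits$species), , drop = FALSE]
  if (anyNA(tr$species)) stop("traits missing for some species")
  numeric_traits <- c("body_length_cm", "doubling_time", "trophic_level")
  categorical_traits <- c("vertical_position", "aggregation", "food_niche")
  rows <- list()
  for (i in seq_len(nrow(m))) {
    w <- m[i, ]
    s <- sum(w)
    if (s <= 0) next
    a <- w / s
    for (trn in numeric_traits) {
      rows[[length(rows) + 1L]] <- data.frame(
        year = years[i], trait = trn, level = NA_character_,
        value = sum(a * tr[[trn]]), stringsAsFactors = FALSE)
    }
    for (trn in categorical_traits) {
      lv <- as.character(tr[[trn]])
      for (l in sort(unique(lv))) {
        rows[[length(rows) + 1L]] <- data.frame(
          year = years[i], trait = trn, level = l,
          value = sum(a[lv == l]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
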