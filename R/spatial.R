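#' Polygon set container
#'
#' A planar partition of the survey domain: per cell an identifier, a vertex
#' ring (lon/lat, unclosed), the centroid, the mean observed depth (m) and
#' optionally the set of survey years with at least one trawl in the cell.
#'
#' @param vertices list of numeric matrices (columns lon, lat), one ring per
#'   polygon, at least 3 vertices each.
#' @param id identifiers (default sequential integers).
#' @param mean_depth per-polygon mean depth in metres (`NA` allowed).
#' @param seeds optional generating points (matrix lon/lat) for Voronoi sets.
#' @param years_present optional named list of integer year vectors.
#' @return list of class `"polygon_set"`.
#' @export
polygon_set <- function(vertices, id = seq_along(vertices),
                        mean_depth = rep(NA_real_, length(vertices)),
                        seeds = NULL, years_present = NULL) {
  stopifnot(is.list(vertices), length(id) == length(vertices),
            length(mean_depth) == length(vertices))
  for (v in vertices) {
    if (!is.matrix(v) || nrow(v) < 3L || ncol(v) != 2L) {
      stop("every polygon needs a 2-column vertex matrix with >= 3 vertices")
    }
  }
  if (any(!is.na(mean_depth) & mean_depth <= 0)) {
    stop("mean depth must be positive where defined")
  }
  centroid <- t(vapply(vertices, polygon_centroid, numeric(2)))
  colnames(centroid) <- c("lon", "lat")
  structure(list(id = as.character(id), vertices = vertices,
                 centroid = centroid, mean_depth = mean_depth,
                 seeds = seeds, years_present = years_present),
            class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("polygon_set: %d cells, depth %s\n", length(x$id),
              if (all(is.na(x$mean_depth))) "undefined" else
                sprintf("%.0f-%.0f m", min(x$mean_depth, na.rm = TRUE),
                        max(x$mean_depth, na.rm = TRUE))))
  invisible(x)
}

#' @export
length.polygon_set <- function(x) length(x$id)

# shoelace area (planar lon/lat) and centroid
polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

polygon_centroid <- function(v) {
  a <- polygon_area(v)
  if (abs(a) < 1e-12) return(colMeans(v))
  x <- v[, 1L]; y <- v[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Voronoi tessellation clipped to a boundary polygon
#'
#' Builds the Voronoi cell of each seed by half-plane intersection: the
#' boundary polygon is successively clipped (Sutherland-Hodgman) by the
#' perpendicular-bisector half-plane against every other seed. Cells form a
#' partition of the boundary and each seed lies inside its own cell.
#'
#' @param seeds numeric matrix (columns lon, lat) of distinct generating
#'   points, at least 3, all inside `boundary`.
#' @param boundary convex boundary polygon as a vertex matrix (columns lon,
#'   lat), counter-clockwise.
#' @param mean_depth optional per-seed mean depth (m).
#' @return a [polygon_set()] with the seeds attached.
#' @export
build_voronoi_polygons <- function(seeds, boundary, mean_depth = NULL) {
  stopifnot(is.matrix(seeds), ncol(seeds) == 2L, nrow(seeds) >= 3L)
  if (anyDuplicated(seeds)) stop("duplicate seeds")
  n <- nrow(seeds)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- boundary
    for (j in seq_len(n)) {
      if (j == i) next
      mid <- (seeds[i, ] + seeds[j, ]) / 2
      nrm <- seeds[j, ] - seeds[i, ]  # inside: (p - mid) . nrm <= 0
      cell <- clip_halfplane(cell, mid, nrm)
      if (nrow(cell) < 3L) break
    }
    if (nrow(cell) < 3L) stop("degenerate Voronoi cell for seed ", i)
    cells[[i]] <- cell
  }
  polygon_set(cells, id = seq_len(n),
              mean_depth = if (is.null(mean_depth)) rep(NA_real_, n)
                           else mean_depth,
              seeds = seeds)
}

# Sutherland-Hodgman clip of polygon 'v' by half-plane (p - mid) . nrm <= 0
clip_halfplane <- function(v, mid, nrm) {
  sgn <- (v[, 1L] - mid[1L]) * nrm[1L] + (v[, 2L] - mid[2L]) * nrm[2L]
  n <- nrow(v)
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    si <- sgn[i]; sj <- sgn[j]
    if (si <= 0) out <- rbind(out, v[i, ])
    if ((si < 0 && sj > 0) || (si > 0 && sj < 0)) {
      t <- si / (si - sj)
      out <- rbind(out, v[i, ] + t * (v[j, ] - v[i, ]))
    }
  }
  out
}

#' Read / write polygon sets as GeoJSON
#'
#' FeatureCollection of Polygon features with properties `polygon_id` and
#' `mean_depth_m`.
#'
#' @param path GeoJSON file path.
#' @return a [polygon_set()] (reader); `path` invisibly (writer).
#' @export
read_polygons_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- g$features
  vertices <- vector("list", length(feats))
  id <- character(length(feats))
  depth <- numeric(length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop("feature ", i, " is not a Polygon")
    }
    ring <- f$geometry$coordinates[[1L]]
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    if (nrow(v) > 1L && all(v[1L, ] == v[nrow(v), ])) {
      v <- v[-nrow(v), , drop = FALSE]  # drop GeoJSON ring closure
    }
    vertices[[i]] <- v
    id[i] <- as.character(f$properties$polygon_id)
    depth[i] <- if (is.null(f$properties$mean_depth_m)) NA_real_
                else as.numeric(f$properties$mean_depth_m)
  }
  polygon_set(vertices, id = id, mean_depth = depth)
}

#' @rdname read_polygons_geojson
#' @param polys a [polygon_set()].
#' @export
write_polygons_geojson <- function(polys, path) {
  stopifnot(inherits(polys, "polygon_set"))
  feats <- lapply(seq_along(polys$id), function(i) {
    v <- polys$vertices[[i]]
    ring <- lapply(seq_len(nrow(v)), function(r) c(v[r, 1L], v[r, 2L]))
    ring[[length(ring) + 1L]] <- ring[[1L]]
    list(type = "Feature",
         properties = list(polygon_id = polys$id[i],
                           mean_depth_m = polys$mean_depth[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Assign trawls to polygons by point-in-polygon
#'
#' Annotates each trawl record with the id of the containing cell. Points on
#' a shared boundary are assigned to the adjacent cell with the lowest id
#' (deterministic tie rule); trawls outside every cell are dropped with a
#' warning (or raise an error when `unmatched = "error"`).
#'
#' @param table a [trawl_table()].
#' @param polys a [polygon_set()].
#' @param unmatched `"drop"` (default) or `"error"`.
#' @return the trawl table as a data frame with a `polygon_id` column (`NA`
#'   for dropped trawls, which are retained in the output but excluded from
#'   polygon aggregations).
#' @export
assign_trawls <- function(table, polys, unmatched = c("drop", "error")) {
  unmatched <- match.arg(unmatched)
  stopifnot(inherits(polys, "polygon_set"))
  df <- as.data.frame(table)
  pts <- unique(df[c("trawl_id", "lon", "lat")])
  xy <- as.matrix(pts[c("lon", "lat")])
  assign <- rep(NA_character_, nrow(pts))
  ord <- order(polys$id)
  for (i in ord) {  # lowest id wins where containment overlaps on edges
    todo <- is.na(assign)
    if (!any(todo)) break
    inside <- mgcv::in.out(polys$vertices[[i]], xy[todo, , drop = FALSE])
    assign[todo][inside] <- polys$id[i]
  }
  # boundary points that in.out leaves unassigned: snap to the nearest edge
  # within tolerance, lowest id first
  left <- which(is.na(assign))
  if (length(left) > 0L) {
    for (p in left) {
      dmin <- vapply(ord, function(i)
        min_edge_distance(xy[p, ], polys$vertices[[i]]), numeric(1))
      hit <- which(dmin < 1e-9)
      if (length(hit) > 0L) assign[p] <- polys$id[ord[hit[1L]]]
    }
  }
  n_out <- sum(is.na(assign))
  if (n_out > 0L) {
    msg <- sprintf("%d trawl(s) outside all polygons", n_out)
    if (unmatched == "error") stop(msg)
    warning(msg, "; dropped from polygon aggregations")
  }
  df$polygon_id <- assign[match(df$trawl_id, pts$trawl_id)]
  df
}

min_edge_distance <- function(p, v) {
  n <- nrow(v)
  d <- numeric(n)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    d[i] <- sqrt(sum((p - (a + t * ab))^2))
  }
  min(d)
}

#' Years with survey coverage per polygon
#'
#' @param assigned data frame from [assign_trawls()] (has `polygon_id`).
#' @return named list: for each polygon id, the sorted integer years with at
#'   least one trawl.
#' @export
polygon_years_present <- function(assigned) {
  stopifnot(!is.null(assigned$polygon_id))
  df <- assigned[!is.na(assigned$polygon_id), c("polygon_id", "year")]
  lapply(split(df$year, df$polygon_id), function(y) sort(unique(y)))
}

#' Retain polygons surveyed in enough years
#'
#' Keeps cells with trawls in at least `min_years` survey years, so temporal
#' comparisons of spatial structure are not driven by changes in sampling
#' extent.
#'
#' @param polys a [polygon_set()] whose `years_present` is populated (or
#'   supply `years_present`).
#' @param min_years minimum number of distinct years (default 30).
#' @param years_present optional named list overriding `polys$years_present`.
#' @return the filtered [polygon_set()].
#' @export
retain_consistent_polygons <- function(polys, min_years = 30L,
                                       years_present = NULL) {
  stopifnot(inherits(polys, "polygon_set"))
  yp <- if (is.null(years_present)) polys$years_present else years_present
  if (is.null(yp)) stop("years_present not populated")
  counts <- vapply(polys$id, function(i)
    length(yp[[i]] %||% integer(0)), integer(1))
  keep <- counts >= min_years
  polygon_set(polys$vertices[keep], id = polys$id[keep],
              mean_depth = polys$mean_depth[keep],
              seeds = if (is.null(polys$seeds)) NULL
                      else polys$seeds[keep, , drop = FALSE],
              years_present = yp[polys$id[keep]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complete-linkage clustering of polygon-period communities
#'
#' Hierarchical agglomerative clustering (complete linkage, via
#' \code{stats::hclust}) of polygon-period relative-biomass compositions
#' under Bray-Curtis dissimilarity, cut into exactly `K` community types.
#' Cluster labels are canonicalized by the descending peak share of each
#' cluster's mean composition (label 1 = cluster whose mean composition is
#' most dominated by a single species), so labels are stable across input
#' row orderings.
#'
#' @param m community matrix over polygon-period units (rows normalized, or
#'   normalized here).
#' @param K number of clusters.
#' @return list of class `"cluster_assignment"`: `assignment` (data frame
#'   `unit`, `cluster`, `linkage_height` at which the unit's cluster merged
#'   fully), `tree` (the `hclust` object), `K`.
#' @export
cluster_polygon_periods <- function(m, K) {
  stopifnot(is.matrix(m))
  if (K > nrow(m)) stop("K exceeds the number of units")
  if (!isTRUE(attr(m, "normalized"))) m <- normalize_rows(m)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  d <- bray_curtis(m)
  hc <- hclust(d, method = "complete")
  cl <- cutree(hc, k = K)
  # canonical labels: order clusters by peak mean-composition share, descending
  peak <- vapply(seq_len(K), function(k)
    max(colMeans(m[cl == k, , drop = FALSE])), numeric(1))
  relabel <- match(seq_len(K), order(peak, decreasing = TRUE))
  cl <- relabel[cl]
  heights <- cluster_completion_heights(hc, cl, K)
  out <- data.frame(unit = rownames(m), cluster = cl,
                    linkage_height = heights[cl],
                    stringsAsFactors = FALSE)
  structure(list(assignment = out, tree = hc, K = K),
            class = "cluster_assignment")
}

# dissimilarity at which each cluster last merged internally (0 for singletons)
cluster_completion_heights <- function(hc, cl, K) {
  n <- length(cl)
  heights <- numeric(K)
  members <- lapply(seq_len(nrow(hc$merge)), function(i) integer(0))
  node_members <- function(i) {
    if (i < 0) -i else members[[i]]
  }
  for (i in seq_len(nrow(hc$merge))) {
    mem <- c(node_members(hc$merge[i, 1L]), node_members(hc$merge[i, 2L]))
    members[[i]] <- mem
    k <- unique(cl[mem])
    if (length(k) == 1L) heights[k] <- max(heights[k], hc$height[i])
  }
  heights
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d units in %d community types\n",
              nrow(x$assignment), x$K))
  print(table(x$assignment$cluster))
  invisible(x)
}

#' Mean composition profile per community-type cluster
#'
#' Arithmetic mean of the relative-biomass rows of each cluster, reported for
#' the focal species plus an `"other"` remainder (rows sum to 1).
#'
#' @param assignment a `"cluster_assignment"`.
#' @param m the community matrix the assignment was built from (rows
#'   normalized, or normalized here).
#' @param focal_species species to report individually.
#' @return data frame: one row per cluster, columns `cluster`, `n_units`, one
#'   per focal species, and `other`.
#' @export
cluster_profiles <- function(assignment, m, focal_species) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!isTRUE(attr(m, "normalized"))) m <- normalize_rows(m)
  a <- assignment$assignment
  if (!all(a$unit %in% rownames(m))) stop("assignment inconsistent with matrix")
  m <- m[a$unit, , drop = FALSE]
  focal_species <- intersect(focal_species, colnames(m))
  out <- lapply(sort(unique(a$cluster)), function(k) {
    prof <- colMeans(m[a$cluster == k, , drop = FALSE])
    row <- c(prof[focal_species], other = sum(prof) - sum(prof[focal_species]))
    data.frame(cluster = k, n_units = sum(a$cluster == k), t(row),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Great-circle distance between lon/lat points
#'
#' Spherical-law-of-cosines geodesic on a sphere of radius 6371.0088 km,
#' via \code{geosphere::distCosine}.
#'
#' @param p1,p2 two-column matrices (lon, lat) or length-2 vectors.
#' @return distance(s) in km.
#' @export
great_circle_km <- function(p1, p2) {
  geosphere::distCosine(p1, p2, r = 6371.0088) # radius in km -> result in km
}

#' Partition compositional variance between depth and distance
#'
#' For all pairs of polygons present in one survey year, regresses
#' logit-transformed Bray-Curtis dissimilarity on log absolute depth
#' difference and log great-circle centroid distance, and reports the
#' adjusted R-squared of the full model plus the partial adjusted R-squared
#' of each predictor (full minus the other predictor alone). Adjusted
#' R-squared uses the small-sample correction
#' `1 - (1 - R2) (n - 1)/(n - p - 1)`.
#'
#' @param m community matrix over polygon-years with rownames
#'   `"<polygon_id>:<year>"` (rows normalized, or normalized here).
#' @param polys a [polygon_set()] supplying centroids and mean depths.
#' @param year the survey year to evaluate.
#' @param eps logit clamp for dissimilarities (default 1e-4).
#' @param eps_depth,eps_dist offsets (m, km) added before the log transforms
#'   to absorb exact zeros (default 1e-3 each).
#' @param log_depth,log_dist disable a predictor's log transform if `FALSE`.
#' @return data frame row of class `"variance_partition"`: `year`,
#'   `r2_distance`, `r2_depth`, `r2_full`, `n_pairs`, `n_polygons`.
#' @export
variance_partition_by_year <- function(m, polys, year, eps = 1e-4,
                                       eps_depth = 1e-3, eps_dist = 1e-3,
                                       log_depth = TRUE, log_dist = TRUE) {
  stopifnot(inherits(polys, "polygon_set"))
  if (!isTRUE(attr(m, "normalized"))) m <- normalize_rows(m)
  want <- grepl(paste0(":", year, "$"), rownames(m))
  sub <- m[want & rowSums(m) > 0, , drop = FALSE]
  pid <- sub("^(.*):[0-9]+$", "\\1", rownames(sub))
  keep <- pid %in% polys$id & !is.na(polys$mean_depth[match(pid, polys$id)])
  sub <- sub[keep, , drop = FALSE]
  pid <- pid[keep]
  P <- nrow(sub)
  if (P < 4L) stop("need at least 4 polygons present in year ", year)
  idx <- match(pid, polys$id)
  bc <- as.matrix(vegan::vegdist(sub, method = "bray"))
  pairs <- which(lower.tri(bc), arr.ind = TRUE)
  y <- bc[lower.tri(bc)]
  y <- log(pmin(pmax(y, eps), 1 - eps) / (1 - pmin(pmax(y, eps), 1 - eps)))
  dd <- abs(polys$mean_depth[idx[pairs[, 1L]]] -
              polys$mean_depth[idx[pairs[, 2L]]])
  gd <- great_circle_km(polys$centroid[idx[pairs[, 1L]], , drop = FALSE],
                        polys$centroid[idx[pairs[, 2L]], , drop = FALSE])
  x_depth <- if (log_depth) log(dd + eps_depth) else dd
  x_dist <- if (log_dist) log(gd + eps_dist) else gd
  if (var(y) == 0) {
    warning("constant dissimilarity response in year ", year)
    out <- data.frame(year = year, r2_distance = 0, r2_depth = 0, r2_full = 0,
                      n_pairs = length(y), n_polygons = P)
    class(out) <- c("variance_partition", "data.frame")
    return(out)
  }
  adj_r2 <- function(fit, p) {
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    n <- length(y)
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  full <- adj_r2(lm(y ~ x_depth + x_dist), 2L)
  only_depth <- adj_r2(lm(y ~ x_depth), 1L)
  only_dist <- adj_r2(lm(y ~ x_dist), 1L)
  out <- data.frame(year = year,
                    r2_distance = full - only_depth,
                    r2_depth = full - only_dist,
                    r2_full = full,
                    n_pairs = length(y),
                    n_polygons = P)
  class(out) <- c("variance_partition", "data.frame")
  out
}

#' Per-year alpha diversity and between-polygon dissimilarity diagnostics
#'
#' Alpha diversity is the mean per-trawl species richness (species with
#' positive biomass per trawl, averaged within each year); beta structure is
#' summarized as the mean and variance of the off-diagonal between-polygon
#' Bray-Curtis dissimilarities within each year.
#'
#' @param m community matrix over polygon-years (rownames
#'   `"<polygon_id>:<year>"`).
#' @param table a [trawl_table()] (or assigned data frame) for the richness
#'   component.
#' @return data frame with `year`, `alpha`, `mean_dissimilarity`,
#'   `var_dissimilarity`, `n_polygons`.
#' @export
diversity_diagnostics <- function(m, table) {
  df <- as.data.frame(table)
  rich <- tapply(df$biomass_kg > 0, df$trawl_id, sum)
  trawl_year <- tapply(df$year, df$trawl_id, `[`, 1L)
  alpha <- tapply(as.numeric(rich), as.integer(trawl_year), mean)
  if (!isTRUE(attr(m, "normalized"))) m <- normalize_rows(m)
  years <- sort(unique(as.integer(sub("^.*:", "", rownames(m)))))
  out <- lapply(years, function(yr) {
    sub <- m[grepl(paste0(":", yr, "$"), rownames(m)), , drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    if (nrow(sub) < 2L) {
      md <- NA_real_; vd <- NA_real_
    } else {
      bc <- vegan::vegdist(sub, method = "bray")
      md <- mean(bc); vd <- var(as.numeric(bc))
    }
    data.frame(year = yr,
               alpha = unname(alpha[as.character(yr)]),
               mean_dissimilarity = md, var_dissimilarity = vd,
               n_polygons = nrow(sub))
  })
  do.call(rbind, out)
}
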