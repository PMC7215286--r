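#' Unit-square lattice polygons
#'
#' Builds a `rows x cols` grid of unit-square tract polygons in row-major
#' order, the geography used by the synthetic-data generator.  Coordinates
#' are planar.
#'
#' @param rows,cols grid dimensions (each at least 1).
#' @return A named list of polygons (names are zero-padded tract ids); each
#'   polygon is a list of rings, each ring a closed two-column matrix of
#'   x/y coordinates.
#' @export
grid_polygons <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  ids <- sprintf("T%04d", seq_len(rows * cols))
  polys <- vector("list", rows * cols)
  k <- 0L
  for (r in seq_len(rows)) {
    for (c0 in seq_len(cols)) {
      k <- k + 1L
      x0 <- c0 - 1; y0 <- r - 1
      ring <- cbind(x = c(x0, x0 + 1, x0 + 1, x0, x0),
                    y = c(y0, y0, y0 + 1, y0 + 1, y0))
      polys[[k]] <- list(ring)
    }
  }
  names(polys) <- ids
  polys
}

#' Queen-contiguity adjacency from polygons
#'
#' Two tracts are neighbours when their boundaries share at least one point
#' (queen rule).  Shared points are detected as shared boundary vertices
#' after snapping to a tolerance, which is exact for lattices and for tract
#' layers whose shared borders carry common nodes; a vertex of one polygon
#' lying strictly inside an edge of another is not detected.
#'
#' @param polygons named list of polygons as produced by [grid_polygons()] or
#'   [read_geojson_polygons()].
#' @param tol coordinate snapping tolerance used when matching vertices.
#' @return An [adjacency_graph()]; disconnected tracts trigger the usual
#'   island warning.
#' @export
build_queen_adjacency <- function(polygons, tol = 1e-8) {
  n <- length(polygons)
  ids <- names(polygons)
  if (is.null(ids) || anyDuplicated(ids))
    stop("polygons must be a named list with unique tract ids")
  keys <- vector("list", n)
  for (i in seq_len(n)) {
    p <- polygons[[i]]
    if (!length(p)) stop("empty geometry for tract ", ids[i])
    vv <- do.call(rbind, p)
    if (!is.matrix(vv) || ncol(vv) < 2L || !nrow(vv) ||
        any(!is.finite(vv[, 1:2])))
      stop("invalid geometry for tract ", ids[i])
    keys[[i]] <- unique(paste(round(vv[, 1] / tol), round(vv[, 2] / tol)))
  }
  vert <- data.frame(key = unlist(keys),
                     poly = rep.int(seq_len(n), lengths(keys)))
  nb <- rep(list(integer(0)), n)
  for (grp in split(vert$poly, vert$key)) {
    if (length(grp) < 2L) next
    for (i in grp) nb[[i]] <- c(nb[[i]], setdiff(grp, i))
  }
  adjacency_graph(nb, ids)
}

#' Read tract polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features carrying the
#' tract identifier as a feature property.
#'
#' @param path GeoJSON file.
#' @param id_property name of the feature property holding the tract id.
#' @return Named list of polygons (each a list of rings; MultiPolygon parts
#'   are flattened into one ring list) with non-id properties attached as the
#'   `"properties"` attribute (a data frame).
#' @export
read_geojson_polygons <- function(path, id_property = "tract_id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  n <- length(feats)
  polys <- vector("list", n)
  ids <- character(n)
  props <- vector("list", n)
  ring_mat <- function(r) {
    m <- do.call(rbind, lapply(r, function(pt) as.numeric(pt[1:2])))
    colnames(m) <- c("x", "y")
    m
  }
  for (i in seq_len(n)) {
    f <- feats[[i]]
    idv <- f$properties[[id_property]]
    if (is.null(idv)) stop("feature ", i, " lacks property '", id_property, "'")
    ids[i] <- as.character(idv)
    g <- f$geometry
    if (is.null(g$type)) stop("feature ", ids[i], " has no geometry")
    rings <- switch(g$type,
      Polygon = lapply(g$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(g$coordinates,
                                   function(pp) lapply(pp, ring_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type '", g$type, "' for tract ", ids[i]))
    polys[[i]] <- rings
    props[[i]] <- f$properties[setdiff(names(f$properties), id_property)]
  }
  if (anyDuplicated(ids)) stop("duplicated tract ids in GeoJSON: ", path)
  names(polys) <- ids
  keep <- unique(unlist(lapply(props, names)))
  if (length(keep)) {
    pr <- as.data.frame(lapply(keep, function(k)
      sapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]])),
      col.names = keep)
    pr$tract_id <- ids
    attr(polys, "properties") <- pr
  }
  polys
}

#' Write tract polygons (with optional per-tract values) to GeoJSON
#'
#' @param polygons named list of polygons.
#' @param path output file.
#' @param properties optional data frame of per-tract feature properties,
#'   with a `tract_id` column or row order matching `polygons`.
#' @param id_property property name used for the tract id.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polygons, path, properties = NULL,
                                   id_property = "tract_id") {
  ids <- names(polygons)
  if (!is.null(properties)) {
    if (!is.null(properties$tract_id)) {
      m <- match(ids, as.character(properties$tract_id))
      if (anyNA(m))
        stop("properties missing tract id(s): ",
             paste(ids[is.na(m)], collapse = ", "))
      properties <- properties[m, setdiff(names(properties), "tract_id"),
                               drop = FALSE]
    } else if (nrow(properties) != length(polygons)) {
      stop("properties rows must match number of polygons")
    }
  }
  feats <- lapply(seq_along(polygons), function(i) {
    rings <- lapply(polygons[[i]], function(r)
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2])))
    pr <- list()
    pr[[id_property]] <- ids[i]
    if (!is.null(properties))
      for (nm in names(properties)) pr[[nm]] <- properties[[nm]][i]
    list(type = "Feature", properties = pr,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Ray-casting point-in-polygon for one ring; points on the boundary count as
# inside.  Planar coordinates.
point_in_ring <- function(px, py, ring) {
  xs <- ring[, 1]; ys <- ring[, 2]
  nv <- length(xs)
  on_seg <- function(ax, ay, bx, by) {
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    if (abs(cross) > 1e-12 * max(1, abs(bx - ax), abs(by - ay))) return(FALSE)
    px >= min(ax, bx) - 1e-12 && px <= max(ax, bx) + 1e-12 &&
      py >= min(ay, by) - 1e-12 && py <= max(ay, by) + 1e-12
  }
  inside <- FALSE
  j <- nv
  for (i in seq_len(nv)) {
    if (on_seg(xs[j], ys[j], xs[i], ys[i])) return(TRUE)
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

point_in_polygon <- function(px, py, polygon) {
  # Outer ring(s) minus holes are not distinguished here: tract layers rarely
  # carry holes and a boundary hit already counts as inside.
  for (ring in polygon) if (point_in_ring(px, py, ring)) return(TRUE)
  FALSE
}

#' Assign outlet points to tract polygons
#'
#' Each point is assigned to the tract whose polygon contains it; points on a
#' shared boundary count as inside both and are assigned deterministically to
#' the lowest tract id (the tie is recorded).  Points contained by no polygon
#' are reported, never fatal.
#'
#' @param points data frame with `longitude` and `latitude` columns (decimal
#'   degrees, treated as planar for the containment test) and optionally an
#'   id column.
#' @param polygons named list of tract polygons.
#' @return list with `counts` (named integer vector over tracts),
#'   `assignment` (per-point tract id or `NA`), `unassigned` (row indices)
#'   and `ties` (rows assigned by the lowest-id rule).
#' @export
assign_points_to_tracts <- function(points, polygons) {
  stopifnot(all(c("longitude", "latitude") %in% names(points)))
  lon <- as.numeric(points$longitude)
  lat <- as.numeric(points$latitude)
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite point coordinates")
  if (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
    stop("coordinates outside valid longitude/latitude ranges")
  ids <- names(polygons)
  ord <- order(ids)          # lowest tract id wins ties
  counts <- stats::setNames(integer(length(ids)), ids)
  assignment <- rep(NA_character_, length(lon))
  ties <- integer(0)
  for (k in seq_along(lon)) {
    hits <- character(0)
    for (i in ord) {
      if (point_in_polygon(lon[k], lat[k], polygons[[i]])) {
        hits <- c(hits, ids[i])
        if (length(hits) == 2L) break   # a tie is a tie; first (lowest) wins
      }
    }
    if (length(hits)) {
      assignment[k] <- hits[[1L]]
      counts[hits[[1L]]] <- counts[hits[[1L]]] + 1L
      if (length(hits) > 1L) ties <- c(ties, k)
    }
  }
  list(counts = counts, assignment = assignment,
       unassigned = which(is.na(assignment)), ties = ties)
}
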