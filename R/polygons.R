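#' Accessible-area (M) polygon
#'
#' An accessible area delimits the biogeographic region a taxon could have
#' reached over relevant time; it bounds model calibration and the drawing
#' of background null points. Geometry is stored as a list of rings (each a
#' closed two-column lon/lat matrix); membership is evaluated with the
#' even-odd rule, so outer rings and holes need no distinction and
#' self-intersecting rings are still well-defined.
#'
#' @param taxon taxon label.
#' @param rings a single two-column matrix or a list of such matrices.
#' @return An object of class `accessible_area`.
#' @export
accessible_area <- function(taxon, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  if (length(rings) == 0L) stop("empty geometry for taxon ", taxon)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3) stop("each ring needs >= 3 lon/lat rows")
    storage.mode(r) <- "double"
    # drop an explicit closing vertex; closure is implicit
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (ring_self_intersects(r))
      warning("self-intersecting ring for taxon `", taxon,
              "`; membership uses the even-odd rule")
    r
  })
  structure(list(taxon = as.character(taxon), rings = rings),
            class = "accessible_area")
}

#' @export
print.accessible_area <- function(x, ...) {
  cat(sprintf("<accessible_area> %s: %d ring(s), %d vertices\n", x$taxon,
              length(x$rings), sum(vapply(x$rings, nrow, 0L))))
  invisible(x)
}

# crude O(n^2) proper-crossing check used only to log repairs
ring_self_intersects <- function(r) {
  n <- nrow(r)
  if (n < 4) return(FALSE)
  seg <- cbind(r, r[c(2:n, 1), , drop = FALSE])
  cross <- function(a, b, c) (b[1]-a[1])*(c[2]-a[2]) - (b[2]-a[2])*(c[1]-a[1])
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) <= 1 || (i == 1 && j == n)) next
    a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
    if (cross(a, b, c) * cross(a, b, d) < 0 &&
        cross(c, d, a) * cross(c, d, b) < 0) return(TRUE)
  }
  FALSE
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Ray-casting with the even-odd rule over all rings of an accessible
#' area. Points lying exactly on a ring edge or vertex count as inside
#' (closed polygons).
#'
#' @param area an [accessible_area].
#' @param pts two-column matrix of lon/lat points.
#' @return Logical vector, `TRUE` for points inside or on the boundary.
#' @export
point_in_area <- function(area, pts) {
  stopifnot(inherits(area, "accessible_area"))
  pts <- as.matrix(pts)
  inside <- rep(FALSE, nrow(pts))
  onedge <- rep(FALSE, nrow(pts))
  for (ring in area$rings) {
    n <- nrow(ring)
    xs <- ring[, 1]; ys <- ring[, 2]
    xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
    for (k in seq_len(nrow(pts))) {
      px <- pts[k, 1]; py <- pts[k, 2]
      # boundary test: point on any segment
      dx <- xe - xs; dy <- ye - ys
      crossp <- dx * (py - ys) - dy * (px - xs)
      within <- (px - xs) * (px - xe) <= 0 & (py - ys) * (py - ye) <= 0
      if (any(abs(crossp) < 1e-12 & within)) { onedge[k] <- TRUE; next }
      # even-odd ray cast (ray towards +x)
      crosses <- ((ys > py) != (ye > py)) &
        (px < xs + (py - ys) * dx / dy)
      if (sum(crosses, na.rm = TRUE) %% 2 == 1) inside[k] <- !inside[k]
    }
  }
  inside | onedge
}

#' Grid cells of a stack falling inside an accessible area
#'
#' @param stack an [env_stack].
#' @param area an [accessible_area].
#' @param drop_na drop cells that are NA in the stack (default `TRUE`).
#' @return Integer vector of linear cell indices.
#' @export
area_cells <- function(stack, area, drop_na = TRUE) {
  ctr <- cell_centers(stack)
  idx <- which(point_in_area(area, ctr))
  if (drop_na) idx <- idx[!as.vector(stack$na_mask)[idx]]
  idx
}

#' Read accessible areas from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon or MultiPolygon features, one
#' feature per taxon. The taxon label is taken from the named property.
#'
#' @param path GeoJSON file path.
#' @param taxon_property name of the feature property holding the taxon
#'   label (default `"taxon"`).
#' @return A named list of [accessible_area] objects.
#' @export
read_polygons <- function(path, taxon_property = "taxon") {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  if (length(feats) == 0L) stop("no features in ", path)
  out <- list()
  for (f in feats) {
    taxon <- f$properties[[taxon_property]]
    if (is.null(taxon)) stop("feature missing `", taxon_property, "` property")
    geom <- f$geometry
    if (is.null(geom) || is.null(geom$type)) stop("null geometry for ", taxon)
    ring_mat <- function(coords)
      do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    out[[taxon]] <- accessible_area(taxon, rings)
  }
  out
}

#' Write accessible areas to a GeoJSON FeatureCollection
#' @param areas list of [accessible_area] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(areas, path) {
  feats <- lapply(areas, function(a) {
    coords <- lapply(a$rings, function(r) {
      r <- rbind(r, r[1, ])                      # close ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(taxon = a$taxon),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
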