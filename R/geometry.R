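# Planar polygon primitives built on the Clipper library (polyclip).
#
# A geometry is a "chor_poly": a list of closed rings, each ring a
# list(x = <numeric>, y = <numeric>).  After normalisation (see
# poly_repair) outer rings carry positive signed area and holes negative,
# so the area of the geometry is the plain sum of signed ring areas.
# Multipolygon parts are just additional outer rings: a species with a
# disjunct range is one geometry.

new_chor_poly <- function(rings) {
  structure(rings, class = "chor_poly")
}

#' @export
print.chor_poly <- function(x, ...) {
  cat("<chor_poly: ", length(x), " ring(s), area ", format(poly_area(x)),
      ">\n", sep = "")
  invisible(x)
}

ring_signed_area <- function(r) {
  n <- length(r$x)
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  0.5 * sum(r$x * r$y[j] - r$x[j] * r$y)
}

#' Area of a polygon geometry
#'
#' Sum of signed ring areas of a normalised geometry (holes count
#' negative), in squared map units.
#'
#' @param p A `chor_poly` geometry.
#' @return A single nonnegative number.
#' @keywords internal
poly_area <- function(p) {
  if (length(p) == 0) return(0)
  sum(vapply(p, ring_signed_area, numeric(1)))
}

poly_bbox <- function(p) {
  xs <- unlist(lapply(p, `[[`, "x"), use.names = FALSE)
  ys <- unlist(lapply(p, `[[`, "y"), use.names = FALSE)
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

bbox_disjoint <- function(a, b) {
  a["xmax"] < b["xmin"] || b["xmax"] < a["xmin"] ||
    a["ymax"] < b["ymin"] || b["ymax"] < a["ymin"]
}

#' Repair and normalise a polygon geometry
#'
#' Applies one zero-width buffer (a self-union under the nonzero fill
#' rule), which resolves self-intersections, enforces consistent ring
#' orientation (outers positive, holes negative) and drops degenerate
#' rings.  Deterministic: identical input gives identical output.
#'
#' @param p A `chor_poly` or bare list of rings.
#' @return A normalised `chor_poly`.
#' @keywords internal
# Spatial resolution for the integer scaling of the clipper backend:
# 2^-40 of the coordinate magnitude (the library default, 2^-31 of the
# diameter, leaves visible quantisation noise in area ratios).
clip_eps <- function(...) {
  m <- 1
  for (p in list(...)) {
    for (r in p) m <- max(m, abs(r$x), abs(r$y))
  }
  m * 2^-40
}

poly_repair <- function(p) {
  if (length(p) == 0) return(new_chor_poly(list()))
  out <- polyclip::polysimplify(unclass(p), filltype = "nonzero",
                                eps = clip_eps(p))
  new_chor_poly(out)
}

poly_op <- function(a, b, op) {
  if (length(a) == 0 || (length(b) == 0 && op == "intersection")) {
    return(new_chor_poly(if (op == "union") unclass(b) else list()))
  }
  if (length(b) == 0) return(new_chor_poly(unclass(a)))
  out <- polyclip::polyclip(unclass(a), unclass(b), op = op,
                            fillA = "nonzero", fillB = "nonzero",
                            eps = clip_eps(a, b))
  new_chor_poly(out)
}

poly_intersect <- function(a, b) {
  if (length(a) && length(b) && bbox_disjoint(poly_bbox(a), poly_bbox(b))) {
    return(new_chor_poly(list()))
  }
  poly_op(a, b, "intersection")
}

poly_union <- function(a, b) poly_op(a, b, "union")

#' Axis-aligned rectangle geometry
#'
#' @param xmin,xmax,ymin,ymax Rectangle limits, `xmin < xmax`,
#'   `ymin < ymax`.
#' @return A `chor_poly` with one counter-clockwise ring.
#' @keywords internal
poly_rect <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  new_chor_poly(list(list(x = c(xmin, xmax, xmax, xmin),
                          y = c(ymin, ymin, ymax, ymax))))
}

# Overlap area between two geometries with the touching-boundaries rule:
# overlaps smaller than `tol` times the smaller area are treated as zero,
# so ranges that merely share a boundary do not count as overlapping.
poly_overlap_area <- function(a, b, tol = 1e-12) {
  o <- poly_area(poly_intersect(a, b))
  floor_area <- tol * min(poly_area(a), poly_area(b))
  if (o <= floor_area) 0 else o
}

point_in_ring <- function(px, py, r) {
  # even-odd ray crossing; used only for WKT/GeoJSON hole assignment
  n <- length(r$x)
  j <- c(n, seq_len(n - 1L))
  inside <- FALSE
  for (k in seq_len(n)) {
    xi <- r$x[k]; yi <- r$y[k]; xj <- r$x[j[k]]; yj <- r$y[j[k]]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
  }
  inside
}

# Group the rings of a normalised geometry into polygons: each outer ring
# (positive area) together with the holes (negative area) it contains.
# Returns a list of lists of rings, outer first.
poly_assemble <- function(p) {
  if (length(p) == 0) return(list())
  signed <- vapply(p, ring_signed_area, numeric(1))
  outers <- which(signed > 0)
  holes <- which(signed < 0)
  polys <- lapply(outers, function(i) list(p[[i]]))
  if (length(holes)) {
    outer_area <- signed[outers]
    for (h in holes) {
      px <- p[[h]]$x[1]; py <- p[[h]]$y[1]
      containing <- outers[vapply(outers, function(i) {
        point_in_ring(px, py, p[[i]])
      }, logical(1))]
      if (length(containing) == 0) next  # dangling hole: drop
      # smallest containing outer owns the hole
      host <- containing[which.min(signed[containing])]
      k <- match(host, outers)
      polys[[k]] <- c(polys[[k]], list(p[[h]]))
    }
  }
  polys
}

## --- WKT ------------------------------------------------------------------

ring_to_wkt <- function(r) {
  # close the ring explicitly, as WKT requires
  x <- c(r$x, r$x[1]); y <- c(r$y, r$y[1])
  paste0("(", paste(paste(format(x, trim = TRUE, scientific = FALSE),
                          format(y, trim = TRUE, scientific = FALSE)),
                    collapse = ", "), ")")
}

#' Serialise a geometry to WKT
#'
#' Writes `POLYGON` for a single outer ring (with any holes) and
#' `MULTIPOLYGON` otherwise.
#'
#' @param p A `chor_poly` geometry.
#' @return A WKT string.
#' @export
poly_to_wkt <- function(p) {
  polys <- poly_assemble(poly_repair(p))
  if (length(polys) == 0) return("POLYGON EMPTY")
  parts <- vapply(polys, function(rings) {
    paste0("(", paste(vapply(rings, ring_to_wkt, character(1)),
                      collapse = ", "), ")")
  }, character(1))
  if (length(parts) == 1) {
    paste0("POLYGON ", parts)
  } else {
    paste0("MULTIPOLYGON (", paste(parts, collapse = ", "), ")")
  }
}

wkt_coords <- function(txt) {
  pairs <- strsplit(trimws(strsplit(txt, ",")[[1]]), "\\s+")
  x <- suppressWarnings(vapply(pairs, function(p) as.numeric(p[1]),
                               numeric(1)))
  y <- suppressWarnings(vapply(pairs, function(p) as.numeric(p[2]),
                               numeric(1)))
  if (anyNA(x) || anyNA(y)) stop("malformed WKT coordinate list: ", txt)
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {  # drop closing vertex
    x <- x[-n]; y <- y[-n]
  }
  list(x = x, y = y)
}

# split "(...), (...)" at top-level commas between balanced groups
split_groups <- function(txt) {
  depth <- 0L; start <- NULL; out <- character(0)
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- depth + 1L
      if (depth == 1L) start <- i
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth == 0L) out <- c(out, substr(txt, start + 1L, i - 1L))
    }
  }
  if (depth != 0L) stop("unbalanced parentheses in WKT")
  out
}

#' Parse a WKT POLYGON or MULTIPOLYGON
#'
#' @param wkt A WKT string (`POLYGON` or `MULTIPOLYGON`; case
#'   insensitive).
#' @return A normalised `chor_poly`.
#' @export
parse_wkt <- function(wkt) {
  txt <- trimws(wkt)
  type <- toupper(sub("^\\s*([A-Za-z]+).*$", "\\1", txt))
  body <- sub("^\\s*[A-Za-z]+\\s*", "", txt)
  if (toupper(body) == "EMPTY") return(new_chor_poly(list()))
  if (type == "POLYGON") {
    rings <- lapply(split_groups(sub("^\\(", "", sub("\\)$", "", body))),
                    wkt_coords)
  } else if (type == "MULTIPOLYGON") {
    inner <- sub("^\\(", "", sub("\\)$", "", body))
    rings <- unlist(lapply(split_groups(inner), function(poly) {
      lapply(split_groups(poly), wkt_coords)
    }), recursive = FALSE)
  } else {
    stop("unsupported WKT geometry type: ", type)
  }
  poly_repair(new_chor_poly(rings))
}

## --- equal-area projection ------------------------------------------------

#' Project longitude/latitude coordinates to an equal-area plane
#'
#' Spherical closed-form projections; coordinates in decimal degrees,
#' output in kilometres.  Available projections: `"cea"` (cylindrical
#' equal-area with standard parallel `lat_ts`), `"laea"` (Lambert
#' azimuthal equal-area centred on `lon_0`, `lat_0`) and `"mollweide"`.
#'
#' @param lon,lat Numeric vectors of equal length, degrees.
#' @param projection One of `"cea"`, `"laea"`, `"mollweide"`.
#' @param lon_0,lat_0 Projection centre, degrees.
#' @param lat_ts Standard parallel for `"cea"`, degrees.
#' @param radius Sphere radius in kilometres (default: mean Earth
#'   radius).
#' @return A list with numeric components `x` and `y` in kilometres.
#' @export
project_lonlat <- function(lon, lat,
                           projection = c("cea", "laea", "mollweide"),
                           lon_0 = 0, lat_0 = 0, lat_ts = 0,
                           radius = 6371.0088) {
  projection <- match.arg(projection)
  rad <- pi / 180
  lam <- (lon - lon_0) * rad
  lam <- ((lam + pi) %% (2 * pi)) - pi
  phi <- lat * rad
  R <- radius
  switch(projection,
    cea = {
      k <- cos(lat_ts * rad)
      list(x = R * lam * k, y = R * sin(phi) / k)
    },
    laea = {
      phi0 <- lat_0 * rad
      denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
      if (any(denom <= 1e-12)) {
        stop("point antipodal to the projection centre; move lon_0/lat_0")
      }
      kp <- sqrt(2 / denom)
      list(x = R * kp * cos(phi) * sin(lam),
           y = R * kp * (cos(phi0) * sin(phi) -
                           sin(phi0) * cos(phi) * cos(lam)))
    },
    mollweide = {
      theta <- phi
      for (i in 1:50) {  # Newton iteration for 2t + sin 2t = pi sin phi
        delta <- (2 * theta + sin(2 * theta) - pi * sin(phi)) /
          (2 + 2 * cos(2 * theta))
        delta[!is.finite(delta)] <- 0
        theta <- theta - delta
        if (max(abs(delta)) < 1e-12) break
      }
      list(x = R * 2 * sqrt(2) / pi * lam * cos(theta),
           y = R * sqrt(2) * sin(theta))
    })
}

project_poly <- function(p, ...) {
  poly_repair(new_chor_poly(lapply(p, function(r) {
    project_lonlat(r$x, r$y, ...)
  })))
}

# Heuristic: could these coordinates plausibly be raw lon/lat degrees?
looks_lonlat <- function(p) {
  if (length(p) == 0) return(FALSE)
  bb <- poly_bbox(p)
  bb["xmin"] >= -180 && bb["xmax"] <= 180 &&
    bb["ymin"] >= -90 && bb["ymax"] <= 90
}
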