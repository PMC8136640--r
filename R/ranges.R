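# Species range tables: a tibble with one row per species carrying the
# (multi)polygon range geometry and its planar area.

#' Build a species range table
#'
#' Constructs the range table used throughout the package: a tibble with
#' columns `species_id` (character), `geometry` (list of planar polygon
#' geometries) and `area` (squared map units).  Rows sharing a
#' `species_id` are unioned into a single geometry, so a disjunct range
#' is one species.  Geometries are repaired once by zero-width buffering;
#' a species whose repaired range still has zero area is an error.
#'
#' @param data A data frame with a `species_id` column and either a
#'   `wkt` character column or a `geometry` list column of `chor_poly`
#'   objects.
#' @param projection Optional equal-area projection name
#'   (see [project_lonlat()]).  When supplied, input coordinates are
#'   interpreted as longitude/latitude degrees and projected; when
#'   `NULL` (default) coordinates must already be planar.  Raw
#'   longitude/latitude input without a projection is refused because
#'   the congruence index is a ratio of planar areas.
#' @param ... Additional arguments passed to [project_lonlat()]
#'   (`lon_0`, `lat_0`, `lat_ts`, `radius`).
#' @return A `species_ranges` tibble.
#' @examples
#' rngs <- species_ranges(data.frame(
#'   species_id = c("A", "B"),
#'   wkt = c("POLYGON ((0 0, 10 0, 10 1, 0 1))",
#'           "POLYGON ((0 0, 12 0, 12 1, 0 1))")))
#' rngs$area
#' @export
species_ranges <- function(data, projection = NULL, ...) {
  if (!"species_id" %in% names(data)) {
    stop("`data` must have a `species_id` column")
  }
  ids <- as.character(data$species_id)
  if (!is.null(data$geometry)) {
    geoms <- data$geometry
  } else if (!is.null(data$wkt)) {
    geoms <- lapply(data$wkt, parse_wkt)
  } else {
    stop("`data` must have a `wkt` or `geometry` column")
  }
  geoms <- lapply(geoms, poly_repair)

  if (!is.null(projection)) {
    geoms <- lapply(geoms, project_poly, projection = projection, ...)
  }

  # union duplicated ids into one (multi)geometry
  if (anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    merged <- lapply(split(geoms, factor(ids, levels = ids[keep])),
                     function(gs) Reduce(poly_union, gs))
    ids <- ids[keep]
    geoms <- merged[ids]
  }

  areas <- vapply(geoms, poly_area, numeric(1))
  bad <- areas <= 0
  if (any(bad)) {
    stop("zero-area or irreparable geometry for species: ",
         paste(ids[bad], collapse = ", "))
  }
  out <- tibble::tibble(species_id = ids,
                        geometry = unname(geoms),
                        area = unname(areas))
  class(out) <- c("species_ranges", class(out))
  out
}

range_lookup <- function(ranges, ids) {
  i <- match(ids, ranges$species_id)
  if (anyNA(i)) {
    stop("unknown species_id: ", paste(ids[is.na(i)], collapse = ", "))
  }
  i
}

#' Read species ranges from a WKT/CSV file
#'
#' Expects a CSV with columns `species_id` and `wkt` (one feature per
#' row; repeated ids are unioned).
#'
#' @param path Path to the CSV file.
#' @param planar Set `TRUE` to assert that coordinates are planar even
#'   though they all fall inside the longitude/latitude bounds.  The
#'   congruence index is a ratio of planar areas, so raw geographic
#'   degrees are refused rather than silently distorted.
#' @inheritParams species_ranges
#' @return A `species_ranges` tibble.
#' @export
read_ranges_wkt <- function(path, projection = NULL, planar = FALSE, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "wkt") %in% names(df))) {
    stop("`", path, "` must have columns `species_id` and `wkt`")
  }
  if (is.null(projection) && !planar) {
    geoms <- lapply(df$wkt, parse_wkt)
    if (length(geoms) && all(vapply(geoms, looks_lonlat, logical(1)))) {
      stop("all coordinates in `", path, "` fall inside ",
           "[-180, 180] x [-90, 90]; if they are longitude/latitude ",
           "degrees supply `projection` (equal-area), or set ",
           "`planar = TRUE` if they are already planar")
    }
  }
  species_ranges(df, projection = projection, ...)
}

#' Write species ranges to a WKT/CSV file
#'
#' @param ranges A `species_ranges` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranges_wkt <- function(ranges, path) {
  df <- data.frame(species_id = ranges$species_id,
                   wkt = vapply(ranges$geometry, poly_to_wkt, character(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

geojson_poly_coords <- function(p) {
  lapply(poly_assemble(p), function(rings) {
    lapply(rings, function(r) {
      # close ring; GeoJSON wants [ [x, y], ... ] with first == last
      x <- c(r$x, r$x[1]); y <- c(r$y, r$y[1])
      mapply(function(a, b) c(a, b), x, y, SIMPLIFY = FALSE)
    })
  })
}

coords_to_rings <- function(coords) {
  lapply(coords, function(ring) {
    m <- do.call(rbind, lapply(ring, as.numeric))
    r <- list(x = m[, 1], y = m[, 2])
    n <- length(r$x)
    if (n > 1 && r$x[1] == r$x[n] && r$y[1] == r$y[n]) {
      r$x <- r$x[-n]; r$y <- r$y[-n]
    }
    r
  })
}

#' Read species ranges from a GeoJSON file
#'
#' Expects a `FeatureCollection` of `Polygon`/`MultiPolygon` features
#' with a `species_id` property.  GeoJSON coordinates are by convention
#' longitude/latitude, so a `projection` is required unless
#' `planar = TRUE` declares them already projected.
#'
#' @param path Path to the GeoJSON file.
#' @param planar Set `TRUE` if coordinates are already planar
#'   equal-area (non-standard GeoJSON).
#' @inheritParams species_ranges
#' @return A `species_ranges` tibble.
#' @export
read_ranges_geojson <- function(path, projection = NULL, planar = FALSE,
                                ...) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("`", path, "` is not a FeatureCollection")
  if (is.null(projection) && !planar) {
    stop("GeoJSON coordinates are longitude/latitude by convention; ",
         "supply `projection` (equal-area) or set `planar = TRUE`")
  }
  rows <- lapply(gj$features, function(f) {
    id <- f$properties$species_id
    if (is.null(id)) stop("feature without a `species_id` property")
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = coords_to_rings(geom$coordinates),
      MultiPolygon = unlist(lapply(geom$coordinates, coords_to_rings),
                            recursive = FALSE),
      stop("unsupported GeoJSON geometry type: ", geom$type))
    list(id = as.character(id), geom = new_chor_poly(rings))
  })
  species_ranges(
    tibble::tibble(species_id = vapply(rows, `[[`, character(1), "id"),
                   geometry = lapply(rows, `[[`, "geom")),
    projection = projection, ...)
}

#' Write species ranges to a GeoJSON file
#'
#' Coordinates are written as they are stored (planar map units); this
#' is a round-trip format for fixtures and results, not a geographic
#' export.
#'
#' @param ranges A `species_ranges` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranges_geojson <- function(ranges, path) {
  features <- purrr::map2(ranges$species_id, ranges$geometry, function(id, g) {
    polys <- geojson_poly_coords(g)
    geometry <- if (length(polys) == 1) {
      list(type = "Polygon", coordinates = polys[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = polys)
    }
    list(type = "Feature",
         properties = list(species_id = id),
         geometry = geometry)
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.species_ranges <- function(x, ...) {
  cat("# Species ranges: ", nrow(x), " species, total area ",
      format(sum(x$area)), "\n", sep = "")
  NextMethod()
}
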