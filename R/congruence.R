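# The spatial congruence index and the pairwise congruence network.

#' Spatial congruence index between two ranges
#'
#' The congruence between ranges a and b is the product of their overlap
#' fractions,
#' \deqn{C_S = (O / A_a) \times (O / A_b) = O^2 / (A_a A_b),}
#' where `O` is the overlap area and `A_a`, `A_b` the two range areas.
#' It equals 0 for disjoint ranges, 1 for identical ranges (up to
#' measure zero), and `A_a / A_b` when a is nested inside b.  Overlaps
#' below `1e-12` of the smaller range are treated as zero, so ranges
#' that merely touch along a boundary are not congruent.
#'
#' @param a,b `chor_poly` geometries, or single rows of a
#'   `species_ranges` tibble.
#' @return A number in `[0, 1]`.
#' @examples
#' sq <- parse_wkt("POLYGON ((0 0, 1 0, 1 1, 0 1))")
#' spatial_congruence(sq, sq)
#' @export
spatial_congruence <- function(a, b) {
  ga <- as_geometry(a, "a"); gb <- as_geometry(b, "b")
  aa <- poly_area(ga); ab <- poly_area(gb)
  if (aa <= 0) stop("zero-area geometry for `a`")
  if (ab <= 0) stop("zero-area geometry for `b`")
  o <- poly_overlap_area(ga, gb)
  min(1, o * o / (aa * ab))
}

as_geometry <- function(x, what) {
  if (inherits(x, "chor_poly")) return(x)
  if (is.data.frame(x) && nrow(x) == 1 && !is.null(x$geometry)) {
    return(x$geometry[[1]])
  }
  if (is.list(x) && !is.null(x$x)) return(new_chor_poly(list(x)))
  stop("`", what, "` must be a chor_poly or a single species_ranges row")
}

#' Build the pairwise congruence network
#'
#' Computes the spatial congruence index for every unordered pair of
#' species and stores the pairs with `cs >= store_floor` as a sparse
#' edge table.  Looking up an absent pair yields congruence 0.  The
#' default floor equals the conventional minimum congruence threshold of
#' a scan (0.1): weaker edges can never activate during a sweep, so
#' dropping them loses nothing.
#'
#' @param ranges A `species_ranges` tibble (the full species pool;
#'   scans may reference any subset of it).
#' @param store_floor Minimum congruence stored, in `[0, 1)`.
#' @return A `congruence_network`: a tibble with columns `species_a`,
#'   `species_b`, `overlap_area` and `cs`, ordered by the input species
#'   order, with the species pool attached as an attribute.
#' @examples
#' rngs <- species_ranges(data.frame(
#'   species_id = c("A", "B", "C"),
#'   wkt = c("POLYGON ((0 0, 10 0, 10 1, 0 1))",
#'           "POLYGON ((0 0, 12 0, 12 1, 0 1))",
#'           "POLYGON ((2 0, 14 0, 14 1, 2 1))")))
#' congruence_network(rngs, store_floor = 0.1)
#' @export
congruence_network <- function(ranges, store_floor = 0.1) {
  stopifnot(inherits(ranges, "species_ranges"))
  if (nrow(ranges) < 2) stop("need at least 2 species to build a network")
  if (anyDuplicated(ranges$species_id)) {
    stop("duplicate species_id in `ranges`")
  }
  stopifnot(store_floor >= 0, store_floor < 1)
  n <- nrow(ranges)
  ia <- integer(0); ib <- integer(0); ov <- numeric(0); cs <- numeric(0)
  bbs <- lapply(ranges$geometry, poly_bbox)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (bbox_disjoint(bbs[[i]], bbs[[j]])) next
      o <- poly_overlap_area(ranges$geometry[[i]], ranges$geometry[[j]])
      if (o <= 0) next
      val <- min(1, o * o / (ranges$area[i] * ranges$area[j]))
      if (val >= store_floor && val > 0) {
        ia <- c(ia, i); ib <- c(ib, j); ov <- c(ov, o); cs <- c(cs, val)
      }
    }
  }
  out <- tibble::tibble(species_a = ranges$species_id[ia],
                        species_b = ranges$species_id[ib],
                        overlap_area = ov,
                        cs = cs)
  structure(out,
            species = ranges$species_id,
            store_floor = store_floor,
            class = c("congruence_network", class(out)))
}

#' Species pool of a congruence network
#' @param network A `congruence_network`.
#' @return Character vector of species ids.
#' @export
network_species <- function(network) attr(network, "species")

#' Look up pairwise congruence values
#'
#' Vectorised over pairs; absent pairs (including self pairs) return 0.
#'
#' @param network A `congruence_network`.
#' @param a,b Character vectors of species ids (recycled).
#' @return Numeric vector of congruence values.
#' @export
network_cs <- function(network, a, b) {
  key <- function(p, q) paste(pmin(p, q), pmax(p, q), sep = "\r")
  edges <- stats::setNames(network$cs,
                           key(network$species_a, network$species_b))
  out <- unname(edges[key(a, b)])
  out[is.na(out)] <- 0
  out[a == b] <- 0
  out
}

# Dense symmetric congruence matrix over the pool (row/col = pool order).
cs_matrix <- function(network) {
  sp <- network_species(network)
  n <- length(sp)
  m <- matrix(0, n, n, dimnames = list(sp, sp))
  ia <- match(network$species_a, sp)
  ib <- match(network$species_b, sp)
  m[cbind(ia, ib)] <- network$cs
  m[cbind(ib, ia)] <- network$cs
  m
}

#' Common and total area of a set of ranges
#'
#' The total area is the area of the union of all member ranges; the
#' common area is the area of their joint intersection.  Their ratio
#' (intersection over union) measures the trade-off between spatial
#' cohesion and comprehensiveness of a species group.
#'
#' @param ranges A `species_ranges` tibble.
#' @param ids Optional character vector selecting a subset of species;
#'   default: all.
#' @return A one-row tibble with `common_area`, `total_area` and
#'   `ratio` (`NA` when the common area is empty and the total is 0,
#'   which cannot happen for valid ranges).
#' @export
common_total_area <- function(ranges, ids = NULL) {
  stopifnot(inherits(ranges, "species_ranges"))
  if (is.null(ids)) ids <- ranges$species_id
  if (length(ids) < 1) stop("need at least one species")
  gs <- ranges$geometry[range_lookup(ranges, ids)]
  common <- Reduce(poly_intersect, gs)
  total <- Reduce(poly_union, gs)
  ca <- poly_area(common); ta <- poly_area(total)
  tibble::tibble(common_area = ca, total_area = ta,
                 ratio = if (ta > 0) ca / ta else NA_real_)
}

#' Write a congruence network edge list to CSV
#'
#' Fixed column order (`species_a`, `species_b`, `overlap_area`, `cs`)
#' and 6-decimal fixed-point numbers, for reproducible diffs.
#'
#' @param network A `congruence_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(network, path) {
  df <- data.frame(species_a = network$species_a,
                   species_b = network$species_b,
                   overlap_area = fixed6(network$overlap_area),
                   cs = fixed6(network$cs))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fixed6 <- function(x) formatC(x, digits = 6, format = "f")
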