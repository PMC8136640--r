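# Synthetic range generators: the 30-species latitudinal gradient used
# to benchmark chorotype methods, and randomised communities of range
# syndromes with planted ground truth.

# Documented reference parametrization of the 30-species gradient.
#
# Two centres of diversity, a southern group S1-S15 anchored at the
# southern edge of the domain and a mirrored northern group N16-N30
# anchored at the northern edge, every bar sharing the same longitudinal
# extent so all ranges overlap the gradient axis.  Within each group
# ranges are strictly nested and lengths increase toward the transition
# zone, mostly in uniform graded steps; a few deliberate exceptions
# produce slightly larger proportional discontinuities that partition
# each group into internally tight blocks (S4-S9 and S10-S15 in the
# south; N16-N21 and N22-N27 in the north), the classic irregularities
# of the scheme.  The differences among N28-N30 are strongly reduced,
# leaving a single larger range discontinuity at the northern extreme
# that isolates a small-range block.  The widest southern and northern
# bars overlap across the transition zone; the narrowest bars of
# opposite groups do not overlap at all.
#
# Lengths are in arbitrary map units; only their ratios matter, since
# the congruence of two nested equal-width bars is exactly the ratio of
# their lengths.
.kj_south_lengths <- c(202, 267, 332, 393, 439, 485, 524, 567, 606,
                       717, 784, 848, 900, 952, 1000)
.kj_north_lengths <- c(1000, 952, 900, 848, 784, 717, 612, 572, 529,
                       489, 442, 394, 316, 304, 289)

#' Specification of the 30-species gradient fixture
#'
#' Returns the parameter block of the simulated latitudinal gradient:
#' two mirrored centres of diversity whose species extend graded, nested
#' ranges into a shared transition zone.  The default bar lengths are
#' the package's documented reference constants (see the package
#' vignette); they encode mostly uniform within-group grading with a few
#' slightly larger discontinuities and strongly reduced range
#' differences among N28-N30.
#'
#' @param n_south,n_north Number of species per group (defaults 15
#'   and 15, ids `S1..S15` and `N16..N30`).
#' @param south_lengths,north_lengths Latitudinal bar lengths.
#'   `south_lengths` is increasing (S1 narrowest), `north_lengths`
#'   decreasing (N16 widest); both groups are strictly nested.
#' @param bar_width Longitudinal extent shared by every bar.
#' @param overlap_span Latitudinal extent shared by the widest southern
#'   and northern bars.
#' @param origin Coordinate offset `c(x, y)` of the south-west corner.
#' @return A `gradient_spec` list, including the derived domain height
#'   `domain = max(south_lengths) + max(north_lengths) - overlap_span`.
#' @export
gradient_spec <- function(n_south = 15, n_north = 15,
                          south_lengths = .kj_south_lengths,
                          north_lengths = .kj_north_lengths,
                          bar_width = 100, overlap_span = 500,
                          origin = c(0, 0)) {
  stopifnot(length(south_lengths) == n_south,
            length(north_lengths) == n_north,
            all(diff(south_lengths) > 0),
            all(diff(north_lengths) < 0),
            all(south_lengths > 0), all(north_lengths > 0),
            bar_width > 0, overlap_span > 0, length(origin) == 2)
  domain <- max(south_lengths) + max(north_lengths) - overlap_span
  if (domain <= max(south_lengths) || domain <= max(north_lengths)) {
    stop("overlap_span too large: a group would span the whole domain")
  }
  structure(list(n_south = n_south, n_north = n_north,
                 south_lengths = south_lengths,
                 north_lengths = north_lengths,
                 bar_width = bar_width, overlap_span = overlap_span,
                 origin = origin, domain = domain),
            class = "gradient_spec")
}

#' Generate the 30-species gradient fixture
#'
#' Deterministically builds the simulated gradient described by a
#' [gradient_spec()]: every species is a thin rectangle (so the full 2-D
#' geometry path is exercised), southern bars rise from the southern
#' origin, northern bars descend from the northern edge, and all bars
#' share the same longitudinal extent.
#'
#' @param spec A [gradient_spec()].
#' @return A `species_ranges` tibble of `n_south + n_north` species with
#'   ids `S1..` and `N..`, southern species first.
#' @examples
#' rngs <- kj_gradient()
#' nrow(rngs)
#' @export
kj_gradient <- function(spec = gradient_spec()) {
  stopifnot(inherits(spec, "gradient_spec"))
  x0 <- spec$origin[1]; y0 <- spec$origin[2]
  ids <- c(paste0("S", seq_len(spec$n_south)),
           paste0("N", spec$n_south + seq_len(spec$n_north)))
  south <- lapply(spec$south_lengths, function(len) {
    poly_rect(x0, x0 + spec$bar_width, y0, y0 + len)
  })
  north <- lapply(spec$north_lengths, function(len) {
    poly_rect(x0, x0 + spec$bar_width, y0 + spec$domain - len,
              y0 + spec$domain)
  })
  species_ranges(tibble::tibble(species_id = ids,
                                geometry = c(south, north)))
}

#' Ground-truth group ids of a gradient fixture
#'
#' @param spec A [gradient_spec()].
#' @return A tibble with `species_id` and `group` (`"S"` or `"N"`).
#' @export
gradient_truth <- function(spec = gradient_spec()) {
  tibble::tibble(
    species_id = c(paste0("S", seq_len(spec$n_south)),
                   paste0("N", spec$n_south + seq_len(spec$n_north))),
    group = rep(c("S", "N"), c(spec$n_south, spec$n_north)))
}

#' Random community realizing one range syndrome
#'
#' Generates a reproducible community of species ranges planted as a
#' single congruent group, realizing one of the classic syndromes of
#' shared distributions: a nuclear region of congruence (near-identical
#' ranges), habitat tracking (elongated ranges sliding along a linear
#' habitat), a gradient of expansion from a common core (nested, growing
#' ranges), a linear gradient (equal-size ranges drifting in space), or
#' disjunct ranges (each species occupying the same two separate
#' patches).  The planted membership is returned as the `truth`
#' attribute, so detection methods can be scored against it.
#'
#' @param kind One of `"nuclear"`, `"habitat_tracking"`,
#'   `"expansion_gradient"`, `"linear_gradient"`, `"disjunct"`.
#' @param n_species Number of species (at least 2).
#' @param seed Integer seed; identical seeds give identical communities.
#' @param jitter Nonnegative amount of uniform random displacement
#'   applied to each range, in map units.
#' @param origin Coordinate offset `c(x, y)`, useful for placing
#'   independent communities far apart.
#' @param prefix Species id prefix.
#' @return A `species_ranges` tibble with attribute `truth`: a tibble
#'   of `species_id` and planted `group`.
#' @examples
#' com <- syndrome_community("nuclear", n_species = 5, seed = 1, jitter = 0)
#' spatial_congruence(com[1, ], com[2, ])
#' @export
syndrome_community <- function(kind = c("nuclear", "habitat_tracking",
                                        "expansion_gradient",
                                        "linear_gradient", "disjunct"),
                               n_species = 6, seed = 1, jitter = 1,
                               origin = c(0, 0), prefix = "sp") {
  kind <- match.arg(kind)
  stopifnot(n_species >= 2, jitter >= 0)
  ids <- paste0(prefix, seq_len(n_species))
  geoms <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    dx <- stats::runif(n_species, -jitter, jitter)
    dy <- stats::runif(n_species, -jitter, jitter)
    base <- 20  # nominal range extent, map units
    lapply(seq_len(n_species), function(i) {
      x0 <- origin[1] + dx[i]; y0 <- origin[2] + dy[i]
      switch(kind,
        nuclear = poly_rect(x0, x0 + base, y0, y0 + base),
        habitat_tracking = {
          # narrow band sliding along a linear habitat
          step <- base / 4
          poly_rect(x0 + (i - 1) * step / 4, x0 + (i - 1) * step / 4 + base / 4,
                    y0 + (i - 1) * step, y0 + (i - 1) * step + 3 * base)
        },
        expansion_gradient = {
          # nested ranges expanding from a shared core
          half <- base / 2 * 1.25^(i - 1)
          poly_rect(x0 - half, x0 + half, y0 - half, y0 + half)
        },
        linear_gradient = {
          # equal-size ranges drifting along one axis
          shift <- (i - 1) * base / 4
          poly_rect(x0 + shift, x0 + shift + base, y0, y0 + base)
        },
        disjunct = {
          gap <- 3 * base
          poly_union(
            poly_rect(x0, x0 + base, y0, y0 + base),
            poly_rect(x0 + gap, x0 + gap + base, y0, y0 + base))
        })
    })
  })
  out <- species_ranges(tibble::tibble(species_id = ids, geometry = geoms))
  attr(out, "truth") <- tibble::tibble(species_id = ids, group = prefix)
  out
}
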