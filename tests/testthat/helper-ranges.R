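# Shared fixtures, all built in code.

rect_wkt <- function(xmin, xmax, ymin, ymax) {
  sprintf("POLYGON ((%g %g, %g %g, %g %g, %g %g))",
          xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax)
}

# Three nested/staggered bars with hand-computed congruences:
# A = [0,10] x [0,1], B = [0,12] x [0,1], C = [2,16] x [0,1].
# Overlaps: A-B 10, B-C 10, A-C 8, so
# cs(A,B) = 100/120 = 0.8333, cs(B,C) = 100/168 = 0.5952,
# cs(A,C) = 64/140 = 0.4571.
bars_abc <- function() {
  species_ranges(data.frame(
    species_id = c("A", "B", "C"),
    wkt = c(rect_wkt(0, 10, 0, 1),
            rect_wkt(0, 12, 0, 1),
            rect_wkt(2, 16, 0, 1))))
}

# Random axis-aligned rectangles in a [0, 100]^2 window, areas bounded
# away from zero.
rand_rect_ranges <- function(n, seed, window = 100, min_side = 5,
                             max_side = 40, prefix = "r") {
  withr::with_seed(seed, {
    x0 <- runif(n, 0, window - min_side)
    y0 <- runif(n, 0, window - min_side)
    w <- runif(n, min_side, max_side)
    h <- runif(n, min_side, max_side)
    geoms <- lapply(seq_len(n), function(i) {
      choroscan:::poly_rect(x0[i], x0[i] + w[i], y0[i], y0[i] + h[i])
    })
    species_ranges(tibble::tibble(
      species_id = sprintf("%s%02d", prefix, seq_len(n)),
      geometry = geoms))
  })
}

# Independent-oracle connected component: the set of species reachable
# from `ref` in the graph whose edges are pairs with cs >= ct, found by
# union-find over the raw pairwise congruence matrix (no reuse of the
# package's expansion code).
oracle_component <- function(ranges, ref, ct, eps = 1e-9) {
  n <- nrow(ranges)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      cs <- spatial_congruence(ranges[i, ], ranges[j, ])
      if (cs >= ct - eps) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  k <- match(ref, ranges$species_id)
  sort(ranges$species_id[roots == roots[k]])
}
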