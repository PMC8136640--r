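test_that("the congruence index matches its closed forms", {
  unit <- parse_wkt(rect_wkt(0, 1, 0, 1))
  expect_equal(spatial_congruence(unit, unit), 1)

  far <- parse_wkt(rect_wkt(5, 6, 0, 1))
  expect_equal(spatial_congruence(unit, far), 0)

  # nested: a (area 50) inside b (area 100) -> (50/50) * (50/100)
  a <- parse_wkt(rect_wkt(0, 10, 0, 5))
  b <- parse_wkt(rect_wkt(0, 10, 0, 10))
  expect_equal(spatial_congruence(a, b), 0.5)

  # two unit squares sharing exactly half their area
  half <- parse_wkt(rect_wkt(0.5, 1.5, 0, 1))
  expect_equal(spatial_congruence(unit, half), 0.25)
})

test_that("network edges on the three-bar community match hand values", {
  bars <- bars_abc()
  net <- congruence_network(bars, store_floor = 0)
  expect_equal(network_cs(net, "A", "B"), 100 / 120, tolerance = 1e-6)
  expect_equal(network_cs(net, "B", "C"), 100 / 168, tolerance = 1e-6)
  expect_equal(network_cs(net, "A", "C"), 64 / 140, tolerance = 1e-6)
  expect_equal(network_cs(net, "B", "A"), network_cs(net, "A", "B"))
  expect_equal(network_cs(net, "A", "A"), 0)

  floored <- congruence_network(bars, store_floor = 0.5)
  expect_equal(nrow(floored), 2)
  expect_equal(network_cs(floored, "A", "C"), 0)  # absent pair reads as 0

  pair <- species_ranges(data.frame(
    species_id = c("X", "Y"),
    wkt = rep(rect_wkt(0, 4, 0, 4), 2)))
  net2 <- congruence_network(pair)
  expect_equal(nrow(net2), 1)
  expect_equal(net2$cs, 1)
})

test_that("network construction validates its input", {
  bars <- bars_abc()
  dup <- bars
  dup$species_id[2] <- "A"
  expect_error(congruence_network(dup), "duplicate")
  expect_error(congruence_network(bars[1, ]), "at least 2")
})

test_that("index symmetry, bounds and nested closed form hold on random pairs", {
  for (seed in 1:20) {
    rngs <- rand_rect_ranges(2, seed = seed)
    ab <- spatial_congruence(rngs[1, ], rngs[2, ])
    ba <- spatial_congruence(rngs[2, ], rngs[1, ])
    expect_identical(ab, ba)
    expect_gte(ab, 0)
    expect_lte(ab, 1)
  }
  # nested pairs: cs equals the area ratio exactly
  withr::with_seed(7, {
    for (i in 1:10) {
      x0 <- runif(1, 0, 50); y0 <- runif(1, 0, 50)
      w <- runif(1, 10, 40); h <- runif(1, 10, 40)
      fx <- runif(2, 0.2, 0.8)
      inner <- choroscan:::poly_rect(x0 + 1, x0 + 1 + fx[1] * (w - 2),
                                     y0 + 1, y0 + 1 + fx[2] * (h - 2))
      outer <- choroscan:::poly_rect(x0, x0 + w, y0, y0 + h)
      expect_equal(spatial_congruence(inner, outer),
                   choroscan:::poly_area(inner) /
                     choroscan:::poly_area(outer),
                   tolerance = 1e-6)
    }
  })
})

test_that("translating a range away never increases congruence", {
  base <- parse_wkt(rect_wkt(0, 10, 0, 10))
  shifts <- seq(0, 12, by = 1)
  cs <- vapply(shifts, function(s) {
    spatial_congruence(base, parse_wkt(rect_wkt(s, s + 10, 0, 10)))
  }, numeric(1))
  expect_true(all(diff(cs) <= 1e-12))
  expect_equal(cs[1], 1)
  expect_equal(cs[length(cs)], 0)
})

test_that("common and total areas follow intersection and union", {
  # bars with C = [2,14]: common [2,10] = 8, total [0,14] = 14
  trio <- species_ranges(data.frame(
    species_id = c("A", "B", "C"),
    wkt = c(rect_wkt(0, 10, 0, 1), rect_wkt(0, 12, 0, 1),
            rect_wkt(2, 14, 0, 1))))
  ct <- common_total_area(trio)
  expect_equal(ct$common_area, 8, tolerance = 1e-6)
  expect_equal(ct$total_area, 14, tolerance = 1e-6)
  expect_equal(ct$ratio, 8 / 14, tolerance = 1e-6)

  one <- common_total_area(trio, "B")
  expect_equal(one$common_area, one$total_area)
  expect_equal(one$common_area, 12)

  apart <- species_ranges(data.frame(
    species_id = c("u", "v"),
    wkt = c(rect_wkt(0, 1, 0, 1), rect_wkt(10, 12, 0, 1))))
  ct2 <- common_total_area(apart)
  expect_equal(ct2$common_area, 0)
  expect_equal(ct2$total_area, 3)

  # invariant: common <= each member area <= total on random sets
  for (seed in 1:5) {
    rngs <- rand_rect_ranges(4, seed = 100 + seed)
    ct3 <- common_total_area(rngs)
    expect_lte(ct3$common_area, min(rngs$area) + 1e-9)
    expect_gte(ct3$total_area, max(rngs$area) - 1e-9)
    expect_gte(ct3$ratio, 0)
    expect_lte(ct3$ratio, 1)
  }
})

test_that("edge lists are written with fixed formatting", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_edges_csv(congruence_network(bars_abc(), store_floor = 0), f)
  got <- utils::read.csv(f)
  expect_equal(names(got), c("species_a", "species_b", "overlap_area", "cs"))
  expect_equal(got$cs[1], 0.833333, tolerance = 1e-6)
})
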