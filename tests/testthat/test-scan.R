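# The threshold-sweep expansion on the three-bar community, traced by
# hand: cs(A,B) = 0.8333, cs(B,C) = 0.5952, cs(A,C) = 0.4571.

bars <- bars_abc()
bars_net <- congruence_network(bars, store_floor = 0)

test_that("expansion admits direct and indirect congruences level by level", {
  ex <- expand_at_threshold(bars_net, bars, "A", 0.80)
  expect_true(ex$closed)
  expect_equal(sort(ex$members$species_id), c("A", "B"))
  expect_equal(ex$closure_depth, 1)

  ex2 <- expand_at_threshold(bars_net, bars, "A", 0.59)
  expect_true(ex2$closed)
  expect_equal(sort(ex2$members$species_id), c("A", "B", "C"))
  expect_equal(ex2$closure_depth, 2)
  m <- ex2$members
  expect_equal(m$depth[m$species_id == "C"], 2L)
  expect_equal(m$via[m$species_id == "C"], "B")  # C joins through B
  expect_lt(m$cs_to_reference[m$species_id == "C"], 0.59)

  ex3 <- expand_at_threshold(bars_net, bars, "A", 0.90)
  expect_true(ex3$closed)
  expect_equal(ex3$members$species_id, "A")  # singleton closure
  expect_equal(ex3$closure_depth, 0)

  ex4 <- expand_at_threshold(bars_net, bars, "A", 0.59,
                             params = scan_params(max_depth = 1))
  expect_false(ex4$closed)
  expect_equal(ex4$failure, "max_depth_reached")

  expect_error(expand_at_threshold(bars_net, bars, "Z", 0.5), "Z")
})

test_that("a reference sweep merges stable compositions into partials", {
  ch <- scan_reference(bars_net, bars, "A")
  expect_true(ch$informative)
  expect_equal(ch$termination, "min_ct_reached")
  expect_equal(nrow(ch$partials), 2)
  expect_equal(sort(ch$partials$species[[1]]), c("A", "B"))
  expect_equal(ch$partials$ct_max[1], 0.83)
  expect_equal(ch$partials$ct_min[1], 0.60)
  expect_equal(sort(ch$partials$species[[2]]), c("A", "B", "C"))
  expect_equal(ch$partials$ct_max[2], 0.59)
  expect_equal(ch$partials$ct_min[2], 0.10)
  expect_equal(ch$partials$depth, c(1L, 2L))
  # area metrics of the full set: common [2,10] = 8, total [0,16] = 16
  expect_equal(ch$partials$common_area[2], 8)
  expect_equal(ch$partials$total_area[2], 16)

  shallow <- scan_reference(bars_net, bars, "A",
                            params = scan_params(max_depth = 1))
  expect_equal(nrow(shallow$partials), 1)
  expect_equal(shallow$partials$ct_min[1], 0.60)
  expect_equal(shallow$termination, "max_depth_reached")
})

test_that("references with no congruent ranges are non-informative", {
  lone <- species_ranges(data.frame(
    species_id = c("A", "B"),
    wkt = c(rect_wkt(0, 1, 0, 1), rect_wkt(50, 51, 0, 1))))
  net <- congruence_network(lone, store_floor = 0)
  ch <- scan_reference(net, lone, "A")
  expect_false(ch$informative)
  expect_equal(nrow(ch$partials), 0)
  expect_equal(ch$termination, "min_ct_reached")
  expect_equal(nrow(tidy(ch)), 0)
})

test_that("scan_all treats references independently over the shared pool", {
  res <- scan_all(bars_net, bars)
  expect_true(all(vapply(res$chorotypes, `[[`, logical(1), "informative")))
  finals <- lapply(res$chorotypes, function(ch) {
    sort(ch$partials$species[[nrow(ch$partials)]])
  })
  for (f in finals) expect_equal(f, c("A", "B", "C"))

  empty <- scan_all(bars_net, bars, references = character(0))
  expect_equal(length(empty$chorotypes), 0)

  only_a <- scan_all(bars_net, bars, references = "A")
  expect_equal(names(only_a$chorotypes), "A")
  # B and C still participate as members of A's partials
  expect_true(all(c("B", "C") %in%
                    unlist(scan_partials(only_a)$species)))

  expect_error(scan_all(bars_net, bars, references = c("A", "nope")),
               "nope")
})

test_that("closed expansions equal the threshold-graph component (oracle)", {
  n_comm <- 60
  withr::with_seed(42, {
    for (i in seq_len(n_comm)) {
      n <- sample(4:12, 1)
      rngs <- rand_rect_ranges(n, seed = 1000 + i, window = 60)
      net <- congruence_network(rngs, store_floor = 0)
      ct <- runif(1, 0.1, 0.9)
      ref <- sample(rngs$species_id, 1)
      off <- scan_params(max_depth = 50, overlap_criterion = FALSE)
      ex <- expand_at_threshold(net, rngs, ref, ct, off)
      expect_true(ex$closed)
      expect_equal(sort(ex$members$species_id),
                   oracle_component(rngs, ref, ct))
      # with the criterion on, a closed group still matches the
      # component and has positive common area
      on <- scan_params(max_depth = 50, overlap_criterion = TRUE)
      ex2 <- expand_at_threshold(net, rngs, ref, ct, on)
      if (ex2$closed) {
        expect_equal(sort(ex2$members$species_id),
                     oracle_component(rngs, ref, ct))
        if (nrow(ex2$members) > 1) {
          cta <- common_total_area(rngs, ex2$members$species_id)
          expect_gt(cta$common_area, 0)
        }
      }
    }
  })
})

test_that("lowering the threshold never shrinks the closed group", {
  off <- scan_params(max_depth = 50, overlap_criterion = FALSE)
  withr::with_seed(11, {
    for (i in 1:10) {
      rngs <- rand_rect_ranges(8, seed = 2000 + i, window = 60)
      net <- congruence_network(rngs, store_floor = 0)
      ref <- rngs$species_id[1]
      cts <- c(0.8, 0.6, 0.4, 0.2)
      sets <- lapply(cts, function(ct) {
        expand_at_threshold(net, rngs, ref, ct, off)$members$species_id
      })
      for (k in seq_along(sets)[-1]) {
        expect_true(all(sets[[k - 1]] %in% sets[[k]]))
      }
    }
  })
})

test_that("closure is symmetric in the reference when the criterion is off", {
  off <- scan_params(max_depth = 50, overlap_criterion = FALSE)
  withr::with_seed(5, {
    for (i in 1:10) {
      rngs <- rand_rect_ranges(8, seed = 3000 + i, window = 60)
      net <- congruence_network(rngs, store_floor = 0)
      ct <- runif(1, 0.2, 0.7)
      s0 <- expand_at_threshold(net, rngs, rngs$species_id[1], ct,
                                off)$members$species_id
      for (s in s0) {
        expect_equal(
          sort(expand_at_threshold(net, rngs, s, ct, off)$members$species_id),
          sort(s0))
      }
    }
  })
})

test_that("closure depth respects the limit and partials are never singletons", {
  g <- kj_gradient()
  for (md in c(1, 3)) {
    res <- scan_ranges(g, references = c("S12", "N17"),
                       params = scan_params(max_depth = md))
    parts <- scan_partials(res)
    if (nrow(parts)) {
      expect_true(all(parts$depth <= md))
      expect_true(all(parts$richness >= 2))
    }
    for (ch in res$chorotypes) {
      expect_true(all(ch$log$closure_depth <= md))
    }
  }
})

test_that("the threshold grid is an exact descending decimal sequence", {
  g <- choroscan:::ct_grid(scan_params())
  expect_equal(g[1], 1)
  expect_equal(g[length(g)], 0.1)
  expect_equal(length(g), 91)
  expect_true(all(abs(diff(g) + 0.01) < 1e-12))
  g2 <- choroscan:::ct_grid(scan_params(ct_max = 0.955, ct_min = 0.9,
                                        ct_step = 0.01))
  expect_equal(g2, 0.955 - 0:5 * 0.01)
})
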