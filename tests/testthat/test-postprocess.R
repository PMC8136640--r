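bars <- bars_abc()
bars_net <- congruence_network(bars, store_floor = 0)
bars_res <- scan_all(bars_net, bars)

test_that("partial chorotypes deduplicate by exact composition", {
  uniq <- unique_partial_chorotypes(bars_res)
  expect_equal(nrow(uniq), 2)  # {A,B} and {A,B,C} from all three refs
  keys <- vapply(uniq$species, paste, character(1), collapse = ",")
  expect_setequal(keys, c("A,B", "A,B,C"))
  full <- uniq[keys == "A,B,C", ]
  expect_equal(full$n_references, 3)
  # widest interval observed across references is kept
  expect_equal(full$ct_min, 0.10)

  single <- scan_all(bars_net, bars, references = "A")
  expect_equal(nrow(unique_partial_chorotypes(single)), 2)

  empty <- scan_all(bars_net, bars, references = character(0))
  expect_equal(nrow(unique_partial_chorotypes(empty)), 0)
  expect_equal(informative_species(empty), character(0))
})

test_that("synonymous chorotypes are grouped and named by mean congruence", {
  fam <- find_synonyms(bars_res, bars_net)
  expect_equal(nrow(fam), 1)
  # means to the other members: A 0.645, B 0.714, C 0.526
  expect_equal(fam$name, "B")
  expect_setequal(fam$synonyms[[1]], c("A", "B", "C"))
  expect_setequal(fam$canonical[[1]], c("A", "B", "C"))
  expect_equal(fam$richness, 3)

  # two spatially separate pairs give two singleton families
  quads <- species_ranges(data.frame(
    species_id = c("P1", "P2", "Q1", "Q2"),
    wkt = c(rect_wkt(0, 10, 0, 10), rect_wkt(0, 10, 0, 10),
            rect_wkt(100, 110, 0, 10), rect_wkt(100, 110, 0, 10))))
  qnet <- congruence_network(quads, store_floor = 0)
  qres <- scan_all(qnet, quads)
  qfam <- find_synonyms(qres, qnet)
  expect_equal(nrow(qfam), 2)
  expect_equal(sort(qfam$richness), c(2L, 2L))

  # non-informative references are excluded from families
  lone <- species_ranges(data.frame(
    species_id = c("A", "B", "far"),
    wkt = c(rect_wkt(0, 10, 0, 1), rect_wkt(0, 10, 0, 1),
            rect_wkt(500, 510, 0, 1))))
  lnet <- congruence_network(lone, store_floor = 0)
  lres <- scan_all(lnet, lone)
  lfam <- find_synonyms(lres, lnet)
  expect_false("far" %in% unlist(lfam$synonyms))
})

test_that("family naming is invariant to reference order", {
  for (perm in list(c("A", "B", "C"), c("C", "A", "B"), c("B", "C", "A"))) {
    res <- scan_all(bars_net, bars, references = perm)
    expect_equal(find_synonyms(res, bars_net)$name, "B")
  }
})

test_that("nesting is the strict-subset partial order", {
  uniq <- unique_partial_chorotypes(bars_res)
  nested <- find_nested(uniq)
  expect_equal(nrow(nested), 1)
  expect_equal(uniq$species[[nested$set]], c("A", "B"))
  expect_equal(uniq$species[[nested$superset]], c("A", "B", "C"))

  expect_equal(nrow(find_nested(list(c("a", "b"), c("a", "b")))), 0)
  expect_equal(nrow(find_nested(list(c("a", "b"), c("c", "d")))), 0)

  # irreflexive and transitive on a random collection
  withr::with_seed(9, {
    sets <- replicate(12, sort(sample(letters[1:8], sample(2:6, 1))),
                      simplify = FALSE)
    rel <- find_nested(sets)
    expect_false(any(rel$set == rel$superset))
    if (nrow(rel) > 1) {
      for (i in seq_len(nrow(rel))) {
        nxt <- rel[rel$set == rel$superset[i], ]
        for (j in seq_len(nrow(nxt))) {
          expect_true(any(rel$set == rel$set[i] &
                            rel$superset == nxt$superset[j]))
        }
      }
    }
  })
})

test_that("independent overlaps pair species-disjoint but stacked families", {
  # a small highland group sitting entirely over a large lowland group
  tepui <- species_ranges(data.frame(
    species_id = c("L1", "L2", "T1", "T2"),
    wkt = c(rect_wkt(0, 100, 0, 100), rect_wkt(0, 100, 0, 100),
            rect_wkt(40, 50, 40, 50), rect_wkt(40, 50, 40, 50))))
  net <- congruence_network(tepui, store_floor = 0)
  res <- scan_all(net, tepui)
  fam <- find_synonyms(res, net)
  expect_equal(nrow(fam), 2)
  ind <- find_independent_overlaps(fam, tepui)
  expect_equal(nrow(ind), 1)
  expect_equal(ind$shared_area, 100)

  # families sharing species are never "independent"
  fam_bars <- find_synonyms(bars_res, bars_net)
  expect_equal(nrow(find_independent_overlaps(fam_bars, bars)), 0)

  # geographically disjoint families are excluded
  apart <- species_ranges(data.frame(
    species_id = c("P1", "P2", "Q1", "Q2"),
    wkt = c(rect_wkt(0, 10, 0, 10), rect_wkt(0, 10, 0, 10),
            rect_wkt(100, 110, 0, 10), rect_wkt(100, 110, 0, 10))))
  anet <- congruence_network(apart, store_floor = 0)
  afam <- find_synonyms(scan_all(anet, apart), anet)
  expect_equal(nrow(find_independent_overlaps(afam, apart)), 0)
})

test_that("summary counts informative species over the whole pool", {
  s <- informative_summary(bars_res)
  expect_equal(s$n_informative, 3)
  expect_equal(s$n_noninformative, 0)
  expect_equal(s$n_unique_partials, 2)

  with_d <- species_ranges(data.frame(
    species_id = c("A", "B", "C", "D"),
    wkt = c(rect_wkt(0, 10, 0, 1), rect_wkt(0, 12, 0, 1),
            rect_wkt(2, 16, 0, 1), rect_wkt(900, 910, 0, 1))))
  dnet <- congruence_network(with_d, store_floor = 0)
  dres <- scan_all(dnet, with_d)
  ds <- informative_summary(dres)
  expect_equal(ds$n_informative, 3)
  expect_equal(ds$n_noninformative, 1)
  expect_false("D" %in% informative_species(dres))

  # membership alone confers informative status: D not a reference
  only_ab <- scan_all(dnet, with_d, references = c("A", "B"))
  expect_true("C" %in% informative_species(only_ab))
})

test_that("zone partition maximises mutually disjoint covering sets", {
  z <- disjoint_zones(list(c("a", "b"), c("c", "d"), c("a", "b", "c", "d")))
  expect_equal(z$n_zones, 2)
  # no exact cover -> 0 zones
  z2 <- disjoint_zones(list(c("a", "b"), c("b", "c")))
  expect_equal(z2$n_zones, 0)
  z3 <- disjoint_zones(unique_partial_chorotypes(bars_res))
  expect_equal(z3$n_zones, 1)
})
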