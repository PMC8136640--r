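# Cross-reference analysis of scan results: deduplicated partial
# chorotypes, synonymous and nested chorotypes, independent overlaps,
# and summary counts.

set_key <- function(species) paste(sort(species), collapse = "\r")

#' Deduplicate partial chorotypes by composition
#'
#' Pools the partial chorotypes of a scan result (or a list of scan
#' results, e.g. runs at several depth limits) and keeps one row per
#' distinct species set, with the widest threshold interval observed and
#' the list of references that generated it.
#'
#' @param result A `scan_result`, or a list of `scan_result` objects to
#'   pool.
#' @return A tibble with one row per unique species set: `species`
#'   (list column, sorted ids), `richness`, `ct_max`, `ct_min`,
#'   `n_references`, `references` (list column), `common_area`,
#'   `total_area`, `ratio`.
#' @export
unique_partial_chorotypes <- function(result) {
  if (inherits(result, "scan_result")) result <- list(result)
  stopifnot(all(vapply(result, inherits, logical(1), "scan_result")))
  parts <- purrr::map_dfr(result, scan_partials)
  if (!nrow(parts)) {
    return(tibble::tibble(species = list(), richness = integer(0),
                          ct_max = numeric(0), ct_min = numeric(0),
                          n_references = integer(0), references = list(),
                          common_area = numeric(0), total_area = numeric(0),
                          ratio = numeric(0)))
  }
  parts |>
    dplyr::mutate(.key = vapply(.data$species, set_key, character(1))) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      species = list(sort(.data$species[[1]])),
      richness = .data$richness[1],
      ct_max = max(.data$ct_max),
      ct_min = min(.data$ct_min),
      n_references = dplyr::n_distinct(.data$reference),
      references = list(sort(unique(.data$reference))),
      common_area = .data$common_area[1],
      total_area = .data$total_area[1],
      ratio = .data$ratio[1],
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$ct_max), .data$.key) |>
    dplyr::select(-".key")
}

#' Informative species of a scan result
#'
#' A species is biogeographically informative when it gives rise to at
#' least one partial chorotype as a reference, or composes one as a
#' member — membership confers the status even on species never used as
#' references.
#'
#' @param result A `scan_result`.
#' @return Sorted character vector of informative species ids.
#' @export
informative_species <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  parts <- scan_partials(result)
  if (!nrow(parts)) return(character(0))
  sort(unique(unlist(parts$species)))
}

#' Group synonymous chorotypes into families
#'
#' Chorotypes from distinct references that converge on the same species
#' set are synonyms.  By default convergence is judged on the final
#' (largest, lowest-threshold) partial of each informative reference;
#' `mode = "full"` requires the complete partial lists to match.  Each
#' family is named after the reference with the highest mean congruence
#' to all other members of the canonical set (ties broken by id order).
#'
#' @param result A `scan_result`.
#' @param network The `congruence_network` used for the scan (needed for
#'   the naming rule).
#' @param mode `"final"` (default) or `"full"`.
#' @return A tibble with one row per family: `name`, `canonical`
#'   (species list column), `richness`, `synonyms` (list column of
#'   references in the family), `n_synonyms`.
#' @export
find_synonyms <- function(result, network, mode = c("final", "full")) {
  stopifnot(inherits(result, "scan_result"))
  mode <- match.arg(mode)
  chs <- purrr::keep(result$chorotypes, "informative")
  if (!length(chs)) {
    return(tibble::tibble(name = character(0), canonical = list(),
                          richness = integer(0), synonyms = list(),
                          n_synonyms = integer(0)))
  }
  keys <- vapply(chs, function(ch) {
    sets <- lapply(ch$partials$species, set_key)
    if (mode == "final") sets[[length(sets)]] else paste(sets, collapse = "\n")
  }, character(1))
  finals <- lapply(chs, function(ch) {
    sort(ch$partials$species[[nrow(ch$partials)]])
  })
  fam_keys <- unique(keys)
  rows <- lapply(fam_keys, function(k) {
    refs <- sort(names(chs)[keys == k])
    canonical <- finals[[which(keys == k)[1]]]
    name <- naming_reference(refs, canonical, network)
    rich <- length(canonical)
    tibble::tibble(name = name, canonical = list(canonical),
                   richness = rich,
                   synonyms = list(refs), n_synonyms = length(refs))
  })
  dplyr::arrange(purrr::list_rbind(rows), .data$name)
}

# Mean congruence of each candidate reference to all OTHER members of
# the canonical set; highest mean wins, ties broken lexicographically.
naming_reference <- function(refs, canonical, network) {
  means <- vapply(refs, function(r) {
    others <- setdiff(canonical, r)
    if (!length(others)) return(0)
    mean(network_cs(network, rep(r, length(others)), others))
  }, numeric(1))
  refs <- refs[order(-means, refs, method = "radix")]
  refs[1]
}

#' Nesting relations among unique partial chorotypes
#'
#' All strict-subset pairs among the deduplicated species sets.
#'
#' @param uniques A tibble from [unique_partial_chorotypes()], or a bare
#'   list of character vectors.
#' @return A tibble with columns `set` and `superset` (indices into
#'   `uniques`), `set_richness` and `superset_richness`.
#' @export
find_nested <- function(uniques) {
  sets <- if (is.data.frame(uniques)) uniques$species else uniques
  n <- length(sets)
  out <- list()
  if (n > 1) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (length(sets[[i]]) < length(sets[[j]]) &&
            all(sets[[i]] %in% sets[[j]])) {
          out[[length(out) + 1L]] <- tibble::tibble(
            set = i, superset = j,
            set_richness = length(sets[[i]]),
            superset_richness = length(sets[[j]]))
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(set = integer(0), superset = integer(0),
                          set_richness = integer(0),
                          superset_richness = integer(0)))
  }
  purrr::list_rbind(out)
}

#' Chorotype families that overlap in space with no species in common
#'
#' Detects pairs of chorotype families whose canonical species sets are
#' disjoint yet whose union geometries intersect with positive area —
#' independent patterns stacked over the same region (e.g. a highland
#' group overlying a lowland one).
#'
#' @param families A tibble from [find_synonyms()].
#' @param ranges The `species_ranges` pool.
#' @return A tibble with columns `family_a`, `family_b` (family names)
#'   and `shared_area`.
#' @export
find_independent_overlaps <- function(families, ranges) {
  n <- nrow(families)
  unions <- lapply(families$canonical, function(sp) {
    Reduce(poly_union, ranges$geometry[range_lookup(ranges, sp)])
  })
  out <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (length(intersect(families$canonical[[i]],
                             families$canonical[[j]]))) next
        shared <- poly_overlap_area(unions[[i]], unions[[j]])
        if (shared > 0) {
          out[[length(out) + 1L]] <- tibble::tibble(
            family_a = families$name[i], family_b = families$name[j],
            shared_area = shared)
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(family_a = character(0), family_b = character(0),
                          shared_area = numeric(0)))
  }
  purrr::list_rbind(out)
}

#' Summary counts of a scan result
#'
#' @param result A `scan_result`.
#' @return A list with `n_references`, `n_species_pool`,
#'   `n_informative`, `n_noninformative` (both over the whole pool),
#'   `n_partials`, `n_unique_partials` and the `richness` distribution
#'   of unique partials (a tibble of `richness`, `n`).
#' @export
informative_summary <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  inf <- informative_species(result)
  uniq <- unique_partial_chorotypes(result)
  list(n_references = length(result$references),
       n_species_pool = length(result$species),
       n_informative = length(inf),
       n_noninformative = length(result$species) - length(inf),
       n_partials = nrow(scan_partials(result)),
       n_unique_partials = nrow(uniq),
       richness = dplyr::count(uniq, .data$richness, name = "n"))
}

#' Maximal partition into non-overlapping zones
#'
#' Among a collection of unique partial chorotypes, finds the largest
#' collection of mutually species-disjoint sets that jointly cover every
#' grouped species, i.e. the finest classification of the region into
#' non-overlapping zones supported by the recovered patterns.  Exact
#' branch-and-bound search; intended for the tens of sets a desk-scale
#' analysis produces.
#'
#' @param uniques A tibble from [unique_partial_chorotypes()], or a bare
#'   list of character vectors.
#' @return A list with `n_zones` (0 if no exact cover exists) and
#'   `zones` (list of species sets of one maximal cover).
#' @export
disjoint_zones <- function(uniques) {
  sets <- if (is.data.frame(uniques)) uniques$species else uniques
  sets <- lapply(sets, sort)
  grouped <- sort(unique(unlist(sets)))
  best <- list(n = 0L, zones = list())
  recurse <- function(remaining, chosen) {
    if (!length(remaining)) {
      if (length(chosen) > best$n) {
        best <<- list(n = length(chosen), zones = chosen)
      }
      return()
    }
    target <- remaining[1]
    for (s in sets) {
      if (target %in% s && all(s %in% remaining)) {
        recurse(setdiff(remaining, s), c(chosen, list(s)))
      }
    }
  }
  if (length(grouped)) recurse(grouped, list())
  list(n_zones = best$n, zones = best$zones)
}
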