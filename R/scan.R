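# The threshold-sweep breadth-first expansion at the heart of the method.
#
# For one reference species and one congruence threshold ct, expansion
# proceeds level by level: level 1 admits every species directly
# congruent to the reference (cs >= ct), level k admits every new
# species congruent to a level k-1 member.  The group "closes" when a
# level admits nobody.  A reference is swept from ct_max down to ct_min
# on an exact decimal grid; every closed non-singleton list is a partial
# chorotype, and the set of all partials from one reference is its
# chorotype.

#' Control parameters for a scan
#'
#' @param max_depth Maximum number of breadth-first passes allowed for a
#'   group to close (reference sits at depth 0, directly congruent
#'   species at depth 1).  Default 7.
#' @param ct_max,ct_min Highest and lowest congruence thresholds of the
#'   sweep, with `0 < ct_min <= ct_max <= 1`.  Defaults 1 and 0.1.
#' @param ct_step Threshold resolution (grid spacing of the sweep).
#'   Default 0.01.
#' @param overlap_criterion If `TRUE` (default), every species joining a
#'   group must share positive overlap area with the running common area
#'   of all previously grouped species; a congruent candidate that
#'   fails this test invalidates the whole threshold round and ends the
#'   reference's sweep.
#' @param cs_epsilon Float tolerance for `cs >= ct` comparisons.
#' @return A `scan_params` list.
#' @export
scan_params <- function(max_depth = 7, ct_max = 1, ct_min = 0.1,
                        ct_step = 0.01, overlap_criterion = TRUE,
                        cs_epsilon = 1e-9) {
  stopifnot(length(max_depth) == 1, max_depth >= 1,
            max_depth == as.integer(max_depth),
            ct_min > 0, ct_min <= ct_max, ct_max <= 1,
            ct_step > 0, cs_epsilon >= 0)
  structure(list(max_depth = as.integer(max_depth), ct_max = ct_max,
                 ct_min = ct_min, ct_step = ct_step,
                 overlap_criterion = isTRUE(overlap_criterion),
                 cs_epsilon = cs_epsilon),
            class = "scan_params")
}

# Exact decimal threshold grid, descending, computed from integer
# multiples of ct_step so ~90 subtractions cannot drift.
ct_grid <- function(params) {
  k_hi <- round(params$ct_max / params$ct_step)
  if (abs(k_hi * params$ct_step - params$ct_max) < 1e-9) {
    k_lo <- ceiling(params$ct_min / params$ct_step - 1e-9)
    (k_hi:k_lo) * params$ct_step
  } else {
    n <- floor((params$ct_max - params$ct_min) / params$ct_step + 1e-9)
    params$ct_max - (0:n) * params$ct_step
  }
}

# Internal scan context: dense congruence matrix + geometry list, all
# indexed by position in the species pool.
scan_context <- function(network, ranges) {
  sp <- network_species(network)
  idx <- range_lookup(ranges, sp)
  list(sp = sp,
       csm = cs_matrix(network),
       geoms = ranges$geometry[idx],
       areas = ranges$area[idx])
}

expand_impl <- function(ctx, ref, ct, params) {
  eps <- params$cs_epsilon
  n <- length(ctx$sp)
  members <- ref
  depth <- 0L
  via <- NA_integer_
  common <- if (params$overlap_criterion) ctx$geoms[[ref]] else NULL
  frontier <- ref
  lev <- 0L
  repeat {
    hit <- ctx$csm[, frontier, drop = FALSE] >= ct - eps
    cand <- setdiff(which(rowSums(hit) > 0), members)
    if (length(cand) == 0) {
      return(list(closed = TRUE, failure = NA_character_, members = members,
                  depth = depth, via = via, closure_depth = lev))
    }
    if (lev + 1L > params$max_depth) {
      return(list(closed = FALSE, failure = "max_depth_reached",
                  members = members, depth = depth, via = via,
                  closure_depth = lev))
    }
    # deterministic admission order: descending best congruence to the
    # frontier, ties broken by species id
    best <- apply(ctx$csm[cand, frontier, drop = FALSE], 1, max)
    ord <- order(-best, ctx$sp[cand], method = "radix")
    cand <- cand[ord]
    for (cd in cand) {
      if (params$overlap_criterion) {
        floor_area <- 1e-12 * min(ctx$areas[cd], poly_area(common))
        inter <- poly_intersect(common, ctx$geoms[[cd]])
        if (poly_area(inter) <= floor_area) {
          return(list(closed = FALSE, failure = "overlap_violated",
                      members = members, depth = depth, via = via,
                      closure_depth = lev))
        }
        common <- inter
      }
      link_cs <- ctx$csm[cd, frontier]
      lk <- frontier[link_cs == max(link_cs)]
      members <- c(members, cd)
      depth <- c(depth, lev + 1L)
      via <- c(via, lk[order(ctx$sp[lk])][1])
    }
    frontier <- cand
    lev <- lev + 1L
  }
}

#' Breadth-first group expansion at one threshold
#'
#' Expands a group from `reference` at congruence threshold `ct`:
#' level 1 holds every species with `cs >= ct` to the reference, level k
#' every new species with `cs >= ct` to a level k-1 member.  The
#' expansion closes when a level admits no species; it fails with
#' `max_depth_reached` when species were admitted at the depth limit and
#' a further pass would admit more, and (with the spatial overlap
#' criterion on) with `overlap_violated` when a congruent candidate
#' shares no area with the intersection of all current members' ranges.
#'
#' @param network A `congruence_network`.
#' @param ranges The `species_ranges` pool backing the network.
#' @param reference A species id present in the network.
#' @param ct Congruence threshold in `[0, 1]`.
#' @param params A [scan_params()] object.
#' @return A `group_expansion`: list with `reference`, `ct`, `members`
#'   (tibble of `species_id`, `depth`, `via`, `cs_to_reference`),
#'   `closed`, `closure_depth` and `failure`
#'   (`NA`, `"max_depth_reached"` or `"overlap_violated"`).
#' @export
expand_at_threshold <- function(network, ranges, reference, ct,
                                params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  ctx <- scan_context(network, ranges)
  ref <- match(reference, ctx$sp)
  if (is.na(ref)) stop("unknown reference species: ", reference)
  ex <- expand_impl(ctx, ref, ct, params)
  members <- tibble::tibble(
    species_id = ctx$sp[ex$members],
    depth = ex$depth,
    via = ifelse(is.na(ex$via), NA_character_, ctx$sp[ex$via]),
    cs_to_reference = ctx$csm[ex$members, ref])
  structure(list(reference = reference, ct = ct, members = members,
                 closed = ex$closed, closure_depth = ex$closure_depth,
                 failure = ex$failure),
            class = "group_expansion")
}

#' @export
print.group_expansion <- function(x, ...) {
  state <- if (x$closed) {
    sprintf("closed at depth %d", x$closure_depth)
  } else {
    sprintf("failed (%s)", x$failure)
  }
  cat(sprintf("<group_expansion> reference %s at ct = %.4g: %s, %d member(s)\n",
              x$reference, x$ct, state, nrow(x$members)))
  invisible(x)
}

sweep_impl <- function(ctx, ref, params) {
  grid <- ct_grid(params)
  partials <- list()
  log_ct <- numeric(0); log_closed <- logical(0)
  log_n <- integer(0); log_depth <- integer(0)
  open <- NULL  # currently merging partial
  termination <- "min_ct_reached"

  flush <- function(open) {
    if (is.null(open)) return(NULL)
    open
  }

  for (ct in grid) {
    ex <- expand_impl(ctx, ref, ct, params)
    log_ct <- c(log_ct, ct); log_closed <- c(log_closed, ex$closed)
    log_n <- c(log_n, length(ex$members))
    log_depth <- c(log_depth, ex$closure_depth)
    if (!ex$closed) {
      termination <- ex$failure
      break
    }
    if (length(ex$members) < 2) next  # singleton closure: skip silently
    key <- paste(sort(ctx$sp[ex$members]), collapse = "\r")
    if (!is.null(open) && open$key == key) {
      open$ct_min <- ct
      open$min_depth <- pmin(open$min_depth,
                             ex$depth[match(open$members, ex$members)])
    } else {
      if (!is.null(open)) partials[[length(partials) + 1L]] <- open
      ord <- order(ctx$sp[ex$members], method = "radix")
      open <- list(key = key,
                   members = ex$members[ord],
                   cs_to_ref = ctx$csm[ex$members[ord], ref],
                   min_depth = ex$depth[ord],
                   depth = ex$closure_depth,
                   ct_max = ct, ct_min = ct)
    }
  }
  if (!is.null(open)) partials[[length(partials) + 1L]] <- open
  list(partials = partials, termination = termination,
       log = tibble::tibble(ct = log_ct, closed = log_closed,
                            n_members = log_n, closure_depth = log_depth))
}

build_chorotype <- function(ctx, ref, sw, ranges) {
  ps <- sw$partials
  n <- length(ps)
  if (n) {
    areas <- lapply(ps, function(p) {
      common_total_area(ranges, ctx$sp[p$members])
    })
    partials <- tibble::tibble(
      partial = seq_len(n),
      species = lapply(ps, function(p) ctx$sp[p$members]),
      richness = vapply(ps, function(p) length(p$members), integer(1)),
      ct_max = vapply(ps, `[[`, numeric(1), "ct_max"),
      ct_min = vapply(ps, `[[`, numeric(1), "ct_min"),
      depth = vapply(ps, `[[`, integer(1), "depth"),
      common_area = vapply(areas, `[[`, numeric(1), "common_area"),
      total_area = vapply(areas, `[[`, numeric(1), "total_area"),
      ratio = vapply(areas, `[[`, numeric(1), "ratio"))
    members <- purrr::map_dfr(seq_len(n), function(i) {
      p <- ps[[i]]
      tibble::tibble(partial = i,
                     species_id = ctx$sp[p$members],
                     cs_to_reference = p$cs_to_ref,
                     min_depth = p$min_depth)
    })
  } else {
    partials <- tibble::tibble(partial = integer(0), species = list(),
                               richness = integer(0), ct_max = numeric(0),
                               ct_min = numeric(0), depth = integer(0),
                               common_area = numeric(0),
                               total_area = numeric(0), ratio = numeric(0))
    members <- tibble::tibble(partial = integer(0),
                              species_id = character(0),
                              cs_to_reference = numeric(0),
                              min_depth = integer(0))
  }
  structure(list(reference = ctx$sp[ref], partials = partials,
                 members = members, informative = n > 0,
                 termination = sw$termination, log = sw$log),
            class = "chorotype")
}

#' Sweep one reference species across the threshold grid
#'
#' Runs [expand_at_threshold()] at every threshold from `ct_max` down to
#' `ct_min` in steps of `ct_step`.  Singleton closures are skipped and
#' the sweep continues; consecutive thresholds closing on the identical
#' species set are merged into one partial chorotype spanning a
#' contiguous threshold interval.  The sweep ends at the first failing
#' threshold (`max_depth_reached` or `overlap_violated`) or when the
#' grid is exhausted (`min_ct_reached`).
#'
#' @inheritParams expand_at_threshold
#' @return A `chorotype`: list with `reference`, `partials` (one row per
#'   partial chorotype, highest thresholds first, with composition,
#'   threshold interval, closure depth and area metrics), `members`
#'   (per-partial member table with congruence to the reference and
#'   minimal depth over the interval), `informative` (at least one
#'   partial recorded), `termination` and the per-threshold `log`.
#' @export
scan_reference <- function(network, ranges, reference,
                           params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  ctx <- scan_context(network, ranges)
  ref <- match(reference, ctx$sp)
  if (is.na(ref)) stop("unknown reference species: ", reference)
  build_chorotype(ctx, ref, sweep_impl(ctx, ref, params), ranges)
}

#' @export
print.chorotype <- function(x, ...) {
  cat(sprintf("<chorotype> reference %s: %s, %d partial(s), termination %s\n",
              x$reference,
              if (x$informative) "informative" else "non-informative",
              nrow(x$partials), x$termination))
  if (nrow(x$partials)) print(x$partials)
  invisible(x)
}

#' Scan every reference species
#'
#' Runs [scan_reference()] independently for each reference.  References
#' may be any subset of the species pool: all pool species remain
#' available as members and indirect links.
#'
#' @inheritParams expand_at_threshold
#' @param references Character vector of reference species ids;
#'   default: every species in the network.  Unknown ids raise an error
#'   before any computation.
#' @return A `scan_result`: list with `chorotypes` (named list of
#'   `chorotype` objects), `references`, `species` (the pool) and
#'   `params`.
#' @export
scan_all <- function(network, ranges, references = NULL,
                     params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  ctx <- scan_context(network, ranges)
  if (is.null(references)) references <- ctx$sp
  refs <- match(references, ctx$sp)
  if (anyNA(refs)) {
    stop("unknown reference species: ",
         paste(references[is.na(refs)], collapse = ", "))
  }
  chorotypes <- lapply(refs, function(r) {
    build_chorotype(ctx, r, sweep_impl(ctx, r, params), ranges)
  })
  names(chorotypes) <- references
  structure(list(chorotypes = chorotypes,
                 references = references,
                 species = ctx$sp,
                 params = params),
            class = "scan_result")
}

#' Build a network and scan in one call
#'
#' Convenience wrapper: computes the congruence network from `ranges`
#' (storing edges down to `ct_min`, below which they can never
#' activate) and scans the given references.  The network is attached
#' to the result as `$network`.
#'
#' @inheritParams scan_all
#' @param ranges A `species_ranges` tibble.
#' @export
scan_ranges <- function(ranges, references = NULL, params = scan_params()) {
  network <- congruence_network(ranges, store_floor = params$ct_min)
  out <- scan_all(network, ranges, references, params)
  out$network <- network
  out
}

#' @export
print.scan_result <- function(x, ...) {
  inf <- sum(vapply(x$chorotypes, `[[`, logical(1), "informative"))
  cat(sprintf(paste0("<scan_result> %d reference(s) over a pool of %d",
                     " species: %d informative\n"),
              length(x$references), length(x$species), inf))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chorotype into the long partial-chorotype table
#'
#' One row per partial chorotype and member, with the member's direct
#' congruence to the reference and minimal depth over the threshold
#' interval, plus the partial's threshold interval, richness and area
#' metrics.
#'
#' @param x A `chorotype`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.chorotype <- function(x, ...) {
  if (!nrow(x$partials)) {
    return(tibble::tibble(reference = character(0), partial = integer(0),
                          member = character(0),
                          cs_to_reference = numeric(0),
                          min_depth = integer(0), ct_max = numeric(0),
                          ct_min = numeric(0), richness = integer(0),
                          common_area = numeric(0), total_area = numeric(0),
                          ratio = numeric(0)))
  }
  meta <- dplyr::select(x$partials, "partial", "ct_max", "ct_min",
                        "richness", "common_area", "total_area", "ratio")
  x$members |>
    dplyr::rename(member = "species_id") |>
    dplyr::left_join(meta, by = "partial") |>
    dplyr::mutate(reference = x$reference, .before = 1)
}

#' Tidy a scan result into the long partial-chorotype table
#'
#' Binds [tidy.chorotype()] over all references.
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @return A tibble with one row per reference, partial and member.
#' @export
tidy.scan_result <- function(x, ...) {
  purrr::map_dfr(x$chorotypes, tidy)
}

#' Per-partial summary of a scan result
#'
#' @param result A `scan_result`.
#' @return A tibble with one row per reference and partial chorotype
#'   (composition as a list column).
#' @export
scan_partials <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  purrr::map_dfr(result$chorotypes, function(ch) {
    if (!nrow(ch$partials)) return(NULL)
    dplyr::mutate(ch$partials, reference = ch$reference, .before = 1)
  })
}

#' One-row summary of a scan result
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @return A tibble with reference, informative, partial and richness
#'   counts.
#' @export
glance.scan_result <- function(x, ...) {
  parts <- scan_partials(x)
  inf <- informative_species(x)
  tibble::tibble(
    n_references = length(x$references),
    n_species_pool = length(x$species),
    n_informative_references =
      sum(vapply(x$chorotypes, `[[`, logical(1), "informative")),
    n_informative_species = length(inf),
    n_partials = nrow(parts),
    n_unique_partials = nrow(unique_partial_chorotypes(x)),
    max_richness = if (nrow(parts)) max(parts$richness) else 0L)
}

#' Per-reference termination log
#'
#' @param result A `scan_result`.
#' @return A tibble with one row per reference: informative status,
#'   termination reason, number of thresholds visited and the last
#'   threshold reached.
#' @export
scan_terminations <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  purrr::map_dfr(result$chorotypes, function(ch) {
    tibble::tibble(reference = ch$reference,
                   informative = ch$informative,
                   termination = ch$termination,
                   n_thresholds = nrow(ch$log),
                   last_ct = if (nrow(ch$log)) min(ch$log$ct) else NA_real_)
  })
}
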