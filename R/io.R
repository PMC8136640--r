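# End-to-end pipeline runner and plain-text configuration.

#' Run configuration for a full scan
#'
#' Bundles every input and parameter of an end-to-end run.  Configs
#' round-trip to YAML via [write_scan_config()] / [read_scan_config()].
#'
#' @param input Path to the range file, or `NULL` when `fixture` is
#'   used.
#' @param format Input format: `"wkt"` (CSV with `species_id`, `wkt`) or
#'   `"geojson"`.
#' @param fixture `NULL`, `"gradient"` or `"syndrome"`: generate the
#'   input internally instead of reading a file.
#' @param references Path to a plain-text file with one reference
#'   species id per line, or a character vector of ids, or `NULL`
#'   (default: all species are references).
#' @param projection Equal-area projection name for geographic input
#'   (see [project_lonlat()]), or `NULL` for planar input.
#' @param planar Assert planar coordinates for input whose coordinates
#'   look geographic.
#' @param out Output directory (created if missing).
#' @param seed Integer seed (only the `"syndrome"` fixture draws random
#'   numbers).
#' @param plot Also write a congruence-diagram figure per informative
#'   reference chorotype.
#' @inheritParams scan_params
#' @return A `scan_config` list.
#' @export
scan_config <- function(input = NULL, format = c("wkt", "geojson"),
                        fixture = NULL, references = NULL,
                        projection = NULL, planar = FALSE,
                        max_depth = 7, ct_max = 1, ct_min = 0.1,
                        ct_step = 0.01, overlap_criterion = TRUE,
                        cs_epsilon = 1e-9,
                        out = "scan_output", seed = 1, plot = FALSE) {
  format <- match.arg(format)
  if (!is.null(fixture)) {
    fixture <- match.arg(fixture, c("gradient", "syndrome"))
  }
  if (is.null(input) && is.null(fixture)) {
    stop("supply `input` or a `fixture`")
  }
  params <- scan_params(max_depth, ct_max, ct_min, ct_step,
                        overlap_criterion, cs_epsilon)
  structure(c(list(input = input, format = format, fixture = fixture,
                   references = references, projection = projection,
                   planar = isTRUE(planar), out = out,
                   seed = as.integer(seed), plot = isTRUE(plot)),
              unclass(params)),
            class = "scan_config")
}

#' Write or read a scan configuration
#'
#' @param config A [scan_config()].
#' @param path YAML file path.
#' @return `write_scan_config()` returns `path` invisibly;
#'   `read_scan_config()` returns a `scan_config`.
#' @export
write_scan_config <- function(config, path) {
  stopifnot(inherits(config, "scan_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_scan_config
#' @export
read_scan_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(scan_config, raw[!vapply(raw, is.null, logical(1))])
}

config_params <- function(config) {
  scan_params(config$max_depth, config$ct_max, config$ct_min,
              config$ct_step, config$overlap_criterion, config$cs_epsilon)
}

load_config_ranges <- function(config) {
  if (!is.null(config$fixture)) {
    switch(config$fixture,
           gradient = kj_gradient(),
           syndrome = syndrome_community(seed = config$seed))
  } else if (config$format == "wkt") {
    read_ranges_wkt(config$input, projection = config$projection,
                    planar = config$planar)
  } else {
    read_ranges_geojson(config$input, projection = config$projection,
                        planar = config$planar)
  }
}

load_config_references <- function(config, ranges) {
  refs <- config$references
  if (is.null(refs)) return(NULL)
  if (length(refs) == 1 && file.exists(refs)) {
    refs <- readLines(refs, warn = FALSE)
    refs <- trimws(refs)
    refs <- refs[nzchar(refs)]
  }
  missing <- setdiff(refs, ranges$species_id)
  if (length(missing)) {
    stop("reference species not in the pool: ",
         paste(missing, collapse = ", "))
  }
  refs
}

#' Run the full pipeline and write result files
#'
#' Loads (or generates) the range maps, builds the congruence network,
#' sweeps every reference, post-processes the chorotypes and writes:
#' `edges.csv` (congruence network), `partials.csv` (long
#' partial-chorotype table), `unique_partials.csv`, `families.csv`
#' (synonymous chorotypes), `nested.csv`, `summary.json` and
#' `scan_log.txt` (all parameters, thresholds visited and termination
#' reason per reference).  CSV numbers use fixed 6-decimal formatting,
#' so reruns with an identical config are byte-identical.
#'
#' @param config A [scan_config()].
#' @return Invisibly, a list with the `scan_result`, the network, the
#'   postprocessed tables and the output `paths`.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  params <- config_params(config)
  ranges <- load_config_ranges(config)
  references <- load_config_references(config, ranges)
  result <- scan_ranges(ranges, references, params)
  network <- result$network

  uniq <- unique_partial_chorotypes(result)
  families <- find_synonyms(result, network)
  nested <- find_nested(uniq)
  summ <- informative_summary(result)
  terminations <- scan_terminations(result)

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    edges = file.path(config$out, "edges.csv"),
    partials = file.path(config$out, "partials.csv"),
    unique_partials = file.path(config$out, "unique_partials.csv"),
    families = file.path(config$out, "families.csv"),
    nested = file.path(config$out, "nested.csv"),
    summary = file.path(config$out, "summary.json"),
    log = file.path(config$out, "scan_log.txt"))

  write_edges_csv(network, paths$edges)

  long <- tidy(result)
  long_out <- dplyr::mutate(long, dplyr::across(
    c("cs_to_reference", "ct_max", "ct_min",
      "common_area", "total_area", "ratio"), fixed6))
  utils::write.csv(long_out, paths$partials, row.names = FALSE, quote = FALSE)

  uniq_out <- data.frame(
    species = vapply(uniq$species, paste, character(1), collapse = ";"),
    richness = uniq$richness,
    ct_max = fixed6(uniq$ct_max), ct_min = fixed6(uniq$ct_min),
    n_references = uniq$n_references,
    references = vapply(uniq$references, paste, character(1),
                        collapse = ";"),
    common_area = fixed6(uniq$common_area),
    total_area = fixed6(uniq$total_area),
    ratio = fixed6(uniq$ratio))
  utils::write.csv(uniq_out, paths$unique_partials, row.names = FALSE,
                   quote = FALSE)

  fam_out <- data.frame(
    name = families$name,
    richness = families$richness,
    synonyms = vapply(families$synonyms, paste, character(1),
                      collapse = ";"),
    canonical = vapply(families$canonical, paste, character(1),
                       collapse = ";"))
  utils::write.csv(fam_out, paths$families, row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(nested), paths$nested, row.names = FALSE,
                   quote = FALSE)

  jsonlite::write_json(
    list(n_species_scanned = length(result$species),
         n_references = summ$n_references,
         n_informative = summ$n_informative,
         n_noninformative = summ$n_noninformative,
         n_partials = summ$n_partials,
         n_unique_partials = summ$n_unique_partials,
         n_families = nrow(families)),
    paths$summary, auto_unbox = TRUE, digits = NA)

  log_lines <- c(
    "# scan log",
    paste0("parameter max_depth: ", params$max_depth),
    paste0("parameter ct_max: ", params$ct_max),
    paste0("parameter ct_min: ", params$ct_min),
    paste0("parameter ct_step: ", params$ct_step),
    paste0("parameter overlap_criterion: ", params$overlap_criterion),
    paste0("parameter cs_epsilon: ", params$cs_epsilon),
    paste0("input: ", if (is.null(config$fixture)) config$input else
      paste0("fixture:", config$fixture)),
    paste0("species pool: ", length(result$species)),
    paste0("references: ", length(result$references)),
    "",
    "reference\tinformative\ttermination\tthresholds_visited\tlast_ct",
    sprintf("%s\t%s\t%s\t%d\t%s", terminations$reference,
            terminations$informative, terminations$termination,
            terminations$n_thresholds, fixed6(terminations$last_ct)))
  writeLines(log_lines, paths$log)

  if (config$plot) {
    for (ref in result$references) {
      ch <- result$chorotypes[[ref]]
      if (!ch$informative) next
      f <- file.path(config$out, paste0("diagram_", ref, ".pdf"))
      grDevices::pdf(f, width = 6, height = 4)
      print(ggplot2::autoplot(ch))
      grDevices::dev.off()
      paths[[paste0("diagram_", ref)]] <- f
    }
  }

  invisible(list(result = result, network = network, unique = uniq,
                 families = families, nested = nested, summary = summ,
                 paths = paths))
}
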