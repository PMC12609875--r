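# ---- readers / writers -------------------------------------------------------

#' Read an annotation table from CSV or JSON
#'
#' Reads per-foot, per-annotator landmark annotations in the declared
#' dialect: CSV with header
#' `foot_id,annotator_id,landmark_index,landmark_name,x,y`, or the JSON
#' equivalent (an array of row objects). The result is validated against the
#' 24-landmark schema by index *and* name; any malformed row or incomplete
#' (foot, annotator) group is a hard error naming the offender. Row order in
#' the file is irrelevant.
#'
#' @param path Path to a `.csv` or `.json` annotation file.
#' @return A validated long annotation tibble, ordered by foot, annotator,
#'   landmark index.
#' @seealso [write_annotations()], [merge_annotations()]
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::fromJSON(path)
    ann <- as_tibble(raw)
  } else {
    # readr warns about parse problems; they are converted to a precise error
    ann <- suppressWarnings(readr::read_csv(
      path,
      col_types = readr::cols(
        foot_id = readr::col_character(),
        annotator_id = readr::col_character(),
        landmark_index = readr::col_integer(),
        landmark_name = readr::col_character(),
        x = readr::col_double(),
        y = readr::col_double()
      )
    ))
    prob <- readr::problems(ann)
    if (nrow(prob) > 0) {
      abort(sprintf("malformed annotation row at line %d of %s: expected %s, got '%s'",
                    prob$row[1], path, prob$expected[1], prob$actual[1]))
    }
  }
  .check_annotation_cols(ann)
  ann <- ann |>
    mutate(landmark_index = as.integer(.data$landmark_index)) |>
    arrange(.data$foot_id, .data$annotator_id, .data$landmark_index)
  validate_annotations(ann)
  ann
}

#' Write an annotation table
#'
#' @param annotations A long annotation tibble.
#' @param path Output path; `.json` writes the JSON dialect, anything else
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  .check_annotation_cols(annotations)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(annotations, path, dataframe = "rows", digits = NA)
  } else {
    readr::write_csv(annotations, path)
  }
  invisible(path)
}

#' Write a consensus geometry table
#'
#' CSV with consensus coordinates plus the per-landmark dispersion and
#' annotator count produced by [merge_annotations()].
#'
#' @param geometry A consensus geometry tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  readr::write_csv(geometry, path)
  invisible(path)
}

#' Read a consensus geometry table
#'
#' @param path CSV written by [write_geometry()].
#' @return A consensus geometry tibble.
#' @export
read_geometry <- function(path) {
  g <- readr::read_csv(path, col_types = readr::cols(
    foot_id = readr::col_character(),
    landmark_index = readr::col_integer(),
    landmark_name = readr::col_character(),
    x = readr::col_double(), y = readr::col_double(),
    dispersion = readr::col_double(), n_annotators = readr::col_integer()
  ))
  .as_xy(g)  # validates completeness
  g
}

#' Write distances in long format
#'
#' CSV with header
#' `foot_id,landmark_i,landmark_j,pair_name,distance,normalized`.
#'
#' @param distances A distance tibble from [pairwise_distances()] or
#'   [normalize_distances()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(distances, path) {
  readr::write_csv(
    select(distances, "foot_id", "landmark_i", "landmark_j",
           "pair_name", "distance", "normalized"),
    path
  )
  invisible(path)
}

# ---- pipeline ----------------------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles the inputs, outputs and tunables of [run_pipeline()]. Threshold
#' overrides are validated with the same invariants as the defaults.
#'
#' @param input Path to an annotation CSV/JSON file.
#' @param out_dir Output directory (created if absent).
#' @param criteria Screening criteria, from [hv_screen_criteria()].
#' @param bands Severity bands, from [hv_severity_bands()] (validated).
#' @param fdr Use Benjamini-Hochberg adjusted p-values for flagging.
#' @param render Write heatmap/box-plot/overlay PNGs (with sidecars).
#' @param overlay_foot Foot id to draw overlays for; default the first foot.
#' @param seed Optional seed recorded in the manifest (the measurement
#'   pipeline itself is deterministic; the seed matters only when screening
#'   uses permutation p-values).
#' @return A list of class `hv_config`.
#' @export
hv_config <- function(input, out_dir,
                      criteria = hv_screen_criteria(),
                      bands = hv_severity_bands(),
                      fdr = FALSE, render = TRUE,
                      overlay_foot = NULL, seed = NULL) {
  .validate_bands(bands)
  if (!is.list(criteria) || !all(c("r_threshold", "alpha") %in% names(criteria))) {
    abort("criteria must come from hv_screen_criteria()")
  }
  structure(as.list(environment()), class = "hv_config")
}

.stage <- function(name, foot_id = NULL, expr) {
  tryCatch(expr, error = function(e) {
    ctx <- if (is.null(foot_id)) "" else paste0(" (foot '", foot_id, "')")
    abort(paste0("pipeline stage '", name, "'", ctx, " failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full annotation-to-screening pipeline
#'
#' Executes merge, measurement (angles + 276 normalized distances), severity
#' classification, correlation screening and rendering on an annotation file,
#' writing every artifact plus a JSON manifest (input hash, configuration,
#' package version, output hashes). Re-running with identical inputs and
#' configuration reproduces byte-identical data artifacts.
#'
#' @param config An [hv_config()] object.
#' @return The manifest, invisibly (also written to
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "hv_config")) abort("config must be created by hv_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  ann <- .stage("read", NULL, read_annotations(config$input))
  geometry <- .stage("merge", NULL, merge_annotations(ann))
  cohort <- .stage("measure", NULL,
                   measure_cohort(geometry, bands = config$bands))
  sev <- .stage("severity", NULL, summarize_severity(cohort))
  scr <- .stage("screen", NULL,
                screen_correlations(cohort, criteria = config$criteria,
                                    fdr = config$fdr, seed = config$seed))

  write_geometry(geometry, out("consensus.csv"))
  readr::write_csv(cohort, out("measures.csv"))
  readr::write_csv(sev, out("severity_summary.csv"))
  readr::write_csv(tidy(scr), out("correlations.csv"))

  files <- c("consensus.csv", "measures.csv", "severity_summary.csv", "correlations.csv")
  if (isTRUE(config$render)) {
    .stage("render", NULL, {
      render_correlation_heatmap(correlation_matrix(scr), out("heatmap.png"))
      render_angle_boxplot(cohort, out("angle_boxplot.png"))
      foot <- config$overlay_foot %||% geometry$foot_id[1]
      flg <- tidy(scr, flagged_only = TRUE) |>
        group_by(.data$pair_name) |>
        slice_max(abs(.data$r), n = 1, with_ties = FALSE) |>
        ungroup()
      spec <- overlay_spec(pair_name = flg$pair_name, r = flg$r)
      render_distance_overlay(filter(geometry, .data$foot_id == foot),
                              spec, out("overlay.png"))
      files <<- c(files, "heatmap.png", "heatmap.csv",
                  "angle_boxplot.png", "overlay.png", "overlay.csv")
    })
  }

  manifest <- list(
    package = "halluxmap",
    version = as.character(utils::packageVersion("halluxmap")),
    input = list(path = config$input,
                 md5 = unname(tools::md5sum(config$input))),
    seed = config$seed,
    criteria = list(r_threshold = as.list(config$criteria$r_threshold),
                    alpha = config$criteria$alpha),
    fdr = config$fdr,
    n_feet = nrow(cohort),
    n_distance_features = sum(names(cohort) %in% .pair_table()$pair_name),
    mean_annotation_dispersion_px = cohort_dispersion(geometry),
    outputs = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(out(f))))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
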