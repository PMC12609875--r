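#' The canonical 24-landmark annotation schema
#'
#' Returns the fixed, ordered set of 24 anatomical landmarks annotated on an
#' anteroposterior (AP) foot radiograph: 9 points on the first metatarsal,
#' 2 on each sesamoid, 4 on the proximal phalanx, 2 on the distal phalanx and
#' 5 on the second metatarsal. Every axis used by the clinical angles
#' (long axes of MT1, MT2, the phalanges, and the MT1 distal articular line)
#' and the distance normalizer (proximal phalanx length, head midpoint to
#' base midpoint) is defined on named points of this schema.
#'
#' Landmark indices are 0-based and contiguous (0--23); all coordinate tables
#' in the package are ordered by this index. Coordinates are image pixel
#' coordinates (origin top-left, y increasing downward); every quantity the
#' package reports uses only coordinate differences, so the convention never
#' leaks into results.
#'
#' @return A tibble with one row per landmark and columns `landmark_index`
#'   (integer, 0--23), `landmark_name` (unique identifier), `bone` (one of
#'   `"MT1"`, `"MT2"`, `"MEDIAL_SESAMOID"`, `"LATERAL_SESAMOID"`,
#'   `"PROXIMAL_PHALANX"`, `"DISTAL_PHALANX"`) and `description`.
#' @examples
#' hv_schema()
#' dplyr::count(hv_schema(), bone)
#' @export
hv_schema <- function() {
  tibble::tribble(
    ~landmark_index, ~landmark_name,               ~bone,               ~description,
    0L,  "mt1_head_center",          "MT1",              "First metatarsal head center",
    1L,  "mt1_head_medial",          "MT1",              "Medial point of the MT1 distal articular surface",
    2L,  "mt1_head_lateral",         "MT1",              "Lateral point of the MT1 distal articular surface",
    3L,  "mt1_head_surface_mid",     "MT1",              "Midpoint of the MT1 distal head surface",
    4L,  "mt1_base_medial",          "MT1",              "Medial point of the MT1 base",
    5L,  "mt1_base_lateral",         "MT1",              "Lateral point of the MT1 base",
    6L,  "mt1_base_midpoint",        "MT1",              "Midpoint of the MT1 base (long-axis origin)",
    7L,  "mt1_shaft_medial_curve",   "MT1",              "Medial curvature point of the MT1 shaft",
    8L,  "mt1_shaft_lateral_curve",  "MT1",              "Lateral curvature point of the MT1 shaft",
    9L,  "mt2_head_center",          "MT2",              "Second metatarsal head center",
    10L, "mt2_head_midpoint",        "MT2",              "Midpoint of the MT2 head surface",
    11L, "mt2_base_medial",          "MT2",              "Medial point of the MT2 base",
    12L, "mt2_base_lateral",         "MT2",              "Lateral point of the MT2 base",
    13L, "mt2_base_midpoint",        "MT2",              "Midpoint of the MT2 base (long-axis origin)",
    14L, "medial_sesamoid_center",   "MEDIAL_SESAMOID",  "Medial (tibial) sesamoid center",
    15L, "medial_sesamoid_edge",     "MEDIAL_SESAMOID",  "Medial edge of the medial sesamoid",
    16L, "lateral_sesamoid_center",  "LATERAL_SESAMOID", "Lateral (fibular) sesamoid center",
    17L, "lateral_sesamoid_edge",    "LATERAL_SESAMOID", "Medial edge of the lateral sesamoid",
    18L, "pp_head_midpoint",         "PROXIMAL_PHALANX", "Proximal phalanx head midpoint (normalizer endpoint)",
    19L, "pp_base_midpoint",         "PROXIMAL_PHALANX", "Proximal phalanx base midpoint (normalizer endpoint)",
    20L, "pp_base_medial",           "PROXIMAL_PHALANX", "Medial point of the proximal phalanx base",
    21L, "pp_base_lateral",          "PROXIMAL_PHALANX", "Lateral point of the proximal phalanx base",
    22L, "dp_tip",                   "DISTAL_PHALANX",   "Distal phalanx tip",
    23L, "dp_base_midpoint",         "DISTAL_PHALANX",   "Distal phalanx base midpoint"
  )
}

# landmark index lookup by name (0-based, as in the schema)
.lm_index <- function(name) {
  s <- hv_schema()
  idx <- s$landmark_index[match(name, s$landmark_name)]
  if (anyNA(idx)) abort(paste0("unknown landmark name(s): ",
                               paste(name[is.na(idx)], collapse = ", ")))
  idx
}

.check_annotation_cols <- function(annotations) {
  need <- c("foot_id", "annotator_id", "landmark_index", "landmark_name", "x", "y")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0) {
    abort(paste0("annotation table is missing column(s): ", paste(miss, collapse = ", ")))
  }
}

#' Validate an annotation table against the landmark schema
#'
#' Checks that every (foot, annotator) group carries exactly the 24 schema
#' landmarks (matched by index *and* name), and that all coordinates are
#' finite and non-negative.
#'
#' @param annotations A long tibble of raw annotations with columns
#'   `foot_id`, `annotator_id`, `landmark_index`, `landmark_name`, `x`, `y`;
#'   24 rows per (foot, annotator).
#' @return `annotations`, invisibly, if valid; otherwise an error naming the
#'   offending foot/annotator or landmark.
#' @export
validate_annotations <- function(annotations) {
  .check_annotation_cols(annotations)
  schema <- hv_schema()

  bad_coord <- !is.finite(annotations$x) | !is.finite(annotations$y) |
    annotations$x < 0 | annotations$y < 0
  if (any(bad_coord)) {
    i <- which(bad_coord)[1]
    abort(sprintf(
      "non-finite or negative coordinate at row %d (foot '%s', annotator '%s', landmark %s)",
      i, annotations$foot_id[i], annotations$annotator_id[i], annotations$landmark_index[i]))
  }

  counts <- annotations |>
    count(.data$foot_id, .data$annotator_id, name = "n_points")
  off <- filter(counts, .data$n_points != 24L)
  if (nrow(off) > 0) {
    abort(sprintf(
      "expected 24 landmarks per (foot, annotator); foot '%s' annotator '%s' has %d",
      off$foot_id[1], off$annotator_id[1], off$n_points[1]))
  }

  key <- annotations |>
    group_by(.data$foot_id, .data$annotator_id) |>
    summarise(
      idx_ok  = identical(sort(as.integer(.data$landmark_index)), schema$landmark_index),
      name_ok = all(schema$landmark_name[match(.data$landmark_index, schema$landmark_index)] ==
                      .data$landmark_name),
      .groups = "drop"
    )
  bad <- filter(key, !.data$idx_ok | !.data$name_ok)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "landmark indices/names do not match the schema for foot '%s', annotator '%s'",
      bad$foot_id[1], bad$annotator_id[1]))
  }
  invisible(annotations)
}

#' Merge multiple annotators into a consensus geometry
#'
#' Consensus coordinates are the arithmetic mean of each landmark across
#' annotators; per-landmark dispersion is the radial standard deviation, the
#' square root of the mean squared Euclidean deviation of annotator points
#' about the consensus. With a single annotator the consensus equals the
#' input and all dispersions are zero.
#'
#' @param annotations A validated long annotation table (see
#'   [validate_annotations()]); may contain several feet, each with one or
#'   more annotators.
#' @return A consensus geometry tibble with one row per (foot, landmark):
#'   columns `foot_id`, `landmark_index`, `landmark_name`, `x`, `y`,
#'   `dispersion` (px) and `n_annotators`, ordered by foot then landmark
#'   index.
#' @examples
#' ann <- simulate_annotators(simulate_foot(foot_params(hva = 25)),
#'                            k = 3, sigma = 2.1, seed = 1)
#' merge_annotations(ann)
#' @export
merge_annotations <- function(annotations) {
  if (nrow(annotations) == 0) abort("empty annotation table")
  validate_annotations(annotations)
  annotations |>
    group_by(.data$foot_id, .data$landmark_index, .data$landmark_name) |>
    summarise(
      n_annotators = n(),
      x_bar = mean(.data$x),
      y_bar = mean(.data$y),
      dispersion = sqrt(mean((.data$x - x_bar)^2 + (.data$y - y_bar)^2)),
      .groups = "drop"
    ) |>
    transmute(.data$foot_id, .data$landmark_index, .data$landmark_name,
              x = .data$x_bar, y = .data$y_bar,
              dispersion = .data$dispersion, n_annotators = .data$n_annotators) |>
    arrange(.data$foot_id, .data$landmark_index)
}

#' Cohort-level annotation dispersion
#'
#' The mean, over all feet and landmarks, of the per-landmark radial
#' dispersion produced by [merge_annotations()] — the single-number
#' reproducibility figure for an annotated cohort, in pixels.
#'
#' @param geometry A consensus geometry tibble (possibly many feet) with a
#'   `dispersion` column.
#' @return A single non-negative number (pixels).
#' @export
cohort_dispersion <- function(geometry) {
  if (is.null(geometry) || nrow(geometry) == 0) abort("empty geometry table")
  if (!"dispersion" %in% names(geometry)) abort("geometry has no 'dispersion' column")
  mean(geometry$dispersion)
}

#' Patient/foot inclusion accounting
#'
#' Applies the study-flow arithmetic for a retrospective radiograph cohort:
#' screened patients minus exclusions for missing radiographs gives included
#' patients; bilateral feet minus feet excluded for prior surgery gives the
#' final analyzed foot count.
#'
#' @param screened_patients Patients initially identified.
#' @param excluded_no_radiograph Patients excluded for missing weightbearing
#'   AP radiographs.
#' @param feet_per_patient Feet contributed per included patient (bilateral
#'   standing AP series: 2).
#' @param feet_excluded Feet excluded for prior surgery altering morphology.
#' @return A one-row tibble with `included_patients`, `candidate_feet` and
#'   `final_feet`.
#' @examples
#' cohort_accounting(457, 279, 2, 21)
#' @export
cohort_accounting <- function(screened_patients = 457, excluded_no_radiograph = 279,
                              feet_per_patient = 2, feet_excluded = 21) {
  included <- screened_patients - excluded_no_radiograph
  if (included < 0) abort("more exclusions than screened patients")
  candidate <- included * feet_per_patient
  tibble(
    included_patients = included,
    candidate_feet = candidate,
    final_feet = candidate - feet_excluded
  )
}
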