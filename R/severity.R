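#' Default radiographic severity bands
#'
#' Clinical severity thresholds for the four angles, in degrees. The printed
#' clinical bands (e.g. HVA mild 15--20, moderate 21--40, severe >40) leave
#' real-valued gaps between integer bounds and say nothing about values below
#' the mild range; the defaults close both: adjacent integer bands meet at
#' their midpoint (mild/moderate HVA boundary 20.5), a shared printed
#' boundary stays with the lower band (HVA of exactly 40 is moderate; severe
#' is strictly greater than 40), and a sub-mild `"normal"` band absorbs
#' everything below the mild lower bound. HIA's mild band already starts at
#' 0, so it carries no normal band.
#'
#' @return A tibble with columns `angle`, `category`, `lower`, `upper`
#'   (degrees) and `lower_closed` (does the band include its lower bound?).
#'   Bands are contiguous — each band's `upper` is the next band's `lower`,
#'   with complementary closure — so every finite value >= 0 maps to exactly
#'   one category. The top band is open above (`upper = Inf`).
#' @export
hv_severity_bands <- function() {
  tibble::tribble(
    ~angle, ~category,  ~lower, ~upper, ~lower_closed,
    "hva",  "normal",      0,    15,    TRUE,
    "hva",  "mild",       15,    20.5,  TRUE,
    "hva",  "moderate",   20.5,  40,    TRUE,
    "hva",  "severe",     40,    Inf,   FALSE,
    "ima",  "normal",      0,     9,    TRUE,
    "ima",  "mild",        9,    11.5,  TRUE,
    "ima",  "moderate",   11.5,  17,    TRUE,
    "ima",  "severe",     17,    Inf,   FALSE,
    "dmaa", "normal",      0,     8,    TRUE,
    "dmaa", "mild",        8,    10.5,  TRUE,
    "dmaa", "moderate",   10.5,  15,    TRUE,
    "dmaa", "severe",     15,    Inf,   FALSE,
    "hia",  "mild",        0,    10,    TRUE,
    "hia",  "moderate",   10,    13,    TRUE,
    "hia",  "severe",     13,    Inf,   FALSE
  )
}

# severity categories in increasing order
SEVERITY_LEVELS <- c("normal", "mild", "moderate", "severe")

.validate_bands <- function(bands) {
  need <- c("angle", "category", "lower", "upper", "lower_closed")
  miss <- setdiff(need, names(bands))
  if (length(miss) > 0) abort(paste0("bands missing column(s): ", paste(miss, collapse = ", ")))
  for (a in unique(bands$angle)) {
    b <- arrange(filter(bands, .data$angle == a), .data$lower)
    if (b$lower[1] != 0 || !b$lower_closed[1]) abort(sprintf("bands for '%s' must start at [0", a))
    if (!is.infinite(b$upper[nrow(b)])) abort(sprintf("top band for '%s' must be open above", a))
    if (any(b$upper <= b$lower)) abort(sprintf("empty band for '%s'", a))
    if (nrow(b) > 1 && any(b$upper[-nrow(b)] != b$lower[-1])) {
      abort(sprintf("bands for '%s' are not contiguous", a))
    }
    if (!all(b$category %in% SEVERITY_LEVELS)) {
      abort(sprintf("unknown category in bands for '%s'", a))
    }
  }
  invisible(bands)
}

#' Classify an angle value into a severity category
#'
#' Deterministically maps angle values (degrees) to severity categories using
#' the contiguous bands of [hv_severity_bands()]; a value falling exactly on
#' a band boundary goes to the band whose closure includes it.
#'
#' @param value Numeric vector of angle values in degrees (finite, >= 0).
#' @param angle One of `"hva"`, `"ima"`, `"dmaa"`, `"hia"` (or any angle
#'   present in `bands`).
#' @param bands A severity band table; defaults to [hv_severity_bands()].
#' @return A character vector of categories, same length as `value`.
#' @examples
#' classify_severity(c(16, 28.8, 46.8), "hva")
#' @export
classify_severity <- function(value, angle, bands = hv_severity_bands()) {
  if (length(angle) != 1 || !angle %in% unique(bands$angle)) {
    abort(paste0("unknown angle name: ", paste(angle, collapse = ", ")))
  }
  .validate_bands(bands)
  if (any(!is.finite(value) | value < 0)) abort("angle values must be finite and >= 0")
  b <- arrange(filter(bands, .data$angle == !!angle), .data$lower)
  idx <- findInterval(value, b$lower)
  # a value sitting exactly on an open lower bound belongs to the band below
  on_open_bound <- idx > 1 & !b$lower_closed[idx] & value == b$lower[idx]
  idx[on_open_bound] <- idx[on_open_bound] - 1L
  b$category[idx]
}

#' Severity distribution of a cohort
#'
#' Per-angle counts, percentages and mean angle by severity category, the
#' standard cohort summary table for radiographic severity.
#'
#' @param cohort A cohort measurement table from [measure_cohort()] (angle
#'   and `*_severity` columns required).
#' @return A tibble with columns `angle`, `category`, `n`, `pct` and
#'   `mean_angle`; within each angle, counts sum to the number of feet and
#'   percentages to 100 (up to rounding).
#' @export
summarize_severity <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0) abort("empty cohort table")
  miss <- setdiff(c(ANGLE_NAMES, paste0(ANGLE_NAMES, "_severity")), names(cohort))
  if (length(miss) > 0) {
    abort(paste0("cohort is missing column(s): ", paste(miss, collapse = ", ")))
  }
  purrr::map_dfr(ANGLE_NAMES, function(a) {
    cohort |>
      group_by(category = .data[[paste0(a, "_severity")]]) |>
      summarise(n = n(), mean_angle = mean(.data[[a]]), .groups = "drop") |>
      mutate(angle = a, pct = 100 * .data$n / sum(.data$n),
             category = factor(.data$category, levels = SEVERITY_LEVELS)) |>
      arrange(.data$category) |>
      mutate(category = as.character(.data$category)) |>
      select("angle", "category", "n", "pct", "mean_angle")
  })
}
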