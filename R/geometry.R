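# ---- internal coordinate plumbing -------------------------------------------

# geometry tibble (one or many feet) -> list(foot_id, X, Y) with X, Y
# n_feet x 24 matrices, columns ordered by landmark_index 0..23
.as_xy <- function(geometry) {
  need <- c("foot_id", "landmark_index", "x", "y")
  miss <- setdiff(need, names(geometry))
  if (length(miss) > 0) {
    abort(paste0("geometry table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  g <- arrange(geometry, .data$foot_id, .data$landmark_index)
  ids <- unique(g$foot_id)
  n <- length(ids)
  if (nrow(g) != 24L * n ||
      !identical(as.integer(g$landmark_index), rep(0:23, n))) {
    abort("each foot must carry exactly the 24 schema landmarks (indices 0-23)")
  }
  list(
    foot_id = ids,
    X = matrix(g$x, nrow = n, ncol = 24, byrow = TRUE),
    Y = matrix(g$y, nrow = n, ncol = 24, byrow = TRUE)
  )
}

# canonical unordered pair set for the 24-landmark schema: lexicographic
# (i, j), i < j; fixes column order of every cohort table and heatmap
.pair_table <- function() {
  s <- hv_schema()
  idx <- utils::combn(s$landmark_index, 2)
  tibble(
    landmark_i = idx[1, ],
    landmark_j = idx[2, ],
    pair_name = paste(s$landmark_name[idx[1, ] + 1L],
                      s$landmark_name[idx[2, ] + 1L], sep = "__")
  )
}

#' Canonical landmark pair labels
#'
#' The 276 unordered landmark pairs of the 24-point schema in canonical
#' (lexicographic) order. This fixed ordering defines the distance-feature
#' columns of every cohort table and the row order of correlation heatmaps.
#'
#' @return A tibble with columns `landmark_i`, `landmark_j` (0-based schema
#'   indices, `landmark_i < landmark_j`) and `pair_name`
#'   (`"<name_i>__<name_j>"`).
#' @export
hv_pairs <- function() .pair_table()

#' Number of unordered landmark pairs
#'
#' The number of unique inter-landmark distances for `n` annotated points,
#' `choose(n, 2) = n(n-1)/2`; 276 for the canonical 24-landmark schema.
#'
#' @param n Number of landmarks (integer, at least 2).
#' @return An integer.
#' @examples
#' count_pairs(24)
#' @export
count_pairs <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n < 2 || n != round(n)) {
    abort("n must be a single integer >= 2")
  }
  as.integer(n * (n - 1) / 2)
}

# ---- angles ------------------------------------------------------------------

#' Unsigned acute angle between two axes
#'
#' Each axis is a directed segment `origin -> tip`; the returned value is the
#' acute angle between the two *lines*, `acos(|u.v| / (|u||v|))` in degrees,
#' in `[0, 90]`. Reversing either axis leaves the result unchanged, so the
#' choice of which landmark is origin and which is tip never matters.
#'
#' @param a,b Axes, each a length-4 numeric vector `c(x0, y0, x1, y1)` or a
#'   2x2 matrix with rows origin and tip.
#' @return Angle in degrees, in `[0, 90]`.
#' @examples
#' angle_between(c(0, 0, 1, 0), c(0, 0, 1, 1)) # 45
#' @export
angle_between <- function(a, b) {
  as_vec <- function(ax, which) {
    if (is.matrix(ax)) ax <- c(t(ax))
    if (length(ax) != 4 || !is.numeric(ax)) {
      abort(paste0("axis '", which, "' must be c(x0, y0, x1, y1) or a 2x2 matrix"))
    }
    ax
  }
  a <- as_vec(a, "a"); b <- as_vec(b, "b")
  .angle_lines(a[3] - a[1], a[4] - a[2], b[3] - b[1], b[4] - b[2])
}

# vectorized acute angle between lines with direction vectors (ux,uy), (vx,vy)
.angle_lines <- function(ux, uy, vx, vy) {
  nu <- sqrt(ux^2 + uy^2)
  nv <- sqrt(vx^2 + vy^2)
  if (any(nu == 0) || any(nv == 0)) abort("zero-length axis")
  cosab <- abs(ux * vx + uy * vy) / (nu * nv)
  acos(pmin(1, cosab)) * 180 / pi
}

#' Axis definitions behind the four clinical angles
#'
#' The landmark assignments defining each angle's two axes, centralized so an
#' alternative convention is a one-row change. Long axes run head to base;
#' DMAA is measured as the complement of the angle between the MT1 long axis
#' and the MT1 distal articular line (so a perpendicular articular surface
#' gives DMAA = 0).
#'
#' @return A tibble with columns `angle`, `a_from`, `a_to`, `b_from`, `b_to`
#'   (landmark names) and `complement` (logical; report `|90 - theta|`
#'   instead of `theta`).
#' @export
hv_axes <- function() {
  tibble::tribble(
    ~angle, ~a_from,           ~a_to,              ~b_from,            ~b_to,              ~complement,
    "hva",  "mt1_head_center", "mt1_base_midpoint", "pp_head_midpoint", "pp_base_midpoint", FALSE,
    "ima",  "mt1_head_center", "mt1_base_midpoint", "mt2_head_center",  "mt2_base_midpoint", FALSE,
    "dmaa", "mt1_head_center", "mt1_base_midpoint", "mt1_head_medial",  "mt1_head_lateral",  TRUE,
    "hia",  "pp_head_midpoint", "pp_base_midpoint", "dp_tip",           "dp_base_midpoint",  FALSE
  )
}

# vectorized over feet: X, Y are n x 24 coordinate matrices
.angles_from_xy <- function(X, Y) {
  axes <- hv_axes()
  out <- matrix(NA_real_, nrow = nrow(X), ncol = nrow(axes),
                dimnames = list(NULL, axes$angle))
  for (k in seq_len(nrow(axes))) {
    ai <- .lm_index(c(axes$a_from[k], axes$a_to[k])) + 1L
    bi <- .lm_index(c(axes$b_from[k], axes$b_to[k])) + 1L
    ux <- X[, ai[2]] - X[, ai[1]]; uy <- Y[, ai[2]] - Y[, ai[1]]
    vx <- X[, bi[2]] - X[, bi[1]]; vy <- Y[, bi[2]] - Y[, bi[1]]
    if (any(ux == 0 & uy == 0) || any(vx == 0 & vy == 0)) {
      abort(sprintf("degenerate axis for angle '%s': coincident endpoints", axes$angle[k]))
    }
    th <- .angle_lines(ux, uy, vx, vy)
    out[, k] <- if (axes$complement[k]) abs(90 - th) else th
  }
  out
}

#' Compute the four clinical angles of a foot geometry
#'
#' From a consensus landmark geometry, computes by vector geometry the
#' Hallux Valgus Angle (HVA: MT1 long axis vs proximal phalanx long axis),
#' the Intermetatarsal Angle (IMA: MT1 vs MT2 long axes), the Distal
#' Metatarsal Articular Angle (DMAA: tilt of the MT1 distal articular line
#' away from perpendicular to the MT1 long axis) and the Hallux
#' Interphalangeal Angle (HIA: proximal vs distal phalanx long axes). All
#' angles use the unsigned acute-angle convention, hence lie in `[0, 90]`
#' degrees and are invariant under rotation, translation and uniform scaling
#' of the landmark set.
#'
#' @param geometry A consensus geometry tibble (one or many feet), as
#'   produced by [merge_annotations()] or [simulate_foot()].
#' @return A tibble with one row per foot: `foot_id`, `hva`, `ima`, `dmaa`,
#'   `hia` (degrees).
#' @examples
#' compute_angles(simulate_foot(foot_params(hva = 30, ima = 12)))
#' @export
compute_angles <- function(geometry) {
  xy <- .as_xy(geometry)
  ang <- .angles_from_xy(xy$X, xy$Y)
  bind_cols(tibble(foot_id = xy$foot_id), as_tibble(ang))
}

# ---- distances ---------------------------------------------------------------

# n_feet x 276 matrix of raw pairwise distances
.distances_from_xy <- function(X, Y, pairs = .pair_table()) {
  i <- pairs$landmark_i + 1L
  j <- pairs$landmark_j + 1L
  sqrt((X[, i, drop = FALSE] - X[, j, drop = FALSE])^2 +
         (Y[, i, drop = FALSE] - Y[, j, drop = FALSE])^2)
}

#' All pairwise inter-landmark distances
#'
#' Computes the Euclidean distance `sqrt((x2-x1)^2 + (y2-y1)^2)` for every
#' unordered landmark pair of the 24-point schema — 276 features per foot —
#' in canonical pair order.
#'
#' @param geometry A consensus geometry tibble (one or many feet).
#' @return A long tibble with one row per (foot, pair): `foot_id`,
#'   `landmark_i`, `landmark_j`, `pair_name`, `distance` (px),
#'   `normalized = FALSE`, `normalizer = NA`.
#' @seealso [normalize_distances()]
#' @export
pairwise_distances <- function(geometry) {
  xy <- .as_xy(geometry)
  pairs <- .pair_table()
  D <- .distances_from_xy(xy$X, xy$Y, pairs)
  tibble(
    foot_id = rep(xy$foot_id, each = nrow(pairs)),
    landmark_i = rep(pairs$landmark_i, length(xy$foot_id)),
    landmark_j = rep(pairs$landmark_j, length(xy$foot_id)),
    pair_name = rep(pairs$pair_name, length(xy$foot_id)),
    distance = c(t(D)),
    normalized = FALSE,
    normalizer = NA_real_
  )
}

# per-foot proximal phalanx length (head midpoint to base midpoint), px
.pp_length <- function(geometry) {
  xy <- .as_xy(geometry)
  i <- .lm_index("pp_head_midpoint") + 1L
  j <- .lm_index("pp_base_midpoint") + 1L
  tibble(
    foot_id = xy$foot_id,
    pp_length = sqrt((xy$X[, i] - xy$X[, j])^2 + (xy$Y[, i] - xy$Y[, j])^2)
  )
}

#' Normalize pairwise distances by proximal phalanx length
#'
#' Divides every raw distance by the foot's proximal phalanx length (head
#' midpoint to base midpoint), making the features dimensionless and
#' comparable across feet and image scales. The proximal phalanx pair itself
#' maps to exactly 1.
#'
#' @param distances A raw distance table from [pairwise_distances()].
#' @param geometry The matching geometry (source of the normalizer).
#' @return The distance tibble with `distance` rescaled,
#'   `normalized = TRUE` and `normalizer` set to the proximal phalanx length
#'   in pixels.
#' @export
normalize_distances <- function(distances, geometry) {
  if (any(distances$normalized)) abort("distances are already normalized")
  pp <- .pp_length(geometry)
  if (any(pp$pp_length == 0)) {
    abort(sprintf("proximal phalanx length is zero for foot '%s'",
                  pp$foot_id[pp$pp_length == 0][1]))
  }
  distances |>
    inner_join(pp, by = "foot_id") |>
    mutate(distance = .data$distance / .data$pp_length,
           normalized = TRUE,
           normalizer = .data$pp_length) |>
    select(-"pp_length")
}

#' Assemble a cohort measurement table
#'
#' Runs the full per-foot measurement stage: the four clinical angles,
#' severity labels per angle, and the 276 normalized pairwise distances
#' spread into canonical-order columns. This wide feet-by-features table is
#' the substrate of correlation screening.
#'
#' @param geometry Consensus geometry tibble for one or many feet.
#' @param bands Severity bands, as from [hv_severity_bands()].
#' @param normalized Normalize distances by proximal phalanx length
#'   (default `TRUE`; `FALSE` keeps raw pixel distances).
#' @return A tibble with one row per foot: `foot_id`, `hva`, `ima`, `dmaa`,
#'   `hia`, `hva_severity`, ..., `hia_severity`, then the 276 distance
#'   columns named by `pair_name`.
#' @examples
#' sim <- simulate_cohort(cohort_params(n_feet = 5, seed = 1))
#' dim(sim$cohort)
#' @export
measure_cohort <- function(geometry, bands = hv_severity_bands(), normalized = TRUE) {
  xy <- .as_xy(geometry)
  ang <- .angles_from_xy(xy$X, xy$Y)
  pairs <- .pair_table()
  D <- .distances_from_xy(xy$X, xy$Y, pairs)
  if (normalized) {
    pp <- .pp_length(geometry)
    ppl <- pp$pp_length[match(xy$foot_id, pp$foot_id)]
    if (any(ppl == 0)) abort("proximal phalanx length is zero; cannot normalize")
    D <- D / ppl
  }
  colnames(D) <- pairs$pair_name
  angles <- as_tibble(ang)
  sev <- purrr::map_dfc(setNames(ANGLE_NAMES, paste0(ANGLE_NAMES, "_severity")),
                        function(a) classify_severity(angles[[a]], a, bands))
  bind_cols(tibble(foot_id = xy$foot_id), angles, sev, as_tibble(D))
}
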