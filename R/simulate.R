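# ---- single-foot construction ------------------------------------------------

#' Parameters of a synthetic forefoot
#'
#' Generative parameters for one 2D forefoot landmark configuration. The
#' construction is a chain of hinge rotations in the image plane: the second
#' metatarsal (MT2) lies along a reference axis; the first metatarsal (MT1)
#' deviates medially from it by `ima`; the proximal phalanx deviates
#' laterally from the MT1 axis by `hva`; the distal phalanx deviates from the
#' proximal phalanx by `hia`; and the MT1 distal articular line is tilted by
#' `dmaa` away from perpendicular to the MT1 axis. Each generative angle is
#' therefore identified by exactly one measured clinical angle, so
#' [compute_angles()] inverts the construction exactly on noise-free feet.
#'
#' Default bone lengths and widths are plausible for an adult AP foot
#' radiograph at standard detector resolution (~0.15 mm/px); all reported
#' measures are angular or normalized, so their absolute scale is
#' inconsequential.
#'
#' @param hva,ima,dmaa,hia Deformity angles in degrees, each in `[0, 60]`.
#' @param mt1_len,mt2_len,pp_len,dp_len Bone long-axis lengths, px.
#' @param mt1_head_width Width of the MT1 distal articular surface, px.
#' @param mt1_base_width,mt1_shaft_width,mt2_base_width,pp_base_width Widths, px.
#' @param sesamoid_sep Separation of the two sesamoid centers, px.
#' @param sesamoid_offset Lateral displacement of the sesamoid complex
#'   relative to the MT1 head, px (tracks deformity in real feet).
#' @param sesamoid_drop Proximal offset of the sesamoids from the MT1 head, px.
#' @param joint_gap Radiographic joint space between adjacent bones, px.
#' @param head_cap Distal offset of head-surface midpoints from head centers, px.
#' @param inter_base Separation of the MT1 and MT2 base midpoints, px.
#' @param rotation,translation,scale Global pose: rotation in degrees,
#'   translation in px (length 2), uniform scale factor (> 0).
#' @return A list of class `foot_params`.
#' @examples
#' compute_angles(simulate_foot(foot_params(hva = 30, ima = 12, dmaa = 10, hia = 8)))
#' @export
foot_params <- function(hva = 0, ima = 0, dmaa = 0, hia = 0,
                        mt1_len = 220, mt2_len = 235, pp_len = 100, dp_len = 60,
                        mt1_head_width = 60, mt1_base_width = 55,
                        mt1_shaft_width = 40, mt2_base_width = 40,
                        pp_base_width = 45,
                        sesamoid_sep = 45, sesamoid_offset = 0, sesamoid_drop = 25,
                        joint_gap = 12, head_cap = 14, inter_base = 65,
                        rotation = 0, translation = c(0, 0), scale = 1) {
  p <- as.list(environment())
  ang <- c(p$hva, p$ima, p$dmaa, p$hia)
  if (any(!is.finite(ang) | ang < 0 | ang > 60)) {
    abort("deformity angles must be finite and in [0, 60] degrees")
  }
  lens <- c(p$mt1_len, p$mt2_len, p$pp_len, p$dp_len, p$mt1_head_width,
            p$mt1_base_width, p$mt1_shaft_width, p$mt2_base_width,
            p$pp_base_width, p$sesamoid_sep, p$sesamoid_drop,
            p$joint_gap, p$head_cap, p$inter_base)
  if (any(!is.finite(lens) | lens <= 0)) abort("lengths and widths must be positive")
  if (!is.finite(p$scale) || p$scale <= 0) abort("scale must be positive")
  if (length(p$translation) != 2) abort("translation must be length 2")
  structure(p, class = "foot_params")
}

# 24 x 2 landmark coordinate matrix in schema order, image convention
# (y grows downward; distal = decreasing y before pose is applied)
.foot_points <- function(p) {
  d2r <- pi / 180
  dirv <- function(phi) c(sin(phi), -cos(phi))   # distal direction at medial tilt -phi
  nrmv <- function(phi) c(cos(phi), sin(phi))    # lateral normal

  phi1 <- -p$ima * d2r
  phipp <- phi1 + p$hva * d2r
  phidp <- phipp + p$hia * d2r
  u1 <- dirv(phi1);  v1 <- nrmv(phi1)
  u0 <- c(0, -1);    v0 <- c(1, 0)
  upp <- dirv(phipp); vpp <- nrmv(phipp)
  udp <- dirv(phidp)

  B1 <- c(300, 800)
  H1 <- B1 + p$mt1_len * u1
  art <- cos(p$dmaa * d2r) * v1 + sin(p$dmaa * d2r) * u1  # articular line direction
  B2 <- B1 + p$inter_base * v0
  H2 <- B2 + p$mt2_len * u0
  ses <- H1 - p$sesamoid_drop * u1 + p$sesamoid_offset * v1
  Pb <- H1 + p$joint_gap * upp
  Ph <- Pb + p$pp_len * upp
  Db <- Ph + p$joint_gap * udp

  pts <- rbind(
    H1,                                            # 0 mt1_head_center
    H1 - (p$mt1_head_width / 2) * art,             # 1 mt1_head_medial
    H1 + (p$mt1_head_width / 2) * art,             # 2 mt1_head_lateral
    H1 + p$head_cap * u1,                          # 3 mt1_head_surface_mid
    B1 - (p$mt1_base_width / 2) * v1,              # 4 mt1_base_medial
    B1 + (p$mt1_base_width / 2) * v1,              # 5 mt1_base_lateral
    B1,                                            # 6 mt1_base_midpoint
    B1 + 0.45 * p$mt1_len * u1 - (p$mt1_shaft_width / 2) * v1,  # 7
    B1 + 0.45 * p$mt1_len * u1 + (p$mt1_shaft_width / 2) * v1,  # 8
    H2,                                            # 9 mt2_head_center
    H2 + p$head_cap * u0,                          # 10 mt2_head_midpoint
    B2 - (p$mt2_base_width / 2) * v0,              # 11 mt2_base_medial
    B2 + (p$mt2_base_width / 2) * v0,              # 12 mt2_base_lateral
    B2,                                            # 13 mt2_base_midpoint
    ses - (p$sesamoid_sep / 2) * v1,               # 14 medial_sesamoid_center
    ses - (p$sesamoid_sep / 2 + 8) * v1,           # 15 medial_sesamoid_edge
    ses + (p$sesamoid_sep / 2) * v1,               # 16 lateral_sesamoid_center
    ses + (p$sesamoid_sep / 2 - 8) * v1,           # 17 lateral_sesamoid_edge
    Ph,                                            # 18 pp_head_midpoint
    Pb,                                            # 19 pp_base_midpoint
    Pb - (p$pp_base_width / 2) * vpp,              # 20 pp_base_medial
    Pb + (p$pp_base_width / 2) * vpp,              # 21 pp_base_lateral
    Db + p$dp_len * udp,                           # 22 dp_tip
    Db                                             # 23 dp_base_midpoint
  )

  th <- p$rotation * d2r
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- p$scale * (pts %*% t(R))
  pts[, 1] <- pts[, 1] + p$translation[1]
  pts[, 2] <- pts[, 2] + p$translation[2]
  dimnames(pts) <- NULL
  pts
}

.points_to_geometry <- function(pts, foot_id, dispersion = rep(0, 24),
                                n_annotators = 1L) {
  s <- hv_schema()
  tibble(
    foot_id = foot_id,
    landmark_index = s$landmark_index,
    landmark_name = s$landmark_name,
    x = pts[, 1], y = pts[, 2],
    dispersion = dispersion,
    n_annotators = as.integer(n_annotators)
  )
}

#' Simulate one noise-free foot geometry
#'
#' Builds the 24-landmark configuration defined by a [foot_params()] set.
#' The construction is deterministic and closed-form; [compute_angles()]
#' recovers the four generative angles exactly (to floating-point precision)
#' on its output.
#'
#' @param params A [foot_params()] object.
#' @param foot_id Identifier for the generated foot.
#' @return A consensus geometry tibble (`dispersion = 0`,
#'   `n_annotators = 1`).
#' @export
simulate_foot <- function(params = foot_params(), foot_id = "foot_1") {
  if (!inherits(params, "foot_params")) abort("params must be created by foot_params()")
  .points_to_geometry(.foot_points(params), foot_id)
}

#' Simulate annotators around a geometry
#'
#' Produces `k` annotation sets per foot by adding independent isotropic
#' Gaussian jitter — standard deviation `sigma` pixels per coordinate — to
#' every landmark, emulating inter-observer digitizing error.
#'
#' @param geometry A geometry tibble (one or many feet); its coordinates are
#'   treated as the true landmark positions.
#' @param k Number of annotators (>= 1).
#' @param sigma Per-coordinate jitter SD in pixels (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A long annotation tibble (`foot_id`, `annotator_id`,
#'   `landmark_index`, `landmark_name`, `x`, `y`) suitable for
#'   [merge_annotations()].
#' @export
simulate_annotators <- function(geometry, k = 3, sigma = 2.1, seed = NULL) {
  if (length(k) != 1 || k < 1 || k != round(k)) abort("k must be a single integer >= 1")
  if (length(sigma) != 1 || !is.finite(sigma) || sigma < 0) abort("sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  g <- arrange(geometry, .data$foot_id, .data$landmark_index)
  out <- purrr::map_dfr(seq_len(k), function(a) {
    tibble(
      foot_id = g$foot_id,
      annotator_id = sprintf("ann_%d", a),
      landmark_index = g$landmark_index,
      landmark_name = g$landmark_name,
      x = g$x + rnorm(nrow(g), 0, sigma),
      y = g$y + rnorm(nrow(g), 0, sigma)
    )
  })
  arrange(out, .data$foot_id, .data$annotator_id, .data$landmark_index)
}

# ---- cohort generation -------------------------------------------------------

#' Parameters of a simulated cohort
#'
#' Settings for [simulate_cohort()]. Per-angle severity mixtures default to
#' the clinical study distribution (HVA 26.6/61.5/11.3 percent
#' mild/moderate/severe, IMA 49.9/37.7/12.0, DMAA 51.3/20.3/28.4, HIA
#' 70.4/26.0/3.0, renormalized to sum to one); a foot's angle is drawn
#' uniformly within its sampled severity band (severe bands are capped at a
#' plausible maximum since the clinical bands are open above).
#'
#' @param n_feet Number of feet (>= 1).
#' @param severity_weights Named list (`hva`, `ima`, `dmaa`, `hia`) of
#'   length-3 mild/moderate/severe mixture weights; each is renormalized.
#' @param annotators Annotators per foot (>= 1).
#' @param sigma Per-coordinate annotator jitter SD, px.
#' @param couplings Optional tibble (`pair_name`, `angle`, `r`) of
#'   distance-angle couplings to inject: each named normalized-distance
#'   column is regenerated as a noisy linear function of the named angle with
#'   target correlation `r`, preserving the column's mean and spread.
#' @param decouple If `TRUE`, the distance block is row-permuted against the
#'   angle columns after measurement, severing all geometric distance-angle
#'   association while preserving both marginals — the all-noise calibration
#'   mode for null screening experiments (injected couplings, if any, are
#'   applied afterwards and so survive).
#' @param pose_jitter Randomize global pose per foot (rotation within +/-10
#'   degrees, translation within +/-25 px, scale within 0.9--1.1); angles and
#'   normalized distances are invariant to it.
#' @param length_cv Coefficient of variation of per-foot bone length
#'   variation (lognormal-free multiplicative Gaussian, truncated at +/-3 SD).
#' @param severe_cap Named numeric upper limits for the open severe bands,
#'   degrees.
#' @param template A [foot_params()] object supplying the skeleton the
#'   per-foot parameters perturb.
#' @param seed Optional integer seed; the whole cohort is a deterministic
#'   function of it.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_feet = 100,
                          severity_weights = list(
                            hva = c(26.6, 61.5, 11.3),
                            ima = c(49.9, 37.7, 12.0),
                            dmaa = c(51.3, 20.3, 28.4),
                            hia = c(70.4, 26.0, 3.0)
                          ),
                          annotators = 3, sigma = 2.1,
                          couplings = NULL, decouple = FALSE,
                          pose_jitter = TRUE, length_cv = 0.05,
                          severe_cap = c(hva = 55, ima = 25, dmaa = 25, hia = 20),
                          template = foot_params(), seed = NULL) {
  if (n_feet < 1) abort("n_feet must be >= 1")
  if (sigma < 0) abort("sigma must be >= 0")
  if (annotators < 1) abort("annotators must be >= 1")
  if (!setequal(names(severity_weights), ANGLE_NAMES)) {
    abort("severity_weights must have elements hva, ima, dmaa, hia")
  }
  severity_weights <- lapply(severity_weights, function(w) {
    if (length(w) != 3 || any(w < 0) || sum(w) == 0) {
      abort("each severity weight vector must be 3 non-negative numbers")
    }
    w / sum(w)
  })
  if (!is.null(couplings)) {
    need <- c("pair_name", "angle", "r")
    if (!all(need %in% names(couplings))) {
      abort("couplings must have columns pair_name, angle, r")
    }
    if (!all(couplings$pair_name %in% .pair_table()$pair_name)) abort("unknown pair_name in couplings")
    if (!all(couplings$angle %in% ANGLE_NAMES)) abort("unknown angle in couplings")
    if (any(abs(couplings$r) >= 1)) abort("coupling |r| must be < 1")
  }
  structure(as.list(environment()), class = "cohort_params")
}

# draw one angle column from its severity mixture: mild/moderate/severe bands
# of hv_severity_bands(), uniform within band, severe capped
.sample_angles <- function(angle, n, weights, cap, bands = hv_severity_bands()) {
  b <- filter(bands, .data$angle == !!angle,
              .data$category %in% c("mild", "moderate", "severe")) |>
    arrange(.data$lower)
  b$upper[3] <- cap
  cat_idx <- sample.int(3, n, replace = TRUE, prob = weights)
  runif(n, b$lower[cat_idx], b$upper[cat_idx])
}

#' Simulate an annotated cohort with known ground truth
#'
#' Draws per-foot deformity angles from the severity mixture, constructs each
#' foot with [foot_params()] geometry (randomized pose and slight bone-length
#' variation), simulates annotator jitter, merges annotations into consensus
#' geometries, and runs the full measurement stage. Returns the wide cohort
#' table together with the generating truth, so recovery can be scored.
#'
#' @param cp A [cohort_params()] object.
#' @return A list with elements:
#'   * `cohort` — the measurement table from [measure_cohort()] (angles,
#'     severity labels, 276 normalized distances);
#'   * `geometry` — the consensus geometry tibble (with dispersions);
#'   * `truth` — a list with `angles` (tibble of true per-foot angles),
#'     `couplings` and `params`.
#' @examples
#' sim <- simulate_cohort(cohort_params(n_feet = 10, seed = 42))
#' head(sim$truth$angles)
#' @export
simulate_cohort <- function(cp = cohort_params()) {
  if (!inherits(cp, "cohort_params")) abort("cp must be created by cohort_params()")
  if (!is.null(cp$seed)) set.seed(cp$seed)
  n <- cp$n_feet
  ids <- sprintf("foot_%04d", seq_len(n))

  true <- tibble(
    foot_id = ids,
    hva = .sample_angles("hva", n, cp$severity_weights$hva, cp$severe_cap[["hva"]]),
    ima = .sample_angles("ima", n, cp$severity_weights$ima, cp$severe_cap[["ima"]]),
    dmaa = .sample_angles("dmaa", n, cp$severity_weights$dmaa, cp$severe_cap[["dmaa"]]),
    hia = .sample_angles("hia", n, cp$severity_weights$hia, cp$severe_cap[["hia"]])
  )

  len_mult <- function() {
    if (cp$length_cv <= 0) return(rep(1, 4))
    pmin(pmax(1 + rnorm(4, 0, cp$length_cv), 1 - 3 * cp$length_cv), 1 + 3 * cp$length_cv)
  }
  tpl <- cp$template
  pts <- array(NA_real_, c(n, 24, 2))
  for (i in seq_len(n)) {
    lm <- len_mult()
    p <- tpl
    p$hva <- true$hva[i]; p$ima <- true$ima[i]
    p$dmaa <- true$dmaa[i]; p$hia <- true$hia[i]
    p$mt1_len <- tpl$mt1_len * lm[1]; p$mt2_len <- tpl$mt2_len * lm[2]
    p$pp_len <- tpl$pp_len * lm[3]; p$dp_len <- tpl$dp_len * lm[4]
    # sesamoid complex drifts laterally with deformity
    p$sesamoid_offset <- tpl$sesamoid_offset + 0.5 * true$hva[i]
    if (cp$pose_jitter) {
      p$rotation <- runif(1, -10, 10)
      p$translation <- runif(2, -25, 25)
      p$scale <- runif(1, 0.9, 1.1)
    }
    pts[i, , ] <- .foot_points(p)
  }

  k <- cp$annotators
  if (k > 1 || cp$sigma > 0) {
    # noise laid out as (n*24*2) x k; consensus adds the per-cell annotator
    # mean, dispersion is the radial SD of the deviations about it
    nm <- matrix(rnorm(n * 24 * 2 * k, 0, cp$sigma), ncol = k)
    mbar <- rowMeans(nm)
    cons <- pts + array(mbar, c(n, 24, 2))
    dev <- array(nm - mbar, c(n, 24, 2, k))
    sq <- dev[, , 1, , drop = FALSE]^2 + dev[, , 2, , drop = FALSE]^2
    disp <- matrix(sqrt(rowMeans(matrix(sq, nrow = n * 24))), n, 24)
  } else {
    cons <- pts
    disp <- matrix(0, n, 24)
  }

  s <- hv_schema()
  geometry <- tibble(
    foot_id = rep(ids, each = 24),
    landmark_index = rep(s$landmark_index, n),
    landmark_name = rep(s$landmark_name, n),
    x = c(t(cons[, , 1])),
    y = c(t(cons[, , 2])),
    dispersion = c(t(disp)),
    n_annotators = as.integer(k)
  )

  cohort <- measure_cohort(geometry)
  pair_cols <- .pair_table()$pair_name

  if (cp$decouple && n > 1) {
    perm <- sample.int(n)
    cohort[pair_cols] <- cohort[perm, pair_cols]
  }

  if (!is.null(cp$couplings) && nrow(cp$couplings) > 0) {
    for (i in seq_len(nrow(cp$couplings))) {
      pair <- cp$couplings$pair_name[i]
      ang <- cp$couplings$angle[i]
      rho <- cp$couplings$r[i]
      col <- cohort[[pair]]
      s0 <- sd(col)
      if (s0 == 0) s0 <- 0.05 * max(mean(col), 1e-8)
      z <- as.numeric(scale(cohort[[ang]]))
      mix <- rho * z + sqrt(1 - rho^2) * rnorm(n)
      cohort[[pair]] <- pmax(mean(col) + s0 * mix, 0)
    }
  }

  list(cohort = cohort, geometry = geometry,
       truth = list(angles = true, couplings = cp$couplings, params = cp))
}
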