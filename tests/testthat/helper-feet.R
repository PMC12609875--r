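# shared fixtures: all built in code at test time

# a random plausible foot parameter set
random_foot_params <- function() {
  foot_params(
    hva = runif(1, 0, 50), ima = runif(1, 0, 20),
    dmaa = runif(1, 0, 25), hia = runif(1, 0, 20),
    rotation = runif(1, -180, 180),
    translation = runif(2, -200, 200),
    scale = runif(1, 0.5, 2)
  )
}

# geometry with arbitrary (non-anatomical) coordinates, for pure-geometry tests
random_geometry <- function(foot_id = "rnd") {
  s <- hv_schema()
  tibble::tibble(
    foot_id = foot_id,
    landmark_index = s$landmark_index,
    landmark_name = s$landmark_name,
    x = runif(24, 0, 1000),
    y = runif(24, 0, 1000),
    dispersion = 0,
    n_annotators = 1L
  )
}

# hand-rolled annotation table for one foot
annotations_from_points <- function(pts_list, foot_id = "f1") {
  s <- hv_schema()
  purrr::imap_dfr(pts_list, function(pts, i) {
    tibble::tibble(
      foot_id = foot_id,
      annotator_id = paste0("a", i),
      landmark_index = s$landmark_index,
      landmark_name = s$landmark_name,
      x = pts[, 1],
      y = pts[, 2]
    )
  })
}

# brute-force oracles, kept deliberately naive and separate from the package
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_distances <- function(pts) {
  out <- numeric(0)
  for (i in 1:(nrow(pts) - 1)) {
    for (j in (i + 1):nrow(pts)) {
      out <- c(out, sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2))
    }
  }
  unname(out)
}

# apply a similarity transform to a geometry tibble
transform_geometry <- function(g, rotation_deg = 0, translation = c(0, 0), scale = 1) {
  th <- rotation_deg * pi / 180
  xn <- scale * (cos(th) * g$x - sin(th) * g$y) + translation[1]
  yn <- scale * (sin(th) * g$x + cos(th) * g$y) + translation[2]
  g$x <- xn
  g$y <- yn
  g
}
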