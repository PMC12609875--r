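# diverging blue-negative / red-positive map over a symmetric r domain;
# values outside the domain are clipped for color only
.r_palette <- function() c("#08306B", "#4292C6", "#F7F7F7", "#EF6548", "#67000D")

#' Map correlation values to overlay colors
#'
#' The pure function behind every rendered color: `r` is clipped to the
#' symmetric domain and mapped through the diverging blue-white-red ramp.
#' Sidecar manifests record its output, so color mapping is testable without
#' touching pixels.
#'
#' @param r Numeric correlation values.
#' @param domain Symmetric domain `c(-d, d)`; values outside are clipped.
#' @return Hex color strings, one per value.
#' @export
r_to_color <- function(r, domain = c(-0.6, 0.6)) {
  if (length(domain) != 2 || domain[1] != -domain[2] || domain[2] <= 0) {
    abort("color domain must be symmetric about 0, c(-d, d)")
  }
  rc <- pmin(pmax(r, domain[1]), domain[2])
  ramp <- grDevices::colorRamp(.r_palette(), space = "Lab")
  rgb <- ramp((rc - domain[1]) / (domain[2] - domain[1]))
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Specification of a distance overlay
#'
#' Selects landmark pairs to draw over a radiograph (or blank canvas), each
#' colored by its correlation coefficient on a diverging blue-to-red scale
#' symmetric about zero (default domain -0.6 to 0.6, matching the screening
#' heatmap).
#'
#' @param pair_name Character vector of canonical pair labels (see
#'   [hv_pairs()]); may be empty.
#' @param r Correlation values, one per pair.
#' @param background Optional path to a PNG radiograph to draw on; `NULL`
#'   renders on a blank canvas.
#' @param canvas Width/height in px of the blank canvas when no background
#'   is given.
#' @param domain Symmetric color-scale domain `c(-d, d)`.
#' @return A list of class `overlay_spec`.
#' @export
overlay_spec <- function(pair_name = character(), r = numeric(),
                         background = NULL, canvas = c(1024, 1024),
                         domain = c(-0.6, 0.6)) {
  if (length(pair_name) != length(r)) abort("pair_name and r must have equal length")
  unknown <- setdiff(pair_name, .pair_table()$pair_name)
  if (length(unknown) > 0) {
    abort(paste0("unknown pair label(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  if (length(domain) != 2 || domain[1] != -domain[2] || domain[2] <= 0) {
    abort("domain must be symmetric about 0")
  }
  if (!is.null(background) && !file.exists(background)) {
    abort(paste0("background image not found: ", background))
  }
  structure(list(pair_name = pair_name, r = r, background = background,
                 canvas = canvas, domain = domain),
            class = "overlay_spec")
}

# segment manifest: endpoints, r, and the exact color each segment gets
.overlay_manifest <- function(geometry, spec) {
  pairs <- filter(.pair_table(), .data$pair_name %in% spec$pair_name)
  sel <- tibble(pair_name = spec$pair_name, r = spec$r) |>
    inner_join(pairs, by = "pair_name")
  g <- arrange(geometry, .data$landmark_index)
  sel |>
    mutate(
      x1 = g$x[match(.data$landmark_i, g$landmark_index)],
      y1 = g$y[match(.data$landmark_i, g$landmark_index)],
      x2 = g$x[match(.data$landmark_j, g$landmark_index)],
      y2 = g$y[match(.data$landmark_j, g$landmark_index)],
      color = if (n() > 0) r_to_color(.data$r, spec$domain) else character(0)
    ) |>
    select("pair_name", "landmark_i", "landmark_j", "r", "color",
           "x1", "y1", "x2", "y2")
}

#' Plot selected distances over a foot
#'
#' Draws the selected landmark pairs as dashed segments between consensus
#' landmark positions, colored by correlation strength on the diverging
#' scale, over a PNG background or blank canvas. Axes follow the image
#' convention (y downward).
#'
#' @param geometry A single foot's consensus geometry tibble.
#' @param spec An [overlay_spec()].
#' @return A ggplot object; its segment manifest (endpoints, r, hex color
#'   per pair) is attached as attribute `"manifest"`.
#' @export
plot_distance_overlay <- function(geometry, spec) {
  if (length(unique(geometry$foot_id)) != 1) abort("overlay expects a single foot")
  man <- .overlay_manifest(geometry, spec)
  if (!is.null(spec$background)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("reading PNG backgrounds requires the 'png' package")
    }
    img <- png::readPNG(spec$background)
    w <- ncol(img); h <- nrow(img)
  } else {
    w <- spec$canvas[1]; h <- spec$canvas[2]
  }
  pl <- ggplot2::ggplot() +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(h, 0), expand = FALSE)
  if (!is.null(spec$background)) {
    pl <- pl + ggplot2::annotation_raster(img, xmin = 0, xmax = w, ymin = h, ymax = 0)
  }
  pl <- pl +
    ggplot2::geom_point(data = geometry,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 0.8, color = "grey40")
  if (nrow(man) > 0) {
    pl <- pl +
      ggplot2::geom_segment(
        data = man,
        ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                     yend = .data$y2, color = .data$r),
        linetype = "dashed", linewidth = 0.7
      )
  }
  pl <- pl +
    ggplot2::scale_color_gradientn(
      colors = .r_palette(), limits = spec$domain,
      oob = scales::squish, name = "r"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  attr(pl, "manifest") <- man
  pl
}

#' Render a distance overlay to disk
#'
#' Writes the overlay as a PNG plus a machine-readable sidecar CSV (the
#' segment manifest: pair, r, endpoints, hex color), so downstream checks can
#' assert on data rather than pixels.
#'
#' @inheritParams plot_distance_overlay
#' @param path Output PNG path; the sidecar is written next to it with a
#'   `.csv` extension.
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()].
#' @return The segment manifest tibble, invisibly.
#' @export
render_distance_overlay <- function(geometry, spec, path,
                                    width = 6, height = 6, dpi = 150) {
  pl <- plot_distance_overlay(geometry, spec)
  ggplot2::ggsave(path, pl, width = width, height = height, dpi = dpi)
  man <- attr(pl, "manifest")
  readr::write_csv(man, .sidecar_path(path))
  invisible(man)
}

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".csv")

#' Heatmap of distance-angle correlations
#'
#' The 276 x 4 matrix of Pearson coefficients as a tile map: pairs on rows
#' (canonical order, top to bottom), angles on columns, diverging color scale
#' clipped to the domain. Values outside the domain keep their true value in
#' the returned data; only their color saturates.
#'
#' @param m A 276 x 4 correlation matrix (as from [correlation_matrix()]) or
#'   an `hv_screen` object.
#' @param domain Symmetric color domain.
#' @return A ggplot object with the plotted long-format values attached as
#'   attribute `"matrix_data"`.
#' @export
plot_correlation_heatmap <- function(m, domain = c(-0.6, 0.6)) {
  if (inherits(m, "hv_screen")) m <- correlation_matrix(m)
  pairs <- .pair_table()
  if (!is.matrix(m) || !identical(dim(m), c(nrow(pairs), length(ANGLE_NAMES)))) {
    abort(sprintf("expected a %d x %d correlation matrix", nrow(pairs), length(ANGLE_NAMES)))
  }
  if (any(abs(m) > 1, na.rm = TRUE)) abort("correlation values must lie in [-1, 1]")
  colnames(m) <- ANGLE_NAMES
  df <- as_tibble(m) |>
    mutate(pair_name = pairs$pair_name) |>
    tidyr::pivot_longer(all_of(ANGLE_NAMES), names_to = "angle", values_to = "r") |>
    mutate(angle = factor(.data$angle, levels = ANGLE_NAMES),
           pair_name = factor(.data$pair_name, levels = rev(pairs$pair_name)))
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$pair_name,
                                         fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colors = .r_palette(), limits = domain,
                                  oob = scales::squish, name = "r") +
    ggplot2::scale_x_discrete(labels = toupper) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 2))
  attr(pl, "matrix_data") <- df
  pl
}

#' Render the correlation heatmap to disk
#'
#' Writes the heatmap PNG plus a sidecar CSV holding the exact plotted values
#' (unclipped), which round-trips to the input matrix.
#'
#' @inheritParams plot_correlation_heatmap
#' @param path Output PNG path; sidecar CSV written alongside.
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()].
#' @return The long-format value tibble, invisibly.
#' @export
render_correlation_heatmap <- function(m, path, domain = c(-0.6, 0.6),
                                       width = 5, height = 10, dpi = 150) {
  pl <- plot_correlation_heatmap(m, domain)
  ggplot2::ggsave(path, pl, width = width, height = height, dpi = dpi)
  df <- attr(pl, "matrix_data") |>
    mutate(angle = as.character(.data$angle), pair_name = as.character(.data$pair_name))
  readr::write_csv(df, .sidecar_path(path))
  invisible(df)
}

#' Box plot of the four clinical angles
#'
#' Distribution of HVA, IMA, DMAA and HIA across a cohort, one box per
#' angle, Tukey whiskers (1.5 x IQR).
#'
#' @param cohort A cohort table with the four angle columns.
#' @return A ggplot object.
#' @export
plot_angle_boxplot <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0) abort("empty cohort table")
  miss <- setdiff(ANGLE_NAMES, names(cohort))
  if (length(miss) > 0) abort(paste0("cohort is missing angle column(s): ",
                                     paste(miss, collapse = ", ")))
  df <- cohort |>
    select(all_of(ANGLE_NAMES)) |>
    tidyr::pivot_longer(everything(), names_to = "angle", values_to = "degrees") |>
    mutate(angle = factor(.data$angle, levels = ANGLE_NAMES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$degrees)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_x_discrete(labels = toupper) +
    ggplot2::labs(x = NULL, y = "degrees") +
    ggplot2::theme_minimal()
}

#' Render the angle box plot to disk
#'
#' @inheritParams plot_angle_boxplot
#' @param path Output PNG path.
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()].
#' @return The plot, invisibly.
#' @export
render_angle_boxplot <- function(cohort, path, width = 5, height = 4, dpi = 150) {
  pl <- plot_angle_boxplot(cohort)
  ggplot2::ggsave(path, pl, width = width, height = height, dpi = dpi)
  invisible(pl)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a correlation screen as a heatmap
#'
#' @param object An `hv_screen` object.
#' @param ... Passed to [plot_correlation_heatmap()].
#' @return A ggplot object.
#' @export
autoplot.hv_screen <- function(object, ...) {
  plot_correlation_heatmap(correlation_matrix(object), ...)
}
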