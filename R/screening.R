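#' Sample Pearson correlation coefficient
#'
#' The product-moment correlation between two equal-length vectors. Thin
#' validating wrapper around [stats::cor()]: correlation is undefined for
#' constant input or fewer than three observations, and both are hard errors
#' here rather than `NA`s, because a silent `NA` in a 1104-record screen is
#' easy to miss.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return A single number in `[-1, 1]`.
#' @examples
#' pearson_r(1:4, c(2, 1, 4, 3)) # 0.6
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("x and y must be finite")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined: zero variance")
  as.numeric(cor(x, y))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the standard t-transform `t = r * sqrt((n - 2) / (1 - r^2))` referred
#' to a t distribution with `n - 2` degrees of freedom (the same test
#' [stats::cor.test()] performs). For `|r| = 1` the transform diverges; the
#' limit `p = 0` is returned with a warning.
#'
#' @param r Pearson coefficient(s) in `[-1, 1]` (vectorized).
#' @param n Number of paired observations (single integer >= 3).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @examples
#' pearson_pvalue(0.6, 4)
#' @export
pearson_pvalue <- function(r, n) {
  if (length(n) != 1 || !is.finite(n) || n < 3) abort("n must be a single integer >= 3")
  if (any(abs(r) > 1)) abort("|r| must not exceed 1")
  p <- rep(0, length(r))
  sat <- abs(r) == 1
  if (any(sat)) warn("|r| = 1: returning the limiting p-value 0")
  tval <- r[!sat] * sqrt((n - 2) / (1 - r[!sat]^2))
  p[!sat] <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p
}

#' Default correlation screening criteria
#'
#' Per-angle absolute-r thresholds and the significance level used to flag
#' distance features: `|r| >= 0.4` for HVA and IMA, `|r| >= 0.3` for DMAA and
#' HIA (where no correlation reaches 0.4), all at two-sided `p < 0.05`.
#'
#' @param r_hva,r_ima,r_dmaa,r_hia Absolute-r thresholds per angle.
#' @param alpha Significance level, in (0, 1).
#' @return A list with elements `r_threshold` (named numeric) and `alpha`.
#' @export
hv_screen_criteria <- function(r_hva = 0.4, r_ima = 0.4, r_dmaa = 0.3, r_hia = 0.3,
                               alpha = 0.05) {
  thr <- c(hva = r_hva, ima = r_ima, dmaa = r_dmaa, hia = r_hia)
  if (any(thr < 0 | thr > 1)) abort("r thresholds must be in [0, 1]")
  if (length(alpha) != 1 || alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  list(r_threshold = thr, alpha = alpha)
}

.cohort_matrices <- function(cohort) {
  pairs <- .pair_table()
  miss <- setdiff(pairs$pair_name, names(cohort))
  if (length(miss) > 0) {
    abort(paste0("cohort is missing ", length(miss), " distance column(s): ",
                 paste(head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) ", ..." else ""))
  }
  miss_a <- setdiff(ANGLE_NAMES, names(cohort))
  if (length(miss_a) > 0) {
    abort(paste0("cohort is missing angle column(s): ", paste(miss_a, collapse = ", ")))
  }
  A <- as.matrix(cohort[ANGLE_NAMES])
  if (anyNA(A)) abort("missing angle values in rows entering correlation screening")
  D <- as.matrix(cohort[pairs$pair_name])
  if (anyNA(D)) abort("missing distance values in rows entering correlation screening")
  list(A = A, D = D, pairs = pairs)
}

#' Screen distance features against the clinical angles
#'
#' Computes the Pearson correlation of each of the 276 normalized distance
#' features with each of the four angles (1104 records), with a two-sided
#' p-value, and flags the records meeting the screening criteria
#' (`p < alpha` and `|r|` at or above the per-angle threshold). No multiple
#' testing correction is applied by default — the screen is an exploratory
#' raw-p filter — but Benjamini-Hochberg adjustment across all 1104 records
#' is available via `fdr = TRUE`.
#'
#' @param cohort A cohort table from [measure_cohort()] (or
#'   [simulate_cohort()]); every distance column and all four angle columns
#'   must be present and complete.
#' @param criteria Screening criteria from [hv_screen_criteria()].
#' @param fdr If `TRUE`, flag on Benjamini-Hochberg adjusted p-values instead
#'   of raw ones.
#' @param method `"t"` for the t-transform p-value (default) or
#'   `"permutation"` for a Monte-Carlo permutation p-value, useful at small
#'   n where the t approximation is doubtful.
#' @param n_perm Number of permutations when `method = "permutation"`.
#' @param seed Optional seed for the permutation draw.
#' @return A tibble of class `hv_screen` with one row per (angle, pair):
#'   `angle`, `landmark_i`, `landmark_j`, `pair_name`, `r`, `p`
#'   (and `p_adj` when `fdr = TRUE`), `n`, `flagged`, `sign`; ordered by
#'   angle (HVA, IMA, DMAA, HIA) then canonical pair order. [tidy()],
#'   [glance()] and [ggplot2::autoplot()] methods are provided.
#' @examples
#' sim <- simulate_cohort(cohort_params(n_feet = 40, seed = 1))
#' scr <- screen_correlations(sim$cohort)
#' glance(scr)
#' @export
screen_correlations <- function(cohort, criteria = hv_screen_criteria(),
                                fdr = FALSE,
                                method = c("t", "permutation"),
                                n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  m <- .cohort_matrices(cohort)
  n <- nrow(m$A)
  if (n < 3) abort("need at least 3 feet to screen correlations")
  if (any(apply(m$A, 2, sd) == 0)) {
    abort("correlation undefined: an angle column has zero variance")
  }
  # the self-normalized proximal phalanx pair is identically 1 in normalized
  # cohorts; correlation is undefined for it (and any other constant
  # feature), so such records carry r = NA and are never flagged
  const_feat <- apply(m$D, 2, sd) == 0
  if (any(const_feat)) {
    warn(paste0(sum(const_feat), " constant distance feature(s) screened as NA: ",
                paste(head(colnames(m$D)[const_feat], 3), collapse = ", ")))
  }

  R <- suppressWarnings(cor(m$D, m$A))   # 276 x 4; NA rows for constant features
  if (method == "t") {
    P <- matrix(NA_real_, nrow(R), ncol(R), dimnames = dimnames(R))
    ok <- !is.na(c(R))
    P[ok] <- pearson_pvalue(c(R)[ok], n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- matrix(0L, nrow = nrow(R), ncol = ncol(R))
    for (b in seq_len(n_perm)) {
      Rp <- suppressWarnings(cor(m$D, m$A[sample.int(n), , drop = FALSE]))
      exceed <- exceed + (abs(Rp) >= abs(R))
    }
    P <- (exceed + 1) / (n_perm + 1)
    P[is.na(R)] <- NA_real_
  }

  rec <- tidyr::expand_grid(
    angle = factor(ANGLE_NAMES, levels = ANGLE_NAMES),
    m$pairs
  ) |>
    arrange(.data$angle) |>
    mutate(
      angle = as.character(.data$angle),
      r = c(R[, ANGLE_NAMES]),
      p = c(P[, ANGLE_NAMES]),
      n = n
    )
  p_use <- if (fdr) stats::p.adjust(rec$p, method = "BH") else rec$p
  rec <- rec |>
    mutate(
      p_adj = if (fdr) p_use else NULL,
      flagged = !is.na(.data$r) & p_use < criteria$alpha &
        abs(.data$r) >= unname(criteria$r_threshold[.data$angle]),
      sign = ifelse(is.na(.data$r), NA_character_,
                    ifelse(.data$r >= 0, "positive", "negative"))
    )
  structure(rec, class = c("hv_screen", class(rec)),
            criteria = criteria, fdr = fdr, method = method)
}

#' Correlation matrix of a full screening record set
#'
#' Reshapes a complete screening result into the 276 x 4 matrix of Pearson
#' coefficients underlying the correlation heatmap, rows in canonical pair
#' order, columns HVA, IMA, DMAA, HIA.
#'
#' @param records An `hv_screen` tibble (all 1104 records present).
#' @return A 276 x 4 numeric matrix with pair names as row names.
#' @export
correlation_matrix <- function(records) {
  pairs <- .pair_table()
  need <- tidyr::expand_grid(angle = ANGLE_NAMES, pair_name = pairs$pair_name)
  have <- select(records, "angle", "pair_name")
  if (nrow(records) != nrow(need) ||
      nrow(anti_join(need, have, by = c("angle", "pair_name"))) > 0) {
    abort("incomplete record set: need one record per (angle, pair)")
  }
  wide <- records |>
    select("angle", "pair_name", "r") |>
    tidyr::pivot_wider(names_from = "angle", values_from = "r")
  M <- as.matrix(wide[match(pairs$pair_name, wide$pair_name), ANGLE_NAMES])
  rownames(M) <- pairs$pair_name
  M
}

# ---- broom-style methods -----------------------------------------------------

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a correlation screen
#'
#' @param x An `hv_screen` object.
#' @param flagged_only Return only flagged records.
#' @param ... Unused.
#' @return A plain tibble of screening records.
#' @export
tidy.hv_screen <- function(x, flagged_only = FALSE, ...) {
  out <- as_tibble(unclass(x))
  if (flagged_only) out <- filter(out, .data$flagged)
  out
}

#' One-row summary of a correlation screen
#'
#' @param x An `hv_screen` object.
#' @param ... Unused.
#' @return A one-row tibble: feet screened, records, flags per angle, alpha.
#' @export
glance.hv_screen <- function(x, ...) {
  crit <- attr(x, "criteria")
  flags <- tidy(x) |>
    group_by(.data$angle) |>
    summarise(nf = sum(.data$flagged), .groups = "drop")
  out <- tibble(
    n_feet = x$n[1],
    n_records = nrow(x),
    n_flagged = sum(x$flagged),
    alpha = crit$alpha,
    fdr = attr(x, "fdr")
  )
  for (a in ANGLE_NAMES) {
    out[[paste0("flagged_", a)]] <- flags$nf[match(a, flags$angle)]
  }
  out
}
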