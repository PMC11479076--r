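#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation after pairwise deletion of missing values,
#' with a two-sided confidence interval from the Fisher z transform:
#' `atanh(r) +/- qnorm(1 - alpha/2) / sqrt(n - 3)`, back-transformed.
#' Perfect correlations (|r| = 1) get the degenerate interval `[r, r]`.
#'
#' @param x,y Numeric vectors of equal length; pairs with any `NA` are
#'   dropped.
#' @param alpha Two-sided error rate (default 0.05 for a 95% CI).
#' @param pair_name Optional label for the result.
#' @param group Optional cohort subset label.
#' @return Tibble row: `pair`, `group`, `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_ci <- function(x, y, alpha = 0.05, pair_name = "x~y",
                       group = "all") {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("insufficient data: need at least 3 complete pairs",
                  call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15 || n <= 3) {
    lo <- hi <- if (abs(r) >= 1 - 1e-15) r else NA_real_
    if (n > 3) { lo <- r; hi <- r }
  } else {
    z <- atanh(r)
    hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
    lo <- tanh(z - hw)
    hi <- tanh(z + hw)
  }
  tibble::tibble(pair = pair_name, group = group, r = r,
                 ci_low = lo, ci_high = hi, n = n)
}

#' Measurements-by-parameters matrix
#'
#' Pivots a tidy parameter table (from [compute_cohort_parameters()]) into
#' one row per measurement with columns named `<target>_angle`,
#' `<target>_ellipse` and `<target>_shift`, using the left-right averaged
#' values on one plane (angle ranges and ellipse areas) plus the axial
#' outward shifts.
#'
#' @param params Tidy parameter tibble.
#' @param plane Plane for angle ranges and ellipse areas
#'   (default `"sagittal"`).
#' @param side Which side's values to use (default `"mean"`).
#' @return Wide tibble with `measurement_id`, `group` (if present) and one
#'   column per parameter.
#' @export
parameter_matrix <- function(params, plane = "sagittal", side = "mean") {
  sel <- params[params$side == side &
                  ((params$metric %in% c("angle_range", "ellipse_area") &
                      params$plane == plane) |
                     params$metric == "outward_shift"), ]
  sel$name <- paste0(sel$target, "_",
                     c(angle_range = "angle", ellipse_area = "ellipse",
                       outward_shift = "shift")[sel$metric])
  keys <- intersect(c("measurement_id", "subject_id", "group"), names(sel))
  tidyr::pivot_wider(sel[, c(keys, "name", "value")],
                     names_from = "name", values_from = "value")
}

#' Default upper-lower limb parameter pair inventory
#'
#' Upper-limb angle ranges (shoulder, elbow) against lower-limb angle ranges
#' (hip, knee), and upper-limb ellipse areas (shoulder, elbow, hand) against
#' lower-limb ellipse areas (hip, knee, heel).
#'
#' @return Tibble with columns `upper`, `lower` (parameter-matrix column
#'   names).
#' @export
default_parameter_pairs <- function() {
  angles <- expand.grid(upper = c("shoulder_angle", "elbow_angle"),
                        lower = c("hip_angle", "knee_angle"),
                        stringsAsFactors = FALSE)
  areas <- expand.grid(
    upper = c("shoulder_ellipse", "elbow_ellipse", "hand_ellipse"),
    lower = c("hip_ellipse", "knee_ellipse", "heel_ellipse"),
    stringsAsFactors = FALSE)
  tibble::as_tibble(rbind(angles, areas))
}

#' Correlation table between upper- and lower-limb parameters
#'
#' Pearson r (with Fisher-z CI) for every requested parameter pair, overall
#' and optionally per cohort group. Measurements are the correlation unit;
#' missing values are handled by pairwise deletion, and cells with fewer
#' than 3 complete pairs or zero variance are flagged rather than computed.
#' Cells with `|r| > 0.3` are marked in the `highlight` column.
#'
#' @param params Tidy parameter tibble from [compute_cohort_parameters()].
#' @param pairs Tibble with `upper`, `lower` columns
#'   (default [default_parameter_pairs()]).
#' @param by_group Also compute per-group cells (default `TRUE` when a
#'   `group` column is present).
#' @param plane,side Passed to [parameter_matrix()].
#' @param alpha CI error rate.
#' @return Tibble: `upper`, `lower`, `group`, `r`, `ci_low`, `ci_high`,
#'   `n`, `ok`, `note`, `highlight`.
#' @export
parameter_correlation_table <- function(params,
                                        pairs = default_parameter_pairs(),
                                        by_group = NULL,
                                        plane = "sagittal", side = "mean",
                                        alpha = 0.05) {
  if (nrow(pairs) == 0) stop("empty pair list", call. = FALSE)
  wide <- parameter_matrix(params, plane, side)
  has_group <- "group" %in% names(wide)
  by_group <- by_group %||% has_group
  groups <- "all"
  if (by_group && has_group) groups <- c("all", unique(wide$group))

  rows <- list()
  for (g in groups) {
    sub <- if (g == "all" || !has_group) wide else wide[wide$group == g, ]
    for (i in seq_len(nrow(pairs))) {
      up <- pairs$upper[i]; lo <- pairs$lower[i]
      res <- tryCatch(
        pearson_ci(sub[[up]], sub[[lo]], alpha,
                   pair_name = paste(up, lo, sep = " ~ "), group = g),
        error = function(e) e
      )
      rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
        tibble::tibble(upper = up, lower = lo, group = g, r = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       n = sum(is.finite(sub[[up]]) & is.finite(sub[[lo]])),
                       ok = FALSE, note = conditionMessage(res))
      } else {
        tibble::tibble(upper = up, lower = lo, group = g, r = res$r,
                       ci_low = res$ci_low, ci_high = res$ci_high,
                       n = res$n, ok = TRUE, note = NA_character_)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$highlight <- !is.na(out$r) & abs(out$r) > 0.3
  out
}

#' Per-group distribution summary
#'
#' Long-format distribution summary of every parameter per cohort group:
#' n (non-missing), mean, SD, median and quartiles — the numbers behind
#' group-comparison violin plots.
#'
#' @param params Tidy parameter tibble with a `group` column.
#' @param metrics Metrics to include (default all).
#' @param side Side filter (default `"mean"`).
#' @return Tibble: `group`, `metric`, `plane`, `target`, `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`.
#' @export
group_distribution_summary <- function(params,
                                       metrics = c("angle_range",
                                                   "ellipse_area",
                                                   "outward_shift"),
                                       side = "mean") {
  if (!"group" %in% names(params)) {
    stop("params must carry a 'group' column", call. = FALSE)
  }
  bad <- setdiff(unique(params$group),
                 c("HD", "PD", "CM", "healthy", "unknown"))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sel <- params[params$metric %in% metrics & params$side == side, ]
  dplyr::summarise(
    dplyr::group_by(sel, .data$group, .data$metric, .data$plane,
                    .data$target),
    n = sum(is.finite(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = if (sum(is.finite(.data$value)) > 1)
      stats::sd(.data$value, na.rm = TRUE) else NA_real_,
    median = stats::median(.data$value, na.rm = TRUE),
    q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
    q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
    .groups = "drop"
  )
}
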