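#' Validation configuration
#'
#' Scoring parameters: the z-score threshold for outlier exclusion (1.96, a
#' two-sided 95% interval), the accuracy category boundaries (RMSE below 5
#' degrees is "excellent", 5-10 degrees inclusive "good", above 10 degrees
#' "unacceptable"), and the gimbal gate (reference |roll| above 85 degrees
#' flags proximity to the Euler singularity).
#'
#' @param z_threshold outlier exclusion |z| threshold (default 1.96).
#' @param excellent_max upper bound of "excellent", degrees (default 5).
#' @param good_max upper bound of "good", degrees (default 10).
#' @param gimbal_gate |roll| gate in degrees for gimbal proximity (default 85).
#' @return a `validation_config` list.
#' @export
validation_config <- function(z_threshold = 1.96, excellent_max = 5,
                              good_max = 10, gimbal_gate = 85) {
  if (z_threshold <= 0) abort("`z_threshold` must be > 0")
  if (!(0 < excellent_max && excellent_max < good_max)) {
    abort("need 0 < excellent_max < good_max")
  }
  structure(list(z_threshold = z_threshold, excellent_max = excellent_max,
                 good_max = good_max, gimbal_gate = gimbal_gate),
            class = "validation_config")
}

#' Per-angle RMSE between aligned sensor and reference trajectories
#'
#' Root-mean-square error per Euler channel, with each sample difference
#' wrapped to (-180, 180] before squaring so errors across the angle seam are
#' measured on the circle. Also reports the fraction of reference samples
#' with |roll| above the gimbal gate -- a flag that pitch/yaw errors in this
#' segment may be singularity artefacts rather than sensor error.
#'
#' @param sensor,reference `euler_trajectory` objects of equal length on the
#'   same grid (see [align_pair()]), already synchronized, heading-corrected
#'   and baselined.
#' @param cfg a [validation_config()].
#' @return a one-row `rmse_triple` tibble: `roll, pitch, yaw` (degrees),
#'   `n_samples`, `gimbal_fraction`.
#' @export
rmse_per_angle <- function(sensor, reference, cfg = validation_config()) {
  if (nrow(sensor) != nrow(reference)) {
    abort("sensor and reference must have equal length; align_pair() them first")
  }
  rmse1 <- function(a, b) sqrt(mean(wrap_deg(a - b)^2))
  out <- tibble(
    roll = rmse1(sensor$roll_deg, reference$roll_deg),
    pitch = rmse1(sensor$pitch_deg, reference$pitch_deg),
    yaw = rmse1(sensor$yaw_deg, reference$yaw_deg),
    n_samples = nrow(sensor),
    gimbal_fraction = mean(abs(reference$roll_deg) > cfg$gimbal_gate)
  )
  class(out) <- c("rmse_triple", class(out))
  out
}

#' z-score outlier exclusion across recordings
#'
#' Single (non-iterative) pass: z-scores are computed on the raw values and
#' values with |z| above the threshold are excluded. With zero spread nothing
#' can be an outlier and everything is kept.
#'
#' @param values numeric vector of per-recording RMSE values (length >= 3;
#'   spread cannot be judged from fewer).
#' @param cfg a [validation_config()].
#' @return a list: `kept`, `excluded` (values), `kept_idx`, `mean`, `sd` of
#'   the kept set, and `sd_raw` of the full set.
#' @export
exclude_outliers <- function(values, cfg = validation_config()) {
  if (length(values) < 3L) {
    abort("need at least 3 values to judge spread for outlier exclusion")
  }
  s <- sd(values)
  if (s == 0) {
    keep <- rep(TRUE, length(values))
  } else {
    keep <- abs((values - mean(values)) / s) <= cfg$z_threshold
  }
  list(kept = values[keep], excluded = values[!keep], kept_idx = which(keep),
       mean = mean(values[keep]), sd = sd(values[keep]), sd_raw = s)
}

#' Accuracy category of an RMSE value
#'
#' @param value RMSE in degrees (>= 0); vectorized.
#' @param cfg a [validation_config()].
#' @return character vector: `"excellent"` (below 5), `"good"` (5 to 10
#'   inclusive), `"unacceptable"` (above 10), under the default boundaries.
#' @export
classify_rmse <- function(value, cfg = validation_config()) {
  if (any(value < 0)) abort("RMSE values cannot be negative")
  dplyr::case_when(
    value < cfg$excellent_max ~ "excellent",
    value <= cfg$good_max ~ "good",
    TRUE ~ "unacceptable"
  )
}

#' Aggregate per-recording RMSE into a placement x movement report
#'
#' For each (placement, movement, angle) cell: applies z-score outlier
#' exclusion across recordings (when at least 3 are available), then reports
#' the mean and SD of the kept values and the accuracy category of the mean.
#' A cell with a single recording reports that value with SD 0.
#'
#' @param results a tibble with columns `placement`, `movement`,
#'   `recording`, `angle` (roll/pitch/yaw), `rmse`; or a wide form with
#'   `roll`, `pitch`, `yaw` columns instead of `angle`/`rmse`.
#' @param cfg a [validation_config()].
#' @return a `validation_report` tibble: one row per placement x movement x
#'   angle with `rmse_mean`, `sd` (kept set), `sd_raw`, `category`,
#'   `n_included`, `n_excluded`.
#' @export
summarize_validation <- function(results, cfg = validation_config()) {
  if (all(c("roll", "pitch", "yaw") %in% names(results))) {
    results <- tidyr::pivot_longer(results, c("roll", "pitch", "yaw"),
                                   names_to = "angle", values_to = "rmse")
  }
  need <- c("placement", "movement", "angle", "rmse")
  if (!all(need %in% names(results))) {
    abort(paste("`results` needs columns", paste(need, collapse = ", ")))
  }
  out <- results |>
    dplyr::group_by(.data$placement, .data$movement, .data$angle) |>
    dplyr::group_modify(function(d, key) {
      v <- d$rmse
      if (length(v) == 0L) {
        return(tibble(rmse_mean = NA_real_, sd = NA_real_, sd_raw = NA_real_,
                      category = "missing", n_included = 0L, n_excluded = 0L))
      }
      if (length(v) >= 3L) {
        ex <- exclude_outliers(v, cfg)
        kept <- ex$kept; sd_raw <- ex$sd_raw
      } else {
        kept <- v; sd_raw <- if (length(v) > 1L) sd(v) else 0
      }
      m <- mean(kept)
      tibble(rmse_mean = m,
             sd = if (length(kept) > 1L) sd(kept) else 0,
             sd_raw = if (length(v) > 1L) sd_raw else 0,
             category = classify_rmse(m, cfg),
             n_included = length(kept),
             n_excluded = length(v) - length(kept))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(angle = factor(.data$angle, levels = c("roll", "pitch", "yaw"))) |>
    dplyr::arrange(.data$placement, .data$movement, .data$angle)
  class(out) <- c("validation_report", class(out))
  out
}

#' Render a validation report as an aligned text grid
#'
#' Rows are placements, columns movement x angle; each cell shows
#' `rmse_mean (sd) <E|G|U>`. Cells without data are marked `--` (mirroring
#' conditions excluded from a study, e.g. by marker occlusion).
#'
#' @param report a `validation_report` from [summarize_validation()].
#' @return the grid as a character vector of lines, invisibly; printed as a
#'   side effect.
#' @export
render_validation_grid <- function(report) {
  cat(format_validation_grid(report), sep = "\n")
  invisible(format_validation_grid(report))
}

format_validation_grid <- function(report) {
  letter <- c(excellent = "E", good = "G", unacceptable = "U", missing = "-")
  wide <- report |>
    dplyr::mutate(cell = ifelse(.data$category == "missing", "--",
                                sprintf("%.1f (%.1f) %s", .data$rmse_mean, .data$sd,
                                        letter[.data$category])),
                  col = paste(.data$movement, .data$angle, sep = "/")) |>
    dplyr::select("placement", "col", "cell") |>
    tidyr::pivot_wider(names_from = "col", values_from = "cell", values_fill = "--")
  cols <- names(wide)
  widths <- vapply(cols, function(cn) max(nchar(c(cn, wide[[cn]]))), integer(1))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste(mapply(pad, cols, widths), collapse = "  ")
  rows <- apply(wide, 1L, function(r) paste(mapply(pad, r, widths), collapse = "  "))
  c(header, rows)
}
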