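#' Read and write sensor component and orientation files
#'
#' All pipeline data round-trips through a documented delimited-text dialect:
#' comma-separated values preceded by `#`-prefixed metadata header lines
#' (`key: value`). Component files carry columns `t_s, x, y, z` with a
#' mandatory `units` header (`g`, `deg/s` or `gauss`); orientation files carry
#' `t_s, roll_deg, pitch_deg, yaw_deg` with `units: deg`. Readers validate
#' units and timestamp monotonicity and report offending line numbers; there
#' is no silent unit guessing.
#'
#' @param recording a `marg_recording`.
#' @param dir directory to write the three component files into (created if
#'   missing).
#' @param paths named character vector/list with entries `accel`, `gyro`,
#'   `mag`.
#' @param traj an `euler_trajectory`.
#' @param path file path.
#' @param extra named character vector of additional header fields (e.g. a
#'   config hash).
#' @return readers return the parsed object; writers return the path(s)
#'   invisibly.
#' @name marg_io
NULL

component_units <- c(accel = "g", gyro = "deg/s", mag = "gauss")

write_header <- function(path, fields) {
  lines <- sprintf("# %s: %s", names(fields), vapply(fields, as.character, ""))
  writeLines(lines, path)
}

#' @rdname marg_io
#' @export
write_marg <- function(recording, dir, extra = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (comp in c("accel", "gyro", "mag")) {
    path <- file.path(dir, paste0(comp, ".csv"))
    fields <- c(list(component = comp, units = component_units[[comp]],
                     rate_hz = recording$rates[[comp]] %||% NA,
                     placement = recording$placement,
                     handedness = recording$handedness,
                     seed = recording$seed %||% "NA"), as.list(extra))
    write_header(path, fields)
    readr::write_csv(recording[[comp]], path, append = TRUE, col_names = TRUE)
    paths[comp] <- path
  }
  invisible(paths)
}

read_header <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  out <- lapply(kv, function(m) if (length(m) == 3L) trimws(m[3]) else NULL)
  names(out) <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[2]) else "", "")
  out[names(out) != ""]
}

read_component <- function(path, component) {
  hdr <- read_header(path)
  if (is.null(hdr$units)) {
    abort(sprintf("%s: missing 'units' header line; refusing to guess units", path))
  }
  expected <- component_units[[component]]
  if (!identical(hdr$units, expected)) {
    abort(sprintf("%s: unit mismatch: expected '%s' for %s, found '%s'",
                  path, expected, component, hdr$units))
  }
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_double()))
  if (!all(c("t_s", "x", "y", "z") %in% names(d))) {
    abort(sprintf("%s: expected columns t_s, x, y, z", path))
  }
  bad <- which(diff(d$t_s) <= 0)
  if (length(bad) > 0L) {
    n_header <- length(grep("^#", readLines(path, n = 50L))) + 1L
    abort(sprintf("%s: non-monotone timestamp at data row %d (file line %d)",
                  path, bad[1] + 1L, bad[1] + 1L + n_header))
  }
  list(data = as_tibble(d), header = hdr)
}

#' @rdname marg_io
#' @export
read_marg <- function(paths) {
  if (is.null(names(paths))) names(paths) <- c("accel", "gyro", "mag")
  parts <- lapply(c(accel = "accel", gyro = "gyro", mag = "mag"),
                  function(comp) read_component(paths[[comp]], comp))
  hdr <- parts$accel$header
  rates <- vapply(parts, function(p) as.numeric(p$header$rate_hz %||% NA), numeric(1))
  new_marg_recording(parts$accel$data, parts$gyro$data, parts$mag$data,
                     placement = hdr$placement %||% "C",
                     handedness = hdr$handedness %||% "right",
                     rates = setNames(rates, c("accel", "gyro", "mag")),
                     seed = if (!is.null(hdr$seed) && hdr$seed != "NA")
                       as.integer(hdr$seed) else NULL)
}

#' @rdname marg_io
#' @export
write_orientation <- function(traj, path, extra = NULL) {
  fields <- c(list(component = "orientation", units = "deg",
                   rate_hz = traj_rate(traj),
                   frame = attr(traj, "frame") %||% "lab"), as.list(extra))
  write_header(path, fields)
  readr::write_csv(as_tibble(traj)[, c("t_s", "roll_deg", "pitch_deg", "yaw_deg")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname marg_io
#' @export
read_orientation <- function(path) {
  hdr <- read_header(path)
  if (is.null(hdr$units)) {
    abort(sprintf("%s: missing 'units' header line; refusing to guess units", path))
  }
  if (!identical(hdr$units, "deg")) {
    abort(sprintf("%s: unit mismatch: expected 'deg', found '%s'", path, hdr$units))
  }
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_double()))
  if (!all(c("t_s", "roll_deg", "pitch_deg", "yaw_deg") %in% names(d))) {
    abort(sprintf("%s: expected columns t_s, roll_deg, pitch_deg, yaw_deg", path))
  }
  bad <- which(diff(d$t_s) <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("%s: non-monotone timestamp at data row %d", path, bad[1] + 1L))
  }
  new_euler_trajectory(d, rate = as.numeric(hdr$rate_hz %||% NA),
                       frame = hdr$frame %||% "lab")
}

#' Serialize a magnetometer calibration to plain text
#'
#' Key-value text (matrix row-major), so a processing run can be reproduced
#' from its artifacts.
#'
#' @param cal a `mag_calibration`.
#' @param path file path.
#' @return `write_mag_calibration()` the path invisibly;
#'   `read_mag_calibration()` the calibration object.
#' @export
write_mag_calibration <- function(cal, path) {
  lines <- c(
    sprintf("soft_iron_inv: %s", paste(sprintf("%.17g", t(cal$soft_iron_inv)), collapse = " ")),
    sprintf("hard_iron: %s", paste(sprintf("%.17g", cal$hard_iron), collapse = " ")),
    sprintf("field_magnitude: %.17g", cal$field_magnitude),
    sprintf("norm_cv: %.17g", cal$norm_cv)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mag_calibration
#' @export
read_mag_calibration <- function(path) {
  kv <- read.dcf(textConnection(readLines(path)))
  num <- function(k) as.numeric(strsplit(trimws(kv[1, k]), "\\s+")[[1]])
  structure(list(
    soft_iron_inv = matrix(num("soft_iron_inv"), 3L, 3L, byrow = TRUE),
    hard_iron = num("hard_iron"),
    field_magnitude = num("field_magnitude"),
    norm_cv = num("norm_cv")
  ), class = "mag_calibration")
}
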