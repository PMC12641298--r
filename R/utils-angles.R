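#' Angle helpers
#'
#' Degree-based angle utilities used throughout the package. All user-facing
#' angles are degrees; radians appear only inside the fusion filter.
#'
#' `wrap_deg()` wraps to the interval (-180, 180]. `unwrap_deg()` removes
#' 360-degree jumps so a wrapped series becomes continuous (the inverse of
#' wrapping, up to a multiple of 360 on the first sample).
#' `circular_mean_deg()` is the direction of the mean unit vector, so averages
#' near the +/-180 seam behave correctly.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of angles in degrees.
#' @examples
#' wrap_deg(190)            # -170
#' circular_mean_deg(c(-179, 179))  # 180, not 0
#' @name angles
NULL

#' @rdname angles
#' @export
wrap_deg <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

#' @rdname angles
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  steps <- wrap_deg(diff(x))
  x[1L] + c(0, cumsum(steps))
}

#' @rdname angles
#' @export
circular_mean_deg <- function(x) {
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## FNV-1a over the deparsed object; a stable short fingerprint for run configs
## written into output headers.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    ## xor the low byte only (h exceeds bitwXor's integer range)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## 32-bit FNV prime multiply (16777619 = 2^24 + 403), carried in doubles:
    ## the 2^24 term reduces mod 2^32 to the low byte, keeping products < 2^53
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %g", name, min))
  }
  invisible(x)
}
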