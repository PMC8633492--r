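# Internal helpers shared across modules.

# Classed error constructor so callers/tests can branch on condition class
# rather than message text.
cf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "culmforce_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

cf_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "culmforce_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps generators deterministic without clobbering the session stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Degree-based trig, exact at multiples of 90 degrees.
cos_deg <- function(x) cospi(x / 180)
sin_deg <- function(x) sinpi(x / 180)
tan_deg <- function(x) sinpi(x / 180) / cospi(x / 180)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Azimuth in degrees in [0, 360).
atan2_deg <- function(y, x) {
  a <- rad2deg(atan2(y, x))
  (a %% 360)
}

#' Convert between incline conventions
#'
#' Bundle incline is measured from the stem cross-sectional (orthogonal)
#' plane, so 90 degrees means parallel to the stem axis. Some workflows
#' prefer the complementary from-axis tilt; this converts between the two.
#'
#' @param incline_deg angle in degrees from the cross-sectional plane.
#' @return the complementary angle (degrees from the stem axis), and
#'   vice versa: the conversion is its own inverse.
#' @examples
#' incline_from_axis(90) # vertical fibre -> 0 from axis
#' incline_from_axis(65) # 25 degrees away from the stem axis
#' @export
incline_from_axis <- function(incline_deg) {
  stopifnot(is.numeric(incline_deg))
  90 - incline_deg
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
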