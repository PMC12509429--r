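#' PARS-3 physical activity score
#'
#' Scores physical activity from the three ordinal grades of the Physical
#' Activity Rating Scale-3 as `intensity * duration * frequency`. Under the
#' default grade coding (intensity 1-5, duration 0-4, frequency 1-5) the
#' maximum attainable score is 100 and a zero duration annihilates the score.
#'
#' @param intensity,duration,frequency integer grade vectors (recycled to a
#'   common length).
#' @param ranges list with elements `intensity`, `duration`, `frequency`,
#'   each a length-2 integer vector giving the inclusive grade range.
#' @return Integer vector of activity scores.
#' @examples
#' pars3_score(5, 4, 5)  # 100
#' pars3_score(3, 2, 4)  # 24
#' @export
pars3_score <- function(intensity, duration, frequency,
                        ranges = pars3_ranges()) {
  n <- max(length(intensity), length(duration), length(frequency))
  g <- list(intensity = rep_len(intensity, n),
            duration  = rep_len(duration, n),
            frequency = rep_len(frequency, n))
  for (nm in names(g)) {
    r <- ranges[[nm]]
    bad <- g[[nm]] < r[1] | g[[nm]] > r[2] | g[[nm]] != round(g[[nm]])
    if (any(bad))
      stop_gapdml("%s grade outside configured range [%d, %d]", nm, r[1], r[2])
  }
  as.integer(g$intensity * g$duration * g$frequency)
}

#' Default PARS-3 grade coding
#'
#' The grade ranges adopted for the three PARS-3 items. They are chosen so
#' that the maximal product is 100 (5 x 4 x 5); the instrument's published
#' descriptions fix the maximum but not the coding, so the ranges are
#' configurable everywhere they are used.
#'
#' @return Named list of length-2 integer ranges.
#' @export
pars3_ranges <- function() {
  list(intensity = c(1L, 5L), duration = c(0L, 4L), frequency = c(1L, 5L))
}

#' Raw intention-behavior gap
#'
#' The unnormalized difference `ideal - actual` between ideal and actual
#' activity scores. A raw difference of 20 points means something different
#' at a baseline of 60 than at a baseline of 20, which is why [delta_z()]
#' rescales it; the raw gap is kept as the traditional comparison outcome.
#'
#' @param ideal,actual numeric score vectors on the 0-100 PARS-3 scale.
#' @return Numeric vector `ideal - actual` (negative values propagate).
#' @examples
#' raw_gap(80, 60)  # 20
#' raw_gap(40, 20)  # 20
#' @export
raw_gap <- function(ideal, actual) {
  stopifnot(is.numeric(ideal), is.numeric(actual))
  ideal - actual
}

#' Baseline-corrected standardized gap
#'
#' Converts raw intention-behavior gaps into the relative index
#' `(ideal - actual) / sigma_actual`, where `sigma_actual` is one standard
#' deviation of the *actual* scores computed over the whole sample. The
#' single full-sample denominator expresses every respondent's gap in units
#' of population spread in achieved activity, removing baseline
#' heterogeneity while preserving ordering within the sample.
#'
#' @param ideal,actual equal-length numeric vectors (length >= 2).
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"` (n). The choice rescales the whole vector by a constant
#'   and is recorded in the result.
#' @return Object of class `gap_scores`: a list with `actual`, `ideal`,
#'   `raw_gap`, `delta_z`, `sigma_actual` and `sd_convention`.
#' @examples
#' g <- delta_z(ideal = c(40, 80), actual = c(20, 60))
#' g$delta_z       # 0.7071 0.7071
#' g$sigma_actual  # 28.2843
#' @export
delta_z <- function(ideal, actual, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(is.numeric(ideal), is.numeric(actual))
  if (length(ideal) != length(actual))
    stop_gapdml("ideal and actual must have equal length")
  if (length(actual) < 2)
    stop_gapdml("need at least 2 respondents to estimate sigma_actual")
  n <- length(actual)
  s2 <- var(actual)
  if (sd_convention == "population") s2 <- s2 * (n - 1) / n
  sigma <- sqrt(s2)
  if (!is.finite(sigma) || sigma <= 0)
    stop_gapdml("actual scores are constant: sigma_actual = 0, delta_z undefined")
  gap <- raw_gap(ideal, actual)
  structure(list(actual = actual, ideal = ideal, raw_gap = gap,
                 delta_z = gap / sigma, sigma_actual = sigma,
                 sd_convention = sd_convention),
            class = "gap_scores")
}

#' @export
print.gap_scores <- function(x, ...) {
  cat("Standardized intention-behavior gap scores\n")
  cat(sprintf("  n = %d respondents, sigma_actual = %.4f (%s SD)\n",
              length(x$actual), x$sigma_actual, x$sd_convention))
  cat(sprintf("  delta_z: mean %.4f, range [%.4f, %.4f]\n",
              mean(x$delta_z), min(x$delta_z), max(x$delta_z)))
  invisible(x)
}
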