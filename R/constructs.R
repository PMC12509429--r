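#' Construct specification
#'
#' A measurement specification for one latent construct: item labels and the
#' standardized loading of each item on the construct, on a 7-point Likert
#' response scale by default. Loadings are taken as given (from an
#' instrument's validation) — the package computes reliability/validity
#' statistics from them and uses them to simulate items, but never estimates
#' them.
#'
#' @param name short construct code, e.g. `"BEN"`.
#' @param loadings numeric vector of standardized loadings, each in (0, 1].
#' @param item_labels optional character labels; defaults to `name1..namek`.
#' @param n_levels number of Likert response levels (default 7).
#' @return Object of class `construct_spec`.
#' @examples
#' construct_spec("BEN", c(0.850, 0.913))
#' @export
construct_spec <- function(name, loadings, item_labels = NULL, n_levels = 7L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(loadings) < 1L || any(loadings <= 0 | loadings > 1))
    stop_gapdml("loadings for %s must all lie in (0, 1]", name)
  if (is.null(item_labels))
    item_labels <- paste0(name, seq_along(loadings))
  if (length(item_labels) != length(loadings))
    stop_gapdml("item_labels and loadings lengths differ for %s", name)
  if (n_levels < 2) stop_gapdml("n_levels must be >= 2")
  structure(list(name = name, loadings = as.numeric(loadings),
                 item_labels = item_labels, n_levels = as.integer(n_levels)),
            class = "construct_spec")
}

#' @export
print.construct_spec <- function(x, ...) {
  cat(sprintf("<construct_spec> %s: %d items (%d-point Likert), loadings %s\n",
              x$name, length(x$loadings), x$n_levels,
              paste(format(x$loadings, nsmall = 3), collapse = ", ")))
  invisible(x)
}

#' Default HBM + UTAUT instrument
#'
#' The thirteen-construct measurement model the package ships as its default
#' instrument: five Health Belief Model constructs (perceived benefits BEN,
#' affective attitude AT, perceived barriers BAR, perceived severity SEV,
#' self-efficacy SE) and eight smart-sports-technology constructs from the
#' UTAUT family (performance expectancy PE, effort expectancy EE, social
#' influence SI, facilitating conditions FC, personal innovation PN,
#' perceived risk PR, social support SS, usage intention UI), with the
#' published standardized loadings of each 7-point Likert item.
#'
#' @return Named list of [construct_spec()] objects.
#' @export
hbm_utaut_constructs <- function() {
  lam <- list(
    BEN = c(0.850, 0.913),
    AT  = c(0.897, 0.824),
    BAR = c(0.504, 0.728, 0.730, 0.741, 0.651),
    SEV = c(0.723, 0.761, 0.858),
    SE  = c(0.829, 0.934, 0.942, 0.837),
    PE  = c(0.915, 0.938, 0.919, 0.844),
    EE  = c(0.900, 0.915, 0.921),
    SI  = c(0.836, 0.955, 0.884),
    FC  = c(0.820, 0.871, 0.828),
    PN  = c(0.867, 0.864, 0.925, 0.895),
    PR  = c(0.663, 0.819, 0.858, 0.746, 0.822),
    SS  = c(0.737, 0.814, 0.864, 0.875),
    UI  = c(0.929, 0.936, 0.883, 0.927)
  )
  out <- lapply(names(lam), function(nm) construct_spec(nm, lam[[nm]]))
  names(out) <- names(lam)
  out
}

# construct codes per theory block (used for default latent correlations
# and for dimension aggregation)
hbm_codes   <- function() c("BEN", "AT", "BAR", "SEV", "SE")
utaut_codes <- function() c("PE", "EE", "SI", "FC", "PN", "PR", "SS", "UI")
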