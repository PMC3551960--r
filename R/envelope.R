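#' Fit a trapezoidal bioclimatic envelope model
#'
#' For each variable the preferred range is the (low, high) percentile pair
#' (default 10th/90th, linear interpolation) of the variable's values at
#' presence cells; the absolute limits are the observed presence min/max,
#' optionally widened by `buffer` times the preferred-range width. The 10/90
#' percentiles and trapezoid form are the usual parameterisation of
#' envelope models of this family; both are configurable because published
#' variants differ.
#'
#' @param presence A [presence_grid()].
#' @param env Training [env_stack()].
#' @param variables Variables to build envelopes for.
#' @param percentiles Length-2 vector of (low, high) percentile levels.
#' @param buffer Widening of the absolute limits as a fraction of the
#'   preferred-range width (default 0).
#' @param combination `"geometric_mean"` (default; keeps the suitability
#'   scale comparable across variable counts) or `"product"` (canonical
#'   envelope-model rule).
#' @return An object of class `envelope_model`.
#' @export
fit_envelope <- function(presence, env,
                         variables = c("sst", "sbt", "salinity"),
                         percentiles = c(0.1, 0.9), buffer = 0,
                         combination = c("geometric_mean", "product")) {
  combination <- match.arg(combination)
  stopifnot(length(variables) >= 1, length(percentiles) == 2,
            percentiles[1] < percentiles[2], buffer >= 0)
  cells <- which(presence$present)
  if (length(cells) < 5) stop("need at least 5 presence cells to fit an envelope")
  trapezoids <- list()
  for (v in variables) {
    layer <- env$layers[[v]]
    if (is.null(layer)) stop("env stack lacks variable: ", v)
    vals <- layer$values[cells]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) stop("variable ", v, " is missing at every presence cell")
    pref <- unname(stats::quantile(vals, percentiles, type = 7))
    width <- pref[2] - pref[1]
    trapezoids[[v]] <- c(
      min_abs = min(vals) - buffer * width,
      pref_min = pref[1], pref_max = pref[2],
      max_abs = max(vals) + buffer * width
    )
  }
  structure(
    list(species = presence$species, trapezoids = trapezoids,
         variables_used = variables, combination_rule = combination,
         percentiles = percentiles, buffer = buffer),
    class = "envelope_model"
  )
}

#' @export
print.envelope_model <- function(x, ...) {
  cat(sprintf("<envelope_model> %s (%s rule)\n", x$species, x$combination_rule))
  for (v in names(x$trapezoids)) {
    cat(sprintf("  %s: (%.4g, %.4g, %.4g, %.4g)\n", v,
                x$trapezoids[[v]][1], x$trapezoids[[v]][2],
                x$trapezoids[[v]][3], x$trapezoids[[v]][4]))
  }
  invisible(x)
}

#' Predict relative suitability from an envelope model
#'
#' Per-variable suitability is the trapezoid: 0 outside the absolute limits,
#' 1 on the preferred plateau, linear ramps between. A degenerate trapezoid
#' (all four knots equal) scores 1 at exactly that value and 0 elsewhere.
#' Per-variable values are combined by the model's rule; missing cells stay
#' missing.
#'
#' @param model An [envelope_model][fit_envelope()].
#' @param env An [env_stack()] supplying all `variables_used`.
#' @return A [suitability_map()] in \[0, 1\].
#' @export
predict_envelope <- function(model, env) {
  spec <- env$spec
  k <- length(model$variables_used)
  prod_s <- matrix(1, spec$n_lat, spec$n_lon)
  for (v in model$variables_used) {
    layer <- env$layers[[v]]
    if (is.null(layer)) stop("env stack lacks variable: ", v)
    sv <- trapezoid_suit(as.vector(layer$values), model$trapezoids[[v]])
    prod_s <- prod_s * matrix(sv, spec$n_lat, spec$n_lon)
  }
  out <- if (model$combination_rule == "geometric_mean") prod_s^(1 / k) else prod_s
  out[!sea_mask(env)] <- NA
  suitability_map(spec, out, species = model$species, model = "envelope",
                  period = env$period_label)
}

#' Serialize / restore an envelope model as JSON
#'
#' @param model An envelope model.
#' @param path JSON file path.
#' @return `write_envelope_model`: `path` invisibly;
#'   `read_envelope_model`: the model.
#' @export
write_envelope_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_envelope_model
#' @export
read_envelope_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$trapezoids <- lapply(x$trapezoids, function(tz) {
    stats::setNames(as.numeric(tz), c("min_abs", "pref_min", "pref_max", "max_abs"))
  })
  structure(x, class = "envelope_model")
}
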