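build_features <- function(env, variables, transforms) {
  # columns in variable-major order: v1_linear, v1_quadratic, v2_linear, ...
  cols <- list(); defs <- list()
  for (v in variables) {
    layer <- env$layers[[v]]
    if (is.null(layer)) stop("env stack lacks variable: ", v)
    raw <- as.vector(layer$values)
    if ("linear" %in% transforms) {
      cols[[length(cols) + 1]] <- raw
      defs[[length(defs) + 1]] <- list(variable = v, transform = "linear")
    }
    if ("quadratic" %in% transforms) {
      cols[[length(cols) + 1]] <- raw^2
      defs[[length(defs) + 1]] <- list(variable = v, transform = "quadratic")
    }
  }
  list(X = do.call(cbind, cols), defs = defs)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a minimal presence-only maximum-entropy model
#'
#' Estimates a Gibbs distribution `q(cell) = exp(sum_j lambda_j f_j(cell))/Z`
#' over the background cells by maximising the L1-penalised presence
#' log-likelihood `sum_presences log q - beta * sum_j |lambda_j|`. Features
#' are linear and quadratic terms of the chosen variables, standardised to
#' mean 0 / sd 1 over the background. This is a self-contained reconstruction
#' of the maximum-entropy principle (no hinge/threshold/product features).
#' Optimisation is proximal gradient ascent with backtracking, so the
#' penalised objective never decreases across iterations. Fitting uses each
#' presence cell once (presence input is a binary grid).
#'
#' @param presence A [presence_grid()].
#' @param env Training [env_stack()].
#' @param background A [region_mask()] of candidate cells; default = all sea
#'   cells. Must contain every presence cell.
#' @param variables Environmental variables to use.
#' @param transforms Feature transforms, subset of `c("linear", "quadratic")`.
#' @param beta L1 regularisation weight (default 0.1).
#' @param max_iter Iteration cap.
#' @param tol Convergence: stop when the objective improves by less than
#'   `tol`.
#' @return An object of class `maxent_model` with weights, standardisation
#'   constants, `log_normalizer`, an objective `trace` and a `converged`
#'   flag.
#' @export
fit_maxent <- function(presence, env, background = NULL,
                       variables = c("sst", "sbt", "salinity"),
                       transforms = c("linear", "quadratic"),
                       beta = 0.1, max_iter = 2000, tol = 1e-8) {
  stopifnot(beta >= 0, max_iter >= 1, tol > 0)
  spec <- env$spec
  bg_mask <- if (is.null(background)) sea_mask(env) else background$member
  bg_idx <- which(bg_mask)
  if (length(bg_idx) == 0) stop("background is empty")
  pres_idx <- which(presence$present)
  if (length(pres_idx) < 5) stop("need at least 5 presence cells")
  if (!all(pres_idx %in% bg_idx)) {
    stop("background must contain every presence cell")
  }

  feats <- build_features(env, variables, transforms)
  X <- feats$X[bg_idx, , drop = FALSE]
  if (any(!is.finite(X))) stop("non-finite feature values on background cells")
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature over the background: ",
         paste(vapply(feats$defs[sds == 0], function(d)
           paste(d$variable, d$transform), character(1)), collapse = ", "))
  }
  X <- sweep(sweep(X, 2, mu), 2, sds, "/")
  pres_rows <- match(pres_idx, bg_idx)
  Xp_mean <- colMeans(X[pres_rows, , drop = FALSE])
  n_pres <- length(pres_idx)

  obj <- function(lambda) {
    eta <- as.vector(X %*% lambda)
    m <- max(eta)
    logZ <- m + log(sum(exp(eta - m)))
    list(value = n_pres * (sum(Xp_mean * lambda) - logZ) - beta * sum(abs(lambda)),
         logZ = logZ, eta = eta)
  }

  p <- ncol(X)
  lambda <- numeric(p)
  cur <- obj(lambda)
  trace <- cur$value
  eta_step <- 1 / n_pres
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- exp(cur$eta - cur$logZ)                 # q over background
    grad <- n_pres * (Xp_mean - as.vector(crossprod(X, w)))
    accepted <- FALSE
    while (eta_step > 1e-14) {
      cand <- soft_threshold(lambda + eta_step * grad, eta_step * beta)
      cand_obj <- obj(cand)
      if (cand_obj$value >= cur$value) {
        improve <- cand_obj$value - cur$value
        lambda <- cand; cur <- cand_obj
        trace <- c(trace, cur$value)
        eta_step <- eta_step * 1.2
        accepted <- TRUE
        if (improve < tol) converged <- TRUE
        break
      }
      eta_step <- eta_step / 2
    }
    if (!accepted) converged <- TRUE  # no ascent direction at machine precision
    if (converged) break
  }

  structure(
    list(species = presence$species,
         feature_defs = feats$defs, weights = lambda,
         feature_means = mu, feature_sds = sds,
         log_normalizer = cur$logZ, beta = beta,
         variables = variables, transforms = transforms,
         converged = converged, n_iter = length(trace) - 1, trace = trace,
         fit_scores = {                       # q scores on background, fit-time
           s <- rep(NA_real_, spec$n_lat * spec$n_lon)
           s[bg_idx] <- exp(cur$eta - cur$logZ)
           s
         }),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %s: %d features, beta=%g, %s after %d iter\n",
              x$species, length(x$weights), x$beta,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Predict relative suitability from a maximum-entropy model
#'
#' Raw scores `exp(sum_j lambda_j f_j)` use the training standardisation
#' constants; standardised features are clamped to +/- 6 sd so extrapolated
#' climates cannot overflow. Scores are rescaled to \[0, 1\] by the maximum
#' over non-missing cells (the raw Gibbs output has no natural prevalence
#' scale).
#'
#' @param model A [maxent_model][fit_maxent()].
#' @param env An [env_stack()] supplying all feature variables.
#' @return A [suitability_map()] in \[0, 1\].
#' @export
predict_maxent <- function(model, env) {
  spec <- env$spec
  feats <- build_features(env, model$variables, model$transforms)
  X <- sweep(sweep(feats$X, 2, model$feature_means), 2, model$feature_sds, "/")
  X <- pmin(pmax(X, -6), 6)
  eta <- as.vector(X %*% model$weights)
  score <- exp(eta)
  score[!sea_mask(env)] <- NA
  mx <- max(score, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("degenerate prediction: no positive scores")
  suitability_map(spec, matrix(score / mx, spec$n_lat, spec$n_lon),
                  species = model$species, model = "maxent",
                  period = env$period_label)
}

#' Serialize / restore a maxent model as JSON
#'
#' @param model A maxent model.
#' @param path JSON file path.
#' @return `write_maxent_model`: `path` invisibly; `read_maxent_model`: the
#'   model (without fit-time background scores).
#' @export
write_maxent_model <- function(model, path) {
  x <- unclass(model)
  x$fit_scores <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$feature_defs <- lapply(seq_len(nrow(x$feature_defs)), function(i) {
    list(variable = x$feature_defs$variable[i],
         transform = x$feature_defs$transform[i])
  })
  structure(x, class = "maxent_model")
}
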