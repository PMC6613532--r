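#' Poisson regression of richness on environmental predictors
#'
#' Fits `richness ~ predictors` with a Poisson error and log link.
#' Predictors are z-score standardized by default, so coefficients are
#' effects per standard deviation and comparable across variables with
#' wildly different units (degrees, millimetres, square kilometres).
#' The log-likelihood includes the `log(y!)` term (the stats::glm
#' convention), AICc applies the small-sample correction
#' `2k(k + 1)/(n - k - 1)`, and both McFadden and Nagelkerke pseudo-R2
#' are reported.
#'
#' @param data A data frame with the response column and predictor columns
#'   (e.g. [richness_per_band()] joined to a covariate table).
#' @param predictors Character vector of predictor column names (may be
#'   empty for the intercept-only model).
#' @param response Response column name (default `"richness"`).
#' @param standardize Z-score the predictors before fitting?
#' @return An object of class `richness_fit`: the underlying `glm` plus
#'   `predictors`, `loglik`, `k`, `n`, `aicc`, `pseudo_r2_mcfadden`,
#'   `pseudo_r2_nagelkerke`.
#' @export
fit_poisson <- function(data, predictors = character(), response = "richness",
                        standardize = TRUE) {
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss)) {
    stop("Missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- data[[response]]
  if (any(y < 0) || any(y != round(y))) {
    stop("Response must be non-negative integer counts.", call. = FALSE)
  }
  df <- data.frame(.y = y)
  for (v in predictors) {
    df[[v]] <- if (standardize) as.numeric(scale(data[[v]])) else data[[v]]
  }
  if (length(predictors) >= 2) {
    cn <- kappa(as.matrix(df[predictors]), exact = TRUE)
    if (cn > 1e6) {
      warning(sprintf("Predictors are near-collinear (condition number %.3g).",
                      cn), call. = FALSE)
    }
  }
  k <- length(predictors) + 1L
  n <- nrow(df)
  if (n < k + 2) stop("Need n >= k + 2 observations.", call. = FALSE)
  form <- stats::reformulate(if (length(predictors)) predictors else "1",
                             response = ".y")
  fit <- stats::glm(form, family = stats::poisson(link = "log"), data = df,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) warning("IRLS did not converge.", call. = FALSE)
  ll <- as.numeric(stats::logLik(fit))
  null_fit <- if (length(predictors)) {
    stats::glm(.y ~ 1, family = stats::poisson(), data = df)
  } else {
    fit
  }
  ll0 <- as.numeric(stats::logLik(null_fit))
  pr2 <- pseudo_r2(ll, ll0, n)
  structure(
    list(glm = fit, predictors = predictors, response = response,
         standardize = standardize, loglik = ll, k = k, n = n,
         aicc = aicc(ll, k, n),
         pseudo_r2_mcfadden = pr2$mcfadden,
         pseudo_r2_nagelkerke = pr2$nagelkerke),
    class = "richness_fit"
  )
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param loglik Model log-likelihood.
#' @param k Number of estimated parameters (intercept included).
#' @param n Sample size.
#' @return The AICc value.
#' @examples
#' aicc(-134.69, k = 2, n = 39) # 273.71
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1.", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Likelihood-based pseudo-R2 measures
#'
#' McFadden: `1 - LL1/LL0`. Nagelkerke:
#' `(1 - exp((2/n)(LL0 - LL1))) / (1 - exp((2/n) LL0))`.
#'
#' @param loglik,loglik_null Log-likelihoods of the model and of the
#'   intercept-only model (or two `richness_fit` objects).
#' @param n Sample size (ignored when fits are supplied).
#' @return A list with `mcfadden` and `nagelkerke`.
#' @export
pseudo_r2 <- function(loglik, loglik_null, n = NULL) {
  if (inherits(loglik, "richness_fit")) {
    n <- loglik$n
    loglik <- loglik$loglik
  }
  if (inherits(loglik_null, "richness_fit")) loglik_null <- loglik_null$loglik
  list(
    mcfadden = 1 - loglik / loglik_null,
    nagelkerke = (1 - exp(2 / n * (loglik_null - loglik))) /
      (1 - exp(2 / n * loglik_null))
  )
}

#' @export
print.richness_fit <- function(x, ...) {
  cat(sprintf("Poisson richness model (%s scale): %s\n",
              if (x$standardize) "standardized" else "raw",
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "intercept only"))
  cat(sprintf("  logLik %.2f, k = %d, n = %d, AICc %.3f, pseudo-R2 %.2f (Nagelkerke) / %.2f (McFadden)\n",
              x$loglik, x$k, x$n, x$aicc, x$pseudo_r2_nagelkerke,
              x$pseudo_r2_mcfadden))
  invisible(x)
}

#' @method tidy richness_fit
#' @export
tidy.richness_fit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    z_value = s[, "z value"],
    p_value = s[, "Pr(>|z|)"]
  )
}

#' @method glance richness_fit
#' @export
glance.richness_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, k = x$k, n = x$n, aicc = x$aicc,
    pseudo_r2_mcfadden = x$pseudo_r2_mcfadden,
    pseudo_r2_nagelkerke = x$pseudo_r2_nagelkerke
  )
}

#' Rank single-predictor Poisson models by AICc
#'
#' Fits one model per predictor and sorts by AICc, with the AICc
#' difference to the best model, both pseudo-R2 variants and the
#' predictor's Wald p-value.
#'
#' @inheritParams fit_poisson
#' @return A tibble, one row per predictor, sorted by `aicc`, with the
#'   list-column `fit` holding each `richness_fit`.
#' @export
rank_single_predictors <- function(data, predictors, response = "richness",
                                   standardize = TRUE) {
  fits <- purrr::map(predictors, function(v) {
    fit_poisson(data, v, response = response, standardize = standardize)
  })
  out <- purrr::map2_dfr(predictors, fits, function(v, f) {
    co <- tidy.richness_fit(f)
    tibble::tibble(
      predictor = v, df = f$k, loglik = f$loglik, aicc = f$aicc,
      pseudo_r2_mcfadden = f$pseudo_r2_mcfadden,
      pseudo_r2_nagelkerke = f$pseudo_r2_nagelkerke,
      estimate = co$estimate[2], p_value = co$p_value[2]
    )
  })
  out$fit <- fits
  out <- out[order(out$aicc), , drop = FALSE]
  out$delta_aicc <- out$aicc - out$aicc[1]
  dplyr::relocate(out, "delta_aicc", .after = "aicc")
}

#' Bidirectional stepwise model selection by AICc
#'
#' Starting from the intercept-only model, repeatedly applies the single
#' predictor addition or removal that most lowers AICc, stopping when no
#' move improves it. Ties are broken by predictor name, so the result does
#' not depend on the column order of the covariate table.
#'
#' @inheritParams fit_poisson
#' @param scope Character vector of candidate predictors (default: all
#'   columns of `data` other than the response and `band`).
#' @return A `richness_fit` for the selected model, with attribute
#'   `"path"`: a tibble logging each accepted move.
#' @export
stepwise_aicc <- function(data, scope = NULL, response = "richness",
                          standardize = TRUE) {
  if (is.null(scope)) scope <- setdiff(names(data), c(response, "band"))
  scope <- sort(scope)
  current <- character()
  best <- fit_poisson(data, current, response, standardize)
  path <- list(tibble::tibble(step = 0L, move = "start", term = NA_character_,
                              aicc = best$aicc))
  step_i <- 0L
  repeat {
    cands <- c(
      purrr::map(setdiff(scope, current),
                 function(v) list(move = "add", term = v,
                                  set = sort(c(current, v)))),
      purrr::map(current,
                 function(v) list(move = "drop", term = v,
                                  set = setdiff(current, v)))
    )
    if (!length(cands)) break
    fits <- purrr::map(cands, function(cc) {
      fit_poisson(data, cc$set, response, standardize)
    })
    a <- vapply(fits, function(f) f$aicc, numeric(1))
    terms <- vapply(cands, function(cc) cc$term, character(1))
    ord <- order(a, terms) # deterministic tie-break by name
    if (a[ord[1]] >= best$aicc - 1e-9) break
    best <- fits[[ord[1]]]
    current <- cands[[ord[1]]]$set
    step_i <- step_i + 1L
    path[[length(path) + 1L]] <- tibble::tibble(
      step = step_i, move = cands[[ord[1]]]$move,
      term = cands[[ord[1]]]$term, aicc = best$aicc
    )
  }
  attr(best, "path") <- dplyr::bind_rows(path)
  best
}
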