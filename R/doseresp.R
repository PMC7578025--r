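#' Four-parameter logistic curve
#'
#' Evaluates the 4PL model
#' \deqn{FA(x) = bottom + \frac{top - bottom}{1 + 10^{(a - x) h}}}
#' where `x` is log10 dose, `a` is the log10 AC50 and `h` the Hill slope.
#' With a positive Hill slope the fraction-affected rises with dose.
#'
#' @param x numeric vector of log10 doses (log10 uM).
#' @param bottom,top asymptotes on the fraction-affected scale.
#' @param log10_ac50 log10 of the half-maximal concentration (uM).
#' @param hill Hill slope (dimensionless, > 0 for rising curves).
#' @return numeric vector of predicted fraction-affected values.
#' @export
fa_4pl <- function(x, bottom, top, log10_ac50, hill) {
  bottom + (top - bottom) / (1 + 10^((log10_ac50 - x) * hill))
}

#' Exact AUC of a 4PL curve over a log10-dose window
#'
#' Closed-form mean of the (unclipped) 4PL curve over
#' `[log10(dose_min), log10(dose_max)]`. Used by the synthetic generator to
#' plant exact ground-truth AUC values; the estimator applied to fitted
#' curves ([auc()]) integrates the clipped curve numerically instead.
#'
#' The antiderivative of `1/(1 + 10^((a-x)h))` is `log(1 + exp(k(x-a)))/k`
#' with `k = h log(10)`.
#'
#' @inheritParams fa_4pl
#' @param dose_range length-2 numeric, dose window in uM (min, max).
#' @return scalar AUC on the 0-1 activity scale (for curves within [0,1]).
#' @export
auc_4pl_exact <- function(bottom, top, log10_ac50, hill,
                          dose_range = c(0.1, 10)) {
  stopifnot(length(dose_range) == 2L, all(dose_range > 0),
            dose_range[1] < dose_range[2])
  x1 <- log10(dose_range[1]); x2 <- log10(dose_range[2])
  k <- hill * log(10)
  # numerically safe log(1 + exp(y))
  softplus <- function(y) ifelse(y > 30, y, log1p(exp(pmin(y, 30))))
  prim <- function(x) softplus(k * (x - log10_ac50)) / k
  bottom + (top - bottom) * (prim(x2) - prim(x1)) / (x2 - x1)
}

# sanitize fit input: two numeric vectors, finite, >= 3 distinct doses
check_fit_points <- function(log10_dose, fa) {
  if (length(log10_dose) != length(fa))
    stop("log10_dose and fa must have equal length")
  keep <- is.finite(log10_dose) & is.finite(fa)
  log10_dose <- log10_dose[keep]; fa <- fa[keep]
  if (length(unique(log10_dose)) < 3L)
    stop("insufficient design: need >= 3 distinct doses")
  list(x = log10_dose, y = fa)
}

tukey_bisquare <- function(r, scale, c = 4.685) {
  if (!is.finite(scale) || scale <= 0) return(rep(1, length(r)))
  u <- r / (c * scale)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  w
}

# Jacobian of the 4PL at parameter vector theta = (bottom, top, a, h)
jac_4pl <- function(x, theta) {
  b <- theta[1]; t <- theta[2]; a <- theta[3]; h <- theta[4]
  u <- 10^((a - x) * h)
  den <- 1 + u
  dfdb <- 1 - 1 / den
  dfdt <- 1 / den
  common <- -(t - b) / den^2 * u * log(10)
  dfda <- common * h
  dfdh <- common * (a - x)
  cbind(dfdb, dfdt, dfda, dfdh)
}

# Box-constrained, robust (IRLS / Tukey bisquare) Levenberg-Marquardt fit
# of the 4PL. With exactly 3 distinct doses the bottom asymptote is pinned
# at 0 (an untreated well has FA = 0 by construction of the normalization),
# which restores identifiability of the remaining 3 parameters.
irls_4pl <- function(x, y, max_iter = 50L, tol = 1e-10, robust = TRUE) {
  n_dose <- length(unique(x))
  pin_bottom <- n_dose == 3L
  mu <- tapply(y, x, mean)
  lo <- c(-0.5, -0.5, min(x) - 1, 0.1)
  hi <- c(0.5, 1.5, max(x) + 1, 10)
  theta <- c(if (pin_bottom) 0 else max(min(mu), lo[1]),
             min(max(mu), hi[2]),
             sort(unique(x))[ceiling(n_dose / 2)],
             1)
  theta <- pmin(pmax(theta, lo), hi)
  free <- if (pin_bottom) 2:4 else 1:4
  lambda <- 1e-3
  converged <- FALSE
  resid <- y - fa_4pl(x, theta[1], theta[2], theta[3], theta[4])
  sse_w <- sum(resid^2)
  w <- rep(1, length(y))
  for (it in seq_len(max_iter)) {
    resid <- y - fa_4pl(x, theta[1], theta[2], theta[3], theta[4])
    if (robust && it > 1L) {
      s <- stats::mad(resid, center = 0)
      w <- tukey_bisquare(resid, s)
      if (all(w == 0)) w <- rep(1, length(y))
    }
    J <- jac_4pl(x, theta)[, free, drop = FALSE]
    g <- crossprod(J, w * resid)
    H <- crossprod(J, w * J)
    step_ok <- FALSE
    for (k in 1:12) {
      Hd <- H + lambda * diag(pmax(diag(H), 1e-8), nrow(H))
      delta <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta
        cand[free] <- pmin(pmax(theta[free] + as.numeric(delta), lo[free]),
                           hi[free])
        r2 <- y - fa_4pl(x, cand[1], cand[2], cand[3], cand[4])
        sse2 <- sum(w * r2^2)
        if (is.finite(sse2) && sse2 <= sum(w * resid^2) + 1e-15) {
          step_size <- max(abs(cand - theta))
          theta <- cand
          lambda <- max(lambda / 3, 1e-10)
          step_ok <- TRUE
          if (step_size < tol * (1 + max(abs(theta)))) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE }  # cannot improve: local optimum
    if (converged) break
  }
  resid <- y - fa_4pl(x, theta[1], theta[2], theta[3], theta[4])
  J <- jac_4pl(x, theta)[, free, drop = FALSE]
  rank_ok <- qr(J, tol = 1e-7)$rank == length(free)
  list(theta = theta, converged = converged, rank_ok = rank_ok,
       rmse = sqrt(mean(resid^2)),
       hill_at_bound = theta[4] <= lo[4] + 1e-9 || theta[4] >= hi[4] - 1e-9,
       pinned_bottom = pin_bottom)
}

#' Cascade dose-response fit (robust 4PL with linear fallback)
#'
#' Fits fraction-affected against log10 dose with a cascade model: a
#' four-parameter logistic is attempted by iteratively reweighted least
#' squares (Tukey bisquare weights, tuning constant 4.685, embedded in a
#' box-constrained Levenberg-Marquardt loop); if the fit does not converge
#' within `max_iter` iterations, the Jacobian is rank-deficient at the
#' solution, or the Hill slope sits on a bound without beating a straight
#' line, the fit falls back to ordinary least squares linear in log10 dose.
#' Which branch fired is recorded.
#'
#' Parameter box: bottom in [-0.5, 0.5], top in [-0.5, 1.5], Hill in
#' [0.1, 10], log10 AC50 within the tested range +/- 1 log. With exactly 3
#' distinct doses (the screen's native design) the bottom asymptote is
#' pinned at 0 so that the remaining three parameters are identifiable.
#'
#' @param log10_dose numeric vector, log10 of dose in uM (replicates allowed).
#' @param fa numeric vector of fraction-affected values, same length.
#' @param dose_range dose window (uM) used for the AUC/IC50 summaries;
#'   defaults to the range of the supplied doses.
#' @param max_iter maximum IRLS iterations before falling back.
#' @return an object of class `pdx_fit`: a list with `fit_kind`
#'   ("FOUR_PL" or "LINEAR"), `params` (named vector: bottom/top/
#'   log10_ac50/hill, or intercept/slope), `converged`, `rmse`, `auc`,
#'   `ic50_uM`, `ic50_flag`, and `dose_range`.
#' @examples
#' x <- rep(log10(c(10, 1, 0.1)), each = 3)
#' fit <- fit_cascade(x, fa_4pl(x, 0, 1, 0, 2))
#' fit$auc
#' @export
fit_cascade <- function(log10_dose, fa, dose_range = NULL, max_iter = 50L) {
  pts <- check_fit_points(log10_dose, fa)
  x <- pts$x; y <- pts$y
  if (is.null(dose_range)) dose_range <- 10^range(x)
  flat <- diff(range(y)) < 1e-12
  use_linear <- FALSE
  f4 <- NULL
  if (flat) {
    use_linear <- TRUE
  } else {
    f4 <- irls_4pl(x, y, max_iter = max_iter)
    lin0 <- stats::lsfit(x, y)
    rmse_lin <- sqrt(mean(lin0$residuals^2))
    if (!f4$converged || !f4$rank_ok ||
        (f4$hill_at_bound && f4$rmse >= rmse_lin)) use_linear <- TRUE
  }
  if (use_linear) {
    if (flat) {
      coefs <- c(intercept = y[1], slope = 0)
      rmse <- 0
    } else {
      ls <- stats::lsfit(x, y)
      coefs <- c(intercept = unname(ls$coefficients[1]),
                 slope = unname(ls$coefficients[2]))
      rmse <- sqrt(mean(ls$residuals^2))
    }
    fit <- structure(list(fit_kind = "LINEAR", params = coefs,
                          converged = TRUE, rmse = rmse,
                          dose_range = dose_range), class = "pdx_fit")
  } else {
    # canonicalize: bottom <= top (hill > 0 by the box, curve is rising)
    th <- f4$theta
    if (th[1] > th[2]) th[c(1, 2)] <- th[c(2, 1)]
    params <- c(bottom = th[1], top = th[2], log10_ac50 = th[3],
                hill = th[4])
    fit <- structure(list(fit_kind = "FOUR_PL", params = params,
                          converged = f4$converged, rmse = f4$rmse,
                          dose_range = dose_range), class = "pdx_fit")
  }
  fit$auc <- auc(fit, dose_range)
  i50 <- ic50(fit)
  fit$ic50_uM <- as.numeric(i50)
  fit$ic50_flag <- attr(i50, "flag")
  fit
}

#' Predict fraction-affected from a cascade fit
#'
#' @param object a `pdx_fit` from [fit_cascade()].
#' @param log10_dose log10 doses at which to evaluate the fitted curve.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pdx_fit <- function(object, log10_dose, ...) {
  p <- object$params
  if (object$fit_kind == "FOUR_PL") {
    fa_4pl(log10_dose, p["bottom"], p["top"], p["log10_ac50"], p["hill"])
  } else {
    unname(p["intercept"] + p["slope"] * log10_dose)
  }
}

#' @export
print.pdx_fit <- function(x, ...) {
  cat(sprintf("<pdx_fit> %s | %s | rmse %.4g | AUC %.3f | IC50 %s uM\n",
              x$fit_kind,
              paste(sprintf("%s=%.4g", names(x$params), x$params),
                    collapse = " "),
              x$rmse, x$auc,
              if (is.na(x$ic50_uM)) paste0("NA (", x$ic50_flag, ")")
              else sprintf("%.3g", x$ic50_uM)))
  invisible(x)
}

#' Normalized area under the fitted dose-response curve
#'
#' Integrates the fitted curve, clipped to [0, 1], over log10 dose across
#' `dose_range` and divides by the width of the log-dose window, yielding a
#' dimensionless activity score where 0 is inactive and 1 is a strong
#' active. Integration is a deterministic composite Simpson rule on 2001
#' points (clipping introduces kinks that the fine fixed grid resolves well
#' below the 1e-6 level).
#'
#' @param fit a `pdx_fit`.
#' @param dose_range length-2 numeric dose window in uM (min < max).
#' @return scalar AUC in [0, 1].
#' @export
auc <- function(fit, dose_range = fit$dose_range) {
  stopifnot(inherits(fit, "pdx_fit"), length(dose_range) == 2L)
  if (!(dose_range[1] > 0) || dose_range[1] >= dose_range[2])
    stop("dose_range must be positive with min < max")
  x1 <- log10(dose_range[1]); x2 <- log10(dose_range[2])
  n <- 2001L  # odd: Simpson needs an even interval count
  xs <- seq(x1, x2, length.out = n)
  ys <- pmin(pmax(predict(fit, xs), 0), 1)
  h <- (x2 - x1) / (n - 1L)
  wts <- c(1, rep(c(4, 2), length.out = n - 2L), 1)
  wts[n - 1L] <- 4
  integral <- h / 3 * sum(wts * ys)
  integral / (x2 - x1)
}

#' IC50 from a cascade fit
#'
#' The dose at which the fitted curve crosses fraction-affected 0.5 within
#' the tested dose window. When the curve never reaches 0.5 in range the
#' value is `NA` with attribute `flag = "no crossing"` (a flag, not an
#' error: shallow or inactive curves legitimately have no IC50).
#'
#' @param fit a `pdx_fit`.
#' @param dose_range dose window (uM) to search; defaults to the fit's.
#' @return scalar dose in uM, or `NA` flagged "no crossing".
#' @export
ic50 <- function(fit, dose_range = fit$dose_range) {
  stopifnot(inherits(fit, "pdx_fit"))
  x1 <- log10(dose_range[1]); x2 <- log10(dose_range[2])
  p <- fit$params
  none <- structure(NA_real_, flag = "no crossing")
  if (fit$fit_kind == "FOUR_PL") {
    b <- p[["bottom"]]; t <- p[["top"]]
    if (abs(t - b) < 1e-12 || 0.5 <= min(b, t) || 0.5 >= max(b, t))
      return(none)
    # invert b + (t-b)/(1+10^((a-x)h)) = 0.5
    x <- p[["log10_ac50"]] - log10((t - b) / (0.5 - b) - 1) / p[["hill"]]
  } else {
    if (abs(p[["slope"]]) < 1e-12) return(none)
    x <- (0.5 - p[["intercept"]]) / p[["slope"]]
  }
  if (!is.finite(x) || x < x1 - 1e-9 || x > x2 + 1e-9) return(none)
  structure(10^x, flag = "ok")
}

#' Fit every drug-model pair in a normalized screen table
#'
#' Convenience driver: groups a long-format normalized table by model and
#' drug, runs [fit_cascade()] on each group, and returns one row per pair.
#'
#' @param normalized data.frame with columns `model_id`, `drug_id`,
#'   `dose_uM`, `replicate`, `FA` (the output of [normalize_plates()]).
#' @param dose_range dose window in uM for AUC/IC50; defaults to the range
#'   of doses present.
#' @return data.frame with one row per (model_id, drug_id): `fit_kind`,
#'   4PL / linear parameters, `converged`, `rmse`, `auc`, `ic50_uM`,
#'   `ic50_flag`.
#' @export
fit_screen <- function(normalized, dose_range = NULL) {
  req <- c("model_id", "drug_id", "dose_uM", "replicate", "FA")
  if (!all(req %in% names(normalized)))
    stop("normalized table must have columns: ", paste(req, collapse = ", "))
  if (is.null(dose_range)) dose_range <- range(normalized$dose_uM)
  key <- interaction(normalized$model_id, normalized$drug_id, drop = TRUE)
  groups <- split(normalized, key)
  rows <- lapply(groups, function(g) {
    fit <- fit_cascade(log10(g$dose_uM), g$FA, dose_range = dose_range)
    p <- fit$params
    data.frame(model_id = g$model_id[1], drug_id = g$drug_id[1],
               fit_kind = fit$fit_kind,
               bottom = if (fit$fit_kind == "FOUR_PL") p[["bottom"]] else NA,
               top = if (fit$fit_kind == "FOUR_PL") p[["top"]] else NA,
               log10_ac50 = if (fit$fit_kind == "FOUR_PL")
                 p[["log10_ac50"]] else NA,
               hill = if (fit$fit_kind == "FOUR_PL") p[["hill"]] else NA,
               intercept = if (fit$fit_kind == "LINEAR")
                 p[["intercept"]] else NA,
               slope = if (fit$fit_kind == "LINEAR") p[["slope"]] else NA,
               converged = fit$converged, rmse = fit$rmse, auc = fit$auc,
               ic50_uM = fit$ic50_uM, ic50_flag = fit$ic50_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
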