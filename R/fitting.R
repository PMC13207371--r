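#' Fit a growth law to a confluency time series
#'
#' Least-squares calibration of the generalized logistic or Gompertz law to
#' observed confluency values, using the closed-form solutions as model
#' functions. Free parameters are `(lam, omega_bar, u0)` for the generalized
#' logistic and `(g, u0)` for Gompertz (only the composite rate
#' `g = lam * omega_bar` is identifiable from a Gompertz curve). The death
#' rate `delta` is held fixed (default 0) unless `fit_delta = TRUE`.
#'
#' Optimization is Levenberg-Marquardt ([minpack.lm::nlsLM()]) restarted from
#' a deterministic grid of initial guesses (`lam` in 0.01/0.1/1 crossed with
#' `omega_bar` in 0.5/2/8 for the generalized logistic; `g` in 0.01/0.1/1 for
#' Gompertz); the best local optimum by RSS wins, ties going to the first
#' found.
#'
#' @param ts A data frame with columns `time` and `value` (confluency in
#'   `(0, 1]`); see [as_timeseries()].
#' @param law `"gen_logistic"` or `"gompertz"`.
#' @param delta Fixed death rate (default 0).
#' @param fit_delta If `TRUE`, `delta` is fitted as an extra free parameter
#'   (its grid start is the supplied `delta`).
#' @return An object of class `fit_result`: list with `law`, `estimates`
#'   (named vector), `delta` (fixed value or estimate), `rss`, `n_obs`, `k`
#'   (number of free parameters), `aic`, `converged`, and `fitted` (model
#'   values at the data times).
#' @examples
#' p <- growth_params("gen_logistic", lam = 0.1, omega_bar = 4, u0 = 0.05)
#' ts <- solve_growth(p, seq(0, 100, 2))
#' fit_growth_law(ts, "gen_logistic")$estimates
#' @export
fit_growth_law <- function(ts, law = c("gen_logistic", "gompertz"),
                           delta = 0, fit_delta = FALSE) {
  law <- match.arg(law)
  stopifnot(is.data.frame(ts), all(c("time", "value") %in% names(ts)))
  tt <- ts$time; y <- ts$value
  if (any(y <= 0) || any(y > 1 + 1e-9))
    stop("confluency values must lie in (0, 1]", call. = FALSE)
  y <- pmin(y, 1)
  n_obs <- length(y)

  model_fun <- function(par) {
    dl <- if (fit_delta) par[["delta"]] else delta
    p <- if (law == "gen_logistic") {
      growth_params("gen_logistic", lam = par[["lam"]],
                    omega_bar = par[["omega_bar"]], delta = dl,
                    u0 = par[["u0"]])
    } else {
      growth_params("gompertz", g = par[["g"]], delta = dl, u0 = par[["u0"]])
    }
    closed_form(p, tt)
  }

  u0_start <- max(min(y[1], 0.99), 1e-4)
  starts <- if (law == "gen_logistic") {
    expand.grid(lam = c(0.01, 0.1, 1), omega_bar = c(0.5, 2, 8), u0 = u0_start)
  } else {
    expand.grid(g = c(0.01, 0.1, 1), u0 = u0_start)
  }
  if (fit_delta) starts$delta <- max(delta, 1e-6)
  par_names <- names(starts)
  k <- length(par_names)
  if (n_obs < k + 1)
    stop("need at least k + 1 observations to fit ", k, " parameters", call. = FALSE)

  lower <- stats::setNames(rep(1e-8, k), par_names)
  upper <- stats::setNames(rep(Inf, k), par_names)
  upper["u0"] <- 1
  if ("omega_bar" %in% par_names) upper["omega_bar"] <- 1e3

  form <- stats::as.formula(
    paste0("y ~ model_fun(c(",
           paste(sprintf("%s = %s", par_names, par_names), collapse = ", "),
           "))"),
    env = environment())

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- as.list(starts[i, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form,
        data = list(y = y),
        start = st, lower = lower[par_names], upper = upper[par_names],
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    return(structure(list(law = law, estimates = NULL, delta = delta,
                          rss = NA_real_, n_obs = n_obs, k = k,
                          aic = NA_real_, converged = FALSE, fitted = NULL),
                     class = "fit_result"))
  }
  est <- stats::coef(best$fit)
  out <- structure(list(law = law,
                        estimates = est,
                        delta = if (fit_delta) est[["delta"]] else delta,
                        rss = best$rss, n_obs = n_obs, k = k,
                        aic = NA_real_,
                        converged = TRUE,
                        fitted = as.numeric(stats::fitted(best$fit))),
                   class = "fit_result")
  out$aic <- aic_score(out)
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$law,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$estimates)) {
    cat("  ", paste(names(x$estimates), signif(x$estimates, 5),
                    sep = " = ", collapse = ", "), "\n")
    cat("  RSS =", signif(x$rss, 5), " AIC =", signif(x$aic, 6),
        " (n =", x$n_obs, ", k =", x$k, ")\n")
  }
  invisible(x)
}

#' AIC of a least-squares fit
#'
#' Least-squares form `AIC = n ln(RSS/n) + 2 (k + 1)`, counting the error
#' variance as an estimated parameter. An exactly zero RSS is floored at
#' `1e-30` and flagged via the `"rss_floored"` attribute.
#'
#' @param fit A [fit_growth_law()] result, or a list with elements `rss`,
#'   `n_obs`, `k` from a converged fit.
#' @return The AIC value.
#' @examples
#' aic_score(list(rss = 1, n_obs = 10, k = 2, converged = TRUE))  # -17.026
#' @export
aic_score <- function(fit) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged))
    stop("AIC requires a converged fit", call. = FALSE)
  rss <- fit$rss; n <- fit$n_obs; k <- fit$k
  floored <- FALSE
  if (rss <= 0) { rss <- 1e-30; floored <- TRUE }
  val <- n * log(rss / n) + 2 * (k + 1)
  if (floored) attr(val, "rss_floored") <- TRUE
  val
}

#' Normalized AIC: Gompertz relative to generalized logistic
#'
#' The ratio `AIC_gompertz / AIC_genlogistic`. When both AICs are negative
#' (the usual case for good fits on the confluency scale), values above 1
#' indicate that Gompertz improves on the generalized logistic after the
#' parameter-count penalty. When the two AICs differ in sign the ratio is
#' not interpretable and is flagged.
#'
#' @param fit_gompertz,fit_genlog Converged [fit_growth_law()] results (or
#'   lists with an `aic` element).
#' @return A list with `ratio` and `interpretable` (both AICs of the same
#'   sign, both nonzero).
#' @export
normalized_aic <- function(fit_gompertz, fit_genlog) {
  a_g <- as.numeric(fit_gompertz$aic)
  a_l <- as.numeric(fit_genlog$aic)
  if (!is.finite(a_g) || !is.finite(a_l))
    stop("both fits must carry finite AIC values", call. = FALSE)
  if (a_l == 0) stop("generalized logistic AIC is zero; ratio undefined", call. = FALSE)
  list(ratio = a_g / a_l,
       interpretable = sign(a_g) == sign(a_l))
}

#' Regression of the AIC ratio on initial confluency
#'
#' Ordinary least squares of the normalized AIC score on the initial
#' confluency, pooled and per group (cell line). A positive slope means the
#' Gompertz description improves, relative to the generalized logistic, as
#' seeding confluency increases.
#'
#' @param experiments Data frame with columns `u0`, `ratio`, and optionally
#'   a grouping column named by `grouping` (default `"cell_line"`).
#' @param grouping Name of the grouping column (ignored when absent).
#' @return A list with `pooled` (list: `slope`, `intercept`, `r2_adj`, `n`)
#'   and `per_group` (data frame with one row per group), or `per_group = NULL`
#'   when no grouping column exists.
#' @export
confluence_aic_regression <- function(experiments, grouping = "cell_line") {
  stopifnot(is.data.frame(experiments),
            all(c("u0", "ratio") %in% names(experiments)))
  ols <- function(df) {
    if (nrow(df) < 3) stop("need >= 3 points per regression", call. = FALSE)
    if (length(unique(df$u0)) < 2)
      stop("degenerate regression: constant u0", call. = FALSE)
    m <- stats::lm(ratio ~ u0, data = df)
    s <- summary(m)
    list(slope = unname(stats::coef(m)[2]),
         intercept = unname(stats::coef(m)[1]),
         r2_adj = s$adj.r.squared, n = nrow(df))
  }
  pooled <- ols(experiments)
  per_group <- NULL
  if (grouping %in% names(experiments)) {
    groups <- split(experiments, experiments[[grouping]])
    per_group <- do.call(rbind, lapply(names(groups), function(gname) {
      r <- ols(groups[[gname]])
      data.frame(group = gname, slope = r$slope, intercept = r$intercept,
                 r2_adj = r$r2_adj, n = r$n)
    }))
    rownames(per_group) <- NULL
  }
  list(pooled = pooled, per_group = per_group)
}

#' Log-log regression of neighborhood size on birth rate
#'
#' Least squares of `ln(omega_bar)` on `ln(lam)` across fitted experiments.
#' Under an exact trade-off `lam * omega_bar = C` the slope is -1 and the
#' intercept `ln C` (e.g. `C = 0.1` gives intercept -2.303, i.e. negated
#' intercept 2.30).
#'
#' @param fits Either a list of converged generalized-logistic
#'   [fit_growth_law()] results, or a data frame with columns `lam` and
#'   `omega_bar`.
#' @return A list with `slope`, `intercept`, `n_used`, and `n_excluded`
#'   (nonpositive estimates are excluded with a warning).
#' @export
lambda_omega_regression <- function(fits) {
  if (is.data.frame(fits)) {
    df <- fits[, c("lam", "omega_bar")]
  } else {
    df <- do.call(rbind, lapply(fits, function(f) {
      data.frame(lam = f$estimates[["lam"]],
                 omega_bar = f$estimates[["omega_bar"]])
    }))
  }
  ok <- df$lam > 0 & df$omega_bar > 0
  if (any(!ok)) warning(sum(!ok), " fits with nonpositive estimates excluded")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) < 2) stop("need >= 2 fits with positive estimates", call. = FALSE)
  m <- stats::lm(log(omega_bar) ~ log(lam), data = df)
  list(slope = unname(stats::coef(m)[2]),
       intercept = unname(stats::coef(m)[1]),
       n_used = nrow(df), n_excluded = sum(!ok))
}
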