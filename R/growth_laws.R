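#' Parameter set for a mean-field growth law
#'
#' Bundles the parameters of one of the contact-inhibition growth laws.
#' Each law reads only the parameters it needs:
#'
#' * `exponential_saturating`: `lam`, `delta`, `u0` — exponential growth with
#'   a hard stop at confluency 1 (birth neighborhood spanning the lattice).
#' * `radial`: `lam`, `delta`, `d`, `u0` (count space `n`) — surface-limited
#'   growth `dn/dt = lam * d * n^((d-1)/d) - delta * n` (Von Bertalanffy at
#'   `d = 3`).
#' * `fractal`: `lam`, `delta`, `d`, `D`, `a`, `u0` (count space) —
#'   `dn/dt = lam * a * n^(D/d) - delta * n` with fractal surface dimension
#'   `d - 1 < D <= d`.
#' * `gen_logistic`: `lam`, `omega_bar`, `delta`, `u0` — Richards growth
#'   `du/dt = lam * u * (1 - u^omega_bar) - delta * u`.
#' * `gompertz`: `g` (or `lam * omega_bar`), `delta`, `u0` —
#'   `du/dt = -g * u * ln(u) - delta * u`. Only the composite rate
#'   `g = lam * omega_bar` is identifiable from a Gompertz curve.
#' * `gen_logistic_corrected` / `gompertz_corrected`: as above plus
#'   `sigma_omega`, the standard deviation of the birth-neighborhood size,
#'   entering through second-order terms in `ln(u)`.
#'
#' @param law Law identifier (see above).
#' @param lam Intrinsic per-capita birth rate (1/time, `>= 0`).
#' @param delta Per-capita death rate (1/time, `>= 0`).
#' @param omega_bar Mean birth-neighborhood size (`> 0`; need not be integer).
#' @param sigma_omega Birth-neighborhood size standard deviation (`>= 0`).
#' @param g Composite Gompertz rate `lam * omega_bar` (Gompertz laws only;
#'   supply either `g` or both `lam` and `omega_bar`).
#' @param d Embedding dimension (radial/fractal laws).
#' @param D Fractal dimension, `d - 1 < D <= d` (fractal law).
#' @param a Fractal length constant (`> 0`, fractal law).
#' @param u0 Initial density in `(0, 1]` (or initial count for count-space laws).
#' @return An object of class `growth_params`.
#' @examples
#' growth_params("gen_logistic", lam = 0.1, omega_bar = 4, u0 = 0.05)
#' growth_params("gompertz", g = 0.1, u0 = 0.1)
#' @export
growth_params <- function(law = c("exponential_saturating", "radial", "fractal",
                                  "gen_logistic", "gompertz",
                                  "gen_logistic_corrected", "gompertz_corrected"),
                          lam = NULL, delta = 0, omega_bar = NULL,
                          sigma_omega = 0, g = NULL, d = NULL, D = NULL,
                          a = NULL, u0 = NULL) {
  law <- match.arg(law)
  stopifnot(delta >= 0, sigma_omega >= 0)
  if (law %in% c("gompertz", "gompertz_corrected")) {
    if (is.null(g)) {
      if (is.null(lam) || is.null(omega_bar))
        stop("gompertz laws need 'g' or both 'lam' and 'omega_bar'", call. = FALSE)
      g <- lam * omega_bar
    }
    stopifnot(g >= 0)
    if (law == "gompertz_corrected" && is.null(omega_bar))
      stop("gompertz_corrected needs 'omega_bar' (and 'sigma_omega')", call. = FALSE)
  } else {
    if (is.null(lam)) stop(sprintf("law '%s' needs 'lam'", law), call. = FALSE)
    stopifnot(lam >= 0)
  }
  if (law %in% c("gen_logistic", "gen_logistic_corrected")) {
    if (is.null(omega_bar) || omega_bar <= 0)
      stop("generalized logistic needs 'omega_bar' > 0", call. = FALSE)
  }
  if (law %in% c("radial", "fractal")) {
    if (is.null(d) || d < 1) stop("radial/fractal need dimension 'd' >= 1", call. = FALSE)
  }
  if (law == "fractal") {
    if (is.null(D) || is.null(a) || a <= 0)
      stop("fractal needs 'D' and 'a' > 0", call. = FALSE)
    if (D <= d - 1 || D > d)
      stop("fractal dimension must satisfy d - 1 < D <= d", call. = FALSE)
  }
  if (!is.null(u0)) {
    if (law %in% c("radial", "fractal")) {
      if (u0 < 0) stop("initial count must be >= 0", call. = FALSE)
    } else if (u0 <= 0 || u0 > 1) {
      stop("initial density 'u0' must be in (0, 1]", call. = FALSE)
    }
  }
  structure(list(law = law, lam = lam, delta = delta, omega_bar = omega_bar,
                 sigma_omega = sigma_omega, g = g, d = d, D = D, a = a,
                 u0 = u0),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  keep <- !vapply(x, is.null, logical(1))
  vals <- unlist(x[keep & names(x) != "law"])
  cat("<growth_params>", x$law, "\n")
  cat(paste0("  ", names(vals), " = ", signif(as.numeric(vals), 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Right-hand side of a mean-field growth law
#'
#' Evaluates `du/dt` (or `dn/dt` for the count-space radial and fractal laws)
#' at the given density/count.
#'
#' @param params A [growth_params()] object.
#' @param u Density (or count for radial/fractal). Gompertz laws require
#'   `u > 0`.
#' @return The growth rate, vectorized over `u`.
#' @examples
#' p <- growth_params("gen_logistic", lam = 0.1, omega_bar = 4)
#' growth_rhs(p, 0.5)   # 0.046875
#' @export
growth_rhs <- function(params, u) {
  stopifnot(inherits(params, "growth_params"))
  if (any(u < 0)) stop("'u' must be nonnegative", call. = FALSE)
  law <- params$law
  if (law %in% c("gompertz", "gompertz_corrected") && any(u == 0))
    stop("Gompertz laws are undefined at u = 0 (ln 0)", call. = FALSE)
  lam <- params$lam; delta <- params$delta
  switch(law,
    gen_logistic = lam * u * (1 - u^params$omega_bar) - delta * u,
    gen_logistic_corrected = {
      s2 <- params$sigma_omega^2
      lam * u * (1 - u^params$omega_bar * (1 + 0.5 * s2 * log(u)^2)) - delta * u
    },
    gompertz = -params$g * u * log(u) - delta * u,
    gompertz_corrected = {
      ob <- params$omega_bar; s2 <- params$sigma_omega^2
      -lam * u * (ob * log(u) + 0.5 * (s2 + ob^2) * log(u)^2) - delta * u
    },
    exponential_saturating = lam * u * (1 - as.numeric(u >= 1)) - delta * u,
    radial = lam * params$d * u^((params$d - 1) / params$d) - delta * u,
    fractal = lam * params$a * u^(params$D / params$d) - delta * u
  )
}

#' Closed-form solution of a growth law
#'
#' Analytic trajectories where they exist:
#'
#' * Gompertz (`g`, `delta`, `u0`): with `v = ln u`,
#'   `v(t) = (ln u0 + delta/g) exp(-g t) - delta/g`.
#' * Generalized logistic: `u = w^(-1/omega_bar)` with
#'   `w(t) = lam/(lam-delta) + (u0^(-omega_bar) - lam/(lam-delta))
#'   exp(-omega_bar (lam-delta) t)`; the degenerate case `lam == delta`
#'   uses the limiting branch `u = (u0^(-omega_bar) + lam omega_bar t)^(-1/omega_bar)`.
#' * Radial with `delta = 0`: `n(t) = (n0^(1/d) + lam t)^d`.
#' * Exponential-saturating with `delta = 0`: `u = min(u0 exp(lam t), 1)`.
#'
#' @param params A [growth_params()] object with `u0` set.
#' @param t Time(s) at which to evaluate (vectorized).
#' @return Density (or count) at `t`.
#' @examples
#' p <- growth_params("gompertz", g = 0.1, u0 = 0.1)
#' closed_form(p, 10)   # 0.1^exp(-1) = 0.4289...
#' @export
closed_form <- function(params, t) {
  stopifnot(inherits(params, "growth_params"))
  if (is.null(params$u0)) stop("'u0' must be set in params", call. = FALSE)
  u0 <- params$u0; delta <- params$delta; lam <- params$lam
  switch(params$law,
    gompertz = {
      g <- params$g
      if (u0 <= 0) stop("gompertz needs u0 > 0", call. = FALSE)
      if (g == 0) return(u0 * exp(-delta * t))
      v <- (log(u0) + delta / g) * exp(-g * t) - delta / g
      exp(v)
    },
    gen_logistic = {
      ob <- params$omega_bar
      if (lam == delta) {
        w <- u0^(-ob) + lam * ob * t
      } else {
        A <- lam / (lam - delta)
        w <- A + (u0^(-ob) - A) * exp(-ob * (lam - delta) * t)
      }
      w^(-1 / ob)
    },
    radial = {
      if (delta != 0)
        stop("radial closed form implemented for delta = 0 only", call. = FALSE)
      d <- params$d
      (u0^(1 / d) + lam * t)^d
    },
    exponential_saturating = {
      if (delta != 0)
        stop("exponential_saturating closed form implemented for delta = 0 only",
             call. = FALSE)
      pmin(u0 * exp(lam * t), 1)
    },
    stop(sprintf("no closed form for law '%s'", params$law), call. = FALSE)
  )
}

#' Numerically integrate a growth law
#'
#' Adaptive integration (via [deSolve::ode()], `lsoda`, relative tolerance
#' 1e-8, absolute tolerance 1e-10) of the selected law from `params$u0` over
#' the given time grid. The discontinuous exponential-saturating law is
#' handled analytically (sliding state at `u = 1`) rather than through the
#' integrator.
#'
#' @param params A [growth_params()] object with `u0` set.
#' @param times Strictly increasing time grid.
#' @return A data frame with columns `time` and `value` (a `cigrow`
#'   time series, see [as_timeseries()]).
#' @examples
#' p <- growth_params("gen_logistic", lam = 0.1, omega_bar = 4, u0 = 0.05)
#' tail(solve_growth(p, seq(0, 100, 5)))
#' @export
solve_growth <- function(params, times) {
  stopifnot(inherits(params, "growth_params"))
  if (is.null(params$u0)) stop("'u0' must be set in params", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  if (params$law == "exponential_saturating" && params$delta == 0) {
    return(as_timeseries(data.frame(time = times, value = closed_form(params, times))))
  }
  rhs <- function(t, y, p) list(growth_rhs(params, max(y, .Machine$double.xmin)))
  t0 <- times[1]
  grid <- if (t0 == 0) times else c(0, times)
  sol <- deSolve::ode(y = c(u = params$u0), times = grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  diag <- attributes(sol)$istate
  if (!is.null(diag) && diag[1] < 0)
    stop("integration failed: istate = ", diag[1], call. = FALSE)
  out <- data.frame(time = sol[, "time"], value = sol[, "u"])
  out <- out[out$time %in% times, , drop = FALSE]
  rownames(out) <- NULL
  as_timeseries(out)
}

#' Nontrivial steady state of a growth law
#'
#' Fixed point with `u > 0` where it exists: generalized logistic
#' `u* = (1 - delta/lam)^(1/omega_bar)`, Gompertz `u* = exp(-delta/g)`,
#' exponential-saturating `u* = 1` when `lam > delta`. Returns 0 (extinction)
#' when `delta >= lam` (for Gompertz, when `g = 0` with `delta > 0`).
#'
#' @param params A [growth_params()] object.
#' @return Steady-state density.
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  delta <- params$delta
  switch(params$law,
    gen_logistic = {
      if (delta >= params$lam) 0 else (1 - delta / params$lam)^(1 / params$omega_bar)
    },
    gompertz = {
      if (params$g <= 0) { if (delta > 0) 0 else NA_real_ }
      else exp(-delta / params$g)
    },
    exponential_saturating = if (params$lam > delta) 1 else 0,
    stop(sprintf("steady state not defined for law '%s'", params$law), call. = FALSE)
  )
}

#' Validity margin of the Gompertz approximation
#'
#' The Gompertz law arises from a Taylor expansion around small neighborhood
#' size and requires `2 omega_bar / (sigma_omega^2 + omega_bar^2)` to be much
#' larger than `|ln u|` — i.e. the population must not be too sparse. "Much
#' larger" is operationalized by a multiplicative strictness factor (default
#' 10): the condition is taken as satisfied when
#' `2 omega_bar / (sigma_omega^2 + omega_bar^2) > factor * |ln u|`.
#'
#' @param omega_bar Mean birth-neighborhood size (`> 0`).
#' @param sigma_omega Neighborhood-size standard deviation (`>= 0`).
#' @param u Density in `(0, 1]`.
#' @param strictness_factor Multiplier operationalizing "much greater than".
#' @return A list with `margin` (left side minus `factor` times right side)
#'   and `satisfied` (logical).
#' @examples
#' gompertz_condition_margin(0.01, 0, exp(-1))  # comfortably satisfied
#' gompertz_condition_margin(8, 0, 0.01)        # violated: sparse, large omega
#' @export
gompertz_condition_margin <- function(omega_bar, sigma_omega, u,
                                      strictness_factor = 10) {
  if (any(u <= 0)) stop("'u' must be positive", call. = FALSE)
  stopifnot(omega_bar > 0, sigma_omega >= 0, strictness_factor > 0)
  lhs <- 2 * omega_bar / (sigma_omega^2 + omega_bar^2)
  margin <- lhs - strictness_factor * abs(log(u))
  list(margin = margin, satisfied = margin > 0)
}

#' Mark a data frame as a cigrow time series
#'
#' A time series is a data frame with numeric columns `time` and `value`
#' (strictly increasing times, nonnegative values), and optional `condition`
#' and `replicate` labels.
#'
#' @param x A data frame with at least columns `time` and `value`.
#' @return `x` with class `c("cigrow_ts", "data.frame")`.
#' @export
as_timeseries <- function(x) {
  stopifnot(is.data.frame(x), all(c("time", "value") %in% names(x)))
  if (any(is.na(x$time)) || any(is.na(x$value)))
    stop("time series must not contain NA", call. = FALSE)
  key <- interaction(
    if ("condition" %in% names(x)) x$condition else 0,
    if ("replicate" %in% names(x)) x$replicate else 0, drop = TRUE)
  for (lev in levels(key)) {
    tt <- x$time[key == lev]
    if (any(diff(tt) <= 0))
      stop("times must be strictly increasing within each series", call. = FALSE)
  }
  if (any(x$value < 0)) stop("values must be nonnegative", call. = FALSE)
  class(x) <- unique(c("cigrow_ts", class(x)))
  x
}
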