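#' Parameters of the two-subpopulation competition model
#'
#' Two subpopulations share the same space: the saturation (generalized
#' logistic) or logarithm (Gompertz) term depends on the total confluency
#' `u = u1 + u2`, while each subpopulation keeps its own birth rate and
#' birth-neighborhood size. Under the generalized logistic law
#' `du_i/dt = lam_i u_i (1 - u^omega_i) - delta u_i`; under Gompertz
#' `du_i/dt = -lam_i omega_i u_i ln(u) - delta u_i`.
#'
#' @param law `"gen_logistic"` or `"gompertz"`.
#' @param lam1,lam2 Subpopulation birth rates (`>= 0`).
#' @param omega1,omega2 Subpopulation birth-neighborhood sizes (`> 0`).
#' @param delta Shared death rate (`>= 0`).
#' @param u1_0,u2_0 Initial confluencies (`>= 0`, `u1_0 + u2_0 <= 1`).
#' @return An object of class `competition_params`.
#' @export
competition_params <- function(law = c("gen_logistic", "gompertz"),
                               lam1, lam2, omega1, omega2, delta = 0,
                               u1_0, u2_0) {
  law <- match.arg(law)
  stopifnot(lam1 >= 0, lam2 >= 0, omega1 > 0, omega2 > 0, delta >= 0,
            u1_0 >= 0, u2_0 >= 0)
  if (u1_0 + u2_0 > 1 + 1e-12)
    stop("initial confluencies must satisfy u1_0 + u2_0 <= 1", call. = FALSE)
  structure(list(law = law, lam1 = lam1, lam2 = lam2, omega1 = omega1,
                 omega2 = omega2, delta = delta, u1_0 = u1_0, u2_0 = u2_0),
            class = "competition_params")
}

#' Right-hand side of the competition model
#'
#' @param params A [competition_params()] object.
#' @param u1,u2 Current subpopulation confluencies (`>= 0`; Gompertz needs
#'   total `u1 + u2 > 0`).
#' @return Numeric vector `c(du1, du2)`.
#' @examples
#' p <- competition_params("gen_logistic", lam1 = 0.1, lam2 = 0.1,
#'                         omega1 = 2, omega2 = 8, u1_0 = 0.25, u2_0 = 0.25)
#' competition_rhs(p, 0.25, 0.25)
#' @export
competition_rhs <- function(params, u1, u2) {
  stopifnot(inherits(params, "competition_params"))
  if (u1 < 0 || u2 < 0) stop("confluencies must be nonnegative", call. = FALSE)
  u <- u1 + u2
  if (params$law == "gen_logistic") {
    c(params$lam1 * u1 * (1 - u^params$omega1) - params$delta * u1,
      params$lam2 * u2 * (1 - u^params$omega2) - params$delta * u2)
  } else {
    if (u <= 0) stop("Gompertz competition undefined at total u = 0", call. = FALSE)
    lu <- log(u)
    c(-params$lam1 * params$omega1 * u1 * lu - params$delta * u1,
      -params$lam2 * params$omega2 * u2 * lu - params$delta * u2)
  }
}

#' Integrate the competition model
#'
#' @param params A [competition_params()] object.
#' @param times Strictly increasing time grid.
#' @return A data frame with columns `time`, `u1`, `u2`, `total`.
#' @export
solve_competition <- function(params, times) {
  stopifnot(inherits(params, "competition_params"))
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    list(competition_rhs(params, y[1], y[2]))
  }
  grid <- if (times[1] == 0) times else c(0, times)
  sol <- deSolve::ode(y = c(u1 = params$u1_0, u2 = params$u2_0), times = grid,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  diag <- attributes(sol)$istate
  if (!is.null(diag) && diag[1] < 0)
    stop("integration failed: istate = ", diag[1], call. = FALSE)
  out <- data.frame(time = sol[, "time"], u1 = sol[, "u1"], u2 = sol[, "u2"])
  out$total <- out$u1 + out$u2
  out <- out[out$time %in% times, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the outcome of an invasion attempt
#'
#' Integrates the competition model until the system equilibrates (maximum
#' absolute derivative below `1e-9`) or the horizon is reached, then
#' classifies by the asymptotic share of subpopulation 2:
#' `< tol` resident retains, `> 1 - tol` invader takes over, otherwise
#' coexistence.
#'
#' @param params A [competition_params()] with `u2_0 > 0`.
#' @param horizon Maximum integration time.
#' @param tol Classification tolerance on the asymptotic share.
#' @return A list with `label` (one of `"resident_retains"`,
#'   `"invader_takes_over"`, `"coexistence"`), `share` (final
#'   `u2 / (u1 + u2)`), `equilibrated` (logical), and `final` (named vector
#'   `u1`, `u2`).
#' @export
invasion_outcome <- function(params, horizon = 5000, tol = 1e-3) {
  stopifnot(inherits(params, "competition_params"))
  if (params$u2_0 <= 0) stop("invader must be present (u2_0 > 0)", call. = FALSE)
  y <- c(params$u1_0, params$u2_0)
  t_now <- 0
  chunk <- max(horizon / 50, 1)
  equilibrated <- FALSE
  while (t_now < horizon) {
    t_end <- min(t_now + chunk, horizon)
    p2 <- params
    p2$u1_0 <- y[1]; p2$u2_0 <- y[2]
    sol <- solve_competition(p2, seq(0, t_end - t_now, length.out = 25))
    y <- pmax(c(sol$u1[nrow(sol)], sol$u2[nrow(sol)]), 0)
    t_now <- t_end
    d <- tryCatch(competition_rhs(params, y[1], y[2]), error = function(e) c(Inf, Inf))
    if (max(abs(d)) < 1e-9) { equilibrated <- TRUE; break }
  }
  share <- if (sum(y) > 0) y[2] / sum(y) else NA_real_
  label <- if (!is.na(share) && share < tol) "resident_retains"
           else if (!is.na(share) && share > 1 - tol) "invader_takes_over"
           else "coexistence"
  list(label = label, share = share, equilibrated = equilibrated,
       final = c(u1 = y[1], u2 = y[2]))
}

#' Invasion landscape over a grid of invader parameters
#'
#' Runs [invasion_outcome()] for every combination of invader birth rate and
#' birth-neighborhood size, holding the resident fixed. For each fixed
#' `omega2` the set of `lam2` producing takeover has threshold structure (an
#' up-set).
#'
#' @param params Baseline [competition_params()]; `lam2` and `omega2` are
#'   overridden by the grids.
#' @param lam2_grid,omega2_grid Positive, sorted grids of invader parameters.
#' @param horizon,tol Passed to [invasion_outcome()].
#' @return A data frame with columns `lam2`, `omega2`, `outcome`,
#'   `final_share`.
#' @export
invasion_landscape <- function(params, lam2_grid, omega2_grid,
                               horizon = 5000, tol = 1e-3) {
  stopifnot(all(lam2_grid > 0), all(omega2_grid > 0),
            !is.unsorted(lam2_grid), !is.unsorted(omega2_grid))
  grid <- expand.grid(lam2 = lam2_grid, omega2 = omega2_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$lam2 <- grid$lam2[i]
    p$omega2 <- grid$omega2[i]
    invasion_outcome(p, horizon = horizon, tol = tol)
  })
  data.frame(lam2 = grid$lam2, omega2 = grid$omega2,
             outcome = vapply(res, `[[`, "", "label"),
             final_share = vapply(res, `[[`, 0, "share"))
}
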