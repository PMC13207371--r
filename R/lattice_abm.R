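#' Lattice neighborhood specification
#'
#' Standard 2D lattice neighborhoods, or a custom offset set. Offsets are
#' (row, col) displacements relative to the focal site, excluding (0, 0).
#'
#' @param kind One of `"von_neumann"` (4 axis-adjacent sites), `"moore"`
#'   (8 sites, Chebyshev radius 1), `"von_neumann2"` (12 sites, Manhattan
#'   radius 2), `"moore2"` (24 sites, Chebyshev radius 2), `"full_domain"`
#'   (every other site on the lattice), or `"custom"`.
#' @param offsets For `kind = "custom"`: a two-column integer matrix of
#'   distinct nonzero (row, col) displacements.
#' @return An object of class `neighborhood_spec` with elements `kind`,
#'   `offsets` (NULL for `full_domain`), and `omega` (NA for `full_domain`).
#' @examples
#' neighborhood_spec("von_neumann")$omega   # 4
#' neighborhood_spec("moore2")$omega        # 24
#' @export
neighborhood_spec <- function(kind = c("von_neumann", "moore", "von_neumann2",
                                       "moore2", "full_domain", "custom"),
                              offsets = NULL) {
  kind <- match.arg(kind)
  if (kind == "full_domain") {
    return(structure(list(kind = kind, offsets = NULL, omega = NA_integer_),
                     class = "neighborhood_spec"))
  }
  if (kind == "custom") {
    if (is.null(offsets)) stop("custom neighborhood needs 'offsets'", call. = FALSE)
    offsets <- as.matrix(offsets)
    storage.mode(offsets) <- "integer"
    if (ncol(offsets) != 2) stop("'offsets' must have two columns", call. = FALSE)
    if (any(offsets[, 1] == 0 & offsets[, 2] == 0))
      stop("offsets must exclude (0, 0)", call. = FALSE)
    if (anyDuplicated(offsets)) stop("duplicate offsets", call. = FALSE)
  } else {
    rng <- -2:2
    g <- expand.grid(dr = rng, dc = rng)
    manh <- abs(g$dr) + abs(g$dc)
    cheb <- pmax(abs(g$dr), abs(g$dc))
    keep <- switch(kind,
      von_neumann  = manh == 1,
      moore        = cheb == 1,
      von_neumann2 = manh >= 1 & manh <= 2,
      moore2       = cheb >= 1 & cheb <= 2
    )
    offsets <- as.matrix(g[keep, c("dr", "dc")])
    storage.mode(offsets) <- "integer"
    dimnames(offsets) <- NULL
  }
  structure(list(kind = kind, offsets = offsets, omega = nrow(offsets)),
            class = "neighborhood_spec")
}

#' Offsets of a neighborhood
#'
#' @param spec A [neighborhood_spec()].
#' @return A two-column integer matrix of (row, col) displacements.
#' @export
neighborhood_offsets <- function(spec) {
  stopifnot(inherits(spec, "neighborhood_spec"))
  if (spec$kind == "full_domain")
    stop("full_domain has no fixed offset set; it spans all other sites",
         call. = FALSE)
  spec$offsets
}

#' Parameters of the on-lattice birth-death-migration model
#'
#' Per-step event probabilities are `min(rate * dt, 1)`; with the default
#' `dt = 1`, `lam = 0.1` means a 10% birth attempt per cell per step, and
#' `m = 1` a certain migration attempt.
#'
#' @param lam Birth rate (per unit time).
#' @param delta Death rate.
#' @param m Migration rate.
#' @param dt Time step (default 1).
#' @param birth_nbhd,migration_nbhd [neighborhood_spec()] objects; the
#'   migration neighborhood may be `"full_domain"` for a well-mixed regime.
#' @param seed RNG seed (mandatory, for reproducibility).
#' @return An object of class `abm_params`.
#' @export
abm_params <- function(lam, delta = 0, m = 0, dt = 1,
                       birth_nbhd = neighborhood_spec("moore"),
                       migration_nbhd = neighborhood_spec("moore"),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  stopifnot(lam >= 0, delta >= 0, m >= 0, dt > 0,
            inherits(birth_nbhd, "neighborhood_spec"),
            inherits(migration_nbhd, "neighborhood_spec"))
  if (birth_nbhd$kind == "full_domain")
    stop("full_domain birth neighborhoods are handled analytically; ",
         "use a finite offset set for the ABM", call. = FALSE)
  structure(list(lam = lam, delta = delta, m = m, dt = dt,
                 birth_nbhd = birth_nbhd, migration_nbhd = migration_nbhd,
                 seed = as.integer(seed)),
            class = "abm_params")
}

#' Lattice state
#'
#' @param occupancy A 0/1 matrix (rows x cols) of site occupancies.
#' @param boundary `"periodic"` (offsets wrap) or `"closed"` (neighborhoods
#'   truncated at the domain edge).
#' @param time Simulation time attached to the state.
#' @return An object of class `lattice_state` with fields `occupancy`,
#'   `width`, `height`, `boundary`, `time`, and `n` (cell count).
#' @export
lattice_state <- function(occupancy, boundary = c("periodic", "closed"),
                          time = 0) {
  boundary <- match.arg(boundary)
  occupancy <- as.matrix(occupancy)
  if (!all(occupancy %in% c(0, 1))) stop("occupancy must be 0/1", call. = FALSE)
  storage.mode(occupancy) <- "integer"
  structure(list(occupancy = occupancy, width = ncol(occupancy),
                 height = nrow(occupancy), boundary = boundary, time = time,
                 n = sum(occupancy)),
            class = "lattice_state")
}

#' Run the on-lattice birth-death-migration simulation
#'
#' At each time step the cells alive at step start are visited in uniformly
#' shuffled order. Each cell (1) attempts migration with probability
#' `min(m dt, 1)`, moving to a uniformly chosen empty site of its migration
#' neighborhood (or of the whole lattice under full-domain migration);
#' (2) attempts birth with probability `min(lam dt, 1)`, placing a daughter
#' at a uniformly chosen empty site of its birth neighborhood; (3) if no
#' daughter was placed (including a fired-but-blocked attempt), dies with
#' probability `min(delta dt, 1)`. Daughters do not act until the next step.
#'
#' @param width,height Lattice dimensions (sites).
#' @param params An [abm_params()] object.
#' @param init `"center"` (single cell at the central site), a
#'   [lattice_state()], a 0/1 occupancy matrix, or an integer number of cells
#'   to scatter uniformly at random.
#' @param steps Number of time steps (`> 0`).
#' @param boundary `"periodic"` or `"closed"`.
#' @param snapshot_steps Integer vector of steps at which to save occupancy
#'   snapshots (step 0 is the initial state).
#' @return A list of class `abm_result`: `trajectory` (data frame with
#'   `step`, `time`, `n`, `blocked`, `surface`, one row per step including
#'   step 0), `final_state` (a [lattice_state()]), `snapshots` (named list of
#'   occupancy matrices), and `params`.
#' @examples
#' p <- abm_params(lam = 0.1, seed = 1)
#' r <- run_abm(32, 32, p, init = "center", steps = 50)
#' tail(r$trajectory)
#' @export
run_abm <- function(width, height, params, init = "center", steps,
                    boundary = c("periodic", "closed"),
                    snapshot_steps = integer(0)) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "abm_params"), width >= 1, height >= 1)
  if (steps <= 0) stop("'steps' must be positive", call. = FALSE)
  l <- width * height

  occ <- matrix(0L, nrow = height, ncol = width)
  if (inherits(init, "lattice_state")) {
    stopifnot(init$width == width, init$height == height)
    occ <- init$occupancy
  } else if (is.matrix(init)) {
    stopifnot(nrow(init) == height, ncol(init) == width)
    occ <- init
    storage.mode(occ) <- "integer"
  } else if (identical(init, "center")) {
    occ[ceiling(height / 2), ceiling(width / 2)] <- 1L
  } else if (is.numeric(init) && length(init) == 1) {
    k <- as.integer(init)
    stopifnot(k >= 0, k <= l)
    set.seed(params$seed)
    occ[sample.int(l, k)] <- 1L
  } else {
    stop("unrecognized 'init'", call. = FALSE)
  }

  pb <- min(params$lam * params$dt, 1)
  pd <- min(params$delta * params$dt, 1)
  pm <- min(params$m * params$dt, 1)
  mig_full <- params$migration_nbhd$kind == "full_domain"
  mig_off <- if (mig_full) matrix(0L, 0, 2) else params$migration_nbhd$offsets

  set.seed(params$seed)
  # occupancy passed row-major: site = row * width + col
  res <- abm_run_cpp(width, height, as.integer(t(occ)),
                     params$birth_nbhd$offsets, mig_off, mig_full,
                     pb, pd, pm, params$dt, as.integer(steps),
                     boundary == "periodic", as.integer(snapshot_steps))
  final <- matrix(res$final_occupancy, nrow = height, ncol = width, byrow = TRUE)
  snaps <- lapply(res$snapshots, function(v)
    matrix(v, nrow = height, ncol = width, byrow = TRUE))
  structure(list(trajectory = res$trajectory,
                 final_state = lattice_state(final, boundary,
                                             time = steps * params$dt),
                 snapshots = snaps,
                 params = params),
            class = "abm_result")
}

.shifted_occ <- function(occ, dr, dc, periodic) {
  h <- nrow(occ); w <- ncol(occ)
  if (periodic) {
    ri <- ((seq_len(h) - 1 + dr) %% h) + 1
    ci <- ((seq_len(w) - 1 + dc) %% w) + 1
    occ[ri, ci, drop = FALSE]
  } else {
    # sites outside a closed domain offer no daughter space: treat as filled
    out <- matrix(1L, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[ok_r, ok_c] <- occ[rs[ok_r], cs[ok_c], drop = FALSE]
    out
  }
}

.blocked_indicator <- function(state, birth_nbhd) {
  occ <- state$occupancy
  periodic <- state$boundary == "periodic"
  off <- neighborhood_offsets(birth_nbhd)
  full <- matrix(1L, nrow(occ), ncol(occ))
  for (k in seq_len(nrow(off))) {
    full <- full * .shifted_occ(occ, off[k, 1], off[k, 2], periodic)
  }
  occ * full
}

#' Fraction of cells with a completely blocked birth neighborhood
#'
#' Counts the cells whose every birth-neighborhood site is occupied. Under
#' `per_cell` normalization this estimates the expected blocked probability
#' entering the mean-field growth law; `per_lattice` divides by the lattice
#' size instead.
#'
#' @param state A [lattice_state()].
#' @param birth_nbhd A finite [neighborhood_spec()].
#' @param normalization `"per_cell"` (default) or `"per_lattice"`.
#' @return The blocked fraction.
#' @export
blocked_fraction <- function(state, birth_nbhd,
                             normalization = c("per_cell", "per_lattice")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(state, "lattice_state"))
  blocked <- sum(.blocked_indicator(state, birth_nbhd))
  if (normalization == "per_cell") {
    if (state$n == 0) stop("per_cell normalization undefined on an empty lattice",
                           call. = FALSE)
    blocked / state$n
  } else {
    blocked / (state$width * state$height)
  }
}

#' Number of surface cells
#'
#' Cells with at least one empty site in their birth neighborhood; equals
#' `n` minus the blocked cell count.
#'
#' @inheritParams blocked_fraction
#' @return Integer count.
#' @export
surface_cell_count <- function(state, birth_nbhd) {
  stopifnot(inherits(state, "lattice_state"))
  state$n - sum(.blocked_indicator(state, birth_nbhd))
}

#' Fractal dimension estimate from surface scaling
#'
#' From the scaling of surface cells with population size,
#' `n_s proportional to n^(D/d)`, the point estimate is
#' `D_hat = d * ln(n_s) / ln(n)`. For a compact population `D_hat` tends to
#' `d - 1`; an irregular boundary pushes it toward `d`.
#'
#' @param n Total cell count (`> 1`), vectorized.
#' @param n_s Surface cell count (`>= 1`), vectorized.
#' @param d Embedding dimension.
#' @return `D_hat`, same length as `n`.
#' @export
fractal_dimension_estimate <- function(n, n_s, d = 2) {
  if (any(n <= 1)) stop("'n' must exceed 1 (log undefined)", call. = FALSE)
  if (any(n_s < 1)) stop("'n_s' must be >= 1", call. = FALSE)
  d * log(n_s) / log(n)
}

#' Ensemble mean and standard deviation of trajectories
#'
#' @param trajectories A list (length `>= 2`) of trajectory data frames on a
#'   common time grid, each with columns `time` and `n`.
#' @return A data frame with `time`, `mean`, and `sd` (pointwise sample SD).
#' @export
ensemble_summary <- function(trajectories) {
  stopifnot(is.list(trajectories), length(trajectories) >= 2)
  t0 <- trajectories[[1]]$time
  for (tr in trajectories) {
    if (length(tr$time) != length(t0) || any(tr$time != t0))
      stop("trajectories must share a common time grid", call. = FALSE)
  }
  mat <- vapply(trajectories, function(tr) as.numeric(tr$n), numeric(length(t0)))
  data.frame(time = t0,
             mean = rowMeans(mat),
             sd = apply(mat, 1, stats::sd))
}

#' Gillespie simulation of the well-mixed birth-death chain
#'
#' Exact event-driven (continuous-time) simulation of the Markov chain on
#' `n = 0, ..., l` with per-capita birth rate `lam * (1 - (n/l)^omega)` and
#' per-capita death rate `delta`. This is the stochastic counterpart of the
#' generalized logistic mean-field law, used for drift/diffusion consistency
#' checks.
#'
#' @param l System size (sites).
#' @param omega Birth-neighborhood size entering the density dependence.
#' @param lam,delta Per-capita birth/death rates.
#' @param n0 Initial cell count (`1 <= n0 <= l`).
#' @param horizon Time horizon.
#' @param seed RNG seed.
#' @param max_events Safety cap on the number of recorded events.
#' @return A data frame with columns `time` and `n`, one row per event
#'   (including the initial state). The run ends at the horizon, at the
#'   absorbing state `n = 0`, or when all rates vanish.
#' @export
wellmixed_gillespie <- function(l, omega, lam, delta, n0, horizon, seed,
                                max_events = 1e7) {
  stopifnot(n0 >= 1, n0 <= l, horizon > 0)
  set.seed(seed)
  res <- gillespie_cpp(l, omega, lam, delta, as.integer(n0), horizon,
                       as.integer(max_events))
  data.frame(time = res$time, n = res$n)
}

#' Empirical drift and diffusion of an ensemble of well-mixed runs
#'
#' Estimates the drift `a(u)` and diffusion `b(u)` of the density
#' `u = n / l` from an ensemble of [wellmixed_gillespie()] runs: trajectories
#' are sampled on a regular grid of width `dt_window`, and the conditional
#' mean and variance of the density increments, scaled by `1/dt_window`, are
#' binned by the density at the window start. As `l` grows these converge to
#' `a(u) = lam (1 - u^omega) u - delta u` and `b(u) = (lam (1 - u^omega) + delta) u / l`.
#'
#' Because the drift varies within a bin and over a window, `a_hat` estimates
#' the bin-average of `a(u)`, not its value at the bin midpoint; supply
#' `drift_fun` to obtain the matching bin-averaged reference (`a_ref`), and
#' keep `dt_window` short relative to `1/|a'(u)|` to limit finite-window
#' bias.
#'
#' @param ensemble List of data frames from [wellmixed_gillespie()].
#' @param l System size used in the runs.
#' @param u_bins Increasing vector of bin edges on density.
#' @param dt_window Window width for increments.
#' @param drift_fun Optional function `u -> a(u)`; when supplied, the output
#'   gains a column `a_ref` with the reference drift averaged over the
#'   densities observed in each bin.
#' @return A data frame with one row per bin: `u_mid`, `u_mean` (mean
#'   observed density at window starts), `a_hat`, `a_se`, `b_hat`, `n_obs`,
#'   and optionally `a_ref`. Empty bins carry `NA`, not zero.
#' @export
empirical_drift_diffusion <- function(ensemble, l, u_bins, dt_window,
                                      drift_fun = NULL) {
  stopifnot(is.list(ensemble), length(ensemble) >= 1, dt_window > 0,
            length(u_bins) >= 2, all(diff(u_bins) > 0))
  us <- numeric(0); dus <- numeric(0)
  for (tr in ensemble) {
    tmax <- max(tr$time)
    grid <- seq(0, tmax, by = dt_window)
    if (length(grid) < 2) next
    f <- stats::stepfun(tr$time[-1], tr$n)
    u <- f(grid) / l
    us <- c(us, u[-length(u)])
    dus <- c(dus, diff(u))
  }
  idx <- findInterval(us, u_bins, rightmost.closed = TRUE)
  nb <- length(u_bins) - 1
  out <- data.frame(u_mid = (u_bins[-1] + u_bins[-length(u_bins)]) / 2,
                    u_mean = NA_real_, a_hat = NA_real_, a_se = NA_real_,
                    b_hat = NA_real_, n_obs = 0L)
  if (!is.null(drift_fun)) out$a_ref <- NA_real_
  for (b in seq_len(nb)) {
    sel <- idx == b
    k <- sum(sel)
    out$n_obs[b] <- k
    if (k >= 2) {
      out$u_mean[b] <- mean(us[sel])
      out$a_hat[b] <- mean(dus[sel]) / dt_window
      out$a_se[b] <- stats::sd(dus[sel]) / sqrt(k) / dt_window
      out$b_hat[b] <- stats::var(dus[sel]) / dt_window
      if (!is.null(drift_fun)) out$a_ref[b] <- mean(drift_fun(us[sel]))
    }
  }
  out
}
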