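#' Design of a synthetic in-vitro confluency experiment
#'
#' Describes a panel of cell lines grown from several initial seeding
#' confluencies, with replicated, noisily observed saturating growth curves.
#' Defaults emulate a seven-line panel seeded at five confluency levels with
#' imaging-style multiplicative measurement noise (2% coefficient of
#' variation plus a small additive floor). Each line's true dynamics follow
#' a generalized logistic law; per-line birth rates span roughly
#' 0.05-0.25 per hour and birth-neighborhood sizes 1-8, the range expected
#' for cells on a 2D substrate.
#'
#' @param n_cell_lines Number of cell lines (used only when `lines` is NULL).
#' @param u0_levels Initial confluencies in `(0, 1)`.
#' @param lines Optional data frame with one row per line: columns
#'   `cell_line`, `law` (`"gen_logistic"` or `"gompertz"`), `lam`,
#'   `omega_bar` (or `g` for Gompertz lines), `delta`.
#' @param cv Coefficient of variation of the multiplicative Gaussian noise.
#' @param floor_sd Standard deviation of the additive noise floor.
#' @param times Sampling times (strictly increasing, in hours).
#' @param replicates Replicates per (line, u0) condition.
#' @param seed RNG seed (mandatory).
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_cell_lines = 7,
                             u0_levels = c(0.01, 0.05, 0.1, 0.2, 0.4),
                             lines = NULL, cv = 0.02, floor_sd = 0.002,
                             times = seq(0, 120, by = 4), replicates = 3,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  stopifnot(all(u0_levels > 0), all(u0_levels < 1), cv >= 0, floor_sd >= 0,
            replicates >= 1, all(diff(times) > 0))
  if (is.null(lines)) {
    lam <- exp(seq(log(0.05), log(0.25), length.out = n_cell_lines))
    omega_bar <- seq(1, 8, length.out = n_cell_lines)
    lines <- data.frame(cell_line = sprintf("line%02d", seq_len(n_cell_lines)),
                        law = "gen_logistic", lam = lam,
                        omega_bar = omega_bar, delta = 0)
  }
  stopifnot(all(c("cell_line", "law", "lam", "delta") %in% names(lines)))
  structure(list(lines = lines, u0_levels = u0_levels, cv = cv,
                 floor_sd = floor_sd, times = times, replicates = replicates,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Generate a synthetic in-vitro confluency dataset
#'
#' For every (cell line, seeding confluency, replicate) the line's true
#' closed-form trajectory is evaluated at the design's sampling times and
#' observed with noise `u_obs = u_true (1 + eps) + eta`, where
#' `eps ~ N(0, cv^2)` and `eta ~ N(0, floor_sd^2)`, clipped to
#' `[1e-6, 1]`. Deterministic given the design seed.
#'
#' @param design A [synthetic_design()].
#' @return A data frame with columns `cell_line`, `u0`, `time`, `confluency`,
#'   `replicate`, carrying the per-line true parameters in the `"truth"`
#'   attribute.
#' @examples
#' d <- synthetic_design(n_cell_lines = 2, replicates = 1, seed = 42)
#' head(generate_invitro_dataset(d))
#' @export
generate_invitro_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  rows <- list()
  for (i in seq_len(nrow(design$lines))) {
    ln <- design$lines[i, ]
    for (u0 in design$u0_levels) {
      p <- if (ln$law == "gen_logistic") {
        growth_params("gen_logistic", lam = ln$lam, omega_bar = ln$omega_bar,
                      delta = ln$delta, u0 = u0)
      } else {
        g <- if ("g" %in% names(ln) && !is.na(ln$g)) ln$g else ln$lam * ln$omega_bar
        growth_params("gompertz", g = g, delta = ln$delta, u0 = u0)
      }
      u_true <- closed_form(p, design$times)
      for (rep in seq_len(design$replicates)) {
        eps <- stats::rnorm(length(u_true), 0, design$cv)
        eta <- stats::rnorm(length(u_true), 0, design$floor_sd)
        u_obs <- pmin(pmax(u_true * (1 + eps) + eta, 1e-6), 1)
        rows[[length(rows) + 1]] <- data.frame(
          cell_line = ln$cell_line, u0 = u0, time = design$times,
          confluency = u_obs, replicate = rep)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- design$lines
  out
}

#' Generate in-silico growth curves across birth-neighborhood sizes
#'
#' Runs the lattice ABM for each birth-neighborhood size `omega` with the
#' birth rate set by the fixed product `lam = lam_omega_product / omega`,
#' the stated death rate, and the requested migration regime, over several
#' seeded replicates. Returns per-`omega` mean density curves together with
#' the per-seed curves, ready for growth-law fitting.
#'
#' @param omega_list Neighborhood sizes; each must map to a named
#'   neighborhood (4, 8, 12, 24).
#' @param lam_omega_product Fixed product `lam * omega` (`> 0`).
#' @param delta Death rate.
#' @param migration_mode `"full_domain"` (well-mixed: migration probability 1
#'   per step into a uniformly chosen empty site of the whole lattice),
#'   `"local"` (Moore-neighborhood random walk at `m = 1`), or `"none"`.
#' @param lattice_dims `c(width, height)`.
#' @param n_seeds Number of replicates per `omega`.
#' @param horizon Number of time steps.
#' @param init_cells Number of initial cells scattered uniformly; the
#'   default seeds 1% of the lattice, matching the lowest in-vitro seeding
#'   level, so that ensemble averaging is not distorted by the growth-timing
#'   jitter of near-single-cell seeds.
#' @param seed Base RNG seed; replicate `j` of neighborhood `omega` uses
#'   `seed + 1000 * omega + j`.
#' @return A list with one element per `omega`, each a list with `omega`,
#'   `lam`, `mean_curve` (data frame `time`, `u`), and `curves` (matrix,
#'   one column per seed).
#' @export
generate_abm_dataset <- function(omega_list = c(4, 8, 12, 24),
                                 lam_omega_product = 0.1, delta = 0.001,
                                 migration_mode = c("full_domain", "local", "none"),
                                 lattice_dims = c(64, 64), n_seeds = 10,
                                 horizon = 1500, init_cells = NULL, seed) {
  migration_mode <- match.arg(migration_mode)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  stopifnot(lam_omega_product > 0)
  if (is.null(init_cells)) init_cells <- max(1L, round(0.01 * prod(lattice_dims)))
  kind_of <- c(`4` = "von_neumann", `8` = "moore", `12` = "von_neumann2",
               `24` = "moore2")
  l <- prod(lattice_dims)
  out <- list()
  for (omega in omega_list) {
    kname <- kind_of[as.character(omega)]
    if (is.na(kname)) stop("unsupported omega: ", omega, call. = FALSE)
    lam <- lam_omega_product / omega
    if (lam > 1) stop("lam * dt > 1: parameter combination infeasible", call. = FALSE)
    mig <- switch(migration_mode,
                  full_domain = neighborhood_spec("full_domain"),
                  local = neighborhood_spec("moore"),
                  none = neighborhood_spec("moore"))
    m <- if (migration_mode == "none") 0 else 1
    curves <- matrix(NA_real_, nrow = horizon + 1, ncol = n_seeds)
    for (j in seq_len(n_seeds)) {
      p <- abm_params(lam = lam, delta = delta, m = m,
                      birth_nbhd = neighborhood_spec(kname),
                      migration_nbhd = mig,
                      seed = seed + 1000 * omega + j)
      r <- run_abm(lattice_dims[1], lattice_dims[2], p, init = init_cells,
                   steps = horizon)
      curves[, j] <- r$trajectory$n / l
    }
    out[[as.character(omega)]] <- list(
      omega = omega, lam = lam,
      mean_curve = data.frame(time = 0:horizon, u = rowMeans(curves)),
      curves = curves)
  }
  out
}
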