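#' Neighborhood occupancy probability under the well-mixed assumption
#'
#' Probability that exactly `x` of the `omega` sites in a focal cell's birth
#' neighborhood are occupied, given `n` cells placed exchangeably on a lattice
#' of `l` sites (the focal cell occupies one site; the other `n - 1` cells are
#' distributed uniformly over the remaining `l - 1` sites). This is the
#' hypergeometric mass
#' \deqn{P(x \mid n) = \binom{\omega}{x}\binom{l-\omega-1}{n-x-1} \big/ \binom{l-1}{n-1}.}
#'
#' Infeasible binomial arguments (e.g. more leftover cells than leftover
#' sites) yield probability 0, so the mass function is total over
#' `x = 0, ..., omega`.
#'
#' @param n Total number of cells on the lattice (integer, `1 <= n <= l`).
#' @param l Total number of lattice sites (integer `>= 1`).
#' @param omega Birth-neighborhood size (integer, `0 <= omega <= l - 1`).
#' @param x Number of occupied neighborhood sites (integer, `0 <= x <= omega`).
#' @param mode `"float"` (default) evaluates via log-gamma differences and is
#'   safe for `l` up to at least 1e6; `"rational"` returns an exact rational
#'   (class `cigrow_rational`) and is available for `l <= 64`.
#' @return A probability (numeric scalar), or an exact rational in
#'   `"rational"` mode (coerce with [as.numeric()]).
#' @examples
#' occupancy_pmf(3, 6, 2, 2)        # = 1/10
#' sum(vapply(0:4, function(x) occupancy_pmf(50, 100, 4, x), 0))  # = 1
#' @seealso [blocked_prob_wellmixed()] for the fully-blocked case `x = omega`.
#' @export
occupancy_pmf <- function(n, l, omega, x, mode = c("float", "rational")) {
  mode <- match.arg(mode)
  check_count <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v != floor(v))
      stop(sprintf("'%s' must be a single integer", nm), call. = FALSE)
  }
  check_count(n, "n"); check_count(l, "l")
  check_count(omega, "omega"); check_count(x, "x")
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (n > l) stop("'n' must not exceed 'l'", call. = FALSE)
  if (omega < 0 || omega > l - 1) stop("'omega' must be in [0, l-1]", call. = FALSE)
  if (x < 0 || x > omega) stop("'x' must be in [0, omega]", call. = FALSE)

  if (mode == "rational") {
    if (l > 64) stop("rational mode is limited to l <= 64", call. = FALSE)
    num <- bi_mul(bi_choose(omega, x), bi_choose(l - omega - 1, n - x - 1))
    den <- bi_choose(l - 1, n - 1)
    return(bi_rational(num, den))
  }
  lognum <- lchoose(omega, x) + lchoose(l - omega - 1, n - x - 1)
  if (!is.finite(lognum)) return(0)
  exp(lognum - lchoose(l - 1, n - 1))
}

#' Probability of a fully blocked birth neighborhood, well-mixed regime
#'
#' Probability that all `omega` sites of a focal cell's birth neighborhood are
#' occupied when cell positions are exchangeable (fast migration). The exact
#' value is the hypergeometric tail term
#' \deqn{P(\omega \mid n) = \prod_{j=0}^{\omega-1} \frac{n-1-j}{l-1-j},}
#' and the large-system limit is \eqn{(n/l)^\omega}.
#'
#' @inheritParams occupancy_pmf
#' @param mode `"exact"` (finite-lattice product form) or `"limit"`
#'   (`(n/l)^omega`, valid for `l, n >> omega`).
#' @return Probability in `[0, 1]`.
#' @examples
#' blocked_prob_wellmixed(500, 1000, 4)                  # about 0.06198
#' blocked_prob_wellmixed(500, 1000, 4, mode = "limit")  # 0.0625
#' @export
blocked_prob_wellmixed <- function(n, l, omega, mode = c("exact", "limit")) {
  mode <- match.arg(mode)
  if (n < 1 || n != floor(n)) stop("'n' must be an integer >= 1", call. = FALSE)
  if (n > l) stop("'n' must not exceed 'l'", call. = FALSE)
  if (omega < 0 || omega > l - 1 || omega != floor(omega))
    stop("'omega' must be an integer in [0, l-1]", call. = FALSE)
  if (mode == "limit") return((n / l)^omega)
  if (omega == 0) return(1)
  j <- 0:(omega - 1)
  f <- (n - 1 - j) / (l - 1 - j)
  if (any(f <= 0)) return(0)
  prod(f)
}

#' Probability of a fully blocked neighborhood, radially growing population
#'
#' For a compact radially growing population (no migration) in `d` dimensions,
#' only surface cells can divide, and the blocked probability equals the bulk
#' fraction \eqn{n_0/n = (1 - n^{-1/d})^d}. The first-order expansion
#' \eqn{1 - d\,n^{-1/d}} is valid for `n >> 1` and is clamped at 0 where the
#' expansion would go negative.
#'
#' @param n Cell count (integer or numeric `>= 1`).
#' @param d Embedding dimension (1, 2, or 3 typically).
#' @param mode `"exact"` or `"firstorder"`.
#' @return Probability in `[0, 1]`.
#' @examples
#' blocked_prob_radial(100, 2)                       # 0.81
#' blocked_prob_radial(100, 2, mode = "firstorder")  # 0.80
#' @export
blocked_prob_radial <- function(n, d, mode = c("exact", "firstorder")) {
  mode <- match.arg(mode)
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  if (d < 1 || d != floor(d)) stop("'d' must be a positive integer", call. = FALSE)
  if (mode == "exact") (1 - n^(-1 / d))^d else pmax(0, 1 - d * n^(-1 / d))
}

#' Blocked probability when the birth neighborhood spans the whole lattice
#'
#' With `omega = l - 1` (every other site is a potential daughter site), a
#' cell is blocked only when the lattice is full, so the blocked probability
#' is the indicator \eqn{I_{n \ge l}}. Growth is therefore exponential until
#' saturation, not logistic.
#'
#' @param n Cell count (integer `>= 0`).
#' @param l Lattice size (integer `>= 1`).
#' @return 0 or 1.
#' @export
blocked_prob_full_neighborhood <- function(n, l) {
  if (n < 0 || l < 1) stop("require n >= 0 and l >= 1", call. = FALSE)
  as.numeric(n >= l)
}

#' Brute-force oracle for the well-mixed blocked probability
#'
#' Places the `n - 1` non-focal cells on the `l - 1` non-focal sites of an
#' abstract site set, either exhaustively or by Monte Carlo, and returns the
#' fraction of configurations in which a designated `omega`-site neighborhood
#' is completely filled. Used as an independent check of the closed form in
#' [blocked_prob_wellmixed()]; it never calls the closed form.
#'
#' @inheritParams occupancy_pmf
#' @param method `"enumerate"` (exhaustive; requires `choose(l-1, n-1) <= 1e6`)
#'   or `"sample"` (Monte Carlo).
#' @param reps Number of Monte Carlo replicates (sample mode).
#' @param seed RNG seed (required in sample mode).
#' @return The blocked fraction. In sample mode the estimate carries
#'   attributes `se` (standard error) and `reps`.
#' @examples
#' oracle_blocked_prob(3, 6, 2)   # 0.1, matches occupancy_pmf(3, 6, 2, 2)
#' @export
oracle_blocked_prob <- function(n, l, omega, method = c("enumerate", "sample"),
                                reps = 10000, seed = NULL) {
  method <- match.arg(method)
  if (n < 1 || n > l) stop("require 1 <= n <= l", call. = FALSE)
  if (omega < 0 || omega > l - 1) stop("'omega' must be in [0, l-1]", call. = FALSE)
  if (omega == 0) return(1)
  if (n == 1) return(0)
  k <- n - 1          # cells to place
  s <- l - 1          # available sites, the first `omega` form the neighborhood
  if (method == "enumerate") {
    total <- choose(s, k)
    if (total > 1e6) stop("enumeration too large: choose(l-1, n-1) > 1e6", call. = FALSE)
    cfg <- utils::combn(s, k)
    hits <- sum(apply(cfg, 2, function(col) all(seq_len(omega) %in% col)))
    est <- hits / total
    attr(est, "hits") <- hits
    attr(est, "total") <- total
    return(est)
  }
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  if (is.null(seed)) stop("sample mode requires a seed", call. = FALSE)
  set.seed(seed)
  blocked <- vapply(seq_len(reps), function(i) {
    occ <- sample.int(s, k)
    all(seq_len(omega) %in% occ)
  }, logical(1))
  est <- mean(blocked)
  structure(est, se = stats::sd(blocked) / sqrt(reps), reps = reps)
}
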