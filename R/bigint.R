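# Minimal arbitrary-precision non-negative integer arithmetic, used only by
# the exact-rational occupancy mode (binomial coefficients for lattices up to
# l = 64 exceed the 2^53 exact-integer range of doubles).
#
# Representation: numeric vector of little-endian digits in base 1e6.
# Supported: construction, addition, multiplication, comparison. Values are
# always normalized (carried, no trailing zero digits except the zero value).

.BI_BASE <- 1e6

bi_norm <- function(d) {
  carry <- 0
  i <- 1
  while (i <= length(d) || carry > 0) {
    if (i > length(d)) d[i] <- 0
    v <- d[i] + carry
    d[i] <- v %% .BI_BASE
    carry <- (v - d[i]) / .BI_BASE
    i <- i + 1
  }
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  d
}

bi <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1, x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(structure(0, class = "cigrow_bigint"))
  d <- numeric(0)
  while (x > 0) {
    r <- x %% .BI_BASE
    d <- c(d, r)
    x <- (x - r) / .BI_BASE
  }
  structure(d, class = "cigrow_bigint")
}

bi_is_zero <- function(a) length(unclass(a)) == 1 && unclass(a)[1] == 0

bi_add <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  n <- max(length(a), length(b))
  length(a) <- n; length(b) <- n
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  structure(bi_norm(a + b), class = "cigrow_bigint")
}

bi_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if ((length(a) == 1 && a[1] == 0) || (length(b) == 1 && b[1] == 0)) {
    return(structure(0, class = "cigrow_bigint"))
  }
  # schoolbook product; partial sums stay below 1e12 * min(na, nb) << 2^53
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  structure(bi_norm(out), class = "cigrow_bigint")
}

# -1, 0, 1 for a < b, a == b, a > b
bi_cmp <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (length(a) != length(b)) return(if (length(a) < length(b)) -1L else 1L)
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

bi_eq <- function(a, b) bi_cmp(a, b) == 0L

bi_to_num <- function(a) {
  a <- unclass(a)
  sum(a * .BI_BASE^(seq_along(a) - 1))
}

#' @exportS3Method
format.cigrow_bigint <- function(x, ...) {
  d <- rev(unclass(x))
  paste0(d[1], paste(sprintf("%06d", d[-1]), collapse = ""))
}

#' @exportS3Method
print.cigrow_bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Pascal-triangle cache of exact binomial coefficients (bigints). Rows are
# built once per session up to the largest requested n.
.bi_choose_cache <- new.env(parent = emptyenv())

bi_choose <- function(a, b) {
  stopifnot(a >= 0, a == floor(a), b == floor(b))
  if (b < 0 || b > a) return(bi(0))
  rows <- get0("rows", envir = .bi_choose_cache)
  if (is.null(rows)) rows <- list(list(bi(1)))
  while (length(rows) < a + 1) {
    prev <- rows[[length(rows)]]
    k <- length(prev)  # row n has n+1 entries; prev is row k-1
    row <- vector("list", k + 1)
    row[[1]] <- bi(1)
    row[[k + 1]] <- bi(1)
    if (k > 1) {
      for (j in 2:k) row[[j]] <- bi_add(prev[[j - 1]], prev[[j]])
    }
    rows[[length(rows) + 1]] <- row
  }
  assign("rows", rows, envir = .bi_choose_cache)
  rows[[a + 1]][[b + 1]]
}

# Exact rational p = num/den (bigints, not reduced). Equality is tested by
# cross-multiplication, so reduction is unnecessary.
bi_rational <- function(num, den) {
  stopifnot(inherits(num, "cigrow_bigint"), inherits(den, "cigrow_bigint"),
            !bi_is_zero(den))
  structure(list(num = num, den = den), class = "cigrow_rational")
}

rat_eq <- function(p, q) {
  bi_eq(bi_mul(p$num, q$den), bi_mul(q$num, p$den))
}

rat_add <- function(p, q) {
  bi_rational(bi_add(bi_mul(p$num, q$den), bi_mul(q$num, p$den)),
              bi_mul(p$den, q$den))
}

# as.numeric() dispatches through as.double
#' @exportS3Method
as.double.cigrow_rational <- function(x, ...) bi_to_num(x$num) / bi_to_num(x$den)

#' @exportS3Method
format.cigrow_rational <- function(x, ...) {
  paste0(format(x$num), "/", format(x$den))
}

#' @exportS3Method
print.cigrow_rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
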