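# Exact nonnegative integer arithmetic on base-1e7 digit vectors.
# Digits are stored little-endian in doubles; every intermediate stays well
# below 2^53, so all operations are exact. Search-space cardinalities exceed
# 10^12 and must never round.

.BIG_BASE <- 1e7

#' Exact big integer
#'
#' Construct an exact nonnegative integer with arbitrary precision, used by
#' the search-space cardinality calculus where counts exceed what a double
#' can hold exactly.
#'
#' @param x a single nonnegative whole number, a decimal digit string, or a
#'   `swarm_bigint`.
#' @return an object of class `swarm_bigint`.
#' @examples
#' bigint(12)
#' bigint("282429536481")
#' @export
bigint <- function(x) {
  if (inherits(x, "swarm_bigint")) return(x)
  if (is.character(x)) {
    if (length(x) != 1L || !grepl("^[0-9]+$", x)) {
      stop("bigint character input must be a single decimal digit string")
    }
    x <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(x)
    starts <- seq(n, 1L, by = -7L)
    digits <- vapply(starts, function(s) {
      as.numeric(substr(x, max(1L, s - 6L), s))
    }, numeric(1))
    return(.big_new(digits))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    stop("bigint requires a single nonnegative whole number")
  }
  if (x > 2^53) stop("numeric input too large to be exact; pass a digit string")
  digits <- numeric(0)
  repeat {
    digits <- c(digits, x %% .BIG_BASE)
    x <- (x - x %% .BIG_BASE) / .BIG_BASE
    if (x == 0) break
  }
  .big_new(digits)
}

.big_new <- function(digits) {
  # strip leading (high-order) zeros, keep at least one digit
  while (length(digits) > 1L && digits[length(digits)] == 0) {
    digits <- digits[-length(digits)]
  }
  structure(list(digits = digits), class = "swarm_bigint")
}

.big_carry <- function(d) {
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= .BIG_BASE) {
      q <- floor(d[i] / .BIG_BASE)
      d[i] <- d[i] - q * .BIG_BASE
      if (i == length(d)) d <- c(d, 0)
      d[i + 1L] <- d[i + 1L] + q
    }
    i <- i + 1L
  }
  d
}

#' @rdname bigint
#' @param a,b `swarm_bigint` (or coercible) operands.
#' @export
big_add <- function(a, b) {
  a <- bigint(a); b <- bigint(b)
  n <- max(length(a$digits), length(b$digits))
  da <- c(a$digits, numeric(n - length(a$digits)))
  db <- c(b$digits, numeric(n - length(b$digits)))
  .big_new(.big_carry(da + db))
}

#' @rdname bigint
#' @export
big_mul <- function(a, b) {
  a <- bigint(a); b <- bigint(b)
  da <- a$digits; db <- b$digits
  res <- numeric(length(da) + length(db))
  for (i in seq_along(da)) {
    if (da[i] == 0) next
    idx <- i:(i + length(db) - 1L)
    res[idx] <- res[idx] + da[i] * db
    res <- .big_carry(res)  # keep partial sums < 2^53
  }
  .big_new(res)
}

#' @rdname bigint
#' @param k nonnegative integer exponent.
#' @export
big_pow <- function(a, k) {
  a <- bigint(a)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != floor(k)) {
    stop("exponent must be a single nonnegative whole number")
  }
  out <- bigint(1)
  base <- a
  while (k > 0) {
    if (k %% 2 == 1) out <- big_mul(out, base)
    k <- (k - k %% 2) / 2
    if (k > 0) base <- big_mul(base, base)
  }
  out
}

#' @export
format.swarm_bigint <- function(x, ...) {
  d <- rev(x$digits)
  head <- format(d[1], scientific = FALSE, trim = TRUE)
  rest <- if (length(d) > 1L) sprintf("%07d", d[-1]) else character(0)
  paste0(head, paste0(rest, collapse = ""))
}

#' @export
print.swarm_bigint <- function(x, ...) {
  cat("<bigint> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.swarm_bigint <- function(x, ...) format(x)

#' @export
as.double.swarm_bigint <- function(x, ...) {
  v <- sum(x$digits * .BIG_BASE^(seq_along(x$digits) - 1))
  if (v > 2^53) warning("bigint exceeds exact double range; value is approximate")
  v
}

#' @export
`==.swarm_bigint` <- function(e1, e2) {
  format(bigint(e1)) == format(bigint(e2))
}
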