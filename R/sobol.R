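# Sobol low-discrepancy sequence (Joe-Kuo direction numbers, dimensions
# 1..6, 30-bit precision, Gray-code ordering) with optional seeded random
# digital-shift scrambling.  Written here because no installed package
# provides Sobol points; validated in the test suite against an independent
# reference implementation's point values.

.SOBOL_BITS <- 30L
.SOBOL_DN <- list( # dims 2..6: s (degree), a (coefficients), m (initial)
  list(s = 1L, a = 0L, m = 1L),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L))
)

# direction integers V[1..bits] for one dimension (1-based dim index)
.sobol_directions <- function(dim) {
  bits <- .SOBOL_BITS
  V <- integer(bits)
  if (dim == 1) {
    for (k in seq_len(bits)) V[k] <- bitwShiftL(1L, bits - k)
    return(V)
  }
  dn <- .SOBOL_DN[[dim - 1]]
  s <- dn$s; a <- dn$a; m <- dn$m
  for (k in seq_len(min(s, bits)))
    V[k] <- bitwShiftL(m[k], bits - k)
  if (bits > s) for (k in (s + 1):bits) {
    V[k] <- bitwXor(V[k - s], bitwShiftR(V[k - s], s))
    if (s > 1) for (i in seq_len(s - 1)) {
      if (bitwAnd(bitwShiftR(a, s - 1L - i), 1L) == 1L)
        V[k] <- bitwXor(V[k], V[k - i])
    }
  }
  V
}

#' Sobol low-discrepancy points
#'
#' Returns points \code{skip, skip+1, ..., skip+n-1} of the d-dimensional
#' Sobol sequence (the unscrambled sequence starts with the origin at index
#' 0).  With \code{scramble = TRUE}, a seeded random digital shift (bitwise
#' XOR with one random integer per dimension) is applied, preserving the
#' sequence's equidistribution while randomizing point locations.
#'
#' @param n number of points.
#' @param d dimension, 1..6.
#' @param scramble apply a random digital shift.
#' @param seed integer seed for the shift (required when scrambling).
#' @param skip index of the first point (default 0).
#' @return n x d matrix of points in [0, 1).
#' @export
sobol_points <- function(n, d, scramble = FALSE, seed = 1L, skip = 0L) {
  stopifnot(n >= 1, d >= 1, d <= 1 + length(.SOBOL_DN), skip >= 0)
  bits <- .SOBOL_BITS
  V <- vapply(seq_len(d), .sobol_directions, integer(bits))
  last <- skip + n - 1L
  if (last >= 2^bits) stop("Sobol index overflow", call. = FALSE)
  X <- matrix(0L, nrow = n, ncol = d)
  x <- integer(d)
  # advance through the sequence in Gray-code order
  i <- 0L
  repeat {
    if (i >= skip) X[i - skip + 1L, ] <- x
    if (i == last) break
    # rightmost zero bit of i (1-based)
    c <- 1L; j <- i
    while (bitwAnd(j, 1L) == 1L) { j <- bitwShiftR(j, 1L); c <- c + 1L }
    x <- bitwXor(x, V[c, ])
    i <- i + 1L
  }
  if (scramble) {
    set.seed(seed)
    shift <- as.integer(floor(runif(d) * 2^bits))
    X <- matrix(bitwXor(X, matrix(shift, n, d, byrow = TRUE)), n, d)
  }
  X / 2^bits
}
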