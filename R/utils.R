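# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%g, %g] (got %g)", name, lower, upper, x)
  invisible(x)
}

#' Centered moving average
#'
#' Sliding-window mean with a symmetric window that shrinks at the edges.
#' A centered local *linear* least-squares fit evaluated at the window
#' midpoint reduces to the window mean, so this doubles as the local linear
#' detrending baseline used by the onset detector.
#'
#' @param x Numeric vector.
#' @param width Window width in samples; even values are promoted to the next
#'   odd integer.
#' @return Numeric vector of the same length as `x`.
#' @keywords internal
running_mean <- function(x, width) {
  n <- length(x)
  width <- as.integer(min(width, n))
  if (width < 1L) width <- 1L
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L || n < 2L) return(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of interior local maxima of `x`, treating plateaus as a single
# maximum located at the plateau midpoint.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the previous non-zero sign through plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  filled <- s
  last <- 0
  for (i in seq_len(n - 1L)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  idx <- which(filled[-(n - 1L)] > 0 & filled[-1L] < 0) + 1L
  # move plateau maxima to the plateau midpoint
  if (length(idx)) {
    idx <- vapply(idx, function(i) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      as.integer((i + j) %/% 2L)
    }, integer(1))
  }
  idx
}

# Topographic prominence of the peak at index `i` of `x`.
peak_prominence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    if (x[j] < left_min) left_min <- x[j]
    j <- j - 1L
  }
  if (j < 1L) left_base <- left_min else left_base <- left_min
  right_min <- h
  j <- i + 1L
  while (j <= n && x[j] <= h) {
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  right_base <- right_min
  h - max(left_base, right_base)
}
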