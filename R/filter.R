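#' Butterworth band-pass design and zero-phase filtering
#'
#' Digital Butterworth band-pass filters designed by the standard analog
#' prototype / frequency transform / bilinear transform route, applied
#' forward-backward (zero phase) with odd reflection padding. Order `n`
#' refers to the low-pass prototype; the band-pass filter has `2n` poles.
#'
#' @name bandpass-filter
#' @keywords internal
NULL

# polynomial coefficients (highest degree first) from roots
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param fs Sampling frequency in Hz (`1/TR` for BOLD data).
#' @param order Prototype order (default 2, giving a 4-pole band-pass).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(f_lo, f_hi, fs, order = 2) {
  stopifnot(f_lo > 0, f_lo < f_hi, f_hi < fs / 2, order >= 1)
  n <- as.integer(order)
  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # prewarped band edges
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * f_lo / fs)
  w2 <- fs2 * tan(pi * f_hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each pole splits in two; n zeros appear at s = 0
  pb <- p * bw / 2
  poles_s <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  zeros_s <- rep(0 + 0i, n)
  gain_s <- bw^n
  # bilinear transform to z-plane
  poles_z <- (fs2 + poles_s) / (fs2 - poles_s)
  zeros_z <- (fs2 + zeros_s) / (fs2 - zeros_s)
  gain_z <- gain_s * Re(prod(fs2 - zeros_s) / prod(fs2 - poles_s))
  # degree balancing: remaining zeros at z = -1
  zeros_z <- c(zeros_z, rep(-1 + 0i, length(poles_z) - length(zeros_z)))
  b <- Re(.poly_from_roots(zeros_z)) * gain_z
  a <- Re(.poly_from_roots(poles_z))
  list(b = b, a = a)
}

#' Filter magnitude response
#'
#' @param filt List with `b`, `a` from [butter_bandpass()].
#' @param f Frequencies in Hz.
#' @param fs Sampling frequency in Hz.
#' @return `|H(f)|` at each frequency.
#' @export
filter_response <- function(filt, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * outer(w, seq_along(filt$b) - 1))
  num <- drop(z %*% filt$b)
  zp <- exp(-1i * outer(w, seq_along(filt$a) - 1))
  den <- drop(zp %*% filt$a)
  Mod(num / den)
}

# IIR filter of every column of x (direct form II transposed, vectorized
# across columns; the time loop is short relative to voxel count)
.iir_filter_cols <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  nx <- nrow(x)
  nc <- ncol(x)
  y <- matrix(0, nx, nc)
  z <- matrix(0, nb - 1, nc)
  for (t in seq_len(nx)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    y[t, ] <- yt
    if (nb > 2) {
      for (j in seq_len(nb - 2)) {
        z[j, ] <- b[j + 1] * xt + z[j + 1, ] - a[j + 1] * yt
      }
    }
    z[nb - 1, ] <- b[nb] * xt - a[nb] * yt
  }
  y
}

#' Zero-phase band-pass filtering of multichannel series
#'
#' Applies the filter forward and backward (squared magnitude response, zero
#' phase lag) with odd-reflection padding of `3 * (2*order)` samples at both
#' ends, matching the common filtfilt convention.
#'
#' @param x Numeric matrix, time in rows, channels (voxels) in columns, or a
#'   vector.
#' @param filt Filter from [butter_bandpass()].
#' @return Filtered matrix (or vector) of the same shape.
#' @export
filtfilt_bandpass <- function(x, filt) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  padlen <- 3L * (length(filt$a) - 1L)
  if (n <= padlen) stop("series too short for the filter (need > ", padlen,
                        " samples, got ", n, ")")
  pre <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[(padlen + 1):2, , drop = FALSE]
  post <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
    x[(n - 1):(n - padlen), , drop = FALSE]
  ext <- rbind(pre, x, post)
  y <- .iir_filter_cols(filt$b, filt$a, ext)
  y <- .iir_filter_cols(filt$b, filt$a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  out <- y[(padlen + 1):(padlen + n), , drop = FALSE]
  if (vec) drop(out) else out
}
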