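#' Teager--Kaiser energy operator
#'
#' Computes phi(n) = f(n)^2 - f(n+1) * f(n-1) at every interior sample. The
#' operator tracks instantaneous amplitude-frequency energy: for a sinusoid
#' A*sin(Omega*n + theta) it returns the constant A^2 * sin(Omega)^2, and it
#' strongly suppresses slowly varying baseline noise relative to nerve
#' bursts, which concentrate both amplitude and frequency change.
#'
#' Boundary samples phi(1) and phi(N) are copied from the nearest interior
#' value so downstream sliding-maximum envelopes see no spurious edge
#' discontinuity. By default the output is full-wave rectified, since the
#' envelope stage expects a non-negative sequence.
#'
#' @param f numeric vector, the band-pass filtered signal (length >= 3).
#' @param rectified logical; return \code{abs(phi)} (default TRUE).
#' @return numeric vector of the same length as \code{f} (uV^2).
#' @export
tke <- function(f, rectified = TRUE) {
  n <- length(f)
  if (n < 3L) stop("TKE operator needs at least 3 samples")
  phi <- numeric(n)
  idx <- 2:(n - 1L)
  phi[idx] <- f[idx]^2 - f[idx + 1L] * f[idx - 1L]
  phi[1L] <- phi[2L]
  phi[n] <- phi[n - 1L]
  if (rectified) abs(phi) else phi
}
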