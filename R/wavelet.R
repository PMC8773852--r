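# Periodized orthogonal Daubechies-6 wavelet transform. No wavelet package
# is declared as a dependency; the transform is a direct pyramidal
# implementation of the 12-tap db6 quadrature-mirror pair with circular
# extension, which makes it an orthonormal map (perfect reconstruction) for
# any even signal length.

# db6 scaling (low-pass) analysis filter, sum = sqrt(2).
.db6_lo <- c(
  0.11154074335010947, 0.49462389039845306, 0.75113390802109540,
  0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
  0.09750160558732304, 0.02752286553030572, -0.03158203931748603,
  0.00055384220116150, 0.00477725751094551, -0.00107730108530848
)
# QMF high-pass: g[k] = (-1)^k h[L-1-k]
.db6_hi <- rev(.db6_lo) * rep(c(1, -1), length.out = length(.db6_lo))

.dwt_step <- function(x, lo = .db6_lo, hi = .db6_hi) {
  n <- length(x)
  L <- length(lo)
  starts <- seq.int(0L, n - 2L, by = 2L)
  idx <- (outer(starts, 0:(L - 1L), "+") %% n) + 1L
  xm <- matrix(x[idx], nrow = length(starts), ncol = L)
  list(a = as.vector(xm %*% lo), d = as.vector(xm %*% hi))
}

.idwt_step <- function(a, d, lo = .db6_lo, hi = .db6_hi) {
  n <- 2L * length(a)
  L <- length(lo)
  starts <- seq.int(0L, n - 2L, by = 2L)
  x <- numeric(n)
  for (m in seq_len(L)) {
    pos <- ((starts + m - 1L) %% n) + 1L
    x[pos] <- x[pos] + a * lo[m] + d * hi[m]
  }
  x
}

# Multi-level periodized DWT: returns list(d = list(d1..dJ), a = aJ).
.dwt <- function(x, levels) {
  if (length(x) %% 2^levels != 0) {
    stop("signal length must be a multiple of 2^levels for periodized DWT")
  }
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- .dwt_step(a)
    d[[j]] <- s$d
    a <- s$a
  }
  list(d = d, a = a)
}

.idwt <- function(coefs) {
  a <- coefs$a
  for (j in rev(seq_along(coefs$d))) {
    a <- .idwt_step(a, coefs$d[[j]])
  }
  a
}

#' Wavelet denoising of a single-lead ECG signal
#'
#' Decomposes the signal with an 8-level periodized Daubechies-6 wavelet
#' transform, zeroes the level-8 approximation band (baseline wander: below
#' about 0.5 Hz at 250 Hz sampling) and the level-1 detail band
#' (high-frequency noise: above about 62 Hz), and reconstructs. The input is
#' reflection-padded up to a multiple of `2^levels` and trimmed back, so the
#' output has the same length as the input.
#'
#' @param x numeric vector, one lead's samples.
#' @param fs sampling frequency in Hz (informational; the default depth of 8
#'   levels is chosen for 250 Hz signals).
#' @param levels decomposition depth (default 8).
#' @return Denoised numeric vector, `length(x)` samples.
#' @export
#' @examples
#' denoise_signal(rep(1, 512))  # DC offset is removed: mean ~ 0
denoise_signal <- function(x, fs = 250, levels = 8L) {
  n <- length(x)
  if (n < 2^levels) {
    stop("signal shorter than the wavelet support: need >= ", 2^levels,
         " samples for ", levels, " levels")
  }
  block <- 2^levels
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    # reflect the tail to avoid a jump at the periodic wrap point
    refl <- rev(x)[seq_len(min(n_pad - n, n))]
    pad <- rep_len(c(refl, rev(refl)), n_pad - n)
    xp <- c(x, pad)
  } else {
    xp <- x
  }
  co <- .dwt(xp, levels)
  co$a <- co$a * 0            # baseline wander
  co$d[[1]] <- co$d[[1]] * 0  # finest-scale noise
  .idwt(co)[seq_len(n)]
}
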