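# HYSCORE (2-D hyperfine sublevel correlation) processing: per-dimension
# 3rd-order polynomial baseline removal, 2-D Hamming apodisation,
# zero-filled 2-D FFT magnitude, folding of the (+,+) and (-,+) quadrants
# (the anti-diagonal symmetrisation) and diagonal symmetrisation.

#' HYSCORE time-domain matrix
#'
#' @param t1_ns,t2_ns time axes in ns (uniform).
#' @param matrix real matrix, rows indexed by t1, columns by t2.
#' @param tau_ns inter-pulse delay tau (metadata).
#' @return A `hyscore_data` list.
#' @export
hyscore_data <- function(t1_ns, t2_ns, matrix, tau_ns = NA) {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(t1_ns),
            ncol(matrix) == length(t2_ns))
  for (ax in list(t1_ns, t2_ns)) {
    dt <- diff(ax)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
      stop("time axes must be uniform", call. = FALSE)
  }
  structure(list(t1 = t1_ns, t2 = t2_ns, matrix = matrix, tau = tau_ns),
            class = "hyscore_data")
}

#' Diagonal symmetrisation of a square frequency map
#'
#' `S <- (S + t(S)) / 2`; idempotent by construction.
#'
#' @param S square numeric matrix.
#' @return Symmetrised matrix.
#' @export
symmetrise_map <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  (S + t(S)) / 2
}

# Hat matrix of a cubic polynomial design on axis t: baseline = H y.
.poly3_hat <- function(t) {
  X <- cbind(1, poly(t, degree = 3))
  X %*% solve(crossprod(X), t(X))
}

#' Process a HYSCORE time matrix to a frequency map
#'
#' Processing chain: 3rd-order polynomial baseline subtraction along each
#' time dimension (rows, then columns), 2-D Hamming apodisation,
#' zero-filling of both dimensions to `zero_fill_factor` times the next
#' power of two (a common square size), 2-D FFT magnitude, folding of the
#' (+,+) and (-,+) quadrants onto one map (the anti-diagonal
#' symmetrisation), and diagonal symmetrisation `(S + t(S)) / 2`, so the
#' returned map equals its transpose.
#'
#' @param data a [hyscore_data()] of at least 8 x 8 points.
#' @param zero_fill_factor zero-filling multiple (default 2).
#' @return A `hyscore_map`: `nu1_mhz`, `nu2_mhz`, non-negative
#'   `magnitude` matrix, `quadrant = "(+,+)"`.
#' @export
hyscore_process <- function(data, zero_fill_factor = 2) {
  stopifnot(inherits(data, "hyscore_data"))
  M <- data$matrix
  n1 <- nrow(M); n2 <- ncol(M)
  if (n1 < 8 || n2 < 8)
    stop("HYSCORE matrix must be at least 8x8", call. = FALSE)
  # baseline along t2 (per row), then along t1 (per column)
  M <- M - M %*% .poly3_hat(data$t2)
  M <- M - .poly3_hat(data$t1) %*% M
  W <- outer(as.numeric(signal::hamming(n1)),
             as.numeric(signal::hamming(n2)))
  M <- M * W
  N <- zero_fill_factor * 2^ceiling(log2(max(n1, n2)))
  P <- matrix(0, N, N)
  P[1:n1, 1:n2] <- M
  G <- Mod(fft(P))
  half <- N / 2
  Qpp <- G[1:half, 1:half]
  # (-,+) quadrant: nu1 = -k maps to row N - k + 1 (k >= 1), row 1 for k=0
  Qmp <- G[c(1, N:(N - half + 2)), 1:half]
  S <- symmetrise_map((Qpp + Qmp) / 2)
  dt1 <- data$t1[2] - data$t1[1]
  dt2 <- data$t2[2] - data$t2[1]
  structure(list(nu1_mhz = (0:(half - 1)) * 1000 / (N * dt1),
                 nu2_mhz = (0:(half - 1)) * 1000 / (N * dt2),
                 magnitude = S, quadrant = "(+,+)"),
            class = "hyscore_map")
}

#' Simulate a separable-tone HYSCORE time matrix
#'
#' `cos(2 pi nu1 t1) cos(2 pi nu2 t2)` on an optional exponential
#' envelope, plus seeded Gaussian noise. Useful as a known-answer input
#' for the processing chain (cross-peaks at (nu1, nu2) and (nu2, nu1)).
#'
#' @param nu1_mhz,nu2_mhz tone frequencies in MHz.
#' @param t_start_ns initial t1 = t2 value (default 56 ns).
#' @param dwell_ns time increment in ns.
#' @param n points per dimension.
#' @param decay_tau_ns optional exponential envelope constant (Inf = none).
#' @param noise_sigma Gaussian noise s.d. (absolute units).
#' @param seed optional RNG seed.
#' @param tau_ns metadata tau.
#' @return A [hyscore_data()].
#' @export
simulate_hyscore_tones <- function(nu1_mhz, nu2_mhz, t_start_ns = 56,
                                   dwell_ns = 16, n = 128,
                                   decay_tau_ns = Inf, noise_sigma = 0,
                                   seed = NULL, tau_ns = 292) {
  t1 <- t_start_ns + dwell_ns * (0:(n - 1))
  t2 <- t1
  env <- if (is.finite(decay_tau_ns))
    outer(exp(-t1 / decay_tau_ns), exp(-t2 / decay_tau_ns)) else 1
  M <- outer(cos(2 * pi * nu1_mhz * 1e-3 * t1),
             cos(2 * pi * nu2_mhz * 1e-3 * t2)) * env
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    M <- M + matrix(rnorm(n * n, 0, noise_sigma), n, n)
  }
  hyscore_data(t1, t2, M, tau_ns = tau_ns)
}
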