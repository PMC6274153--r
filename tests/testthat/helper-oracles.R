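# Independent oracles, deliberately naive: bisection equilibrium solvers and
# direct mole bookkeeping, used to cross-check the package's closed-form and
# recursive implementations.

# 1:1 equilibrium by bisection on f(c) = ka (H - c)(G - c) - c
oracle_complex_1to1 <- function(H, G, ka) {
  if (ka == 0 || H == 0 || G == 0) return(0)
  if (is.infinite(ka)) return(min(H, G))
  f <- function(cc) ka * (H - cc) * (G - cc) - cc
  lo <- 0; hi <- min(H, G)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# single-complex m:n equilibrium by bisection on the extent of reaction
oracle_complex_mn <- function(H, G, beta, m, n) {
  cmax <- min(H / m, G / n)
  if (cmax == 0 || beta == 0) return(0)
  f <- function(cc) beta * (H - m * cc)^m * (G - n * cc)^n - cc
  lo <- 0; hi <- cmax
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ITC heats recomputed by direct bookkeeping: bisection equilibrium at every
# injection, explicit dilution of the pre-existing complex
oracle_itc_heats <- function(exp, n, ka, dh) {
  V0 <- exp$cell_volume
  M <- exp$cell_conc; X <- 0
  c_prev <- 0
  q <- numeric(length(exp$injection_volumes))
  for (i in seq_along(exp$injection_volumes)) {
    f <- exp$injection_volumes[i] / V0
    M <- M * (1 - f)
    X <- X * (1 - f) + exp$syringe_conc * f
    ci <- oracle_complex_1to1(X, n * M, ka)
    q[i] <- dh * V0 * (ci - c_prev * (1 - f)) * 1e9
    c_prev <- ci
  }
  q
}

# short-lived temp files for IO round-trip tests
tmpf <- function(ext) tempfile(fileext = ext)
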