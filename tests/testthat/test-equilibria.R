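# 1:1 and m:n equilibrium solvers, Job curves and maxima.

test_that("equilibrium limits and the quadratic root match the bisection oracle", {
  # no association / no host
  expect_equal(solve_equilibrium_1to1(1e-4, 1e-4, 0)$complex_conc, 0)
  st0 <- solve_equilibrium_1to1(0, 5e-5, 1e4)
  expect_equal(st0$complex_conc, 0)
  expect_equal(st0$free_guest, 5e-5)
  # stoichiometric limit
  expect_equal(solve_equilibrium_1to1(1e-4, 3e-5, Inf)$complex_conc, 3e-5)

  # frozen oracle value: bisection on ka (H-c)(G-c) = c at H=G=1e-4, ka=1e4
  st <- solve_equilibrium_1to1(1e-4, 1e-4, 1e4)
  expect_equal(st$complex_conc, 3.8196601125e-05, tolerance = 1e-9)
  expect_equal(bound_fraction(st), 0.38196601125, tolerance = 1e-9)
})

test_that("equilibrium state satisfies mass balance and the Ka identity", {
  cases <- expand.grid(H = c(1e-6, 1e-4, 1e-2), G = c(5e-7, 2e-4),
                       ka = c(1e2, 1e5, 1e8))
  for (i in seq_len(nrow(cases))) {
    st <- solve_equilibrium_1to1(cases$H[i], cases$G[i], cases$ka[i])
    expect_gte(st$complex_conc, 0)
    expect_lte(st$complex_conc, min(st$total_host, st$total_guest))
    expect_equal(st$free_host + st$complex_conc, st$total_host,
                 tolerance = 1e-12)
    expect_equal(st$free_guest + st$complex_conc, st$total_guest,
                 tolerance = 1e-12)
    if (st$complex_conc > 0)
      expect_equal(st$ka * st$free_host * st$free_guest, st$complex_conc,
                   tolerance = 1e-9)
  }
})

test_that("closed form agrees with bisection over a wide log-spaced grid", {
  kas <- 10^seq(1, 8, length.out = 8)
  concs <- 10^seq(-6, -2, length.out = 4)
  for (ka in kas) for (H in concs) for (G in concs) {
    got <- solve_equilibrium_1to1(H, G, ka)$complex_conc
    want <- oracle_complex_1to1(H, G, ka)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("complex concentration is monotone in ka, host and guest totals", {
  base <- list(H = 1e-4, G = 8e-5, ka = 1e4)
  c_of <- function(H, G, ka) solve_equilibrium_1to1(H, G, ka)$complex_conc
  kas <- 10^seq(0, 8, by = 0.5)
  expect_true(all(diff(vapply(kas, function(k) c_of(base$H, base$G, k),
                              numeric(1))) >= 0))
  Hs <- seq(1e-6, 1e-3, length.out = 30)
  expect_true(all(diff(vapply(Hs, function(h) c_of(h, base$G, base$ka),
                              numeric(1))) >= 0))
  Gs <- seq(1e-6, 1e-3, length.out = 30)
  expect_true(all(diff(vapply(Gs, function(g) c_of(base$H, g, base$ka),
                              numeric(1))) >= 0))
})

test_that("bound fraction depends only on ka*C for equimolar solutions", {
  # scaling totals by s and ka by 1/s leaves the fraction invariant
  f1 <- bound_fraction(solve_equilibrium_1to1(1e-4, 1e-4, 1e4))
  f2 <- bound_fraction(solve_equilibrium_1to1(1e-5, 1e-5, 1e5))
  f3 <- bound_fraction(solve_equilibrium_1to1(1e-3, 1e-3, 1e3))
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(f1, f3, tolerance = 1e-12)
  # but diluting without rescaling ka changes it
  expect_lt(bound_fraction(solve_equilibrium_1to1(1e-5, 1e-5, 1e4)), f1)
})

test_that("input validation names the offending parameter", {
  expect_error(solve_equilibrium_1to1(-1e-5, 1e-4, 1e4), "total_host")
  expect_error(solve_equilibrium_1to1(1e-4, -1, 1e4), "total_guest")
  expect_error(solve_equilibrium_1to1(1e-4, 1e-4, -5), "ka")
  expect_error(bound_fraction(solve_equilibrium_1to1(1e-4, 0, 1e4)),
               "total_guest")
  expect_error(job_curve(1e-4, mole_fractions = c(0, 0.5, 1.2), ka = 1e4),
               "mole fraction")
  expect_error(job_curve(0, ka = 1e4), "total_conc")
})

test_that("Job curves vanish at the endpoints and are symmetric for 1:1", {
  jc <- job_curve(1e-4, mole_fractions = c(0, 1), ka = 1e4)
  expect_equal(jc$complex_concs, c(0, 0))
  # frozen oracle value at x = 0.5 (H = G = 5e-5, ka = 1e4)
  jm <- job_curve(1e-4, mole_fractions = c(0.25, 0.5, 0.75), ka = 1e4)
  expect_equal(jm$complex_concs[2], 1.3397459622e-05, tolerance = 1e-9)
  # exchange symmetry
  x <- seq(0.1, 0.9, by = 0.1)
  js <- job_curve(1e-4, mole_fractions = x, ka = 1e4)
  expect_equal(js$complex_concs, rev(js$complex_concs), tolerance = 1e-12)
})

test_that("Job maximum is 0.5 for any 1:1 curve and m/(m+n) for m:n", {
  # the two study concentration/affinity combinations
  expect_equal(job_maximum(job_curve(5e-5, ka = 1.30e4)), 0.5,
               tolerance = 1e-6)
  expect_equal(job_maximum(job_curve(8e-5, ka = 1.05e5)), 0.5,
               tolerance = 1e-6)
  # random draws
  set.seed(42)
  for (i in 1:20) {
    ka <- 10^stats::runif(1, 2, 7)
    ct <- 10^stats::runif(1, -5, -3)
    expect_equal(job_maximum(job_curve(ct, ka = ka)), 0.5, tolerance = 1e-6)
  }
  # 1:2 host:guest single complex peaks at 1/3
  jc12 <- job_curve(1e-4, mole_fractions = seq(0, 1, length.out = 21),
                    ka = 1e9, m = 1L, n = 2L)
  expect_equal(job_maximum(jc12), 1 / 3, tolerance = 1e-4)
  # cross-check the m:n solver against its bisection oracle
  expect_equal(solve_equilibrium_mn(6e-5, 8e-5, 1e9, m = 1L, n = 2L),
               oracle_complex_mn(6e-5, 8e-5, 1e9, 1, 2), tolerance = 1e-10)
})

test_that("flat Job curves and short grids are rejected", {
  flat <- job_curve(1e-4, mole_fractions = c(0, 0.5, 1), ka = 0)
  expect_error(job_maximum(flat), "flat")
  two <- job_curve(1e-4, mole_fractions = c(0, 1), ka = 1e4)
  expect_error(job_maximum(two), "3 points")
})

test_that("empirical Job curves (observable only, no model) are refined by parabola", {
  x <- seq(0, 1, length.out = 11)
  jc <- job_curve(1e-4, mole_fractions = x, ka = 2e4)
  emp <- jc
  emp$ka <- NULL                      # strip the model: data-only curve
  emp$observable <- jc$complex_concs * 1.7e4
  expect_equal(job_maximum(emp), 0.5, tolerance = 0.02)
})
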