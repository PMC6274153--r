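# ITC dilution bookkeeping, heat simulation and (N, Ka, dH) estimation.

default_exp <- function(cell_conc = 1e-4, k = 20, dv = 2e-6, heats = NULL)
  itc_experiment(2e-4, cell_conc, 2e-3, rep(dv, k), heats = heats)

test_that("cell concentrations follow the recursive overflow model", {
  # dV -> 0 leaves concentrations essentially unchanged
  tiny <- itc_experiment(2e-4, 5e-5, 2e-3, rep(1e-12, 2))
  cc <- track_cell_concentrations(tiny)
  expect_equal(cc$guest_total[2], 5e-5, tolerance = 1e-6)
  # full-replacement limit: one injection of the whole cell volume
  full <- itc_experiment(2e-4, 5e-5, 2e-3, 2e-4)
  cf <- track_cell_concentrations(full)
  expect_equal(cf$guest_total, 0)
  expect_equal(cf$host_total, 2e-3)
  # geometric dilution: 10 x 2 uL into 200 uL scales guest by 0.99^10
  ten <- default_exp(cell_conc = 5e-5, k = 10)
  ct <- track_cell_concentrations(ten)
  expect_equal(ct$guest_total[10], 5e-5 * 0.99^10, tolerance = 1e-12)
})

test_that("experiment validation guards unphysical schedules", {
  expect_error(itc_experiment(2e-4, 5e-5, 2e-3, rep(2e-5, 11)),
               "cumulative")
  expect_error(itc_experiment(2e-4, 2e-3, 5e-5, rep(2e-6, 10)),
               "syringe_conc")
  expect_error(itc_experiment(2e-4, 5e-5, 2e-3, c(2e-6, -1e-6)),
               "positive")
})

test_that("simulated heats match the independent bisection bookkeeping oracle", {
  ex <- default_exp(cell_conc = 1e-4)
  q <- simulate_itc_heats(ex, n = 1, ka = 1.34e4, dh = -15.60)
  q_oracle <- oracle_itc_heats(ex, n = 1, ka = 1.34e4, dh = -15.60)
  expect_equal(q, q_oracle, tolerance = 1e-9)
  # athermal binding releases no heat
  expect_equal(simulate_itc_heats(ex, 1, 1e4, 0), rep(0, 20))
})

test_that("the stoichiometric limit converts units exactly (kcal -> ucal)", {
  # with ka = Inf and excess guest, every injected mole binds:
  # q_i = dh * moles injected * 1e9 ucal/kcal
  ex <- default_exp(cell_conc = 1e-4, k = 8)
  q <- simulate_itc_heats(ex, n = 1, ka = Inf, dh = -10)
  moles_per_inj <- 2e-3 * 2e-6
  expect_equal(q[1], -10 * moles_per_inj * 1e9, tolerance = 1e-12)
  expect_equal(q[4], -10 * moles_per_inj * 1e9, tolerance = 1e-6)
})

test_that("cumulative heat is conserved against mole tracking at saturation", {
  ex <- default_exp(cell_conc = 5e-5, k = 20)
  n <- 1; ka <- 1e6; dh <- -12
  q <- simulate_itc_heats(ex, n, ka, dh)
  cc <- track_cell_concentrations(ex)
  # complex remaining in the cell plus complex expelled by displacement
  c_i <- vapply(seq_len(20), function(i)
    oracle_complex_1to1(cc$host_total[i], n * cc$guest_total[i], ka),
    numeric(1))
  fr <- ex$injection_volumes / ex$cell_volume
  expelled <- sum(c(0, c_i[-20]) * fr)
  expect_equal(sum(q), dh * ex$cell_volume * (c_i[20] + expelled) * 1e9,
               tolerance = 1e-9)
})

test_that("noiseless ITC fits recover (N, Ka, dH) within 0.5%", {
  ex <- generate_itc(cell_conc = 5e-5, n = 1.12, ka = 4.95e4, dh = -11.08)
  fit <- fit_itc(ex)
  expect_true(fit$converged)
  expect_equal(fit$n, 1.12, tolerance = 5e-3)
  expect_equal(fit$ka, 4.95e4, tolerance = 5e-3)
  expect_equal(fit$dh, -11.08, tolerance = 5e-3)
  # derived identities hold exactly
  expect_identical(fit$dg, delta_g_from_ka(fit$ka, fit$temperature))
  expect_identical(fit$tds, fit$dh - fit$dg)

  # sign symmetry: endothermic mirror recovers the flipped enthalpy
  ex2 <- generate_itc(cell_conc = 5e-5, n = 1.12, ka = 4.95e4, dh = 11.08)
  fit2 <- fit_itc(ex2)
  expect_equal(fit2$dh, 11.08, tolerance = 5e-3)
})

test_that("all three published ITC parameter sets round-trip", {
  for (nm in c("CT_itc", "FT_itc", "NT_itc")) {
    truth <- study_design(nm)$args
    fit <- fit_itc(generate_study(nm))
    expect_equal(fit$n, truth$n, tolerance = 5e-3)
    expect_equal(fit$ka, truth$ka, tolerance = 5e-3)
    expect_equal(fit$dh, truth$dh, tolerance = 5e-3)
  }
})

test_that("degenerate heats and short schedules are refused", {
  ex <- default_exp(k = 20)
  ex$heats <- rep(0, 20)
  expect_error(fit_itc(ex), "all heats are zero")
  expect_error(fit_itc(default_exp(k = 20)), "no heats")
  short <- default_exp(k = 6, heats = rnorm(6))
  expect_error(fit_itc(short), "at least 8")
})

test_that("unreached saturation raises the low-identifiability flag", {
  # only 4 uL of titrant into 0.5 mM guest: molar ratio stays far below N
  ex <- generate_itc(cell_conc = 5e-4, n = 1, ka = 1e5, dh = -10,
                     injection_volumes = rep(5e-7, 8))
  fit <- fit_itc(ex)
  expect_true(fit$identifiability_low)
  sat <- fit_itc(generate_study("FT_itc"))
  expect_false(sat$identifiability_low)
})

test_that("the normalized heat curve inflects at molar ratio ~ N", {
  # c = ka * M0 * n >= 10: half-height crossing sits within one injection of N
  for (n_true in c(0.8, 1.0, 1.2)) {
    ex <- generate_itc(cell_conc = 2e-4, n = n_true, ka = 5e5, dh = -10,
                       syringe_conc = 4e-3, injection_volumes = rep(2e-6, 30))
    cc <- track_cell_concentrations(ex)
    ratio <- cc$host_total / cc$guest_total
    moles_inj <- ex$syringe_conc * ex$injection_volumes
    ndh <- ex$heats / (moles_inj * 1e9)  # kcal per mol injectant
    cross <- ratio[which(ndh > -5)[1]]   # first point past half height
    expect_lt(abs(cross - n_true), diff(ratio[1:2]) * 1.5)
  }
})

test_that("parameter recovery at 2% heat noise stays inside 10% median error", {
  # c = ka * M0 * n spanning ~1 to 1000
  designs <- list(list(cell = 2e-5, ka = 5e4),   # c = 1
                  list(cell = 2e-4, ka = 5e4),   # c = 10
                  list(cell = 2e-4, ka = 5e5),   # c = 100
                  list(cell = 2e-4, ka = 5e6))   # c = 1000
  errs <- unlist(lapply(seq_along(designs), function(d) {
    de <- designs[[d]]
    clean <- generate_itc(de$cell, n = 1, ka = de$ka, dh = -11)
    sigma <- 0.02 * max(abs(clean$heats))
    vapply(1:50, function(s) {
      ex <- generate_itc(de$cell, n = 1, ka = de$ka, dh = -11,
                         noise_sigma = sigma, seed = 300 + 50 * d + s)
      abs(fit_itc(ex)$ka - de$ka) / de$ka
    }, numeric(1))
  }))
  expect_length(errs, 200)
  expect_lt(stats::median(errs), 0.10)
})
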