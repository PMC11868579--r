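test_that("cumulative heat honours its limiting cases", {
  p <- binding_params(n = 1, Kd = 1e-6, dH = -10)
  V0 <- 1.4e-3
  expect_equal(cumulative_heat(1e-5, 0, p, V0), 0)       # no ligand, no heat
  p0 <- binding_params(1, 1e-6, 0)
  expect_equal(cumulative_heat(1e-5, 5e-5, p0, V0), 0)   # no enthalpy, no heat
  # stoichiometric limit: at very tight binding and excess ligand the heat
  # saturates at n * M * dH * V0
  tight <- binding_params(1, 1e-15, -10)
  expect_equal(cumulative_heat(1e-5, 5e-5, tight, V0),
               1 * 1e-5 * -10 * V0, tolerance = 1e-6)
})

test_that("saturation fraction matches a root-finder oracle mid-titration", {
  # oracle: solve Ka = ML / ((M - ML)(X - ML)) for bound concentration ML
  # with uniroot, independent of the closed-form quadratic
  oracle_Q <- function(M, X, n, Kd, dH, V0) {
    Ka <- 1 / Kd
    f <- function(ML) Ka * (n * M - ML) * (X - ML) - ML
    ML <- uniroot(f, c(0, min(n * M, X)), tol = 1e-15)$root
    ML * dH * V0
  }
  V0 <- 1.4e-3
  cases <- expand.grid(M = c(5e-6, 2e-5), X = c(1e-6, 1e-5, 4e-5),
                       n = c(0.8, 1, 1.4), Kd = c(1e-8, 1e-6, 1e-4))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    p <- binding_params(cs$n, cs$Kd, -8)
    expect_equal(cumulative_heat(cs$M, cs$X, p, V0),
                 oracle_Q(cs$M, cs$X, cs$n, cs$Kd, -8, V0),
                 tolerance = 1e-8)
  }
})

test_that("saturation fraction stays within [0, 1] over wide random inputs", {
  set.seed(123)
  for (i in 1:200) {
    M <- 10^runif(1, -7, -3)
    X <- 10^runif(1, -8, -2)
    n <- runif(1, 0.3, 3)
    Kd <- 10^runif(1, -12, -2)
    p <- binding_params(n, Kd, -10)
    Q <- cumulative_heat(M, X, p, 1.4e-3)
    theta <- Q / (n * M * -10 * 1.4e-3)
    expect_gte(theta, 0)
    expect_lte(theta, 1 + 1e-12)
  }
})

test_that("simulated titrations are deterministic and obey degenerate limits", {
  p <- titration_protocol(1.4e-3, 1e-5, 1.3e-4, rep(16.4e-6, 17))
  bp <- binding_params(1, 1e-7, -10)
  a <- simulate_titration(p, bp, noise_sd = 1e-9, seed = 42)
  b <- simulate_titration(p, bp, noise_sd = 1e-9, seed = 42)
  expect_identical(a$heats, b$heats)
  # zero enthalpy, zero offset, zero noise: an all-zero thermogram
  zero <- simulate_titration(p, binding_params(1, 1e-7, 0))
  expect_equal(zero$heats, rep(0, 17))
})

test_that("total released heat is conserved over a saturating titration", {
  # with a large excess of tight-binding ligand the summed injection heats
  # (net of dilution bookkeeping) approach n * M_effective * dH * V0
  p <- titration_protocol(1.4e-3, 1e-5, 1e-3, rep(16.4e-6, 20))
  bp <- binding_params(1, 1e-10, -10)
  tg <- simulate_titration(p, bp)
  conc <- fragsite:::itc_concentrations(p)
  k <- nrow(conc)
  # invert the per-injection displacement bookkeeping to recover Q_final
  Qfinal <- 0
  for (i in seq_len(k)) {
    f <- p$injection_volumes[i] / p$cell_volume
    Qfinal <- (tg$heats[i] + Qfinal * (1 - f / 2)) / (1 + f / 2)
  }
  expect_equal(Qfinal, bp$n * conc$M[k] * bp$dH * p$cell_volume,
               tolerance = 1e-3)
})

test_that("noiseless parameters round-trip through the fit to high precision", {
  p <- titration_protocol(1.4e-3, 1e-5, 1.3e-4, rep(16.4e-6, 17))
  truth <- binding_params(n = 1, Kd = 1e-7, dH = -10)
  tg <- simulate_titration(p, truth, noise_sd = 0, q_dil = -2e-9)
  fit <- fit_one_set_of_sites(tg)
  expect_true(fit$converged)
  expect_equal(fit$params$n, 1, tolerance = 1e-6)
  expect_equal(fit$params$Kd, 1e-7, tolerance = 1e-6)
  expect_equal(fit$params$dH, -10, tolerance = 1e-6)
  expect_equal(fit$q_dil, -2e-9, tolerance = 1e-6)
  # thermodynamic identities
  expect_equal(fit$dG, 1.9872e-3 * 298.15 * log(fit$params$Kd), tolerance = 1e-10)
  expect_equal(fit$dG, fit$params$dH + fit$minus_TdS, tolerance = 1e-10)
  expect_equal(fit$c_value, 1 * 1e-5 / fit$params$Kd, tolerance = 1e-6)
})

test_that("recovery holds across noise levels and c-values", {
  # median relative Kd error <= 2% noiseless, <= 15% at 1% relative noise
  p <- titration_protocol(1.4e-3, 1e-5, 1.3e-4, rep(16.4e-6, 17))
  for (cval in c(5, 50, 500)) {
    Kd_true <- 1 * 1e-5 / cval
    truth <- binding_params(1, Kd_true, -10)
    clean <- simulate_titration(p, truth)
    for (noise_frac in c(0, 0.01)) {
      errs <- vapply(1:8, function(s) {
        tg <- simulate_titration(p, truth,
                                 noise_sd = noise_frac * max(abs(clean$heats)),
                                 seed = 1000 + s)
        fit <- suppressWarnings(fit_one_set_of_sites(tg))
        abs(fit$params$Kd / Kd_true - 1)
      }, numeric(1))
      lim <- if (noise_frac == 0) 0.02 else 0.15
      expect_lte(median(errs), lim)
    }
  }
})

test_that("degenerate thermograms are flagged instead of silently fitted", {
  p <- titration_protocol(1.4e-3, 1e-5, 1.3e-4, rep(16.4e-6, 17))
  flat <- thermogram(rep(0, 17), p)
  fit <- suppressWarnings(fit_one_set_of_sites(flat))
  expect_true(!fit$converged || abs(fit$params$dH) < 1e-6)
  short <- thermogram(c(-1e-8, -5e-9, -1e-9), titration_protocol(
    1.4e-3, 1e-5, 1.3e-4, rep(16.4e-6, 3)))
  expect_error(fit_one_set_of_sites(short), "injections")
})

test_that("fits warn when the c-value leaves the reliable window", {
  p <- titration_protocol(1.4e-3, 1e-5, 1.3e-4, rep(16.4e-6, 17))
  weak <- binding_params(1, 2e-5, -10)    # c = 0.5, below the window
  tg <- simulate_titration(p, weak)
  expect_warning(fit <- fit_one_set_of_sites(tg), "c-value")
})

test_that("thermograms round-trip through the microcalorie CSV format", {
  p <- titration_protocol(1.4e-3, 1e-5, 1.3e-4, rep(16.4e-6, 17))
  tg <- simulate_titration(p, binding_params(1, 1e-7, -10), noise_sd = 2e-10,
                           seed = 5)
  tmp <- tempfile(fileext = ".csv")
  write_thermogram_csv(tg, tmp)
  back <- read_thermogram_csv(tmp, cell_conc = 1e-5, syringe_conc = 1.3e-4)
  expect_equal(back$heats, tg$heats, tolerance = 1e-9)
  expect_equal(back$protocol$injection_volumes, tg$protocol$injection_volumes)
})
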