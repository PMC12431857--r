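# Hill-model and one-site binding fits.

test_that("the Hill model honours its midpoint, limits and monotonicity", {
  hp <- hill_params(nc_min = 10, nc_max = 90, kd_uM = 420, n_hill = 3.7)
  expect_equal(hill_model(420, hp), 50)
  expect_equal(hill_model(0, hp), 10)
  expect_equal(hill_model(1e9, hp), 90, tolerance = 1e-4)
  cc <- seq(0, 2000, by = 10)
  expect_true(all(diff(hill_model(cc, hp)) >= 0))
  # direct evaluation: nc_max 80, kd 420, n 4 at conc 840 -> 80 / (1 + 2^-4)
  expect_equal(hill_model(840, hill_params(0, 80, 420, 4)), 80 / (1 + 2^-4))
  expect_error(hill_params(nc_min = 5, nc_max = 1))
})

test_that("noiseless titrations identify the Hill parameters exactly", {
  hp <- hill_params(nc_min = 2, nc_max = 60, kd_uM = 420, n_hill = 4)
  conc <- round(exp(seq(log(100), log(1000), length.out = 12)))
  series <- data.frame(conc_uM = conc, field_id = 1L,
                       count = hill_model(conc, hp))
  fit <- fit_hill(series)
  expect_equal(fit$params$kd_uM, 420, tolerance = 1e-6)
  expect_equal(fit$params$n_hill, 4, tolerance = 1e-6)
  expect_equal(fit$params$nc_min, 2, tolerance = 1e-4)
  expect_equal(fit$params$nc_max, 60, tolerance = 1e-6)
  expect_false(fit$extrapolated)
})

test_that("Hill fit agrees with a profiled grid-search oracle", {
  hp <- hill_params(nc_min = 0, nc_max = 40, kd_uM = 400, n_hill = 3)
  ser <- sim_titration(titration_spec(
    hp, conc_grid_uM = c(120, 220, 330, 450, 650, 900),
    fields_per_conc = 6, seed = 19))
  # oracle: dense grid over (kd, n) with the linear params (nc_min,
  # nc_max - nc_min) profiled by least squares under nc_min >= 0, the
  # same constraint the fit imposes on a count baseline
  grid <- expand.grid(kd = seq(300, 550, by = 2.5), n = seq(1.5, 6, by = 0.05))
  rss <- vapply(seq_len(nrow(grid)), function(i) {
    f <- 1 / (1 + (grid$kd[i] / ser$conc_uM)^grid$n[i])
    co <- coef(lm(ser$count ~ f))
    if (co[1] < 0) {  # profile on the nc_min = 0 boundary
      b <- sum(ser$count * f) / sum(f^2)
      sum((ser$count - b * f)^2)
    } else {
      sum(lm(ser$count ~ f)$residuals^2)
    }
  }, numeric(1))
  best <- grid[which.min(rss), ]
  fit <- fit_hill(ser)
  expect_lt(abs(fit$params$kd_uM - best$kd), 2.5)
  expect_lt(abs(fit$params$n_hill - best$n), 0.05)
  expect_lte(fit$rss, min(rss) + 1e-4)
})

test_that("Hill fit is scale-equivariant in concentration", {
  ser <- sim_titration(titration_spec(hill_params(0, 40, 420, 4), seed = 23))
  f1 <- fit_hill(ser)
  ser2 <- ser; ser2$conc_uM <- ser$conc_uM * 10
  f2 <- fit_hill(ser2)
  expect_equal(f2$params$kd_uM, 10 * f1$params$kd_uM, tolerance = 1e-4)
  expect_equal(f2$params$n_hill, f1$params$n_hill, tolerance = 1e-4)
})

test_that("Hill fit refuses degenerate inputs and supports fixed nc_min", {
  expect_error(fit_hill(data.frame(conc_uM = c(1, 2, 3, 4), field_id = 1,
                                   count = 0)), "no transition")
  expect_error(fit_hill(data.frame(conc_uM = c(1, 2, 3), field_id = 1,
                                   count = c(1, 2, 3))), "4 distinct")
  ser <- sim_titration(titration_spec(hill_params(0, 40, 420, 4), seed = 2))
  fit <- fit_hill(ser, fix_nc_min = 0)
  expect_identical(fit$params$nc_min, 0)
  expect_lt(abs(fit$params$kd_uM - 420) / 420, 0.15)
})

test_that("Hill kd bias is below 5% at the standard field design", {
  kd <- vapply(1:25, function(s)
    fit_hill(sim_titration(titration_spec(hill_params(0, 50, 420, 4),
                                          seed = s)))$params$kd_uM,
    numeric(1))
  expect_lt(abs(mean(kd) - 420) / 420, 0.05)
})

test_that("noiseless isotherms identify kd exactly; regimes are flagged", {
  iso <- sim_isotherm(isotherm_spec(kd_uM = 50, noise_sigma = 0, seed = 1))
  fit <- fit_one_site(iso, labeled_conc_uM = 0.02)
  expect_equal(fit$kd_uM, 50, tolerance = 1e-6)
  expect_false(fit$extrapolated)
  expect_false(fit$stoichiometric)

  # labeled concentration far above kd: stoichiometric titration regime
  stoi <- sim_isotherm(isotherm_spec(kd_uM = 2, labeled_conc_nM = 2e5,
                                     titrant_top_uM = 4000,
                                     noise_sigma = 0, seed = 1))
  sfit <- fit_one_site(stoi, labeled_conc_uM = 200)
  expect_true(sfit$stoichiometric)
})

test_that("bootstrap CIs are deterministic, collapse when noiseless, shrink with n", {
  ser <- sim_titration(titration_spec(hill_params(0, 40, 420, 4), seed = 3))
  fit_kd <- function(d) c(kd = fit_hill(d)$params$kd_uM)
  ci1 <- bootstrap_ci(ser, fit_kd, n_boot = 200, seed = 5,
                      strata = "conc_uM")
  ci2 <- bootstrap_ci(ser, fit_kd, n_boot = 200, seed = 5,
                      strata = "conc_uM")
  expect_identical(ci1, ci2)

  hp <- hill_params(2, 60, 420, 4)
  conc <- round(exp(seq(log(100), log(1000), length.out = 8)))
  clean <- data.frame(conc_uM = conc, field_id = 1,
                      count = hill_model(conc, hp))
  ci0 <- bootstrap_ci(clean, fit_kd, n_boot = 200, seed = 1)
  expect_lt(ci0["kd", "upper"] - ci0["kd", "lower"], 420 * 0.3)

  big <- sim_titration(titration_spec(hill_params(0, 40, 420, 4),
                                      fields_per_conc = 36, seed = 3))
  ci_big <- bootstrap_ci(big, fit_kd, n_boot = 200, seed = 5,
                         strata = "conc_uM")
  expect_lt(ci_big["kd", "upper"] - ci_big["kd", "lower"],
            ci1["kd", "upper"] - ci1["kd", "lower"])
})
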