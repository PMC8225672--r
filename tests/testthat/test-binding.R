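test_that("Tr-FRET ratio is acceptor over donor and scale invariant", {
  expect_equal(tr_fret_ratio(1, 1), 1)
  expect_equal(tr_fret_ratio(i_490 = 4, i_520 = 2), 0.5)
  expect_equal(tr_fret_ratio(8, 4), tr_fret_ratio(2, 1))
  expect_error(tr_fret_ratio(0, 1), "positive")
})

test_that("noiseless saturation round trip recovers all four parameters within 1%", {
  ser <- generate_titration(bmax = 0.30, k_half = 0.8, ns_slope = 0.005,
                            offset = 0.05)
  fit <- fit_saturation(ser)
  est <- stats::setNames(fit$parameters$estimate, fit$parameters$term)
  truth <- c(offset = 0.05, bmax = 0.30, k_half = 0.8, ns_slope = 0.005)
  expect_equal(est[names(truth)], truth, tolerance = 0.01)
  expect_identical(fit$classification, "specific")
})

test_that("pure linear series is classified nonspecific-only with slope recovered", {
  lin <- generate_titration(bmax = 0, ns_slope = 0.01, offset = 0.02)
  fit <- suppressWarnings(fit_saturation(lin))
  expect_identical(fit$classification, "nonspecific")
  est <- stats::setNames(fit$parameters$estimate, fit$parameters$term)
  expect_equal(est[["ns_slope"]], 0.01, tolerance = 1e-6)
  expect_equal(est[["bmax"]], 0)
  expect_true(is.na(glance(fit)$saturation_x))
})

test_that("a series saturating at lipid-to-receptor ratio 4-5 reports it there", {
  ser <- generate_titration()  # defaults emulate the reference assay
  fit <- fit_saturation(ser)
  expect_gte(fit$saturation_x, 4)
  expect_lte(fit$saturation_x, 5)
})

test_that("saturation fit recovery at 2% noise: median Bmax error < 5%, classification >= 95%", {
  n_ok <- 0; bmax_err <- numeric(100)
  for (s in 1:100) {
    truth_bmax <- 0.30
    noisy <- if (s %% 4 == 0) {
      truth_bmax <- 0
      generate_titration(bmax = 0, ns_slope = 0.01, offset = 0.05,
                         noise_sd = 0.02 * 0.1, seed = s)
    } else {
      generate_titration(bmax = truth_bmax, noise_sd = 0.02 * 0.3, seed = s)
    }
    fit <- tryCatch(suppressWarnings(fit_saturation(noisy)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    est <- stats::setNames(fit$parameters$estimate, fit$parameters$term)
    if (truth_bmax > 0) {
      bmax_err[s] <- abs(est[["bmax"]] - truth_bmax) / truth_bmax
      n_ok <- n_ok + (fit$classification == "specific")
    } else {
      bmax_err[s] <- NA
      n_ok <- n_ok + (fit$classification == "nonspecific")
    }
  }
  expect_lt(stats::median(bmax_err, na.rm = TRUE), 0.05)
  expect_gte(n_ok / 100, 0.95)
})

test_that("normalization maps the reference to 100 and is idempotent", {
  expect_equal(normalize_to_reference(2, 2), 100)
  expect_equal(normalize_to_reference(1, 2), 50)
  v <- c(50, 100, 120)
  expect_equal(normalize_to_reference(v, 100), v)  # idempotent on normalized data
  expect_error(normalize_to_reference(1, 0), "positive")
})

test_that("calibration inversion: intercept maps to 0, linear round trip exact", {
  curve <- calibration_curve(slope = 10, intercept = 0)
  expect_equal(lipid_per_receptor(0, curve, 0.5), 0)
  # slope 10/uM, intensity 35, receptor 0.5 uM -> 7 lipids per receptor
  expect_equal(as.numeric(lipid_per_receptor(35, curve, 0.5)), 7)
  std <- tibble::tibble(conc_um = seq(0, 4, by = 0.5),
                        intensity = 3 + 12.5 * seq(0, 4, by = 0.5))
  fitted_curve <- fit_calibration(std)
  back <- as.numeric(lipid_per_receptor(std$intensity, fitted_curve, 1))
  expect_equal(back, std$conc_um, tolerance = 1e-9)
})

test_that("sub-intercept intensities give ratio 0 with warning; extrapolation flagged", {
  curve <- calibration_curve(slope = 10, intercept = 5, valid_range = c(0, 2))
  expect_warning(r <- lipid_per_receptor(2, curve, 0.5), "below")
  expect_equal(as.numeric(r), 0)
  r2 <- lipid_per_receptor(40, curve, 0.5)  # conc 3.5 > valid range
  expect_true(attr(r2, "extrapolated"))
})

test_that("laurdan GP definition, bounds, and scale invariance", {
  expect_equal(laurdan_gp(1, 1), 0)
  expect_equal(laurdan_gp(1, 0), 1)
  expect_equal(laurdan_gp(0, 1), -1)
  expect_equal(laurdan_gp(3, 1), laurdan_gp(6, 2))
  gp <- laurdan_gp(runif(20), runif(20))
  expect_true(all(gp >= -1 & gp <= 1))
  expect_error(laurdan_gp(0, 0), "positive")
})
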