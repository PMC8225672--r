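popc <- list(tau = c(294.0, 826.8), shares = c(0.353, 0.647))

test_that("noiseless biexponential round trip recovers parameters to 0.1%", {
  tr <- generate_decay(popc$tau, popc$shares)
  fit <- fit_decay(tr, 2)
  expect_equal(fit$components$lifetime_us, popc$tau, tolerance = 1e-3)
  fr <- molecular_fractions(fit)
  expect_equal(fr$fraction_pct, 100 * popc$shares, tolerance = 1e-5)
  expect_lt(max(abs(fr$fraction_pct - 100 * popc$shares)), 0.1)
})

test_that("noiseless single-exponential fit is exact with tiny residuals", {
  tr <- generate_decay(500, 1)
  fit <- fit_decay(tr, 1)
  expect_equal(fit$components$lifetime_us, 500, tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(molecular_fractions(fit)$fraction_pct, 100)
  expect_equal(molecular_fractions(fit, "lifetime")$fraction_pct, 100)
})

test_that("noiseless round trips hold across 1-2 component parameter draws", {
  cases <- list(list(tau = 700, sh = 1),
                list(tau = c(150, 900), sh = c(0.2, 0.8)),
                list(tau = c(267.2, 557.8), sh = c(0.637, 0.363)),
                list(tau = c(599.3, 1070.2), sh = c(0.25, 0.75)))
  for (cs in cases) {
    fit <- fit_decay(generate_decay(cs$tau, cs$sh), length(cs$tau))
    expect_equal(fit$components$lifetime_us, cs$tau, tolerance = 1e-3)
    expect_equal(molecular_fractions(fit)$fraction_pct, 100 * cs$sh,
                 tolerance = 1e-4)
  }
})

test_that("fit is invariant to positive intensity rescaling", {
  tr <- generate_decay(popc$tau, popc$shares)
  tr2 <- dplyr::mutate(tr, intensity = intensity * 37.5)
  f1 <- fit_decay(tr, 2); f2 <- fit_decay(tr2, 2)
  expect_equal(f1$components$lifetime_us, f2$components$lifetime_us,
               tolerance = 1e-8)
  expect_equal(molecular_fractions(f1)$fraction_pct,
               molecular_fractions(f2)$fraction_pct, tolerance = 1e-8)
})

test_that("1% noise, fixed seed: lifetimes within 5%, fractions within 2 points", {
  tr <- generate_decay(popc$tau, popc$shares,
                       noise = "gaussian", noise_level = 0.01, seed = 42)
  fit <- fit_decay(tr, 2)
  expect_lt(max(abs(fit$components$lifetime_us - popc$tau) / popc$tau), 0.05)
  fr <- molecular_fractions(fit)
  expect_lt(max(abs(fr$fraction_pct - 100 * popc$shares)), 2)
})

test_that("no systematic fraction bias at 2% noise (mean within simulation SE)", {
  fr <- vapply(1:60, function(s) {
    tr <- generate_decay(popc$tau, popc$shares, t_step = 4,
                         noise = "gaussian", noise_level = 0.02, seed = s)
    molecular_fractions(
      fit_decay(tr, 2, lifetime_grid = c(100, 400, 1200)))$fraction_pct[1]
  }, numeric(1))
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 35.3), se)
})

test_that("input validation: short traces, NA, zero intensity, bad n", {
  tr <- generate_decay(500, 1)
  expect_error(fit_decay(tr[1:40, ], 1), "50 samples")
  expect_error(fit_decay(dplyr::mutate(tr, intensity = 0), 1),
               "identically zero")
  bad <- tr; bad$intensity[3] <- NA
  expect_error(fit_decay(bad, 1), "NA")
  expect_error(fit_decay(tr, 4), "n_components")
})

test_that("degenerate lifetimes are flagged and warned", {
  tr <- generate_decay(c(500, 505), c(0.5, 0.5))
  expect_warning(fit <- fit_decay(tr, 2), "Degenerate")
  expect_true(fit$degenerate)
})

test_that("model selection: 1 for single, 2 for the reference regime, merge for near-ties", {
  expect_identical(as.integer(select_model(generate_decay(500, 1))), 1L)
  tr2 <- generate_decay(popc$tau, popc$shares,
                        noise = "gaussian", noise_level = 0.005, seed = 7)
  expect_identical(as.integer(select_model(tr2)), 2L)
  trd <- generate_decay(c(500, 505), c(0.5, 0.5))
  sel <- select_model(trd)
  expect_identical(as.integer(sel), 1L)
  expect_true(isTRUE(attr(sel, "degenerate")))
})

test_that("model selection is deterministic for a fixed trace", {
  tr <- generate_decay(popc$tau, popc$shares,
                       noise = "gaussian", noise_level = 0.005, seed = 7)
  expect_identical(as.integer(select_model(tr)), as.integer(select_model(tr)))
})

test_that("fraction conventions: amplitude ratio and lifetime weighting", {
  comp <- tibble::tibble(lifetime_us = c(294, 826.8),
                         amplitude = c(0.353, 0.647))
  expect_equal(molecular_fractions(comp)$fraction_pct, c(35.3, 64.7))
  comp2 <- tibble::tibble(lifetime_us = c(300, 900), amplitude = c(0.5, 0.5))
  # hand arithmetic: 0.5*300 / (0.5*300 + 0.5*900) = 0.25
  expect_equal(molecular_fractions(comp2, "lifetime")$fraction_pct, c(25, 75))
  expect_error(
    molecular_fractions(tibble::tibble(lifetime_us = 1, amplitude = 0)),
    "zero")
})

test_that("fractions sum to 100 and permute with the components", {
  comp <- tibble::tibble(lifetime_us = c(100, 400, 900),
                         amplitude = c(0.2, 0.5, 0.3))
  for (conv in c("amplitude", "lifetime")) {
    fr <- molecular_fractions(comp, conv)
    expect_equal(sum(fr$fraction_pct), 100, tolerance = 1e-9)
    fr_rev <- molecular_fractions(comp[3:1, ], conv)
    expect_equal(fr_rev$fraction_pct, rev(fr$fraction_pct))
  }
})

test_that("tidy/glance expose the fit in broom shape", {
  fit <- fit_decay(generate_decay(popc$tau, popc$shares), 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("component", "lifetime_us", "lifetime_se", "amplitude",
                     "amplitude_se", "fraction_pct"))
  gl <- glance(fit)
  expect_identical(gl$n_components, 2L)
  expect_gt(gl$residual_runs_p, 0.05)
})
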