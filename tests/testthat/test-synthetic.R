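test_that("generated shares are probability vectors and reproducible", {
  cfg <- tiny_config(seed = 7)
  sh <- generate_share_dataset(cfg)
  sums <- sh |>
    dplyr::group_by(district_id, season) |>
    dplyr::summarise(s = sum(share), lag = sum(lag_share), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(abs(sums$lag - 1) < 1e-12))
  expect_true(all(sh$share >= 0 & sh$share <= 1))
  expect_identical(sh, generate_share_dataset(tiny_config(seed = 7)))
  expect_false(identical(sh, generate_share_dataset(tiny_config(seed = 8))))
})

test_that("at zero noise, shares equal the logistic transform of the true predictors", {
  cfg <- tiny_config(seed = 3, share_noise_sd = 0)
  sh <- generate_share_dataset(cfg)
  wide <- sh |>
    tidyr::pivot_wider(names_from = use,
                       values_from = c(share, lag_share, dprice))
  ridx <- match(wide$season, c("spring", "summer", "winter"))
  u1 <- (wide$lag_share_rice - wide$lag_share_idle) * cfg$alpha[ridx] +
    wide$dprice_rice * cfg$beta[cbind(ridx, 1)] +
    wide$droad * cfg$eta_road[cbind(ridx, 1)] +
    wide$dprecip * cfg$eta_precip[cbind(ridx, 1)]
  u2 <- (wide$lag_share_nonrice - wide$lag_share_idle) * cfg$alpha[ridx] +
    wide$dprice_nonrice * cfg$beta[cbind(ridx, 2)] +
    wide$droad * cfg$eta_road[cbind(ridx, 2)] +
    wide$dprecip * cfg$eta_precip[cbind(ridx, 2)]
  expected <- shares_from_logodds(u1, u2)
  expect_equal(wide$share_rice, expected$s_rice, tolerance = 1e-14)
  expect_equal(wide$share_nonrice, expected$s_nonrice, tolerance = 1e-14)
})

test_that("district panel satisfies the baseline feasibility invariants", {
  cfg <- tiny_config(seed = 5)
  pan <- generate_district_panel(cfg)
  expect_true(all(pan$theta > 0 & pan$theta < 1))
  expect_true(all(pan$price > 0 & pan$n_base > 0 & pan$area > 0))
  # seasonal potential covers the baseline cultivated share
  cult <- pan |>
    dplyr::group_by(district_id, season) |>
    dplyr::summarise(cult = sum(share_b), cip = cip[1], ci = ci[1],
                     .groups = "drop")
  expect_true(all(cult$cip >= cult$cult - 1e-12))
  # annual intensity equals the summed seasonal cultivated share
  ann <- cult |> dplyr::group_by(district_id) |>
    dplyr::summarise(tot = sum(cult), ci = ci[1], .groups = "drop")
  expect_equal(ann$tot, ann$ci, tolerance = 1e-12)
  expect_identical(pan, generate_district_panel(tiny_config(seed = 5)))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_districts = 0), class = "nitroplan_config_error")
  expect_error(synthetic_config(share_noise_sd = -1), class = "nitroplan_config_error")
  expect_error(synthetic_config(grid_shape = c(2, 5)), class = "nitroplan_config_error")
  expect_error(synthetic_config(rho = matrix(1.2, 3, 2)), class = "nitroplan_config_error")
  expect_error(synthetic_config(zero_input_frac = 1), class = "nitroplan_config_error")
})

test_that("noiseless household yields are exactly linear in transformed inputs", {
  cfg <- tiny_config(seed = 2, yield_noise_sd = 0, zero_input_frac = 0)
  pan <- generate_district_panel(cfg)
  hh <- generate_household_sample(cfg, pan)
  # within one district x season x crop cell the fixed effect is constant:
  # asinh(yield) - rho*asinh(urea) - b1*asinh(labor) - b2*hyb - b3*hyv
  # must be constant across households
  ridx <- match(hh$season, c("spring", "summer", "winter"))
  cidx <- ifelse(hh$crop == "rice", 1L, 2L)
  resid <- asinh(hh$yield) - cfg$rho[cbind(ridx, cidx)] * asinh(hh$urea) -
    cfg$labor_coef[ridx] * asinh(hh$labor) -
    cfg$hybrid_coef * hh$hybrid_share - cfg$hyv_coef * hh$hyv_share
  spread <- tapply(resid, hh$district_id, function(x) diff(range(x)))
  expect_true(all(spread < 1e-10))
  # and the Cobb-Douglas identity holds to high accuracy at field
  # magnitudes: log(yield) is linear in log inputs up to a constant per
  # district x season x crop cell (the asinh/log offset depends on the
  # cell's elasticities)
  log_resid <- log(hh$yield) - cfg$rho[cbind(ridx, cidx)] * log(hh$urea) -
    cfg$labor_coef[ridx] * log(hh$labor) -
    cfg$hybrid_coef * hh$hybrid_share - cfg$hyv_coef * hh$hyv_share
  cell <- interaction(hh$district_id, hh$season, hh$crop)
  log_spread <- tapply(log_resid, cell, function(x) diff(range(x)))
  expect_true(all(log_spread < 5e-3))
})

test_that("requested zero-input fraction is realized and samples are reproducible", {
  cfg <- tiny_config(seed = 9, n_districts = 16, zero_input_frac = 0.1)
  pan <- generate_district_panel(cfg)
  hh <- generate_household_sample(cfg, pan)
  n <- nrow(hh)
  p_hat <- mean(hh$urea == 0)
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  expect_identical(hh, generate_household_sample(cfg, pan))
  expect_true(all(hh$hybrid_share >= 0 & hh$hyv_share >= 0 &
                    hh$hybrid_share + hh$hyv_share <= 1))
})

test_that("toy rasters drain strictly downhill and are reproducible", {
  cfg <- tiny_config(seed = 4)
  r <- generate_toy_rasters(cfg)
  expect_true(all(r$retention >= 0 & r$retention <= 1))
  # every non-final column strictly above its eastern neighbor
  expect_true(all(r$dem[, -ncol(r$dem)] > r$dem[, -1]))
  expect_gte(length(unique(as.vector(r$districts))), 2)
  expect_true(all(vapply(r$load_fert, function(m) all(m >= 0), logical(1))))
  r2 <- generate_toy_rasters(tiny_config(seed = 4))
  expect_identical(r, r2)
  expect_error(generate_toy_rasters(synthetic_config(grid_shape = c(3, 2))),
               class = "nitroplan_config_error")
})

test_that("ASCII grid round trip preserves values and NODATA", {
  m <- matrix(c(1.5, -2, NA, 4, 0, 6), 2, 3)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, path, xll = 10, yll = 20, cellsize = 30)
  back <- read_ascii_grid(path)
  expect_equal(unclass(back)[seq_along(m)], as.vector(m))
  expect_equal(attr(back, "cellsize"), 30)
})
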