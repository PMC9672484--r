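test_that("logistic transform maps log-odds to normalized shares, overflow-safe", {
  expect_equal(as.numeric(shares_from_logodds(0, 0)[1, ]), rep(1 / 3, 3))
  expect_equal(as.numeric(shares_from_logodds(log(2.5), log(1.5))[1, ]),
               c(0.2, 0.5, 0.3))
  big <- shares_from_logodds(800, 0)
  expect_true(all(is.finite(as.matrix(big))))
  expect_equal(big$s_rice, 1, tolerance = 1e-12)
  set.seed(1)
  s <- shares_from_logodds(rnorm(100, 0, 50), rnorm(100, 0, 50))
  expect_true(all(abs(rowSums(as.matrix(s)) - 1) < 1e-12))
  expect_true(all(as.matrix(s) >= 0))
  expect_error(shares_from_logodds(NaN, 0), "finite")
})

test_that("log-odds transform inverts the logistic form exactly", {
  sh <- generate_share_dataset(tiny_config(seed = 21))
  trans <- logodds_transform(sh)
  wide <- trans |>
    dplyr::select(district_id, season, crop, logodds) |>
    tidyr::pivot_wider(names_from = crop, values_from = logodds)
  obs <- sh |>
    dplyr::select(district_id, season, use, share) |>
    tidyr::pivot_wider(names_from = use, values_from = share) |>
    dplyr::rename(obs_idle = idle, obs_rice = rice, obs_nonrice = nonrice)
  both <- dplyr::bind_cols(wide, shares_from_logodds(wide$rice, wide$nonrice)) |>
    dplyr::inner_join(obs, by = c("district_id", "season"))
  expect_equal(both$s_rice, both$obs_rice, tolerance = 1e-12)
  expect_equal(both$s_nonrice, both$obs_nonrice, tolerance = 1e-12)
  expect_equal(both$s_idle, both$obs_idle, tolerance = 1e-12)
})

test_that("log-odds arithmetic and zero-share flooring behave as specified", {
  data <- tibble::tibble(
    district_id = 1L, season = "spring",
    use = c("idle", "rice", "nonrice"),
    share = c(0.2, 0.5, 0.3), lag_share = c(0.3, 0.3, 0.4),
    dprice = c(0, 1, -1), droad = 0.1, dprecip = 0.2)
  tr <- logodds_transform(data)
  expect_equal(tr$logodds[tr$crop == "rice"], log(2.5))
  expect_equal(tr$d_lag_share[tr$crop == "rice"], 0)
  # equal shares give zero log-odds
  data2 <- data; data2$share <- c(0.3, 0.3, 0.4)
  tr2 <- logodds_transform(data2)
  expect_equal(tr2$logodds[tr2$crop == "rice"], 0)
  # a zero share is floored (with renormalization) and counted
  data3 <- data; data3$share <- c(0, 0.6, 0.4)
  expect_message(tr3 <- logodds_transform(data3), "floored 1")
  expect_equal(attr(tr3, "n_floored"), 1L)
  expect_true(all(is.finite(tr3$logodds)))
})

test_that("SUR recovers the true system in the noiseless limit", {
  cfg <- tiny_config(seed = 31, n_districts = 64, share_noise_sd = 0)
  fit <- estimate_sur(generate_share_dataset(cfg))
  co <- fit$coefficients
  truth <- c(
    cfg$alpha[co$season[co$term == "inertia"]],
    cfg$beta[cbind(match(co$season[co$term == "dprice"], rownames(cfg$beta)),
                   match(co$crop[co$term == "dprice"], colnames(cfg$beta)))],
    cfg$eta_road[cbind(match(co$season[co$term == "droad"], rownames(cfg$eta_road)),
                       match(co$crop[co$term == "droad"], colnames(cfg$eta_road)))],
    cfg$eta_precip[cbind(match(co$season[co$term == "dprecip"], rownames(cfg$eta_precip)),
                         match(co$crop[co$term == "dprecip"], colnames(cfg$eta_precip)))])
  expect_lt(max(abs(co$estimate - truth)), 1e-6)
  expect_equal(fit$r.squared, 1, tolerance = 1e-9)
})

test_that("SUR estimates are consistent and within sampling error of truth", {
  cfg <- tiny_config(seed = 32, n_districts = 64)
  fit <- estimate_sur(generate_share_dataset(cfg))
  expect_true(fit$converged)
  co <- fit$coefficients
  # inertia coefficients are shared within season (one row per season)
  expect_equal(nrow(co[co$term == "inertia", ]), 3L)
  z <- abs(co$estimate[co$term == "inertia"] - cfg$alpha) /
    co$std.error[co$term == "inertia"]
  expect_true(all(z < 4))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("degenerate regressors raise an estimation error naming the equation", {
  sh <- generate_share_dataset(tiny_config(seed = 33))
  sh$dprice <- 0  # no price variation in any equation
  expect_error(estimate_sur(sh), "singular")
  small <- generate_share_dataset(tiny_config(seed = 33, n_districts = 4))
  expect_error(estimate_sur(small), "at least")
})

test_that("predicted shares are probability vectors that reproduce the fit", {
  cfg <- tiny_config(seed = 34, share_noise_sd = 0)
  sh <- generate_share_dataset(cfg)
  fit <- estimate_sur(sh)
  pred <- predict_shares(fit, sh)
  expect_true(all(abs(rowSums(as.matrix(pred[, c("s_idle", "s_rice", "s_nonrice")])) - 1) < 1e-12))
  # noiseless data: predictions on the estimation sample return the data
  obs <- sh |>
    dplyr::select(district_id, season, use, share) |>
    tidyr::pivot_wider(names_from = use, values_from = share) |>
    dplyr::inner_join(pred, by = c("district_id", "season"))
  expect_equal(obs$s_rice, obs$rice, tolerance = 1e-6)
  expect_equal(obs$s_idle, obs$idle, tolerance = 1e-6)
  expect_error(predict_shares(fit, sh[, setdiff(names(sh), "droad")]), "missing")
})

test_that("marginal effects follow the logistic derivative formula", {
  co <- sur_stub_fit(beta = c(spring_rice = 0.4, spring_nonrice = 0.2))
  base <- tibble::tibble(
    district_id = 1L, season = "spring", crop = c("rice", "nonrice"),
    share_b = c(0.5, 0.2))
  me <- marginal_effects(co, base, zero_insignificant = FALSE)
  own <- me$effect[me$crop == "rice" & me$wrt == "rice"]
  cross <- me$effect[me$crop == "nonrice" & me$wrt == "rice"]
  expect_equal(own, 0.5 * (1 - 0.5) * 0.4)
  expect_equal(cross, -0.2 * 0.5 * 0.4)
  # idle row closes the system: effects sum to zero over the three uses
  sums <- me |>
    dplyr::group_by(district_id, season, wrt) |>
    dplyr::summarise(s = sum(effect), .groups = "drop")
  expect_true(all(abs(sums$s) < 1e-15))
})

test_that("insignificant price coefficients are zeroed when requested", {
  co <- sur_stub_fit(beta = c(spring_rice = 0.4, spring_nonrice = 0.2),
                     significant = FALSE)
  base <- tibble::tibble(
    district_id = 1L, season = "spring", crop = c("rice", "nonrice"),
    share_b = c(0.5, 0.2))
  expect_true(all(marginal_effects(co, base)$effect == 0))
  expect_false(all(marginal_effects(co, base, zero_insignificant = FALSE)$effect == 0))
})

test_that("analytic marginal effects match finite differences of the logistic form", {
  set.seed(77)
  for (k in 1:20) {
    s <- as.numeric(shares_from_logodds(rnorm(1, 0, 1.5), rnorm(1, 0, 1.5))[1, ])
    beta <- rnorm(2, 0, 0.5)
    fit <- sur_stub_fit(beta = c(spring_rice = beta[1], spring_nonrice = beta[2]))
    base <- tibble::tibble(district_id = 1L, season = "spring",
                           crop = c("rice", "nonrice"), share_b = s[2:3])
    me <- marginal_effects(fit, base, zero_insignificant = FALSE)
    u0 <- c(log(s[2] / s[1]), log(s[3] / s[1]))
    h <- 1e-6
    for (kk in 1:2) {
      du <- c(0, 0); du[kk] <- beta[kk] * h
      up <- shares_from_logodds(u0[1] + du[1], u0[2] + du[2])
      dn <- shares_from_logodds(u0[1] - du[1], u0[2] - du[2])
      fd_rice <- (up$s_rice - dn$s_rice) / (2 * h)
      fd_non <- (up$s_nonrice - dn$s_nonrice) / (2 * h)
      wrt <- c("rice", "nonrice")[kk]
      expect_equal(me$effect[me$crop == "rice" & me$wrt == wrt], fd_rice,
                   tolerance = 1e-6)
      expect_equal(me$effect[me$crop == "nonrice" & me$wrt == wrt], fd_non,
                   tolerance = 1e-6)
    }
  }
})
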