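fast_control <- function(...) nitroplan_control(n_starts = 3L, ...)

test_that("baseline export is the theta-weighted nitrogen applied", {
  pan <- closed_form_panel()
  # one district, one season: 0.2 * 80 kg/acre * 600 acres
  expect_equal(baseline_export(pan), 0.2 * 80 * 600)
  pan0 <- pan; pan0$theta <- 0
  expect_equal(baseline_export(pan0), 0)
  # additivity over districts
  pan2 <- dplyr::bind_rows(pan, pan |> dplyr::mutate(district_id = 2L))
  class(pan2) <- class(pan)
  expect_equal(baseline_export(pan2), 2 * baseline_export(pan))
})

test_that("fixed-area single-cell solve matches the closed-form optimum", {
  pan <- closed_form_panel(inflate = 1.3)
  sol <- solve_seasonal(pan, fix_land = TRUE, control = fast_control())
  L <- pan$share_b * pan$area
  v_b <- L * pan$yield_b * pan$price
  n_star <- (v_b / (L * pan$price * pan$delta))^(1 / pan$rho)
  expect_lt(abs(sol$decisions$n_opt - n_star) / n_star, 1e-4)
  expect_equal(sol$decisions$l_opt, L)
  expect_true(attr(sol$audit, "feasible"))
})

test_that("optimized export never exceeds the baseline (feasible incumbent)", {
  pan <- tight_oracle_panel()
  for (sol in list(solve_seasonal(pan, control = fast_control()),
                   solve_seasonal_spatial(pan, control = fast_control()))) {
    expect_lte(sol$objective, sol$baseline_export * (1 + 1e-9))
    expect_true(attr(sol$audit, "feasible"))
  }
})

test_that("district revenue constraints nest inside the national one", {
  cfg <- tiny_config(seed = 51, n_districts = 6)
  pan <- generate_district_panel(cfg)
  hh <- generate_household_sample(cfg, pan)
  cal <- calibrate_delta(pan, estimate_elasticities(hh)$rho)
  s_seasonal <- solve_seasonal(cal, control = fast_control())
  s_spatial <- solve_seasonal_spatial(cal, control = fast_control())
  expect_lte(s_spatial$objective, s_seasonal$objective * (1 + 1e-6))
  # the seasonal solution is itself feasible under the national constraint
  audit_cross <- audit_solution(cal, within_scenario(s_seasonal, "seasonal-spatial"))
  expect_true(attr(audit_cross, "feasible"))
})

test_that("solver agrees with the exhaustive grid oracle on a tiny instance", {
  pan <- equal_price_oracle_panel()
  orc <- grid_oracle(pan, "seasonal",
                     control = nitroplan_control())
  sol <- solve_seasonal(pan, control = fast_control())
  expect_lt(abs(sol$objective - orc$objective) / orc$objective, 0.01)
  # oracle bound property: a grid point can never beat the solver by more
  # than the solver's own feasibility tolerance
  pan2 <- tight_oracle_panel()
  orc2 <- grid_oracle(pan2, "seasonal-spatial")
  sol2 <- solve_seasonal_spatial(pan2, control = fast_control())
  expect_gte(orc2$objective, sol2$objective * (1 - 1e-6))
})

test_that("refining the oracle grid never worsens its objective", {
  pan <- equal_price_oracle_panel()
  coarse <- grid_oracle(pan, "seasonal", n_refine = 5L, n_seeds = 1L)
  fine <- grid_oracle(pan, "seasonal", n_refine = 60L, n_seeds = 1L)
  expect_lte(fine$objective, coarse$objective * (1 + 1e-12))
})

test_that("the optimum is invariant to a common rescaling of all prices", {
  pan <- tight_oracle_panel()
  sol1 <- solve_seasonal(pan, control = fast_control())
  pan2 <- pan; pan2$price <- pan2$price * 10
  class(pan2) <- class(pan)
  sol2 <- solve_seasonal(pan2, control = fast_control())
  expect_equal(sol2$objective, sol1$objective, tolerance = 1e-5)
  expect_equal(sol2$decisions$n_opt, sol1$decisions$n_opt, tolerance = 1e-4)
})

test_that("integrated scenario recovers the baseline at zero price change", {
  cfg <- tiny_config(seed = 52, n_districts = 8)
  pan <- generate_district_panel(cfg)
  cal <- calibrate_delta(pan, estimate_elasticities(
    generate_household_sample(cfg, pan))$rho)
  fit <- estimate_sur(generate_share_dataset(cfg))
  me <- marginal_effects(fit, cal)
  cost <- cost_baseline(cal)
  geo <- nitroplan:::panel_geometry(cal, NULL)
  prob <- nitroplan:::build_integrated_problem(geo, me, cost,
                                               nitroplan_control())
  dec0 <- prob$decode(prob$x0)  # x = 0, N = N^b
  expect_equal(dec0$l_opt, geo$pan$share_b * geo$pan$area, tolerance = 1e-12)
  expect_equal(dec0$x_opt, rep(0, nrow(dec0)))
  co <- cost[match(paste(geo$pan$district_id, geo$pan$season, geo$pan$crop),
                   paste(cost$district_id, cost$season, cost$crop)), ]
  dc0 <- cost_change(co, geo$pan$delta, geo$pan$rho, geo$pan$n_base)
  expect_equal(dc0, rep(0, nrow(dec0)), tolerance = 1e-12)
  expect_equal(prob$obj(prob$x0) * prob$baseline_export, baseline_export(cal))
  expect_lte(max(prob$hin(prob$x0)), 1e-9)
})

test_that("with all marginal effects zero, integrated reduces to nitrogen-only", {
  pan <- closed_form_panel(inflate = 1.2)
  pan$crop <- "rice"
  fit <- sur_stub_fit(beta = c(winter_rice = 0.3, winter_nonrice = 0.1),
                      significant = FALSE)  # zeroed effects
  me <- marginal_effects(fit, pan)
  expect_true(all(me$effect == 0))
  cost <- cost_baseline(pan)
  # disable the price instruments so the only channel left is nitrogen
  sol <- solve_integrated(pan, me, cost, control = fast_control(x_frac = 0))
  expect_equal(sol$decisions$l_opt, pan$share_b * pan$area, tolerance = 1e-12)
  # independent reference: with L fixed, revenue with the effective price
  # p + dc(N) binds at the optimum; solve that one-dimensional condition
  L <- pan$share_b * pan$area
  v_b <- L * pan$yield_b * pan$price
  rev <- function(n) {
    y <- pan$delta * n^pan$rho
    dc <- pan$p_n * n / y - cost$c_b
    L * y * (pan$price + dc) - v_b
  }
  n_star <- stats::uniroot(rev, c(1, pan$n_base), tol = 1e-12)$root
  expect_equal(sol$decisions$n_opt, n_star, tolerance = 1e-5)
})

test_that("the audit independently verifies constraints and flags violations", {
  pan <- tight_oracle_panel()
  # calibrate productivity to the baseline so that the baseline allocation
  # attains the revenue and rice bounds exactly
  pan$delta <- pan$yield_b / pan$n_base^pan$rho
  # the baseline allocation audited as a solution: feasible, with the
  # revenue and rice constraints binding by construction
  base_sol <- list(scenario = "seasonal",
                   decisions = tibble::tibble(
                     district_id = pan$district_id, season = pan$season,
                     crop = pan$crop, n_opt = pan$n_base,
                     l_opt = pan$share_b * pan$area),
                   objective = baseline_export(pan))
  audit <- audit_solution(pan, base_sol)
  expect_true(attr(audit, "feasible"))
  expect_true(all(audit$binding[audit$constraint == "revenue_district"]))
  expect_true(audit$binding[audit$constraint == "rice_production"])
  expect_equal(attr(audit, "objective_recomputed"), base_sol$objective,
               tolerance = 1e-12)
  expect_true(attr(audit, "objective_match"))
  # pushing one cell's area beyond the seasonal cap is caught
  bad <- base_sol
  bad$decisions$l_opt[1] <- pan$cip[1] * pan$area[1] * 1.05
  audit_bad <- audit_solution(pan, bad)
  expect_false(attr(audit_bad, "feasible"))
  expect_true(any(audit_bad$slack_rel[audit_bad$constraint == "land_seasonal"] < 0))
})

test_that("solver objective matches its audit recomputation to 1e-8", {
  pan <- tight_oracle_panel()
  sol <- solve_seasonal(pan, control = fast_control())
  expect_true(attr(sol$audit, "objective_match"))
  expect_equal(attr(sol$audit, "objective_recomputed"), sol$objective,
               tolerance = 1e-8)
})
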