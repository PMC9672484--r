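test_that("flow on a tilted plane drains to the lowest corner", {
  dem <- outer(3:1, 3:1, function(r, c) r + 0.5 * c)  # falls toward SE
  flow <- compute_flow_field(dem)
  # follow every pixel's path; all must terminate at the SE corner (3,3)
  for (p in seq_along(dem)) {
    cur <- p
    for (step in 1:20) {
      nxt <- flow$downstream[cur]
      if (is.na(nxt)) break
      cur <- nxt
    }
    expect_equal(cur, 9L)  # linear index of (3,3)
  }
  expect_equal(flow$direction[3, 3], 0L)
})

test_that("a column ramp yields straight parallel eastward flow lines", {
  dem <- matrix(rep(6:1, each = 5), 5, 6)
  flow <- compute_flow_field(dem)
  expect_true(all(flow$direction[, -6] == 1L))  # E for every non-outlet cell
  expect_true(all(flow$direction[, 6] == 0L))
})

test_that("D8 directions match the brute-force lowest-neighbor oracle", {
  for (seed in 1:5) {
    dem <- random_pit_free_dem(8, 8, seed)
    flow <- compute_flow_field(dem)
    expect_identical(flow$direction, d8_oracle(dem))
  }
})

test_that("interior pits are rejected with the offending pixel named", {
  dem <- outer(5:1, 5:1, `+`)
  dem[3, 3] <- -10
  expect_error(compute_flow_field(dem), "row 3, col 3")
})

test_that("delivery ratios are the downstream retention products", {
  # 1x3 chain: source -> intermediate (retention 0.8) -> stream
  dem <- matrix(c(3, 2, 1), 1, 3)
  flow <- compute_flow_field(dem)
  retention <- matrix(c(0.5, 0.8, 0), 1, 3)
  streams <- matrix(c(0, 0, 1), 1, 3)
  ratio <- delivery_ratios(flow, retention, streams)
  expect_equal(as.vector(ratio), c(0.2, 1, 1))  # own-cell retention unused

  # retention == 0 delivers everything
  ret0 <- matrix(0, 1, 3)
  expect_equal(as.vector(delivery_ratios(flow, ret0, streams)), c(1, 1, 1))
})

test_that("delivery ratios equal the independent path-walk product", {
  for (seed in 6:9) {
    dem <- random_pit_free_dem(6, 6, seed)
    streams <- matrix(0L, 6, 6); streams[, 6] <- 1L
    set.seed(seed + 100)
    retention <- matrix(runif(36, 0, 0.9), 6, 6)
    ratio <- delivery_ratios(compute_flow_field(dem), retention, streams)
    expect_equal(ratio, path_product_oracle(dem, retention, streams))
  }
})

test_that("paths that never reach a stream are an error", {
  dem <- matrix(c(3, 2, 1), 1, 3)
  flow <- compute_flow_field(dem)
  streams <- matrix(0L, 1, 3)  # outlet is not a stream
  expect_error(delivery_ratios(flow, matrix(0.1, 1, 3), streams),
               "does not reach a stream")
  expect_error(delivery_ratios(flow, matrix(1.5, 1, 3), matrix(1L, 1, 3)),
               "\\[0, 1\\]")
})

test_that("district exports are zonal sums of load times ratio", {
  load <- matrix(c(0, 10, 4, 6), 2, 2)
  ratio <- matrix(c(1, 0.5, 0.25, 1), 2, 2)
  districts <- matrix(c(1, 1, 2, 2), 2, 2)
  run <- run_ndr(load, ratio, districts)
  expect_equal(run$district$export, c(0 * 1 + 10 * 0.5, 4 * 0.25 + 6 * 1))
  expect_equal(run$district$load, c(10, 10))
  expect_true(all(run$export <= run$load + 1e-12))
  expect_equal(sum(run_ndr(load * 0, ratio, districts)$district$export), 0)
  expect_error(run_ndr(-load, ratio, districts), "non-negative")
})

test_that("two-run differencing isolates the fertilizer-attributable ratio", {
  cfg <- tiny_config(seed = 11)
  r <- generate_toy_rasters(cfg)
  flow <- compute_flow_field(r$dem)
  ratio <- delivery_ratios(flow, r$retention, r$streams)
  fert <- r$load_fert$spring
  run_n <- run_ndr(r$load_natural, ratio, r$districts)
  run_f <- run_ndr(fert + r$load_natural, ratio, r$districts)
  theta <- fertilizer_theta(run_f, run_n)
  expect_true(all(theta$valid))
  expect_true(all(theta$theta >= 0 & theta$theta <= 1))
  # hand-computed difference quotient
  manual <- (run_f$district$export - run_n$district$export) /
    (run_f$district$load - run_n$district$load)
  expect_equal(theta$theta, manual)
  # theta invariant to the magnitude of the natural background (linearity)
  run_n2 <- run_ndr(3 * r$load_natural, ratio, r$districts)
  run_f2 <- run_ndr(fert + 3 * r$load_natural, ratio, r$districts)
  expect_equal(fertilizer_theta(run_f2, run_n2)$theta, theta$theta,
               tolerance = 1e-12)
  # zero natural load degenerates to export/load of the fertilizer run
  run_f0 <- run_ndr(fert, ratio, r$districts)
  run_00 <- run_ndr(fert * 0, ratio, r$districts)
  expect_equal(fertilizer_theta(run_f0, run_00)$theta,
               run_f0$district$export / run_f0$district$load)
  # identical runs flag every district undefined
  same <- fertilizer_theta(run_f, run_f)
  expect_true(all(!same$valid))
  expect_true(all(is.na(same$theta)))
})

test_that("raising retention anywhere never raises any district export", {
  cfg <- tiny_config(seed = 12)
  r <- generate_toy_rasters(cfg)
  flow <- compute_flow_field(r$dem)
  base_ratio <- delivery_ratios(flow, r$retention, r$streams)
  base <- run_ndr(r$load_fert$winter, base_ratio, r$districts)
  set.seed(99)
  for (k in 1:5) {
    ret2 <- pmin(1, r$retention + matrix(runif(length(r$retention), 0, 0.3),
                                         nrow(r$retention)))
    run2 <- run_ndr(r$load_fert$winter,
                    delivery_ratios(flow, ret2, r$streams), r$districts)
    expect_true(all(run2$district$export <= base$district$export + 1e-9))
  }
})

test_that("the seasonal theta table covers every district band and season", {
  cfg <- tiny_config(seed = 13)
  tt <- ndr_theta_table(generate_toy_rasters(cfg))
  expect_setequal(unique(tt$season), c("spring", "summer", "winter"))
  expect_true(all(tt$valid))
  expect_true(all(tt$theta > 0 & tt$theta < 1))
})
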