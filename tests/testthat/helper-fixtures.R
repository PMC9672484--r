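# Shared fixtures, all built in code.

# small synthetic config for fast module tests
tiny_config <- function(seed = 1, n_districts = 8, ...) {
  synthetic_config(seed = seed, n_districts = n_districts,
                   grid_shape = c(10, 10), households_per_cell = 10, ...)
}

# single-cell panel with an inflated productivity, so the revenue constraint
# binds strictly below the baseline nitrogen rate and the one-variable
# optimum has a nontrivial closed form
closed_form_panel <- function(inflate = 1.3) {
  pan <- tibble::tibble(
    district_id = 1L, season = "winter", crop = "nonrice",
    share_b = 0.6, area = 1000, ci = 0.6, cip = 0.8,
    price = 10, p_n = 20, n_base = 80, yield_b = 2000, theta = 0.2,
    rho = 0.12)
  pan$delta <- pan$yield_b / pan$n_base^pan$rho * inflate
  class(pan) <- c("nitroplan_panel", class(pan))
  pan
}

# 2-district x 2-season instance with a common crop price and generous land
# caps: the optimum concentrates production in the low-theta season with
# revenue binding, a regime both the NLP solver and the grid oracle resolve
equal_price_oracle_panel <- function() {
  pan <- tidyr::expand_grid(district_id = 1:2, season = c("spring", "winter"),
                            crop = "rice") |>
    dplyr::mutate(
      share_b = c(0.5, 0.4, 0.45, 0.55),
      area = c(1000, 1000, 1500, 1500),
      cip = 0.95, price = 10, p_n = 20,
      n_base = c(80, 90, 70, 100),
      yield_b = c(2000, 2200, 1800, 2400),
      theta = c(0.1, 0.3, 0.12, 0.25),
      rho = 0.12, ci = 1.8)
  pan$delta <- pan$yield_b / pan$n_base^pan$rho * 1.15
  class(pan) <- c("nitroplan_panel", class(pan))
  pan
}

# harder 2x2 instance (unequal prices, tight caps); the solver typically
# beats a finite grid here, so only bound-style comparisons apply
tight_oracle_panel <- function() {
  pan <- tidyr::expand_grid(district_id = 1:2, season = c("spring", "winter"),
                            crop = "rice") |>
    dplyr::mutate(
      share_b = c(0.5, 0.4, 0.45, 0.55),
      area = c(1000, 1000, 1500, 1500),
      cip = c(0.7, 0.6, 0.7, 0.8),
      price = c(10, 11, 9, 12), p_n = 20,
      n_base = c(80, 90, 70, 100),
      yield_b = c(2000, 2200, 1800, 2400),
      theta = c(0.1, 0.3, 0.12, 0.25),
      rho = 0.12) |>
    dplyr::group_by(district_id) |>
    dplyr::mutate(ci = sum(share_b)) |>
    dplyr::ungroup()
  pan$delta <- pan$yield_b / pan$n_base^pan$rho * 1.15
  class(pan) <- c("nitroplan_panel", class(pan))
  pan
}

# relabel a solution's scenario so it can be audited against another
# scenario's constraint set
within_scenario <- function(sol, scenario) {
  sol$scenario <- scenario
  sol
}

# hand-built share-system fit with chosen price coefficients, for testing
# marginal effects and prediction without running the estimator
sur_stub_fit <- function(beta = c(spring_rice = 0.4, spring_nonrice = 0.2),
                         significant = TRUE) {
  seasons <- c("spring", "summer", "winter")
  co <- dplyr::bind_rows(
    tibble::tibble(term = "inertia", season = seasons, crop = "both"),
    tidyr::expand_grid(term = c("dprice", "droad", "dprecip"),
                       season = seasons, crop = c("rice", "nonrice"))) |>
    dplyr::mutate(estimate = 0, std.error = 0.1, statistic = 0, p.value = 1,
                  significant = FALSE)
  for (nm in names(beta)) {
    parts <- strsplit(nm, "_")[[1]]
    i <- which(co$term == "dprice" & co$season == parts[1] & co$crop == parts[2])
    co$estimate[i] <- beta[[nm]]
    co$significant[i] <- significant
    co$p.value[i] <- if (significant) 0.01 else 0.9
  }
  structure(list(coefficients = co, sigma = diag(6), vcov = diag(21),
                 r.squared = NA_real_, n_districts = 0L, n_equations = 6L,
                 iterations = 0L, converged = TRUE, degenerate = FALSE,
                 df.residual = Inf, sig_level = 0.10, epsilon = 1e-4,
                 n_floored = 0L),
            class = "nitroplan_sur")
}

# random pit-free DEM: a tilted plane plus bounded roughness, so every cell
# keeps a strictly lower neighbor toward the south-east
random_pit_free_dem <- function(nr, nc, seed) {
  set.seed(seed)
  base <- outer((nr:1) * 1.0, (nc:1) * 0.7, `+`)
  base + matrix(runif(nr * nc, -0.15, 0.15), nr, nc)
}

# brute-force D8 oracle: argmin neighbor elevation in fixed scan order
d8_oracle <- function(dem) {
  offs <- cbind(c(0, 1, 1, 1, 0, -1, -1, -1), c(1, 1, 0, -1, -1, -1, 0, 1))
  nr <- nrow(dem); nc <- ncol(dem)
  dir <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      best <- Inf; bk <- 0L
      for (k in 1:8) {
        r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (dem[r2, c2] < best) { best <- dem[r2, c2]; bk <- k }
      }
      dir[r, c] <- if (best < dem[r, c]) bk else 0L
    }
  }
  dir
}

# independent delivery-ratio oracle: walk each pixel's path explicitly
path_product_oracle <- function(dem, retention, streams) {
  offs <- cbind(c(0, 1, 1, 1, 0, -1, -1, -1), c(1, 1, 0, -1, -1, -1, 0, 1))
  dir <- d8_oracle(dem)
  nr <- nrow(dem); nc <- ncol(dem)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (streams[r, c] != 0) { out[r, c] <- 1; next }
      prod <- 1
      cr <- r; cc <- c
      repeat {
        k <- dir[cr, cc]
        if (k == 0L) { prod <- NA_real_; break }
        cr2 <- cr + offs[k, 1]; cc2 <- cc + offs[k, 2]
        if (streams[cr2, cc2] != 0) break
        prod <- prod * (1 - retention[cr2, cc2])
        cr <- cr2; cc <- cc2
      }
      out[r, c] <- prod
    }
  }
  out
}
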