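#' Generate a synthetic land-use share dataset
#'
#' Draws, for every district and season, lagged shares, covariate changes and
#' current shares from the logistic share system with the configuration's
#' true coefficients. Lagged (pre-period) shares come from a seeded latent
#' logistic draw; current shares are the logistic transform of the true
#' linear predictors plus log-odds noise, so at `share_noise_sd = 0` the
#' generated shares equal the noiseless logistic values to machine precision.
#'
#' @param cfg A [synthetic_config()].
#' @return A long tibble (ShareDataset): columns `district_id`, `season`,
#'   `use`, `share`, `lag_share`, `dprice` (0 for idle), `droad`, `dprecip`.
#'   Shares sum to one within each district x season.
#' @export
generate_share_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "nitroplan_config"))
  with_local_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$n_districts
    grid <- tidyr::expand_grid(district_id = seq_len(n), season = SEASONS)
    m <- nrow(grid)

    # pre-period (lagged) shares from a latent logistic draw
    a1 <- rnorm(m, 0.4, 0.8)
    a2 <- rnorm(m, 0.3, 0.8)
    lag <- shares_from_logodds(a1, a2)

    dprice1 <- rnorm(m, 0, cfg$dprice_sd)
    dprice2 <- rnorm(m, 0, cfg$dprice_sd)
    droad <- rnorm(m, 0, cfg$droad_sd)
    dprecip <- rnorm(m, 0, cfg$dprecip_sd)
    eps1 <- rnorm(m, 0, cfg$share_noise_sd)
    eps2 <- rnorm(m, 0, cfg$share_noise_sd)

    ridx <- match(grid$season, SEASONS)
    u1 <- (lag$s_rice - lag$s_idle) * cfg$alpha[ridx] +
      dprice1 * cfg$beta[cbind(ridx, 1)] +
      droad * cfg$eta_road[cbind(ridx, 1)] +
      dprecip * cfg$eta_precip[cbind(ridx, 1)] + eps1
    u2 <- (lag$s_nonrice - lag$s_idle) * cfg$alpha[ridx] +
      dprice2 * cfg$beta[cbind(ridx, 2)] +
      droad * cfg$eta_road[cbind(ridx, 2)] +
      dprecip * cfg$eta_precip[cbind(ridx, 2)] + eps2
    cur <- shares_from_logodds(u1, u2)

    wide <- dplyr::bind_cols(grid, cur,
                             tibble::tibble(lag_idle = lag$s_idle,
                                            lag_rice = lag$s_rice,
                                            lag_nonrice = lag$s_nonrice,
                                            dprice1 = dprice1,
                                            dprice2 = dprice2,
                                            droad = droad,
                                            dprecip = dprecip))
    long <- dplyr::bind_rows(
      wide |> dplyr::transmute(.data$district_id, .data$season, use = "idle",
                               share = .data$s_idle, lag_share = .data$lag_idle,
                               dprice = 0, .data$droad, .data$dprecip),
      wide |> dplyr::transmute(.data$district_id, .data$season, use = "rice",
                               share = .data$s_rice, lag_share = .data$lag_rice,
                               dprice = .data$dprice1, .data$droad, .data$dprecip),
      wide |> dplyr::transmute(.data$district_id, .data$season, use = "nonrice",
                               share = .data$s_nonrice, lag_share = .data$lag_nonrice,
                               dprice = .data$dprice2, .data$droad, .data$dprecip)
    ) |>
      dplyr::arrange(.data$district_id,
                     factor(.data$season, levels = season_levels()),
                     factor(.data$use, levels = crop_labels()))
    long
  })
}

#' Generate a synthetic district panel
#'
#' Builds the complete district x season x crop parameter table the
#' optimization stage consumes: baseline shares (from the logistic share
#' system of [generate_share_dataset()] under the same seed), physical
#' cropland area, baseline and potential cropping intensities, net crop
#' prices, nitrogen input prices, baseline nitrogen rates and yields, and
#' nitrogen delivery ratios. The seasonal cropping-intensity potential is
#' drawn with positive headroom above the baseline cultivated share, and the
#' annual cropping intensity equals the baseline annual cultivated share, so
#' the baseline allocation is feasible (and the annual land constraint binds)
#' by construction.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble of class `nitroplan_panel` with one row per
#'   district x season x crop (`crop` in `"rice"`, `"nonrice"`): columns
#'   `district_id`, `season`, `crop`, `share_b`, `area` (acres, district
#'   physical cropland), `ci` (baseline annual cropping intensity), `cip`
#'   (seasonal potential), `price` (net price, Taka/kg), `p_n` (nitrogen
#'   price, Taka/kg), `n_base` (kg/acre), `yield_b` (kg/acre,
#'   rice-equivalent), `theta` (delivery ratio).
#' @export
generate_district_panel <- function(cfg) {
  stopifnot(inherits(cfg, "nitroplan_config"))
  shares <- generate_share_dataset(cfg)
  wide <- shares |>
    dplyr::select("district_id", "season", "use", "share") |>
    tidyr::pivot_wider(names_from = "use", values_from = "share")

  with_local_seed(derive_seed(cfg$seed, 2L), {
    n <- cfg$n_districts
    districts <- tibble::tibble(
      district_id = seq_len(n),
      area = runif(n, 5e4, 2e5)
    )
    cells <- tidyr::expand_grid(district_id = seq_len(n), season = SEASONS) |>
      dplyr::left_join(wide, by = c("district_id", "season")) |>
      dplyr::mutate(
        cultivated = .data$rice + .data$nonrice,
        cip = pmin(1, .data$cultivated + runif(dplyr::n(), 0.05, 0.25)),
        p_n = runif(dplyr::n(), 16, 24),
        theta = runif(dplyr::n(), cfg$theta_range[1], cfg$theta_range[2])
      )
    ci_tab <- cells |>
      dplyr::group_by(.data$district_id) |>
      dplyr::summarise(ci = sum(.data$cultivated), .groups = "drop")

    long <- dplyr::bind_rows(
      cells |> dplyr::transmute(.data$district_id, .data$season, crop = "rice",
                                share_b = .data$rice, .data$cip, .data$p_n,
                                .data$theta),
      cells |> dplyr::transmute(.data$district_id, .data$season, crop = "nonrice",
                                share_b = .data$nonrice, .data$cip, .data$p_n,
                                .data$theta)
    ) |>
      dplyr::mutate(
        price = ifelse(.data$crop == "rice",
                       runif(dplyr::n(), 8, 12), runif(dplyr::n(), 9, 14)),
        n_base = runif(dplyr::n(), 40, 120),
        yield_b = runif(dplyr::n(), 1200, 3000)
      ) |>
      dplyr::left_join(districts, by = "district_id") |>
      dplyr::left_join(ci_tab, by = "district_id") |>
      dplyr::select("district_id", "season", "crop", "share_b", "area", "ci",
                    "cip", "price", "p_n", "n_base", "yield_b", "theta") |>
      dplyr::arrange(.data$district_id,
                     factor(.data$season, levels = season_levels()),
                     .data$crop)
    class(long) <- c("nitroplan_panel", class(long))
    long
  })
}

#' Baseline aggregates of a district panel
#'
#' Computes the baseline quantities the optimization constraints reference:
#' district production value \eqn{v^b_i}, national production value
#' \eqn{v^b}, and national rice production \eqn{Y^b_1}, all evaluated at the
#' baseline shares, yields and prices (so the baseline allocation satisfies
#' the revenue and food-security constraints with equality).
#'
#' @param panel A panel from [generate_district_panel()] (or read from disk).
#' @return A list with `district` (tibble `district_id`, `v_b`), `v_b`
#'   (national value, Taka), `y1_b` (national rice production, kg).
#' @export
panel_baseline <- function(panel) {
  validate_panel(panel)
  dist <- panel |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(
      v_b = sum(.data$share_b * .data$area * .data$yield_b * .data$price),
      .groups = "drop")
  rice <- panel |> dplyr::filter(.data$crop == "rice")
  list(district = dist,
       v_b = sum(dist$v_b),
       y1_b = sum(rice$share_b * rice$area * rice$yield_b))
}

validate_panel <- function(panel) {
  req <- c("district_id", "season", "crop", "share_b", "area", "ci", "cip",
           "price", "p_n", "n_base", "yield_b", "theta")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols)) {
    stop_input("panel is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (any(panel$theta < 0 | panel$theta > 1)) {
    stop_input("panel delivery ratios must lie in [0, 1]")
  }
  if (any(panel$area <= 0) || any(panel$price < 0) || any(panel$n_base <= 0) ||
      any(panel$yield_b <= 0)) {
    stop_input("panel areas, nitrogen rates and yields must be positive; prices non-negative")
  }
  invisible(panel)
}

#' Generate a synthetic household yield sample
#'
#' Draws, for every district x season x crop cell of the panel, a fixed
#' number of households with urea and labor inputs, hybrid/HYV area shares,
#' and yields from the inverse-hyperbolic-sine Cobb-Douglas yield model with
#' the configuration's true elasticities and a district fixed effect. A
#' configurable fraction of urea and labor entries is set to exactly zero to
#' exercise the inverse-hyperbolic-sine path of the estimator. At
#' `yield_noise_sd = 0` the transformed yield is an exact linear function of
#' the transformed inputs.
#'
#' @param cfg A [synthetic_config()].
#' @param panel Panel generated from the same config (supplies the district
#'   baseline nitrogen rates around which household urea use is drawn).
#' @return A tibble (HouseholdSample): `household_id`, `district_id`,
#'   `season`, `crop`, `yield` (kg/acre), `urea` (kg/acre), `labor`
#'   (hours/acre), `hybrid_share`, `hyv_share`.
#' @export
generate_household_sample <- function(cfg, panel) {
  stopifnot(inherits(cfg, "nitroplan_config"))
  validate_panel(panel)
  with_local_seed(derive_seed(cfg$seed, 3L), {
    n_h <- cfg$households_per_cell
    cells <- panel |>
      dplyr::select("district_id", "season", "crop", "n_base")
    m <- nrow(cells) * n_h
    hh <- cells[rep(seq_len(nrow(cells)), each = n_h), ] |>
      dplyr::mutate(household_id = seq_len(m), .before = 1)

    district_effect <- setNames(
      4.0 + rnorm(cfg$n_districts, 0, 0.15), seq_len(cfg$n_districts))

    ridx <- match(hh$season, SEASONS)
    cidx <- ifelse(hh$crop == "rice", 1L, 2L)
    urea <- hh$n_base / cfg$urea_n_factor * rlnorm(m, 0, 0.25)
    labor <- rlnorm(m, log(300), 0.4)
    if (cfg$zero_input_frac > 0) {
      urea[runif(m) < cfg$zero_input_frac] <- 0
      labor[runif(m) < cfg$zero_input_frac] <- 0
    }
    g1 <- stats::rgamma(m, 2); g2 <- stats::rgamma(m, 2); g3 <- stats::rgamma(m, 3)
    hybrid <- g1 / (g1 + g2 + g3)
    hyv <- g2 / (g1 + g2 + g3)

    lin <- cfg$rho[cbind(ridx, cidx)] * asinh(urea) +
      cfg$labor_coef[ridx] * asinh(labor) +
      cfg$hybrid_coef * hybrid +
      cfg$hyv_coef * hyv +
      district_effect[as.character(hh$district_id)] +
      rnorm(m, 0, cfg$yield_noise_sd)

    tibble::tibble(
      household_id = hh$household_id,
      district_id = hh$district_id,
      season = hh$season,
      crop = hh$crop,
      yield = sinh(lin),
      urea = urea,
      labor = labor,
      hybrid_share = hybrid,
      hyv_share = hyv
    )
  })
}
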