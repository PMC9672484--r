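#' Configuration for the synthetic study system
#'
#' Bundles every knob of the synthetic data-generating process: the true
#' coefficients of the logistic land-use share system, the true Cobb-Douglas
#' yield-nitrogen elasticities, noise scales, and raster dimensions. The
#' defaults emulate a 64-district country with three cropping seasons
#' (spring, summer, winter) and three land uses per season (rice, non-rice,
#' idle), which is the setting every downstream stage of the package assumes.
#'
#' Shares are generated from a logistic (multinomial-logit) system with idle
#' land as the residual category: the linear predictor of crop \eqn{j} in
#' season \eqn{r} is
#' \deqn{u_{rj} = (s^0_{rj} - s^0_{r0})\alpha_r + x_{rj}\beta_{rj} +
#'   z_r \eta_{rj} + \epsilon_{rj},}
#' where \eqn{s^0} are lagged shares (the inertia variable), \eqn{x_{rj}} the
#' net-price change, and \eqn{z_r} the road-density and precipitation changes.
#' Noise enters on the linear-predictor (log-odds) scale so the SUR estimator
#' of the share system is correctly specified.
#'
#' Household yields are generated from the inverse-hyperbolic-sine form of
#' the Cobb-Douglas yield function,
#' \deqn{\mathrm{asinh}(y_h) = \rho_{rj}\,\mathrm{asinh}(U_h) +
#'   b_1\,\mathrm{asinh}(Lab_h) + b_2 Hyb_h + b_3 HYV_h + D_i + \epsilon_h,}
#' which coincides with the log Cobb-Douglas form up to terms of order
#' \eqn{1/x^2} at the magnitudes generated (yields in kg/acre).
#'
#' @param seed Integer seed; the same (config, seed) pair reproduces every
#'   fixture bit for bit.
#' @param n_districts Number of districts (default 64).
#' @param grid_shape Integer vector `c(rows, cols)` for the toy rasters;
#'   both must be at least 3.
#' @param alpha Length-3 numeric, true inertia coefficient per season.
#' @param beta 3x2 matrix (season x crop), true own net-price-change
#'   coefficients for rice and non-rice.
#' @param eta_road,eta_precip 3x2 matrices, true covariate-change
#'   coefficients (difference vs the idle category).
#' @param rho 3x2 matrix in (0,1), true yield-nitrogen elasticities.
#' @param labor_coef,hybrid_coef,hyv_coef True auxiliary yield coefficients.
#' @param share_noise_sd Standard deviation of the log-odds noise.
#' @param yield_noise_sd Standard deviation of the household yield noise on
#'   the asinh scale.
#' @param zero_input_frac Fraction of household urea/labor entries set to
#'   exactly zero, exercising the inverse-hyperbolic-sine path.
#' @param households_per_cell Households drawn per district x season x crop.
#' @param dprice_sd,droad_sd,dprecip_sd Scales of the covariate changes.
#' @param theta_range Range from which district x season delivery ratios are
#'   drawn (defaults bracket realistic watershed values).
#' @param n_raster_districts Number of district bands on the toy rasters.
#' @param urea_n_factor kg of nitrogen per kg of urea (applied consistently
#'   wherever urea rates are converted to nitrogen).
#'
#' @return An object of class `nitroplan_config` (a named list).
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, n_districts = 8)
#' panel <- generate_district_panel(cfg)
synthetic_config <- function(seed = 1L,
                             n_districts = 64L,
                             grid_shape = c(24L, 24L),
                             alpha = c(3.5, 2.5, 5.0),
                             beta = rbind(c(0.06, 0.13),
                                          c(0.07, 0.04),
                                          c(0.40, 0.30)),
                             eta_road = rbind(c(0.5, 0.5),
                                              c(7.0, 8.0),
                                              c(-2.5, -1.5)),
                             eta_precip = rbind(c(0.2, 0.3),
                                                c(-0.1, -0.1),
                                                c(2.5, 12.0)),
                             rho = rbind(c(0.12, 0.09),
                                         c(0.13, 0.10),
                                         c(0.06, 0.11)),
                             labor_coef = c(0.55, 0.70, 0.15),
                             hybrid_coef = 0.3,
                             hyv_coef = 0.2,
                             share_noise_sd = 0.15,
                             yield_noise_sd = 0.30,
                             zero_input_frac = 0.05,
                             households_per_cell = 25L,
                             dprice_sd = 0.5,
                             droad_sd = 0.05,
                             dprecip_sd = 0.2,
                             theta_range = c(0.05, 0.35),
                             n_raster_districts = 4L,
                             urea_n_factor = 0.46) {
  if (length(n_districts) != 1 || n_districts < 1) {
    stop_config("`n_districts` must be a positive integer, got %s", n_districts)
  }
  if (length(grid_shape) != 2 || any(grid_shape < 3)) {
    stop_config("`grid_shape` must be c(rows, cols) with both >= 3")
  }
  if (share_noise_sd < 0 || yield_noise_sd < 0) {
    stop_config("noise scales must be non-negative")
  }
  if (zero_input_frac < 0 || zero_input_frac >= 1) {
    stop_config("`zero_input_frac` must lie in [0, 1)")
  }
  if (any(rho <= 0) || any(rho >= 1)) {
    stop_config("all elasticities `rho` must lie strictly in (0, 1)")
  }
  if (length(alpha) != 3 || !all(dim(beta) == c(3, 2)) ||
      !all(dim(eta_road) == c(3, 2)) || !all(dim(eta_precip) == c(3, 2)) ||
      !all(dim(rho) == c(3, 2))) {
    stop_config("coefficient blocks must be length-3 (alpha) or 3x2 matrices")
  }
  if (theta_range[1] <= 0 || theta_range[2] > 1 || diff(theta_range) < 0) {
    stop_config("`theta_range` must be an increasing range inside (0, 1]")
  }
  dimnames(beta) <- dimnames(eta_road) <- dimnames(eta_precip) <-
    dimnames(rho) <- list(SEASONS, c("rice", "nonrice"))
  structure(
    list(
      seed = as.integer(seed),
      n_districts = as.integer(n_districts),
      n_seasons = 3L,
      grid_shape = as.integer(grid_shape),
      alpha = setNames(alpha, SEASONS),
      beta = beta,
      eta_road = eta_road,
      eta_precip = eta_precip,
      rho = rho,
      labor_coef = setNames(labor_coef, SEASONS),
      hybrid_coef = hybrid_coef,
      hyv_coef = hyv_coef,
      share_noise_sd = share_noise_sd,
      yield_noise_sd = yield_noise_sd,
      zero_input_frac = zero_input_frac,
      households_per_cell = as.integer(households_per_cell),
      dprice_sd = dprice_sd,
      droad_sd = droad_sd,
      dprecip_sd = dprecip_sd,
      theta_range = theta_range,
      n_raster_districts = as.integer(n_raster_districts),
      urea_n_factor = urea_n_factor
    ),
    class = "nitroplan_config"
  )
}

#' @export
print.nitroplan_config <- function(x, ...) {
  cat("<nitroplan_config>\n")
  cat(sprintf("  seed: %d | districts: %d | seasons: %d | grid: %dx%d\n",
              x$seed, x$n_districts, x$n_seasons,
              x$grid_shape[1], x$grid_shape[2]))
  cat(sprintf("  share noise sd: %.3g | yield noise sd: %.3g | zero-input frac: %.3g\n",
              x$share_noise_sd, x$yield_noise_sd, x$zero_input_frac))
  invisible(x)
}
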