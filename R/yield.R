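# Cobb-Douglas yield function: inverse-hyperbolic-sine estimation of the
# yield-nitrogen elasticities with district fixed effects, productivity
# calibration, and the nitrogen cost-change function used by the integrated
# optimization.

#' Inverse hyperbolic sine
#'
#' \eqn{\mathrm{ihs}(x) = \ln(x + \sqrt{x^2 + 1})}: a log-like transform that
#' is exact at zero and agrees with \eqn{\ln(2x)} up to \eqn{O(1/x^2)} for
#' large \eqn{x}, so zero input records need no ad-hoc shifting.
#'
#' @param x Numeric vector.
#' @return `asinh(x)`.
#' @export
#' @examples
#' ihs(0)            # 0
#' ihs(100) - log(200)  # ~ 1.25e-05
ihs <- function(x) {
  if (any(!is.finite(x))) stop_input("`ihs` requires finite input")
  asinh(x)
}

# within-district demeaning OLS with correct fixed-effect degrees of freedom;
# drops collinear regressors (after demeaning) with a warning
fe_ols <- function(y, X, district) {
  district <- as.factor(district)
  G <- nlevels(district)
  demean <- function(v) v - ave(v, district)
  yd <- demean(y)
  Xd <- apply(X, 2, demean)
  qx <- qr(Xd)
  dropped <- character(0)
  if (qx$rank < ncol(Xd)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(Xd)[setdiff(seq_len(ncol(Xd)), keep)]
    Xd <- Xd[, keep, drop = FALSE]
    qx <- qr(Xd)
  }
  if (qx$rank == 0) stop_input("all regressors perfectly collinear with the fixed effects")
  b <- qr.coef(qx, yd)
  res <- as.numeric(yd - Xd %*% b)
  df <- length(y) - ncol(Xd) - G
  if (df <= 0) stop_input("not enough observations for the fixed-effects regression")
  s2 <- sum(res^2) / df
  XtXinv_piv <- chol2inv(qr.R(qx))
  piv <- qx$pivot
  vcov_b <- matrix(NA_real_, ncol(Xd), ncol(Xd),
                   dimnames = list(colnames(Xd), colnames(Xd)))
  vcov_b[piv, piv] <- XtXinv_piv * s2
  se <- sqrt(diag(vcov_b))
  # overall R^2, fixed effects included in the fit
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(coef = b, se = se, df = df, r2 = r2, dropped = dropped,
       n = length(y), n_districts = G)
}

#' Estimate yield-nitrogen elasticities from household data
#'
#' Fits, separately for each season x crop cell, the inverse-hyperbolic-sine
#' Cobb-Douglas yield regression
#' \deqn{\mathrm{asinh}(y_h) = \rho\,\mathrm{asinh}(Urea_h) +
#'   b_1\,\mathrm{asinh}(Labor_h) + b_2\,Hybrid_h + b_3\,HYV_h + D_i + \epsilon_h}
#' with district fixed effects absorbed by within-demeaning. A regressor that
#' is perfectly collinear after demeaning (e.g. the HYV share when every
#' plot in a cell is either hybrid or HYV) is dropped with a warning and
#' reported in the `dropped` column.
#'
#' @param hh Household sample: columns `district_id`, `season`, `crop`,
#'   `yield`, `urea`, `labor`, `hybrid_share`, `hyv_share`.
#' @return Object of class `nitroplan_yield`: a `coefficients` tibble
#'   (`season`, `crop`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`), a `cells` tibble (`season`, `crop`, `r.squared`, `n`,
#'   `n_districts`, `dropped`), and the elasticity table `rho` (`season`,
#'   `crop`, `rho`).
#' @export
estimate_elasticities <- function(hh) {
  req <- c("district_id", "season", "crop", "yield", "urea", "labor",
           "hybrid_share", "hyv_share")
  missing_cols <- setdiff(req, names(hh))
  if (length(missing_cols)) {
    stop_input("household sample is missing columns: %s",
               paste(missing_cols, collapse = ", "))
  }
  cells <- hh |> dplyr::distinct(.data$season, .data$crop) |>
    dplyr::arrange(factor(.data$season, levels = season_levels()), .data$crop)
  fits <- purrr::pmap(cells, function(season, crop) {
    d <- hh |> dplyr::filter(.data$season == !!season, .data$crop == !!crop)
    counts <- table(d$district_id)
    keep_dist <- names(counts)[counts >= 2]
    if (length(keep_dist) == 0) {
      stop_input("no district with >= 2 households in cell %s/%s", season, crop)
    }
    d <- d[as.character(d$district_id) %in% keep_dist, ]
    X <- cbind(urea = ihs(d$urea), labor = ihs(d$labor),
               hybrid = d$hybrid_share, hyv = d$hyv_share)
    fit <- fe_ols(ihs(d$yield), X, d$district_id)
    if (length(fit$dropped)) {
      rlang::warn(sprintf(
        "cell %s/%s: dropped collinear regressor(s) %s",
        season, crop, paste(fit$dropped, collapse = ", ")))
    }
    if ("urea" %not in% names(fit$coef)) {
      stop_input("cell %s/%s: urea regressor dropped, elasticity not identified",
                 season, crop)
    }
    stat <- fit$coef / fit$se
    list(
      coefficients = tibble::tibble(
        season = season, crop = crop, term = names(fit$coef),
        estimate = as.numeric(fit$coef), std.error = fit$se,
        statistic = as.numeric(stat),
        p.value = 2 * pt(abs(stat), df = fit$df, lower.tail = FALSE)),
      cell = tibble::tibble(
        season = season, crop = crop, r.squared = fit$r2, n = fit$n,
        n_districts = fit$n_districts,
        dropped = paste(fit$dropped, collapse = ","))
    )
  })
  coefs <- purrr::list_rbind(purrr::map(fits, "coefficients"))
  cell_tab <- purrr::list_rbind(purrr::map(fits, "cell"))
  rho <- coefs |>
    dplyr::filter(.data$term == "urea") |>
    dplyr::select("season", "crop", rho = "estimate")
  structure(list(coefficients = coefs, cells = cell_tab, rho = rho),
            class = "nitroplan_yield")
}

#' @export
print.nitroplan_yield <- function(x, ...) {
  cat("<nitroplan_yield> yield-nitrogen elasticities by season x crop\n")
  print(x$rho, n = Inf)
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.nitroplan_yield <- function(x, ...) x$coefficients

#' @rdname glance
#' @export
glance.nitroplan_yield <- function(x, ...) x$cells

#' Calibrate district productivities
#'
#' Inverts the Cobb-Douglas yield function at the baseline: given the
#' estimated elasticity \eqn{\hat\rho_{rj}} and baseline nitrogen rate and
#' yield, the total-factor-productivity coefficient is
#' \eqn{\hat\delta_{irj} = y^b_{irj} / (N^b_{irj})^{\hat\rho_{rj}}}, so the
#' calibrated function reproduces the baseline yield exactly in every cell.
#'
#' @param panel District panel (see [generate_district_panel()]).
#' @param rho Elasticity table (`season`, `crop`, `rho`), e.g. the `rho`
#'   element of [estimate_elasticities()].
#' @return The panel with columns `rho` and `delta` appended.
#' @export
calibrate_delta <- function(panel, rho) {
  validate_panel(panel)
  out <- panel |>
    dplyr::left_join(rho, by = c("season", "crop"))
  if (any(is.na(out$rho))) {
    stop_input("no elasticity supplied for some season x crop cells")
  }
  bad <- out$n_base == 0 & out$yield_b > 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop_input("cannot calibrate district %s %s/%s: zero baseline nitrogen with positive yield",
               out$district_id[i], out$season[i], out$crop[i])
  }
  out |> dplyr::mutate(delta = .data$yield_b / .data$n_base^.data$rho)
}

#' Cobb-Douglas yield at a nitrogen rate
#'
#' \eqn{y(N) = \delta N^{\rho}}; zero at \eqn{N = 0} for \eqn{\rho > 0}.
#'
#' @param delta Productivity coefficient(s).
#' @param rho Elasticity(ies) in \[0, 1).
#' @param n Nitrogen rate(s), kg/acre; must be non-negative.
#' @return Yield(s), kg/acre.
#' @export
yield_at <- function(delta, rho, n) {
  if (any(n < 0)) stop_input("nitrogen rates must be non-negative")
  delta * n^rho
}

#' Baseline nitrogen cost table
#'
#' The baseline average nitrogen cost per unit of output is
#' \eqn{c^b_{irj} = p^N_{ir} N^b_{irj} / y^b_{irj}}.
#'
#' @param panel District panel (requires `p_n`, `n_base`, `yield_b`).
#' @return Tibble: `district_id`, `season`, `crop`, `p_n`, `n_base`, `c_b`.
#' @export
cost_baseline <- function(panel) {
  validate_panel(panel)
  panel |>
    dplyr::transmute(.data$district_id, .data$season, .data$crop, .data$p_n,
                     .data$n_base,
                     c_b = .data$p_n * .data$n_base / .data$yield_b)
}

#' Change in average nitrogen cost per unit output
#'
#' \eqn{\Delta c(N) = p^N N / y(N) - c^b}: zero at the baseline rate and,
#' for \eqn{\rho < 1}, strictly increasing in \eqn{N} (diminishing returns
#' make each marginal kilogram of nitrogen buy less output).
#'
#' @param cost Cost baseline rows (needs `p_n` and `c_b`), e.g. from
#'   [cost_baseline()].
#' @param delta,rho Calibrated productivity and elasticity.
#' @param n Nitrogen rate(s), kg/acre; must be positive.
#' @return \eqn{\Delta c} per row.
#' @export
cost_change <- function(cost, delta, rho, n) {
  if (any(n <= 0)) stop_input("`cost_change` requires positive nitrogen rates")
  y <- yield_at(delta, rho, n)
  if (any(y <= 0)) stop_input("yield is zero at the supplied nitrogen rate")
  cost$p_n * n / y - cost$c_b
}
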