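#' Convert log-odds (vs idle) to a share triple
#'
#' The land-use share system is logistic with idle land as the residual
#' category: given log-odds \eqn{u_j = \ln(s_j/s_0)} for rice (j = 1) and
#' non-rice (j = 2),
#' \deqn{s_j = \exp(u_j) / (1 + \exp(u_1) + \exp(u_2)),}
#' and the idle share is the remainder. Evaluation is overflow-safe: the
#' largest predictor is factored out before exponentiation, so arbitrarily
#' large log-odds saturate cleanly at a degenerate share vector.
#'
#' @param u1,u2 Numeric vectors of log-odds of rice and non-rice against
#'   idle. Recycled to a common length.
#' @return A tibble with columns `s_idle`, `s_rice`, `s_nonrice`; each row is
#'   a probability vector (non-negative, sums to one).
#' @export
#' @examples
#' shares_from_logodds(0, 0)                # (1/3, 1/3, 1/3)
#' shares_from_logodds(log(2.5), log(1.5))  # (0.2, 0.5, 0.3)
shares_from_logodds <- function(u1, u2) {
  n <- max(length(u1), length(u2))
  u1 <- rep_len(as.numeric(u1), n)
  u2 <- rep_len(as.numeric(u2), n)
  if (any(!is.finite(u1)) || any(!is.finite(u2))) {
    stop_input("log-odds must be finite")
  }
  m <- pmax(0, u1, u2)
  e0 <- exp(-m)
  e1 <- exp(u1 - m)
  e2 <- exp(u2 - m)
  denom <- e0 + e1 + e2
  tibble::tibble(s_idle = e0 / denom, s_rice = e1 / denom, s_nonrice = e2 / denom)
}

#' Stack a share dataset into the log-odds regression table
#'
#' Linearizes the logistic share system by taking, for each season and each
#' crop \eqn{j \in \{rice, nonrice\}}, the log of the odds of crop \eqn{j}
#' against idle. The response is \eqn{\ln(s_{rj}/s_{r0})} and the regressors
#' are the difference in initial (lagged) share \eqn{s^0_{rj} - s^0_{r0}},
#' the own net-price change, and the covariate changes (road density,
#' planting-period precipitation). The result is the stacked table the SUR
#' estimator consumes: one equation block per season x crop.
#'
#' Rows with a zero crop or idle share cannot be logged; they are floored at
#' `epsilon` and the triple renormalized before the transform. The number of
#' floored rows is reported via a message and stored in the
#' `"n_floored"` attribute.
#'
#' @param data Share dataset in long form: columns `district_id`, `season`,
#'   `use` (`"idle"`, `"rice"`, `"nonrice"`), `share`, `lag_share`, `dprice`
#'   (0 for idle), `droad`, `dprecip`.
#' @param epsilon Floor applied to zero shares before the log-odds
#'   (default 1e-4).
#' @return A tibble with one row per district x season x crop: columns
#'   `district_id`, `season`, `crop`, `logodds`, `d_lag_share`, `dprice`,
#'   `droad`, `dprecip`.
#' @export
logodds_transform <- function(data, epsilon = 1e-4) {
  req <- c("district_id", "season", "use", "share", "lag_share",
           "dprice", "droad", "dprecip")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop_input("share dataset is missing columns: %s",
               paste(missing_cols, collapse = ", "))
  }
  wide <- data |>
    dplyr::select(dplyr::all_of(req)) |>
    tidyr::pivot_wider(names_from = "use",
                       values_from = c("share", "lag_share", "dprice"))
  need <- c("share_idle", "share_rice", "share_nonrice",
            "lag_share_idle", "lag_share_rice", "lag_share_nonrice")
  if (!all(need %in% names(wide))) {
    stop_input("share dataset must contain uses idle, rice and nonrice for every district x season")
  }

  floor_renorm <- function(s0, s1, s2) {
    m <- cbind(s0, s1, s2)
    floored <- m < epsilon
    m[floored] <- epsilon
    m / rowSums(m)
  }
  cur <- floor_renorm(wide$share_idle, wide$share_rice, wide$share_nonrice)
  n_floored <- sum(rowSums(cbind(wide$share_idle, wide$share_rice,
                                 wide$share_nonrice) < epsilon) > 0)
  if (n_floored > 0) {
    rlang::inform(sprintf(
      "logodds_transform: floored %d district x season rows with shares below %.2g",
      n_floored, epsilon))
  }

  base <- tibble::tibble(
    district_id = wide$district_id,
    season = wide$season,
    s_idle = as.numeric(cur[, 1]),
    s_rice = as.numeric(cur[, 2]),
    s_nonrice = as.numeric(cur[, 3]),
    lag_idle = wide$lag_share_idle,
    lag_rice = wide$lag_share_rice,
    lag_nonrice = wide$lag_share_nonrice,
    dprice_rice = wide$dprice_rice,
    dprice_nonrice = wide$dprice_nonrice,
    droad = wide$droad,
    dprecip = wide$dprecip
  )
  out <- dplyr::bind_rows(
    base |> dplyr::transmute(
      district_id = .data$district_id, season = .data$season, crop = "rice",
      logodds = log(.data$s_rice / .data$s_idle),
      d_lag_share = .data$lag_rice - .data$lag_idle,
      dprice = .data$dprice_rice, droad = .data$droad, dprecip = .data$dprecip),
    base |> dplyr::transmute(
      district_id = .data$district_id, season = .data$season, crop = "nonrice",
      logodds = log(.data$s_nonrice / .data$s_idle),
      d_lag_share = .data$lag_nonrice - .data$lag_idle,
      dprice = .data$dprice_nonrice, droad = .data$droad, dprecip = .data$dprecip)
  ) |>
    dplyr::arrange(factor(.data$season, levels = season_levels()),
                   .data$crop, .data$district_id)
  degenerate <- out |>
    dplyr::group_by(.data$season, .data$crop) |>
    dplyr::summarise(all_bad = all(!is.finite(.data$logodds)), .groups = "drop")
  if (any(degenerate$all_bad)) {
    stop_input("all rows degenerate in equation(s): %s",
               paste(degenerate$season[degenerate$all_bad],
                     degenerate$crop[degenerate$all_bad],
                     sep = "/", collapse = ", "))
  }
  attr(out, "n_floored") <- n_floored
  out
}
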