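# Seemingly unrelated regression for the six-equation log-odds share system,
# with the inertia coefficient restricted to be equal across the two crop
# equations of a season.

sur_equations <- function() {
  tidyr::expand_grid(season = SEASONS, crop = c("nonrice", "rice")) |>
    dplyr::arrange(factor(.data$season, levels = season_levels()), .data$crop)
}

sur_param_table <- function() {
  dplyr::bind_rows(
    tibble::tibble(term = "inertia", season = SEASONS, crop = "both"),
    tidyr::expand_grid(term = c("dprice", "droad", "dprecip"),
                       season = SEASONS, crop = c("rice", "nonrice"))
  )
}

# Build the stacked design. Rows are ordered equation-major (all districts of
# equation 1 first), districts ascending within each equation.
sur_design <- function(trans) {
  eqs <- sur_equations()
  params <- sur_param_table()
  n_par <- nrow(params)
  blocks <- purrr::pmap(eqs, function(season, crop) {
    rows <- trans |>
      dplyr::filter(.data$season == !!season, .data$crop == !!crop) |>
      dplyr::arrange(.data$district_id)
    X <- matrix(0, nrow(rows), n_par)
    put <- function(term, crop_key, value) {
      j <- which(params$term == term & params$season == season &
                   params$crop == crop_key)
      X[, j] <<- value
    }
    put("inertia", "both", rows$d_lag_share)
    put("dprice", crop, rows$dprice)
    put("droad", crop, rows$droad)
    put("dprecip", crop, rows$dprecip)
    list(X = X, y = rows$logodds, district_id = rows$district_id)
  })
  ns <- vapply(blocks, function(b) length(b$y), integer(1))
  if (length(unique(ns)) != 1) {
    stop_input("equations have unequal numbers of districts (%s)",
               paste(ns, collapse = ", "))
  }
  ids <- lapply(blocks, `[[`, "district_id")
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop_input("district sets differ across equations")
  }
  list(X = do.call(rbind, lapply(blocks, `[[`, "X")),
       y = unlist(lapply(blocks, `[[`, "y")),
       n = ns[1], n_eq = nrow(eqs), params = params, equations = eqs)
}

#' Estimate the land-use share system by seemingly unrelated regression
#'
#' Transforms the share dataset to the stacked log-odds system (six
#' equations: three seasons x two crops, idle as the base category) and
#' estimates it by iterated feasible GLS. The cross-equation error
#' covariance is estimated from residuals with a residual
#' degrees-of-freedom correction and the GLS step is iterated until the
#' covariance converges. The inertia ("difference in initial share")
#' coefficient is restricted to be equal across the two crop equations
#' within a season. When the system is (numerically) noiseless the residual
#' covariance is degenerate and the estimator returns the exact
#' least-squares solution directly.
#'
#' @param data Share dataset in long form (see [logodds_transform()]).
#' @param epsilon Share floor forwarded to [logodds_transform()].
#' @param tol Convergence tolerance on the residual covariance (default
#'   1e-8, relative).
#' @param max_iter Maximum FGLS iterations (default 100).
#' @param sig_level Two-sided significance level for the coefficient flags
#'   (default 0.10).
#' @return An object of class `nitroplan_sur` with a `coefficients` tibble
#'   (`term`, `season`, `crop`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `significant`), the estimated error covariance `sigma`, the
#'   system weighted R-squared `r.squared`, iteration diagnostics, and the
#'   coefficient covariance `vcov`.
#' @export
estimate_sur <- function(data, epsilon = 1e-4, tol = 1e-8, max_iter = 100,
                         sig_level = 0.10) {
  trans <- logodds_transform(data, epsilon = epsilon)
  des <- sur_design(trans)
  X <- des$X
  y <- des$y
  n <- des$n
  n_eq <- des$n_eq
  k_eq <- 4L  # regressors per equation
  if (n < k_eq + 2L) {
    stop_input("need at least %d districts per equation, got %d", k_eq + 2L, n)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- des$params[qx$pivot[(qx$rank + 1):ncol(X)], ]
    stop_input("singular regressor matrix; deficient in equation(s): %s",
               paste(bad$season, bad$crop, bad$term, sep = "/", collapse = ", "))
  }

  ols <- qr.coef(qx, y)
  resid_mat <- function(b) matrix(y - X %*% b, n, n_eq)
  sigma_of <- function(E) crossprod(E) / (n - k_eq)

  b <- ols
  Sigma <- sigma_of(resid_mat(b))
  degenerate <- max(diag(Sigma)) < 1e-20
  iterations <- 0L
  converged <- TRUE
  if (!degenerate) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      iterations <- it
      C <- tryCatch(chol(solve(Sigma)), error = function(e) NULL)
      if (is.null(C)) {
        degenerate <- TRUE
        break
      }
      Xa <- array(X, c(n, n_eq, ncol(X)))
      Xs <- matrix(0, n * n_eq, ncol(X))
      Ct <- t(C)
      for (j in seq_len(ncol(X))) {
        Xs[, j] <- as.vector(Xa[, , j] %*% Ct)
      }
      ys <- as.vector(matrix(y, n, n_eq) %*% Ct)
      fit <- qr(Xs)
      b_new <- qr.coef(fit, ys)
      Sigma_new <- sigma_of(resid_mat(b_new))
      delta <- max(abs(Sigma_new - Sigma)) / max(1, max(abs(Sigma)))
      b <- b_new
      Sigma <- Sigma_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  }

  if (degenerate) {
    # (numerically) zero residual covariance: OLS is exact and GLS weights
    # are undefined; report least-squares coefficients.
    b <- ols
    Sigma <- sigma_of(resid_mat(b))
    XtXi <- solve(crossprod(X))
    s2 <- mean(diag(Sigma))
    vcov_b <- XtXi * s2
  } else {
    C <- chol(solve(Sigma))
    Xa <- array(X, c(n, n_eq, ncol(X)))
    Xs <- matrix(0, n * n_eq, ncol(X))
    Ct <- t(C)
    for (j in seq_len(ncol(X))) Xs[, j] <- as.vector(Xa[, , j] %*% Ct)
    vcov_b <- solve(crossprod(Xs))
  }

  se <- sqrt(pmax(diag(vcov_b), 0))
  df <- n * n_eq - ncol(X)
  statistic <- ifelse(se > 0, b / se, Inf * sign(b))
  p <- 2 * pt(abs(statistic), df = df, lower.tail = FALSE)

  # system weighted R-squared (weighted by the inverse error covariance,
  # totals centered per equation)
  E <- resid_mat(b)
  Y <- matrix(y, n, n_eq)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (degenerate) {
    r2 <- 1 - sum(E^2) / sum(Yc^2)
  } else {
    Ct <- t(chol(solve(Sigma)))
    r2 <- 1 - sum((E %*% Ct)^2) / sum((Yc %*% Ct)^2)
  }

  coefs <- des$params |>
    dplyr::mutate(estimate = as.numeric(b),
                  std.error = se,
                  statistic = as.numeric(statistic),
                  p.value = p,
                  significant = .data$p.value < sig_level) |>
    tibble::as_tibble()

  structure(
    list(coefficients = coefs, sigma = Sigma, vcov = vcov_b,
         r.squared = r2, n_districts = n, n_equations = n_eq,
         iterations = iterations, converged = converged,
         degenerate = degenerate, df.residual = df,
         sig_level = sig_level, epsilon = epsilon,
         n_floored = attr(trans, "n_floored") %||% 0L),
    class = "nitroplan_sur")
}

#' @export
print.nitroplan_sur <- function(x, ...) {
  cat(sprintf("<nitroplan_sur> %d districts, %d equations, system weighted R^2 = %.3f\n",
              x$n_districts, x$n_equations, x$r.squared))
  cat(sprintf("  FGLS iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Tidy a fitted share system
#'
#' @param x A `nitroplan_sur` object.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `season`, `crop`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `significant`).
#' @export
tidy.nitroplan_sur <- function(x, ...) x$coefficients

#' Glance at a fitted share system
#'
#' @param x A `nitroplan_sur` object.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `n.districts`, `n.equations`,
#'   `iterations`, `converged`.
#' @export
glance.nitroplan_sur <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, n.districts = x$n_districts,
                 n.equations = x$n_equations, iterations = x$iterations,
                 converged = x$converged)
}

#' Generic for broom-style tidying
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic for broom-style one-row model summaries
#' @param x Object to summarise.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")

sur_coef_value <- function(fit, term, season, crop) {
  co <- fit$coefficients
  i <- which(co$term == term & co$season == season & co$crop == crop)
  if (length(i) != 1) stop_input("coefficient %s/%s/%s not found", term, season, crop)
  co$estimate[i]
}

#' Predict share triples from a fitted share system
#'
#' Evaluates the estimated linear predictors (log-odds vs idle) on new
#' covariates and maps them through the overflow-safe logistic transform, so
#' predictions are always probability vectors.
#'
#' @param object A `nitroplan_sur` fit.
#' @param newdata Share dataset in the same long form used for estimation
#'   (the `share` column may be absent).
#' @param ... Unused.
#' @return Tibble: `district_id`, `season`, `s_idle`, `s_rice`, `s_nonrice`.
#' @export
predict_shares <- function(object, newdata, ...) {
  stopifnot(inherits(object, "nitroplan_sur"))
  req <- c("district_id", "season", "use", "lag_share", "dprice", "droad", "dprecip")
  missing_cols <- setdiff(req, names(newdata))
  if (length(missing_cols)) {
    stop_input("`newdata` is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  wide <- newdata |>
    dplyr::select(dplyr::all_of(req)) |>
    tidyr::pivot_wider(names_from = "use",
                       values_from = c("lag_share", "dprice"))
  u <- function(crop_key) {
    alpha <- vapply(wide$season, function(s) sur_coef_value(object, "inertia", s, "both"), 0)
    beta <- vapply(wide$season, function(s) sur_coef_value(object, "dprice", s, crop_key), 0)
    eroad <- vapply(wide$season, function(s) sur_coef_value(object, "droad", s, crop_key), 0)
    eprec <- vapply(wide$season, function(s) sur_coef_value(object, "dprecip", s, crop_key), 0)
    lag <- wide[[paste0("lag_share_", crop_key)]]
    dpr <- wide[[paste0("dprice_", crop_key)]]
    (lag - wide$lag_share_idle) * alpha + dpr * beta +
      wide$droad * eroad + wide$dprecip * eprec
  }
  shares <- shares_from_logodds(u("rice"), u("nonrice"))
  dplyr::bind_cols(wide |> dplyr::select("district_id", "season"), shares)
}

#' @export
predict.nitroplan_sur <- function(object, newdata, ...) {
  predict_shares(object, newdata, ...)
}

#' Analytic price marginal effects of the share system
#'
#' For the logistic share system the marginal effect of the season-\eqn{r}
#' net-price change of crop \eqn{k} on the share of crop \eqn{j}, evaluated
#' at the baseline shares of district \eqn{i}, is
#' \deqn{\partial s_{rj}/\partial x_{rk}\big|_i =
#'   s^b_{irj}\,(\mathbf{1}\{j = k\} - s^b_{irk})\,\hat\beta_{rk}.}
#' A price coefficient that is statistically insignificant at the fit's
#' significance level is replaced by zero when `zero_insignificant` is on.
#' The derived idle response (minus the sum over the two crops) is included,
#' so each (district, season, k) block of effects sums to zero.
#'
#' @param fit A `nitroplan_sur` fit.
#' @param baseline_shares Baseline shares in panel form: columns
#'   `district_id`, `season`, `crop` (`"rice"`/`"nonrice"`), `share_b`.
#' @param zero_insignificant Zero out insignificant price coefficients
#'   (default `TRUE`, as used by the integrated optimization).
#' @return Tibble: `district_id`, `season`, `crop` (the responding share,
#'   including `"idle"`), `wrt` (the price that moves), `effect`.
#' @export
marginal_effects <- function(fit, baseline_shares, zero_insignificant = TRUE) {
  stopifnot(inherits(fit, "nitroplan_sur"))
  req <- c("district_id", "season", "crop", "share_b")
  missing_cols <- setdiff(req, names(baseline_shares))
  if (length(missing_cols)) {
    stop_input("`baseline_shares` is missing columns: %s",
               paste(missing_cols, collapse = ", "))
  }
  wide <- baseline_shares |>
    dplyr::select(dplyr::all_of(req)) |>
    tidyr::pivot_wider(names_from = "crop", values_from = "share_b")
  for (crop_col in c("rice", "nonrice")) {
    if (!crop_col %in% names(wide)) wide[[crop_col]] <- 0
  }
  co <- fit$coefficients |> dplyr::filter(.data$term == "dprice")
  beta_of <- function(season, crop_key) {
    i <- which(co$season == season & co$crop == crop_key)
    est <- co$estimate[i]
    if (zero_insignificant && !co$significant[i]) est <- 0
    est
  }
  grid <- tidyr::expand_grid(row = seq_len(nrow(wide)),
                             crop = c("rice", "nonrice"),
                             wrt = c("rice", "nonrice"))
  s_of <- function(rows, crop_key) {
    ifelse(crop_key == "rice", wide$rice[rows], wide$nonrice[rows])
  }
  beta_k <- unname(mapply(beta_of, wide$season[grid$row], grid$wrt))
  s_j <- s_of(grid$row, grid$crop)
  s_k <- s_of(grid$row, grid$wrt)
  eff <- as.numeric(s_j * ((grid$crop == grid$wrt) - s_k) * beta_k)
  out <- tibble::tibble(
    district_id = wide$district_id[grid$row],
    season = wide$season[grid$row],
    crop = grid$crop, wrt = grid$wrt, effect = eff)
  idle <- out |>
    dplyr::group_by(.data$district_id, .data$season, .data$wrt) |>
    dplyr::summarise(effect = -sum(.data$effect), .groups = "drop") |>
    dplyr::mutate(crop = "idle", .after = "season")
  dplyr::bind_rows(out, idle) |>
    dplyr::arrange(.data$district_id,
                   factor(.data$season, levels = season_levels()),
                   factor(.data$crop, levels = crop_labels()), .data$wrt)
}
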