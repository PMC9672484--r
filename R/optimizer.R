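# Nonlinear programs minimizing national nitrogen export subject to revenue,
# food-security and cropland constraints. Three scenarios:
#   seasonal          - revenue maintained district by district
#   seasonal-spatial  - one national revenue constraint
#   integrated        - areas respond to price instruments via the estimated
#                       share system; decision variables are nitrogen rates
#                       and net-price changes
# All solves are multistart local optimizations from the (feasible) baseline
# plus seeded jitters; the best audit-feasible candidate is returned, so the
# reported objective never exceeds the baseline export.

#' Optimizer control settings
#'
#' @param n_min_frac Lower bound on nitrogen rates as a fraction of each
#'   cell's baseline rate (default 0.05; the Cobb-Douglas yield degenerates
#'   at zero nitrogen).
#' @param n_max Upper bound on nitrogen rates (kg/acre); default twice the
#'   largest baseline rate in the panel.
#' @param x_frac Bound on net-price changes as a fraction of each cell's
#'   baseline price (default 0.25, keeping the linearized area response in
#'   its validity range).
#' @param n_starts Multistart count, baseline start included (default 5).
#' @param jitter_sd Relative s.d. of the seeded multistart jitter.
#' @param maxeval Iteration cap for the local solver.
#' @param feas_tol Relative feasibility tolerance (default 1e-6).
#' @param seed Seed for the multistart jitter.
#' @return A list of class `nitroplan_control`.
#' @export
nitroplan_control <- function(n_min_frac = 0.05, n_max = NULL, x_frac = 0.25,
                              n_starts = 5L, jitter_sd = 0.10,
                              maxeval = 2000L, feas_tol = 1e-6, seed = 1L) {
  if (feas_tol <= 0) stop_config("`feas_tol` must be positive")
  structure(list(n_min_frac = n_min_frac, n_max = n_max, x_frac = x_frac,
                 n_starts = as.integer(n_starts), jitter_sd = jitter_sd,
                 maxeval = as.integer(maxeval), feas_tol = feas_tol,
                 seed = as.integer(seed)),
            class = "nitroplan_control")
}

#' Baseline national nitrogen export
#'
#' Evaluates the export objective at the baseline allocation:
#' \eqn{\sum_{i,r,j} \theta_{ir} N^b_{irj} (s^b_{irj} \bar L_i)} in kg.
#'
#' @param panel District panel.
#' @return Baseline export (kg).
#' @export
baseline_export <- function(panel) {
  validate_panel(panel)
  sum(panel$theta * panel$n_base * panel$share_b * panel$area)
}

# ---- shared problem geometry -----------------------------------------------

panel_geometry <- function(panel, rho_delta) {
  pan <- panel |>
    dplyr::arrange(.data$district_id,
                   factor(.data$season, levels = unique(.data$season)),
                   .data$crop)
  if (!all(c("rho", "delta") %in% names(pan))) {
    if (is.null(rho_delta)) {
      stop_input("panel must carry `rho` and `delta` columns (see calibrate_delta()), or pass `rho`")
    }
    pan <- calibrate_delta(pan, rho_delta)
  }
  base <- panel_baseline(pan)
  dist_ids <- sort(unique(pan$district_id))
  ds_key <- paste(pan$district_id, pan$season)
  ds_levels <- unique(ds_key)
  list(
    pan = pan,
    n_cell = nrow(pan),
    d_idx = match(pan$district_id, dist_ids),
    n_dist = length(dist_ids),
    dist_ids = dist_ids,
    ds_idx = match(ds_key, ds_levels),
    n_ds = length(ds_levels),
    rice = pan$crop == "rice",
    l_base = pan$share_b * pan$area,
    l_cap_cell = pan$cip * pan$area,             # seasonal potential area
    annual_cap = as.numeric(tapply(pan$ci * pan$area,
                                   match(pan$district_id, dist_ids),
                                   max)),        # CI_i * Lbar_i per district
    v_b_i = base$district$v_b[match(dist_ids, base$district$district_id)],
    v_b = base$v_b,
    y1_b = base$y1_b
  )
}

# aggregate cell values by group index (fast zonal sum)
gsum <- function(x, idx, n) {
  as.numeric(rowsum(x, idx, reorder = TRUE)[, 1][match(seq_len(n), sort(unique(idx)))])
}

# ---- N,L scenarios (seasonal / seasonal-spatial) ---------------------------

build_nl_problem <- function(geo, scenario, control, fix_land = FALSE) {
  pan <- geo$pan
  m <- geo$n_cell
  n_max <- control$n_max %||% (2 * max(pan$n_base))
  sN <- pan$n_base
  sL <- geo$l_cap_cell
  nu0 <- rep(1, m)
  lam0 <- geo$l_base / sL
  be <- sum(pan$theta * pan$n_base * geo$l_base)

  per_district_rev <- scenario == "seasonal"
  has_rice <- any(geo$rice) && geo$y1_b > 0
  n_var <- if (fix_land) m else 2L * m
  nu_of <- function(v) v[seq_len(m)]
  lam_of <- function(v) if (fix_land) lam0 else v[m + seq_len(m)]

  obj <- function(v) {
    sum(pan$theta * (nu_of(v) * sN) * (lam_of(v) * sL)) / be
  }
  obj_grad <- function(v) {
    gN <- pan$theta * sN * lam_of(v) * sL / be
    if (fix_land) gN else c(gN, pan$theta * sL * nu_of(v) * sN / be)
  }

  # constraint blocks (all written as g(v) <= 0, relative scaling)
  hin <- function(v) {
    N <- nu_of(v) * sN
    L <- lam_of(v) * sL
    y <- pan$delta * N^pan$rho
    rev_cell <- L * y * pan$price
    g_rev <- if (per_district_rev) {
      1 - gsum(rev_cell, geo$d_idx, geo$n_dist) / geo$v_b_i
    } else {
      1 - sum(rev_cell) / geo$v_b
    }
    g_rice <- if (has_rice) 1 - sum((L * y)[geo$rice]) / geo$y1_b else NULL
    g_land <- gsum(L, geo$ds_idx, geo$n_ds) /
      tapply(geo$l_cap_cell, geo$ds_idx, max) - 1
    g_annual <- gsum(L, geo$d_idx, geo$n_dist) / geo$annual_cap - 1
    c(g_rev, g_rice, as.numeric(g_land), as.numeric(g_annual))
  }

  n_rev <- if (per_district_rev) geo$n_dist else 1L
  n_rice <- if (has_rice) 1L else 0L
  n_con <- n_rev + n_rice + geo$n_ds + geo$n_dist
  # land rows are linear in the decisions: precompute them once
  J_const <- matrix(0, n_con, n_var)
  if (!fix_land) {
    caps_ds <- tapply(geo$l_cap_cell, geo$ds_idx, max)
    J_const[cbind(n_rev + n_rice + geo$ds_idx, m + seq_len(m))] <-
      sL / caps_ds[geo$ds_idx]
    J_const[cbind(n_rev + n_rice + geo$n_ds + geo$d_idx, m + seq_len(m))] <-
      sL / geo$annual_cap[geo$d_idx]
  }
  rev_row <- if (per_district_rev) geo$d_idx else rep(1L, m)
  rev_scale <- if (per_district_rev) geo$v_b_i[geo$d_idx] else rep(geo$v_b, m)

  hinjac <- function(v) {
    N <- nu_of(v) * sN
    L <- lam_of(v) * sL
    y <- pan$delta * N^pan$rho
    dy_dnu <- pan$delta * pan$rho * N^(pan$rho - 1) * sN
    J <- J_const
    J[cbind(rev_row, seq_len(m))] <- -L * dy_dnu * pan$price / rev_scale
    if (!fix_land) {
      J[cbind(rev_row, m + seq_len(m))] <- -sL * y * pan$price / rev_scale
    }
    if (has_rice) {
      r_rice <- n_rev + 1L
      J[r_rice, seq_len(m)] <- ifelse(geo$rice, -L * dy_dnu / geo$y1_b, 0)
      if (!fix_land) {
        J[r_rice, m + seq_len(m)] <- ifelse(geo$rice, -sL * y / geo$y1_b, 0)
      }
    }
    J
  }

  lower <- c(rep(control$n_min_frac, m),
             if (!fix_land) rep(0, m))
  upper <- c(n_max / sN, if (!fix_land) rep(1, m))
  x0 <- c(nu0, if (!fix_land) lam0)

  decode <- function(v) {
    tibble::tibble(
      district_id = pan$district_id, season = pan$season, crop = pan$crop,
      n_opt = nu_of(v) * sN, l_opt = lam_of(v) * sL)
  }
  list(obj = obj, obj_grad = obj_grad, hin = hin, hinjac = hinjac,
       lower = lower, upper = upper, x0 = x0, decode = decode,
       baseline_export = be, n_var = n_var)
}

# ---- integrated scenario ---------------------------------------------------

build_integrated_problem <- function(geo, me, cost, control) {
  pan <- geo$pan
  m <- geo$n_cell
  n_max <- control$n_max %||% (2 * max(pan$n_base))
  sN <- pan$n_base
  be <- sum(pan$theta * pan$n_base * geo$l_base)

  # price-change variables: one per district x season x crop, aligned with
  # the panel rows (x_ir1 on the rice row, x_ir2 on the non-rice row)
  x_idx_of <- function(district, season, crop) {
    match(paste(district, season, crop),
          paste(pan$district_id, pan$season, pan$crop))
  }
  me_crop <- me |> dplyr::filter(.data$crop %in% c("rice", "nonrice"))
  row_of_effect <- x_idx_of(me_crop$district_id, me_crop$season, me_crop$crop)
  col_of_effect <- x_idx_of(me_crop$district_id, me_crop$season, me_crop$wrt)
  # effects referencing crops the panel does not carry have no decision
  # variable to act on; drop them
  present <- !is.na(row_of_effect) & !is.na(col_of_effect)
  me_crop <- me_crop[present, ]
  row_of_effect <- row_of_effect[present]
  col_of_effect <- col_of_effect[present]
  covered <- unique(row_of_effect)
  if (length(setdiff(seq_len(m), covered)) == m) {
    # no panel cell has any effect row: allowed only if that is intentional
    # (all-zero response); an empty table is almost surely a join mistake
    if (nrow(me_crop) == 0) {
      stop_input("marginal-effects table does not align with the panel")
    }
  }
  # share response matrix: s(x) = share_b + S x  (dense m x m, 2 nonzeros/row)
  S <- matrix(0, m, m)
  S[cbind(row_of_effect, col_of_effect)] <- me_crop$effect
  A <- pan$area * S                       # L(x) = l_base + A x

  co <- cost
  key <- paste(pan$district_id, pan$season, pan$crop)
  co <- co[match(key, paste(co$district_id, co$season, co$crop)), ]
  if (any(is.na(co$c_b))) stop_input("cost baseline does not cover the panel")

  nu_of <- function(v) v[seq_len(m)]
  x_of <- function(v) v[m + seq_len(m)]
  L_of <- function(x) geo$l_base + as.numeric(A %*% x)
  s_of <- function(x) pan$share_b + as.numeric(S %*% x)

  obj <- function(v) {
    sum(pan$theta * (nu_of(v) * sN) * L_of(x_of(v))) / be
  }
  obj_grad <- function(v) {
    N <- nu_of(v) * sN
    c(pan$theta * sN * L_of(x_of(v)) / be,
      as.numeric(crossprod(A, pan$theta * N)) / be)
  }

  hin <- function(v) {
    N <- nu_of(v) * sN
    x <- x_of(v)
    L <- L_of(x)
    s <- s_of(x)
    y <- pan$delta * N^pan$rho
    # revenue with the new effective price p + x + dc(N)
    dc <- co$p_n * N / y - co$c_b
    rev <- sum(L * y * (pan$price + x + dc))
    s_cult <- gsum(s, geo$ds_idx, geo$n_ds)
    c(1 - rev / geo$v_b,
      1 - sum((L * y)[geo$rice]) / geo$y1_b,
      gsum(L, geo$ds_idx, geo$n_ds) / tapply(geo$l_cap_cell, geo$ds_idx, max) - 1,
      gsum(L, geo$d_idx, geo$n_dist) / geo$annual_cap - 1,
      -s,            # implied crop shares >= 0
      s - 1,         # implied crop shares <= 1
      s_cult - 1)    # implied idle share >= 0
  }

  # everything except the revenue and rice rows is linear: precompute
  n_con <- 2L + geo$n_ds + geo$n_dist + 2L * m + geo$n_ds
  J_const <- matrix(0, n_con, 2L * m)
  caps_ds <- as.numeric(tapply(geo$l_cap_cell, geo$ds_idx, max))
  agg_ds <- matrix(0, geo$n_ds, m); agg_ds[cbind(geo$ds_idx, seq_len(m))] <- 1
  agg_d <- matrix(0, geo$n_dist, m); agg_d[cbind(geo$d_idx, seq_len(m))] <- 1
  J_const[2L + seq_len(geo$n_ds), m + seq_len(m)] <- (agg_ds %*% A) / caps_ds
  J_const[2L + geo$n_ds + seq_len(geo$n_dist), m + seq_len(m)] <-
    (agg_d %*% A) / as.numeric(geo$annual_cap)
  r0 <- 2L + geo$n_ds + geo$n_dist
  J_const[r0 + seq_len(m), m + seq_len(m)] <- -S
  J_const[r0 + m + seq_len(m), m + seq_len(m)] <- S
  J_const[r0 + 2L * m + seq_len(geo$n_ds), m + seq_len(m)] <- agg_ds %*% S

  hinjac <- function(v) {
    N <- nu_of(v) * sN
    x <- x_of(v)
    L <- L_of(x)
    y <- pan$delta * N^pan$rho
    dy <- pan$delta * pan$rho * N^(pan$rho - 1)
    dc <- co$p_n * N / y - co$c_b
    peff <- pan$price + x + dc
    J <- J_const
    # rev = sum(L*y*(p + x) + L*(p_n*N - c_b*y))
    drev_dN <- L * ((pan$price + x - co$c_b) * dy + co$p_n)
    J[1, seq_len(m)] <- -drev_dN * sN / geo$v_b
    # d rev/dx_k: area response through A plus the direct price term
    drev_dx <- as.numeric(crossprod(A, y * peff)) + L * y
    J[1, m + seq_len(m)] <- -drev_dx / geo$v_b
    J[2, seq_len(m)] <- ifelse(geo$rice, -L * dy * sN / geo$y1_b, 0)
    J[2, m + seq_len(m)] <- -as.numeric(crossprod(A[geo$rice, , drop = FALSE],
                                                  y[geo$rice])) / geo$y1_b
    J
  }

  x_cap <- control$x_frac * pan$price
  lower <- c(rep(control$n_min_frac, m), -x_cap)
  upper <- c(n_max / sN, x_cap)
  x0 <- c(rep(1, m), rep(0, m))

  decode <- function(v) {
    x <- x_of(v)
    tibble::tibble(
      district_id = pan$district_id, season = pan$season, crop = pan$crop,
      n_opt = nu_of(v) * sN, l_opt = L_of(x), x_opt = x)
  }
  list(obj = obj, obj_grad = obj_grad, hin = hin, hinjac = hinjac,
       lower = lower, upper = upper, x0 = x0, decode = decode,
       baseline_export = be, n_var = 2L * m)
}

# ---- multistart driver -----------------------------------------------------

solve_multistart <- function(problem, control) {
  starts <- list(problem$x0)
  if (control$n_starts > 1) {
    with_local_seed(derive_seed(control$seed, 11L), {
      for (k in seq_len(control$n_starts - 1L)) {
        jit <- problem$x0 * (1 + rnorm(problem$n_var, 0, control$jitter_sd)) +
          ifelse(problem$x0 == 0,
                 rnorm(problem$n_var, 0, control$jitter_sd) *
                   (problem$upper - problem$lower) / 4, 0)
        starts[[k + 1L]] <- pmin(pmax(jit, problem$lower), problem$upper)
      }
    })
  }
  # engine by scale: sequential quadratic programming is precise but its
  # per-iteration cost grows cubically with the variable count, so large
  # panels use an augmented Lagrangian with an L-BFGS inner solver
  use_slsqp <- problem$n_var <= 60
  run_local <- function(x0) {
    if (use_slsqp) {
      nloptr::slsqp(x0, fn = problem$obj, gr = problem$obj_grad,
                    lower = problem$lower, upper = problem$upper,
                    hin = problem$hin, hinjac = problem$hinjac,
                    control = list(maxeval = control$maxeval,
                                   xtol_rel = 1e-10),
                    deprecatedBehavior = FALSE)
    } else {
      nloptr::auglag(x0, fn = problem$obj, gr = problem$obj_grad,
                     lower = problem$lower, upper = problem$upper,
                     hin = problem$hin, hinjac = problem$hinjac,
                     localsolver = "LBFGS",
                     control = list(maxeval = control$maxeval),
                     deprecatedBehavior = FALSE)
    }
  }
  candidates <- list()
  log <- list()
  for (k in seq_along(starts)) {
    res <- tryCatch(run_local(starts[[k]]), error = function(e) NULL)
    if (!is.null(res)) {
      candidates[[length(candidates) + 1L]] <-
        list(par = res$par, source = sprintf("solver-start-%d", k),
             convergence = res$convergence)
    }
    candidates[[length(candidates) + 1L]] <-
      list(par = starts[[k]], source = sprintf("start-%d", k), convergence = NA)
  }
  best <- NULL
  for (cand in candidates) {
    viol <- max(problem$hin(cand$par))
    # accept at half the audit tolerance so audited feasibility is clean
    feasible <- viol <= 0.5 * control$feas_tol
    f <- problem$obj(cand$par)
    log[[length(log) + 1L]] <- tibble::tibble(
      source = cand$source, objective_scaled = f, max_violation = viol,
      feasible = feasible)
    if (feasible && (is.null(best) || f < best$f)) {
      best <- list(par = cand$par, f = f, source = cand$source)
    }
  }
  if (is.null(best)) {
    stop_input("no feasible candidate found (baseline start infeasible?)")
  }
  list(best = best, log = purrr::list_rbind(log))
}

finish_solution <- function(scenario, problem, ms, panel, control,
                            me = NULL, cost = NULL) {
  decisions <- problem$decode(ms$best$par)
  sol <- structure(
    list(scenario = scenario,
         decisions = decisions,
         objective = ms$best$f * problem$baseline_export,
         baseline_export = problem$baseline_export,
         status = if (grepl("^solver", ms$best$source)) "optimal" else "incumbent",
         source = ms$best$source,
         multistart = ms$log,
         control = control),
    class = "nitroplan_solution")
  sol$audit <- audit_solution(panel, sol, me = me, cost = cost)
  sol
}

#' Seasonal optimization scenario
#'
#' Minimizes national nitrogen export over per-acre nitrogen rates and
#' harvested areas, holding every district's production revenue at or above
#' its baseline (revenue maintained district by district), keeping national
#' rice production at baseline, and respecting the seasonal and annual
#' cropland constraints.
#'
#' @param panel District panel carrying calibrated `rho` and `delta`
#'   columns (see [calibrate_delta()]), or pass `rho` to calibrate here.
#' @param rho Optional elasticity table forwarded to [calibrate_delta()].
#' @param control A [nitroplan_control()].
#' @param fix_land Hold harvested areas at their baseline values and
#'   optimize nitrogen rates only.
#' @return A `nitroplan_solution`: decision tibble, objective (kg of
#'   nitrogen exported), solver status, multistart log and feasibility audit.
#' @export
solve_seasonal <- function(panel, rho = NULL, control = nitroplan_control(),
                           fix_land = FALSE) {
  geo <- panel_geometry(panel, rho)
  problem <- build_nl_problem(geo, "seasonal", control, fix_land = fix_land)
  ms <- solve_multistart(problem, control)
  finish_solution("seasonal", problem, ms, geo$pan, control)
}

#' Seasonal-spatial optimization scenario
#'
#' As [solve_seasonal()], but the district revenue constraints are replaced
#' by a single national revenue constraint, allowing production to relocate
#' across districts. Its feasible set contains the seasonal scenario's, so
#' its optimum is never worse.
#'
#' @inheritParams solve_seasonal
#' @return A `nitroplan_solution`.
#' @export
solve_seasonal_spatial <- function(panel, rho = NULL,
                                   control = nitroplan_control(),
                                   fix_land = FALSE) {
  geo <- panel_geometry(panel, rho)
  problem <- build_nl_problem(geo, "seasonal-spatial", control,
                              fix_land = fix_land)
  ms <- solve_multistart(problem, control)
  finish_solution("seasonal-spatial", problem, ms, geo$pan, control)
}

#' Integrated (price-instrument) optimization scenario
#'
#' Replaces the area decision variables by the linearized response of the
#' share system to net-price changes: \eqn{L_{irj}(x) = \bar L_i (s^b_{irj}
#' + \sum_k \partial s_{rj}/\partial x_{rk}\, x_{irk})}. Decision variables
#' are nitrogen rates and the price changes; implied shares are kept inside
#' \[0, 1\] by explicit constraints, and the revenue constraint uses the
#' effective price \eqn{p + x + \Delta c(N)} with \eqn{\Delta c} the change
#' in average nitrogen cost per unit output.
#'
#' @inheritParams solve_seasonal
#' @param me Marginal-effects table from [marginal_effects()] (built with
#'   significance zeroing on).
#' @param cost Cost baseline from [cost_baseline()].
#' @return A `nitroplan_solution`; decisions include the optimal price
#'   changes `x_opt`.
#' @export
solve_integrated <- function(panel, me, cost, rho = NULL,
                             control = nitroplan_control()) {
  geo <- panel_geometry(panel, rho)
  problem <- build_integrated_problem(geo, me, cost, control)
  ms <- solve_multistart(problem, control)
  finish_solution("integrated", problem, ms, geo$pan, control,
                  me = me, cost = cost)
}

#' @export
print.nitroplan_solution <- function(x, ...) {
  cat(sprintf("<nitroplan_solution> scenario: %s (%s)\n", x$scenario, x$status))
  cat(sprintf("  nitrogen export: %.4g kg (baseline %.4g kg, %.1f%% reduction)\n",
              x$objective, x$baseline_export,
              100 * (1 - x$objective / x$baseline_export)))
  feas <- attr(x$audit, "feasible")
  cat(sprintf("  audit: %s; binding constraints: %d\n",
              if (isTRUE(feas)) "feasible" else "INFEASIBLE",
              sum(x$audit$binding)))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.nitroplan_solution <- function(x, ...) x$decisions

#' @rdname glance
#' @export
glance.nitroplan_solution <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, objective = x$objective,
                 baseline_export = x$baseline_export,
                 reduction_pct = 100 * (1 - x$objective / x$baseline_export),
                 status = x$status,
                 feasible = isTRUE(attr(x$audit, "feasible")),
                 n_binding = sum(x$audit$binding))
}
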