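# Independent feasibility audit: every constraint is re-evaluated from the
# raw decision values with plain split/loop arithmetic, deliberately not
# sharing code with the solver's vectorized constraint closures.

#' Audit a solution against the scenario's constraints
#'
#' Recomputes the objective and every constraint of the solution's scenario
#' from the decision table alone, reporting relative slacks and the binding
#' set. This is the source of truth for feasibility: the solver's own
#' convergence report is never trusted directly.
#'
#' @param panel District panel with `rho` and `delta` columns.
#' @param sol A `nitroplan_solution` (or a compatible list with elements
#'   `scenario`, `decisions`, `objective`).
#' @param me,cost Marginal effects and cost baseline; required for the
#'   integrated scenario.
#' @param tol Relative tolerance for feasibility and the binding flag
#'   (default 1e-6).
#' @return A tibble with columns `constraint`, `group`, `value`, `bound`,
#'   `sense`, `slack_rel`, `binding`; attributes `feasible` (all relative
#'   slacks above `-tol`) and `objective_recomputed`.
#' @export
audit_solution <- function(panel, sol, me = NULL, cost = NULL, tol = 1e-6) {
  validate_panel(panel)
  dec <- sol$decisions
  pan <- panel |>
    dplyr::inner_join(dec, by = c("district_id", "season", "crop"))
  if (nrow(pan) != nrow(panel)) {
    stop_input("decision table does not cover the panel")
  }
  base <- panel_baseline(panel)

  rows <- list()
  add <- function(constraint, group, value, bound, sense) {
    # relative slack; bounds of magnitude <= 1 (e.g. share bounds at 0 or 1)
    # are assessed on the unit scale
    scale <- max(abs(bound), 1)
    slack <- if (sense == ">=") (value - bound) / scale else (bound - value) / scale
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      constraint = constraint, group = as.character(group),
      value = value, bound = bound, sense = sense,
      slack_rel = slack, binding = abs(slack) < tol)
  }

  # objective, recomputed cell by cell
  obj <- 0
  for (i in seq_len(nrow(pan))) {
    obj <- obj + pan$theta[i] * pan$n_opt[i] * pan$l_opt[i]
  }

  yields <- pan$delta * pan$n_opt^pan$rho

  if (identical(sol$scenario, "integrated")) {
    if (is.null(me) || is.null(cost)) {
      stop_input("auditing the integrated scenario requires `me` and `cost`")
    }
    co <- cost[match(paste(pan$district_id, pan$season, pan$crop),
                     paste(cost$district_id, cost$season, cost$crop)), ]
    dc <- co$p_n * pan$n_opt / yields - co$c_b
    rev <- sum(pan$l_opt * yields * (pan$price + pan$x_opt + dc))
    add("revenue_national", "all", rev, base$v_b, ">=")
    # implied shares within [0, 1]
    s_impl <- pan$l_opt / pan$area
    for (i in seq_len(nrow(pan))) {
      add("share_lower", paste(pan$district_id[i], pan$season[i], pan$crop[i]),
          s_impl[i], 0, ">=")
      add("share_upper", paste(pan$district_id[i], pan$season[i], pan$crop[i]),
          s_impl[i], 1, "<=")
    }
    for (key in unique(paste(pan$district_id, pan$season))) {
      sel <- paste(pan$district_id, pan$season) == key
      add("share_cultivated", key, sum(s_impl[sel]), 1, "<=")
    }
  } else if (identical(sol$scenario, "seasonal")) {
    for (d in unique(pan$district_id)) {
      sel <- pan$district_id == d
      rev_d <- sum(pan$l_opt[sel] * yields[sel] * pan$price[sel])
      v_b_d <- base$district$v_b[base$district$district_id == d]
      add("revenue_district", d, rev_d, v_b_d, ">=")
    }
  } else {
    rev <- sum(pan$l_opt * yields * pan$price)
    add("revenue_national", "all", rev, base$v_b, ">=")
  }

  rice_sel <- pan$crop == "rice"
  if (any(rice_sel) && base$y1_b > 0) {
    add("rice_production", "all", sum(pan$l_opt[rice_sel] * yields[rice_sel]),
        base$y1_b, ">=")
  }

  for (key in unique(paste(pan$district_id, pan$season))) {
    sel <- paste(pan$district_id, pan$season) == key
    cap <- pan$cip[sel][1] * pan$area[sel][1]
    add("land_seasonal", key, sum(pan$l_opt[sel]), cap, "<=")
  }
  for (d in unique(pan$district_id)) {
    sel <- pan$district_id == d
    cap <- pan$ci[sel][1] * pan$area[sel][1]
    add("land_annual", d, sum(pan$l_opt[sel]), cap, "<=")
  }

  out <- purrr::list_rbind(rows)
  attr(out, "feasible") <- all(out$slack_rel >= -tol)
  attr(out, "objective_recomputed") <- obj
  attr(out, "objective_match") <-
    abs(obj - sol$objective) <= 1e-8 * max(1, abs(sol$objective))
  out
}
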