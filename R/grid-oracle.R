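#' Exhaustive grid-search oracle for tiny instances
#'
#' Verification oracle for the optimization scenarios on very small panels
#' (at most 2 districts x 2 seasons with free areas): enumerates a full
#' coarse grid over the decision variables, harvests several well-separated
#' elite candidates, and refines each by a pattern-refined grid search (the
#' incumbent's cross-product neighborhood is re-enumerated; the spacing is
#' kept while a pass improves and halved when it stalls, so refining the
#' grid never worsens the result).
#'
#' The search runs in two parameterizations of the area decision and keeps
#' the better result: plain harvested area \eqn{L} (cropland caps are then
#' box edges the grid hits exactly) and per-cell revenue
#' \eqn{u = L\,y(N)\,p} (the revenue and rice constraints are then sums of
#' coordinates, so the search can step along a binding revenue constraint
#' without leaving it). Feasibility and the objective are evaluated with
#' vectorized arithmetic written independently of the NLP solver's
#' constraint closures.
#'
#' @param panel Small district panel with `rho` and `delta` columns.
#' @param scenario `"seasonal"` or `"seasonal-spatial"`.
#' @param n_points Grid points per variable in the global pass (default 6).
#' @param n_seeds Elite candidates refined after the global pass (default 4).
#' @param n_refine Cap on refinement passes per seed (default 3000).
#' @param refine_points Grid points per variable per refinement pass
#'   (default 3: the incumbent's full cross-product neighborhood).
#' @param contraction Spacing shrink factor applied when a refinement pass
#'   fails to improve (default 0.5).
#' @param control A [nitroplan_control()] (supplies the nitrogen bounds).
#' @param fix_land Fix areas at baseline and enumerate nitrogen rates only.
#' @param chunk Maximum number of grid points evaluated at once.
#' @return A list: `objective` (kg), `decisions` tibble, `n_evaluated`.
#' @export
grid_oracle <- function(panel, scenario = c("seasonal", "seasonal-spatial"),
                        n_points = 6L, n_seeds = 4L, n_refine = 3000L,
                        refine_points = 3L, contraction = 0.5,
                        control = nitroplan_control(), fix_land = FALSE,
                        chunk = 2e5, verbose = FALSE) {
  scenario <- match.arg(scenario)
  validate_panel(panel)
  if (!all(c("rho", "delta") %in% names(panel))) {
    stop_input("panel must carry `rho` and `delta` columns")
  }
  pan <- panel |>
    dplyr::arrange(.data$district_id,
                   factor(.data$season, levels = unique(.data$season)),
                   .data$crop)
  m <- nrow(pan)
  if (m > 4 && !fix_land) {
    stop_input("grid oracle supports at most 4 cells with free areas, got %d", m)
  }
  base <- panel_baseline(pan)
  n_max <- control$n_max %||% (2 * max(pan$n_base))
  l_base <- pan$share_b * pan$area
  l_cap <- pan$cip * pan$area

  dist_ids <- sort(unique(pan$district_id))
  d_idx <- match(pan$district_id, dist_ids)
  ds_key <- paste(pan$district_id, pan$season)
  ds_levels <- unique(ds_key)
  ds_idx <- match(ds_key, ds_levels)
  ds_cap <- vapply(ds_levels, function(k) l_cap[ds_key == k][1], 0)
  annual_cap <- vapply(dist_ids, function(d) {
    (pan$ci * pan$area)[pan$district_id == d][1]
  }, 0)
  v_b_i <- base$district$v_b[match(dist_ids, base$district$district_id)]
  rice <- pan$crop == "rice"
  check_rice <- any(rice) && base$y1_b > 0

  n_var <- if (fix_land) m else 2L * m
  n_eval <- 0L

  # objective for a block of points; `mode` decides what columns m+1..2m
  # mean: "area" = L directly, "revenue" = u = L * y(N) * price
  make_evaluate <- function(mode) {
    function(P) {
      N <- P[, seq_len(m), drop = FALSE]
      Y <- exp(sweep(sweep(log(N), 2, pan$rho, `*`), 2, log(pan$delta), `+`))
      L <- if (fix_land) {
        matrix(l_base, nrow(P), m, byrow = TRUE)
      } else if (mode == "area") {
        P[, m + seq_len(m), drop = FALSE]
      } else {
        P[, m + seq_len(m), drop = FALSE] /
          (Y * matrix(pan$price, nrow(P), m, byrow = TRUE))
      }
      rev_cell <- L * Y * matrix(pan$price, nrow(P), m, byrow = TRUE)
      feasible <- rep(TRUE, nrow(P))
      if (scenario == "seasonal") {
        for (d in seq_along(dist_ids)) {
          feasible <- feasible &
            rowSums(rev_cell[, d_idx == d, drop = FALSE]) >= v_b_i[d] * (1 - 1e-9)
        }
      } else {
        feasible <- feasible & rowSums(rev_cell) >= base$v_b * (1 - 1e-9)
      }
      if (check_rice) {
        feasible <- feasible &
          rowSums((L * Y)[, rice, drop = FALSE]) >= base$y1_b * (1 - 1e-9)
      }
      for (s in seq_along(ds_levels)) {
        feasible <- feasible &
          rowSums(L[, ds_idx == s, drop = FALSE]) <= ds_cap[s] * (1 + 1e-9)
      }
      for (d in seq_along(dist_ids)) {
        feasible <- feasible &
          rowSums(L[, d_idx == d, drop = FALSE]) <= annual_cap[d] * (1 + 1e-9)
      }
      obj <- rowSums(sweep(N * L, 2, pan$theta, `*`))
      obj[!feasible] <- Inf
      obj
    }
  }

  run_mode <- function(mode) {
    evaluate <- make_evaluate(mode)
    # all area (or revenue) coordinates share one range so the grid spacing
    # is common across cells: equal-sum pair moves between cells then keep a
    # binding revenue or land-total constraint exactly
    u_hi <- max(l_cap * pan$delta * n_max^pan$rho * pan$price)
    lo <- c(control$n_min_frac * pan$n_base, if (!fix_land) rep(0, m))
    hi <- c(rep(n_max, m),
            if (!fix_land) rep(if (mode == "area") max(l_cap) else u_hi, m))

    sweep_box <- function(box_lo, box_hi, np, keep = 1L) {
      grids <- lapply(seq_len(n_var), function(j) {
        seq(box_lo[j], box_hi[j], length.out = np)
      })
      total <- np^n_var
      pool_obj <- numeric(0)
      pool_par <- NULL
      done <- 0
      while (done < total) {
        take <- min(chunk, total - done)
        idx <- done + seq_len(take)
        P <- matrix(0, take, n_var)
        rem <- idx - 1
        for (j in seq_len(n_var)) {
          P[, j] <- grids[[j]][rem %% np + 1]
          rem <- rem %/% np
        }
        obj <- evaluate(P)
        best_k <- utils::head(order(obj), keep)
        best_k <- best_k[is.finite(obj[best_k])]
        if (length(best_k)) {
          pool_obj <- c(pool_obj, obj[best_k])
          pool_par <- rbind(pool_par, P[best_k, , drop = FALSE])
        }
        done <- done + take
        n_eval <<- n_eval + take
      }
      list(obj = pool_obj, par = pool_par)
    }

    global <- sweep_box(lo, hi, n_points, keep = 8L)
    base_L <- l_base
    base_coord <- if (fix_land) pan$n_base else c(
      pan$n_base,
      if (mode == "area") base_L
      else base_L * pan$delta * pan$n_base^pan$rho * pan$price)
    seeds <- list(base_coord)
    if (length(global$obj)) {
      ord <- order(global$obj)
      sep <- 0.10 * (hi - lo)
      for (i in ord) {
        cand <- global$par[i, ]
        distinct <- all(vapply(seeds, function(s) any(abs(s - cand) > sep),
                               logical(1)))
        if (distinct || length(seeds) == 1L) {
          seeds[[length(seeds) + 1L]] <- cand
        }
        if (length(seeds) >= n_seeds + 1L) break
      }
    }

    best_par <- seeds[[1]]
    best_obj <- evaluate(matrix(best_par, 1))[1]
    half <- (refine_points - 1) / 2
    for (seed in seeds) {
      spacing <- (hi - lo) / (n_points - 1)
      cur <- seed
      cur_obj <- evaluate(matrix(cur, 1))[1]
      for (pass in seq_len(n_refine)) {
        box_lo <- pmax(lo, cur - half * spacing)
        box_hi <- pmin(hi, cur + half * spacing)
        res <- sweep_box(box_lo, box_hi, refine_points, keep = 1L)
        improved <- FALSE
        if (length(res$obj)) {
          k <- which.min(res$obj)
          if (res$obj[k] < cur_obj * (1 - 1e-12)) {
            step <- res$par[k, ] - cur
            cur <- res$par[k, ]
            cur_obj <- res$obj[k]
            improved <- TRUE
            # accelerate along the successful displacement
            repeat {
              trial <- pmin(pmax(cur + step, lo), hi)
              trial_obj <- evaluate(matrix(trial, 1))[1]
              n_eval <<- n_eval + 1L
              if (is.finite(trial_obj) && trial_obj < cur_obj * (1 - 1e-12)) {
                cur <- trial
                cur_obj <- trial_obj
              } else break
            }
          }
        }
        if (!improved) {
          spacing <- spacing * contraction
          if (max(spacing / pmax(hi - lo, 1e-300)) < 1e-6) break
        }
      }
      if (verbose) {
        rlang::inform(sprintf("mode %s seed -> objective %.6g", mode, cur_obj))
      }
      if (is.finite(cur_obj) && cur_obj < best_obj) {
        best_obj <- cur_obj
        best_par <- cur
      }
    }
    if (!is.finite(best_obj)) return(NULL)
    N_best <- best_par[seq_len(m)]
    L_best <- if (fix_land) {
      l_base
    } else if (mode == "area") {
      best_par[m + seq_len(m)]
    } else {
      best_par[m + seq_len(m)] /
        (pan$delta * N_best^pan$rho * pan$price)
    }
    list(objective = best_obj, n = N_best, l = L_best)
  }

  modes <- if (fix_land) "area" else c("area", "revenue")
  results <- purrr::compact(lapply(modes, run_mode))
  if (!length(results)) stop_input("no feasible grid point found")
  best <- results[[which.min(vapply(results, `[[`, 0, "objective"))]]
  decisions <- tibble::tibble(
    district_id = pan$district_id, season = pan$season, crop = pan$crop,
    n_opt = best$n, l_opt = best$l)
  list(objective = best$objective, decisions = decisions, n_evaluated = n_eval)
}
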