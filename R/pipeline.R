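# End-to-end orchestration of the three modelling steps, with a manifest for
# reproducibility. The land-use (share-system) fit runs only when the
# integrated scenario is requested; the other scenarios need only the
# delivery ratios and the calibrated yield function.

#' Workflow configuration
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_districts Districts in the synthetic country.
#' @param scenarios Character subset of `"seasonal"`, `"seasonal-spatial"`,
#'   `"integrated"`.
#' @param theta_source `"panel"` uses the synthetic panel's delivery ratios;
#'   `"ndr"` computes them from the toy rasters via two-run differencing and
#'   maps the raster district bands cyclically onto the panel districts;
#'   `"file"` reads a table supplied in `theta_path` (e.g. from an external
#'   watershed-model run).
#' @param theta_path Path of an external delivery-ratio table (CSV:
#'   `district_id`, `season`, `theta`), used when `theta_source = "file"`.
#' @param out_dir Output directory for artifacts and the manifest
#'   (created if missing); `NULL` for a temporary directory.
#' @param zero_insignificant Zero statistically insignificant price
#'   coefficients in the marginal effects (default `TRUE`).
#' @param control A [nitroplan_control()] for the optimization stage.
#' @param config_args Extra arguments forwarded to [synthetic_config()].
#' @return A list of class `nitroplan_run_config`.
#' @export
run_config <- function(seed = 1L, n_districts = 64L,
                       scenarios = c("seasonal", "seasonal-spatial"),
                       theta_source = c("panel", "ndr", "file"),
                       theta_path = NULL, out_dir = NULL,
                       zero_insignificant = TRUE,
                       control = nitroplan_control(seed = seed),
                       config_args = list()) {
  theta_source <- match.arg(theta_source)
  bad <- setdiff(scenarios, c("seasonal", "seasonal-spatial", "integrated"))
  if (length(bad)) stop_config("unknown scenario(s): %s", paste(bad, collapse = ", "))
  if (theta_source == "file" && is.null(theta_path)) {
    stop_config("`theta_path` is required when `theta_source = \"file\"`")
  }
  structure(list(seed = as.integer(seed), n_districts = as.integer(n_districts),
                 scenarios = scenarios, theta_source = theta_source,
                 theta_path = theta_path, out_dir = out_dir,
                 zero_insignificant = zero_insignificant,
                 control = control, config_args = config_args),
            class = "nitroplan_run_config")
}

#' Run the integrated workflow end to end
#'
#' Generates (or loads) all inputs, computes delivery ratios, calibrates the
#' yield function, fits the land-use share system when the integrated
#' scenario asks for it, solves the requested optimization scenarios, audits
#' every solution, and writes all artifacts plus a manifest recording the
#' configuration, seed and output checksums.
#'
#' @param config A [run_config()].
#' @return A list of class `nitroplan_run`: `panel`, `theta`, `yield_fit`,
#'   `sur_fit` (or `NULL`), `solutions` (named list), `comparison`,
#'   `manifest`, `out_dir`.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "nitroplan_run_config"))
  out_dir <- config$out_dir %||% tempfile("nitroplan_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name, t0) {
    stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      rlang::abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
                   class = "nitroplan_stage_error", parent = e)
    })
    tick(name, t0)
    res
  }

  cfg <- do.call(synthetic_config,
                 c(list(seed = config$seed, n_districts = config$n_districts),
                   config$config_args))

  panel <- run_stage("synthetic_panel", generate_district_panel(cfg))

  theta <- run_stage("delivery_ratios", {
    if (config$theta_source == "panel") {
      panel |> dplyr::distinct(.data$district_id, .data$season, .data$theta) |>
        dplyr::mutate(valid = TRUE)
    } else if (config$theta_source == "ndr") {
      rasters <- generate_toy_rasters(cfg)
      tt <- ndr_theta_table(rasters)
      bands <- max(tt$district_id)
      map <- tibble::tibble(
        district_id = seq_len(cfg$n_districts),
        band = (seq_len(cfg$n_districts) - 1L) %% bands + 1L)
      map |>
        dplyr::left_join(tt, by = c("band" = "district_id"),
                         relationship = "many-to-many") |>
        dplyr::select("district_id", "season", "theta", "valid")
    } else {
      read_theta_table(config$theta_path) |>
        dplyr::mutate(valid = TRUE)
    }
  })
  if (config$theta_source != "panel") {
    if (any(!theta$valid)) {
      stop_input("delivery-ratio table has undefined entries for districts: %s",
                 paste(unique(theta$district_id[!theta$valid]), collapse = ", "))
    }
    panel <- panel |>
      dplyr::select(-"theta") |>
      dplyr::left_join(theta |> dplyr::select("district_id", "season", "theta"),
                       by = c("district_id", "season"))
    class(panel) <- c("nitroplan_panel", class(panel))
  }

  hh <- run_stage("household_sample", generate_household_sample(cfg, panel))
  yfit <- run_stage("yield_fit", estimate_elasticities(hh))
  panel_cal <- run_stage("calibration", calibrate_delta(panel, yfit$rho))

  sfit <- NULL
  me <- NULL
  cost <- NULL
  if ("integrated" %in% config$scenarios) {
    shares <- run_stage("share_dataset", generate_share_dataset(cfg))
    sfit <- run_stage("landuse_fit", estimate_sur(shares))
    me <- marginal_effects(sfit, panel,
                           zero_insignificant = config$zero_insignificant)
    cost <- cost_baseline(panel)
  }

  solutions <- list()
  for (sc in config$scenarios) {
    solutions[[sc]] <- run_stage(paste0("optimize_", sc), {
      if (sc == "seasonal") {
        solve_seasonal(panel_cal, control = config$control)
      } else if (sc == "seasonal-spatial") {
        solve_seasonal_spatial(panel_cal, control = config$control)
      } else {
        solve_integrated(panel_cal, me, cost, control = config$control)
      }
    })
  }

  comparison <- compare_scenarios(solutions, panel_cal)

  # artifacts
  write_district_panel(panel_cal, file.path(out_dir, "panel.csv"))
  write_household_sample(hh, file.path(out_dir, "households.csv"))
  write_theta_table(theta, file.path(out_dir, "theta.csv"))
  write_table_csv(tidy(yfit), file.path(out_dir, "yield_coefficients.csv"))
  if (!is.null(sfit)) {
    write_table_csv(tidy(sfit), file.path(out_dir, "landuse_coefficients.csv"))
  }
  for (sc in names(solutions)) {
    write_solution(solutions[[sc]], file.path(out_dir, gsub("-", "_", sc)))
  }
  write_table_csv(comparison, file.path(out_dir, "comparison.csv"))

  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(
    list(seed = config$seed, n_districts = config$n_districts,
         scenarios = config$scenarios, theta_source = config$theta_source,
         zero_insignificant = config$zero_insignificant,
         control = unclass(config$control)),
    config_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("nitroplan")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(config_path)),
    stage_seconds = stages,
    outputs = lapply(setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(panel = panel_cal, theta = theta, yield_fit = yfit,
                 sur_fit = sfit, solutions = solutions,
                 comparison = comparison, manifest = manifest,
                 out_dir = out_dir),
            class = "nitroplan_run")
}

#' Compare optimization scenarios against the baseline
#'
#' @param solutions A list of `nitroplan_solution` objects (possibly empty;
#'   the baseline row is always included).
#' @param panel The panel the solutions were computed on.
#' @return A tibble with one row per scenario plus the baseline: `scenario`,
#'   `objective` (kg N exported), `reduction_pct`, `status`, `feasible`,
#'   `n_binding`. The attribute `"per_acre"` carries the district x season
#'   per-acre export table (`theta * N` averaged over harvested area),
#'   supporting seasonal comparisons of export intensity.
#' @export
compare_scenarios <- function(solutions, panel) {
  validate_panel(panel)
  be <- baseline_export(panel)
  rows <- list(tibble::tibble(
    scenario = "baseline", objective = be, baseline_export = be,
    reduction_pct = 0, status = "baseline", feasible = TRUE,
    n_binding = NA_integer_))
  per_acre <- list(
    panel |>
      dplyr::group_by(.data$district_id, .data$season) |>
      dplyr::summarise(
        export_per_acre = sum(.data$theta * .data$n_base * .data$share_b *
                                .data$area) /
          sum(.data$share_b * .data$area),
        .groups = "drop") |>
      dplyr::mutate(scenario = "baseline", .before = 1))
  for (sol in solutions) {
    if (!identical(sort(unique(sol$decisions$district_id)),
                   sort(unique(panel$district_id)))) {
      stop_input("solution and panel cover different districts")
    }
    rows[[length(rows) + 1L]] <- glance(sol)
    dec <- panel |>
      dplyr::inner_join(sol$decisions, by = c("district_id", "season", "crop"))
    per_acre[[length(per_acre) + 1L]] <- dec |>
      dplyr::group_by(.data$district_id, .data$season) |>
      dplyr::summarise(
        export_per_acre = sum(.data$theta * .data$n_opt * .data$l_opt) /
          pmax(sum(.data$l_opt), 1e-9),
        .groups = "drop") |>
      dplyr::mutate(scenario = sol$scenario, .before = 1)
  }
  out <- purrr::list_rbind(rows)
  attr(out, "per_acre") <- purrr::list_rbind(per_acre)
  out
}
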