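# Delimited-text readers/writers for the package's tabular artifacts.
# Everything is plain comma-separated UTF-8 with a header row.

write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

read_table_csv <- function(path, required) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop_input("%s is missing columns: %s", path,
               paste(missing_cols, collapse = ", "))
  }
  x
}

#' Read / write a district panel
#' @param panel A district panel tibble.
#' @param path File path (CSV with header).
#' @return The panel (readers) or `path` invisibly (writers).
#' @export
write_district_panel <- function(panel, path) {
  validate_panel(panel)
  write_table_csv(panel, path)
}

#' @rdname write_district_panel
#' @export
read_district_panel <- function(path) {
  x <- read_table_csv(path, c("district_id", "season", "crop", "share_b",
                              "area", "ci", "cip", "price", "p_n", "n_base",
                              "yield_b", "theta"))
  validate_panel(x)
  class(x) <- c("nitroplan_panel", class(x))
  x
}

#' Read / write a land-use share dataset
#' @param data Share dataset in long form.
#' @param path File path.
#' @return The dataset (reader) or `path` invisibly (writer).
#' @export
write_share_dataset <- function(data, path) write_table_csv(data, path)

#' @rdname write_share_dataset
#' @export
read_share_dataset <- function(path) {
  read_table_csv(path, c("district_id", "season", "use", "share", "lag_share",
                         "dprice", "droad", "dprecip"))
}

#' Read / write a household yield sample
#' @param hh Household sample tibble.
#' @param path File path.
#' @return The sample (reader) or `path` invisibly (writer).
#' @export
write_household_sample <- function(hh, path) write_table_csv(hh, path)

#' @rdname write_household_sample
#' @export
read_household_sample <- function(path) {
  read_table_csv(path, c("household_id", "district_id", "season", "crop",
                         "yield", "urea", "labor", "hybrid_share", "hyv_share"))
}

#' Read / write a delivery-ratio table
#' @param theta Tibble `district_id`, `season`, `theta`, `valid`.
#' @param path File path.
#' @return The table (reader) or `path` invisibly (writer).
#' @export
write_theta_table <- function(theta, path) write_table_csv(theta, path)

#' @rdname write_theta_table
#' @export
read_theta_table <- function(path) {
  read_table_csv(path, c("district_id", "season", "theta"))
}

#' Write a solution's decision table and run report
#'
#' @param sol A `nitroplan_solution`.
#' @param stem Output path stem; writes `<stem>_decisions.csv` and
#'   `<stem>_report.json`.
#' @return The stem, invisibly.
#' @export
write_solution <- function(sol, stem) {
  stopifnot(inherits(sol, "nitroplan_solution"))
  write_table_csv(sol$decisions, paste0(stem, "_decisions.csv"))
  report <- list(
    scenario = sol$scenario,
    objective_kg = sol$objective,
    baseline_export_kg = sol$baseline_export,
    reduction_pct = 100 * (1 - sol$objective / sol$baseline_export),
    status = sol$status,
    source = sol$source,
    feasible = isTRUE(attr(sol$audit, "feasible")),
    binding_constraints = sol$audit$constraint[sol$audit$binding],
    multistart = sol$multistart
  )
  jsonlite::write_json(report, paste0(stem, "_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}
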