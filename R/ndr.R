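# Nutrient-transport stage: D8 flow routing, downslope delivery ratios,
# district export aggregation, and two-run differencing for the
# fertilizer-attributable delivery ratio.

# neighbor scan order (fixed, also the tie-break order): E,SE,S,SW,W,NW,N,NE
D8_OFFSETS <- cbind(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
                    dc = c(1, 1, 0, -1, -1, -1, 0, 1))

#' Compute the D8 flow field of a DEM
#'
#' Each cell drains entirely to its lowest 8-neighbor (ties broken by a fixed
#' E, SE, S, SW, W, NW, N, NE scan order, so routing is deterministic). A
#' cell with no strictly lower neighbor is an outlet if it lies on the grid
#' boundary; an interior cell with no lower neighbor is a pit and raises an
#' error naming the pixel. Strict descent along every flow step makes the
#' field acyclic, and ordering cells by elevation gives a topological order.
#'
#' @param dem Numeric elevation matrix.
#' @return A list of class `nitroplan_flow`: `direction` (integer matrix,
#'   1-8 neighbor code, 0 for outlets), `downstream` (integer matrix of
#'   linear cell indices, `NA` at outlets), and `order` (integer vector of
#'   linear indices sorted downstream-first, i.e. by increasing elevation).
#' @export
compute_flow_field <- function(dem) {
  if (!is.matrix(dem) || !is.numeric(dem)) stop_input("`dem` must be a numeric matrix")
  nr <- nrow(dem)
  nc <- ncol(dem)
  best_elev <- matrix(Inf, nr, nc)
  best_dir <- matrix(0L, nr, nc)
  best_idx <- matrix(NA_integer_, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(8)) {
    r2 <- rows + D8_OFFSETS[k, "dr"]
    c2 <- cols + D8_OFFSETS[k, "dc"]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb_elev <- matrix(Inf, nr, nc)
    idx <- (c2 - 1L) * nr + r2
    nb_elev[ok] <- dem[idx[ok]]
    take <- nb_elev < best_elev  # strict: first neighbor wins ties in scan order
    best_dir[take] <- k
    best_idx[take] <- idx[take]
    best_elev[take] <- nb_elev[take]
  }
  flat <- best_elev >= dem  # no strictly lower neighbor
  best_dir[flat] <- 0L
  best_idx[flat] <- NA_integer_
  interior <- rows > 1 & rows < nr & cols > 1 & cols < nc
  pits <- which(flat & interior, arr.ind = TRUE)
  if (nrow(pits) > 0) {
    stop_input("interior pit at pixel (row %d, col %d): no lower neighbor",
               pits[1, 1], pits[1, 2])
  }
  structure(
    list(direction = best_dir, downstream = best_idx,
         order = order(dem)),  # increasing elevation = downstream first
    class = "nitroplan_flow")
}

#' Per-pixel delivery ratios along the flow field
#'
#' The delivery ratio of a pixel is the product, over the strictly
#' downstream pixels on its flow path up to (and excluding) the first stream
#' pixel, of one minus the retention efficiency of each traversed pixel.
#' Stream pixels deliver fully (ratio 1); the loading pixel's own retention
#' is not applied. Computed in a single pass over the topological order.
#'
#' @param flow A flow field from [compute_flow_field()].
#' @param retention Matrix of retention efficiencies in \[0, 1\].
#' @param streams 0/1 matrix marking stream pixels; every flow path must
#'   reach a stream.
#' @return Matrix of per-pixel delivery ratios in \[0, 1\].
#' @export
delivery_ratios <- function(flow, retention, streams) {
  stopifnot(inherits(flow, "nitroplan_flow"))
  if (any(retention < 0 | retention > 1, na.rm = TRUE)) {
    stop_input("retention efficiencies must lie in [0, 1]")
  }
  dims <- dim(flow$direction)
  if (!all(dim(retention) == dims) || !all(dim(streams) == dims)) {
    stop_input("retention/stream rasters must match the flow-field dimensions")
  }
  ratio <- matrix(NA_real_, dims[1], dims[2])
  is_stream <- streams != 0
  for (p in flow$order) {
    if (is_stream[p]) {
      ratio[p] <- 1
      next
    }
    d <- flow$downstream[p]
    if (is.na(d)) {
      rc <- arrayInd(p, dims)
      stop_input("flow path from pixel (row %d, col %d) does not reach a stream",
                 rc[1], rc[2])
    }
    ratio[p] <- if (is_stream[d]) 1 else (1 - retention[d]) * ratio[d]
  }
  ratio
}

#' Route a load raster and aggregate exports by district
#'
#' Pixel export is load times delivery ratio; district export and load are
#' zonal sums over the district raster.
#'
#' @param load Matrix of per-pixel nitrogen loads (kg); must be non-negative.
#' @param ratios Matrix of per-pixel delivery ratios from [delivery_ratios()].
#' @param districts Integer matrix of district ids.
#' @return A list of class `nitroplan_ndr_run`: matrices `load`, `ratio`,
#'   `export`, and a tibble `district` with columns `district_id`, `load`,
#'   `export`.
#' @export
run_ndr <- function(load, ratios, districts) {
  if (any(load < 0, na.rm = TRUE)) stop_input("nitrogen loads must be non-negative")
  if (!all(dim(load) == dim(ratios)) || !all(dim(load) == dim(districts))) {
    stop_input("load, ratio and district rasters must share dimensions")
  }
  export <- load * ratios
  district <- tibble::tibble(
    district_id = as.integer(names(tapply(load, districts, sum))),
    load = as.numeric(tapply(load, districts, sum)),
    export = as.numeric(tapply(export, districts, sum))
  )
  structure(list(load = load, ratio = ratios, export = export,
                 district = district),
            class = "nitroplan_ndr_run")
}

#' Fertilizer-attributable delivery ratio by two-run differencing
#'
#' Runs the transport model twice — once with fertilizer plus natural loads
#' and once with natural loads only — and takes, per district, the ratio of
#' the export difference to the load difference. Because pixel export is
#' linear in pixel load, the differencing exactly isolates the
#' fertilizer-attributable component, and the result is invariant to the
#' magnitude of the natural load. Districts with (numerically) zero
#' fertilizer load are flagged invalid rather than dropped.
#'
#' @param run_fert `nitroplan_ndr_run` with fertilizer + natural loads.
#' @param run_natural `nitroplan_ndr_run` with natural loads only, on the
#'   same flow field, retention and districts.
#' @return A tibble: `district_id`, `theta` (`NA` where undefined), `valid`.
#' @export
fertilizer_theta <- function(run_fert, run_natural) {
  stopifnot(inherits(run_fert, "nitroplan_ndr_run"),
            inherits(run_natural, "nitroplan_ndr_run"))
  if (!identical(run_fert$district$district_id,
                 run_natural$district$district_id)) {
    stop_input("the two runs cover different district sets")
  }
  if (any(run_natural$load > run_fert$load + 1e-12)) {
    stop_input("natural-only load exceeds total load on some pixels")
  }
  dl <- run_fert$district$load - run_natural$district$load
  de <- run_fert$district$export - run_natural$district$export
  scale <- pmax(run_fert$district$load, 1)
  valid <- dl > 1e-12 * scale
  theta <- ifelse(valid, de / dl, NA_real_)
  tibble::tibble(district_id = run_fert$district$district_id,
                 theta = theta, valid = valid)
}

#' Seasonal delivery-ratio table from a toy raster stack
#'
#' Convenience wrapper for the full stage: computes the flow field and
#' delivery ratios once (retention is not seasonal), then for every seasonal
#' fertilizer load raster performs the two-run differencing against the
#' natural-only background.
#'
#' @param rasters A raster stack from [generate_toy_rasters()] (or an
#'   equivalently named list).
#' @return A tibble: `district_id`, `season`, `theta`, `valid`.
#' @export
ndr_theta_table <- function(rasters) {
  flow <- compute_flow_field(rasters$dem)
  ratio <- delivery_ratios(flow, rasters$retention, rasters$streams)
  run_nat <- run_ndr(rasters$load_natural, ratio, rasters$districts)
  purrr::imap(rasters$load_fert, function(fert, season) {
    run_f <- run_ndr(fert + rasters$load_natural, ratio, rasters$districts)
    fertilizer_theta(run_f, run_nat) |>
      dplyr::mutate(season = season, .after = "district_id")
  }) |>
    purrr::list_rbind()
}
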