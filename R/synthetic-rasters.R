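#' Generate toy rasters for the nutrient-transport stage
#'
#' Builds a small, internally consistent raster stack: a DEM tilted toward
#' the east with bounded seeded roughness so that every cell keeps a strictly
#' lower eastern (and south-eastern) neighbor — no flats and no interior pits
#' by construction; a stream along the last (easternmost) column that
#' receives all drainage; a land-cover map (cropland / natural / water);
#' horizontal district bands; per-class retention efficiencies; a natural
#' background nitrogen load everywhere; and one fertilizer load raster per
#' season applied on cropland pixels only, with seasonal intensity
#' multipliers (winter > spring > summer, mirroring dry-season
#' fertilizer-intensive cropping).
#'
#' @param cfg A [synthetic_config()]; `grid_shape` must be at least 3x3.
#' @return A list of class `nitroplan_rasters`: matrices `dem`, `landcover`
#'   (1 cropland, 2 natural, 3 water), `districts`, `retention`, `streams`
#'   (0/1), `load_natural`, and `load_fert` — a named list of one fertilizer
#'   load matrix (kg per cell) per season.
#' @export
generate_toy_rasters <- function(cfg) {
  stopifnot(inherits(cfg, "nitroplan_config"))
  nr <- cfg$grid_shape[1]
  nc <- cfg$grid_shape[2]
  if (nr < 3 || nc < 3) stop_config("raster grid must be at least 3x3")
  with_local_seed(derive_seed(cfg$seed, 4L), {
    # Base tilt: 1 unit of drop per column step east, 2 per row step south is
    # not needed -- east-draining keeps the stream column the global low side.
    col_drop <- 1.0
    row_drop <- 0.35
    base <- outer((nr:1) * row_drop, (nc:1) * col_drop, `+`)
    # roughness bounded below half the smallest guaranteed drop keeps strict
    # descent to the E neighbor everywhere
    rough <- matrix(runif(nr * nc, -row_drop / 4, row_drop / 4), nr, nc)
    dem <- base + rough

    streams <- matrix(0L, nr, nc)
    streams[, nc] <- 1L

    landcover <- matrix(1L, nr, nc)
    natural_mask <- matrix(runif(nr * nc) < 0.2, nr, nc)
    landcover[natural_mask] <- 2L
    landcover[, nc] <- 3L

    bands <- cfg$n_raster_districts
    districts <- matrix(rep(ceiling(seq_len(nr) / nr * bands), nc), nr, nc)

    retention_by_class <- c(`1` = 0.25, `2` = 0.60, `3` = 0.0)
    retention <- matrix(retention_by_class[as.character(landcover)], nr, nc)

    load_natural <- matrix(runif(nr * nc, 0.5, 2), nr, nc)
    base_fert <- matrix(runif(nr * nc, 20, 60), nr, nc)
    base_fert[landcover != 1L] <- 0
    mult <- c(spring = 1.0, summer = 0.8, winter = 1.3)
    load_fert <- lapply(mult, function(k) base_fert * k)

    structure(
      list(dem = dem, landcover = landcover, districts = districts,
           retention = retention, streams = streams,
           load_natural = load_natural, load_fert = load_fert),
      class = "nitroplan_rasters")
  })
}
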