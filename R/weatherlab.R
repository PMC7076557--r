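# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generation never perturbs a user's
# random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic temperate climate
#'
#' Parameters of the seeded synthetic daily weather generator that
#' stands in for a gridded nowcasting product in tests and demos. The
#' defaults emulate a Slovenian lowland site: annual mean 10 degC,
#' seasonal amplitude 10 degC peaking in late July (day 205), a diurnal
#' range of 8 degC and day-to-day noise of 1.5 degC.
#'
#' @param annual_mean annual mean temperature, degC.
#' @param annual_amplitude half-range of the seasonal sinusoid, degC
#'   (`>= 0`).
#' @param phase_day day of year of the seasonal temperature peak.
#' @param diurnal_range mean daily max-min spread, degC (`>= 0`).
#' @param noise_sd standard deviation of the daily noise terms, degC
#'   (`>= 0`).
#' @param seed integer seed for the generator.
#' @param year calendar year the series covers.
#' @param latitude site latitude, degrees north.
#' @return A list of class `"climate_spec"`.
#' @export
climate_spec <- function(annual_mean = 10, annual_amplitude = 10,
                         phase_day = 205, diurnal_range = 8,
                         noise_sd = 1.5, seed = 1L, year = 2020L,
                         latitude = 46.05) {
  if (annual_amplitude < 0 || diurnal_range < 0 || noise_sd < 0)
    stop("amplitude, diurnal_range and noise_sd must be >= 0",
         call. = FALSE)
  structure(list(annual_mean = annual_mean,
                 annual_amplitude = annual_amplitude,
                 phase_day = phase_day, diurnal_range = diurnal_range,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 year = as.integer(year), latitude = latitude),
            class = "climate_spec")
}

#' Generate a synthetic daily weather series
#'
#' One calendar year (1 January to 31 December) of daily minimum, mean
#' and maximum air temperatures: the mean follows a seasonal sinusoid
#' plus Gaussian noise, and the minimum and maximum sit half the
#' diurnal range below/above the mean with additional one-sided
#' (absolute-valued) noise applied outward, so the ordering
#' `i_min <= i_mean <= i_max` holds by construction rather than by
#' clipping. Deterministic given the spec's seed; the caller's RNG
#' state is left untouched. The seed is recorded in the `"seed"`
#' attribute of the result for provenance.
#'
#' @param spec a [climate_spec()].
#' @return A validated weather series (see [weather_series()]) covering
#'   the spec's year.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "climate_spec"))
  dates <- seq(as.Date(paste0(spec$year, "-01-01")),
               as.Date(paste0(spec$year, "-12-31")), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  with_seed(spec$seed, {
    base <- spec$annual_mean + spec$annual_amplitude *
      cos(2 * pi * (doy - spec$phase_day) / 365)
    i_mean <- base + stats::rnorm(n, 0, spec$noise_sd)
    i_max <- i_mean + spec$diurnal_range / 2 +
      abs(stats::rnorm(n, 0, spec$noise_sd))
    i_min <- i_mean - spec$diurnal_range / 2 -
      abs(stats::rnorm(n, 0, spec$noise_sd))
    w <- weather_series(dates, i_min, i_mean, i_max)
    attr(w, "seed") <- spec$seed
    w
  })
}

#' Generate a synthetic gridded weather cube
#'
#' A stack of per-cell daily weather series on an `ny` x `nx`
#' geographic grid with a deterministic south-to-north temperature
#' gradient (`lapse` degC per cell, added to the annual mean; negative
#' values make the north colder) and an optional host-species mask
#' with a given fraction of non-host cells. Cell series are generated
#' from a single seeded stream in fixed row-major order, so the cube
#' is reproducible from the spec alone.
#'
#' @param spec a [climate_spec()]; its `latitude` is used as the
#'   latitude of the grid's southern edge.
#' @param nx,ny grid dimensions (columns, rows), `>= 1`.
#' @param lapse temperature change per cell going north, degC.
#' @param mask_fraction fraction of cells marked as non-host
#'   (default 0).
#' @param cellsize cell size in degrees (default 0.05).
#' @param origin_x longitude of the western edge (default 14.0).
#' @return A `"grid_cube"` object: list with `dates`, 3-D arrays
#'   `tmin`, `tmean`, `tmax` (day x row x col, row 1 = northernmost),
#'   logical `host_mask` (row x col, `TRUE` = host present),
#'   georeferencing (`origin_x`, `origin_y` southern edge, `cellsize`,
#'   `crs`) and `year`.
#' @export
generate_grid <- function(spec, nx, ny, lapse = -0.5,
                          mask_fraction = 0, cellsize = 0.05,
                          origin_x = 14.0) {
  stopifnot(inherits(spec, "climate_spec"), nx >= 1, ny >= 1,
            mask_fraction >= 0, mask_fraction <= 1)
  dates <- seq(as.Date(paste0(spec$year, "-01-01")),
               as.Date(paste0(spec$year, "-12-31")), by = "day")
  nt <- length(dates)
  tmin <- tmean <- tmax <- array(NA_real_, c(nt, ny, nx))
  with_seed(spec$seed, {
    for (r in seq_len(ny)) {
      # row 1 is the northernmost row: ny - r cells north of the
      # southern edge
      cells_north <- ny - r
      for (cc in seq_len(nx)) {
        sp <- spec
        sp$annual_mean <- spec$annual_mean + lapse * cells_north
        doy <- as.integer(format(dates, "%j"))
        base <- sp$annual_mean + sp$annual_amplitude *
          cos(2 * pi * (doy - sp$phase_day) / 365)
        i_mean <- base + stats::rnorm(nt, 0, sp$noise_sd)
        tmax[, r, cc] <- i_mean + sp$diurnal_range / 2 +
          abs(stats::rnorm(nt, 0, sp$noise_sd))
        tmin[, r, cc] <- i_mean - sp$diurnal_range / 2 -
          abs(stats::rnorm(nt, 0, sp$noise_sd))
        tmean[, r, cc] <- i_mean
      }
    }
    host <- matrix(stats::runif(ny * nx) >= mask_fraction, ny, nx)
    if (mask_fraction >= 1) host[] <- FALSE
    structure(list(dates = dates, tmin = tmin, tmean = tmean,
                   tmax = tmax, host_mask = host, origin_x = origin_x,
                   origin_y = spec$latitude, cellsize = cellsize,
                   crs = "EPSG:4326", year = spec$year,
                   seed = spec$seed),
              class = "grid_cube")
  })
}

#' Extract one cell of a grid cube as a weather series
#'
#' @param cube a `"grid_cube"`.
#' @param row,col cell indices (row 1 = northernmost).
#' @return A validated weather series for that cell.
#' @export
cell_series <- function(cube, row, col) {
  weather_series(cube$dates, cube$tmin[, row, col],
                 cube$tmean[, row, col], cube$tmax[, row, col])
}

#' Latitude of each grid row's cell centres
#'
#' Derived from the cube's georeferencing: the southern edge latitude
#' plus half-cell offsets; row 1 is the northernmost row. For a
#' projected CRS the geotransform does not carry latitude, so a
#' per-run override must be supplied instead.
#'
#' @param cube a `"grid_cube"`.
#' @param latitude_override single latitude used for every cell when
#'   the cube's CRS is projected (required in that case).
#' @return Numeric vector of length `ny`, row 1 first.
#' @export
cell_latitudes <- function(cube, latitude_override = NULL) {
  ny <- dim(cube$tmin)[2]
  if (!is.null(latitude_override)) return(rep(latitude_override, ny))
  if (!grepl("^EPSG:43", cube$crs))
    stop("cube CRS ", cube$crs, " is projected; supply ",
         "`latitude_override`", call. = FALSE)
  cube$origin_y + (rev(seq_len(ny)) - 0.5) * cube$cellsize
}
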