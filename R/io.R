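#' Read / write a daily weather series as CSV
#'
#' The weather CSV has columns `date` (ISO-8601), `i_min`, `i_mean`,
#' `i_max`. Reading validates the full series invariants and reports
#' the first violated one with its date or row number.
#'
#' @param path file path.
#' @return `read_weather_csv()`: a validated weather series.
#' @export
read_weather_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "i_min", "i_mean", "i_max")
  if (!all(need %in% names(raw)))
    stop(path, ": expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  d <- as.Date(raw$date)
  if (anyNA(d))
    stop(path, ": unparseable date at line ",
         which(is.na(d))[1] + 1L, call. = FALSE)
  weather_series(d, raw$i_min, raw$i_mean, raw$i_max)
}

#' @rdname read_weather_csv
#' @param w a weather series.
#' @return `write_weather_csv()`: `path`, invisibly.
#' @export
write_weather_csv <- function(w, path) {
  w <- validate_weather(w)
  utils::write.csv(data.frame(date = format(w$date), i_min = w$i_min,
                              i_mean = w$i_mean, i_max = w$i_max),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read onset observations from CSV
#'
#' Columns: `site`, `year`, `latitude`, `observed_swarming`,
#' `observed_infestation` (ISO dates; empty = not observed). Every row
#' must carry at least one observed date.
#'
#' @param path file path.
#' @return Data frame with `Date` observation columns.
#' @export
read_observations_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("site", "year", "latitude", "observed_swarming",
            "observed_infestation")
  if (!all(need %in% names(raw)))
    stop(path, ": expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  to_date <- function(x) as.Date(ifelse(nzchar(trimws(x)), x, NA))
  out <- data.frame(site = raw$site, year = as.integer(raw$year),
                    latitude = as.numeric(raw$latitude),
                    observed_swarming = to_date(raw$observed_swarming),
                    observed_infestation = to_date(raw$observed_infestation))
  bad <- which(is.na(out$observed_swarming) &
                 is.na(out$observed_infestation))
  if (length(bad))
    stop(path, ": row ", bad[1], " has no observed date", call. = FALSE)
  out
}

# Provenance header lines (commented) carrying the parameter set used.
params_header <- function(p) {
  c(sprintf("# swarm_dd=%g infest_dd=%g flight_t=%g daylength_gate=%g",
            p$swarm_dd, p$infest_dd, p$flight_t, p$daylength_gate),
    sprintf("# k_total=%g hibernation_min=%g start=%s end=%s",
            p$k_total, p$hibernation_min, p$start_date, p$end_date),
    sprintf("# dev: dt_l=%g t_o=%g dt_u=%g alpha=%g beta=%g gamma=%g t_max=%g",
            p$dev$dt_l, p$dev$t_o, p$dev$dt_u, p$dev$alpha, p$dev$beta,
            p$dev$gamma, p$dev$t_max_nl))
}

#' Write point-simulation results to CSV
#'
#' Two fixed-layout files: a per-brood summary (one row per scenario
#' and brood: onset date, final relative thermal sum, survival) and a
#' long-form daily table (`date`, `scenario`, `brood_id`, `tsum`,
#' `stage`). Both start with commented provenance lines recording the
#' full parameter set used, so a run can be reproduced from its
#' outputs.
#'
#' @param fit a `"rity"` object.
#' @param summary_path,daily_path output file paths (`NULL` = skip).
#' @return Invisibly, a list with the two paths.
#' @export
write_results_csv <- function(fit, summary_path = NULL,
                              daily_path = NULL) {
  p <- attr(fit, "params")
  hdr <- params_header(p)
  emit <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_path)) emit(summary.rity(fit), summary_path)
  if (!is.null(daily_path)) emit(as.data.frame(fit), daily_path)
  invisible(list(summary = summary_path, daily = daily_path))
}

#' Write / read a gridded weather cube as plain text
#'
#' The cube is serialised into a directory: `meta.txt` holds
#' `key=value` georeferencing and provenance (grid shape, origin, cell
#' size, CRS, year, seed), `mask.asc` the host mask as an ESRI ASCII
#' grid, and `temps.csv` the three daily fields in long form
#' (`date,row,col,tmin,tmean,tmax`). Reading validates shape and the
#' daily time axis and reconstructs an identical cube.
#'
#' @param cube a `"grid_cube"`.
#' @param dir directory to create/fill.
#' @return `write_grid()`: `dir` invisibly; `read_grid()`: the cube.
#' @export
write_grid <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(cube$tmin)
  meta <- c(nt = dm[1], ny = dm[2], nx = dm[3],
            origin_x = cube$origin_x, origin_y = cube$origin_y,
            cellsize = cube$cellsize, crs = cube$crs,
            year = cube$year,
            seed = if (is.null(cube$seed)) NA else cube$seed,
            start = format(cube$dates[1]))
  writeLines(paste0(names(meta), "=", meta), file.path(dir, "meta.txt"))
  write_raster(cube$host_mask * 1L, file.path(dir, "mask.asc"),
               origin_x = cube$origin_x, origin_y = cube$origin_y,
               cellsize = cube$cellsize, nodata = -1)
  idx <- expand.grid(row = seq_len(dm[2]), col = seq_len(dm[3]))
  long <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
    r <- idx$row[i]; cc <- idx$col[i]
    data.frame(date = format(cube$dates), row = r, col = cc,
               tmin = cube$tmin[, r, cc], tmean = cube$tmean[, r, cc],
               tmax = cube$tmax[, r, cc])
  }))
  utils::write.csv(long, file.path(dir, "temps.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_grid
#' @export
read_grid <- function(dir) {
  meta_lines <- readLines(file.path(dir, "meta.txt"))
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  nt <- as.integer(meta["nt"]); ny <- as.integer(meta["ny"])
  nx <- as.integer(meta["nx"])
  long <- utils::read.csv(file.path(dir, "temps.csv"),
                          stringsAsFactors = FALSE)
  dates <- sort(unique(as.Date(long$date)))
  if (length(dates) != nt || any(diff(as.integer(dates)) != 1))
    stop(dir, ": time axis is not daily and gap-free", call. = FALSE)
  shape <- function(v) {
    a <- array(NA_real_, c(nt, ny, nx))
    a[cbind(match(as.Date(long$date), dates), long$row, long$col)] <- v
    if (anyNA(a)) stop(dir, ": incomplete temperature cube", call. = FALSE)
    a
  }
  mask <- read_raster(file.path(dir, "mask.asc"))
  if (!all(dim(mask$values) == c(ny, nx)))
    stop(dir, ": mask shape ", paste(dim(mask$values), collapse = "x"),
         " does not match cube ", ny, "x", nx, call. = FALSE)
  if (abs(mask$origin_x - as.numeric(meta["origin_x"])) > 1e-9 ||
      abs(mask$origin_y - as.numeric(meta["origin_y"])) > 1e-9 ||
      abs(mask$cellsize - as.numeric(meta["cellsize"])) > 1e-9)
    stop(dir, ": mask georeferencing (", mask$origin_x, ",",
         mask$origin_y, ",", mask$cellsize, ") does not match cube (",
         meta["origin_x"], ",", meta["origin_y"], ",",
         meta["cellsize"], ")", call. = FALSE)
  structure(list(dates = dates, tmin = shape(long$tmin),
                 tmean = shape(long$tmean), tmax = shape(long$tmax),
                 host_mask = mask$values == 1,
                 origin_x = as.numeric(meta["origin_x"]),
                 origin_y = as.numeric(meta["origin_y"]),
                 cellsize = as.numeric(meta["cellsize"]),
                 crs = unname(meta["crs"]),
                 year = as.integer(meta["year"]),
                 seed = suppressWarnings(as.integer(meta["seed"]))),
            class = "grid_cube")
}

#' Write / read a single-band raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster: six header lines (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' rows of values, northernmost row first. `NA` cells are written as
#' the nodata sentinel.
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param path output path.
#' @param origin_x,origin_y lower-left corner coordinates.
#' @param cellsize cell size.
#' @param nodata nodata sentinel written for `NA` cells (default -1,
#'   declared in the header).
#' @return `write_raster()`: `path` invisibly; `read_raster()`: a list
#'   with `values` matrix (nodata as `NA`) and the georeferencing.
#' @export
write_raster <- function(values, path, origin_x = 0, origin_y = 0,
                         cellsize = 1, nodata = -1) {
  values <- as.matrix(values)
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
               paste("xllcorner", origin_x), paste("yllcorner", origin_y),
               paste("cellsize", cellsize), paste("NODATA_value", nodata)),
             con)
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- vapply(hdr, `[`, "", 2)
  h <- stats::setNames(vals, keys)
  nr <- as.integer(h["nrows"]); nc <- as.integer(h["ncols"])
  nodata <- as.numeric(h["nodata_value"])
  m <- do.call(rbind, lapply(lines[7:(6 + nr)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!all(dim(m) == c(nr, nc)))
    stop(path, ": raster body does not match header dims", call. = FALSE)
  m[m == nodata] <- NA
  list(values = m, origin_x = as.numeric(h["xllcorner"]),
       origin_y = as.numeric(h["yllcorner"]),
       cellsize = as.numeric(h["cellsize"]), nodata = nodata)
}
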