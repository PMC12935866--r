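# Trial and configuration file I/O.  Canonical trial format:
#   markers.csv : time_s, SACR_x, SACR_y, SACR_z, LASI_x, ... (mm)
#   grf.csv     : time_s, fz_N
#   meta.json   : units, rate, axis convention
# Axis convention: x = AP (+forward), y = ML (+left), z = VT (+up).

#' Write a trial to a directory in the canonical CSV format
#'
#' @param trial a `synthetic_trial` or list with `markers` and `vgrf`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mk <- trial$markers
  n <- nrow(mk$positions[[1]])
  time_s <- (seq_len(n) - 1) / mk$rate
  cols <- list(time_s = time_s)
  for (nm in names(mk$positions)) {
    m <- mk$positions[[nm]]
    cols[[paste0(nm, "_x")]] <- m[, 1]
    cols[[paste0(nm, "_y")]] <- m[, 2]
    cols[[paste0(nm, "_z")]] <- m[, 3]
  }
  utils::write.csv(as.data.frame(cols),
                   file.path(dir, "markers.csv"), row.names = FALSE)
  gr <- trial$vgrf
  utils::write.csv(data.frame(time_s = (seq_along(gr$fz) - 1) / gr$rate,
                              fz_N = gr$fz),
                   file.path(dir, "grf.csv"), row.names = FALSE)
  meta <- list(position_units = "mm", force_units = "N",
               marker_rate_hz = mk$rate, grf_rate_hz = gr$rate,
               axes = list(x = "AP (+forward)", y = "ML (+left)",
                           z = "VT (+up)"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a trial directory in the canonical CSV format
#'
#' Counterpart of [write_trial()]; see [ingest_external_trial()] for unit
#' auto-detection on third-party exports.
#'
#' @param dir trial directory containing `markers.csv` and `grf.csv`.
#' @param units `"auto"`, `"mm"` or `"m"`; `"auto"` reads `meta.json` when
#'   present and otherwise guesses from the coordinate magnitudes
#'   (pelvis-height positions expressed in meters are of order 1).
#' @return list with `markers` (a `marker_series`) and `vgrf`
#'   (a `force_signal`).
#' @export
read_trial <- function(dir, units = c("auto", "mm", "m")) {
  units <- match.arg(units)
  mfile <- file.path(dir, "markers.csv")
  gfile <- file.path(dir, "grf.csv")
  if (!file.exists(mfile)) stop("markers.csv not found in ", dir)
  if (!file.exists(gfile)) stop("grf.csv not found in ", dir)
  md <- utils::read.csv(mfile, check.names = FALSE)
  gd <- utils::read.csv(gfile, check.names = FALSE)
  if (!"time_s" %in% names(md) || !"time_s" %in% names(gd)) {
    stop("trial CSVs must contain a time_s column")
  }
  if (!"fz_N" %in% names(gd)) stop("grf.csv must contain an fz_N column")

  marker_names <- unique(sub("_[xyz]$", "", setdiff(names(md), "time_s")))
  missing <- setdiff(PELVIS_MARKERS, marker_names)
  if (length(missing) > 0) {
    stop(sprintf("missing pelvis marker(s): %s", paste(missing, collapse = ", ")))
  }
  rate <- 1 / stats::median(diff(md$time_s))
  positions <- lapply(marker_names, function(nm) {
    need <- paste0(nm, c("_x", "_y", "_z"))
    if (!all(need %in% names(md))) {
      stop(sprintf("marker %s is missing one of its x/y/z columns", nm))
    }
    as.matrix(md[, need])
  })
  names(positions) <- marker_names

  meta_units <- NULL
  mj <- file.path(dir, "meta.json")
  if (file.exists(mj)) {
    meta <- jsonlite::read_json(mj)
    meta_units <- meta$position_units
  }
  eff_units <- if (units != "auto") units
               else if (!is.null(meta_units)) meta_units
               else if (max(abs(vapply(positions, function(m) max(abs(m)),
                                       numeric(1)))) < 50) "m"
               else "mm"
  if (identical(eff_units, "m")) {
    positions <- lapply(positions, function(m) m * 1000)
  }
  grate <- 1 / stats::median(diff(gd$time_s))
  list(markers = marker_series(rate, positions),
       vgrf = force_signal(grate, gd$fz_N))
}

#' Ingest an external trial
#'
#' Validated ingest of a trial recorded outside the package, with unit
#' auto-detection (meters vs millimeters) and an explicit override.  Only
#' the canonical CSV layout is supported; `format = "c3d"` raises a
#' descriptive error.
#'
#' @param path trial directory.
#' @param format `"csv"` (supported) or `"c3d"` (not available).
#' @param units `"auto"`, `"mm"` or `"m"`.
#' @return list with `markers` and `vgrf`, as [read_trial()].
#' @export
ingest_external_trial <- function(path, format = c("csv", "c3d"),
                                  units = "auto") {
  format <- match.arg(format)
  if (format == "c3d") {
    stop("C3D ingest is not available in this installation; export the ",
         "trial to the canonical CSV layout (markers.csv + grf.csv)")
  }
  if (!dir.exists(path)) stop("trial directory not found: ", path)
  read_trial(path, units = units)
}

#' Write / read a run configuration (YAML)
#'
#' @param config a [gts_config()] list.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   validated [gts_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "gts_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(gts_config, x)
}
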