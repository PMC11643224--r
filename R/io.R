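# Serialization: trajectories to a directory of CSV/JSON files, flat
# key = value configuration files, radius datasets as CSV.

#' Write a trajectory to a directory
#'
#' Layout: `radius.csv` (time_days, radius), `series.csv` (per-step audit
#' scalars), `snapshot_XXXX.csv` (one row per node with the state and
#' derived fields), `metadata.json` (parameters, load, controls, solver
#' provenance). Numbers are written with full precision so the round trip
#' is lossless.
#'
#' @param traj a trajectory
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) format(x, digits = 17) else x)
    df
  }
  utils::write.csv(fmt(data.frame(time_days = traj$times, radius = traj$radii)),
                   file.path(dir, "radius.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(traj$series), file.path(dir, "series.csv"),
                   row.names = FALSE, quote = FALSE)
  for (i in seq_along(traj$snapshots)) {
    sn <- traj$snapshots[[i]]
    df <- sn$fields
    df$t <- sn$state$t
    df$R <- sn$state$R
    utils::write.csv(fmt(df),
                     file.path(dir, sprintf("snapshot_%04d.csv", i)),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(traj$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a trajectory directory
#'
#' Inverse of [write_trajectory()]; reconstructs the radius series, audit
#' series, snapshots (as [radial_state()] plus derived fields) and
#' metadata.
#'
#' @param dir directory written by [write_trajectory()]
#' @return a `trajectory` object
#' @export
read_trajectory <- function(dir) {
  rad <- utils::read.csv(file.path(dir, "radius.csv"))
  series <- utils::read.csv(file.path(dir, "series.csv"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  snaps <- list()
  files <- sort(list.files(dir, pattern = "^snapshot_\\d+\\.csv$",
                           full.names = TRUE))
  variant <- meta$variant
  for (f in files) {
    df <- utils::read.csv(f)
    st <- radial_state(
      N = nrow(df), R = df$R[1], fer = df$fer, fetheta = df$fetheta,
      c = df$c, p = if ("p" %in% names(df)) df$p else NULL, t = df$t[1]
    )
    fields <- df[, setdiff(names(df), c("t", "R")), drop = FALSE]
    snaps[[length(snaps) + 1]] <- list(state = st, fields = fields)
  }
  structure(
    list(times = rad$time_days, radii = rad$radius, snapshots = snaps,
         series = series, metadata = meta),
    class = "trajectory"
  )
}

#' Write a radius dataset as CSV
#' @param data a [radius_dataset()]
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_radius_dataset <- function(data, path) {
  df <- data.frame(time_days = format(data$times, digits = 17),
                   radius = format(data$radii, digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a radius dataset from CSV
#' @param path CSV with columns `time_days` and `radius`
#' @param provenance provenance tag
#' @return a [radius_dataset()]
#' @export
read_radius_dataset <- function(path, provenance = "user") {
  df <- utils::read.csv(path)
  if (!all(c("time_days", "radius") %in% names(df))) {
    stop("dataset must have columns time_days and radius")
  }
  radius_dataset(df$time_days, df$radius, provenance = provenance)
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers when possible, otherwise kept as strings. Known parameter
#' keys populate a [model_params()], `load_*` keys a [boundary_load()], and
#' solver keys the matching control list.
#'
#' @param path configuration file
#' @return list with `params`, `load`, `control_args`, `sim` (R0, t_max,
#'   variant) and `raw` (every parsed pair)
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  raw <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    raw[[key]] <- if (!is.na(num)) num else val
  }
  pk <- intersect(names(raw), c("K", "k", "eta", "gamma_c", "L", "beta"))
  params <- do.call(model_params, raw[pk])
  load_kind <- if (!is.null(raw$load_kind)) raw$load_kind else "free"
  load <- switch(load_kind,
    free = boundary_load("free"),
    gel = boundary_load("gel", cH = raw$load_cH, R0_gel = raw$load_R0_gel,
                        release_time = raw$load_release_time),
    pressure = boundary_load("pressure", Pext = raw$load_Pext),
    stop(sprintf("unknown load_kind '%s'", load_kind))
  )
  ck <- intersect(names(raw),
                  c("N", "dt", "tol", "max_iter", "beta_tilde", "eps_fb",
                    "snapshot_every"))
  sim <- list(
    R0 = if (!is.null(raw$R0)) raw$R0 else 100,
    t_max = if (!is.null(raw$t_max)) raw$t_max else 10,
    variant = if (!is.null(raw$variant)) raw$variant else "incompressible"
  )
  list(params = params, load = load, control_args = raw[ck], sim = sim,
       raw = raw)
}
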