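# File interchange: trajectory CSV + sidecar JSON, point-cloud TSV +
# cohort manifest JSON. Headers carry explicit unit suffixes (_s, _um, _pN)
# so a mis-united file fails loudly rather than silently.

#' Write / read a bead trajectory as CSV with a JSON sidecar
#'
#' The CSV has columns `time_s`, `x_um`, `force_pN`; the sidecar
#' (`<path>.json`) records `bead_radius_um` and any metadata.
#'
#' @param traj a [bead_trajectory()].
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a [bead_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "bead_trajectory"))
  utils::write.csv(data.frame(time_s = traj$times, x_um = traj$displacement,
                              force_pN = traj$force),
                   path, row.names = FALSE)
  side <- list(bead_radius_um = traj$bead_radius)
  if (!is.null(traj$meta$truth$omega))
    side$omega_rad_s <- traj$meta$truth$omega
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "x_um", "force_pN")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trajectory CSV missing column(s): ", paste(missing, collapse = ", "),
         " (unit-suffixed headers are required)")
  if (any(diff(df$time_s) <= 0))
    stop("column 'time_s' must be strictly increasing")
  sidecar <- paste0(path, ".json")
  radius <- 1.4
  meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$bead_radius_um)) radius <- side$bead_radius_um
    meta <- side
  }
  bead_trajectory(df$time_s, df$x_um, df$force_pN, radius, meta = meta)
}

#' Write / read nuclear-body clouds as TSV with a cohort manifest
#'
#' The TSV has columns `nucleus_id`, `x_um`, `y_um`, `z_um`, `radius_um`.
#' The manifest JSON maps each nucleus id to its condition
#' `{g_multiple, time_s}`.
#'
#' @param clouds named list of [nucleolus_cloud()] objects (names are
#'   nucleus ids).
#' @param path TSV file path.
#' @param manifest_path manifest JSON path (default `<path>.manifest.json`).
#' @return `write_cloud` returns `path` invisibly; `read_cloud` returns a
#'   named list of clouds with `meta$g_multiple` / `meta$time_s` attached
#'   (frames are `"raw"`; frame provenance is not serialized).
#' @export
write_cloud <- function(clouds, path,
                        manifest_path = paste0(path, ".manifest.json")) {
  if (inherits(clouds, "nucleolus_cloud")) clouds <- list(nucleus_1 = clouds)
  if (is.null(names(clouds)) || any(names(clouds) == ""))
    stop("'clouds' must be a named list (names are nucleus ids)")
  rows <- Map(function(id, cl) {
    data.frame(nucleus_id = id, x_um = cl$positions[, 1],
               y_um = cl$positions[, 2], z_um = cl$positions[, 3],
               radius_um = cl$radii)
  }, names(clouds), clouds)
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- lapply(clouds, function(cl)
    list(g_multiple = cl$meta$g_multiple %||% 1,
         time_s = cl$meta$time_s %||% 0))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_cloud
#' @export
read_cloud <- function(path, manifest_path = paste0(path, ".manifest.json")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("nucleus_id", "x_um", "y_um", "z_um", "radius_um")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cloud TSV missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$radius_um <= 0)) stop("negative or zero radius in cloud TSV")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  ids <- unique(df$nucleus_id)
  unknown <- setdiff(ids, names(manifest))
  if (length(manifest) && length(unknown))
    stop("nucleus id(s) absent from manifest: ",
         paste(unknown, collapse = ", "))
  out <- lapply(ids, function(id) {
    sub <- df[df$nucleus_id == id, ]
    meta <- list()
    if (length(manifest)) {
      meta$g_multiple <- manifest[[id]]$g_multiple
      meta$time_s <- manifest[[id]]$time_s
    }
    nucleolus_cloud(as.matrix(sub[, c("x_um", "y_um", "z_um")]),
                    sub$radius_um, frame = "raw", meta = meta)
  })
  names(out) <- ids
  out
}
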