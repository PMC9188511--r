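# Container formats: k-space container (validated native serialization),
# schedule CSV, YAML run configuration, NIfTI image series with JSON
# sidecar, ground-truth JSON. Every artifact embeds the configuration hash
# and seed so identical configurations reproduce identical outputs.

.kspace_fields <- c("samples", "coords", "schedule", "noise_covariance",
                    "params", "meta")

#' Hash of a configuration object
#'
#' MD5 of the canonical serialization, used to stamp outputs for
#' reproducibility bookkeeping.
#' @param x any serializable object.
#' @return hex string.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Write / read the k-space container
#'
#' Losslessly persists a `kspace_data` object (samples, coordinates,
#' schedule, noise covariance, sequence parameters, metadata). The container
#' is R's native serialization with a format tag and per-dataset validation
#' on read; missing datasets produce a descriptive error.
#'
#' @param data a `kspace_data`.
#' @param path file path (conventionally `.kspace.rds`).
#' @return `write_kspace` returns `path` invisibly; `read_kspace` the
#'   restored `kspace_data`.
#' @export
write_kspace <- function(data, path) {
  stopifnot(inherits(data, "kspace_data"))
  payload <- unclass(data)
  payload$format <- "starstack-kspace"
  payload$format_version <- 1L
  payload$config_hash <- config_hash(list(data$params, data$meta))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("unreadable k-space container: ",
                                               conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "starstack-kspace")) {
    stop("not a starstack k-space container: ", path)
  }
  missing <- setdiff(.kspace_fields, names(payload))
  if (length(missing)) {
    stop("k-space container is missing dataset(s): ",
         paste(missing, collapse = ", "))
  }
  structure(payload[.kspace_fields], class = "kspace_data")
}

#' Write / read a spoke schedule as CSV
#'
#' Columns `global_index, star_index, kz_index, azimuth_deg, time_s`;
#' pattern metadata is stored in `#`-prefixed header lines so the round trip
#' restores a complete `spoke_schedule`.
#'
#' @param schedule a `spoke_schedule`.
#' @param path CSV file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "spoke_schedule"))
  sq <- attr(schedule, "sequence")
  hdr <- c(
    sprintf("# pattern=%s", attr(schedule, "pattern")),
    sprintf("# n_kz=%d", attr(schedule, "n_kz")),
    sprintf("# tiny_angle_order=%d", attr(schedule, "tiny_angle_order")),
    sprintf("# tr=%.10g te=%.10g flip_angle=%.10g", sq$tr, sq$te, sq$flip_angle),
    sprintf("# n_readout=%d matrix=%d n_slices=%d oversampling_factor=%.10g",
            sq$n_readout, sq$matrix, sq$n_slices, sq$oversampling_factor),
    sprintf("# voxel_size=%s", paste(sq$voxel_size, collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(schedule), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    sub(paste0(key, "="), "", m[m != ""][1])
  }
  df <- read.csv(text = paste(lines[!startsWith(lines, "#")], collapse = "\n"))
  sq <- sequence_params(tr = as.numeric(kv("tr")), te = as.numeric(kv("te")),
                        flip_angle = as.numeric(kv("flip_angle")),
                        n_readout = as.integer(kv("n_readout")),
                        matrix = as.integer(kv("matrix")),
                        n_slices = as.integer(kv("n_slices")),
                        oversampling_factor = as.numeric(kv("oversampling_factor")),
                        voxel_size = as.numeric(strsplit(kv("voxel_size"), ",")[[1]]))
  structure(df, class = c("spoke_schedule", "data.frame"),
            pattern = kv("pattern"), n_kz = as.integer(kv("n_kz")),
            tiny_angle_order = as.integer(kv("tiny_angle_order")),
            sequence = sq)
}

#' Write / read a run configuration as YAML
#'
#' @param config named list (typically trajectory/recon/phantom sections plus
#'   seeds and output paths).
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Write an image series as 4D NIfTI with a JSON sidecar
#'
#' Magnitude frames are written in NIfTI (x, y, z, t) order with the voxel
#' geometry in `pixdim` and the frame period as the time step; frame rate,
#' configuration hash and provenance go to `<path>.json`.
#'
#' @param series an `image_series`.
#' @param path output path (e.g. `series.nii.gz`).
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  arr <- aperm(Mod(series$frames), c(4, 3, 2, 1))  # (x,y,z,t)
  dt <- if (is.finite(series$frame_rate)) 1 / series$frame_rate else 1
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$voxel_size, dt)
  RNifti::writeNifti(img, path)
  sidecar <- list(frame_rate_fps = series$frame_rate,
                  frame_times_s = series$frame_times,
                  voxel_size_mm = series$voxel_size,
                  config_hash = config_hash(series$provenance))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write phantom ground truth as JSON
#'
#' Stores the analytic tracks, motion state and programmed parameters (not
#' the voxel masks, which are reproducible from the generator seed).
#'
#' @param scene a `phantom_scene`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(scene, path) {
  stopifnot(inherits(scene, "phantom_scene"))
  gt <- scene$ground_truth
  keep <- setdiff(names(gt), "bolus_masks")
  out <- gt[keep]
  out$seed <- scene$seed
  out$frame_times <- scene$frame_times
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
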