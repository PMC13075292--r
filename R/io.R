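#' Write a scan trace to delimited text
#'
#' The trace dialect is a CSV with two numeric columns (`t_s`, `signal`)
#' preceded by a commented metadata header of `# key: value` lines carrying
#' the scan kinematics (`scan_speed_mm_s`, `scan_start_clock_min`,
#' `x_start_mm`, `sample_rate_hz`) and units.
#'
#' @param trace A [scan_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_trace <- function(trace, path) {
  stopifnot(inherits(trace, "scan_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(scan_speed_mm_s = trace$scan_speed,
            scan_start_clock_min = trace$scan_start_clock,
            x_start_mm = trace$x_start,
            sample_rate_hz = trace$sample_rate)
  writeLines(c(sprintf("# %s: %.15g", names(meta), meta),
               "# units: t_s seconds, signal arbitrary (conductivity scale)",
               "t_s,signal"), con)
  writeLines(sprintf("%.15g,%.15g", trace$t, trace$signal), con)
  invisible(path)
}

#' Read a scan trace written by [write_scan_trace()]
#'
#' @param path File path.
#' @return A [scan_trace()].
#' @export
read_scan_trace <- function(path) {
  if (!file.exists(path)) .stop_io(sprintf("no such trace file: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", hdr))
  meta <- list()
  for (m in kv) if (length(m) == 3) meta[[m[2]]] <- m[3]
  need <- c("scan_speed_mm_s", "scan_start_clock_min", "x_start_mm")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    .stop_io(sprintf("trace %s lacks metadata: %s", path,
                     paste(miss, collapse = ", ")))
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("t_s", "signal") %in% names(dat)))
    .stop_io(sprintf("trace %s lacks t_s/signal columns", path))
  scan_trace(dat$t_s, dat$signal,
             scan_speed = as.numeric(meta$scan_speed_mm_s),
             scan_start_clock = as.numeric(meta$scan_start_clock_min),
             x_start = as.numeric(meta$x_start_mm),
             sample_rate = if (is.null(meta$sample_rate_hz)) NULL
                           else as.numeric(meta$sample_rate_hz))
}

#' Write boundary fixes to CSV
#'
#' Columns: `clock_min`, `t_boundary_s`, `x_boundary_mm`, `method`,
#' `quality`, `valid`.
#'
#' @param fixes A `boundary_fixes` data frame (the attached `all_fixes`
#'   attribute, including invalid scans, is written when present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  all <- attr(fixes, "all_fixes")
  if (is.null(all)) all <- as.data.frame(fixes)
  utils::write.csv(all, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth of a synthetic experiment to CSV
#'
#' @param truth Data frame with columns `conc_mM`, `clock_min`, `true_x_mm`,
#'   `true_U`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration table
#'
#' CSV with columns `conc_mM`, `v_mrb` and optional `replicate`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path)) .stop_io(sprintf("no such calibration table: %s", path))
  tab <- utils::read.csv(path, comment.char = "#")
  if (!all(c("conc_mM", "v_mrb") %in% names(tab)))
    .stop_io("calibration table needs columns conc_mM and v_mrb")
  tab
}

#' Save or load a calibration model document
#'
#' The model is stored as a small YAML document holding the slope, intercept,
#' R^2, concentration range, LOD and the conventions used, so a saved
#' calibration can be reused for prediction.
#'
#' @param model An `"mrb_calibration"`.
#' @param path File path.
#' @return `write_calibration_model()` returns `path` invisibly;
#'   `read_calibration_model()` returns the `"mrb_calibration"`.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "mrb_calibration"))
  doc <- list(model = "v_mrb = slope_a * log10(conc_mM) + intercept_b",
              slope_a_mm_min_per_decade = model$slope_a,
              intercept_b_mm_min = model$intercept_b,
              r2 = model$r2,
              conc_range_mM = as.numeric(model$conc_range),
              lod_mM = if (is.na(model$lod)) NULL else model$lod,
              lod_convention = "10^(((v_blank + k*blank_sd) - b)/a)",
              n_points = nrow(model$data),
              data = list(conc_mM = model$data$conc_mM,
                          v_mrb = model$data$v_mrb))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  if (!file.exists(path)) .stop_io(sprintf("no such model file: %s", path))
  doc <- yaml::read_yaml(path)
  need <- c("slope_a_mm_min_per_decade", "intercept_b_mm_min", "conc_range_mM")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    .stop_io(sprintf("model file %s lacks field(s): %s", path,
                     paste(miss, collapse = ", ")))
  dat <- if (!is.null(doc$data))
    data.frame(conc_mM = unlist(doc$data$conc_mM),
               v_mrb = unlist(doc$data$v_mrb))
  else data.frame(conc_mM = numeric(0), v_mrb = numeric(0))
  structure(list(slope_a = doc$slope_a_mm_min_per_decade,
                 intercept_b = doc$intercept_b_mm_min,
                 r2 = if (is.null(doc$r2)) NA_real_ else doc$r2,
                 conc_range = as.numeric(unlist(doc$conc_range_mM)),
                 lod = if (is.null(doc$lod_mM)) NA_real_ else doc$lod_mM,
                 data = dat),
            class = "mrb_calibration")
}

#' Read an experiment configuration from YAML
#'
#' The YAML file may set any argument of [experiment_config()] except
#' `channel` and `window`, which are described by the sub-maps `channel:`
#' (`length`, `width`, `depth`) and `window:` (`shape`, `actuator_width`,
#' `pickup_width`, `gap`). Unknown fields raise a configuration error naming
#' the field.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's `seed` field.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path, seed = NULL) {
  if (!file.exists(path)) .stop_io(sprintf("no such config file: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) .stop_config(
                    sprintf("cannot parse config %s: %s", path, conditionMessage(e))))
  if (!is.list(raw)) .stop_config(sprintf("config %s is not a mapping", path))
  known <- setdiff(names(formals(experiment_config)), c("channel", "window"))
  bad <- setdiff(names(raw), c(known, "channel", "window"))
  if (length(bad))
    .stop_config(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$velocity_law)) {
    vl <- unlist(args$velocity_law)
    if (!all(c("a", "b") %in% names(vl)))
      .stop_config("config field velocity_law must have keys a and b")
    args$velocity_law <- vl[c("a", "b")]
  }
  if (!is.null(args$concentrations)) args$concentrations <- unlist(args$concentrations)
  if (!is.null(args$drift_coeffs)) args$drift_coeffs <- unlist(args$drift_coeffs)
  if (!is.null(raw$channel)) args$channel <- do.call(channel_geometry, raw$channel)
  if (!is.null(raw$window)) args$window <- do.call(electrode_window, raw$window)
  if (!is.null(seed)) args$seed <- seed
  do.call(experiment_config, args)
}

#' Write a run manifest
#'
#' Every CLI run writes one JSON manifest recording the command, the input
#' configuration (path and md5), the seed, output paths, the package version
#' and a timestamp, so that runs can be audited and reproduced.
#'
#' @param command Command name.
#' @param out_dir Directory receiving the manifest (`manifest.json`).
#' @param seed Seed used (or `NA`).
#' @param inputs,outputs Character vectors of paths.
#' @param config_path Optional configuration file to fingerprint.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(command, out_dir, seed = NA, inputs = character(0),
                           outputs = character(0), config_path = NULL) {
  man <- list(command = command,
              seed = if (is.na(seed)) NULL else as.integer(seed),
              inputs = as.list(inputs), outputs = as.list(outputs),
              config = if (is.null(config_path)) NULL else
                list(path = config_path,
                     md5 = unname(tools::md5sum(config_path))),
              package_version = as.character(utils::packageVersion("mrbscan")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
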