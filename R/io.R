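# File formats: list-mode phase space (CSV canonical, Parquet optional),
# run configuration (YAML), analysis reports (JSON).

ps_schema <- c("t0", "v0", "st0", "sv0", "t1", "v1", "st1", "sv1",
               "e_in", "e_out", "wepl")

#' Write list-mode phase space to disk
#'
#' Columns: `t0,v0,st0,sv0,t1,v1,st1,sv1,e_in,e_out,wepl` (positions in mm at
#' the front/rear scorer, directions as slopes dt/du and dv/du, energies in
#' MeV, WEPL in mm). Tracker depths are stored in a `# u_front=... u_rear=...`
#' comment line (CSV) or in file metadata (Parquet).
#'
#' @param records particle records (data.frame)
#' @param path output path; format chosen by extension (`.csv` or `.parquet`)
#' @return `path`, invisibly
#' @export
write_phase_space <- function(records, path) {
  stopifnot(all(ps_schema %in% names(records)))
  uf <- attr(records, "u_front") %||% 0
  ur <- attr(records, "u_rear") %||% NA_real_
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for Parquet output")
    tb <- arrow::arrow_table(as.data.frame(records)[ps_schema])
    tb <- tb$ReplaceSchemaMetadata(list(u_front = as.character(uf),
                                        u_rear = as.character(ur)))
    arrow::write_parquet(tb, path)
  } else {
    con <- file(path, "w")
    writeLines(sprintf("# u_front=%.9g u_rear=%.9g", uf, ur), con)
    close(con)
    data.table::fwrite(as.data.frame(records)[ps_schema], path, append = TRUE,
                       col.names = TRUE)
  }
  invisible(path)
}

#' Read list-mode phase space from disk
#'
#' Validates the column schema and drops rows violating record invariants
#' (`e_out > e_in`, non-finite values, negative WEPL) with a reported count.
#'
#' @param path a `.csv` or `.parquet` file written by [write_phase_space()]
#'   or an external scorer with the same schema
#' @return a `data.table` of records with `u_front`/`u_rear` attributes
#' @export
read_phase_space <- function(path) {
  stopifnot(file.exists(path))
  uf <- 0; ur <- NA_real_
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for Parquet input")
    tb <- arrow::read_parquet(path, as_data_frame = FALSE)
    md <- tb$metadata
    if (!is.null(md$u_front)) uf <- as.numeric(md$u_front)
    if (!is.null(md$u_rear)) ur <- as.numeric(md$u_rear)
    rec <- data.table::setDT(as.data.frame(tb))
  } else {
    first <- readLines(path, n = 1)
    if (!length(first)) stop("phase-space file is empty")
    if (grepl("^#", first)) {
      m <- regmatches(first, regexec(
        "u_front=([-0-9.eE+]+)\\s+u_rear=([-0-9.eE+]+)", first))[[1]]
      if (length(m) == 3) { uf <- as.numeric(m[2]); ur <- as.numeric(m[3]) }
    }
    rec <- data.table::fread(path, skip = if (grepl("^#", first)) 1L else 0L)
  }
  if (!all(ps_schema %in% names(rec)))
    stop("phase-space schema error: missing columns ",
         paste(setdiff(ps_schema, names(rec)), collapse = ", "))
  rec <- rec[, ps_schema, with = FALSE]
  n0 <- nrow(rec)
  if (n0 == 0) stop("phase-space schema error: no records")
  ok <- Reduce(`&`, lapply(rec, is.finite)) &
    rec$e_out <= rec$e_in & rec$wepl >= 0
  rec <- rec[ok]
  dropped <- n0 - nrow(rec)
  if (dropped > 0)
    message(dropped, " invalid record(s) dropped")
  data.table::setattr(rec, "u_front", uf)
  data.table::setattr(rec, "u_rear", ur)
  data.table::setattr(rec, "n_dropped", dropped)
  rec
}

# known configuration keys per section
config_keys <- list(
  beam = c("kinetic_energy", "spot_sigma", "divergence_sigma", "spot_spacing",
           "field_size", "n_primaries", "rng_seed"),
  transport = c("step_length", "straggling_enabled", "scattering_enabled",
                "outlier_fraction", "outlier_offset", "bohr_rate", "rng_seed"),
  path = c("lambda0", "lambda1"),
  reconstruction = c("pixel_size", "extent", "center", "depth_step",
                     "sigma_mult"),
  fs = c("sigma", "sg_window", "sg_polyorder"),
  qa = c("noise_roi", "esf_half_len", "esf_half_width", "esf_bin",
         "cap_nyquist"),
  run = c("phantom", "seed", "out_dir")
)

#' Read a pipeline run configuration (YAML)
#'
#' Sections `beam`, `transport`, `path`, `reconstruction`, `fs`, `qa`, `run`
#' mirror the corresponding function parameters. Unknown sections or keys are
#' rejected.
#'
#' @param path YAML file
#' @return a `run_config` (named list of sections)
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  bad <- setdiff(names(cfg), names(config_keys))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    extra <- setdiff(names(cfg[[sec]]), config_keys[[sec]])
    if (length(extra))
      stop("unknown key(s) in [", sec, "]: ", paste(extra, collapse = ", "))
  }
  invisible(cfg)
}

#' Write a pipeline run configuration (YAML)
#' @param cfg a `run_config` (named list of sections)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
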