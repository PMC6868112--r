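.record_header <- c("time_min", "glucose_g_per_L", "insulin_mU_per_L",
                    "glucagon_pmol_per_L", "fhgp_g_per_h_per_L",
                    "rd_g_per_h_per_L")

# full-precision numeric formatting so write/read round-trips are lossless
.fmt <- function(x) vapply(x, function(v) sprintf("%.17g", v), character(1))

#' Write a subject record to CSV
#'
#' Column layout (times in minutes, the study convention; internal time is
#' hours): `time_min,glucose_g_per_L,insulin_mU_per_L,glucagon_pmol_per_L,`
#' `fhgp_g_per_h_per_L,rd_g_per_h_per_L`. Values are written with 17
#' significant digits so the round trip is lossless to full double
#' precision.
#'
#' @param record a `subject_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subject_record <- function(record, path) {
  df <- data.frame(time_min = .fmt(record$time_min),
                   glucose_g_per_L = .fmt(record$G),
                   insulin_mU_per_L = .fmt(record$I),
                   glucagon_pmol_per_L = .fmt(record$E),
                   fhgp_g_per_h_per_L = .fmt(record$F_hgp),
                   rd_g_per_h_per_L = .fmt(record$Rd))
  names(df) <- .record_header
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject record from CSV
#'
#' @param path CSV file with the exact [write_subject_record()] header.
#' @param subject_id,visit identifiers to store in the record; parsed from a
#'   `<id>_<visit>.csv` filename when omitted.
#' @return A `subject_record`.
#' @export
read_subject_record <- function(path, subject_id = NULL, visit = NULL) {
  df <- read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(.record_header, names(df))
  if (length(missing_cols))
    stop("malformed record CSV '", basename(path), "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), .record_header)
  if (length(extra))
    stop("malformed record CSV '", basename(path), "': unknown column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  base <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  if (is.null(subject_id)) subject_id <- parts[1]
  if (is.null(visit)) visit <- if (length(parts) > 1) parts[2] else "before"
  structure(list(subject_id = subject_id, visit = visit,
                 time_min = df$time_min,
                 G = df$glucose_g_per_L, I = df$insulin_mU_per_L,
                 E = df$glucagon_pmol_per_L, F_hgp = df$fhgp_g_per_h_per_L,
                 Rd = df$rd_g_per_h_per_L,
                 true_params = NULL, true_baseline = NULL),
            class = "subject_record")
}

#' Read a flat key-value parameter file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Unknown keys are rejected against the allowed set.
#'
#' @param path file path.
#' @param allowed character vector of permitted keys.
#' @return Named numeric list.
#' @export
read_kv_config <- function(path, allowed) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, integer(1)) != 2L]
  if (length(bad))
    stop("malformed line(s) in '", basename(path), "': ",
         paste(bad, collapse = "; "), call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2L)))
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown key(s) in '", basename(path), "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicated key(s) in '", basename(path), "'", call. = FALSE)
  setNames(as.list(vals), keys)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory for cohort CSVs, parameter tables and
#'   reports.
#' @param seed global seed; all stochastic stages derive their seeds from it.
#' @param spec a [cohort_spec()] (its seed is overridden by `seed`).
#' @param prot a [protocol()].
#' @param fixed a [fixed_kinetics()].
#' @param noise a [noise_model()].
#' @param smoothing a [smoothing_config()].
#' @param verbose print one structured line per pipeline stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("gct_run_"), seed = 1L,
                       spec = cohort_spec(), prot = protocol(),
                       fixed = fixed_kinetics(), noise = noise_model(),
                       smoothing = smoothing_config(), verbose = TRUE) {
  spec$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 prot = prot, fixed = fixed, noise = noise,
                 smoothing = smoothing, verbose = verbose),
            class = "run_config")
}

.log_stage <- function(config, stage, ...) {
  if (isTRUE(config$verbose))
    message(sprintf("[gctmod:%s] %s", stage, sprintf(...)))
}

#' Simulate a cohort to disk
#'
#' Writes one CSV per subject and visit (`S01_before.csv`, ...), a
#' ground-truth parameter CSV, and a JSON manifest recording the seed and
#' package version. A fixed seed yields a bytewise-identical file set.
#'
#' @param config a [run_config()].
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  coh <- generate_paired_cohort(config$spec, config$prot, config$fixed,
                                config$noise)
  for (subj in coh)
    for (rec in subj)
      write_subject_record(rec, file.path(config$out_dir,
                                          sprintf("%s_%s.csv", rec$subject_id,
                                                  rec$visit)))
  truth <- attr(coh, "ground_truth")
  write.csv(truth, file.path(config$out_dir, "ground_truth.csv"),
            row.names = FALSE)
  manifest <- list(seed = config$seed,
                   n_subjects = config$spec$n_subjects,
                   treatment_K1prime_multiplier =
                     config$spec$treatment_K1prime_multiplier,
                   package = "gctmod",
                   version = as.character(packageVersion("gctmod")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage(config, "simulate", "wrote %d records to %s in %.1fs",
             2L * config$spec$n_subjects, config$out_dir,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(config$out_dir)
}

#' Fit every record in a directory
#'
#' Runs baseline estimation, hormone fitting and profiling per record CSV;
#' writes `params_before.csv` and `params_after.csv` (one row per subject,
#' fitted parameters plus observed `G_max`). Per-record failures are
#' reported and skipped; the run continues.
#'
#' @param config a [run_config()]; records are read from `config$out_dir`.
#' @return Named list of the two parameter tables, invisibly.
#' @export
run_fit <- function(config = run_config()) {
  files <- list.files(config$out_dir, pattern = "^S[0-9]+_(before|after)\\.csv$",
                      full.names = TRUE)
  if (!length(files))
    stop("no record CSVs found in '", config$out_dir, "'", call. = FALSE)
  t0 <- Sys.time()
  tabs <- list()
  for (v in c("before", "after")) {
    fv <- files[grepl(paste0("_", v, "\\.csv$"), files)]
    fits <- list()
    recs <- list()
    for (f in fv) {
      rec <- read_subject_record(f)
      fit <- tryCatch(profile_fit(rec, config$smoothing, config$prot,
                                  config$fixed),
                      error = function(e) {
                        warning("fit failed for ", basename(f), ": ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (!is.null(fit)) {
        fits[[rec$subject_id]] <- fit
        recs[[rec$subject_id]] <- rec
      }
    }
    if (!length(fits)) stop("all fits failed for visit '", v, "'", call. = FALSE)
    tab <- parameter_table(fits, recs)
    out <- cbind(subject_id = rownames(tab), tab)
    write.csv(out, file.path(config$out_dir, sprintf("params_%s.csv", v)),
              row.names = FALSE)
    tabs[[v]] <- tab
  }
  .log_stage(config, "fit", "fitted %d records in %.1fs", length(files),
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(tabs)
}

#' Compare before/after parameter tables
#'
#' Reads `params_before.csv`/`params_after.csv`, runs [summarize_cohort()],
#' and writes `comparison.csv` plus a plain-text report with both receptor
#' change computations.
#'
#' @param config a [run_config()].
#' @return The `cohort_summary`, invisibly.
#' @export
run_compare <- function(config = run_config()) {
  read_tab <- function(v) {
    f <- file.path(config$out_dir, sprintf("params_%s.csv", v))
    if (!file.exists(f)) stop("missing parameter table '", f, "'", call. = FALSE)
    df <- read.csv(f)
    rownames(df) <- df$subject_id
    df$subject_id <- NULL
    df
  }
  before <- read_tab("before")
  after <- read_tab("after")
  if (!setequal(rownames(before), rownames(after)))
    stop("subject mismatch between visits: ",
         paste(union(setdiff(rownames(before), rownames(after)),
                     setdiff(rownames(after), rownames(before))),
               collapse = ", "), call. = FALSE)
  summ <- summarize_cohort(before, after)
  write.csv(summ$comparison, file.path(config$out_dir, "comparison.csv"),
            row.names = FALSE)
  rep_path <- file.path(config$out_dir, "report.txt")
  con <- file(rep_path, "w")
  sink(con)
  print(summ)
  sink()
  close(con)
  .log_stage(config, "compare", "wrote comparison for %d parameters",
             nrow(summ$comparison))
  invisible(summ)
}

#' Run the full pipeline
#'
#' [run_simulate()], [run_fit()], [run_compare()] in sequence.
#'
#' @param config a [run_config()].
#' @return The final `cohort_summary`, invisibly.
#' @export
run_all <- function(config = run_config()) {
  run_simulate(config)
  run_fit(config)
  run_compare(config)
}
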