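.measurement_cols <- c("fish_id", "tank_id", "trial", "arm", "matrix",
                       "time_h", "cortisol_ng_ml")

#' Validate a measurement table
#'
#' Checks the tidy long-format schema used throughout the package: required
#' columns, allowed factor levels, strictly positive concentrations,
#' non-negative times, no duplicate `(fish_id, time_h, matrix)` keys, and --
#' when a [study_design()] is supplied -- membership of every `time_h` in the
#' design's sampling times. Violations are reported with the offending row
#' numbers.
#'
#' @param table A data.frame.
#' @param design Optional [study_design()] for time-membership checks.
#' @return The table, invisibly, if valid; otherwise an error listing every
#'   offending row.
#' @export
validate_measurements <- function(table, design = NULL) {
  if (!is.data.frame(table)) stop("measurement table must be a data.frame")
  missing_cols <- setdiff(.measurement_cols, names(table))
  if (length(missing_cols))
    stop("measurement table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  problems <- character()
  bad <- function(rows, msg) {
    if (length(rows))
      problems <<- c(problems, paste0(msg, " (row ",
                                      paste(rows, collapse = ", "), ")"))
  }
  if (!is.numeric(table$time_h))
    problems <- c(problems, "time_h is not numeric")
  if (!is.numeric(table$cortisol_ng_ml))
    problems <- c(problems, "cortisol_ng_ml is not numeric")
  if (!length(problems)) {
    bad(which(!is.finite(table$time_h) | table$time_h < 0),
        "time_h must be finite and >= 0")
    bad(which(!is.finite(table$cortisol_ng_ml) | table$cortisol_ng_ml <= 0),
        "cortisol_ng_ml must be finite and > 0")
    bad(which(!table$trial %in% c("ACTH", "cortisol")),
        "trial must be 'ACTH' or 'cortisol'")
    bad(which(!table$arm %in% c("treatment", "control")),
        "arm must be 'treatment' or 'control'")
    bad(which(!table$matrix %in% c("plasma", "mucus")),
        "matrix must be 'plasma' or 'mucus'")
    key <- paste(table$fish_id, table$time_h, table$matrix, sep = "\r")
    bad(which(duplicated(key)), "duplicate (fish_id, time_h, matrix) key")
    if (!is.null(design)) {
      stopifnot(inherits(design, "study_design"))
      bad(which(!table$time_h %in% design$sampling_times),
          paste0("time_h not among design sampling times (",
                 paste(design$sampling_times, collapse = ", "), ")"))
    }
  }
  if (length(problems))
    stop("invalid measurement table:\n  ", paste(problems, collapse = "\n  "))
  invisible(table)
}

#' Read and validate a measurement CSV
#'
#' Expects a comma-separated, period-decimal, UTF-8 file with a header row
#' and the columns `fish_id, tank_id, trial, arm, matrix, time_h,
#' cortisol_ng_ml`.
#'
#' @param path Path to the CSV file.
#' @param design Optional [study_design()]; if given, sampling times are
#'   checked against it.
#' @return A validated measurement table.
#' @export
load_measurements <- function(path, design = NULL) {
  if (!file.exists(path)) stop("load_measurements: no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  validate_measurements(tab, design)
  tab
}

#' Write a measurement table to CSV
#'
#' @param table A validated measurement table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  validate_measurements(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset a measurement table for one model fit
#'
#' Treatment subsets filter on (trial, matrix, arm = treatment). Control
#' subsets with `pool_controls = TRUE` pool control rows from every trial for
#' the given matrix, mirroring the pooled-control fits. Plasma subsets are
#' additionally restricted to the first sampling window (time `<=`
#' `plasma_cutoff`) so that repeat sampling cannot contaminate the
#' short-timescale plasma model; mucus subsets span the full timeframe.
#'
#' @param table A validated measurement table.
#' @param trial `"ACTH"` or `"cortisol"`; ignored when pooling controls.
#' @param matrix `"plasma"` or `"mucus"`.
#' @param arm `"treatment"` or `"control"`.
#' @param pool_controls If `TRUE` (only valid with `arm = "control"`), pool
#'   both trials' control rows.
#' @param plasma_cutoff Upper time bound applied to plasma subsets (h).
#' @return The non-empty subset, a measurement table.
#' @export
subset_for_model <- function(table, trial = NULL,
                             matrix = c("plasma", "mucus"),
                             arm = c("treatment", "control"),
                             pool_controls = FALSE, plasma_cutoff = 12) {
  validate_measurements(table)
  matrix <- match.arg(matrix)
  arm <- match.arg(arm)
  if (pool_controls && arm != "control")
    stop("subset_for_model: pool_controls only applies to control subsets")
  keep <- table$matrix == matrix & table$arm == arm
  if (!pool_controls) {
    if (is.null(trial))
      stop("subset_for_model: 'trial' is required unless pooling controls")
    trial <- match.arg(trial, c("ACTH", "cortisol"))
    keep <- keep & table$trial == trial
  }
  if (matrix == "plasma") keep <- keep & table$time_h <= plasma_cutoff
  out <- table[keep, , drop = FALSE]
  if (!nrow(out))
    stop("subset_for_model: empty subset for ",
         if (pool_controls) "pooled-control " else paste0(trial, "/"),
         matrix, "/", arm)
  rownames(out) <- NULL
  out
}

#' Intra- and inter-assay coefficients of variation
#'
#' QC summary of immunoassay duplicates. The intra-assay CV is the mean over
#' samples of `100 * sd(replicates) / mean(replicates)` (sample sd, n-1
#' denominator). The inter-assay CV is `100 * sd / mean` of the plate-level
#' mean of a common reference sample across plates.
#'
#' @param dups Long-format data.frame with columns `sample_id`, `plate_id`,
#'   `value` -- one row per replicate, at least two replicates per sample.
#' @param reference `sample_id` of the common reference run on every plate;
#'   defaults to the sample present on the most plates.
#' @return List with `intra_cv` and `inter_cv` (percent). With a single
#'   plate `inter_cv` is `NA` and `single_plate = TRUE` is flagged.
#' @export
assay_cv <- function(dups, reference = NULL) {
  stopifnot(is.data.frame(dups),
            all(c("sample_id", "plate_id", "value") %in% names(dups)))
  if (any(dups$value <= 0)) stop("assay_cv: replicate values must be > 0")
  counts <- table(dups$sample_id)
  if (any(counts < 2))
    stop("assay_cv: every sample needs >= 2 replicates; offending sample(s): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  per_sample <- vapply(split(dups$value, dups$sample_id),
                       function(v) 100 * stats::sd(v) / mean(v), 0)
  intra <- mean(per_sample)

  if (is.null(reference)) {
    plates_per_sample <- vapply(split(dups$plate_id, dups$sample_id),
                                function(p) length(unique(p)), 0L)
    reference <- names(plates_per_sample)[which.max(plates_per_sample)]
  }
  ref <- dups[dups$sample_id == reference, , drop = FALSE]
  plate_means <- vapply(split(ref$value, ref$plate_id), mean, 0)
  if (length(plate_means) < 2) {
    return(list(intra_cv = intra, inter_cv = NA_real_, single_plate = TRUE,
                reference = reference))
  }
  inter <- 100 * stats::sd(plate_means) / mean(plate_means)
  list(intra_cv = intra, inter_cv = inter, single_plate = FALSE,
       reference = reference)
}

#' Summarise concentrations at one sampling time
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator) and count of
#' the concentrations observed at a given time -- typically time 0, whose
#' mean is the baseline threshold used by the exceedance computation.
#'
#' @param table A validated measurement table (already subset as desired).
#' @param time Sampling time in hours.
#' @return List with `mean`, `sd` (`NA` and `sd_undefined = TRUE` when only
#'   one row exists) and `n`.
#' @export
baseline_summary <- function(table, time = 0) {
  validate_measurements(table)
  v <- table$cortisol_ng_ml[table$time_h == time]
  if (!length(v)) stop("baseline_summary: no rows at time ", time, " h")
  if (length(v) == 1L)
    return(list(mean = v, sd = NA_real_, n = 1L, sd_undefined = TRUE))
  list(mean = mean(v), sd = stats::sd(v), n = length(v), sd_undefined = FALSE)
}
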