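long_cols <- c("subject_id", "unit_id", "group_id", "occasion", "week",
               "sccs", "ks2", "kon")

#' Read a long-format repeated-measures table
#'
#' Reads and validates the pipeline's CSV dialect: one row per (subject,
#' occasion) with columns `subject_id, unit_id, group_id, occasion, week,
#' sccs, ks2, kon`. `kon` is expected at occasion 1 only; `ks2` at least at
#' the first and last occasion of each subject. Scores are validated against
#' the instrument ranges. Subjects with fewer than 2 occasions are rejected
#' (dropped, listed in the `"rejected"` attribute); subjects with fewer than
#' 4 occasions are kept with a warning, since study-like series have 4-9.
#'
#' @param path CSV file path.
#' @param instruments Instrument battery, as from [default_instruments()].
#' @return A validated data frame of class `"scc_long"`, with attribute
#'   `"rejected"` naming any dropped subjects.
#' @export
read_scc_long <- function(path, instruments = default_instruments()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(long_cols, names(df))
  if (length(missing))
    stop("schema-error: missing column(s): ", paste(missing, collapse = ", "))
  validate_scc_long(df, instruments)
}

# shared validation so in-memory tables go through the same checks
validate_scc_long <- function(df, instruments = default_instruments()) {
  df <- df[order(df$subject_id, df$occasion), long_cols]
  key <- paste(df$subject_id, df$occasion)
  if (anyDuplicated(key))
    stop("integrity-error: duplicate (subject_id, occasion) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  check_range <- function(x, spec, col) {
    bad <- which(!is.na(x) & (x < spec$score_min | x > spec$score_max))
    if (length(bad))
      stop(sprintf("value-error: %s out of range [%g, %g] at row(s) %s",
                   col, spec$score_min, spec$score_max,
                   paste(utils::head(bad, 10), collapse = ", ")))
  }
  check_range(df$sccs, instruments$sccs, "sccs")
  check_range(df$ks2, instruments$ks2, "ks2")
  check_range(df$kon, instruments$kon, "kon")
  if (anyNA(df$sccs)) stop("value-error: sccs must be observed at every occasion")

  occ_per_subj <- split(df$occasion, df$subject_id)
  bad_first <- names(occ_per_subj)[vapply(occ_per_subj, function(o)
    o[1] != 1L || any(diff(o) <= 0), logical(1))]
  if (length(bad_first))
    stop("integrity-error: occasions must increase from 1 for subject(s): ",
         paste(bad_first, collapse = ", "))

  k <- lengths(occ_per_subj)
  rejected <- names(k)[k < 2]
  if (length(rejected)) {
    warning("rejecting subject(s) with fewer than 2 occasions: ",
            paste(rejected, collapse = ", "))
    df <- df[!df$subject_id %in% rejected, ]
  }
  short <- names(k)[k >= 2 & k < 4]
  if (length(short))
    warning("subject(s) with fewer than 4 occasions (study range is 4-9): ",
            paste(short, collapse = ", "))

  structure(df, class = c("scc_long", "data.frame"), rejected = rejected)
}

#' Read a pipeline run configuration
#'
#' Flat key-value (YAML) configuration for [scc_process()]. Recognized keys
#' (all optional, shown with defaults): `scc_rci: 3.48`, `ks2_rci: 56.6`,
#' `scc_cutoff: 34`, `kon_cutoff: auto`, `seed: 1`, `kmeans_nstart: 10`.
#'
#' @param path YAML file path.
#' @return Named list of configuration values with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(scc_rci = 3.48, ks2_rci = 56.6, scc_cutoff = 34,
                   kon_cutoff = "auto", seed = 1, kmeans_nstart = 10)
  out <- utils::modifyList(defaults, cfg[names(cfg) %in% names(defaults)])
  if (!is.numeric(out$scc_rci) || out$scc_rci <= 0 ||
      !is.numeric(out$ks2_rci) || out$ks2_rci <= 0)
    stop("invalid-config: thresholds must be positive")
  if (!identical(out$kon_cutoff, "auto") && !is.numeric(out$kon_cutoff))
    stop("invalid-config: kon_cutoff must be 'auto' or a number")
  out
}
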