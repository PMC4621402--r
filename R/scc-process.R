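#' Fit the SCC process-outcome analysis
#'
#' The package's central fitting function. Takes a long-format
#' repeated-measures table (or a path to one, or a synthetic cohort from
#' [simulate_scc_cohort()]) and runs the full pipeline:
#'
#' 1. per-subject logarithmic trend, fluctuation RMSE, and five-class shape
#'    classification ([classify_shape()]);
#' 2. personality dispositions from the SCC cutoff and the KON-2006 median
#'    of the integrated subgroup ([categorize_disposition()]), with k-means
#'    cluster validation;
#' 3. pre-post KS-II change scores, improvement flags, the shape-by-
#'    improvement G-test battery, fluctuation-outcome correlations by
#'    stratum, the fluctuation x disposition interaction regression, the
#'    two-factor ANOVA, and the three-level variance-components null model.
#'
#' @param data A `"scc_long"` table, a CSV path, or an `"scc_cohort"`.
#' @param scc_rci Reliable-change threshold on the SCCS (default 3.48).
#' @param ks2_rci Reliable-change threshold on the KS-II (default 56.6).
#' @param scc_cutoff Integration cutoff on baseline SCCS (default 34).
#' @param kon_cutoff `"auto"` (median KON-2006 of the integrated subgroup)
#'   or a fixed number.
#' @param seed Seed for the k-means cluster validation.
#' @param kmeans_nstart Restarts for k-means.
#' @param instruments Instrument battery for input validation.
#' @return An object of class `"scc_process"`: list with `subjects` (one row
#'   per subject: trend coefficients, `rmse`, `shape`, `disposition`,
#'   `change`, `improved`, ...), `cutoffs`, `trends` (per-subject
#'   `log_trend_fit`s), and `tests` (`g_tests`, `correlations`,
#'   `interaction`, `anova`, `variance_components`, `kmeans_validation`).
#' @examples
#' coh <- simulate_scc_cohort(seed = 7)
#' fit <- scc_process(coh, seed = 7)
#' fit
#' @export
scc_process <- function(data, scc_rci = 3.48, ks2_rci = 56.6,
                        scc_cutoff = 34, kon_cutoff = "auto", seed = 1,
                        kmeans_nstart = 10,
                        instruments = default_instruments()) {
  long <- if (is.character(data)) read_scc_long(data, instruments)
          else if (inherits(data, "scc_cohort"))
            validate_scc_long(data$long, instruments)
          else if (inherits(data, "scc_long")) data
          else validate_scc_long(as.data.frame(data), instruments)

  by_subj <- split(long, long$subject_id)
  trends <- lapply(by_subj, function(d)
    suppressWarnings(fit_log_trajectory(d$sccs, d$occasion)))
  subjects <- data.frame(
    subject_id = names(by_subj),
    unit_id = vapply(by_subj, function(d) as.character(d$unit_id[1]), ""),
    group_id = vapply(by_subj, function(d) as.character(d$group_id[1]), ""),
    k = vapply(by_subj, nrow, 0L),
    scc_t1 = vapply(by_subj, function(d) d$sccs[1], 0),
    kon_t1 = vapply(by_subj, function(d) d$kon[1], 0),
    ks2_pre = vapply(by_subj, function(d) d$ks2[1], 0),
    ks2_post = vapply(by_subj, function(d) d$ks2[nrow(d)], 0),
    intercept = vapply(trends, `[[`, 0, "intercept"),
    slope = vapply(trends, `[[`, 0, "slope"),
    rmse = vapply(trends, `[[`, 0, "rmse"),
    shape = factor(vapply(by_subj, function(d)
      classify_shape(d$sccs, scc_rci), ""), levels = shape_levels()),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (anyNA(subjects$kon_t1))
    stop("value-error: kon must be observed at occasion 1 for every subject")
  if (anyNA(subjects$ks2_pre) || anyNA(subjects$ks2_post))
    stop("value-error: ks2 must be observed at the first and last occasion")

  kc <- if (identical(kon_cutoff, "auto"))
    kon_cutoff_from_integrated(subjects$scc_t1, subjects$kon_t1, scc_cutoff)
  else kon_cutoff
  subjects$disposition <- categorize_disposition(subjects$scc_t1,
                                                 subjects$kon_t1,
                                                 scc_cutoff, kc)
  subjects$is_if <- subjects$disposition == "integrated_functional"
  subjects$change <- change_score(subjects$ks2_pre, subjects$ks2_post,
                                  c(instruments$ks2$score_min,
                                    instruments$ks2$score_max))
  subjects$improved <- improvement_flag(subjects$change, ks2_rci)

  tests <- list(
    g_tests = shape_frequency_tests(subjects$shape, subjects$disposition,
                                    subjects$improved),
    correlations = list(
      integrated_functional = tryCatch(
        with(subjects[subjects$is_if, ], subgroup_correlation(rmse, change)),
        error = function(e) NULL),
      other_three = tryCatch(
        with(subjects[!subjects$is_if, ], subgroup_correlation(rmse, change)),
        error = function(e) NULL)
    ),
    interaction = tryCatch(
      fit_interaction_model(subjects$change, subjects$rmse, subjects$is_if),
      error = function(e) {
        message("interaction model skipped: ", conditionMessage(e)); NULL
      }),
    anova = tryCatch(
      two_way_anova(subjects$change, subjects$shape, subjects$is_if),
      error = function(e) {
        message("two-way ANOVA skipped: ", conditionMessage(e)); NULL
      }),
    variance_components = variance_components_null(subjects$change,
                                                   subjects$group_id,
                                                   subjects$unit_id),
    kmeans_validation = tryCatch(
      validate_dispositions_kmeans(subjects$scc_t1, subjects$kon_t1,
                                   subjects$disposition, seed = seed,
                                   nstart = kmeans_nstart),
      error = function(e) {
        message("k-means validation skipped: ", conditionMessage(e)); NULL
      })
  )

  structure(
    list(subjects = subjects, trends = trends,
         cutoffs = list(scc_rci = scc_rci, ks2_rci = ks2_rci,
                        scc_cutoff = scc_cutoff, kon_cutoff = kc),
         tests = tests, rejected = attr(long, "rejected"),
         call = match.call()),
    class = "scc_process"
  )
}

#' @export
print.scc_process <- function(x, ...) {
  n <- nrow(x$subjects)
  cat(sprintf("SCC process-outcome analysis: %d subjects\n", n))
  cat(sprintf("Cutoffs: SCC RCI %.2f, KS-II RCI %.1f, SCC cutoff %d, KON cutoff %.4g\n",
              x$cutoffs$scc_rci, x$cutoffs$ks2_rci, x$cutoffs$scc_cutoff,
              x$cutoffs$kon_cutoff))
  cat("\nShape counts:\n"); print(table(x$subjects$shape))
  cat("\nDisposition counts:\n"); print(table(x$subjects$disposition))
  cat(sprintf("\nImproved (change > %.1f): %d / %d\n",
              x$cutoffs$ks2_rci, sum(x$subjects$improved), n))
  invisible(x)
}

#' @export
summary.scc_process <- function(object, ...) {
  structure(list(fit = object), class = "summary.scc_process")
}

#' @export
print.summary.scc_process <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$tests$kmeans_validation)) {
    cat("\n"); print(f$tests$kmeans_validation)
  }
  cat("\n"); print(f$tests$variance_components)
  if (!is.null(f$tests$interaction)) { cat("\n"); print(f$tests$interaction) }
  if (!is.null(f$tests$anova)) { cat("\n"); print(f$tests$anova) }
  gt <- f$tests$g_tests
  cat("\nG-tests (whole sample):\n")
  print(gt[gt$stratum == "whole_sample",
           c("shape", "a", "b", "c", "d", "statistic", "p")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.scc_process <- function(object, ...) {
  if (is.null(object$tests$interaction)) return(NULL)
  coef(object$tests$interaction)
}

#' @export
residuals.scc_process <- function(object, ...) {
  unlist(lapply(object$trends, `[[`, "residuals"), use.names = TRUE)
}

#' @export
fitted.scc_process <- function(object, ...) {
  unlist(lapply(object$trends, `[[`, "fitted"), use.names = TRUE)
}

#' @export
plot.scc_process <- function(x, ...) {
  cells <- tapply(x$subjects$change,
                  list(x$subjects$shape, x$subjects$is_if),
                  mean)
  sh <- seq_len(nrow(cells))
  graphics::matplot(sh, cells, type = "b", pch = c(1, 16), lty = 1:2,
                    col = c("grey40", "black"), xaxt = "n",
                    xlab = "Shape of SCC change",
                    ylab = "Mean KS-II change (pre - post)", ...)
  graphics::axis(1, at = sh, labels = abbreviate(rownames(cells), 8),
                 cex.axis = 0.8)
  graphics::legend("topright", legend = c("other three", "integrated-functional"),
                   pch = c(1, 16), lty = 1:2, col = c("grey40", "black"),
                   bty = "n")
  graphics::abline(h = x$cutoffs$ks2_rci, lty = 3)
  invisible(x)
}

#' Write the run report
#'
#' Emits the per-subject table, CSV tables for the variance components,
#' interaction fit, ANOVA and G-test battery, a JSON summary of every
#' statistic, and a short Markdown report.
#'
#' @param fit An `"scc_process"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scc_report <- function(fit, dir) {
  stopifnot(inherits(fit, "scc_process"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tdir <- file.path(dir, "tables")
  if (!dir.exists(tdir)) dir.create(tdir)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(tdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  subj_path <- file.path(dir, "subjects.csv")
  utils::write.csv(fit$subjects, subj_path, row.names = FALSE)
  paths <- c(paths, subj_path)
  w(fit$tests$variance_components$components, "variance_components.csv")
  if (!is.null(fit$tests$interaction))
    w(fit$tests$interaction$coefficients, "interaction_fit.csv")
  if (!is.null(fit$tests$anova)) {
    w(fit$tests$anova$table, "anova.csv")
    w(fit$tests$anova$cells, "anova_cells.csv")
  }
  w(fit$tests$g_tests, "g_tests.csv")

  js <- list(
    schema_version = 1L,
    n = nrow(fit$subjects),
    cutoffs = fit$cutoffs,
    shape_counts = as.list(table(fit$subjects$shape)),
    disposition_counts = as.list(table(fit$subjects$disposition)),
    n_improved = sum(fit$subjects$improved),
    variance_components = fit$tests$variance_components$components,
    interaction = if (!is.null(fit$tests$interaction)) list(
      coefficients = fit$tests$interaction$coefficients,
      explained = as.list(fit$tests$interaction$explained),
      r_squared = fit$tests$interaction$r_squared
    ),
    anova = if (!is.null(fit$tests$anova)) fit$tests$anova$table,
    g_tests = fit$tests$g_tests,
    kmeans_cramers_v = if (!is.null(fit$tests$kmeans_validation))
      fit$tests$kmeans_validation$cramers_v,
    correlations = lapply(fit$tests$correlations, function(z)
      if (is.null(z)) NULL else z[c("r", "n", "p")]),
    rejected_subjects = fit$rejected
  )
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(js, jpath, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows")
  paths <- c(paths, jpath)

  md <- c(
    "# SCC process-outcome report", "",
    sprintf("Subjects: %d; improved: %d", nrow(fit$subjects),
            sum(fit$subjects$improved)),
    sprintf("Cutoffs: SCC RCI %.2f, KS-II RCI %.1f, SCC %d, KON %.4g",
            fit$cutoffs$scc_rci, fit$cutoffs$ks2_rci,
            fit$cutoffs$scc_cutoff, fit$cutoffs$kon_cutoff),
    "", "## Shape counts", "",
    paste(names(table(fit$subjects$shape)),
          as.integer(table(fit$subjects$shape)), sep = ": "),
    "", "## Disposition counts", "",
    paste(names(table(fit$subjects$disposition)),
          as.integer(table(fit$subjects$disposition)), sep = ": ")
  )
  mpath <- file.path(dir, "report.md")
  writeLines(md, mpath)
  invisible(c(paths, mpath))
}
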