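#' Pre-post symptom change score
#'
#' Change in KS-II neurotic symptom intensity, computed as pre minus post so
#' that positive values mean fewer symptoms after therapy (improvement
#' direction).
#'
#' @param ks2_pre,ks2_post Pre- and post-therapy KS-II total scores.
#' @param score_range Valid KS-II range used for validation
#'   (default `c(0, 595)`).
#' @return `ks2_pre - ks2_post` (vectorized).
#' @examples
#' change_score(339, 236)  # 103
#' @export
change_score <- function(ks2_pre, ks2_post, score_range = c(0, 595)) {
  bad <- !is.finite(ks2_pre) | !is.finite(ks2_post) |
    ks2_pre < score_range[1] | ks2_pre > score_range[2] |
    ks2_post < score_range[1] | ks2_post > score_range[2]
  if (any(bad))
    stop("invalid-argument: KS-II scores out of range at position(s) ",
         paste(which(bad), collapse = ", "))
  ks2_pre - ks2_post
}

#' Improvement flag
#'
#' A subject "improved" iff the pre-post change exceeds the KS-II
#' reliable-change threshold (strictly greater than 56.6 by default).
#' Deterioration and no-reliable-change are pooled as "no improvement".
#'
#' @param change Change score(s), positive = fewer symptoms.
#' @param threshold Reliable-change threshold (default 56.6).
#' @return Logical vector.
#' @export
improvement_flag <- function(change, threshold = 56.6) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("invalid-argument: threshold must be positive")
  change > threshold
}

#' Likelihood-ratio G-test on a 2x2 table
#'
#' The likelihood-ratio chi-square \eqn{G = 2 \sum O \ln(O/E)} over the four
#' cells, with expected counts from the independence margins and the
#' convention that cells with \eqn{O = 0} contribute 0. Preferred over the
#' Pearson chi-square (with continuity correction) when expected counts are
#' small. Referred to the chi-square distribution with 1 df.
#'
#' @param a,b,c,d Cell counts. Rows: improvement / no improvement; columns:
#'   in-shape / not-in-shape (`a` = improved and in-shape).
#' @return An object of class `"g_test"`: list with `statistic`, `df`, `p`,
#'   `table`.
#' @examples
#' g_test_2x2(20, 19, 9, 37)  # G ~ 9.59
#' @export
g_test_2x2 <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  if (any(!is.finite(o)) || any(o < 0) || any(o != round(o)))
    stop("invalid-table: counts must be non-negative integers")
  O <- matrix(o, nrow = 2, byrow = TRUE)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("invalid-table: zero row or column margin")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  terms <- ifelse(O > 0, O * log(O / E), 0)
  g <- 2 * sum(terms)
  g <- max(g, 0)  # guard against -0 from rounding on exact independence
  structure(
    list(statistic = g, df = 1L,
         p = stats::pchisq(g, df = 1L, lower.tail = FALSE),
         table = O),
    class = "g_test"
  )
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio G-test: G(%d) = %.2f, p = %.4g\n",
              x$df, x$statistic, x$p))
  invisible(x)
}

#' Shape-by-improvement G-test battery
#'
#' For the whole sample and each of the four personality dispositions, and
#' for each of the five trajectory shapes, builds the fourfold table
#' (improvement / no improvement) x (in-shape / all other shapes) and runs
#' [g_test_2x2()] — up to 25 tests. Strata where a margin is zero (e.g. a
#' shape nobody shows, or a stratum where everyone improved) are skipped and
#' flagged.
#'
#' @param shape Shape labels (factor or character in [shape_levels()]).
#' @param disposition Disposition labels (factor or character in
#'   [disposition_levels()]).
#' @param improved Logical improvement flags.
#' @return Data frame with one row per (stratum, shape): counts `a`, `b`,
#'   `c`, `d`, `statistic`, `df`, `p`, and `skipped`.
#' @export
shape_frequency_tests <- function(shape, disposition, improved) {
  shape <- factor(shape, levels = shape_levels())
  disposition <- factor(disposition, levels = disposition_levels())
  stopifnot(length(shape) == length(disposition),
            length(shape) == length(improved))
  strata <- c("whole_sample", disposition_levels())
  out <- list()
  for (st in strata) {
    in_st <- if (st == "whole_sample") rep(TRUE, length(shape))
             else !is.na(disposition) & disposition == st
    for (sh in shape_levels()) {
      in_sh <- shape == sh
      a <- sum(improved[in_st] & in_sh[in_st])
      b <- sum(improved[in_st] & !in_sh[in_st])
      cc <- sum(!improved[in_st] & in_sh[in_st])
      dd <- sum(!improved[in_st] & !in_sh[in_st])
      res <- tryCatch(g_test_2x2(a, b, cc, dd), error = function(e) NULL)
      if (is.null(res))
        message(sprintf("skipping G-test for %s / %s: zero margin", st, sh))
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, shape = sh, a = a, b = b, c = cc, d = dd,
        statistic = if (is.null(res)) NA_real_ else res$statistic,
        df = 1L,
        p = if (is.null(res)) NA_real_ else res$p,
        skipped = is.null(res),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Fluctuation-outcome correlation within a stratum
#'
#' Pearson correlation between per-subject SCC fluctuation (RMSE) and the
#' pre-post symptom change within a subgroup, with the two-sided test.
#'
#' @param rmse Fluctuation statistics.
#' @param change Change scores.
#' @return List with `r`, `n`, `df`, `p`.
#' @export
subgroup_correlation <- function(rmse, change) {
  stopifnot(length(rmse) == length(change))
  n <- length(rmse)
  if (n < 3) stop("invalid-argument: need at least 3 observations")
  if (stats::sd(rmse) == 0 || stats::sd(change) == 0)
    stop("undefined-correlation: zero variance")
  ct <- stats::cor.test(rmse, change, method = "pearson")
  list(r = unname(ct$estimate), n = n, df = unname(ct$parameter),
       p = ct$p.value)
}

#' Fluctuation x disposition interaction regression
#'
#' Least-squares fit of the symptom change score on SCC fluctuation (RMSE),
#' a disposition contrast (indicator for integrated-functional vs the pooled
#' other three dispositions), and their interaction:
#' `change ~ rmse + is_if + rmse:is_if`. A negative interaction coefficient
#' means the fluctuation-outcome slope is flatter among the
#' integrated-functional patients than in the other three groups combined.
#'
#' Per-term "explained variance" is the sequential (Type I) incremental R²
#' in the order rmse, disposition, interaction; the shares sum to the total
#' R².
#'
#' @param change Change scores.
#' @param rmse SCC fluctuation statistics.
#' @param is_if Logical or 0/1: integrated-functional indicator.
#' @return An object of class `"scc_interaction_fit"`: list with
#'   `coefficients` (estimate, t, p per term), `explained` (sequential R²
#'   per term), `r_squared`, `n`, and the underlying `lm` fit.
#' @export
fit_interaction_model <- function(change, rmse, is_if) {
  is_if <- as.numeric(is_if)
  stopifnot(length(change) == length(rmse), length(change) == length(is_if))
  if (all(is_if == is_if[1]))
    stop("invalid-argument: both disposition strata must be non-empty")
  dat <- data.frame(change = change, rmse = rmse, is_if = is_if)
  fit <- stats::lm(change ~ rmse * is_if, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("degenerate-design: collinear predictors")
  sm <- summary(fit)
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  sst <- sum(ss)
  expl <- ss[seq_len(nrow(an) - 1L)] / sst
  names(expl) <- rownames(an)[seq_len(nrow(an) - 1L)]
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    t = sm$coefficients[, 3],
    p = sm$coefficients[, 4],
    row.names = NULL
  )
  structure(
    list(coefficients = coefs, explained = expl,
         r_squared = sm$r.squared, n = nrow(dat), fit = fit),
    class = "scc_interaction_fit"
  )
}

#' @export
print.scc_interaction_fit <- function(x, ...) {
  cat("Symptom change ~ SCC fluctuation x disposition (IF vs rest)\n")
  print(transform(x$coefficients,
                  estimate = round(estimate, 3), t = round(t, 2),
                  p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("Sequential R2: %s; total R2 = %.3f (n = %d)\n",
              paste(sprintf("%s %.1f%%", names(x$explained),
                            100 * x$explained), collapse = ", "),
              x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.scc_interaction_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Two-factor ANOVA of symptom change on shape x disposition
#'
#' Factorial ANOVA of the pre-post change score on trajectory shape
#' (5 levels) and the integrated-functional contrast (2 levels) with their
#' interaction, using Type-III sums of squares with sum-to-zero contrasts
#' (unbalanced designs allowed). Effect sizes are partial eta-squared,
#' \eqn{SS_{effect} / (SS_{effect} + SS_{error})}. Factor levels with no
#' observations are dropped with a notice.
#'
#' @param change Change scores.
#' @param shape Shape labels.
#' @param is_if Logical or 0/1 integrated-functional indicator.
#' @return An object of class `"scc_anova"`: list with `table` (term, df, F,
#'   partial eta2, p), `cells` (per shape x disposition cell n, mean, SD),
#'   and the `lm` fit.
#' @export
two_way_anova <- function(change, shape, is_if) {
  shape <- factor(shape, levels = shape_levels())
  stopifnot(length(change) == length(shape), length(change) == length(is_if))
  if (any(table(shape) == 0)) {
    empty <- names(which(table(shape) == 0))
    message("dropping empty shape level(s): ", paste(empty, collapse = ", "))
    shape <- droplevels(shape)
  }
  disp2 <- factor(ifelse(as.logical(is_if), "integrated_functional",
                         "other_three"),
                  levels = c("integrated_functional", "other_three"))
  dat <- data.frame(change = change, shape = shape, disp2 = disp2)
  fit <- stats::lm(change ~ shape * disp2, data = dat,
                   contrasts = list(shape = "contr.sum", disp2 = "contr.sum"))
  a3 <- car::Anova(fit, type = 3, singular.ok = TRUE)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  ss_err <- a3["Residuals", "Sum Sq"]
  tab <- data.frame(
    term = rownames(a3)[keep],
    df = a3$Df[keep],
    df_error = a3["Residuals", "Df"],
    F = a3$`F value`[keep],
    partial_eta2 = a3$`Sum Sq`[keep] / (a3$`Sum Sq`[keep] + ss_err),
    p = a3$`Pr(>F)`[keep],
    row.names = NULL
  )
  cells <- stats::aggregate(change ~ shape + disp2, data = dat,
                            FUN = function(z) c(n = length(z), mean = mean(z),
                                                sd = stats::sd(z)))
  cells <- data.frame(cells[1:2], unclass(cells$change))
  structure(list(table = tab, cells = cells, fit = fit),
            class = "scc_anova")
}

#' @export
print.scc_anova <- function(x, ...) {
  cat("Two-factor ANOVA: change ~ shape * disposition (Type III)\n")
  print(transform(x$table, F = round(F, 2),
                  partial_eta2 = round(partial_eta2, 3), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}
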