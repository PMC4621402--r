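#' Disposition labels
#'
#' The four personality dispositions from crossing integrated/disintegrated
#' (baseline SCCS at or above vs below the SCC cutoff) with
#' functional/dysfunctional (baseline KON-2006 below vs at/above the KON
#' cutoff).
#'
#' @return Character vector of the four labels.
#' @export
disposition_levels <- function() {
  c("integrated_functional", "integrated_dysfunctional",
    "disintegrated_functional", "disintegrated_dysfunctional")
}

#' KON-2006 cutoff from the integrated subgroup
#'
#' The median baseline KON-2006 score among subjects whose baseline SCCS is
#' at or above the SCC cutoff ("integrated" subjects). The median is computed
#' on the integrated subgroup only but is then applied to the whole cohort
#' when categorizing dispositions.
#'
#' @param scc_t1 Baseline SCCS scores.
#' @param kon_t1 Baseline KON-2006 scores (same length).
#' @param scc_cutoff Integration cutoff on the SCCS (default 34; `>=` is
#'   integrated).
#' @return The median KON-2006 score of the integrated subgroup.
#' @export
kon_cutoff_from_integrated <- function(scc_t1, kon_t1, scc_cutoff = 34) {
  if (length(scc_t1) != length(kon_t1))
    stop("invalid-argument: scc_t1 and kon_t1 differ in length")
  integ <- scc_t1 >= scc_cutoff
  if (!any(integ))
    stop("invalid-cohort: no subject reaches the SCC integration cutoff")
  stats::median(kon_t1[integ])
}

#' Categorize subjects into the four personality dispositions
#'
#' A subject is "integrated" iff baseline SCCS `>= scc_cutoff` and
#' "functional" iff baseline KON-2006 `< kon_cutoff` (strict). The label is
#' the cross of the two flags.
#'
#' @inheritParams kon_cutoff_from_integrated
#' @param kon_cutoff Functionality cutoff on the KON-2006 (strict `<` is
#'   functional).
#' @return Factor with levels [disposition_levels()], same length as input.
#' @examples
#' categorize_disposition(c(45, 26), c(17, 60), 34, 34)
#' @export
categorize_disposition <- function(scc_t1, kon_t1, scc_cutoff = 34,
                                   kon_cutoff = 34) {
  if (length(scc_t1) != length(kon_t1))
    stop("invalid-argument: scc_t1 and kon_t1 differ in length")
  integrated <- scc_t1 >= scc_cutoff
  functional <- kon_t1 < kon_cutoff
  lab <- ifelse(integrated,
                ifelse(functional, "integrated_functional",
                       "integrated_dysfunctional"),
                ifelse(functional, "disintegrated_functional",
                       "disintegrated_dysfunctional"))
  factor(lab, levels = disposition_levels())
}

#' Cramer's V for a contingency table
#'
#' Effect-size measure of association between two categorical variables:
#' \eqn{V = \sqrt{\chi^2 / (n (\min(r, c) - 1))}} with the uncorrected
#' Pearson chi-square statistic.
#'
#' @param tab A contingency table (matrix of counts).
#' @return V in \[0, 1\].
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  if (n < 1 || any(dim(tab) < 2))
    stop("invalid-argument: table needs at least 2 non-empty rows and columns")
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  unname(sqrt(chi2 / (n * (min(dim(tab)) - 1))))
}

#' Validate the disposition split against k-means clusters
#'
#' Runs k-means (default k = 4, multiple restarts, seeded) on the
#' z-standardized baseline (SCCS, KON-2006) pairs and cross-tabulates the
#' cluster assignment against the cutoff-based disposition labels. Agreement
#' is summarized by Cramer's V: values near 1 mean the two categorizations
#' coincide up to relabeling.
#'
#' @inheritParams kon_cutoff_from_integrated
#' @param labels Disposition labels (factor or character), one per subject.
#' @param k Number of clusters (default 4; must be >= 2).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of random restarts (default 10).
#' @return An object of class `"cluster_validation"`: list with
#'   `contingency` (k x 4 count matrix), `cramers_v`, `n`.
#' @export
validate_dispositions_kmeans <- function(scc_t1, kon_t1, labels, k = 4,
                                         seed = 1, nstart = 10) {
  n <- length(scc_t1)
  if (k < 2) stop("invalid-cohort: k must be at least 2")
  if (n < k) stop("invalid-cohort: fewer subjects than clusters")
  x <- cbind(scc = scc_t1, kon = kon_t1)
  if (any(apply(x, 2, stats::sd) == 0))
    stop("invalid-cohort: a clustering feature has zero variance")
  xs <- scale(x)
  set.seed(seed)
  km <- stats::kmeans(xs, centers = k, nstart = nstart)
  labels <- factor(labels, levels = disposition_levels())
  tab <- table(cluster = km$cluster, disposition = labels)
  structure(
    list(contingency = unclass(tab), cramers_v = cramers_v(tab), n = n),
    class = "cluster_validation"
  )
}

#' @export
print.cluster_validation <- function(x, ...) {
  r <- nrow(x$contingency); cc <- ncol(x$contingency)
  cat(sprintf("k-means vs disposition split: Cramer's V(%d, N = %d) = %.2f\n",
              (r - 1) * (cc - 1), x$n, x$cramers_v))
  invisible(x)
}
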