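#' Synthetic cohort configuration
#'
#' Study-like defaults for the synthetic repeated-measures cohort: four
#' personality dispositions with fixed sizes 22/21/10/32; baseline SCCS,
#' KON-2006 and KS-II (pre) means/SDs per disposition; per-disposition
#' trajectory-shape frequencies; KS-II change distributions per shape x
#' disposition contrast; and a 3-unit / 7-group clustering layout.
#'
#' Two outcome models are available. `"cells"` (default) draws the KS-II
#' change from a normal per (shape, disposition-contrast) cell; improvement
#' then emerges from the drawn change relative to the 56.6 threshold rather
#' than being assigned first. `"rmse"` generates the change from a linear
#' model on the subject's realized SCC fluctuation with a
#' fluctuation-by-disposition interaction (`rmse_coef`), for
#' parameter-recovery simulations.
#'
#' @param n Named or positional integer vector: subjects per disposition, in
#'   the order of [disposition_levels()].
#' @param k Occasions per subject: a single value (default 6), or a length-2
#'   range from which each subject's k is drawn uniformly.
#' @param noise_sd SD of the Gaussian occasion noise added to the shape
#'   archetype curve (default 1 raw SCCS point).
#' @param scc_rci Reliable-change threshold used to verify archetype
#'   self-consistency (default 3.48).
#' @param baseline Data frame with one row per disposition and columns
#'   `scc_mean`, `scc_sd`, `kon_mean`, `kon_sd`, `ks2_mean`, `ks2_sd`.
#' @param shape_probs 4 x 5 matrix of shape probabilities per disposition
#'   (rows sum to 1); defaults are the empirical shape frequencies per
#'   disposition.
#' @param change_cells Data frame with columns `shape`, `if_mean`, `if_sd`,
#'   `other_mean`, `other_sd`: KS-II change distributions per shape for the
#'   integrated-functional vs pooled-other contrast.
#' @param outcome `"cells"` or `"rmse"`.
#' @param rmse_coef Coefficients (intercept, rmse, is_if, interaction) for
#'   the `"rmse"` outcome model.
#' @param rmse_resid_sd Residual SD for the `"rmse"` outcome model.
#' @param group_sizes,group_units Therapy-group layout: relative sizes of the
#'   7 groups and the unit each belongs to.
#' @return An object of class `"scc_cohort_config"` (a list).
#' @export
scc_cohort_config <- function(
    n = c(integrated_functional = 22, integrated_dysfunctional = 21,
          disintegrated_functional = 10, disintegrated_dysfunctional = 32),
    k = 6,
    noise_sd = 1,
    scc_rci = 3.48,
    baseline = data.frame(
      disposition = disposition_levels(),
      scc_mean = c(45, 41, 28, 26), scc_sd = c(8, 5, 3, 5),
      kon_mean = c(17, 54, 18, 60), kon_sd = c(11, 15, 10, 15),
      ks2_mean = c(233, 315, 260, 339), ks2_sd = c(85, 99, 104, 84)
    ),
    shape_probs = rbind(
      integrated_functional       = c(3, 7, 5, 2, 5) / 22,
      integrated_dysfunctional    = c(4, 9, 3, 2, 3) / 21,
      disintegrated_functional    = c(1, 3, 3, 1, 2) / 10,
      disintegrated_dysfunctional = c(7, 10, 9, 1, 5) / 32
    ),
    change_cells = data.frame(
      shape = shape_levels(),
      if_mean = c(120, 30, 20, 129, -45),
      if_sd = c(60, 116, 80, 58, 50),
      other_mean = c(85, 103, 25, -15, -55),
      other_sd = c(85, 87, 95, 68, 55)
    ),
    outcome = c("cells", "rmse"),
    rmse_coef = c(intercept = 1.92, rmse = 29.76, is_if = 61.25,
                  interaction = -48.49),
    rmse_resid_sd = 80,
    group_sizes = c(9, 9, 9, 16, 16, 13, 13),
    group_units = c(1, 1, 1, 2, 2, 3, 3)) {
  outcome <- match.arg(outcome)
  if (length(n) != 4 || any(n < 1))
    stop("invalid-config: need positive sizes for all four dispositions")
  if (!all(abs(rowSums(shape_probs) - 1) < 1e-8) || any(shape_probs < 0))
    stop("invalid-config: shape probabilities must be non-negative and sum to 1 per disposition")
  if (any(c(baseline$scc_sd, baseline$kon_sd, baseline$ks2_sd) < 0) ||
      any(c(change_cells$if_sd, change_cells$other_sd) < 0))
    stop("invalid-config: SDs must be non-negative")
  if (length(group_sizes) != length(group_units))
    stop("invalid-config: group_sizes and group_units differ in length")
  if (any(k < 4) || any(k > 9) || length(k) > 2)
    stop("invalid-config: k must be a value or range within 4..9")
  structure(
    list(n = n, k = k, noise_sd = noise_sd, scc_rci = scc_rci,
         baseline = baseline, shape_probs = shape_probs,
         change_cells = change_cells, outcome = outcome,
         rmse_coef = rmse_coef, rmse_resid_sd = rmse_resid_sd,
         group_sizes = group_sizes, group_units = group_units,
         scc_range = c(12, 60), ks2_range = c(0, 595),
         kon_range = c(0, 235)),
    class = "scc_cohort_config"
  )
}

# inverse-CDF truncated normal draw, vectorized over mean/sd
# (deterministic under set.seed)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  out <- stats::qnorm(p, mean, sd)
  deg <- rep_len(sd, n) == 0
  if (any(deg)) out[deg] <- pmin(pmax(rep_len(mean, n)[deg], lo), hi)
  out
}

# Step sizes (consecutive-occasion differences) of the noise-free archetype
# curve for each shape, sized so that every intended reliable change clears
# the 3.48 threshold with margin against occasion noise.
archetype_steps <- function(shape, k) {
  if (k < 4) stop("invalid-config: archetypes need at least 4 occasions")
  switch(shape,
    monotonic_increase  = c(7, rep(1, k - 2)),
    monotonic_decrease  = c(-7, rep(-1, k - 2)),
    v_shape             = c(1, -7, 8, rep(1, k - 4)),
    discontinuous_other = c(9, -6, -6, rep(1, k - 4)),
    plateau             = rep(0, k - 1),
    stop("invalid-config: unknown shape ", shape)
  )
}

#' Generate a synthetic study-like cohort
#'
#' Draws a cohort with known ground truth: fixed disposition sizes; baseline
#' SCCS/KON-2006/KS-II from truncated normals within instrument ranges; a
#' trajectory shape per subject from the per-disposition frequencies; an
#' archetype SCC curve anchored at the subject's baseline SCCS (clamped so
#' the noise-free curve stays within 12-60) plus Gaussian occasion noise; and
#' a KS-II post score implied by the drawn change. Deterministic given
#' `seed`.
#'
#' @param config An [scc_cohort_config()].
#' @param seed Integer seed.
#' @return An object of class `"scc_cohort"`: list with `subjects` (one row
#'   per subject, including ground-truth `true_shape` and
#'   `true_disposition`), `long` (the long-format measurement table), and
#'   `config`.
#' @export
simulate_scc_cohort <- function(config = scc_cohort_config(), seed = 1) {
  stopifnot(inherits(config, "scc_cohort_config"))
  set.seed(seed)
  disp <- disposition_levels()
  n_total <- sum(config$n)
  true_disposition <- factor(rep(disp, times = config$n), levels = disp)
  id <- sprintf("S%03d", seq_len(n_total))

  # clustering layout
  gprob <- config$group_sizes / sum(config$group_sizes)
  grp <- sample(seq_along(config$group_sizes), n_total, replace = TRUE,
                prob = gprob)
  group_id <- sprintf("G%d", grp)
  unit_id <- sprintf("U%d", config$group_units[grp])

  b <- config$baseline[match(true_disposition, config$baseline$disposition), ]
  scc_t1 <- rtruncnorm(n_total, b$scc_mean, b$scc_sd,
                       config$scc_range[1], config$scc_range[2])
  kon_t1 <- rtruncnorm(n_total, b$kon_mean, b$kon_sd,
                       config$kon_range[1], config$kon_range[2])
  ks2_pre <- rtruncnorm(n_total, b$ks2_mean, b$ks2_sd,
                        config$ks2_range[1], config$ks2_range[2])

  true_shape <- character(n_total)
  for (d in disp) {
    idx <- which(true_disposition == d)
    true_shape[idx] <- sample(shape_levels(), length(idx), replace = TRUE,
                              prob = config$shape_probs[d, ])
  }
  true_shape <- factor(true_shape, levels = shape_levels())

  k_i <- if (length(config$k) == 2)
    sample(config$k[1]:config$k[2], n_total, replace = TRUE)
  else rep(config$k, n_total)

  series <- vector("list", n_total)
  rmse_i <- numeric(n_total)
  for (i in seq_len(n_total)) {
    steps <- archetype_steps(as.character(true_shape[i]), k_i[i])
    cs <- cumsum(steps)
    lo <- config$scc_range[1] - min(0, min(cs))
    hi <- config$scc_range[2] - max(0, max(cs))
    start <- min(max(scc_t1[i], lo), hi)
    curve <- start + c(0, cs)
    if (classify_shape(curve, config$scc_rci) != as.character(true_shape[i]))
      stop("invalid-config: archetype is not self-consistent at zero noise")
    scores <- curve + stats::rnorm(k_i[i], 0, config$noise_sd)
    scores <- pmin(pmax(scores, config$scc_range[1]), config$scc_range[2])
    scc_t1[i] <- scores[1]
    series[[i]] <- scores
    rmse_i[i] <- fluctuation_rmse(scores)
  }

  is_if <- true_disposition == "integrated_functional"
  if (config$outcome == "cells") {
    cc <- config$change_cells[match(true_shape, config$change_cells$shape), ]
    mu <- ifelse(is_if, cc$if_mean, cc$other_mean)
    sg <- ifelse(is_if, cc$if_sd, cc$other_sd)
    change_draw <- stats::rnorm(n_total, mu, sg)
  } else {
    bcoef <- config$rmse_coef
    change_draw <- bcoef[["intercept"]] + bcoef[["rmse"]] * rmse_i +
      bcoef[["is_if"]] * is_if + bcoef[["interaction"]] * is_if * rmse_i +
      stats::rnorm(n_total, 0, config$rmse_resid_sd)
  }
  ks2_post <- pmin(pmax(ks2_pre - change_draw,
                        config$ks2_range[1]), config$ks2_range[2])

  subjects <- data.frame(
    subject_id = id, unit_id = unit_id, group_id = group_id,
    scc_t1 = scc_t1, kon_t1 = kon_t1,
    ks2_pre = ks2_pre, ks2_post = ks2_post,
    change = ks2_pre - ks2_post,
    improved = (ks2_pre - ks2_post) > 56.6,
    true_shape = true_shape, true_disposition = true_disposition,
    k = k_i, rmse = rmse_i,
    stringsAsFactors = FALSE
  )

  long <- do.call(rbind, lapply(seq_len(n_total), function(i) {
    k <- k_i[i]
    data.frame(
      subject_id = id[i], unit_id = unit_id[i], group_id = group_id[i],
      occasion = seq_len(k), week = 2 * (seq_len(k) - 1L),
      sccs = series[[i]],
      ks2 = c(ks2_pre[i], rep(NA_real_, k - 2), ks2_post[i]),
      kon = c(kon_t1[i], rep(NA_real_, k - 1)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(long) <- NULL

  structure(list(subjects = subjects, long = long, config = config,
                 seed = seed),
            class = "scc_cohort")
}

#' @export
print.scc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic SCC cohort: %d subjects, %d measurements (seed %d)\n",
              nrow(x$subjects), nrow(x$long), x$seed))
  print(table(x$subjects$true_disposition, x$subjects$true_shape))
  invisible(x)
}

#' Write the bundled fixture cohort
#'
#' Writes the small long-format CSV fixture (24 subjects, 5 occasions, low
#' occasion noise) plus its ground-truth sidecar. Regeneration is
#' byte-identical for a given seed.
#'
#' @param dir Output directory.
#' @param seed Integer seed (default 42, the bundled fixture's seed).
#' @return Invisibly, the paths of the two files written.
#' @export
write_fixture_cohort <- function(dir, seed = 42) {
  cfg <- scc_cohort_config(n = c(6, 6, 6, 6), k = 5, noise_sd = 0.25)
  coh <- simulate_scc_cohort(cfg, seed = seed)
  long <- coh$long
  long$sccs <- round(long$sccs, 2)
  long$ks2 <- round(long$ks2, 1)
  long$kon <- round(long$kon, 1)
  truth <- coh$subjects[, c("subject_id", "true_disposition", "true_shape")]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- file.path(dir, "scc_fixture.csv")
  f2 <- file.path(dir, "scc_fixture_truth.csv")
  utils::write.csv(long, f1, row.names = FALSE, quote = FALSE)
  utils::write.csv(truth, f2, row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2))
}
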