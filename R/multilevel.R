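# Three-level variance-components null model for the pre-post change score:
# subjects (level 1) nested in therapy groups (level 2) nested in units
# (level 3). Point estimates come from lme4; Wald z = estimate / SE uses a
# numerical Hessian of the directly-coded REML deviance, since lme4 does not
# report standard errors for variance components.

# -2 * REML log-likelihood of the intercept-only model as a function of the
# variance components (residual, group, unit). Zg / Zu are indicator
# matrices; either may be NULL when that level is absent.
neg2_reml_vc <- function(v, y, Zg, Zu) {
  n <- length(y)
  V <- diag(v[1], n)
  if (!is.null(Zg)) V <- V + v[2] * tcrossprod(Zg)
  if (!is.null(Zu)) V <- V + v[3] * tcrossprod(Zu)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e12)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  xvx <- sum(Vi_1)
  beta <- sum(Vi_y) / xvx
  r <- y - beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  logdetV + log(xvx) + sum(r * Vi_r)
}

#' Three-level variance-components null model
#'
#' Fits the intercept-only random-effects model for the pre-post symptom
#' change score with random intercepts for therapy group (level 2) and
#' therapeutic unit (level 3), by REML via [lme4::lmer()]. Returns the three
#' variance components with Wald statistics (estimate / SE, normal
#' reference), computed from the curvature of the REML deviance. The Wald
#' test is a boundary-unfriendly approximation for variance parameters and
#' is reported `NA` for components estimated at (numerically) zero.
#'
#' If only one unit (or one group) is present, the corresponding component is
#' reported as 0 with a notice.
#'
#' @param change Change scores, one per subject.
#' @param group Therapy-group identifiers.
#' @param unit Therapeutic-unit identifiers; each group must belong to
#'   exactly one unit.
#' @return An object of class `"scc_varcomp"`: list with `components`
#'   (data.frame: parameter, estimate, wald_z, p), `intercept`, `n`.
#' @export
variance_components_null <- function(change, group, unit) {
  n <- length(change)
  stopifnot(length(group) == n, length(unit) == n)
  g2u <- tapply(as.character(unit), as.character(group),
                function(u) length(unique(u)))
  if (any(g2u > 1))
    stop("invalid-argument: a therapy group belongs to more than one unit")
  unit <- factor(unit)
  group <- factor(paste(as.character(unit), as.character(group), sep = ":"))
  comp <- data.frame(parameter = c("residual", "var_group", "var_unit"),
                     estimate = c(0, 0, 0), wald_z = NA_real_, p = NA_real_)

  if (stats::sd(change) == 0) {
    message("all change scores identical; all variance components are 0")
    return(structure(list(components = comp, intercept = change[1], n = n),
                     class = "scc_varcomp"))
  }

  has_unit <- nlevels(unit) > 1
  has_group <- nlevels(group) > 1
  if (!has_unit) message("single unit: level-3 variance reported as 0")
  if (!has_group) message("single group: level-2 variance reported as 0")

  if (!has_group && !has_unit) {
    comp$estimate[1] <- stats::var(change)  # REML residual = sample variance
    se <- comp$estimate[1] * sqrt(2 / (n - 1))
    comp$wald_z[1] <- comp$estimate[1] / se
    comp$p[1] <- 2 * stats::pnorm(-abs(comp$wald_z[1]))
    return(structure(list(components = comp, intercept = mean(change), n = n),
                     class = "scc_varcomp"))
  }

  form <- if (has_unit && has_group) change ~ 1 + (1 | unit) + (1 | group)
          else change ~ 1 + (1 | group)
  dat <- data.frame(change = change, group = group, unit = unit)
  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  est_resid <- vc$vcov[vc$grp == "Residual"]
  est_group <- if (has_group) vc$vcov[vc$grp == "group"] else 0
  est_unit <- if (has_unit) vc$vcov[vc$grp == "unit"] else 0
  comp$estimate <- c(est_resid, est_group, est_unit)

  # Wald SEs from the REML deviance Hessian at the estimates, over the
  # components not stuck at the zero boundary.
  Zg <- if (has_group) stats::model.matrix(~ 0 + group, dat) else NULL
  Zu <- if (has_unit) stats::model.matrix(~ 0 + unit, dat) else NULL
  v_hat <- comp$estimate
  tol <- 1e-6 * stats::var(change)
  free <- which(c(TRUE, has_group, has_unit) & v_hat > tol)
  if (length(free)) {
    f <- function(par) {
      v <- v_hat
      v[free] <- par
      neg2_reml_vc(v, change, Zg, Zu)
    }
    H <- tryCatch(stats::optimHess(v_hat[free], f), error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cv)) {
        se <- sqrt(pmax(diag(as.matrix(cv)), 0))
        ok <- se > 0
        comp$wald_z[free[ok]] <- v_hat[free[ok]] / se[ok]
        comp$p[free[ok]] <- 2 * stats::pnorm(-abs(comp$wald_z[free[ok]]))
      }
    }
  }
  structure(
    list(components = comp, intercept = unname(lme4::fixef(fit)[1]), n = n,
         fit = fit),
    class = "scc_varcomp"
  )
}

#' @export
print.scc_varcomp <- function(x, ...) {
  cat(sprintf("Variance components of the change score (n = %d, REML)\n",
              x$n))
  cat(sprintf("Intercept (grand mean): %.2f\n", x$intercept))
  print(transform(x$components, estimate = round(estimate, 2),
                  wald_z = round(wald_z, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}
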