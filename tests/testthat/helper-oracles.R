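# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Rule-by-rule shape oracle: encode consecutive differences as a symbol
# string (u = reliable increase, d = reliable decrease, n = neither) and
# classify with pattern matching. Vectorized over a matrix of series.
oracle_shape <- function(scores, rci = 3.48) {
  d <- diff(scores)
  s <- paste(ifelse(d > rci, "u", ifelse(d < -rci, "d", "n")), collapse = "")
  oracle_shape_from_string(s)
}

oracle_shape_from_string <- function(s) {
  out <- rep("discontinuous_other", length(s))
  out[!grepl("[ud]", s)] <- "plateau"
  has_u <- grepl("u", s, fixed = TRUE)
  has_d <- grepl("d", s, fixed = TRUE)
  out[has_u & !has_d] <- "monotonic_increase"
  out[has_d & !has_u] <- "monotonic_decrease"
  out[grepl("^[^d]*du[^d]*$", s)] <- "v_shape"
  out
}

# matrix of series (rows) -> oracle labels, vectorized
oracle_shape_matrix <- function(m, rci = 3.48) {
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  sym <- matrix("n", nrow(d), ncol(d))
  sym[d > rci] <- "u"
  sym[d < -rci] <- "d"
  s <- do.call(paste0, asplit(sym, 2))
  oracle_shape_from_string(s)
}

# Closed-form OLS on the (1, ln t) design via explicit normal equations.
oracle_log_ols <- function(y, t = seq_along(y)) {
  X <- cbind(1, log(t))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- as.numeric(X %*% beta)
  list(intercept = beta[1], slope = beta[2], fitted = fitted,
       rmse = sqrt(sum((y - fitted)^2) / length(y)))
}

# Algebraic form of the likelihood-ratio statistic on a 2x2 table of
# proportions: G = 2 n sum p log(p / (prow pcol)).
oracle_g_algebraic <- function(a, b, c, d) {
  n <- a + b + c + d
  p <- c(a, b, c, d) / n
  pr <- c(a + b, a + b, c + d, c + d) / n
  pc <- c(a + c, b + d, a + c, b + d) / n
  2 * n * sum(ifelse(p > 0, p * log(p / (pr * pc)), 0))
}

# Table 5 of the study as per-subject labels: disposition x shape x
# improvement counts expanded into a data frame. Used as in-paper input for
# the G-test battery.
table5_subjects <- function() {
  counts <- rbind(
    # disposition, shape, improved n, not-improved n
    c("integrated_functional", "monotonic_increase", 3, 0),
    c("integrated_functional", "v_shape", 4, 3),
    c("integrated_functional", "discontinuous_other", 2, 3),
    c("integrated_functional", "plateau", 2, 0),
    c("integrated_functional", "monotonic_decrease", 0, 5),
    c("integrated_dysfunctional", "monotonic_increase", 1, 3),
    c("integrated_dysfunctional", "v_shape", 6, 3),
    c("integrated_dysfunctional", "discontinuous_other", 1, 2),
    c("integrated_dysfunctional", "plateau", 0, 2),
    c("integrated_dysfunctional", "monotonic_decrease", 0, 3),
    c("disintegrated_functional", "monotonic_increase", 0, 1),
    c("disintegrated_functional", "v_shape", 1, 2),
    c("disintegrated_functional", "discontinuous_other", 2, 1),
    c("disintegrated_functional", "plateau", 0, 1),
    c("disintegrated_functional", "monotonic_decrease", 0, 2),
    c("disintegrated_dysfunctional", "monotonic_increase", 6, 1),
    c("disintegrated_dysfunctional", "v_shape", 9, 1),
    c("disintegrated_dysfunctional", "discontinuous_other", 2, 7),
    c("disintegrated_dysfunctional", "plateau", 0, 1),
    c("disintegrated_dysfunctional", "monotonic_decrease", 0, 5)
  )
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n_imp <- as.integer(counts[i, 3]); n_no <- as.integer(counts[i, 4])
    if (n_imp + n_no == 0) return(NULL)
    data.frame(disposition = counts[i, 1], shape = counts[i, 2],
               improved = rep(c(TRUE, FALSE), c(n_imp, n_no)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
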