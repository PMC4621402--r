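test_that("cohort generation is deterministic given the seed", {
  a <- simulate_scc_cohort(seed = 123)
  b <- simulate_scc_cohort(seed = 123)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$long, b$long)
  c2 <- simulate_scc_cohort(seed = 124)
  expect_false(identical(a$long$sccs, c2$long$sccs))
})

test_that("disposition sizes are fixed, not sampled", {
  coh <- simulate_scc_cohort(seed = 2)
  expect_equal(unname(table(coh$subjects$true_disposition)),
               c(22, 21, 10, 32), ignore_attr = TRUE)
  expect_equal(nrow(coh$subjects), 85)
})

test_that("zero occasion noise recovers every true shape", {
  cfg <- scc_cohort_config(noise_sd = 0)
  coh <- simulate_scc_cohort(cfg, seed = 3)
  got <- vapply(split(coh$long$sccs, coh$long$subject_id), classify_shape, "")
  truth <- coh$subjects$true_shape[match(names(got), coh$subjects$subject_id)]
  expect_equal(unname(got), as.character(truth))
})

test_that("scores stay within instrument ranges and series have the configured length", {
  coh <- simulate_scc_cohort(seed = 4)
  expect_true(all(coh$long$sccs >= 12 & coh$long$sccs <= 60))
  expect_true(all(coh$subjects$ks2_pre >= 0 & coh$subjects$ks2_pre <= 595))
  expect_true(all(coh$subjects$ks2_post >= 0 & coh$subjects$ks2_post <= 595))
  expect_true(all(table(coh$long$subject_id) == 6))
  expect_equal(coh$subjects$scc_t1[match(coh$long$subject_id[coh$long$occasion == 1],
                                         coh$subjects$subject_id)],
               coh$long$sccs[coh$long$occasion == 1])
  # variable series lengths when a range is configured
  cfg <- scc_cohort_config(k = c(4, 9))
  coh2 <- simulate_scc_cohort(cfg, seed = 4)
  expect_true(all(table(coh2$long$subject_id) >= 4 &
                    table(coh2$long$subject_id) <= 9))
})

test_that("generated outcome cells converge to their configured means", {
  set.seed(0)
  vals <- c()
  for (s in 1:40) {
    coh <- simulate_scc_cohort(seed = 1000 + s)
    sub <- coh$subjects
    cell <- sub$true_shape == "v_shape" &
      sub$true_disposition != "integrated_functional"
    vals <- c(vals, sub$change[cell])
  }
  # configured (non-IF, V-shape) change distribution: mean 103, SD 87
  expect_lt(abs(mean(vals) - 103), 3 * 87 / sqrt(length(vals)) + 2)
})

test_that("the auto KON cutoff lands near the study's 34 on default cohorts", {
  meds <- vapply(1:30, function(s) {
    coh <- simulate_scc_cohort(seed = 2000 + s)
    kon_cutoff_from_integrated(coh$subjects$scc_t1, coh$subjects$kon_t1, 34)
  }, 0)
  expect_lt(abs(mean(meds) - 34), 5)
})

test_that("shape recovery degrades as occasion noise grows", {
  acc <- vapply(c(0.5, 2.5), function(ns) {
    cfg <- scc_cohort_config(noise_sd = ns)
    hits <- vapply(1:5, function(s) {
      coh <- simulate_scc_cohort(cfg, seed = 3000 + s)
      got <- vapply(split(coh$long$sccs, coh$long$subject_id),
                    classify_shape, "")
      truth <- coh$subjects$true_shape[match(names(got),
                                             coh$subjects$subject_id)]
      mean(got == as.character(truth))
    }, 0)
    mean(hits)
  }, 0)
  expect_gt(acc[1], acc[2])
})

test_that("invalid configurations are rejected", {
  expect_error(scc_cohort_config(n = c(1, 2, 3)), "invalid-config")
  expect_error(scc_cohort_config(shape_probs = rbind(
    c(0.5, 0.5, 0, 0, 0.5), c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0),
    c(1, 0, 0, 0, 0))), "invalid-config")
  expect_error(scc_cohort_config(k = 3), "invalid-config")
})

test_that("the bundled fixture regenerates byte-identically", {
  tmp <- tempfile("fixture"); dir.create(tmp)
  tmp2 <- tempfile("fixture2"); dir.create(tmp2)
  on.exit(unlink(c(tmp, tmp2), recursive = TRUE), add = TRUE)
  paths <- write_fixture_cohort(tmp, seed = 42)
  shipped <- system.file("extdata", c("scc_fixture.csv", "scc_fixture_truth.csv"),
                         package = "sccproc")
  for (i in 1:2) {
    expect_identical(readLines(paths[i]), readLines(shipped[i]))
  }
  # same seed twice: identical bytes
  paths2 <- write_fixture_cohort(tmp2, seed = 42)
  expect_identical(readLines(paths[1]), readLines(paths2[1]))
})

test_that("the fixture's classified shapes match its embedded ground truth", {
  fx <- system.file("extdata", "scc_fixture.csv", package = "sccproc")
  truth <- read.csv(system.file("extdata", "scc_fixture_truth.csv",
                                package = "sccproc"))
  long <- read_scc_long(fx)
  got <- vapply(split(long$sccs, long$subject_id), classify_shape, "")
  expect_equal(unname(got[truth$subject_id]), truth$true_shape)
})
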