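test_that("a constant series yields no calls", {
  s <- lh_series(seq(0, 150, 5), rep(2, 31))
  expect_equal(nrow(detect_pulses(s)), 0)
})

test_that("noise-free rendered pulses are recovered within one sample, with no extras", {
  g <- lh_gen_params(mu_ipi = 25, amp_mean = 2, amp_cv = 0.2,
                     baseline = 0.2, assay_cv = 0)
  for (s in 1:10) {
    tr <- sample_pulse_times(g, c(0, 150), rng_seed = 100 + s)
    clean <- render_lh(tr, g, rng_seed = 200 + s)
    calls <- detect_pulses(clean)$time_min
    expect_equal(length(calls), length(tr))
    for (tt in tr) expect_lte(min(abs(calls - tt)), 5)
  }
})

test_that("detector meets its sensitivity and false-call targets on noisy cohorts", {
  g <- lh_gen_params(mu_ipi = 25)
  det <- detector_params()
  hits <- 0; truths <- 0; extras <- 0; hours <- 0
  for (s in 1:50) {
    cohort <- generate_cohort(g, g, n_animals = 1, seed = 5000 + s)
    a <- cohort[[1]]
    calls <- detect_pulses(a$series, det)$time_min
    truths <- truths + length(a$train)
    for (tt in a$train) if (any(abs(calls - tt) <= 5.01)) hits <- hits + 1
    extras <- extras +
      sum(vapply(calls, function(cc) all(abs(a$train - cc) > 5.01),
                 logical(1)))
    hours <- hours + 2.5
  }
  expect_gte(hits / truths, 0.9)
  expect_lte(extras / hours, 0.1)
})

test_that("shifting the sampling grid by one sample shifts all calls equally", {
  g <- lh_gen_params(mu_ipi = 25, assay_cv = 0)
  tr <- sample_pulse_times(g, c(10, 140), rng_seed = 3)
  clean <- render_lh(tr, g, rng_seed = 4)
  shifted <- lh_series(clean$time_min + 5, clean$lh_ngml)
  a <- detect_pulses(clean)$time_min
  b <- detect_pulses(shifted)$time_min
  expect_equal(b, a + 5)
})

test_that("irregular grids and too-short series are rejected", {
  expect_error(detect_pulses(lh_series(c(0, 5), c(1, 2))), "3 samples")
  s <- lh_series(seq(0, 150, 5), rep(1, 31))
  s$time_min[10] <- 47
  expect_error(detect_pulses(s), "regular")
})

test_that("window interval means follow the censoring convention", {
  r <- compute_ipi(c(10, 35, 60), c(0, 60))
  expect_equal(r$mean_ipi, 25)
  expect_equal(r$n_pulses, 3L)
  expect_false(r$censored)
  # a call exactly at the window boundary belongs to the earlier window
  expect_equal(compute_ipi(c(10, 35, 60), c(60, 150))$n_pulses, 0L)
  none <- compute_ipi(numeric(0), c(60, 150))
  expect_true(none$censored)
  expect_equal(none$mean_ipi, 90)
  one <- compute_ipi(70, c(60, 150))
  expect_true(one$censored)
  expect_equal(one$mean_ipi, 90)
})

test_that("arm summaries report group means and SEM", {
  mk <- function(pre, post) list(
    pre = compute_ipi(cumsum(c(5, rep(pre, 3))), c(0, 60)),
    post = compute_ipi(60 + cumsum(c(5, rep(post, 3))), c(60, 150)))
  res <- list(mk(20, 20), mk(25, 25), mk(30, 30))
  s <- summarize_arm(res, arm = "demo")
  expect_equal(s$pre_mean, 25)
  expect_equal(s$pre_sem, sd(c(20, 25, 30)) / sqrt(3))
  expect_equal(s$per_animal$delta_ipi, rep(0, 3))
  # all-censored post windows collapse to the 90-min ceiling with zero SEM
  cens <- lapply(1:3, function(i) list(
    pre = compute_ipi(c(10, 30, 50), c(0, 60)),
    post = compute_ipi(numeric(0), c(60, 150))))
  sc <- summarize_arm(cens, arm = "cens")
  expect_equal(sc$post_mean, 90)
  expect_equal(sc$post_sem, 0)
  expect_true(all(sc$per_animal$post_censored))
  expect_error(summarize_arm(list()), "empty")
})

test_that("the repeated-measures comparison needs at least two complete arms", {
  g <- lh_gen_params()
  one <- summarize_arm(lapply(1:3, function(i) list(
    pre = compute_ipi(c(10, 30, 50), c(0, 60)),
    post = compute_ipi(c(70, 95, 120), c(60, 150)))), arm = "a")
  expect_error(compare_windows(list(one)), "two arms")
})

test_that("the interaction test holds its nominal size under the null", {
  gen_summary <- function(arm, seed) {
    g <- lh_gen_params(mu_ipi = 25)
    cohort <- generate_cohort(g, g, n_animals = 7, seed = seed, arm = arm)
    summarize_arm(lapply(cohort, function(a) {
      calls <- detect_pulses(a$series)
      list(pre = compute_ipi(calls, c(0, 60)),
           post = compute_ipi(calls, c(60, 150)))
    }), arm = arm)
  }
  n_rep <- 400
  rej <- 0
  for (r in seq_len(n_rep)) {
    s1 <- gen_summary("a", 10000 + 2 * r)
    s2 <- gen_summary("b", 10001 + 2 * r)
    res <- compare_windows(list(s1, s2))
    p <- res$p[res$effect == "arm:time"]
    if (p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("a true treatment shift is detected in most replicates", {
  n_rep <- 150
  hit <- 0
  for (r in seq_len(n_rep)) {
    pre <- lh_gen_params(mu_ipi = 25)
    sh <- lh_gen_params(mu_ipi = 40)
    mk <- function(post_params, seed, arm) {
      cohort <- generate_cohort(pre, post_params, n_animals = 7,
                                seed = seed)
      summarize_arm(lapply(cohort, function(a) {
        calls <- detect_pulses(a$series)
        list(pre = compute_ipi(calls, c(0, 60)),
             post = compute_ipi(calls, c(60, 150)))
      }), arm = arm)
    }
    s_ctrl <- mk(pre, 30000 + 2 * r, "ctrl")
    s_trt <- mk(sh, 30001 + 2 * r, "trt")
    res <- compare_windows(list(s_ctrl, s_trt))
    if (res$p[res$effect == "arm:time"] < 0.05) hit <- hit + 1
  }
  expect_gt(hit / n_rep, 0.5)
})
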