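test_that("streak context determines suspicion", {
  ## alternation-rich context: a 10-long repetition contradicts the learned
  ## low repetition probability -> suspicious
  alt <- function(n, s = 1L) rep(c(s, 3L - s), length.out = n)
  stim_s <- c(alt(40), rep(1L, 10), alt(330, s = 2L))
  sq_s <- make_seq(stim_s)
  tr_s <- run_observer(hier_observer(pc = 1 / 75, grid_n = 50), sq_s)
  st_s <- classify_streaks(tr_s, find_streaks(sq_s))
  target <- st_s[st_s$start == 41L, ]
  expect_equal(target$label, "suspicious")

  ## repetition-rich context: the same streak is expected -> non-suspicious
  stim_n <- c(rep(1L, 18), 2L, 1L, 2L, rep(1L, 10), 2L, alt(348, s = 1L))
  sq_n <- make_seq(stim_n)
  tr_n <- run_observer(hier_observer(pc = 1 / 75, grid_n = 50), sq_n)
  st_n <- classify_streaks(tr_n, find_streaks(sq_n))
  target_n <- st_n[st_n$start == 22L, ]
  expect_equal(target_n$label, "non_suspicious")

  ## degenerate pc = 0 classification is flagged
  tr0 <- run_observer(hier_observer(pc = 0, grid_n = 20), sq_s)
  expect_warning(classify_streaks(tr0, find_streaks(sq_s)), "degenerate")

  ## streaks outside the trace are refused
  st_bad <- find_streaks(sq_s)
  st_bad$end[1] <- nrow(sq_s) + 5L
  expect_error(classify_streaks(tr_s, st_bad), "beyond")
})

test_that("identical pre and post reports give zero effects", {
  d <- shared_design()
  subj <- generate_subject(shared_hier_trace(), d, noiseless_noise())
  q <- d$questions$trial
  subj$p_report[q] <- 0.6
  subj$conf_report[q] <- 0.4
  eff <- pre_post_change(subj, d)
  expect_true(all(eff$d_conf == 0))
  expect_true(all(eff$d_prob == 0))
})

test_that("missing reports drop the affected streak with a warning", {
  d <- shared_design()
  subj <- generate_subject(shared_hier_trace(), d, noiseless_noise())
  sel <- d$streaks[d$streaks$selected, ]
  subj$p_report[sel$pre_trial[1]] <- NA_real_
  expect_warning(eff <- pre_post_change(subj, d), "dropped")
  expect_equal(nrow(eff), 15L)
})

test_that("model-level effects show the hierarchical confidence signature", {
  d <- shared_design()
  eff_h <- pre_post_change(shared_hier_trace(), d)
  eff_f <- pre_post_change(shared_flat_trace(), d)
  ## hierarchical: strong confidence drop after suspicious streaks only
  m_h <- tapply(eff_h$d_conf, eff_h$label, mean)
  expect_lt(m_h[["suspicious"]], -0.5)
  expect_gt(m_h[["suspicious"]] * -1, m_h[["non_suspicious"]] * -1)
  ## flat: confidence drops after both types with no type difference of the
  ## hierarchical magnitude
  m_f <- tapply(eff_f$d_conf, eff_f$label, mean)
  expect_lt(m_f[["suspicious"]], 0)
  expect_lt(m_f[["non_suspicious"]], 0)
  gap_h <- m_h[["non_suspicious"]] - m_h[["suspicious"]]
  gap_f <- m_f[["non_suspicious"]] - m_f[["suspicious"]]
  expect_gt(gap_h, gap_f + 0.2)
})

test_that("streak-type contrast handles identical effects and sign convention", {
  eff <- data.frame(subject = rep(1:3, each = 4),
                    label = rep(c("suspicious", "non_suspicious"), 6),
                    d_conf = 0.25, d_prob = 0, d_dist = 0)
  out <- streak_type_contrast(eff, "d_conf")
  expect_equal(out$mean, 0)
  expect_equal(out$t, 0)
  ## suspicious drop of -1 vs non-suspicious 0 gives a +1 contrast
  eff$d_conf <- ifelse(eff$label == "suspicious", -1, 0)
  out2 <- streak_type_contrast(eff, "d_conf")
  expect_equal(out2$mean, 1)
  ## subjects missing one type are dropped
  eff3 <- eff[!(eff$subject == 3 & eff$label == "suspicious"), ]
  expect_warning(out3 <- streak_type_contrast(eff3, "d_conf"), "dropped")
  expect_equal(out3$n, 2L)
})

test_that("subject-versus-model regression recovers identity and known slopes", {
  set.seed(16)
  x <- lapply(1:5, function(i) runif(80))
  reg_id <- subject_regression(x, x)
  expect_equal(unname(reg_id$beta$mean), 1, tolerance = 1e-12)
  expect_equal(unname(reg_id$rho_mean), 1, tolerance = 1e-12)

  ## attenuated cohort: slope 0.66 with report noise recovers 0.66
  x <- lapply(1:23, function(i) runif(100))
  y <- lapply(x, function(xx) 0.5 + 0.66 * (xx - 0.5) + rnorm(100, 0, 0.15))
  reg <- subject_regression(y, x)
  expect_lt(abs(reg$beta$mean - 0.66), 2 * reg$beta$sem)
  expect_gt(reg$beta$t, 5)
  expect_error(subject_regression(y, lapply(x, function(z) z * 0 + 0.3)),
               "constant")
})

test_that("residual confidence tracks optimal confidence only when present", {
  set.seed(17)
  n_subj <- 15; n_q <- 120
  make_subj <- function(with_opt) {
    p <- runif(n_q, 0.05, 0.95)
    nxt <- ifelse(runif(n_q) < p, 1L, 2L)
    cov <- first_order_covariates(p, nxt)
    opt <- rnorm(n_q)
    conf <- 0.4 * cov$dist - 0.2 * cov$entropy + 0.05 * cov$surprise +
      rnorm(n_q, 0, 0.05)
    if (with_opt) conf <- conf + 0.1 * opt
    list(conf = conf, opt = opt, cov = cov)
  }
  pure <- lapply(1:n_subj, function(i) make_subj(FALSE))
  out0 <- residual_confidence_test(lapply(pure, `[[`, "conf"),
                                   lapply(pure, `[[`, "opt"),
                                   lapply(pure, `[[`, "cov"))
  expect_lt(abs(out0$beta$mean), 0.02)
  mixed <- lapply(1:n_subj, function(i) make_subj(TRUE))
  out1 <- residual_confidence_test(lapply(mixed, `[[`, "conf"),
                                   lapply(mixed, `[[`, "opt"),
                                   lapply(mixed, `[[`, "cov"))
  expect_gt(out1$beta$mean, 0)
  expect_gt(out1$beta$t, 2)
})

test_that("exclusion is strict below the 0.18 correlation threshold", {
  set.seed(18)
  n <- 100
  x <- as.numeric(scale(rnorm(n)))
  e <- as.numeric(scale(resid(lm(rnorm(n) ~ x))))  # empirically orthogonal to x
  make_y <- function(r) r * x + sqrt(1 - r^2) * e   # sample correlation exactly r
  ys <- list(make_y(0.18 + 1e-6), make_y(0.18 - 1e-6), make_y(0.9),
             make_y(-0.2))
  out <- exclusion_filter(ys, list(x, x, x, x))
  expect_equal(out$rho, c(0.18 + 1e-6, 0.18 - 1e-6, 0.9, -0.2),
               tolerance = 1e-10)
  expect_equal(out$included, c(1L, 3L))   # the threshold itself stays in
  expect_equal(out$excluded, c(2L, 4L))   # strictly below is out
})

test_that("apparent learning rate is the update-to-prediction-error ratio", {
  ## a pure delta rule has a constant apparent rate equal to its alpha
  set.seed(19)
  y <- rbinom(200, 1, 0.7)
  alpha <- 0.13
  m <- numeric(200)
  m[1] <- 0.5
  for (t in 2:200) m[t] <- m[t - 1] + alpha * (y[t] - m[t - 1])
  tr <- make_seq(ifelse(y == 1, 1L, 2L))
  tr$p1 <- m
  lr <- apparent_learning_rate(tr)
  expect_equal(lr, rep(alpha, 199), tolerance = 1e-12)

  ## no update -> 0; jumping to the observation -> 1
  tr$p1 <- rep(0.3, 200)
  expect_equal(apparent_learning_rate(tr), rep(0, 199))
  tr$p1 <- c(0.5, as.numeric(y[-1]))
  lr2 <- apparent_learning_rate(tr)
  expect_true(all(lr2[!is.na(lr2)] == 1))

  ## vanishing prediction errors are masked
  tr$p1 <- as.numeric(y)  # estimate equals the incoming observation at times
  lr3 <- apparent_learning_rate(tr)
  expect_true(anyNA(lr3))
})
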