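test_that("the prior trace starts uniform: estimate one half, log-precision ~ ln 12", {
  tr <- run_observer(hier_observer(pc = 1 / 75, grid_n = 50),
                     make_seq(c(1L)))
  expect_equal(tr$p1[1], 0.5)
  expect_equal(tr$conf[1], log(12), tolerance = 0.01)  # grid-discretized uniform
  ## uncoupled and frequency variants share the prior moments
  tru <- run_observer(hier_observer(pc = 0.1, grid_n = 50,
                                    coupling = "uncoupled"), make_seq(c(2L)))
  expect_equal(tru$p1[1], 0.5)
})

test_that("with pc = 0 the filter reduces to conjugate Beta updating", {
  ## k repetitions of stimulus 1: posterior of p(1|1) is Beta(1 + k, 1)
  k <- 8
  tr <- run_observer(hier_observer(pc = 0, grid_n = 200),
                     make_seq(rep(1L, k + 1)))
  expect_equal(tr$mean11[k + 1], beta_mean(1 + k, 1), tolerance = 1e-3)
  expect_equal(tr$conf11[k + 1], -log(beta_var(1 + k, 1)), tolerance = 1e-2)
})

test_that("with pc = 1 the posterior is re-injected from the prior every trial", {
  set.seed(12)
  tr <- run_observer(hier_observer(pc = 1, grid_n = 20),
                     make_seq(sample(1:2, 60, replace = TRUE)))
  expect_true(all(abs(tr$p1 - 0.5) < 1e-12))
})

test_that("forward filtering matches brute-force change-point enumeration", {
  set.seed(13)
  for (rep in 1:3) {
    T <- sample(4:6, 1)
    G <- 5
    pc <- runif(1, 0.05, 0.6)
    stim <- sample(1:2, T, replace = TRUE)
    tr <- run_observer(hier_observer(pc = pc, grid_n = G), make_seq(stim))
    mo <- oracle_moments(oracle_coupled_joint(stim, pc, G))
    expect_equal(tr$mean11[T], mo$mean11, tolerance = 1e-10)
    expect_equal(tr$var11[T], mo$var11, tolerance = 1e-10)
    expect_equal(tr$mean22[T], mo$mean22, tolerance = 1e-10)
    expect_equal(tr$var22[T], mo$var22, tolerance = 1e-10)
  }
})

test_that("predictions are grid-robust", {
  set.seed(14)
  stim <- sample(1:2, 300, replace = TRUE, prob = c(0.7, 0.3))
  t100 <- run_observer(hier_observer(pc = 0.02, grid_n = 100), make_seq(stim))
  t200 <- run_observer(hier_observer(pc = 0.02, grid_n = 200), make_seq(stim))
  expect_lt(max(abs(t100$p1 - t200$p1)), 1e-4)
})

test_that("the uncoupled filter only diffuses the unobserved transition", {
  ## during a streak of 1s, the p(2|2) chain receives no likelihood: its
  ## estimate decays monotonically toward the prior 0.5 and its confidence
  ## decreases
  stim <- c(rep(2L, 40), rep(1L, 30))
  tr <- run_observer(hier_observer(pc = 0.02, grid_n = 50,
                                   coupling = "uncoupled"), make_seq(stim))
  during <- 42:70  # after the 2->1 alternation, only mixing acts on p(2|2)
  dm <- diff(abs(tr$mean22[during] - 0.5))
  expect_true(all(dm <= 1e-12))
  expect_true(all(diff(tr$conf22[during]) < 0))
})

test_that("coupled and uncoupled filters agree when no change is possible", {
  set.seed(15)
  stim <- sample(1:2, 200, replace = TRUE)
  tc <- run_observer(hier_observer(pc = 0, grid_n = 60), make_seq(stim))
  tu <- run_observer(hier_observer(pc = 0, grid_n = 60,
                                   coupling = "uncoupled"), make_seq(stim))
  ## with pc = 0 the joint stays a product: marginals coincide
  expect_equal(tc$mean11, tu$mean11, tolerance = 1e-10)
  expect_equal(tc$var22, tu$var22, tolerance = 1e-10)
})

test_that("the hierarchical observer resets at block boundaries", {
  stim <- c(rep(1L, 50), rep(2L, 50))
  tr <- run_observer(hier_observer(pc = 0.01, grid_n = 30),
                     make_seq(stim, block = rep(1:2, each = 50)))
  expect_equal(tr$p1[51], 0.5)
  expect_equal(tr$conf[51], tr$conf[1])
})

test_that("sharper posteriors yield strictly larger confidence", {
  tr <- run_observer(hier_observer(pc = 0, grid_n = 100),
                     make_seq(rep(1L, 30)))
  expect_true(all(diff(tr$conf11) > 0))  # each repetition sharpens p(1|1)
})
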