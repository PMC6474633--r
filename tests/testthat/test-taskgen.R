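test_that("stable periods are truncated geometric and tile the block exactly", {
  set.seed(1)
  cfg <- gen_config()
  p <- sample_stable_periods(cfg, 1520)
  expect_identical(sum(p), 1520L)
  expect_true(all(p <= 300))
  expect_true(all(p >= 1))

  expect_true(all(sample_stable_periods(gen_config(mean_period = 1), 50) == 1))
  expect_error(sample_stable_periods(gen_config(mean_period = 75,
                                                change_prob = 0), -1))
  expect_error(gen_config(mean_period = 0), "positive")
})

test_that("empirical period mean matches the truncated-geometric expectation", {
  set.seed(2)
  cfg <- gen_config()
  p <- sample_stable_periods(cfg, 75 * 1e5)
  p <- p[-length(p)]  # last period is truncated to fit, not a fair draw
  o <- truncated_geom_moments(75, 300)
  z <- (mean(p) - o$mean) / sqrt(o$var / length(p))
  expect_lt(abs(z), 2)
})

test_that("transition-probability draws respect range and odds-fold constraint", {
  set.seed(3)
  cfg <- gen_config()
  first <- sample_transition_probs(cfg)
  expect_true(all(first >= 0.1 & first <= 0.9))

  ## from p = 0.5 (odds 1), a fourfold step forces p >= 0.8 or p <= 0.2
  for (i in 1:200) {
    nxt <- sample_transition_probs(cfg, prev = c(0.5, 0.5))
    fold <- odds_fold <- pmax((nxt / (1 - nxt)), ((1 - nxt) / nxt))
    ok <- nxt >= 0.8 | nxt <= 0.2
    expect_true(any(ok))
  }

  ## constraint holds on at least one coordinate for arbitrary prev
  for (i in 1:500) {
    prev <- runif(2, 0.1, 0.9)
    nxt <- sample_transition_probs(cfg, prev = prev)
    o <- function(p) p / (1 - p)
    fold <- pmax(o(nxt) / o(prev), o(prev) / o(nxt))
    expect_true(any(fold >= 4 - 1e-12))
    expect_true(all(nxt >= 0.1 & nxt <= 0.9))
  }

  ## infeasible fold raises (odds range on [0.1, 0.9] spans at most 81-fold)
  expect_error(sample_transition_probs(gen_config(min_odds_fold = 100),
                                       prev = c(0.5, 0.5), max_tries = 200L),
               "odds-fold")
})

test_that("coupled blocks share change points; the no-change limit is constant", {
  set.seed(4)
  blk <- generate_block(gen_config())
  expect_identical(blk$cp1, blk$cp2)
  expect_equal(nrow(blk), 380L)
  expect_true(all(blk$stim %in% 1:2))

  quiet <- generate_block(gen_config(mean_period = 1e6, max_period = 1e9,
                                     change_prob = 1e-6))
  expect_false(any(quiet$cp1))
  expect_equal(length(unique(quiet$p11)), 1L)
  expect_equal(length(unique(quiet$p22)), 1L)
})

test_that("stimuli follow the generative repetition probability", {
  set.seed(5)
  ## narrow probability range pins the repetition probability near 0.8
  cfg <- gen_config(prob_low = 0.79, prob_high = 0.81, min_odds_fold = 1)
  reps <- tot <- 0
  for (i in 1:200) {
    blk <- generate_block(cfg)
    prev1 <- which(blk$stim[-380] == 1L)
    reps <- reps + sum(blk$stim[prev1 + 1L] == 1L)
    tot <- tot + length(prev1)
  }
  phat <- reps / tot
  se <- sqrt(0.8 * 0.2 / tot)
  expect_lt(abs(phat - 0.8), 2 * se + 0.01)  # 0.01 covers the 0.79-0.81 spread
})

test_that("uncoupled change points are independent across the two probabilities", {
  set.seed(6)
  cfg <- gen_config(coupled = FALSE)
  cp1 <- cp2 <- logical(0)
  for (i in 1:150) {
    blk <- generate_block(cfg)
    cp1 <- c(cp1, blk$cp1)
    cp2 <- c(cp2, blk$cp2)
    ## the redrawn coordinate satisfies the fold constraint by itself
    for (t in which(blk$cp1)) {
      o <- function(p) p / (1 - p)
      f <- max(o(blk$p11[t]) / o(blk$p11[t - 1]),
               o(blk$p11[t - 1]) / o(blk$p11[t]))
      expect_gte(f, 4 - 1e-9)
    }
  }
  r <- cor(cp1, cp2)
  expect_lt(abs(r), 3 / sqrt(length(cp1)))
})

test_that("streak detection applies the length-7 and after-15th-stimulus rules", {
  ## alternating filler, then embedded runs
  alt <- function(n, start = 1L) rep(c(start, 3L - start), length.out = n)
  ## filler ends on symbol 2 so the embedded run of 1s is exactly maximal
  stim <- c(alt(19, start = 2L), rep(1L, 7), alt(354, start = 2L))
  st <- find_streaks(make_seq(stim))
  expect_equal(nrow(st), 1L)
  expect_equal(st$start, 20L)
  expect_equal(st$length, 7L)
  expect_equal(st$symbol, 1L)
  expect_true(st$terminated)

  ## run of 6 is not a streak
  stim6 <- c(alt(19, start = 2L), rep(1L, 6), alt(355, start = 2L))
  expect_equal(nrow(find_streaks(make_seq(stim6))), 0L)

  ## run of 10 starting at block trial 10 is excluded
  stim10 <- c(alt(9, start = 2L), rep(1L, 10), alt(361, start = 2L))
  expect_equal(nrow(find_streaks(make_seq(stim10))), 0L)

  ## runs never merge across block boundaries
  two <- make_seq(c(alt(370), rep(1L, 10), rep(1L, 10), alt(370, start = 2L)),
                  block = rep(1:2, each = 380))
  st2 <- find_streaks(two)
  expect_equal(nrow(st2), 1L)  # block-2 run starts at local trial 1 < 16
  expect_false(st2$terminated)
})

test_that("assembled designs meet the question and streak contracts", {
  d <- shared_design()
  q <- d$questions
  expect_equal(nrow(q), 100L)
  expect_equal(sum(q$type %in% c("pre", "post")), 32L)
  expect_equal(sum(d$streaks$selected), 16L)
  expect_equal(table(d$streaks$label[d$streaks$selected])[["suspicious"]], 8L)
  expect_equal(table(d$streaks$label[d$streaks$selected])[["non_suspicious"]], 8L)
  expect_false(anyDuplicated(q$trial) > 0)

  ## random questions are never adjacent to any other question
  rq <- q$trial[q$type == "random"]
  others <- q$trial
  for (t in rq) expect_true(all(abs(t - setdiff(others, t)) >= 2))

  ## pre and post questions probe the non-repeating transition: the stimulus
  ## just observed at both question trials is the non-repeated symbol
  sel <- d$streaks[d$streaks$selected, ]
  expect_true(all(d$sequence$stim[sel$pre_trial] == 3L - sel$symbol))
  expect_true(all(d$sequence$stim[sel$post_trial] == 3L - sel$symbol))

  ## selected streak durations are matched between labels
  dur <- tapply(sel$length, sel$label, mean)
  expect_lte(abs(dur[["suspicious"]] - dur[["non_suspicious"]]),
             d$meta$duration_tol)
})

test_that("design regeneration from the stored seed is bit-exact", {
  obs <- hier_observer(pc = 1 / 75, grid_n = 25)
  d1 <- assemble_experiment(gen_config(), observer = obs, seed = 77L)
  d2 <- assemble_experiment(gen_config(), observer = obs, seed = 77L)
  expect_identical(d1$sequence, d2$sequence)
  expect_identical(d1$questions, d2$questions)
  expect_identical(d1$streaks, d2$streaks)
})

test_that("infeasible selection constraints raise with diagnostics", {
  cfg <- gen_config(n_streak_questions = 200L)  # 50 streaks per label: impossible
  expect_error(assemble_experiment(cfg,
                                   observer = hier_observer(grid_n = 25),
                                   seed = 1, max_tries = 3L),
               "rejections")
})

test_that("yaml round trip of the generative configuration", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("mean_period: 60", "coupled: no", "block_length: 200"), f)
  cfg <- read_gen_config(f)
  expect_equal(cfg$mean_period, 60)
  expect_false(cfg$coupled)
  expect_equal(cfg$block_length, 200L)
  expect_equal(cfg$max_period, 300L)  # defaults fill the rest
  writeLines("not_a_field: 3", f)
  expect_error(read_gen_config(f), "unknown config keys")
})

test_that("design export writes the trial matrix and a JSON sidecar", {
  d <- shared_design()
  f <- file.path(tempdir(), "design.csv")
  write_design(d, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 1520L)
  expect_equal(ncol(tab), 9L)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", f))
  expect_equal(length(side$questions), 100L)  # one object per question row
})
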