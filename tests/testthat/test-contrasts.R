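post_block_cols <- expand.grid(stimulation = c("active", "sham"),
                               block = 1:3, stringsAsFactors = FALSE)

test_that("paired differences match hand-computed mean and SE", {
  vals <- matrix(c(0.5, 0.1,
                   0.3, 0.0,
                   0.2, 0.4,
                   0.6, 0.1), nrow = 4, byrow = TRUE)
  cells <- make_cells(vals, cols = data.frame(
    stimulation = c("active", "sham"), block = 1, stringsAsFactors = FALSE))
  eff <- paired_difference(cells, a = list(stimulation = "active", block = 1),
                           b = list(stimulation = "sham", block = 1))
  d <- c(0.4, 0.3, -0.2, 0.5)
  expect_equal(eff$mean, mean(d))
  expect_equal(eff$se, sd(d) / 2)
  expect_equal(eff$df, 3)
  expect_equal(eff$n, 4)
  expect_false(eff$degenerate)

  same <- make_cells(matrix(0.3, 4, 2), cols = data.frame(
    stimulation = c("active", "sham"), block = 1, stringsAsFactors = FALSE))
  eff0 <- paired_difference(same, a = list(stimulation = "active", block = 1),
                            b = list(stimulation = "sham", block = 1))
  expect_equal(eff0$mean, 0)
  expect_true(eff0$degenerate)

  expect_error(paired_difference(cells[-1, ],
                                 a = list(stimulation = "active", block = 1),
                                 b = list(stimulation = "sham", block = 1)),
               "missing cell")
})

test_that("effect summaries equal a naive recomputation to 1e-12", {
  set.seed(51)
  for (i in 1:20) {
    scores <- rnorm(sample(5:40, 1))
    eff <- rewardbf:::summarize_scores(scores)
    expect_equal(eff$mean, sum(scores) / length(scores), tolerance = 1e-12)
    expect_equal(eff$se, sd(scores) / sqrt(length(scores)), tolerance = 1e-12)
  }
})

test_that("the double-baselined mood index subtracts time then stimulation", {
  cols <- expand.grid(stimulation = c("active", "sham"),
                      phase = c("pre", "post"), stringsAsFactors = FALSE)
  set.seed(52)
  vals <- matrix(rnorm(6 * 4, 25, 4), nrow = 6)
  cells <- make_cells(vals, cols = cols)
  cells$score <- cells$rb

  eff <- double_baseline_index(cells, "pa")
  brute <- vapply(1:6, function(i) {
    (vals[i, cols$stimulation == "active" & cols$phase == "post"] -
       vals[i, cols$stimulation == "active" & cols$phase == "pre"]) -
      (vals[i, cols$stimulation == "sham" & cols$phase == "post"] -
         vals[i, cols$stimulation == "sham" & cols$phase == "pre"])
  }, 0)
  expect_equal(eff$mean, mean(brute), tolerance = 1e-12)
  expect_equal(unname(attr(eff, "contrast_scores")), brute, tolerance = 1e-12)

  # negative affect flips the sign: positive index = NA decreased
  eff_na <- double_baseline_index(cells, "na")
  expect_equal(eff_na$mean, -eff$mean, tolerance = 1e-12)

  # adding a session-wide constant to all four cells changes nothing
  shifted <- cells
  shifted$score <- shifted$score + 7.5
  expect_equal(double_baseline_index(shifted, "pa")$mean, eff$mean,
               tolerance = 1e-12)

  # all four cells equal per participant gives exactly zero
  flat <- make_cells(matrix(rep(c(20, 30, 25, 28), times = 4), nrow = 4),
                     cols = cols)
  flat$score <- flat$rb
  expect_equal(double_baseline_index(flat, "pa")$mean, 0)
})

test_that("the 2x3 interaction contrast applies B1 - .5 B2 - .5 B3 to the differences", {
  # per-block active-sham differences (.3, .1, .1) for everyone
  vals <- matrix(rep(c(0.3, 0, 0.1, 0, 0.1, 0), 5), nrow = 5, byrow = TRUE)
  cells <- make_cells(vals, cols = post_block_cols)
  eff <- interaction_contrast_2x3(cells)
  expect_equal(eff$mean, 0.3 - 0.5 * 0.1 - 0.5 * 0.1)
  expect_true(eff$degenerate)

  # identical active and sham profiles cancel exactly
  same <- make_cells(matrix(rep(c(0.2, 0.2, 0.5, 0.5, 0.9, 0.9), 4),
                            nrow = 4, byrow = TRUE), cols = post_block_cols)
  expect_equal(interaction_contrast_2x3(same)$mean, 0)

  expect_error(interaction_contrast_2x3(cells, weights = c(1, -0.4, -0.5)))
})

test_that("participant-specific constants cancel in the interaction contrast", {
  set.seed(53)
  vals <- matrix(rnorm(8 * 6), nrow = 8)
  cells <- make_cells(vals, cols = post_block_cols)
  base <- interaction_contrast_2x3(cells)
  shifted_vals <- vals + rnorm(8)  # one constant per participant, all cells
  shifted <- make_cells(shifted_vals, cols = post_block_cols)
  eff <- interaction_contrast_2x3(shifted)
  expect_equal(eff$mean, base$mean, tolerance = 1e-12)
  expect_equal(eff$se, base$se, tolerance = 1e-12)
})

test_that("a simulated stimulation-by-block interaction is recovered", {
  set.seed(54)
  true_contrast <- 0.25
  reps <- 100
  est <- numeric(reps)
  for (r in 1:reps) {
    n <- 12
    # active block 1 carries the whole effect; matching the contrast weights
    base <- matrix(rnorm(n * 6, 0, 0.3), nrow = n)
    base[, post_block_cols$stimulation == "active" &
           post_block_cols$block == 1] <-
      base[, post_block_cols$stimulation == "active" &
             post_block_cols$block == 1] + true_contrast
    est[r] <- interaction_contrast_2x3(make_cells(base,
                                                  cols = post_block_cols))$mean
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - true_contrast), 2 * mc_se + 1e-9)
})

test_that("covariate adjustment is identity at slope zero and exact at slope one", {
  cols <- expand.grid(phase = c("pre", "post"),
                      stimulation = c("active", "sham"), block = 1:3,
                      stringsAsFactors = FALSE)
  n <- 10
  ids <- sprintf("P%02d", 1:n)
  x <- setNames(seq(30, 48, length.out = n), ids)
  set.seed(55)
  vals <- matrix(rnorm(n * 12), nrow = n)
  cells <- make_cells(vals, ids = ids, cols = cols)

  # slope exactly zero (constant cell values): adjustment is the identity
  flat <- make_cells(matrix(rep(1:12, each = n), nrow = n, byrow = FALSE),
                     ids = ids, cols = cols)
  flat$rb <- rep(seq(0.1, 1.2, by = 0.1), times = n)
  adj0 <- ancova_adjusted_means(flat, x)
  expect_equal(adj0$rb, flat$rb, tolerance = 1e-9)

  # slope one: cell value = centred covariate + cell constant
  xc <- x - mean(x)
  vals1 <- outer(unname(xc), rep(1, 12)) + matrix(rep(1:12, each = n), nrow = n)
  cells1 <- make_cells(vals1, ids = ids, cols = cols)
  adj1 <- ancova_adjusted_means(cells1, x)
  # removing the slope-one covariate trend leaves the cell constants
  expect_equal(adj1$rb, rep(1:12, times = n),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(ancova_adjusted_means(cells, setNames(rep(40, n), ids)),
               "constant covariate")
})

test_that("the 2x2x3 contrast differences the block contrast across time", {
  cols <- expand.grid(phase = c("pre", "post"),
                      stimulation = c("active", "sham"), block = 1:3,
                      stringsAsFactors = FALSE)
  # time-invariant profiles cancel exactly
  set.seed(56)
  profile <- rnorm(6)
  vals <- matrix(rep(rep(profile, each = 2), 5), nrow = 5, byrow = TRUE)
  cells <- make_cells(vals, cols = cols)
  expect_equal(interaction_contrast_2x2x3(cells)$mean, 0, tolerance = 1e-12)

  # a known three-way interaction: effect only in post-active block 1
  n <- 9
  vals2 <- matrix(rnorm(n * 12, 0, 1e-6), nrow = n)
  sel <- cols$phase == "post" & cols$stimulation == "active" & cols$block == 1
  vals2[, sel] <- vals2[, sel] + 0.4
  eff <- interaction_contrast_2x2x3(make_cells(vals2, cols = cols))
  expect_equal(eff$mean, 0.4, tolerance = 1e-4)
})

test_that("cell tables computed from trials feed the contrasts consistently", {
  set.seed(57)
  st <- simulate_study(design = study_design(6), seed = 57)
  rb <- rb_cell_table(st$trials)
  expect_equal(nrow(rb), 6 * 12)  # 2 stim x 2 phase x 3 blocks per participant
  eff <- paired_difference(rb,
                           a = list(stimulation = "active", phase = "post", block = 1),
                           b = list(stimulation = "sham", phase = "post", block = 1))
  # brute-force the same quantity straight from the trial log
  brute <- vapply(sprintf("P%02d", 1:6), function(id) {
    sub <- st$trials[st$trials$participant_id == id &
                       st$trials$phase == "post" & st$trials$block == 1, ]
    a <- response_bias(tabulate_block(sub[sub$stimulation == "active", ]))$value
    s <- response_bias(tabulate_block(sub[sub$stimulation == "sham", ]))$value
    a - s
  }, 0)
  expect_equal(eff$mean, mean(brute), tolerance = 1e-12)
})
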