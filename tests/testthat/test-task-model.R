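test_that("trial validation rejects malformed logs and reward-accuracy violations", {
  expect_error(validate_trials(data.frame()), "empty")
  good <- make_participant()
  expect_silent(validate_trials(good))

  bad <- good
  bad$block[1] <- 5L
  expect_error(validate_trials(bad), "block")

  bad <- good
  bad$rewarded[1] <- TRUE
  bad$correct[1] <- FALSE
  expect_error(validate_trials(bad), "rewarded")

  bad <- good
  bad$role[bad$stimulus == "long"][1] <- "lean"  # role flips within a phase
  expect_error(validate_trials(bad), "role")
})

test_that("RT filter removes too-fast, too-slow and missing responses", {
  trials <- make_participant(n_per_block = 10)
  trials$rt_ms[1] <- 150
  trials$rt_ms[2] <- 2500
  trials$response[3] <- "none"
  res <- filter_trials(trials)
  expect_equal(nrow(res$trials), nrow(trials) - 3L)
  expect_false(any(res$trials$rt_ms < 200 | res$trials$rt_ms > 2000))
  expect_false(any(res$trials$response == "none"))
  # boundary values are retained
  trials$rt_ms[4] <- 200; trials$rt_ms[5] <- 2000
  res2 <- filter_trials(trials)
  expect_true(all(c(200, 2000) %in% res2$trials$rt_ms))
})

test_that("clean participants are retained with reason 'none'", {
  res <- filter_trials(make_participant())
  expect_false(res$report$excluded)
  expect_equal(res$report$reason, "none")
  expect_equal(res$report$rt_violation_fraction, 0)
})

test_that("a participant with 11% out-of-range trials is excluded for RT violations", {
  trials <- make_participant(n_per_block = 100, blocks = 1:3)  # 1200 trials
  expect_equal(nrow(trials), 1200L)
  trials$rt_ms[seq_len(132)] <- 100  # 132/1200 = 11% > 10%
  res <- filter_trials(trials)
  expect_true(res$report$excluded)
  expect_equal(res$report$reason, "rt_violation_rate")
  expect_equal(res$report$rt_violation_fraction, 0.11)
  expect_equal(nrow(res$trials), 0L)
  # exactly 10% does not trigger
  trials$rt_ms <- 500
  trials$rt_ms[seq_len(120)] <- 100
  expect_false(filter_trials(trials)$report$excluded)
})

test_that("one-key responders and incomplete sessions are excluded", {
  trials <- make_participant()
  trials$response[trials$session == 2] <- "long"
  trials$correct <- trials$response == trials$stimulus
  res <- filter_trials(trials)
  expect_equal(res$report$reason, "one_key_responder")

  half <- make_participant()
  half <- half[half$session == 1, ]
  res <- filter_trials(half)
  expect_equal(res$report$reason, "incomplete_sessions")
})

test_that("filtering retained trials again changes nothing (idempotence)", {
  trials <- rbind(make_participant("P01"), make_participant("P02"))
  trials$rt_ms[c(1, 5, 9)] <- c(10, 3000, 199)
  once <- filter_trials(trials)
  twice <- filter_trials(once$trials)
  expect_identical(once$trials, twice$trials)
  expect_false(any(twice$report$excluded))
})

test_that("block tabulation partitions retained trials by role and accuracy", {
  # all correct, 50 rich / 50 lean
  stim <- rep(c("long", "short"), 50)
  all_correct <- do.call(rbind, lapply(seq_along(stim), function(i) {
    make_trial(trial = ((i - 1L) %% 100L) + 1L, stimulus = stim[i],
               role = ifelse(stim[i] == "long", "rich", "lean"))
  }))
  counts <- tabulate_block(all_correct)
  expect_equal(unlist(counts),
               c(rich_correct = 50, rich_incorrect = 0,
                 lean_correct = 50, lean_incorrect = 0))

  four <- rbind(
    make_trial(trial = 1L, stimulus = "long", role = "rich", response = "long"),
    make_trial(trial = 2L, stimulus = "long", role = "rich", response = "short"),
    make_trial(trial = 3L, stimulus = "short", role = "lean", response = "short"),
    make_trial(trial = 4L, stimulus = "short", role = "lean", response = "long")
  )
  expect_equal(unlist(tabulate_block(four)),
               c(rich_correct = 1, rich_incorrect = 1,
                 lean_correct = 1, lean_incorrect = 1))

  mixed <- rbind(make_trial(block = 1L), make_trial(block = 2L))
  expect_error(tabulate_block(mixed), "block")
})

test_that("tabulated counts match a brute-force recount on simulated blocks", {
  set.seed(11)
  trials <- simulate_participant(agent_params(), "P01")
  for (sub in split(trials, list(trials$session, trials$phase, trials$block))) {
    counts <- tabulate_block(sub)
    recount <- table(role = sub$role, correct = sub$correct)
    expect_equal(counts$rich_correct, sum(sub$role == "rich" & sub$correct))
    expect_equal(counts$lean_incorrect, sum(sub$role == "lean" & !sub$correct))
    expect_equal(sum(unlist(counts)), nrow(sub))  # conservation
    expect_true(all(unlist(counts) <= 50))
  }
})

test_that("response bias follows the half-log cross-ratio formula", {
  expect_equal(response_bias(block_counts(30, 20, 30, 20))$value, 0)
  expect_equal(response_bias(block_counts(40, 10, 25, 25))$value,
               0.5 * log(4), tolerance = 1e-12)

  corrected <- response_bias(block_counts(50, 0, 25, 25))
  expect_true(corrected$corrected)
  expect_equal(corrected$value,
               0.5 * log((50.5 * 25.5) / (0.5 * 25.5)), tolerance = 1e-12)

  expect_error(response_bias(block_counts(0, 0, 0, 0)), "empty")
})

test_that("response bias is antisymmetric under rich/lean swap and zero at equal odds", {
  set.seed(21)
  for (i in 1:50) {
    x <- as.integer(sample(0:50, 4, replace = TRUE))
    if (all(x == 0)) x[1] <- 1L
    rb <- response_bias(block_counts(x[1], x[2], x[3], x[4]))
    swapped <- response_bias(block_counts(x[3], x[4], x[1], x[2]))
    expect_equal(rb$value, -swapped$value, tolerance = 1e-12)
  }
  # equal correct/incorrect ratios give exactly zero bias
  for (k in 1:5) {
    rb <- response_bias(block_counts(8 * k, 2 * k, 4 * k, k))
    expect_equal(rb$value, 0, tolerance = 1e-12)
  }
})

test_that("PANAS scoring sums the right items and validates the range", {
  expect_equal(score_panas(rep(1, 20)), list(pa = 10, na = 10))
  expect_equal(score_panas(rep(5, 20)), list(pa = 50, na = 50))

  items <- integer(20)
  items[panas_item_map$pa] <- 3L
  items[panas_item_map$na] <- 1L
  expect_equal(score_panas(items), list(pa = 30, na = 10))

  expect_error(score_panas(c(rep(1, 19), 6)), "1..5")
  expect_error(score_panas(rep(1, 19)))
})

test_that("PANAS subscale sums are invariant to shuffling items with the map", {
  set.seed(31)
  items <- sample(1:5, 20, replace = TRUE)
  ref <- score_panas(items)
  for (i in 1:10) {
    perm <- sample(20)
    map <- list(pa = match(panas_item_map$pa, perm),
                na = match(panas_item_map$na, perm))
    expect_equal(score_panas(items[perm], map), ref)
  }
})

test_that("TEPS scoring splits anticipatory and consummatory subscales", {
  s <- score_teps(rep(1, 18))
  expect_equal(s, list(ant = 10, con = 8, total = 18))
  s6 <- score_teps(rep(6, 18))
  expect_equal(s6$total, 108)
  expect_equal(s6$total, s6$ant + s6$con)
  expect_error(score_teps(rep(7, 18)), "1..6")
})

test_that("floor-effect rate flags scales dominated by their minimum", {
  res <- floor_effect_rate(c(rep(10, 54), rep(11:15, length.out = 66)),
                           minimum = 10)
  expect_equal(res$rate, 0.45)
  expect_true(res$flagged)

  expect_equal(floor_effect_rate(c(11, 12, 13), minimum = 10),
               list(rate = 0, flagged = FALSE))
  expect_equal(floor_effect_rate(rep(10, 8), minimum = 10),
               list(rate = 1, flagged = TRUE))
  # exactly at threshold is not flagged
  expect_false(floor_effect_rate(c(rep(TRUE, 3), rep(FALSE, 17)))$flagged)
  expect_error(floor_effect_rate(numeric(0), minimum = 0), "no measures")
})

test_that("trial logs and questionnaires round-trip through their CSV dialects", {
  dir <- withr::local_tempdir()
  trials <- make_participant()
  path <- file.path(dir, "trials.csv")
  write_trial_log(trials, path)
  back <- read_trial_log(path)
  expect_equal(back, trials)
  header <- readLines(path, n = 1)
  expect_equal(header, paste(c("participant_id", "session", "stimulation",
                               "phase", "block", "trial", "stimulus", "role",
                               "response", "correct", "rewarded", "rt_ms"),
                             collapse = ","))

  q <- data.frame(participant_id = "P01", timepoint = "pre_active",
                  instrument = "panas", item_index = 1:20,
                  response = rep(2L, 20), stringsAsFactors = FALSE)
  qp <- file.path(dir, "q.csv")
  write_questionnaires(q, qp)
  expect_equal(read_questionnaires(qp), q)
  scored <- score_questionnaires(q)
  expect_equal(scored$panas_pa, 20)
  expect_equal(scored$panas_na, 20)
})
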