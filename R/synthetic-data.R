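#' Reinforcement schedule specification
#'
#' The asymmetric reward schedule of the probabilistic learning task: per
#' block, 50 long and 50 short stimuli in pseudo-random order, with 40
#' planned rewards split 30 (rich role) / 10 (lean role).
#'
#' @param n_blocks Number of blocks per task application.
#' @param trials_per_block Trials per block.
#' @param long_per_block,short_per_block Stimulus counts per block.
#' @param rich_rewards,lean_rewards Planned rewards per block by role; the
#'   schedule keeps the 3:1 rich/lean asymmetry.
#' @return A `schedule_spec` object.
#' @export
schedule_spec <- function(n_blocks = 3, trials_per_block = 100,
                          long_per_block = 50, short_per_block = 50,
                          rich_rewards = 30, lean_rewards = 10) {
  stopifnot(long_per_block + short_per_block == trials_per_block)
  stopifnot(rich_rewards >= 0, lean_rewards >= 0)
  if (rich_rewards != 3 * lean_rewards) {
    stop("schedule must keep the 3:1 rich/lean reward asymmetry", call. = FALSE)
  }
  if (rich_rewards > min(long_per_block, short_per_block) ||
      lean_rewards > min(long_per_block, short_per_block)) {
    stop("planned rewards exceed the number of trials of that role", call. = FALSE)
  }
  structure(
    list(n_blocks = n_blocks, trials_per_block = trials_per_block,
         long_per_block = long_per_block, short_per_block = short_per_block,
         rewards_per_block = rich_rewards + lean_rewards,
         rich_rewards = rich_rewards, lean_rewards = lean_rewards),
    class = "schedule_spec"
  )
}

#' Build one task application's trial schedule
#'
#' Shuffles stimuli within each block and marks the planned-reward trials:
#' `rich_rewards` among the rich-role trials and `lean_rewards` among the
#' lean-role trials of each block.
#'
#' @param spec A [schedule_spec()].
#' @param rich_stimulus Which stimulus carries the rich role ("long" or
#'   "short") for this application.
#' @param seed Optional integer; when given, the schedule is drawn from a
#'   fresh RNG stream seeded with it (identical seeds give identical
#'   schedules).
#' @return A data.frame with columns `block`, `trial`, `stimulus`, `role`,
#'   `planned_reward`.
#' @export
build_schedule <- function(spec = schedule_spec(),
                           rich_stimulus = c("long", "short"), seed = NULL) {
  stopifnot(inherits(spec, "schedule_spec"))
  rich_stimulus <- match.arg(rich_stimulus)
  if (!is.null(seed)) set.seed(seed)
  lean_stimulus <- setdiff(c("long", "short"), rich_stimulus)
  blocks <- lapply(seq_len(spec$n_blocks), function(b) {
    stimulus <- sample(c(rep("long", spec$long_per_block),
                         rep("short", spec$short_per_block)))
    role <- ifelse(stimulus == rich_stimulus, "rich", "lean")
    planned <- logical(spec$trials_per_block)
    planned[sample(which(role == "rich"), spec$rich_rewards)] <- TRUE
    planned[sample(which(role == "lean"), spec$lean_rewards)] <- TRUE
    data.frame(block = b, trial = seq_len(spec$trials_per_block),
               stimulus = stimulus, role = role, planned_reward = planned,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}

#' Generative parameters of a simulated responder
#'
#' A criterion-learning signal-detection agent: on each trial the probability
#' of choosing the rich-role response is
#' `plogis(dprime/2 * s + criterion)` with `s = +1` on rich-role stimuli and
#' `-1` on lean-role stimuli, so the expected response bias equals the
#' criterion (in log-odds units). After every delivered reward the criterion
#' drifts toward the rich response by `learn_rate`, saturating at +/- 3.
#'
#' @param dprime Perceptual discriminability, log-odds units (>= 0).
#' @param criterion0 Initial decision criterion (log-odds units).
#' @param learn_rate Criterion drift per delivered reward.
#' @param lapse Probability of a uniformly random response.
#' @param stim_effect Additive criterion shift applied in post-active task
#'   applications only (the injectable ground-truth stimulation effect).
#' @param rt_meanlog,rt_sdlog Lognormal reaction-time parameters; draws are
#'   truncated to [1, 5000] ms.
#' @return An `agent_params` object.
#' @export
agent_params <- function(dprime = 2.2, criterion0 = 0, learn_rate = 0.002,
                         lapse = 0.05, stim_effect = 0,
                         rt_meanlog = log(500), rt_sdlog = 0.3) {
  stopifnot(dprime >= 0, lapse >= 0, lapse <= 1, rt_sdlog > 0)
  structure(
    list(dprime = dprime, criterion0 = criterion0, learn_rate = learn_rate,
         lapse = lapse, stim_effect = stim_effect,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
    class = "agent_params"
  )
}

#' Study design: participants, conditions and counterbalancing
#'
#' Every participant completes all four stimulation-by-phase cells (active /
#' sham crossed with pre / post); stimulation order alternates across
#' participants so the active-first / sham-first split is balanced for even n.
#'
#' @param n_participants Number of participants (default 30).
#' @return A `study_design` object with a `participants` data.frame
#'   (`participant_id`, `order`).
#' @export
study_design <- function(n_participants = 30) {
  stopifnot(n_participants >= 1)
  ids <- sprintf("P%02d", seq_len(n_participants))
  order <- ifelse(seq_len(n_participants) %% 2L == 1L,
                  "active_first", "sham_first")
  structure(
    list(n_participants = n_participants,
         participants = data.frame(participant_id = ids, order = order,
                                   stringsAsFactors = FALSE)),
    class = "study_design"
  )
}

# rewards are delivered on correct trials following the planned schedule; a
# planned reward falling on an incorrect trial is re-queued to the next
# correct same-role trial and dropped at block end
simulate_application <- function(agent, schedule, post_active) {
  criterion0 <- agent$criterion0 + if (post_active) agent$stim_effect else 0
  n <- nrow(schedule)
  p_lo <- stats::plnorm(1, agent$rt_meanlog, agent$rt_sdlog)
  p_hi <- stats::plnorm(5000, agent$rt_meanlog, agent$rt_sdlog)
  rt <- stats::qlnorm(stats::runif(n, p_lo, p_hi),
                      agent$rt_meanlog, agent$rt_sdlog)
  lapse_draw <- stats::runif(n) < agent$lapse
  u <- stats::runif(n)
  u_lapse <- stats::runif(n)

  role_sign <- ifelse(schedule$role == "rich", 1, -1)
  rich_stim <- schedule$stimulus[schedule$role == "rich"][1]
  lean_stim <- setdiff(c("long", "short"), rich_stim)

  response <- character(n)
  correct <- logical(n)
  rewarded <- logical(n)
  criterion <- criterion0
  pending <- c(rich = 0L, lean = 0L)
  current_block <- schedule$block[1]

  for (i in seq_len(n)) {
    if (schedule$block[i] != current_block) {
      pending[] <- 0L  # drop unused quota at block end
      current_block <- schedule$block[i]
    }
    if (lapse_draw[i]) {
      resp_rich <- u_lapse[i] < 0.5
    } else {
      p_rich <- stats::plogis(agent$dprime / 2 * role_sign[i] + criterion)
      resp_rich <- u[i] < p_rich
    }
    response[i] <- if (resp_rich) rich_stim else lean_stim
    correct[i] <- response[i] == schedule$stimulus[i]
    if (correct[i]) {
      r <- schedule$role[i]
      if (schedule$planned_reward[i]) {
        rewarded[i] <- TRUE
      } else if (pending[[r]] > 0L) {
        rewarded[i] <- TRUE
        pending[[r]] <- pending[[r]] - 1L
      }
    } else if (schedule$planned_reward[i]) {
      pending[[schedule$role[i]]] <- pending[[schedule$role[i]]] + 1L
    }
    if (rewarded[i]) {
      criterion <- min(3, max(-3, criterion + agent$learn_rate))
    }
  }
  data.frame(block = schedule$block, trial = schedule$trial,
             stimulus = schedule$stimulus, role = schedule$role,
             response = response, correct = correct, rewarded = rewarded,
             rt_ms = round(rt, 1), stringsAsFactors = FALSE)
}

#' Simulate all four task applications for one participant
#'
#' Two sessions (one active, one sham, order as given) each with a pre- and a
#' post-stimulation task application. The rich stimulus is drawn at random for
#' each pre application and reversed at post, matching the counterbalancing
#' procedure; the agent's criterion restarts at `criterion0` for every
#' application, with `stim_effect` added in the post-active application only.
#'
#' @param agent An [agent_params()] object.
#' @param participant_id Participant label.
#' @param order "active_first" or "sham_first".
#' @param spec A [schedule_spec()].
#' @return A trial-log data.frame (see [validate_trials()]).
#' @export
simulate_participant <- function(agent, participant_id = "P01",
                                 order = c("active_first", "sham_first"),
                                 spec = schedule_spec()) {
  stopifnot(inherits(agent, "agent_params"))
  order <- match.arg(order)
  stim_by_session <- if (order == "active_first") c("active", "sham")
                     else c("sham", "active")
  out <- list()
  for (session in 1:2) {
    pre_rich <- sample(c("long", "short"), 1)
    post_rich <- setdiff(c("long", "short"), pre_rich)  # reversed at post
    for (phase in c("pre", "post")) {
      rich_stim <- if (phase == "pre") pre_rich else post_rich
      sched <- build_schedule(spec, rich_stimulus = rich_stim)
      app <- simulate_application(
        agent, sched,
        post_active = (phase == "post" && stim_by_session[session] == "active")
      )
      app <- cbind(
        data.frame(participant_id = participant_id, session = session,
                   stimulation = stim_by_session[session], phase = phase,
                   stringsAsFactors = FALSE),
        app
      )
      out[[length(out) + 1L]] <- app
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, TRIAL_COLUMNS]
}

#' Agent population for study simulation
#'
#' Per-participant parameters are drawn around these population values;
#' `learn_rate` draws are truncated at zero.
#'
#' @param dprime_mean,dprime_sd Discriminability distribution.
#' @param criterion0_sd SD of the initial criterion around zero.
#' @param learn_rate_mean,learn_rate_sd Criterion learning-rate distribution.
#' @param lapse Shared lapse probability.
#' @param stim_effect Shared true stimulation effect on the post-active
#'   criterion (log-odds units).
#' @param rt_meanlog,rt_sdlog Shared reaction-time parameters.
#' @return An `agent_population` object.
#' @export
agent_population <- function(dprime_mean = 2.2, dprime_sd = 0.3,
                             criterion0_sd = 0.2,
                             learn_rate_mean = 0.002, learn_rate_sd = 0.001,
                             lapse = 0.05, stim_effect = 0,
                             rt_meanlog = log(500), rt_sdlog = 0.3) {
  structure(
    list(dprime_mean = dprime_mean, dprime_sd = dprime_sd,
         criterion0_sd = criterion0_sd,
         learn_rate_mean = learn_rate_mean, learn_rate_sd = learn_rate_sd,
         lapse = lapse, stim_effect = stim_effect,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
    class = "agent_population"
  )
}

#' Mood-shift specification for questionnaire simulation
#'
#' Pre-to-post changes (sum-scale points) in PANAS PA and NA under each
#' stimulation condition; the study-level null has all four at zero.
#'
#' @param pa_active,pa_sham,na_active,na_sham Change injected at the post
#'   administration of the given condition.
#' @return A plain list.
#' @export
mood_effects <- function(pa_active = 0, pa_sham = 0,
                         na_active = 0, na_sham = 0) {
  list(pa_active = pa_active, pa_sham = pa_sham,
       na_active = na_active, na_sham = na_sham)
}

simulate_panas_items <- function(trait, item_mean, shift_per_item,
                                 state_sd = 0.3, sd_item = 0.6) {
  # `state` is an administration-level mood fluctuation shared by the ten
  # items; it dominates the variance of pre-to-post change scores
  state <- stats::rnorm(1, 0, state_sd)
  latent <- item_mean + trait + state + shift_per_item +
    stats::rnorm(10, 0, sd_item)
  pmin(5L, pmax(1L, as.integer(round(latent))))
}

#' Simulate a complete synthetic study
#'
#' Draws a population of criterion-learning responders, simulates every
#' participant's four task applications, and generates PANAS (four
#' administrations: pre/post of each stimulation session) and baseline TEPS
#' item responses from latent normal mood with the declared condition shifts,
#' clipped to the response scales. Each participant gets an independent RNG
#' stream derived from the root seed (`seed + 1000 * i`), so participant-level
#' results are reproducible in isolation.
#'
#' @param design A [study_design()].
#' @param population An [agent_population()].
#' @param mood A [mood_effects()] list.
#' @param seed Root seed (keep below ~2e6 so derived streams stay within
#'   integer range).
#' @param spec A [schedule_spec()].
#' @param panas_pa_item_mean,panas_na_item_mean Latent item means; the NA
#'   default sits near the scale floor, as observed in non-clinical samples.
#' @param dir Optional directory: when given, writes `trials.csv`,
#'   `questionnaires.csv` and a `ground_truth.json` sidecar.
#' @return A list with `trials`, `questionnaires`, `ground_truth`.
#' @export
simulate_study <- function(design = study_design(),
                           population = agent_population(),
                           mood = mood_effects(), seed = 1,
                           spec = schedule_spec(),
                           panas_pa_item_mean = 2.9,
                           panas_na_item_mean = 0.6,
                           dir = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(population, "agent_population"))
  trials <- list()
  quests <- list()
  truth <- list()
  for (i in seq_len(design$n_participants)) {
    set.seed(seed + 1000L * i)
    row <- design$participants[i, ]
    agent <- agent_params(
      dprime = max(0, stats::rnorm(1, population$dprime_mean, population$dprime_sd)),
      criterion0 = stats::rnorm(1, 0, population$criterion0_sd),
      learn_rate = max(0, stats::rnorm(1, population$learn_rate_mean,
                                       population$learn_rate_sd)),
      lapse = population$lapse, stim_effect = population$stim_effect,
      rt_meanlog = population$rt_meanlog, rt_sdlog = population$rt_sdlog
    )
    trials[[i]] <- simulate_participant(agent, row$participant_id, row$order,
                                        spec)
    truth[[i]] <- c(list(participant_id = row$participant_id,
                         order = row$order), unclass(agent))

    trait_pa <- stats::rnorm(1, 0, 0.5)
    trait_na <- stats::rnorm(1, 0, 0.3)
    shifts <- list(
      pre_active = c(pa = 0, na = 0),
      post_active = c(pa = mood$pa_active / 10, na = mood$na_active / 10),
      pre_sham = c(pa = 0, na = 0),
      post_sham = c(pa = mood$pa_sham / 10, na = mood$na_sham / 10)
    )
    for (tp in names(shifts)) {
      pa_items <- simulate_panas_items(trait_pa, panas_pa_item_mean,
                                       shifts[[tp]][["pa"]])
      na_items <- simulate_panas_items(trait_na, panas_na_item_mean,
                                       shifts[[tp]][["na"]])
      resp <- integer(20)
      resp[panas_item_map$pa] <- pa_items
      resp[panas_item_map$na] <- na_items
      quests[[length(quests) + 1L]] <- data.frame(
        participant_id = row$participant_id, timepoint = tp,
        instrument = "panas", item_index = 1:20, response = resp,
        stringsAsFactors = FALSE)
    }
    teps_latent <- 4.3 + stats::rnorm(1, 0, 0.5) + stats::rnorm(18, 0, 0.8)
    quests[[length(quests) + 1L]] <- data.frame(
      participant_id = row$participant_id, timepoint = "baseline",
      instrument = "teps", item_index = 1:18,
      response = pmin(6L, pmax(1L, as.integer(round(teps_latent)))),
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, trials)
  quests <- do.call(rbind, quests)
  rownames(trials) <- rownames(quests) <- NULL
  ground_truth <- list(seed = seed, mood_effects = mood,
                       population = unclass(population),
                       participants = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_trial_log(trials, file.path(dir, "trials.csv"))
    write_questionnaires(quests, file.path(dir, "questionnaires.csv"))
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(trials = trials, questionnaires = quests, ground_truth = ground_truth)
}
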