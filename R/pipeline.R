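#' Registry of informed priors for the registered analyses
#'
#' Each entry records the originating study's one-degree-of-freedom effect:
#' the prior used against observed data is a shifted t centred on the original
#' mean difference with scale equal to the original sample SD; the
#' design-analysis variant (see [design_analysis()]) instead uses the original
#' SE as scale, representing the sampling uncertainty of the original effect.
#'
#' @return A named list of class `prior_registry`; each entry holds `prior`
#'   (a [prior_model()]), `location`, `sd_original`, `se_original`,
#'   `n_original`, `df`.
#' @export
default_prior_registry <- function() {
  entry <- function(location, sd_original, se_original, n_original, df) {
    list(prior = prior_model("shifted_t", location, sd_original, df),
         location = location, sd_original = sd_original,
         se_original = se_original, n_original = n_original, df = df)
  }
  structure(list(
    # primary 1df effect: active - sham response bias, block 1
    primary_ahn = entry(0.14, 0.26, 0.063, 18, 17),
    # stimulation x block interaction reduced to a linear contrast
    interaction_ahn = entry(0.16, 0.08 * sqrt(18), 0.08, 18, 17),
    # time x stimulation x block (covariate-adjusted) reduced contrast
    interaction_duprat = entry(0.14, 0.33, 0.07, 21, 20),
    # treatment effect on PANAS positive affect change
    pa_forbes = entry(4.91, 0.82 * sqrt(96), 0.82, 96, 95),
    # treatment effect on PANAS negative affect, oriented so positive =
    # negative mood decreased
    na_forbes = entry(5.92, 0.94 * sqrt(96), 0.94, 96, 95),
    # block-3 post-sham response bias vs zero (manipulation check)
    manipulation_ahn = entry(0.19, 0.26, 0.061, 18, 17),
    manipulation_duprat = entry(0.26, 0.32, 0.070, 21, 20)
  ), class = "prior_registry")
}

#' Design analysis for a registry entry at a planned sample size
#'
#' Scales the original SE by `sqrt(n_original / n_target)` and evaluates the
#' Bayes factor expected if the planned study observes a mean of exactly zero,
#' using the SE-scaled informed prior.
#'
#' @param entry One entry of [default_prior_registry()].
#' @param n_target Planned sample size.
#' @return A `design_analysis` object with `se_scaled` and
#'   `expected_bf_under_null`.
#' @export
#' @examples
#' design_analysis(default_prior_registry()$primary_ahn, 30)
design_analysis <- function(entry, n_target = 30) {
  da <- scale_se(entry$se_original, entry$n_original, n_target)
  design_prior <- prior_model("shifted_t", entry$location, entry$se_original,
                              entry$df)
  da$expected_bf_under_null <- expected_bf_under_null(design_prior,
                                                      da$se_scaled,
                                                      n_target - 1)
  da
}

#' Analysis configuration
#'
#' @param rt_low,rt_high Reaction-time retention bounds (ms).
#' @param violation_threshold Participant exclusion threshold on the
#'   unusable-trial fraction.
#' @param floor_threshold Floor-effect flagging threshold.
#' @param priors A [default_prior_registry()] (or a modified copy).
#' @param n_cap,bf_upper,bf_lower Sequential stopping-rule settings.
#' @param seed Seed recorded with reports.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(rt_low = 200, rt_high = 2000,
                            violation_threshold = 0.10,
                            floor_threshold = 0.15,
                            priors = default_prior_registry(),
                            n_cap = 30, bf_upper = 6, bf_lower = 1 / 6,
                            seed = 1) {
  structure(
    list(rt_low = rt_low, rt_high = rt_high,
         violation_threshold = violation_threshold,
         floor_threshold = floor_threshold, priors = priors,
         n_cap = n_cap, bf_upper = bf_upper, bf_lower = bf_lower,
         seed = seed),
    class = "analysis_config"
  )
}

panas_cells <- function(scored) {
  sub <- scored[scored$instrument == "panas", , drop = FALSE]
  parts <- strsplit(sub$timepoint, "_", fixed = TRUE)
  data.frame(participant_id = sub$participant_id,
             phase = vapply(parts, `[`, "", 1L),
             stimulation = vapply(parts, `[`, "", 2L),
             pa = sub$panas_pa, na = sub$panas_na,
             stringsAsFactors = FALSE)
}

#' Run the full registered analysis suite
#'
#' Executes, in order: trial filtering and participant exclusion; per-cell
#' response bias; the primary block-1 active-vs-sham Bayes test (two-sided and
#' directional) with its paired t-test and the default-Cauchy one-sample
#' decomposition; double-baselined PANAS PA/NA Bayes tests, paired t-tests,
#' per-condition exploratory decompositions and NA floor-effect check; both
#' interaction replications (linear-contrast reduction of the
#' stimulation-by-block interaction with its RM ANOVA, and the
#' covariate-adjusted three-way reduction with its RM ANCOVA); the
#' manipulation checks; the design analysis for the primary prior; and the
#' sequential stopping-rule evaluation.
#'
#' @param trials Trial log data.frame (see [read_trial_log()]).
#' @param questionnaires Long questionnaire data.frame
#'   (see [read_questionnaires()]).
#' @param config An [analysis_config()].
#' @return A list of class `study_report`: `metrics` (flat named list of
#'   numbers), `exclusions`, `rb_cells` (group summary), `anova`, `ancova`,
#'   `stopping`, `log` (operation provenance with input hashes).
#' @export
run_registered_analyses <- function(trials, questionnaires,
                                    config = analysis_config()) {
  log <- character()
  note <- function(op, x) {
    log[[length(log) + 1L]] <<- sprintf("%s [input %s]", op, input_hash(x))
    invisible(NULL)
  }
  metrics <- list()

  # -- exclusions -----------------------------------------------------------
  note("filter_trials", trials)
  filt <- filter_trials(trials, config$rt_low, config$rt_high,
                        config$violation_threshold)
  retained <- filt$trials
  included <- filt$report$participant_id[!filt$report$excluded]
  if (length(included) < 2L) stop("fewer than 2 retained participants", call. = FALSE)
  metrics$n_included <- length(included)
  metrics$n_excluded <- sum(filt$report$excluded)

  # -- response bias per cell ----------------------------------------------
  note("rb_cell_table", retained)
  rb <- rb_cell_table(retained)
  rb_summary <- stats::aggregate(rb ~ stimulation + phase + block, rb, mean)

  pri <- config$priors

  # -- primary 1df test -----------------------------------------------------
  note("paired_difference primary", rb)
  primary <- paired_difference(rb,
                               a = list(stimulation = "active", phase = "post", block = 1),
                               b = list(stimulation = "sham", phase = "post", block = 1))
  metrics$primary_mean <- primary$mean
  metrics$primary_se <- primary$se
  metrics$primary_bf <- informed_bf(primary, pri$primary_ahn$prior)$bf10
  dir_prior <- pri$primary_ahn$prior
  dir_prior$direction <- "positive"
  metrics$primary_bf_directional <- informed_bf(primary, dir_prior)$bf10
  tt <- paired_t(primary)
  metrics$primary_t <- tt$t; metrics$primary_p <- tt$p
  metrics$primary_d <- tt$cohens_d

  # exploratory: post-active block-1 bias against zero, default Cauchy prior
  pa_b1 <- cell_vector(rb, list(stimulation = "active", phase = "post", block = 1), "rb")
  t_b1 <- one_sample_t(pa_b1)
  metrics$post_active_b1_t <- t_b1$t
  metrics$post_active_b1_bf01_cauchy <-
    default_onesample_bf(t_b1$t, t_b1$n)$bf01

  # -- mood indices ---------------------------------------------------------
  note("score_questionnaires", questionnaires)
  scored <- score_questionnaires(questionnaires)
  pan <- panas_cells(scored)
  pan <- pan[pan$participant_id %in% included, , drop = FALSE]

  pa_idx <- double_baseline_index(pan, "pa", value = "pa")
  na_idx <- double_baseline_index(pan, "na", value = "na")
  metrics$pa_index_mean <- pa_idx$mean
  metrics$pa_index_bf <- informed_bf(pa_idx, pri$pa_forbes$prior)$bf10
  metrics$na_index_mean <- na_idx$mean
  metrics$na_index_bf <- informed_bf(na_idx, pri$na_forbes$prior)$bf10
  pa_post <- paired_t(paired_difference(pan,
                                        a = list(stimulation = "active", phase = "post"),
                                        b = list(stimulation = "sham", phase = "post"),
                                        value = "pa"))
  na_post <- paired_t(paired_difference(pan,
                                        a = list(stimulation = "active", phase = "post"),
                                        b = list(stimulation = "sham", phase = "post"),
                                        value = "na"))
  metrics$pa_post_t <- pa_post$t; metrics$pa_post_p <- pa_post$p
  metrics$na_post_t <- na_post$t; metrics$na_post_p <- na_post$p

  # exploratory decompositions: per-condition pre-to-post changes
  for (stim in c("active", "sham")) {
    ch_pa <- paired_difference(pan, a = list(stimulation = stim, phase = "post"),
                               b = list(stimulation = stim, phase = "pre"),
                               value = "pa")
    metrics[[paste0("pa_", stim, "_change_bf")]] <-
      informed_bf(ch_pa, pri$pa_forbes$prior)$bf10
    metrics[[paste0("pa_", stim, "_change_t")]] <- paired_t(ch_pa)$t
    # decrease index: positive = negative mood went down
    ch_na <- paired_difference(pan, a = list(stimulation = stim, phase = "pre"),
                               b = list(stimulation = stim, phase = "post"),
                               value = "na")
    metrics[[paste0("na_", stim, "_decrease_bf")]] <-
      informed_bf(ch_na, pri$na_forbes$prior)$bf10
    metrics[[paste0("na_", stim, "_decrease_t")]] <- paired_t(ch_na)$t
  }

  floor_na <- floor_effect_rate(pan$na, minimum = 10,
                                threshold = config$floor_threshold)
  metrics$na_floor_rate <- floor_na$rate
  metrics$na_floor_flagged <- as.numeric(floor_na$flagged)

  # -- interaction replications --------------------------------------------
  post_rb <- rb[rb$phase == "post", , drop = FALSE]
  int23 <- interaction_contrast_2x3(post_rb)
  metrics$interaction_2x3_mean <- int23$mean
  metrics$interaction_2x3_bf <- informed_bf(int23, pri$interaction_ahn$prior)$bf10
  note("rm_anova post stimulation x block", post_rb)
  aov_post <- rm_anova(post_rb, within = c("stimulation", "block"))

  teps <- scored[scored$instrument == "teps", , drop = FALSE]
  covariate <- stats::setNames(teps$teps_con, teps$participant_id)
  covariate <- covariate[names(covariate) %in% included]
  adj <- ancova_adjusted_means(rb, covariate)
  int223 <- interaction_contrast_2x2x3(adj)
  metrics$interaction_2x2x3_mean <- int223$mean
  metrics$interaction_2x2x3_se <- int223$se
  metrics$interaction_2x2x3_bf <-
    informed_bf(int223, pri$interaction_duprat$prior)$bf10
  note("rm_ancova time x stimulation x block", rb)
  ancova <- rm_ancova(rb, covariate, within = c("phase", "stimulation", "block"))

  # -- manipulation checks --------------------------------------------------
  sham_b3 <- cell_vector(rb, list(stimulation = "sham", phase = "post", block = 3), "rb")
  mt <- one_sample_t(sham_b3)
  metrics$manipulation_t <- mt$t; metrics$manipulation_p <- mt$p
  mb3 <- summarize_scores(sham_b3)
  metrics$manipulation_bf_ahn <- informed_bf(mb3, pri$manipulation_ahn$prior)$bf10
  metrics$manipulation_bf_duprat <-
    informed_bf(mb3, pri$manipulation_duprat$prior)$bf10

  # -- design analysis and stopping rule ------------------------------------
  da <- design_analysis(pri$primary_ahn, config$n_cap)
  metrics$design_se_scaled <- da$se_scaled
  metrics$design_expected_bf_null <- da$expected_bf_under_null

  monitored <- c(metrics$primary_bf, metrics$pa_index_bf, metrics$na_index_bf)
  decision <- stopping_rule(monitored, n_collected = metrics$n_included,
                            n_cap = config$n_cap, upper = config$bf_upper,
                            lower = config$bf_lower)
  metrics$stopping_decision_code <-
    match(decision, c("continue", "stop_h1", "stop_h0", "stop_cap"))

  structure(
    list(metrics = metrics, exclusions = filt$report, rb_cells = rb_summary,
         anova = aov_post, ancova = ancova,
         stopping = list(decision = decision, monitored_bfs = monitored),
         config_seed = config$seed, log = log),
    class = "study_report"
  )
}

# lightweight provenance hash of an operation's input
input_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.integer(bytes) * seq_along(bytes)) %% 0xFFFFFFF)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n")
  cat(sprintf("  participants: %d included, %d excluded\n",
              x$metrics$n_included, x$metrics$n_excluded))
  cat(sprintf("  primary BF10 = %.3f (directional %.3f), t(%d) = %.3f, p = %.3f\n",
              x$metrics$primary_bf, x$metrics$primary_bf_directional,
              x$metrics$n_included - 1, x$metrics$primary_t, x$metrics$primary_p))
  cat(sprintf("  PA index BF = %.3f; NA index BF = %.3f (NA floor rate %.2f)\n",
              x$metrics$pa_index_bf, x$metrics$na_index_bf,
              x$metrics$na_floor_rate))
  cat(sprintf("  interaction BFs: 2x3 = %.3f, 2x2x3 = %.3f\n",
              x$metrics$interaction_2x3_bf, x$metrics$interaction_2x2x3_bf))
  cat(sprintf("  manipulation-check BFs = %.3f / %.3f\n",
              x$metrics$manipulation_bf_ahn, x$metrics$manipulation_bf_duprat))
  cat(sprintf("  stopping rule: %s\n", x$stopping$decision))
  invisible(x)
}

#' Serialise a study report
#'
#' Writes `report.json` (flat metrics map plus tables) and a human-readable
#' `report.txt` rendering.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(metrics = report$metrics,
                  exclusions = report$exclusions,
                  rb_cells = report$rb_cells,
                  anova = report$anova$table,
                  ancova = report$ancova$table,
                  stopping = report$stopping,
                  seed = report$config_seed,
                  log = report$log)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Generate a preset synthetic fixture
#'
#' Convenience presets over [simulate_study()]: `null` has no stimulation or
#' mood effects; `paper_like` keeps a null stimulation effect but injects the
#' observed-regime mood drops (PA falling more after active than sham
#' stimulation, NA flat near its floor); `effectful` injects a +0.3 log-unit
#' stimulation effect on post-active response bias.
#'
#' @param kind One of "null", "paper_like", "effectful".
#' @param seed Root seed.
#' @param dir Optional output directory (see [simulate_study()]).
#' @param n_participants Number of participants (default 30).
#' @return As [simulate_study()].
#' @export
generate_fixture <- function(kind = c("null", "paper_like", "effectful"),
                             seed = 1, dir = NULL, n_participants = 30) {
  kind <- match.arg(kind)
  pop <- switch(kind,
    null = agent_population(stim_effect = 0),
    paper_like = agent_population(stim_effect = 0),
    effectful = agent_population(stim_effect = 0.3)
  )
  mood <- switch(kind,
    null = mood_effects(),
    paper_like = mood_effects(pa_active = -2.9, pa_sham = -1.6),
    effectful = mood_effects()
  )
  simulate_study(design = study_design(n_participants), population = pop,
                 mood = mood, seed = seed, dir = dir)
}
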