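#' @keywords internal
"_PACKAGE"

# canonical trial-log column order; the on-disk CSV dialect uses exactly this
# header, lower-case enumerations and 0/1 booleans
TRIAL_COLUMNS <- c("participant_id", "session", "stimulation", "phase",
                   "block", "trial", "stimulus", "role", "response",
                   "correct", "rewarded", "rt_ms")

#' Validate a trial log
#'
#' Checks the structural invariants of a trial-level task log: column set,
#' enumeration levels, block 1-3 and trial 1-100 ranges, reward only on
#' correct responses, and a fixed stimulus-to-role mapping within each
#' (participant, session, phase).
#'
#' @param trials A data.frame with the columns `participant_id`, `session`,
#'   `stimulation`, `phase`, `block`, `trial`, `stimulus`, `role`, `response`,
#'   `correct`, `rewarded`, `rt_ms`.
#' @return The validated data.frame, invisibly; errors describe the first
#'   violated invariant.
#' @export
validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) stop("empty trial log", call. = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("trial log missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  chk_enum <- function(col, levels) {
    bad <- !trials[[col]] %in% levels
    if (any(bad)) {
      stop(sprintf("invalid %s value(s): %s", col,
                   paste(unique(trials[[col]][bad]), collapse = ", ")),
           call. = FALSE)
    }
  }
  chk_enum("session", c(1L, 2L))
  chk_enum("stimulation", c("active", "sham"))
  chk_enum("phase", c("pre", "post"))
  chk_enum("stimulus", c("long", "short"))
  chk_enum("role", c("rich", "lean"))
  chk_enum("response", c("long", "short", "none"))
  if (!all(trials$block %in% 1:3)) stop("block must be in 1..3", call. = FALSE)
  if (!all(trials$trial %in% 1:100)) stop("trial must be in 1..100", call. = FALSE)
  if (!all(trials$correct %in% c(TRUE, FALSE)) ||
      !all(trials$rewarded %in% c(TRUE, FALSE))) {
    stop("correct/rewarded must be logical", call. = FALSE)
  }
  if (any(trials$rewarded & !trials$correct)) {
    stop("rewarded trials must be correct (reward follows only correct responses)",
         call. = FALSE)
  }
  if (any(trials$rt_ms < 0, na.rm = TRUE)) stop("negative rt_ms", call. = FALSE)
  # role must be a fixed function of stimulus within (participant, session, phase)
  key <- interaction(trials$participant_id, trials$session, trials$phase,
                     trials$stimulus, drop = TRUE)
  n_roles <- tapply(trials$role, key, function(r) length(unique(r)))
  if (any(n_roles > 1L)) {
    stop("role is not a fixed function of stimulus within a task application",
         call. = FALSE)
  }
  invisible(trials)
}

#' Filter trials and flag participants for exclusion
#'
#' Removes trials with reaction times outside `[rt_low, rt_high]` and trials
#' with no response, then flags participants for exclusion when (in order of
#' precedence) a session is missing, all responses within a session use one
#' key, or unusable trials exceed 10 percent of their total. Missing responses
#' count toward the violation budget.
#'
#' @param trials A validated trial log (see [validate_trials()]).
#' @param rt_low,rt_high Retention bounds in ms (default 200 and 2000,
#'   inclusive).
#' @param violation_threshold Exclude when the unusable-trial fraction exceeds
#'   this (default 0.10).
#' @param drop_excluded Drop flagged participants' trials from the retained
#'   set (default TRUE).
#' @return A list with `trials` (retained rows) and `report`, a data.frame
#'   with one row per participant: `participant_id`, `excluded`, `reason`
#'   (one of "incomplete_sessions", "one_key_responder", "rt_violation_rate",
#'   "none"), `rt_violation_fraction`.
#' @export
filter_trials <- function(trials, rt_low = 200, rt_high = 2000,
                          violation_threshold = 0.10, drop_excluded = TRUE) {
  stopifnot(rt_low < rt_high)
  validate_trials(trials)

  ok_rt <- trials$rt_ms >= rt_low & trials$rt_ms <= rt_high
  responded <- trials$response != "none"
  usable <- ok_rt & responded

  ids <- unique(trials$participant_id)
  report <- do.call(rbind, lapply(ids, function(id) {
    sub <- trials[trials$participant_id == id, , drop = FALSE]
    frac <- mean(!(usable[trials$participant_id == id]))
    reason <- "none"
    if (!all(c(1L, 2L) %in% sub$session)) {
      reason <- "incomplete_sessions"
    } else {
      one_key <- vapply(split(sub$response[sub$response != "none"],
                              sub$session[sub$response != "none"]),
                        function(r) length(unique(r)) <= 1L, logical(1))
      if (any(one_key)) {
        reason <- "one_key_responder"
      } else if (frac > violation_threshold) {
        reason <- "rt_violation_rate"
      }
    }
    data.frame(participant_id = id, excluded = reason != "none",
               reason = reason, rt_violation_fraction = frac,
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL

  keep <- usable
  if (drop_excluded) {
    excluded_ids <- report$participant_id[report$excluded]
    keep <- keep & !(trials$participant_id %in% excluded_ids)
  }
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' Tabulate one block into rich/lean by correct/incorrect counts
#'
#' @param trials Retained trials belonging to a single
#'   (participant, session, phase, block).
#' @return A `block_counts` object with fields `rich_correct`,
#'   `rich_incorrect`, `lean_correct`, `lean_incorrect`.
#' @export
tabulate_block <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0L)
  key_cols <- c("participant_id", "session", "phase", "block")
  for (col in key_cols) {
    if (length(unique(trials[[col]])) > 1L) {
      stop("trials span more than one ", col, "; tabulate one block at a time",
           call. = FALSE)
    }
  }
  rich <- trials$role == "rich"
  block_counts(
    rich_correct = sum(rich & trials$correct),
    rich_incorrect = sum(rich & !trials$correct),
    lean_correct = sum(!rich & trials$correct),
    lean_incorrect = sum(!rich & !trials$correct)
  )
}

#' Construct a 2x2 block count table
#'
#' @param rich_correct,rich_incorrect,lean_correct,lean_incorrect Non-negative
#'   counts of retained trials.
#' @return A `block_counts` object.
#' @export
block_counts <- function(rich_correct, rich_incorrect,
                         lean_correct, lean_incorrect) {
  counts <- c(rich_correct = rich_correct, rich_incorrect = rich_incorrect,
              lean_correct = lean_correct, lean_incorrect = lean_incorrect)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "block_counts")
}

#' Signal-detection response bias for one block
#'
#' The log-odds preference for the richly rewarded stimulus irrespective of
#' accuracy:
#' \deqn{RB = \tfrac{1}{2}\,\ln\frac{Rich_{correct} \cdot
#'   Lean_{incorrect}}{Rich_{incorrect} \cdot Lean_{correct}}}
#' When any cell is zero, 0.5 is added to all four cells (the standard
#' log-linear correction) and the result is flagged `corrected`.
#'
#' @param counts A [block_counts()] object.
#' @return A list of class `response_bias` with `value` (natural-log units)
#'   and `corrected`.
#' @export
#' @examples
#' response_bias(block_counts(40, 10, 25, 25))  # 0.5 * log(4)
response_bias <- function(counts) {
  stopifnot(inherits(counts, "block_counts"))
  x <- unlist(counts)
  if (all(x == 0)) stop("empty block: all four counts are zero", call. = FALSE)
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  value <- 0.5 * log((x["rich_correct"] * x["lean_incorrect"]) /
                       (x["rich_incorrect"] * x["lean_correct"]))
  structure(list(value = unname(value), corrected = corrected),
            class = "response_bias")
}

#' @export
print.response_bias <- function(x, ...) {
  cat(sprintf("Response bias: %.4f%s\n", x$value,
              if (x$corrected) " (zero-cell correction applied)" else ""))
  invisible(x)
}

# Standard published item assignments; shipped as configuration because the
# instruments themselves are fixed, but overridable for translated versions.

#' @rdname score_panas
#' @format NULL
#' @export
panas_item_map <- list(
  pa = c(1L, 3L, 5L, 9L, 10L, 12L, 14L, 16L, 17L, 19L),
  na = c(2L, 4L, 6L, 7L, 8L, 11L, 13L, 15L, 18L, 20L)
)

#' @rdname score_teps
#' @format NULL
#' @export
teps_item_map <- list(
  ant = c(1L, 4L, 6L, 8L, 10L, 11L, 13L, 15L, 16L, 18L),
  con = c(2L, 3L, 5L, 7L, 9L, 12L, 14L, 17L)
)

#' Score the PANAS
#'
#' Sums the ten positive-affect and ten negative-affect items (each rated
#' 1-5), giving PA and NA scores in 10-50.
#'
#' @param items Numeric vector of 20 item responses in item order.
#' @param item_map List with integer vectors `pa` and `na` giving the item
#'   indices of each subscale (default: standard published assignment).
#' @return A list with `pa` and `na`.
#' @export
score_panas <- function(items, item_map = panas_item_map) {
  stopifnot(length(items) == 20L)
  if (any(!items %in% 1:5)) {
    stop("PANAS responses must be integers in 1..5", call. = FALSE)
  }
  stopifnot(length(item_map$pa) == 10L, length(item_map$na) == 10L,
            !anyDuplicated(c(item_map$pa, item_map$na)))
  list(pa = sum(items[item_map$pa]), na = sum(items[item_map$na]))
}

#' Score the TEPS
#'
#' Sums the anticipatory (10 items) and consummatory (8 items) pleasure
#' subscales; their total indexes hedonic capacity.
#'
#' @param items Numeric vector of 18 item responses (1-6 Likert) in item
#'   order.
#' @param item_map List with integer vectors `ant` and `con` (default:
#'   standard published assignment).
#' @return A list with `ant`, `con` and `total = ant + con`.
#' @export
score_teps <- function(items, item_map = teps_item_map) {
  stopifnot(length(items) == 18L)
  if (any(!items %in% 1:6)) {
    stop("TEPS responses must be integers in 1..6", call. = FALSE)
  }
  stopifnot(length(item_map$ant) == 10L, length(item_map$con) == 8L,
            !anyDuplicated(c(item_map$ant, item_map$con)))
  ant <- sum(items[item_map$ant]); con <- sum(items[item_map$con])
  list(ant = ant, con = con, total = ant + con)
}

#' Floor-effect rate of a set of scale measures
#'
#' Fraction of measures at the scale minimum; scales dominated by their floor
#' (rate above the threshold, conventionally 15 percent) have limited
#' sensitivity to decreases.
#'
#' @param scores Numeric vector of observed scale scores, or a logical vector
#'   of at-minimum indicators.
#' @param minimum Scale minimum (required when `scores` is numeric).
#' @param threshold Flagging threshold on the rate (default 0.15).
#' @return A list with `rate` and `flagged` (`rate > threshold`).
#' @export
#' @examples
#' floor_effect_rate(c(rep(10, 54), rep(12, 66)), minimum = 10)
floor_effect_rate <- function(scores, minimum = NULL, threshold = 0.15) {
  if (length(scores) == 0L) stop("no measures supplied", call. = FALSE)
  if (is.logical(scores)) {
    at_min <- scores
  } else {
    if (is.null(minimum)) stop("supply the scale minimum", call. = FALSE)
    at_min <- scores == minimum
  }
  rate <- mean(at_min)
  list(rate = rate, flagged = rate > threshold)
}

#' Read / write the trial-log CSV dialect
#'
#' Plain CSV with the exact canonical header, lower-case enumerations and
#' 0/1 booleans.
#'
#' @param path File path.
#' @return `read_trial_log` returns a validated data.frame.
#' @export
read_trial_log <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(trials), TRIAL_COLUMNS)) {
    stop("trial log header must be exactly: ",
         paste(TRIAL_COLUMNS, collapse = ", "), call. = FALSE)
  }
  trials$correct <- as.logical(trials$correct)
  trials$rewarded <- as.logical(trials$rewarded)
  validate_trials(trials)
  trials
}

#' @rdname read_trial_log
#' @param trials Trial data.frame to write.
#' @export
write_trial_log <- function(trials, path) {
  validate_trials(trials)
  out <- trials[, TRIAL_COLUMNS]
  out$correct <- as.integer(out$correct)
  out$rewarded <- as.integer(out$rewarded)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the questionnaire CSV dialect
#'
#' Long format: `participant_id`, `timepoint` (e.g. "pre_active",
#' "post_sham", "baseline"), `instrument` ("panas" or "teps"), `item_index`,
#' `response`.
#'
#' @param path File path.
#' @export
read_questionnaires <- function(path) {
  q <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "timepoint", "instrument", "item_index", "response")
  if (!identical(names(q), need)) {
    stop("questionnaire header must be exactly: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(q$instrument %in% c("panas", "teps")))
  q
}

#' @rdname read_questionnaires
#' @param q Questionnaire data.frame to write.
#' @export
write_questionnaires <- function(q, path) {
  utils::write.csv(q, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score a long-format questionnaire table
#'
#' @param q Long questionnaire data (see [read_questionnaires()]).
#' @return A data.frame with one row per (participant, timepoint): `panas_pa`,
#'   `panas_na` for PANAS administrations; `teps_ant`, `teps_con`,
#'   `teps_total` for TEPS.
#' @export
score_questionnaires <- function(q) {
  out <- list()
  for (grp in split(q, list(q$participant_id, q$timepoint, q$instrument),
                    drop = TRUE)) {
    items <- grp$response[order(grp$item_index)]
    row <- data.frame(participant_id = grp$participant_id[1],
                      timepoint = grp$timepoint[1],
                      instrument = grp$instrument[1],
                      stringsAsFactors = FALSE)
    if (grp$instrument[1] == "panas") {
      s <- score_panas(items)
      row$panas_pa <- s$pa; row$panas_na <- s$na
      row$teps_ant <- NA_integer_; row$teps_con <- NA_integer_
      row$teps_total <- NA_integer_
    } else {
      s <- score_teps(items)
      row$panas_pa <- NA_integer_; row$panas_na <- NA_integer_
      row$teps_ant <- s$ant; row$teps_con <- s$con; row$teps_total <- s$total
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
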