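#' Per-cell response-bias table
#'
#' Computes the response bias of every (participant, stimulation, phase,
#' block) cell from retained trials.
#'
#' @param trials Retained trial log (after [filter_trials()]).
#' @return A data.frame with columns `participant_id`, `stimulation`, `phase`,
#'   `block`, `rb`, `corrected`.
#' @export
rb_cell_table <- function(trials) {
  validate_trials(trials)
  cells <- split(trials, list(trials$participant_id, trials$stimulation,
                              trials$phase, trials$block), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(sub) {
    rb <- response_bias(tabulate_block(sub))
    data.frame(participant_id = sub$participant_id[1],
               stimulation = sub$stimulation[1], phase = sub$phase[1],
               block = sub$block[1], rb = rb$value, corrected = rb$corrected,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$participant_id, out$stimulation, out$phase, out$block), ]
}

# pull one cell as a named per-participant vector; `key` is a named list of
# column = value filters
cell_vector <- function(cells, key, value) {
  keep <- rep(TRUE, nrow(cells))
  for (col in names(key)) keep <- keep & cells[[col]] == key[[col]]
  sub <- cells[keep, , drop = FALSE]
  if (anyDuplicated(sub$participant_id)) {
    stop("cell key does not identify a unique cell per participant", call. = FALSE)
  }
  stats::setNames(sub[[value]], sub$participant_id)
}

summarize_scores <- function(scores) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 participants", call. = FALSE)
  out <- effect_summary(mean(scores), stats::sd(scores) / sqrt(n), n - 1, n)
  attr(out, "contrast_scores") <- scores
  out
}

align_participants <- function(...) {
  vecs <- list(...)
  all_ids <- unique(unlist(lapply(vecs, names)))
  ids <- Reduce(intersect, lapply(vecs, names))
  if (length(ids) < length(all_ids)) {
    stop("missing cell(s) for participant(s): ",
         paste(setdiff(all_ids, ids), collapse = ", "), call. = FALSE)
  }
  lapply(vecs, function(v) v[ids])
}

#' Paired difference between two cells
#'
#' Per-participant difference `a - b`, summarised to a one-degree-of-freedom
#' effect (mean, SE = sd/sqrt(n), df = n - 1).
#'
#' @param cells A long cell table (e.g. from [rb_cell_table()]).
#' @param a,b Named lists of column = value filters identifying one cell per
#'   participant, e.g. `list(stimulation = "active", phase = "post", block = 1)`.
#' @param value Name of the value column (default "rb").
#' @return An [effect_summary()]; the per-participant scores are attached as
#'   attribute `contrast_scores`. A zero-variance difference is flagged
#'   degenerate.
#' @export
paired_difference <- function(cells, a, b, value = "rb") {
  va <- cell_vector(cells, a, value)
  vb <- cell_vector(cells, b, value)
  al <- align_participants(va, vb)
  summarize_scores(al[[1]] - al[[2]])
}

#' Double-baselined mood index
#'
#' Per participant: the pre-to-post change under active stimulation minus the
#' same change under sham, `(post - pre)_active - (post - pre)_sham`. For the
#' negative-affect measure the index is sign-flipped so that positive values
#' mean negative mood decreased under active relative to sham.
#'
#' @param scores A data.frame with columns `participant_id`, `stimulation`
#'   ("active"/"sham"), `phase` ("pre"/"post") and the value column.
#' @param measure "pa" or "na" (controls the sign convention).
#' @param value Name of the value column (default "score").
#' @return An [effect_summary()] with attribute `contrast_scores`.
#' @export
double_baseline_index <- function(scores, measure = c("pa", "na"),
                                  value = "score") {
  measure <- match.arg(measure)
  v <- align_participants(
    cell_vector(scores, list(stimulation = "active", phase = "post"), value),
    cell_vector(scores, list(stimulation = "active", phase = "pre"), value),
    cell_vector(scores, list(stimulation = "sham", phase = "post"), value),
    cell_vector(scores, list(stimulation = "sham", phase = "pre"), value)
  )
  idx <- (v[[1]] - v[[2]]) - (v[[3]] - v[[4]])
  if (measure == "na") idx <- -idx  # positive = negative mood decreased
  summarize_scores(idx)
}

#' One-degree-of-freedom contrast for a stimulation-by-block interaction
#'
#' Per participant, the active-minus-sham difference in each block is reduced
#' by the linear contrast `(A1 - S1) - 0.5 (A2 - S2) - 0.5 (A3 - S3)`: a
#' block-1 effect exceeding the average of blocks 2 and 3.
#'
#' @param cells A long cell table with columns `participant_id`,
#'   `stimulation`, `block` and the value column (six cells per participant).
#' @param value Name of the value column (default "rb").
#' @param weights Contrast weights over blocks 1..3 (must sum to 0).
#' @return An [effect_summary()] with attribute `contrast_scores`.
#' @export
interaction_contrast_2x3 <- function(cells, value = "rb",
                                     weights = c(1, -0.5, -0.5)) {
  stopifnot(length(weights) == 3L, abs(sum(weights)) < 1e-12)
  diffs <- lapply(1:3, function(b) {
    al <- align_participants(
      cell_vector(cells, list(stimulation = "active", block = b), value),
      cell_vector(cells, list(stimulation = "sham", block = b), value)
    )
    al[[1]] - al[[2]]
  })
  diffs <- align_participants(diffs[[1]], diffs[[2]], diffs[[3]])
  scores <- weights[1] * diffs[[1]] + weights[2] * diffs[[2]] +
    weights[3] * diffs[[3]]
  summarize_scores(scores)
}

#' Covariate-adjust a cell table (ANCOVA-style)
#'
#' Within every cell, regresses the cell values on the grand-mean-centred
#' covariate and replaces each participant's value by its adjusted value
#' `v - b_cell (x - xbar)`; cell means of the adjusted values equal the
#' covariate-adjusted cell means evaluated at the grand covariate mean.
#'
#' @param cells A long cell table; every column other than `participant_id`
#'   and `value` is treated as a cell factor.
#' @param covariate Named numeric vector (names = participant ids), e.g.
#'   TEPS consummatory scores.
#' @param value Name of the value column (default "rb").
#' @return The cell table with the value column adjusted.
#' @export
ancova_adjusted_means <- function(cells, covariate, value = "rb") {
  ids <- unique(cells$participant_id)
  if (!all(ids %in% names(covariate))) {
    stop("covariate missing for some participants", call. = FALSE)
  }
  x <- covariate[as.character(cells$participant_id)]
  if (stats::sd(covariate[ids]) == 0) {
    stop("constant covariate: adjustment undefined", call. = FALSE)
  }
  xc <- x - mean(covariate[ids])  # grand-mean centring
  factor_cols <- setdiff(names(cells), c("participant_id", value, "corrected"))
  cell_id <- interaction(cells[factor_cols], drop = TRUE)
  adjusted <- cells
  for (lev in levels(cell_id)) {
    sel <- cell_id == lev
    b <- stats::coef(stats::lm(cells[[value]][sel] ~ xc[sel]))[2]
    adjusted[[value]][sel] <- cells[[value]][sel] - b * xc[sel]
  }
  adjusted
}

#' One-degree-of-freedom contrast for a time x stimulation x block interaction
#'
#' Applies the stimulation-by-block linear contrast separately at each level
#' of the time factor and takes the per-participant difference
#' `L(post) - L(pre)`, reducing the three-way interaction to a single paired
#' score. Typically applied to covariate-adjusted cells
#' (see [ancova_adjusted_means()]).
#'
#' @param cells A long cell table with columns `participant_id`, `phase`
#'   ("pre"/"post"), `stimulation`, `block` and the value column (twelve cells
#'   per participant).
#' @param value Name of the value column (default "rb").
#' @param weights Block contrast weights (must sum to 0).
#' @return An [effect_summary()] with attribute `contrast_scores`.
#' @export
interaction_contrast_2x2x3 <- function(cells, value = "rb",
                                       weights = c(1, -0.5, -0.5)) {
  lin <- function(phase) {
    sub <- cells[cells$phase == phase, , drop = FALSE]
    eff <- interaction_contrast_2x3(sub, value = value, weights = weights)
    attr(eff, "contrast_scores")
  }
  al <- align_participants(lin("post"), lin("pre"))
  summarize_scores(al[[1]] - al[[2]])
}
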