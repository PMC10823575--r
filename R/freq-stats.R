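#' Paired / one-sample t-test from an effect summary
#'
#' `t = mean / se` with the summary's df, two-sided p, and `d = t / sqrt(n)`.
#'
#' @param effect An [effect_summary()] (with `n` set for the d conversion), or
#'   a numeric vector of per-participant scores.
#' @param mu0 Null value for [one_sample_t()] on raw values (default 0).
#' @return A list of class `t_test_result`: `t`, `df`, `p`, `cohens_d`, `n`.
#' @export
#' @examples
#' paired_t(effect_summary(-0.253, 0.187, 29, n = 30))
paired_t <- function(effect) {
  if (is.numeric(effect)) effect <- summarize_scores(effect)
  stopifnot(inherits(effect, "effect_summary"))
  if (effect$degenerate) stop("degenerate effect summary (SE = 0)", call. = FALSE)
  t <- effect$mean / effect$se
  n <- if (!is.null(effect$n)) effect$n else effect$df + 1
  structure(
    list(t = t, df = effect$df, p = 2 * stats::pt(-abs(t), effect$df),
         cohens_d = t / sqrt(n), n = n),
    class = "t_test_result"
  )
}

#' @rdname paired_t
#' @export
one_sample_t <- function(effect, mu0 = 0) {
  if (is.numeric(effect)) {
    if (stats::sd(effect) == 0) {
      stop("constant values: degenerate one-sample test", call. = FALSE)
    }
    effect <- summarize_scores(effect - mu0)
  } else {
    stopifnot(inherits(effect, "effect_summary"))
    effect <- effect_summary(effect$mean - mu0, effect$se, effect$df, effect$n)
  }
  paired_t(effect)
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.3f, d = %.3f\n", x$df, x$t, x$p, x$cohens_d))
  invisible(x)
}

#' Effect-size conversions for F tests
#'
#' Partial eta-squared from an F ratio, `eta^2 = F df1 / (F df1 + df2)`, and
#' the Cohen's d equivalent `d = 2 sqrt(eta^2 / (1 - eta^2))`.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return A number.
#' @export
#' @examples
#' d_from_eta(eta_p_sq_from_f(4.808, 2, 58))
eta_p_sq_from_f <- function(f, df1, df2) {
  stopifnot(f >= 0, df1 > 0, df2 > 0)
  f * df1 / (f * df1 + df2)
}

#' @rdname eta_p_sq_from_f
#' @param eta Partial eta-squared in [0, 1).
#' @export
d_from_eta <- function(eta) {
  stopifnot(eta >= 0)
  if (eta >= 1) stop("eta squared of 1 gives an infinite d", call. = FALSE)
  2 * sqrt(eta / (1 - eta))
}

# long cell table -> wide matrix of within-cell columns plus the idata frame
reshape_within <- function(cells, value, within, id = "participant_id") {
  for (w in within) cells[[w]] <- factor(cells[[w]])
  ids <- unique(cells[[id]])
  combos <- expand.grid(lapply(cells[within], levels),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(combos) <- within
  mat <- matrix(NA_real_, nrow = length(ids), ncol = nrow(combos),
                dimnames = list(ids, NULL))
  for (j in seq_len(nrow(combos))) {
    keep <- rep(TRUE, nrow(cells))
    for (w in within) keep <- keep & cells[[w]] == combos[j, w]
    sub <- cells[keep, , drop = FALSE]
    if (nrow(sub) != length(ids) || anyDuplicated(sub[[id]])) {
      stop("unbalanced within-subject data: every participant needs every cell",
           call. = FALSE)
    }
    mat[as.character(sub[[id]]), j] <- sub[[value]]
  }
  idata <- as.data.frame(lapply(combos, factor))
  list(mat = mat, idata = idata, ids = ids)
}

extract_anova_table <- function(av, alpha_sphericity = 0.05) {
  # HF epsilon can exceed 1 and car warns when clamping; HF is not used here
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  effects <- setdiff(rownames(uni), "(Intercept)")
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  out <- do.call(rbind, lapply(effects, function(e) {
    ss <- uni[e, "Sum Sq"]; err <- uni[e, "Error SS"]
    df1 <- uni[e, "num Df"]; df2 <- uni[e, "den Df"]
    fval <- uni[e, "F value"]; p <- uni[e, "Pr(>F)"]
    if (!is.finite(fval) && isTRUE(all.equal(ss, 0))) {
      # zero effect and zero error variance: the data show no effect at all
      fval <- 0; p <- 1
    }
    sph_p <- NA_real_; gg_eps <- NA_real_; corrected <- FALSE
    if (!is.null(sph) && e %in% rownames(sph)) {
      sph_p <- sph[e, "p-value"]
      gg_eps <- adj[e, "GG eps"]
      if (is.finite(sph_p) && sph_p < alpha_sphericity) {
        p <- adj[e, "Pr(>F[GG])"]
        corrected <- TRUE
      }
    }
    eta <- ss / (ss + err)
    if (!is.finite(eta)) eta <- 0  # 0/0: no effect, no error variance
    data.frame(effect = e, F = fval, df1 = df1, df2 = df2, p = p,
               partial_eta_sq = eta,
               cohens_d_equiv = if (eta < 1) d_from_eta(eta) else Inf,
               gg_epsilon = gg_eps, sphericity_p = sph_p,
               corrected = corrected, sum_sq = ss, error_ss = err,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Repeated-measures ANOVA for fully within-subject designs
#'
#' Type-III sums-of-squares partition on the within-cell means, with a
#' Mauchly sphericity test for every effect with more than one numerator df;
#' when sphericity is violated (Mauchly p < .05) the Greenhouse-Geisser
#' corrected p-value is reported. Significant main effects of factors with
#' more than two levels get Bonferroni-adjusted pairwise paired comparisons.
#'
#' @param cells Long cell table with an id column, the within factor columns
#'   and the value column; must be complete and balanced (no imputation).
#' @param value Name of the value column (default "rb").
#' @param within Character vector of within-subject factor names.
#' @param id Participant id column (default "participant_id").
#' @param posthoc_alpha Significance level gating the post-hoc comparisons.
#' @return A list of class `rm_anova_result`: `table` (per-effect F, df,
#'   p, partial eta squared, d equivalent, GG epsilon, sphericity p,
#'   corrected flag, sums of squares) and `posthoc` (named list of pairwise
#'   comparison tables).
#' @export
rm_anova <- function(cells, value = "rb", within, id = "participant_id",
                     posthoc_alpha = 0.05) {
  rw <- reshape_within(cells, value, within, id)
  if (nrow(rw$mat) < 2L) stop("need at least 2 participants", call. = FALSE)
  mod <- stats::lm(rw$mat ~ 1)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mod, idata = rw$idata, idesign = idesign, type = 3)
  tab <- extract_anova_table(av)

  posthoc <- list()
  for (w in within) {
    row <- tab[tab$effect == w, ]
    if (nrow(row) == 1L && row$p < posthoc_alpha &&
        nlevels(rw$idata[[w]]) > 2L) {
      # participant means per level, averaged over the other factors
      lev <- levels(rw$idata[[w]])
      means <- sapply(lev, function(l) {
        rowMeans(rw$mat[, rw$idata[[w]] == l, drop = FALSE])
      })
      pairs <- utils::combn(lev, 2, simplify = FALSE)
      ph <- do.call(rbind, lapply(pairs, function(pr) {
        tt <- paired_t(means[, pr[1]] - means[, pr[2]])
        data.frame(level_a = pr[1], level_b = pr[2],
                   mean_a = mean(means[, pr[1]]), mean_b = mean(means[, pr[2]]),
                   t = tt$t, df = tt$df, p_raw = tt$p,
                   stringsAsFactors = FALSE)
      }))
      ph$p_bonferroni <- pmin(1, ph$p_raw * nrow(ph))
      posthoc[[w]] <- ph
    }
  }
  structure(list(table = tab, posthoc = posthoc), class = "rm_anova_result")
}

#' Repeated-measures ANCOVA with a between-subject covariate
#'
#' As [rm_anova()], with the grand-mean-centred covariate entering the
#' between-subject model so that the covariate's interactions with every
#' within-subject effect are estimated and reported.
#'
#' @inheritParams rm_anova
#' @param covariate Named numeric vector (names = participant ids) with
#'   nonzero variance.
#' @return A list of class `rm_anova_result`.
#' @export
rm_ancova <- function(cells, covariate, value = "rb", within,
                      id = "participant_id") {
  rw <- reshape_within(cells, value, within, id)
  if (!all(rownames(rw$mat) %in% names(covariate))) {
    stop("covariate missing for some participants", call. = FALSE)
  }
  x <- covariate[rownames(rw$mat)]
  if (stats::sd(x) == 0) stop("constant covariate", call. = FALSE)
  xc <- x - mean(x)
  mod <- stats::lm(rw$mat ~ xc)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mod, idata = rw$idata, idesign = idesign, type = 3)
  structure(list(table = extract_anova_table(av), posthoc = list()),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%s: F(%g, %g) = %.3f, p = %.3f%s, eta_p^2 = %.3f, d = %.2f\n",
                tab$effect[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p[i],
                if (tab$corrected[i]) " (GG-corrected)" else "",
                tab$partial_eta_sq[i], tab$cohens_d_equiv[i]))
  }
  if (length(x$posthoc)) {
    cat("Bonferroni post-hocs:",
        paste(names(x$posthoc), collapse = ", "), "\n")
  }
  invisible(x)
}
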