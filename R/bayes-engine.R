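#' One-degree-of-freedom effect summary
#'
#' The (mean, SE, df) triple that every Bayesian and frequentist test in the
#' pipeline consumes. Per-participant contrast scores reduce to this form with
#' \code{df = n - 1}.
#'
#' @param mean Observed mean difference (effect units).
#' @param se Standard error of the mean, same units. Must be >= 0; a zero SE
#'   marks a degenerate summary that downstream tests refuse.
#' @param df Degrees of freedom (integer >= 1).
#' @param n Optional sample size; for paired/one-sample effects `df = n - 1`.
#' @return An object of class `effect_summary`.
#' @export
#' @examples
#' effect_summary(-0.253, 0.187, 29, n = 30)
effect_summary <- function(mean, se, df, n = NULL) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  stopifnot(is.numeric(se), length(se) == 1L, is.finite(se), se >= 0)
  stopifnot(is.numeric(df), length(df) == 1L, df >= 1)
  if (!is.null(n)) {
    stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
    if (abs(df - (n - 1)) > 1e-8) {
      stop("for one-sample/paired effects df must equal n - 1", call. = FALSE)
    }
  }
  structure(
    list(mean = mean, se = se, df = as.integer(round(df)), n = n,
         degenerate = (se == 0)),
    class = "effect_summary"
  )
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("Effect summary: M = %.4g, SE = %.4g, df = %d%s%s\n",
              x$mean, x$se, x$df,
              if (!is.null(x$n)) sprintf(", n = %d", x$n) else "",
              if (x$degenerate) " [degenerate: SE = 0]" else ""))
  invisible(x)
}

#' Prior model for the alternative hypothesis
#'
#' Encodes H1 as a distribution over the raw effect size: a shifted and scaled
#' t (optionally truncated at zero for a directional prediction), a half-t, or
#' a zero-centred Cauchy (the default-prior family used by the JZS test).
#'
#' For replication tests the prior is built from the original study's reported
#' effect: location = its mean difference, scale and df taken from its report.
#'
#' @param family One of "shifted_t", "half_t", "cauchy_zero".
#' @param location Prior centre (must be 0 for `cauchy_zero`).
#' @param scale Prior scale, > 0.
#' @param df Prior degrees of freedom (ignored for `cauchy_zero`, which is t
#'   with df = 1).
#' @param direction "two_sided", "positive" or "negative". For `shifted_t` a
#'   directional choice truncates the prior at zero on the predicted side and
#'   renormalises; `half_t` must be directional.
#' @return An object of class `prior_model`.
#' @export
#' @examples
#' prior_model("shifted_t", location = 0.14, scale = 0.26, df = 17)
prior_model <- function(family = c("shifted_t", "half_t", "cauchy_zero"),
                        location = 0, scale = 1, df = 1,
                        direction = c("two_sided", "positive", "negative")) {
  family <- match.arg(family)
  direction <- match.arg(direction)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  stopifnot(is.numeric(location), length(location) == 1L, is.finite(location))
  stopifnot(is.numeric(df), length(df) == 1L, df >= 1)
  if (family == "half_t" && direction == "two_sided") {
    stop("half_t priors are directional; choose direction 'positive' or 'negative'",
         call. = FALSE)
  }
  if (family == "half_t") location <- 0
  if (family == "cauchy_zero") {
    if (location != 0) stop("cauchy_zero priors have location 0", call. = FALSE)
    df <- 1
  }
  structure(
    list(family = family, location = location, scale = scale, df = df,
         direction = direction),
    class = "prior_model"
  )
}

#' @export
print.prior_model <- function(x, ...) {
  cat(sprintf("Prior: %s(location = %.4g, scale = %.4g, df = %g), %s\n",
              x$family, x$location, x$scale, x$df, x$direction))
  invisible(x)
}

# prior density over effect size delta, truncated/renormalised as declared
prior_density <- function(prior, delta) {
  core <- stats::dt((delta - prior$location) / prior$scale, prior$df) / prior$scale
  lo <- -Inf; hi <- Inf
  if (prior$family == "half_t" || prior$direction != "two_sided") {
    if (prior$direction == "positive") lo <- 0 else hi <- 0
  }
  mass <- stats::pt((hi - prior$location) / prior$scale, prior$df) -
    stats::pt((lo - prior$location) / prior$scale, prior$df)
  out <- ifelse(delta >= lo & delta <= hi, core / mass, 0)
  out
}

prior_support <- function(prior) {
  lo <- -Inf; hi <- Inf
  if (prior$family == "half_t" || prior$direction != "two_sided") {
    if (prior$direction == "positive") lo <- 0 else hi <- 0
  }
  c(lo, hi)
}

new_bayes_factor <- function(bf10, marginal_h1, marginal_h0, integration_error,
                             method) {
  stopifnot(bf10 > 0)
  structure(
    list(bf10 = bf10, bf01 = 1 / bf10,
         marginal_h1 = marginal_h1, marginal_h0 = marginal_h0,
         integration_error = integration_error, method = method),
    class = "bayes_factor"
  )
}

#' @export
print.bayes_factor <- function(x, digits = 4, ...) {
  cat(sprintf("Bayes factor (%s): BF10 = %.*g, BF01 = %.*g (integration error < %.2g)\n",
              x$method, digits, x$bf10, digits, x$bf01, x$integration_error))
  invisible(x)
}

#' Informed-prior Bayes factor for a 1df effect summary
#'
#' Evidence for an alternative whose effect-size distribution comes from a
#' prior study, against a point null. The likelihood of the observed mean is a
#' t density with the data's degrees of freedom, location delta and scale equal
#' to the data SE; the marginal under H1 integrates that likelihood over the
#' prior:
#' \deqn{BF_{10} = \frac{\int f_t(m \mid \delta, se, df)\,\pi(\delta)\,d\delta}{
#'   f_t(m \mid 0, se, df)}}
#'
#' Directional priors are the same t truncated at zero on the predicted side
#' and renormalised.
#'
#' @param data An [effect_summary()].
#' @param prior A [prior_model()] of family `shifted_t` or `half_t`.
#' @param rel_tol Relative quadrature tolerance.
#' @return A `bayes_factor` object with fields `bf10`, `bf01`, `marginal_h1`,
#'   `marginal_h0`, `integration_error`.
#' @export
#' @examples
#' # primary replication test: observed (-0.253, 0.187, df 29) against a prior
#' # centred on the original +0.14 effect with its sample SD 0.26
#' informed_bf(effect_summary(-0.253, 0.187, 29),
#'             prior_model("shifted_t", 0.14, 0.26, 17))
informed_bf <- function(data, prior, rel_tol = 1e-10) {
  stopifnot(inherits(data, "effect_summary"), inherits(prior, "prior_model"))
  if (data$degenerate) stop("degenerate effect summary (SE = 0)", call. = FALSE)
  if (prior$family == "cauchy_zero") {
    stop("use default_onesample_bf() for the zero-centred Cauchy prior",
         call. = FALSE)
  }

  lik <- function(delta) {
    stats::dt((data$mean - delta) / data$se, data$df) / data$se
  }
  integrand <- function(delta) lik(delta) * prior_density(prior, delta)

  # heavy t tails: integrate over prior location +/- 12 of the wider of the
  # two scales, clipped to the prior's support, then let integrate() refine
  half_width <- 12 * max(prior$scale, data$se)
  supp <- prior_support(prior)
  lo <- max(supp[1], min(prior$location, data$mean) - half_width)
  hi <- min(supp[2], max(prior$location, data$mean) + half_width)
  if (!is.finite(supp[1])) lo <- min(prior$location, data$mean) - half_width
  if (!is.finite(supp[2])) hi <- max(prior$location, data$mean) + half_width
  lo <- max(supp[1], lo); hi <- min(supp[2], hi)

  quad <- stats::integrate(integrand, lo, hi, rel.tol = rel_tol,
                           abs.tol = 0, subdivisions = 2000L,
                           stop.on.error = FALSE)
  if (quad$message != "OK") {
    stop("marginal likelihood integration failed: ", quad$message, call. = FALSE)
  }
  marginal_h1 <- quad$value
  marginal_h0 <- lik(0)
  if (marginal_h1 <= 0) stop("marginal likelihood underflowed to zero", call. = FALSE)
  bf10 <- marginal_h1 / marginal_h0
  err <- quad$abs.error / marginal_h0
  if (err > 1e-6 * bf10) {
    stop(sprintf("integration error bound %.3g exceeds 1e-6 * BF10", err),
         call. = FALSE)
  }
  new_bayes_factor(bf10, marginal_h1, marginal_h0, err, method = "informed t prior")
}

#' Default one-sample (JZS) Bayes factor
#'
#' The standard default-prior alternative for a one-sample/paired t statistic:
#' a zero-centred Cauchy prior with the given scale on the standardised effect
#' size, against the point null. The marginal under H1 integrates the
#' noncentral-t likelihood of the observed t over the prior:
#' \deqn{BF_{10} = \frac{\int f_{nct}(t \mid df, \delta\sqrt{n})\,
#'   \mathrm{Cauchy}(\delta; 0, r)\,d\delta}{f_t(t \mid df)}}
#'
#' @param t_stat Observed t statistic.
#' @param n Sample size (>= 2); df = n - 1.
#' @param scale Cauchy prior scale on the standardised effect, default
#'   `sqrt(2)/2`.
#' @return A `bayes_factor` object.
#' @export
#' @examples
#' default_onesample_bf(1.87, n = 30)  # BF01 close to 1.11
default_onesample_bf <- function(t_stat, n, scale = sqrt(2) / 2) {
  stopifnot(is.numeric(t_stat), length(t_stat) == 1L, is.finite(t_stat))
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  df <- n - 1
  integrand <- function(delta) {
    # dt() warns about sub-1e-8 precision loss in the noncentral density;
    # negligible against the quadrature tolerance
    suppressWarnings(stats::dt(t_stat, df, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, scale)
  }
  # the noncentral-t density underflows far from t/sqrt(n); a generous finite
  # window keeps integrate() stable while losing negligible Cauchy tail mass
  centre <- t_stat / sqrt(n)
  half_width <- max(12 * scale, abs(centre) + 12 * scale, 10 / sqrt(n))
  quad <- stats::integrate(integrand, centre - half_width, centre + half_width,
                           rel.tol = 1e-9, abs.tol = 0, subdivisions = 2000L,
                           stop.on.error = FALSE)
  if (quad$message != "OK") {
    stop("JZS marginal integration failed: ", quad$message, call. = FALSE)
  }
  marginal_h1 <- quad$value
  marginal_h0 <- stats::dt(t_stat, df)
  bf10 <- marginal_h1 / marginal_h0
  new_bayes_factor(bf10, marginal_h1, marginal_h0,
                   quad$abs.error / marginal_h0, method = "JZS Cauchy")
}

#' Scale a prior study's standard error to a planned sample size
#'
#' The design-analysis step: assuming measurement variance comparable to the
#' original study, the SE expected at the planned n is
#' \code{se_original * sqrt(n_original / n_target)}.
#'
#' @param se_original Original study SE (> 0).
#' @param n_original Original sample size.
#' @param n_target Planned sample size.
#' @return A list of class `design_analysis` with `se_original`, `n_original`,
#'   `n_target`, `se_scaled`.
#' @export
#' @examples
#' scale_se(0.063, 18, 30)  # se_scaled ~ 0.049
scale_se <- function(se_original, n_original, n_target) {
  stopifnot(se_original > 0, n_original > 0, n_target > 0)
  structure(
    list(se_original = se_original, n_original = n_original,
         n_target = n_target,
         se_scaled = se_original * sqrt(n_original / n_target)),
    class = "design_analysis"
  )
}

#' @export
print.design_analysis <- function(x, ...) {
  cat(sprintf("Design analysis: SE %.4g (n = %g) -> %.4g at planned n = %g",
              x$se_original, x$n_original, x$se_scaled, x$n_target))
  if (!is.null(x$expected_bf_under_null)) {
    cat(sprintf("; expected BF10 under null = %.3g", x$expected_bf_under_null))
  }
  cat("\n")
  invisible(x)
}

#' Expected Bayes factor under the null at a planned sample size
#'
#' Evaluates the informed-prior Bayes factor at a hypothetical observation of
#' exactly zero with the scaled SE: the evidence the design would yield if the
#' true effect were null and the sample mean landed on it.
#'
#' @param prior A [prior_model()].
#' @param se_scaled SE expected at the planned sample size (see [scale_se()]).
#' @param df_target Degrees of freedom at the planned sample size.
#' @return The expected BF10 (a number < 1 for any prior placing mass away
#'   from zero).
#' @export
#' @examples
#' expected_bf_under_null(prior_model("shifted_t", 0.14, 0.063, 17),
#'                        scale_se(0.063, 18, 30)$se_scaled, 29)
expected_bf_under_null <- function(prior, se_scaled, df_target) {
  informed_bf(effect_summary(0, se_scaled, df_target), prior)$bf10
}

#' Sequential Bayes-factor stopping rule
#'
#' Data collection stops when every monitored Bayes factor exceeds the upper
#' threshold (evidence for H1), every one falls below the lower threshold
#' (evidence for H0), or the participant cap is reached.
#'
#' @param bf_values Numeric vector of current BF10 values (non-empty).
#' @param n_collected Participants collected so far.
#' @param n_cap Maximum sample size (default 30).
#' @param upper,lower Evidence thresholds (default 6 and 1/6).
#' @return One of "continue", "stop_h1", "stop_h0", "stop_cap".
#' @export
#' @examples
#' stopping_rule(c(7.1, 8.0), n_collected = 20)  # "stop_h1"
stopping_rule <- function(bf_values, n_collected, n_cap = 30,
                          upper = 6, lower = 1 / 6) {
  if (length(bf_values) == 0L) stop("no Bayes factors supplied", call. = FALSE)
  stopifnot(all(is.finite(bf_values)), all(bf_values > 0))
  stopifnot(upper > 1, lower < 1, lower > 0)
  if (all(bf_values > upper)) return("stop_h1")
  if (all(bf_values < lower)) return("stop_h0")
  if (n_collected >= n_cap) return("stop_cap")
  "continue"
}
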