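# brute-force trapezoid oracle for the informed-prior Bayes factor:
# 1e5-point fixed grid spanning the prior location and the data mean by
# 12 of the wider scale, clipped to the truncation support
grid_informed_bf <- function(mean, se, df, loc, scale, pdf,
                             direction = "two_sided", n_grid = 1e5) {
  half <- 12 * max(scale, se)
  lo <- min(loc, mean) - half
  hi <- max(loc, mean) + half
  if (direction == "positive") lo <- max(lo, 0)
  if (direction == "negative") hi <- min(hi, 0)
  delta <- seq(lo, hi, length.out = n_grid)
  lik <- dt((mean - delta) / se, df) / se
  pri <- dt((delta - loc) / scale, pdf) / scale
  mass <- switch(direction,
    two_sided = 1,
    positive = 1 - pt((0 - loc) / scale, pdf),
    negative = pt((0 - loc) / scale, pdf)
  )
  h <- delta[2] - delta[1]
  integrand <- lik * pri / mass
  num <- h * (sum(integrand) - 0.5 * (integrand[1] + integrand[n_grid]))
  num / (dt(mean / se, df) / se)
}

# trapezoid oracle for the JZS one-sample Bayes factor
grid_jzs_bf <- function(t_stat, n, scale = sqrt(2) / 2, n_grid = 1e5) {
  centre <- t_stat / sqrt(n)
  half <- max(12 * scale, abs(centre) + 12 * scale)
  delta <- seq(centre - half, centre + half, length.out = n_grid)
  integrand <- suppressWarnings(dt(t_stat, n - 1, ncp = delta * sqrt(n))) *
    dcauchy(delta, 0, scale)
  h <- delta[2] - delta[1]
  num <- h * (sum(integrand) - 0.5 * (integrand[1] + integrand[n_grid]))
  num / dt(t_stat, n - 1)
}

# textbook sums-of-squares partition for a fully-within two-factor design,
# written directly from cell/marginal means: an oracle independent of the
# mlm machinery behind rm_anova()
manual_rm_anova_2f <- function(mat, f1, f2) {
  n <- nrow(mat)
  grand <- mean(mat)
  subj <- rowMeans(mat)

  a_means <- vapply(levels(f1), function(a) mean(mat[, f1 == a]), 0)
  b_means <- vapply(levels(f2), function(b) mean(mat[, f2 == b]), 0)

  ss_a <- n * nlevels(f2) * sum((a_means - grand)^2)
  ss_b <- n * nlevels(f1) * sum((b_means - grand)^2)
  ss_ab <- 0
  for (a in levels(f1)) for (b in levels(f2)) {
    m_ab <- mean(mat[, f1 == a & f2 == b])
    ss_ab <- ss_ab + n * (m_ab - a_means[[a]] - b_means[[b]] + grand)^2
  }

  ss_err_a <- 0
  for (a in levels(f1)) {
    sm <- rowMeans(mat[, f1 == a, drop = FALSE])
    ss_err_a <- ss_err_a + nlevels(f2) * sum((sm - subj - a_means[[a]] + grand)^2)
  }
  ss_err_b <- 0
  for (b in levels(f2)) {
    sm <- rowMeans(mat[, f2 == b, drop = FALSE])
    ss_err_b <- ss_err_b + nlevels(f1) * sum((sm - subj - b_means[[b]] + grand)^2)
  }
  ss_total <- sum((mat - grand)^2)
  ss_subject <- ncol(mat) * sum((subj - grand)^2)
  ss_err_ab <- ss_total - ss_subject - ss_a - ss_b - ss_ab - ss_err_a - ss_err_b

  df_a <- nlevels(f1) - 1; df_b <- nlevels(f2) - 1; df_ab <- df_a * df_b
  list(
    ss = c(a = ss_a, b = ss_b, ab = unname(ss_ab)),
    err = c(a = ss_err_a, b = ss_err_b, ab = ss_err_ab),
    F = c(a = (ss_a / df_a) / (ss_err_a / (df_a * (n - 1))),
          b = (ss_b / df_b) / (ss_err_b / (df_b * (n - 1))),
          ab = (ss_ab / df_ab) / (ss_err_ab / (df_ab * (n - 1)))),
    ss_total = ss_total, ss_subject = ss_subject
  )
}
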