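#' One-way repeated-measures ANOVA with Huynh-Feldt correction
#'
#' Classic within-subject decomposition: condition and subject sums of
#' squares, error = subject x condition interaction. When a Mauchly test
#' rejects sphericity at `sphericity_alpha` (or when `always_correct`), the
#' numerator and denominator degrees of freedom are multiplied by the
#' Huynh-Feldt epsilon (clamped to at most 1).
#'
#' @param scores Long data frame with columns `subject`, `condition`,
#'   `score` (complete cases: every subject in every condition), or a wide
#'   numeric matrix/data frame of subjects x conditions.
#' @param always_correct Apply the correction regardless of the sphericity
#'   test.
#' @param sphericity_alpha Rejection level of the Mauchly pre-test.
#' @return An `rm_anova` object with `F`, `df_num`, `df_den`, `epsilon`
#'   (1 when uncorrected), `epsilon_gg`, `epsilon_hf`, `mauchly_w`,
#'   `mauchly_p`, `corrected`, `p`.
#' @export
rm_anova_hf <- function(scores, always_correct = FALSE,
                        sphericity_alpha = 0.05) {
  wide <- scores_to_wide(scores)
  n <- nrow(wide); k <- ncol(wide)
  if (k < 2) abort("At least 2 conditions are required.")
  if (n < 3) abort("At least 3 subjects are required.")
  if (anyNA(wide)) abort("Missing cells: complete cases are required.")

  grand <- mean(wide)
  cond_means <- colMeans(wide)
  subj_means <- rowMeans(wide)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f_stat <- if (ms_err == 0) {
    if (ms_cond == 0) 0 else Inf
  } else ms_cond / ms_err

  # Greenhouse-Geisser epsilon from the contrast covariance, Huynh-Feldt
  # correction on top, Mauchly W for the sphericity pre-test.
  S <- stats::cov(wide)
  C <- contr_orthonormal(k)
  Tm <- t(C) %*% S %*% C
  eps_gg <- (sum(diag(Tm)))^2 / (df1 * sum(Tm * Tm))
  eps_hf <- (n * df1 * eps_gg - 2) / (df1 * (n - 1 - df1 * eps_gg))
  eps_hf <- min(1, max(eps_hf, df1^-1))
  ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  mauchly <- mauchly_test(ev, n, k)

  corrected <- always_correct ||
    (!is.na(mauchly$p) && mauchly$p < sphericity_alpha)
  eps <- if (corrected) eps_hf else 1
  p <- pf(f_stat, df1 * eps, df2 * eps, lower.tail = FALSE)
  structure(list(
    F = f_stat, df_num = df1 * eps, df_den = df2 * eps, epsilon = eps,
    epsilon_gg = eps_gg, epsilon_hf = eps_hf, mauchly_w = mauchly$w,
    mauchly_p = mauchly$p, corrected = corrected, p = p,
    n_subjects = n, n_conditions = k,
    ss = c(condition = ss_cond, subject = ss_subj, error = ss_err)),
    class = "rm_anova")
}

scores_to_wide <- function(scores) {
  if (is.matrix(scores)) return(scores)
  scores <- as_tibble(scores)
  if (all(c("subject", "condition", "score") %in% names(scores))) {
    wide <- tidyr::pivot_wider(scores[c("subject", "condition", "score")],
                               names_from = "condition",
                               values_from = "score")
    return(as.matrix(wide[-1]))
  }
  as.matrix(scores)
}

contr_orthonormal <- function(k) {
  H <- stats::contr.helmert(k)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

mauchly_test <- function(ev, n, k) {
  d <- k - 1
  if (d < 2) return(list(w = NA_real_, p = NA_real_))
  ev <- pmax(ev, 0)
  if (any(ev <= 0)) return(list(w = 0, p = 0))
  w <- prod(ev) / (mean(ev))^d
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
  chi <- -(n - 1) * f * log(w)
  df <- d * (d + 1) / 2 - 1
  list(w = w, p = pchisq(chi, df, lower.tail = FALSE))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%.4g, %.4g) = %.4g, p = %.3g%s\n",
              x$df_num, x$df_den, x$F, x$p,
              if (x$corrected)
                sprintf(" (Huynh-Feldt epsilon = %.3f)", x$epsilon)
              else ""))
  invisible(x)
}

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(term = "condition", statistic = x$F, df_num = x$df_num,
         df_den = x$df_den, epsilon = x$epsilon, p.value = x$p)
}

#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_conditions = x$n_conditions,
         epsilon_gg = x$epsilon_gg, epsilon_hf = x$epsilon_hf,
         mauchly_w = x$mauchly_w, mauchly_p = x$mauchly_p,
         corrected = x$corrected)
}

#' Pairwise within-subject t-tests with Benjamini-Hochberg correction
#'
#' All condition pairs are compared with paired t-tests and the p-values
#' adjusted by the Benjamini-Hochberg step-up procedure over the family of
#' pairwise contrasts. A zero-variance difference with zero mean is reported
#' as p = 1; a zero-variance nonzero difference is degenerate (p = 0).
#'
#' @inheritParams rm_anova_hf
#' @return Tibble with `condition_a`, `condition_b`, `mean_diff`,
#'   `statistic`, `df`, `p.value`, `p.adjusted`, `degenerate`.
#' @export
pairwise_t_fdr <- function(scores) {
  wide <- scores_to_wide(scores)
  k <- ncol(wide)
  if (k < 2) abort("At least 2 conditions are required.")
  conds <- colnames(wide) %||% paste0("c", seq_len(k))
  pairs <- utils::combn(k, 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- wide[, a] - wide[, b]
    if (sd(d) == 0) {
      degen <- mean(d) != 0
      rows[[j]] <- tibble(
        condition_a = conds[a], condition_b = conds[b], mean_diff = mean(d),
        statistic = if (degen) Inf * sign(mean(d)) else 0,
        df = length(d) - 1,
        p.value = if (degen) 0 else 1, degenerate = degen)
    } else {
      tt <- t.test(wide[, a], wide[, b], paired = TRUE)
      rows[[j]] <- tibble(
        condition_a = conds[a], condition_b = conds[b],
        mean_diff = unname(tt$estimate), statistic = unname(tt$statistic),
        df = unname(tt$parameter), p.value = tt$p.value, degenerate = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p.adjusted <- p.adjust(out$p.value, method = "BH")
  dplyr::relocate(out, "p.adjusted", .after = "p.value")
}

#' Item-level OLS regression with a pointwise confidence band
#'
#' Ordinary least squares of a per-pair outcome (retroactive memorability
#' difference or dependence) on its relatedness value, with t-based
#' slope/intercept inference and a pointwise 95% confidence band over the
#' predictor range. For the change-both condition, pass
#' `x = r_cue + r_target` (the additive cue+target relatedness).
#'
#' @param data Data frame containing the variables, or `NULL` when `x`, `y`
#'   are vectors.
#' @param x,y Column names (tidy-eval) or numeric vectors.
#' @param level Confidence level for the band (default 0.95).
#' @param n_band Number of band evaluation points.
#' @return An `item_regression` object wrapping the `lm` fit, with a `band`
#'   tibble (`x`, `fit`, `lower`, `upper`).
#' @export
item_regression <- function(data = NULL, x, y, level = 0.95, n_band = 100) {
  if (is.null(data)) {
    xv <- x; yv <- y
  } else {
    xv <- rlang::eval_tidy(rlang::enquo(x), data)
    yv <- rlang::eval_tidy(rlang::enquo(y), data)
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("At least 3 pairs are required.")
  if (var(xv) == 0) abort("Zero variance in the predictor.")
  fit <- lm(yv ~ xv, data = data.frame(xv = xv, yv = yv))
  grid <- data.frame(xv = seq(min(xv), max(xv), length.out = n_band))
  ci <- predict(fit, newdata = grid, interval = "confidence", level = level)
  smry <- summary(fit)$coefficients
  structure(list(
    fit = fit,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    slope_se = smry["xv", "Std. Error"],
    intercept_se = smry["(Intercept)", "Std. Error"],
    slope_p = smry["xv", "Pr(>|t|)"],
    intercept_p = smry["(Intercept)", "Pr(>|t|)"],
    r = unname(sign(coef(fit)[2]) * sqrt(summary(fit)$r.squared)),
    n = length(xv), level = level,
    data = tibble(x = xv, y = yv),
    band = tibble(x = grid$xv, fit = ci[, "fit"], lower = ci[, "lwr"],
                  upper = ci[, "upr"])),
    class = "item_regression")
}

#' @export
print.item_regression <- function(x, ...) {
  cat(sprintf(
    "Item regression (n = %d): slope = %.4g (p = %.3g), intercept = %.4g (p = %.3g), r = %.3f\n",
    x$n, x$slope, x$slope_p, x$intercept, x$intercept_p, x$r))
  invisible(x)
}

#' @method tidy item_regression
#' @export
tidy.item_regression <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_se, x$slope_se),
         p.value = c(x$intercept_p, x$slope_p))
}

#' @method glance item_regression
#' @export
glance.item_regression <- function(x, ...) {
  tibble(r = x$r, r.squared = x$r^2, n = x$n, level = x$level)
}

#' Partial correlation of two variables controlling for a third
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing each
#' on `z`, with a t-test on `n - 3` degrees of freedom.
#'
#' @param x,y,z Numeric vectors of equal length (at least 4 complete
#'   observations).
#' @return Tibble with `estimate`, `statistic`, `df`, `p.value`, `n`.
#' @export
partial_correlation <- function(x, y, z) {
  ok <- complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) abort("At least 4 complete observations are required.")
  if (var(z) > 0 && var(x) > 0 && abs(cor(x, z)) >= 1 - 1e-12) {
    abort("Collinearity with the covariate: partial correlation undefined.")
  }
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    return(tibble(estimate = NA_real_, statistic = NA_real_, df = n - 3,
                  p.value = NA_real_, n = n))
  }
  r <- cor(rx, ry)
  df <- n - 3
  tval <- r * sqrt(df) / sqrt(1 - r^2)
  tibble(estimate = r, statistic = tval, df = df,
         p.value = 2 * pt(abs(tval), df, lower.tail = FALSE), n = n)
}
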