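# Publication-bias diagnostics: Egger's regression and Begg's rank test.

#' Egger's linear regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `theta_i / se_i` on the
#' precision `1 / se_i`; a non-zero intercept signals small-study effects.
#' The intercept is tested two-sided against a t distribution with k - 2
#' degrees of freedom.
#'
#' @param effects `effect_estimate`s / `fourfold`s / data.frame with
#'   `log_or` and `se` (see [pool_fixed_iv()]); at least 3 studies.
#' @return A `bias_test` list: `test = "egger"`, `k`, `intercept`, `se`,
#'   `t`, `p`, plus `slope`.
#' @export
egger_test <- function(effects) {
  eff <- effects_frame(effects)
  k <- nrow(eff)
  if (k < 3) stop("Egger's test requires at least 3 studies", call. = FALSE)
  precision <- 1 / eff$se
  if (stats::sd(precision) == 0) {
    stop("all standard errors are equal: precision is a degenerate regressor",
         call. = FALSE)
  }
  std_effect <- eff$log_or / eff$se
  fit <- stats::lm(std_effect ~ precision)
  sm <- summary(fit)$coefficients
  structure(
    list(test = "egger", k = k,
         intercept = sm["(Intercept)", "Estimate"],
         se = sm["(Intercept)", "Std. Error"],
         t = sm["(Intercept)", "t value"],
         p = sm["(Intercept)", "Pr(>|t|)"],
         slope = sm["precision", "Estimate"]),
    class = "bias_test"
  )
}

#' Begg and Mazumdar's rank-correlation test
#'
#' Kendall rank correlation between the variance-standardized deviations
#' `(theta_i - theta_hat) / sqrt(v_i - v_hat)` and the variances `v_i`,
#' where `theta_hat` and `v_hat` are the inverse-variance fixed pooled
#' estimate and its variance. The normal approximation
#' `z = (P - Q) / sqrt(k (k-1) (2k+5) / 18)` (equivalently
#' `tau / sqrt(2(2k+5) / (9 k (k-1)))`) is used with a continuity
#' correction of 1 on `P - Q`.
#'
#' For a study with `v_i <= v_hat` (possible only in edge cases) the
#' standardization clamps the denominator at `sqrt(eps)` with
#' `eps = 1e-8` and emits a warning.
#'
#' @param effects As in [egger_test()]; at least 3 studies.
#' @param pooled Optional `pooled_result` supplying `theta_hat` and `v_hat`;
#'   by default the inverse-variance fixed pool of `effects` is used.
#' @return A `bias_test` list: `test = "begg"`, `k`, `tau`, `z`, `p`.
#' @export
begg_test <- function(effects, pooled = NULL) {
  eff <- effects_frame(effects)
  k <- nrow(eff)
  if (k < 3) stop("Begg's test requires at least 3 studies", call. = FALSE)
  vi <- eff$se^2
  if (is.null(pooled)) pooled <- pool_fixed_iv(eff)
  theta_hat <- pooled$log_or
  v_hat <- pooled$se^2
  eps <- 1e-8
  v_star <- vi - v_hat
  if (any(v_star <= 0)) {
    warning("some study variances do not exceed the pooled variance; ",
            "standardization clamped at eps = 1e-8")
    v_star <- pmax(v_star, eps)
  }
  t_std <- (eff$log_or - theta_hat) / sqrt(v_star)
  # Kendall score: concordant minus discordant pairs (ties score 0)
  score <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      score <- score + sign(t_std[j] - t_std[i]) * sign(vi[j] - vi[i])
    }
  }
  n_pairs <- k * (k - 1) / 2
  tau <- score / n_pairs
  denom <- sqrt(k * (k - 1) * (2 * k + 5) / 18)
  z <- if (abs(score) <= 1) 0 else sign(score) * (abs(score) - 1) / denom
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(test = "begg", k = k, tau = tau, z = z, p = p),
    class = "bias_test"
  )
}

#' Funnel-plot data export
#'
#' Per-study quantities sufficient to draw a funnel plot externally.
#'
#' @param effects As in [egger_test()].
#' @return A data.frame: `study_id`, `log_or`, `se`, `precision` (1/se) and
#'   `std_effect` (log_or/se).
#' @export
funnel_data <- function(effects) {
  eff <- effects_frame(effects)
  data.frame(
    study_id = eff$study_id, log_or = eff$log_or, se = eff$se,
    precision = 1 / eff$se, std_effect = eff$log_or / eff$se,
    stringsAsFactors = FALSE
  )
}

#' @export
print.bias_test <- function(x, ...) {
  if (x$test == "egger") {
    cat(sprintf("Egger's test (k=%d): intercept %.3f (SE %.3f), t=%.3f, p=%.3f\n",
                x$k, x$intercept, x$se, x$t, x$p))
  } else {
    cat(sprintf("Begg's test (k=%d): tau=%.3f, z=%.3f, p=%.3f\n",
                x$k, x$tau, x$z, x$p))
  }
  invisible(x)
}
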