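# Per-study effects and pooled estimators.
#
# Per-study effect: log OR = ln(ad/bc), SE = sqrt(1/a+1/b+1/c+1/d) (Woolf).
# Fixed-effect pooling: Mantel-Haenszel (default; variance of the log MH OR
# by Robins-Breslow-Greenland) or inverse-variance. Random effects:
# DerSimonian-Laird moment estimator of tau^2 on top of the IV pass.
# Heterogeneity (Cochran's Q, I^2, tau^2) is always computed with
# inverse-variance weights around the IV fixed estimate, so that the
# heterogeneity assessment does not depend on the MH/IV choice.

Z975 <- stats::qnorm(0.975)

#' Per-study odds ratio and standard error
#'
#' Computes the log odds ratio `ln(ad/bc)` and its Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` from a (continuity-corrected, informative)
#' fourfold table.
#'
#' @param table A `fourfold` (see [build_fourfold()], [apply_continuity()]).
#' @return An `effect_estimate`: list with `log_or`, `se`, `or`, `ci_low`,
#'   `ci_high` (95% Wald interval) and `study_id`.
#' @examples
#' ff <- build_fourfold(rs1063192_studies()[1, ], "homozygote")
#' study_effect(ff)  # OR = (2*58)/(53*5) ~ 0.438
#' @export
study_effect <- function(table) {
  if (!table$informative) {
    stop("cannot estimate an effect from a non-informative table",
         call. = FALSE)
  }
  if (min(table$a, table$b, table$c, table$d) == 0) {
    stop("zero cell remains (continuity policy 'none'): odds ratio undefined",
         call. = FALSE)
  }
  log_or <- log(table$a * table$d / (table$b * table$c))
  se <- sqrt(1 / table$a + 1 / table$b + 1 / table$c + 1 / table$d)
  structure(
    list(log_or = log_or, se = se, or = exp(log_or),
         ci_low = exp(log_or - Z975 * se), ci_high = exp(log_or + Z975 * se),
         study_id = table$study_id),
    class = "effect_estimate"
  )
}

# Effects as a data.frame; accepts a list of fourfolds or of effect_estimates.
effects_frame <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("log_or", "se") %in% names(x)))
    if (is.null(x$study_id)) x$study_id <- as.character(seq_len(nrow(x)))
    return(x)
  }
  eff <- lapply(x, function(e) {
    if (inherits(e, "fourfold")) e <- study_effect(e)
    e
  })
  data.frame(
    study_id = vapply(eff, function(e)
      as.character(e$study_id %||% NA_character_), character(1)),
    log_or = vapply(eff, function(e) e$log_or, numeric(1)),
    se = vapply(eff, function(e) e$se, numeric(1)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Heterogeneity from IV weights around the IV fixed estimate.
heterogeneity_iv <- function(log_or, se) {
  k <- length(log_or)
  w <- 1 / se^2
  theta_iv <- sum(w * log_or) / sum(w)
  Q <- sum(w * (log_or - theta_iv)^2)
  df <- k - 1L
  if (df <= 0) {
    return(list(Q = 0, df = 0L, p_Q = 1, I2 = 0, tau2 = 0,
                theta_iv = theta_iv, se_iv = 1 / sqrt(sum(w))))
  }
  p_Q <- stats::pchisq(Q, df, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, df = as.integer(df), p_Q = p_Q, I2 = I2, tau2 = tau2,
       theta_iv = theta_iv, se_iv = 1 / sqrt(sum(w)))
}

new_pooled_result <- function(model, method, k, log_or, se, het,
                              studies = NULL, weights = NULL) {
  z <- log_or / se
  structure(
    list(model = model, method = method, k = as.integer(k),
         log_or = log_or, se = se, or = exp(log_or),
         ci_low = exp(log_or - Z975 * se), ci_high = exp(log_or + Z975 * se),
         z = z, p = 2 * stats::pnorm(-abs(z)),
         Q = het$Q, df = het$df, p_Q = het$p_Q, I2 = het$I2,
         tau2 = if (method == "RANDOM_DL") het$tau2 else 0,
         studies = studies, weights = weights),
    class = "pooled_result"
  )
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' Pools fourfold tables with the Mantel-Haenszel estimator
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`; the variance of the
#' log pooled OR uses the Robins-Breslow-Greenland formula. Heterogeneity
#' (Q, I-squared) is computed with inverse-variance weights around the IV
#' fixed estimate.
#'
#' @param tables List of informative, continuity-corrected `fourfold`s for
#'   the same genetic model.
#' @return A `pooled_result` with `method = "FIXED_MH"`.
#' @export
pool_fixed_mh <- function(tables) {
  k <- length(tables)
  if (k == 0) stop("no informative studies to pool", call. = FALSE)
  A <- vapply(tables, function(t) t$a, numeric(1))
  B <- vapply(tables, function(t) t$b, numeric(1))
  C <- vapply(tables, function(t) t$c, numeric(1))
  D <- vapply(tables, function(t) t$d, numeric(1))
  n <- A + B + C + D
  R <- sum(A * D / n)
  S <- sum(B * C / n)
  log_or <- log(R / S)
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (A + D) / n
  Qc <- (B + C) / n
  Ri <- A * D / n
  Si <- B * C / n
  var_mh <- sum(P * Ri) / (2 * R^2) +
    sum(P * Si + Qc * Ri) / (2 * R * S) +
    sum(Qc * Si) / (2 * S^2)
  eff <- effects_frame(tables)
  het <- heterogeneity_iv(eff$log_or, eff$se)
  new_pooled_result(tables[[1]]$model, "FIXED_MH", k, log_or, sqrt(var_mh),
                    het, studies = eff, weights = Si / S)
}

#' Inverse-variance fixed-effect pooling
#'
#' Weights each study's log OR by the reciprocal of its variance:
#' pooled estimate `sum(w theta) / sum(w)` with `SE = 1/sqrt(sum(w))`.
#'
#' @param effects List of `effect_estimate`s (or `fourfold`s, or a
#'   data.frame with `log_or` and `se` columns).
#' @param model Genetic-model tag carried into the result.
#' @return A `pooled_result` with `method = "FIXED_IV"`.
#' @export
pool_fixed_iv <- function(effects, model = NA_character_) {
  eff <- effects_frame(effects)
  if (nrow(eff) == 0) stop("no studies to pool", call. = FALSE)
  het <- heterogeneity_iv(eff$log_or, eff$se)
  w <- 1 / eff$se^2
  new_pooled_result(model, "FIXED_IV", nrow(eff), het$theta_iv, het$se_iv,
                    het, studies = eff, weights = w / sum(w))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Estimates the between-study variance by the DerSimonian-Laird moment
#' estimator `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` from
#' the inverse-variance fixed pass, then re-pools with weights
#' `1 / (se^2 + tau^2)`. With `tau^2 = 0` the result coincides exactly with
#' [pool_fixed_iv()].
#'
#' @inheritParams pool_fixed_iv
#' @return A `pooled_result` with `method = "RANDOM_DL"`; requires k >= 2.
#' @export
pool_random_dl <- function(effects, model = NA_character_) {
  eff <- effects_frame(effects)
  if (nrow(eff) < 2) {
    stop("random-effects pooling requires at least 2 studies", call. = FALSE)
  }
  het <- heterogeneity_iv(eff$log_or, eff$se)
  w_star <- 1 / (eff$se^2 + het$tau2)
  log_or <- sum(w_star * eff$log_or) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  new_pooled_result(model, "RANDOM_DL", nrow(eff), log_or, se, het,
                    studies = eff, weights = w_star / sum(w_star))
}

#' Fixed- vs random-effects selection rule
#'
#' A random-effects model is used when the Q test indicates heterogeneity at
#' `p_Q < alpha_Q` or when `I^2 > I2_cut` percent; otherwise the
#' fixed-effects model applies. Both inequalities are strict, so the
#' boundary values (`p_Q = 0.1`, `I^2 = 50`) select the fixed model.
#'
#' @param p_Q Heterogeneity p-value from Cochran's Q.
#' @param I2 I-squared, in percent.
#' @param alpha_Q Q-test threshold (default 0.1).
#' @param I2_cut I-squared threshold in percent (default 50).
#' @param fixed Which fixed estimator to name: `"MH"` or `"IV"`.
#' @return `"RANDOM_DL"`, `"FIXED_MH"` or `"FIXED_IV"`.
#' @export
select_model <- function(p_Q, I2, alpha_Q = 0.1, I2_cut = 50,
                         fixed = c("MH", "IV")) {
  fixed <- match.arg(fixed)
  if (p_Q < alpha_Q || I2 > I2_cut) "RANDOM_DL" else paste0("FIXED_", fixed)
}

#' Meta-analysis of one genetic model over a study table
#'
#' Runs the full pipeline for a single contrast: builds per-study 2x2
#' tables, drops non-informative studies (recording them), applies the
#' continuity policy, pools, and — under `method = "auto"` — chooses fixed
#' or random effects by [select_model()] on the inverse-variance Q test.
#'
#' @param table A `study_table`.
#' @param model One of [genetic_models()].
#' @param method `"auto"` (heterogeneity-driven, default), `"fixed"`, or
#'   `"random"`.
#' @param fixed Fixed-effect estimator: `"MH"` (Mantel-Haenszel, default) or
#'   `"IV"` (inverse-variance).
#' @param continuity Zero-cell policy, see [apply_continuity()].
#' @param alpha_Q,I2_cut Thresholds for [select_model()].
#' @return A `pooled_result`; additionally carries `excluded_rows`
#'   (non-informative row indices), `rows` (informative row indices) and
#'   `selected` (`TRUE` when the method came from the auto rule).
#' @examples
#' meta_analyze(rs1063192_studies(), "homozygote")  # OR 0.55, Fixed
#' @export
meta_analyze <- function(table, model,
                         method = c("auto", "fixed", "random"),
                         fixed = c("MH", "IV"),
                         continuity = c("add_half_all_cells_if_any_zero",
                                        "none"),
                         alpha_Q = 0.1, I2_cut = 50) {
  method <- match.arg(method)
  fixed <- match.arg(fixed)
  continuity <- match.arg(continuity)
  model <- match.arg(model, genetic_models())
  ffs <- fourfold_tables(table, model, continuity = continuity)
  k <- length(ffs$tables)
  if (k == 0) stop("no informative studies for model ", model, call. = FALSE)
  eff <- effects_frame(ffs$tables)
  het <- heterogeneity_iv(eff$log_or, eff$se)
  chosen <- switch(method,
    auto = select_model(het$p_Q, het$I2, alpha_Q, I2_cut, fixed),
    fixed = paste0("FIXED_", fixed),
    random = "RANDOM_DL"
  )
  if (chosen == "RANDOM_DL" && k < 2) chosen <- paste0("FIXED_", fixed)
  res <- switch(chosen,
    FIXED_MH = pool_fixed_mh(ffs$tables),
    FIXED_IV = pool_fixed_iv(ffs$tables, model = model),
    RANDOM_DL = pool_random_dl(ffs$tables, model = model)
  )
  res$model <- model
  res$excluded_rows <- ffs$excluded
  res$rows <- ffs$rows
  res$selected <- method == "auto"
  res$tables <- ffs$tables
  res
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %.4f (95%% CI %.4f-%.4f), log OR %.4f (SE %.4f)\n",
              x$study_id, x$or, x$ci_low, x$ci_high, x$log_or, x$se))
  invisible(x)
}

#' @export
print.pooled_result <- function(x, ...) {
  lab <- if (is.na(x$model)) "" else paste0(model_label(x$model), ", ")
  cat(sprintf("Pooled OR (%s%s, k=%d): %.2f (95%% CI %.2f-%.2f), p=%.3g\n",
              lab, x$method, x$k, x$or, x$ci_low, x$ci_high, x$p))
  cat(sprintf("Heterogeneity: Q=%.2f (df=%d, p=%.3f), I2=%.1f%%, tau2=%.4f\n",
              x$Q, x$df, x$p_Q, x$I2, x$tau2))
  invisible(x)
}
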