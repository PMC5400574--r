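# Hardy-Weinberg equilibrium testing and allele-based power calculation.

#' Pearson chi-squared test for Hardy-Weinberg equilibrium
#'
#' Compares observed control genotype counts against the Hardy-Weinberg
#' expectations `n(1-q)^2, 2nq(1-q), nq^2` at the observed effect-allele
#' frequency `q = (2 cc + tc) / 2n`, on 1 degree of freedom (one free allele
#' frequency), with no continuity correction. A monomorphic sample
#' (`q` equal to 0 or 1) carries no information about equilibrium and is
#' reported as not assessable rather than tested.
#'
#' @param tt,tc,cc Genotype counts (T-homozygote, heterozygote,
#'   C-homozygote); total must be at least 1.
#' @return An `hwe_result`: list with `chi2`, `df = 1`, `p`, `assessable`,
#'   `maf` (minor-allele frequency) and `allele_freq` (effect-allele
#'   frequency q). `chi2` and `p` are `NA` when not assessable.
#' @examples
#' hwe_test(58, 31, 5)   # Abu-Amero2016 controls: p > 0.05
#' hwe_test(25, 50, 25)  # perfect equilibrium: chi2 = 0, p = 1
#' @export
hwe_test <- function(tt, tc, cc) {
  n <- tt + tc + cc
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  q <- (2 * cc + tc) / (2 * n)
  if (q == 0 || q == 1) {
    return(structure(
      list(chi2 = NA_real_, df = 1L, p = NA_real_, assessable = FALSE,
           maf = 0, allele_freq = q),
      class = "hwe_result"
    ))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((c(tt, tc, cc) - expected)^2 / expected)
  structure(
    list(chi2 = chi2, df = 1L,
         p = stats::pchisq(chi2, 1, lower.tail = FALSE),
         assessable = TRUE, maf = min(q, 1 - q), allele_freq = q),
    class = "hwe_result"
  )
}

#' Per-study HWE summary for a study table
#'
#' Recomputes Hardy-Weinberg equilibrium in the controls of every cohort
#' and, when the table carries a reported flag (`hwe_flag_reported`),
#' compares it with the recomputed verdict (`Y` when p > 0.05,
#' `not_assessable` for monomorphic controls).
#'
#' @param table A `study_table`.
#' @param alpha Significance level for the recomputed flag (default 0.05).
#' @return A data.frame: study, chi2, p, assessable, maf, recomputed flag
#'   and (if available) reported flag plus agreement.
#' @export
hwe_table <- function(table, alpha = 0.05) {
  res <- lapply(seq_len(nrow(table)), function(i) {
    h <- hwe_test(table$ctrl_tt[i], table$ctrl_tc[i], table$ctrl_cc[i])
    data.frame(
      study_id = table$study_id[i],
      chi2 = h$chi2, p = h$p, assessable = h$assessable, maf = h$maf,
      hwe_flag = if (!h$assessable) "not_assessable"
                 else if (h$p > alpha) "Y" else "N",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (!is.null(table$hwe_flag_reported)) {
    out$hwe_flag_reported <- table$hwe_flag_reported
    out$agrees <- out$hwe_flag == out$hwe_flag_reported
  }
  rownames(out) <- NULL
  out
}

#' Statistical power of an allele-contrast case-control comparison
#'
#' Normal-approximation power for detecting an allele odds ratio at a
#' two-sided significance level. The expected case allele frequency is
#' derived from the control frequency and the assumed OR via
#' `odds_case = OR * odds_control`; the SE of the log OR comes from the
#' expected allele-count 2x2 table at the given sample sizes (2 alleles per
#' subject); power is
#' `Phi(|ln OR|/SE - z_{1-alpha/2}) + Phi(-|ln OR|/SE - z_{1-alpha/2})`.
#'
#' @param n_cases,n_controls Numbers of case and control subjects.
#' @param control_maf Effect-allele frequency in controls, in (0, 1).
#' @param assumed_or Allele odds ratio to detect (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `power_result`: list with `power`, `assumed_or`, `alpha`,
#'   `n_cases`, `n_controls`, `control_maf`, `case_maf`, `se_log_or` and
#'   a `method` note.
#' @examples
#' power_analysis(11316, 24055, 0.257, assumed_or = 0.76)$power  # ~1
#' @export
power_analysis <- function(n_cases, n_controls, control_maf, assumed_or,
                           alpha = 0.05) {
  if (control_maf <= 0 || control_maf >= 1) {
    stop("control_maf must lie strictly between 0 and 1", call. = FALSE)
  }
  if (assumed_or <= 0) stop("assumed_or must be positive", call. = FALSE)
  q0 <- control_maf
  odds1 <- assumed_or * q0 / (1 - q0)
  q1 <- odds1 / (1 + odds1)
  m_case <- 2 * n_cases
  m_ctrl <- 2 * n_controls
  se <- sqrt(1 / (m_case * q1) + 1 / (m_case * (1 - q1)) +
             1 / (m_ctrl * q0) + 1 / (m_ctrl * (1 - q0)))
  z_crit <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(log(assumed_or)) / se
  power <- stats::pnorm(ncp - z_crit) + stats::pnorm(-ncp - z_crit)
  structure(
    list(power = power, assumed_or = assumed_or, alpha = alpha,
         n_cases = n_cases, n_controls = n_controls,
         control_maf = control_maf, case_maf = q1, se_log_or = se,
         method = "allele-contrast normal approximation (2N independent alleles)"),
    class = "power_result"
  )
}

#' Pooled effect-allele frequency of controls
#'
#' Allele frequency of the effect allele C over all control genotypes of a
#' study table combined; the natural input for [power_analysis()].
#'
#' @param table A `study_table`.
#' @return A single frequency in `[0, 1]`.
#' @export
pooled_control_maf <- function(table) {
  sum(2 * table$ctrl_cc + table$ctrl_tc) /
    (2 * sum(table$ctrl_tt + table$ctrl_tc + table$ctrl_cc))
}

#' @export
print.hwe_result <- function(x, ...) {
  if (!x$assessable) {
    cat("HWE: not assessable (monomorphic controls)\n")
  } else {
    cat(sprintf("HWE chi2=%.4f (df=1), p=%.4f, MAF=%.3f\n", x$chi2, x$p, x$maf))
  }
  invisible(x)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power %.3f to detect OR %.2f at alpha %.2f (%d cases / %d controls, control allele freq %.3f)\n",
              x$power, x$assumed_or, x$alpha, x$n_cases, x$n_controls,
              x$control_maf))
  invisible(x)
}
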