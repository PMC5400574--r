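# Simulation of study tables with the generative structure the analysis
# assumes: control genotypes in Hardy-Weinberg proportions at a study-level
# allele frequency, a common (or normally heterogeneous) allele log OR, and
# case genotypes in HW proportions at the implied case allele frequency.

#' Configuration for the study-table simulator
#'
#' Defaults mirror the scale of the packaged rs1063192 dataset: 14 cohorts,
#' a protective allele OR of 0.76, homogeneous effects (`tau = 0`), control
#' minor-allele frequencies uniform on (0.10, 0.45) and per-arm sample sizes
#' uniform on 100-2000 subjects.
#'
#' @param k Number of studies.
#' @param true_allele_or True allele odds ratio (> 0).
#' @param tau Between-study SD of the log OR (>= 0).
#' @param maf_law Lower/upper bounds of the uniform law for the control
#'   effect-allele frequency, inside (0, 1).
#' @param n_case_law,n_ctrl_law Integer ranges (low, high) for per-study
#'   case and control sample sizes.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(k = 14, true_allele_or = 0.76, tau = 0,
                             maf_law = c(0.10, 0.45),
                             n_case_law = c(100L, 2000L),
                             n_ctrl_law = c(100L, 2000L),
                             seed = 1L) {
  stopifnot(k >= 1, true_allele_or > 0, tau >= 0,
            length(maf_law) == 2, maf_law[1] > 0, maf_law[2] < 1,
            maf_law[1] <= maf_law[2],
            n_case_law[1] >= 1, n_case_law[1] <= n_case_law[2],
            n_ctrl_law[1] >= 1, n_ctrl_law[1] <= n_ctrl_law[2])
  structure(
    list(k = as.integer(k), true_allele_or = true_allele_or, tau = tau,
         maf_law = maf_law,
         n_case_law = as.integer(n_case_law),
         n_ctrl_law = as.integer(n_ctrl_law),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# HW genotype probabilities at effect-allele frequency q, ordered TT/TC/CC.
hw_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Simulate a study genotype table
#'
#' For each study: the control effect-allele frequency `q` is drawn from
#' the configured uniform law; control genotypes are multinomial under
#' Hardy-Weinberg at `q`; the study's log OR is
#' `ln(true_allele_or) + Normal(0, tau^2)`; the case allele frequency `q'`
#' solves `odds(q') = OR_study * odds(q)`; and case genotypes are
#' multinomial under Hardy-Weinberg at `q'`. Ethnicity and source-of-control
#' labels are assigned round-robin over
#' {Caucasian, Asian, African} x {HB, PB}, so every stratum is populated
#' for k >= 6.
#'
#' @param config A [synthetic_config()].
#' @return A `study_table` with k rows, consumable by the whole pipeline.
#' @examples
#' tab <- simulate_study_table(synthetic_config(k = 6, seed = 42))
#' meta_analyze(tab, "allele")
#' @export
simulate_study_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  simulate_study_table_impl(config)
}

# Internal: draws one table from the current RNG state (no re-seeding),
# so replicate loops can advance the stream.
simulate_study_table_impl <- function(config) {
  k <- config$k
  q0 <- stats::runif(k, config$maf_law[1], config$maf_law[2])
  log_or <- log(config$true_allele_or) + stats::rnorm(k, 0, config$tau)
  odds1 <- exp(log_or) * q0 / (1 - q0)
  q1 <- odds1 / (1 + odds1)
  n_case <- sample_range(k, config$n_case_law)
  n_ctrl <- sample_range(k, config$n_ctrl_law)
  eth <- rep(c("Caucasian", "Asian", "African"), length.out = k)
  soc <- rep(rep(c("HB", "PB"), each = 3), length.out = k)
  rows <- lapply(seq_len(k), function(i) {
    case_g <- stats::rmultinom(1, n_case[i], hw_probs(q1[i]))[, 1]
    ctrl_g <- stats::rmultinom(1, n_ctrl[i], hw_probs(q0[i]))[, 1]
    data.frame(
      study_id = sprintf("sim%02d", i), year = 2000L + i,
      ethnicity = eth[i], soc = soc[i],
      case_tt = case_g[1], case_tc = case_g[2], case_cc = case_g[3],
      ctrl_tt = ctrl_g[1], ctrl_tc = ctrl_g[2], ctrl_cc = ctrl_g[3],
      stringsAsFactors = FALSE
    )
  })
  as_study_table(do.call(rbind, rows),
                 provenance = sprintf("simulated (k=%d, OR=%g, tau=%g, seed=%d)",
                                      k, config$true_allele_or, config$tau,
                                      config$seed))
}

sample_range <- function(k, range) {
  if (range[1] == range[2]) rep(range[1], k)
  else sample(range[1]:range[2], k, replace = TRUE)
}

#' Null-calibration of the pipeline's tests by simulation
#'
#' Simulates meta-analyses and records how often each test rejects: the
#' pooled z-test (at `alpha`), Cochran's Q test (at `alpha_Q`), and Egger's
#' and Begg's tests (at `alpha`). With `true_allele_or = 1` and `tau = 0`
#' this measures empirical type-I error; with heterogeneity or a real
#' effect it measures power.
#'
#' @param config A [synthetic_config()]; for type-I error of the pooled
#'   test use `true_allele_or = 1`.
#' @param replicates Number of simulated meta-analyses; 0 gives an empty
#'   report.
#' @param alpha Level for the pooled, Egger and Begg tests (default 0.05).
#' @param alpha_Q Level for the Q test (default 0.1).
#' @param model Genetic model analysed in each replicate (default allele).
#' @return A data.frame with one row per test: rejections, replicates,
#'   empirical rate and its binomial Monte-Carlo SE.
#' @export
simulate_null_meta <- function(config, replicates, alpha = 0.05,
                               alpha_Q = 0.1, model = "allele") {
  stopifnot(inherits(config, "synthetic_config"), replicates >= 0)
  tests <- c("pooled_z", "cochran_q", "egger", "begg")
  if (replicates == 0) {
    return(data.frame(test = character(0), alpha = numeric(0),
                      rejections = integer(0), replicates = integer(0),
                      rate = numeric(0), mc_se = numeric(0)))
  }
  set.seed(config$seed)
  rej <- setNames(numeric(4), tests)
  n_eval <- setNames(numeric(4), tests)
  for (r in seq_len(replicates)) {
    tab <- simulate_study_table_impl(config)
    res <- tryCatch(meta_analyze(tab, model, method = "fixed"),
                    error = function(e) NULL)
    if (is.null(res)) next
    n_eval["pooled_z"] <- n_eval["pooled_z"] + 1
    if (res$p < alpha) rej["pooled_z"] <- rej["pooled_z"] + 1
    if (res$df >= 1) {
      n_eval["cochran_q"] <- n_eval["cochran_q"] + 1
      if (res$p_Q < alpha_Q) rej["cochran_q"] <- rej["cochran_q"] + 1
    }
    if (res$k >= 3) {
      eg <- tryCatch(egger_test(res$studies), error = function(e) NULL)
      if (!is.null(eg)) {
        n_eval["egger"] <- n_eval["egger"] + 1
        if (eg$p < alpha) rej["egger"] <- rej["egger"] + 1
      }
      bg <- tryCatch(suppressWarnings(begg_test(res$studies)),
                     error = function(e) NULL)
      if (!is.null(bg)) {
        n_eval["begg"] <- n_eval["begg"] + 1
        if (bg$p < alpha) rej["begg"] <- rej["begg"] + 1
      }
    }
  }
  rate <- ifelse(n_eval > 0, rej / n_eval, NA_real_)
  data.frame(
    test = tests,
    alpha = c(alpha, alpha_Q, alpha, alpha),
    rejections = as.integer(rej), replicates = as.integer(n_eval),
    rate = rate,
    mc_se = sqrt(rate * (1 - rate) / pmax(n_eval, 1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
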