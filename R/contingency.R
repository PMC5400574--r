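# Collapsing 3-genotype counts to 2x2 tables under genetic-model contrasts.

#' The five genetic-model contrasts
#'
#' Names of the five standard ways of collapsing a biallelic 3-genotype
#' case-control table to a 2x2 table, with C as the effect allele
#' throughout: `allele` (C vs T, counting 2N alleles), `dominant`
#' (CC+TC vs TT), `recessive` (CC vs TC+TT), `homozygote` (CC vs TT,
#' heterozygotes dropped) and `heterozygote` (TC vs TT, CC-homozygotes
#' dropped).
#'
#' @return Character vector of the five model names.
#' @export
genetic_models <- function() {
  c("allele", "dominant", "recessive", "homozygote", "heterozygote")
}

#' Human-readable contrast label for a genetic model
#'
#' @param model One of [genetic_models()].
#' @return A label such as `"C vs. T"` or `"CC vs. TT"`.
#' @export
model_label <- function(model) {
  model <- match.arg(model, genetic_models())
  switch(model,
    allele = "C vs. T",
    dominant = "CC + TC vs. TT",
    recessive = "CC vs. TT + TC",
    homozygote = "CC vs. TT",
    heterozygote = "TC vs. TT"
  )
}

#' Build the 2x2 event table for one study under a genetic model
#'
#' Collapses a study's genotype counts into the fourfold table
#' (a = case events, b = case non-events, c = control events, d = control
#' non-events) for the requested contrast. For the allele model each subject
#' contributes two alleles, treated as independent observations (the
#' standard approximation in this literature). The homozygote and
#' heterozygote contrasts drop the genotype class not involved in the
#' comparison.
#'
#' A table is flagged non-informative when there are no events in both arms
#' (`a = 0` and `c = 0`) or no non-events in both arms (`b = 0` and
#' `d = 0`): such a study carries no information about the odds ratio and
#' is excluded from pooling for that contrast only. The flag is evaluated
#' before any continuity correction. Degenerate tables are flagged, never
#' rejected.
#'
#' @param record A single-row `study_table` slice (or equivalent list).
#' @param model One of [genetic_models()].
#' @return A `fourfold` object: list with `a`, `b`, `c`, `d`, `model`,
#'   `study_id`, `informative` and `corrected` (always `FALSE` here; see
#'   [apply_continuity()]).
#' @examples
#' rec <- rs1063192_studies()[1, ]  # Abu-Amero2016
#' build_fourfold(rec, "homozygote")  # a=2 b=53 c=5 d=58
#' @export
build_fourfold <- function(record, model) {
  model <- match.arg(model, genetic_models())
  cells <- switch(model,
    allele = c(
      a = 2 * record$case_cc + record$case_tc,
      b = 2 * record$case_tt + record$case_tc,
      c = 2 * record$ctrl_cc + record$ctrl_tc,
      d = 2 * record$ctrl_tt + record$ctrl_tc
    ),
    dominant = c(
      a = record$case_cc + record$case_tc, b = record$case_tt,
      c = record$ctrl_cc + record$ctrl_tc, d = record$ctrl_tt
    ),
    recessive = c(
      a = record$case_cc, b = record$case_tc + record$case_tt,
      c = record$ctrl_cc, d = record$ctrl_tc + record$ctrl_tt
    ),
    homozygote = c(
      a = record$case_cc, b = record$case_tt,
      c = record$ctrl_cc, d = record$ctrl_tt
    ),
    heterozygote = c(
      a = record$case_tc, b = record$case_tt,
      c = record$ctrl_tc, d = record$ctrl_tt
    )
  )
  cells <- as.numeric(cells)
  informative <- !((cells[1] == 0 && cells[3] == 0) ||
                   (cells[2] == 0 && cells[4] == 0))
  structure(
    list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
         model = model,
         study_id = if (!is.null(record$study_id)) record$study_id else NA_character_,
         informative = informative, corrected = FALSE),
    class = "fourfold"
  )
}

#' Continuity correction for sparse 2x2 tables
#'
#' Under the default policy, a study whose fourfold table contains any zero
#' cell gets 0.5 added to all four cells (the convention of the mainstream
#' meta-analysis software family); tables without zeros are untouched.
#' Applying a correction to a non-informative table is a contract error —
#' such tables must be excluded, not patched.
#'
#' @param table A `fourfold` from [build_fourfold()].
#' @param policy `"add_half_all_cells_if_any_zero"` (default) or `"none"`.
#' @return The corrected `fourfold`; `corrected` is `TRUE` iff cells changed.
#' @export
apply_continuity <- function(table,
                             policy = c("add_half_all_cells_if_any_zero",
                                        "none")) {
  policy <- match.arg(policy)
  if (!table$informative) {
    stop("continuity correction applied to a non-informative table",
         call. = FALSE)
  }
  if (policy == "add_half_all_cells_if_any_zero" &&
      min(table$a, table$b, table$c, table$d) == 0) {
    table$a <- table$a + 0.5
    table$b <- table$b + 0.5
    table$c <- table$c + 0.5
    table$d <- table$d + 0.5
    table$corrected <- TRUE
  }
  table
}

#' All per-study 2x2 tables for one genetic model
#'
#' Convenience wrapper running [build_fourfold()] over every row of a study
#' table and [apply_continuity()] over the informative ones.
#'
#' @param table A `study_table`.
#' @param model One of [genetic_models()].
#' @param continuity Continuity policy passed to [apply_continuity()].
#' @return A list with `tables` (informative, corrected `fourfold`s),
#'   `excluded` (row indices of non-informative studies) and `rows`
#'   (row indices of the informative ones, parallel to `tables`).
#' @export
fourfold_tables <- function(table, model,
                            continuity = c("add_half_all_cells_if_any_zero",
                                           "none")) {
  continuity <- match.arg(continuity)
  ffs <- lapply(seq_len(nrow(table)), function(i) {
    build_fourfold(table[i, , drop = FALSE], model)
  })
  informative <- vapply(ffs, function(f) f$informative, logical(1))
  list(
    tables = lapply(ffs[informative], apply_continuity, policy = continuity),
    excluded = which(!informative),
    rows = which(informative)
  )
}

#' @export
print.fourfold <- function(x, ...) {
  cat(sprintf("fourfold [%s] %s: a=%g b=%g c=%g d=%g%s%s\n",
              x$model, x$study_id, x$a, x$b, x$c, x$d,
              if (x$corrected) " (0.5 added)" else "",
              if (!x$informative) " NON-INFORMATIVE" else ""))
  invisible(x)
}
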