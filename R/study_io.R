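# Reading, validating and writing per-study genotype count tables.
#
# A study table is a data.frame with one row per case-control cohort and the
# mandatory columns study_id, year, ethnicity, soc, case_tt, case_tc,
# case_cc, ctrl_tt, ctrl_tc, ctrl_cc. The genotype columns refer to the
# effect allele C: `*_cc` counts C-homozygotes, `*_tc` heterozygotes and
# `*_tt` T-homozygotes. Any further column is carried along and usable as a
# subgroup label.

MANDATORY_COLUMNS <- c(
  "study_id", "year", "ethnicity", "soc",
  "case_tt", "case_tc", "case_cc", "ctrl_tt", "ctrl_tc", "ctrl_cc"
)
COUNT_COLUMNS <- MANDATORY_COLUMNS[5:10]
ETHNICITY_LEVELS <- c("Caucasian", "Asian", "African", "other")
SOC_LEVELS <- c("HB", "PB")

#' Read a study genotype table from TSV or CSV
#'
#' Parses a delimited file with one row per case-control cohort and validates
#' it (see [validate_study_table()]). Mandatory columns are `study_id`,
#' `year`, `ethnicity`, `soc` and the six genotype counts `case_tt`,
#' `case_tc`, `case_cc`, `ctrl_tt`, `ctrl_tc`, `ctrl_cc`; unknown columns are
#' retained and can serve as extra grouping labels. `study_id` values need
#' not be unique — independent cohorts reported in one publication share an
#' id and are treated as separate analysis units.
#'
#' @param path Path to the input file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated `study_table` (a `data.frame` subclass) with a
#'   `provenance` attribute recording the source path.
#' @examples
#' tab <- rs1063192_studies()
#' table_totals(tab)
#' @seealso [rs1063192_studies()] for the packaged example dataset.
#' @export
read_study_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          fileEncoding = "UTF-8")
  as_study_table(df, provenance = path)
}

#' Construct a study table from a data.frame
#'
#' @param df A data.frame carrying the mandatory study-table columns.
#' @param provenance Free-text note on where the rows came from.
#' @return A validated `study_table`.
#' @export
as_study_table <- function(df, provenance = "in-memory") {
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("study table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  validate_study_table(df)
  structure(df, class = c("study_table", "data.frame"),
            provenance = provenance)
}

#' Validate a study genotype table
#'
#' Checks that all six genotype counts are non-negative integers, that every
#' cohort has at least one case and one control, and that `ethnicity` and
#' `soc` come from their closed vocabularies (`Caucasian`, `Asian`,
#' `African`, `other`; `HB`, `PB`). Errors name the offending row and field.
#'
#' @param df A data.frame with the mandatory columns.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_study_table <- function(df) {
  for (col in COUNT_COLUMNS) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop("column ", col, " must be numeric", call. = FALSE)
    }
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      stop("row ", bad[1], ", field ", col,
           ": counts must be non-negative integers (got ",
           v[bad[1]], ")", call. = FALSE)
    }
  }
  case_tot <- df$case_tt + df$case_tc + df$case_cc
  ctrl_tot <- df$ctrl_tt + df$ctrl_tc + df$ctrl_cc
  if (any(case_tot < 1)) {
    stop("row ", which(case_tot < 1)[1], ": case total must be >= 1",
         call. = FALSE)
  }
  if (any(ctrl_tot < 1)) {
    stop("row ", which(ctrl_tot < 1)[1], ": control total must be >= 1",
         call. = FALSE)
  }
  bad_eth <- which(!df$ethnicity %in% ETHNICITY_LEVELS)
  if (length(bad_eth) > 0) {
    stop("row ", bad_eth[1], ", field ethnicity: unknown value '",
         df$ethnicity[bad_eth[1]], "' (allowed: ",
         paste(ETHNICITY_LEVELS, collapse = ", "), ")", call. = FALSE)
  }
  bad_soc <- which(!df$soc %in% SOC_LEVELS)
  if (length(bad_soc) > 0) {
    stop("row ", bad_soc[1], ", field soc: unknown value '",
         df$soc[bad_soc[1]], "' (allowed: HB, PB)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a study table back to disk
#'
#' Round-trips with [read_study_table()]: counts and metadata are reproduced
#' field-for-field.
#'
#' @param table A `study_table`.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_study_table <- function(table, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep,
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Case, control and row totals of a study table
#'
#' @param table A `study_table` (or any data.frame with the count columns);
#'   an empty table yields zeros.
#' @return A list with `total_cases`, `total_controls` and `n_rows`.
#' @examples
#' table_totals(rs1063192_studies())  # 11316 cases, 24055 controls, 16 rows
#' @export
table_totals <- function(table) {
  list(
    total_cases = sum(table$case_tt + table$case_tc + table$case_cc),
    total_controls = sum(table$ctrl_tt + table$ctrl_tc + table$ctrl_cc),
    n_rows = nrow(table)
  )
}

#' Packaged CDKN2B rs1063192 glaucoma study table
#'
#' Genotype counts for the CDKN2B rs1063192 polymorphism from 14 published
#' case-control studies of glaucoma (16 cohorts; two publications each
#' contribute two independent cohorts), totalling 11,316 cases and 24,055
#' controls, together with ethnicity, source of controls (hospital- vs
#' population-based), country, genotyping method and the Hardy-Weinberg
#' flag as reported by each study. The reported HWE flag is carried for
#' comparison only; the pipeline recomputes HWE from the control counts
#' (see [hwe_table()]).
#'
#' @return A `study_table` with 16 rows.
#' @export
rs1063192_studies <- function() {
  path <- system.file("extdata", "rs1063192_glaucoma.tsv",
                      package = "snpmeta", mustWork = TRUE)
  read_study_table(path, dialect = "tsv")
}

#' @export
print.study_table <- function(x, ...) {
  tot <- table_totals(x)
  cat(sprintf("study_table: %d cohort(s), %d cases / %d controls\n",
              tot$n_rows, tot$total_cases, tot$total_controls))
  cat("provenance:", attr(x, "provenance"), "\n")
  print.data.frame(x, ...)
  invisible(x)
}
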