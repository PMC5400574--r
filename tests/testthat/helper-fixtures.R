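# Shared builders for tests: tiny study records and raw fourfold tables.

make_record <- function(case = c(10, 10, 10), ctrl = c(10, 10, 10),
                        study_id = "S1", ethnicity = "Asian", soc = "PB",
                        year = 2000) {
  data.frame(
    study_id = study_id, year = year, ethnicity = ethnicity, soc = soc,
    case_tt = case[1], case_tc = case[2], case_cc = case[3],
    ctrl_tt = ctrl[1], ctrl_tc = ctrl[2], ctrl_cc = ctrl[3],
    stringsAsFactors = FALSE
  )
}

make_table <- function(...) {
  as_study_table(do.call(rbind, list(...)), provenance = "test")
}

# A raw fourfold with given cells, bypassing genotype collapsing.
raw_ff <- function(a, b, c, d, model = "allele", study_id = "S1") {
  structure(
    list(a = a, b = b, c = c, d = d, model = model, study_id = study_id,
         informative = !((a == 0 && c == 0) || (b == 0 && d == 0)),
         corrected = FALSE),
    class = "fourfold"
  )
}

# Effect estimates as a plain data.frame input.
eff_df <- function(log_or, se, study_id = NULL) {
  data.frame(
    study_id = study_id %||% paste0("S", seq_along(log_or)),
    log_or = log_or, se = se, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
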