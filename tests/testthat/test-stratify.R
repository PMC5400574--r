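test_that("subgroup study counts on the packaged table match the analysis strata", {
  tab <- rs1063192_studies()
  k_eth <- function(model) {
    rep <- subgroup_analysis(tab, model, "ethnicity")
    vapply(rep$strata[c("Caucasian", "Asian", "African")],
           function(r) if (is.null(r)) 0L else r$k, integer(1))
  }
  k_soc <- function(model) {
    rep <- subgroup_analysis(tab, model, "soc")
    vapply(rep$strata[c("HB", "PB")],
           function(r) if (is.null(r)) 0L else r$k, integer(1))
  }
  expect_equal(unname(k_eth("allele")), c(5L, 7L, 3L))
  expect_equal(unname(k_eth("dominant")), c(5L, 7L, 3L))
  expect_equal(unname(k_eth("recessive")), c(5L, 7L, 2L))
  expect_equal(unname(k_eth("homozygote")), c(5L, 7L, 2L))
  expect_equal(unname(k_eth("heterozygote")), c(5L, 7L, 3L))
  expect_equal(unname(k_soc("allele")), c(6L, 9L))
  expect_equal(unname(k_soc("recessive")), c(6L, 8L))
  expect_equal(unname(k_soc("homozygote")), c(6L, 8L))
})

test_that("Caucasian homozygote stratum reproduces the published estimate", {
  rep <- subgroup_analysis(rs1063192_studies(), "homozygote", "ethnicity")
  cauc <- rep$strata$Caucasian
  expect_equal(cauc$k, 5L)
  expect_equal(round(cauc$or, 2), 0.51)
  expect_equal(round(cauc$ci_low, 2), 0.44)
  expect_equal(round(cauc$ci_high, 2), 0.58)
  expect_equal(rep$strata$African$k, 2L)  # recessive-style sparsity drops 2 rows
})

test_that("strata partition the informative set and k values add up", {
  tab <- rs1063192_studies()
  for (m in genetic_models()) {
    overall <- meta_analyze(tab, m)
    for (g in c("ethnicity", "soc")) {
      rep <- subgroup_analysis(tab, m, g)
      ks <- vapply(rep$strata, function(r) if (is.null(r)) 0L else r$k,
                   integer(1))
      expect_equal(sum(ks), overall$k)
      rows <- sort(unlist(lapply(names(rep$strata), function(cat) {
        r <- rep$strata[[cat]]
        if (is.null(r)) return(integer(0))
        which(tab[[g]] == cat)[r$rows]
      })))
      expect_equal(rows, overall$rows)  # union of strata = overall set
    }
  }
})

test_that("a one-study table grouped by its own label reduces to the study effect", {
  tab <- make_table(make_record(case = c(20, 15, 5), ctrl = c(18, 16, 6)))
  rep <- subgroup_analysis(tab, "allele", "soc")
  expect_length(rep$strata, 1)
  res <- rep$strata$PB
  expect_equal(res$k, 1L)
  single <- study_effect(apply_continuity(build_fourfold(tab[1, ], "allele")))
  expect_equal(res$or, single$or, tolerance = 1e-12)
})

test_that("per-stratum selection can differ from the inherited overall method", {
  tab <- rs1063192_studies()
  hb_inherit <- subgroup_analysis(tab, "allele", "soc")$strata$HB
  hb_per <- subgroup_analysis(tab, "allele", "soc",
                              method = "per_stratum")$strata$HB
  expect_equal(hb_inherit$method, "RANDOM_DL")   # overall allele is random
  expect_equal(hb_per$method, "FIXED_MH")        # HB alone is homogeneous
  expect_equal(hb_inherit$p_Q, hb_per$p_Q)       # heterogeneity unaffected
})

test_that("leave-one-out covers each informative study exactly once", {
  tab <- rs1063192_studies()
  rep <- leave_one_out(tab, "allele")
  expect_equal(nrow(rep$omissions), 15)
  expect_equal(sort(rep$omissions$omitted_row), sort(rep$overall$rows))
  expect_true(all(rep$omissions$k == 14))
  # stability: every omission CI overlaps the overall CI
  expect_true(all(rep$omissions$ci_low <= rep$overall$ci_high &
                  rep$omissions$ci_high >= rep$overall$ci_low))
})

test_that("leave-one-out limit cases behave sensibly", {
  two <- make_table(
    make_record(case = c(30, 20, 10), ctrl = c(25, 25, 10), study_id = "A"),
    make_record(case = c(40, 15, 5), ctrl = c(20, 30, 10), study_id = "B")
  )
  rep <- leave_one_out(two, "allele")
  expect_equal(nrow(rep$omissions), 2)
  for (i in 1:2) {
    remaining <- study_effect(apply_continuity(
      build_fourfold(two[-rep$omissions$omitted_row[i], ], "allele")))
    expect_equal(rep$omissions$or[i], remaining$or, tolerance = 1e-12)
  }
  one <- make_table(make_record())
  expect_error(leave_one_out(one, "allele"), "at least 2")

  # omitting an extreme study pulls the pooled estimate toward the remainder
  three <- make_table(
    make_record(case = c(30, 20, 10), ctrl = c(30, 20, 10), study_id = "null1"),
    make_record(case = c(31, 19, 10), ctrl = c(29, 21, 10), study_id = "null2"),
    make_record(case = c(5, 20, 35), ctrl = c(45, 12, 3), study_id = "extreme")
  )
  rep3 <- leave_one_out(three, "allele")
  full <- meta_analyze(three, "allele")
  drop_extreme <- rep3$omissions[rep3$omissions$omitted_study == "extreme", ]
  expect_lt(abs(log(drop_extreme$or)), abs(full$log_or))
})

test_that("leave-one-out pooled OR stays within the range of remaining study ORs", {
  tab <- rs1063192_studies()
  rep <- leave_one_out(tab, "homozygote")
  ffs <- fourfold_tables(tab, "homozygote")
  ors <- vapply(ffs$tables, function(f) study_effect(f)$or, numeric(1))
  for (i in seq_len(nrow(rep$omissions))) {
    rest <- ors[ffs$rows != rep$omissions$omitted_row[i]]
    expect_gte(rep$omissions$or[i], min(rest))
    expect_lte(rep$omissions$or[i], max(rest))
  }
})
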