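# Detection rates, variant tallies, demographics and the yield regressions.

test_that("detection rates reproduce the per-strategy arithmetic", {
  analyses <- read_strategy_table(strategy_table_path())
  dr <- detection_rates(analyses)
  row <- function(s) dr[dr$strategy == s, ]
  expect_equal(row("CES")[, c("n_analyses", "n_informative", "percent_1dp")],
               data.frame(n_analyses = 16L, n_informative = 4L,
                          percent_1dp = 25.0), ignore_attr = TRUE)
  expect_equal(row("ES-Solo")$n_informative / row("ES-Solo")$n_analyses, 9 / 19)
  expect_equal(row("ES-Duo")$percent_1dp, 28.6)
  expect_equal(row("ES-Trio")$n_analyses, 71L)
  expect_equal(row("ES-Trio")$n_informative, 32L)
  expect_equal(row("ES")$n_analyses, 97L)
  expect_equal(row("Total")$n_analyses, 113L)
  expect_equal(row("Total")$n_probands, 103L)
  expect_equal(row("Total")$percent_1dp, 45.6)
  # strata sum to the total analyses count, which exceeds the proband count
  strata <- dr[dr$strategy %in% c("CES", "ES-Solo", "ES-Duo", "ES-Trio"), ]
  expect_equal(sum(strata$n_analyses), row("Total")$n_analyses)
  expect_gt(row("Total")$n_analyses, row("Total")$n_probands)
  expect_equal(es_participant_count(analyses), 246L)

  expect_error(detection_rates(data.frame(proband_id = "x", strategy = "WGS",
                                          informative = TRUE)),
               "unknown strategy")
  empty <- detection_rates(analyses[0, ])
  expect_equal(empty$n_analyses, 0L)
})

test_that("variant tallies dedupe homozygotes and partition cleanly", {
  one <- data.frame(key = "k1", variant_class = "SNV", origin = "biparental",
                    clinvar_id = NA)
  expect_equal(variant_tallies(one)$n_distinct, 1L)
  tal <- variant_tallies(read_informative_table())
  expect_equal(tal$n_snv + tal$n_cnv, tal$n_distinct)
  expect_equal(tal$n_de_novo + tal$n_inherited + tal$n_unknown, tal$n_distinct)
  expect_equal(tal$n_clinvar + tal$n_novel, tal$n_distinct)
})

test_that("demographics summary handles single-row and mixed cohorts", {
  one <- data.frame(sex = "male", age = 7, care = "public", capital = TRUE)
  d <- demographics_summary(one)
  expect_equal(d$age_median[d$group == "male"], 7)
  expect_equal(d$age_iqr[d$group == "male"], 0)
  cohort <- data.frame(sex = c(rep("male", 49), rep("female", 54)),
                       age = rep(8, 103), care = "public", capital = TRUE)
  d <- demographics_summary(cohort)
  expect_equal(d$pct[d$group == "male"], 47.6)
  expect_equal(d$n[d$group == "total"], 103L)
})

test_that("cohort table derives age groups from age", {
  probands <- data.frame(proband_id = c("a", "b", "c", "d"), sex = "male",
                         age = c(3, 12, 17.9, 18), care = "public",
                         capital = TRUE, congenital = TRUE,
                         neurological = TRUE, immune = FALSE,
                         strategy = "trio")
  results <- data.frame(proband_id = c("a", "b", "c", "d"),
                        informative = c(TRUE, FALSE, TRUE, FALSE))
  ct <- build_cohort_table(probands, results)
  expect_identical(as.character(ct$age_group),
                   c("0-12", "12-18", "12-18", "18-52"))
  expect_identical(ct$informative, c(TRUE, FALSE, TRUE, FALSE))
})

sim_cohort_table <- function(n, beta = NULL, seed = 1) {
  # direct covariate simulation for the regression tests
  set.seed(seed)
  age <- round(runif(n, 0, 52), 1)
  x <- data.frame(
    proband_id = sprintf("p%d", seq_len(n)), sex = sample(c("male", "female"),
                                                          n, TRUE),
    age = age, care = sample(c("public", "private"), n, TRUE),
    capital = TRUE, congenital = sample(c(TRUE, FALSE), n, TRUE),
    neurological = sample(c(TRUE, FALSE), n, TRUE),
    immune = sample(c(TRUE, FALSE), n, TRUE),
    n_systems = sample(2:11, n, TRUE), strategy = "trio")
  lp <- qlogis(0.45)
  if (!is.null(beta)) {
    lp <- lp + beta * as.integer(age >= 12 & age < 18)
  }
  inf <- rbinom(n, 1, plogis(lp)) == 1
  build_cohort_table(x, data.frame(proband_id = x$proband_id,
                                   informative = inf))
}

test_that("a null covariate's bivariate CI covers 1 and matches the 2x2 oracle", {
  ct <- sim_cohort_table(800, seed = 31)
  fit <- fit_yield_models(ct)
  biv <- fit[fit$model == "bivariate", ]
  sexrow <- biv[biv$variable == "sex_male", ]
  expect_true(sexrow$ci_low <= 1 && 1 <= sexrow$ci_high)
  # closed-form cross-product ratio for a binary covariate
  tab <- table(ct$sex == "male", ct$informative)
  or_oracle <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  expect_equal(sexrow$or, unname(or_oracle), tolerance = 1e-6)
})

test_that("degenerate outcomes are reported as failures, not crashes", {
  ct <- sim_cohort_table(50, seed = 32)
  ct$informative <- TRUE
  out <- fit_yield_models(ct)
  expect_match(out$note[1], "single class")
  expect_true(all(is.na(out$or)))
})

test_that("multivariate model recovers a known age-group effect", {
  ct <- sim_cohort_table(2000, beta = log(3.5), seed = 33)
  fit <- fit_yield_models(ct)
  row <- fit[fit$model == "bivariate" & fit$term == "age_group12-18", ]
  expect_true(row$ci_low <= 3.5 && 3.5 <= row$ci_high)
})
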