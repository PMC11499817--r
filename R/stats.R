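# Cohort-level descriptive statistics, informative-variant tallies and the
# diagnostic-yield logistic regressions.

#' Round half-up to one decimal, as used in the summary tables
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Detection rate by familial and sequencing strategy
#'
#' One input row per analysis; re-sequenced probands contribute one row per
#' analysis. Per-stratum percentages use the stratum's analysis count as
#' denominator; the ES subtotal and cohort total use distinct probands with
#' an informative finding over analyses and distinct probands respectively.
#'
#' @param analyses Data frame with `proband_id`, `strategy` (one of CES,
#'   ES-Solo, ES-Duo, ES-Trio) and logical `informative`.
#' @return Data frame with rows per stratum plus `ES` and `Total`:
#'   `strategy`, `n_analyses`, `n_informative`, `percent` (raw) and
#'   `percent_1dp` (half-up, 1 decimal).
#' @export
detection_rates <- function(analyses) {
  strata <- c("CES", "ES-Solo", "ES-Duo", "ES-Trio")
  bad <- setdiff(unique(analyses$strategy), strata)
  if (length(bad)) {
    stop(sprintf("unknown strategy label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(analyses) == 0L) {
    return(data.frame(strategy = "Total", n_analyses = 0L, n_probands = 0L,
                      n_informative = 0L, percent = NA_real_,
                      percent_1dp = NA_real_))
  }
  row_for <- function(label, sub, denom_probands = FALSE) {
    n_pro <- length(unique(sub$proband_id))
    n_inf <- length(unique(sub$proband_id[sub$informative]))
    denom <- if (denom_probands) n_pro else nrow(sub)
    pct <- if (denom > 0L) 100 * n_inf / denom else NA_real_
    data.frame(strategy = label, n_analyses = nrow(sub), n_probands = n_pro,
               n_informative = n_inf, percent = pct,
               percent_1dp = round_half_up(pct), stringsAsFactors = FALSE)
  }
  rows <- lapply(intersect(strata, unique(analyses$strategy)), function(s) {
    row_for(s, analyses[analyses$strategy == s, , drop = FALSE])
  })
  es <- analyses[analyses$strategy != "CES", , drop = FALSE]
  if (nrow(es)) rows <- c(rows, list(row_for("ES", es)))
  rows <- c(rows, list(row_for("Total", analyses, denom_probands = TRUE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Participant count implied by ES family strategies
#'
#' Trios contribute three participants, duos two, solos one; clinical-exome
#' (CES) analyses are proband-only re-uses of the same probands and do not
#' add participants.
#'
#' @param analyses Data frame as in [detection_rates()].
#' @return Integer participant count.
#' @export
es_participant_count <- function(analyses) {
  w <- c("ES-Trio" = 3L, "ES-Duo" = 2L, "ES-Solo" = 1L)
  es <- analyses[analyses$strategy %in% names(w), , drop = FALSE]
  sum(w[es$strategy])
}

#' Tallies over the distinct informative variants
#'
#' Distinctness is by [variant_key()], so a homozygote counts as one
#' variant. Percentages are reported over the distinct-variant denominator.
#'
#' @param candidates Informative candidate data frame with `key`,
#'   `variant_class`, `origin` and `clinvar_id` columns (e.g. the
#'   `candidates` element of [run_cohort()] or [informative_results()]).
#' @return List of counts and percentages: `n_distinct`, `n_snv`, `n_cnv`,
#'   `n_de_novo`, `n_inherited`, `n_unknown`, `n_clinvar`, `n_novel` and
#'   matching `pct_*` fields.
#' @export
variant_tallies <- function(candidates) {
  d <- candidates[!duplicated(candidates$key), , drop = FALSE]
  n <- nrow(d)
  inherited <- d$origin %in% c("maternal", "paternal", "biparental")
  de_novo <- d$origin == "de_novo"
  unknown <- !inherited & !de_novo
  clinvar <- !is.na(d$clinvar_id)
  pct <- function(k) if (n > 0L) 100 * k / n else NA_real_
  list(
    n_distinct = n,
    n_snv = sum(d$variant_class != "CNV"),
    n_cnv = sum(d$variant_class == "CNV"),
    n_de_novo = sum(de_novo), pct_de_novo = pct(sum(de_novo)),
    n_inherited = sum(inherited), pct_inherited = pct(sum(inherited)),
    n_unknown = sum(unknown),
    n_clinvar = sum(clinvar), pct_clinvar = pct(sum(clinvar)),
    n_novel = sum(!clinvar), pct_novel = pct(sum(!clinvar))
  )
}

#' Solved-case split by inheritance-mode group
#'
#' @param records List of `result_record` objects (or the `records` element
#'   of a pipeline result).
#' @return List with `n_solved` and counts `AD`, `AR`, `XL` (a solved
#'   proband is attributed to the mode group of its solving gene; the first
#'   solving gene is used if several).
#' @export
solved_split <- function(records) {
  groups <- c(AD = 0L, AR = 0L, XL = 0L)
  n_solved <- 0L
  for (rec in records) {
    if (rec$category != "solved") next
    n_solved <- n_solved + 1L
    g <- rec$genes[rec$genes$category == "solved", , drop = FALSE]
    grp <- g$mode_group[1L]
    groups[grp] <- groups[grp] + 1L
  }
  list(n_solved = n_solved, AD = unname(groups["AD"]),
       AR = unname(groups["AR"]), XL = unname(groups["XL"]))
}

#' Demographic summary of a cohort table
#'
#' @param cohort Data frame with `sex`, `age`, `care`, `capital` columns.
#' @return Data frame by sex plus a total row: counts, percentage, median /
#'   IQR / range of age, counts and percentages in public care and with a
#'   provider in the capital.
#' @export
demographics_summary <- function(cohort) {
  n_all <- nrow(cohort)
  row_for <- function(label, sub) {
    if (nrow(sub) == 0L) {
      return(data.frame(group = label, n = 0L, pct = 0,
                        age_median = NA_real_, age_iqr = NA_real_,
                        age_min = NA_real_, age_max = NA_real_,
                        n_public = 0L, pct_public = NA_real_,
                        n_capital = 0L, pct_capital = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(
      group = label, n = nrow(sub),
      pct = round_half_up(100 * nrow(sub) / n_all),
      age_median = stats::median(sub$age),
      age_iqr = unname(stats::quantile(sub$age, 0.75) -
                         stats::quantile(sub$age, 0.25)),
      age_min = min(sub$age), age_max = max(sub$age),
      n_public = sum(sub$care == "public"),
      pct_public = round_half_up(100 * mean(sub$care == "public")),
      n_capital = sum(sub$capital),
      pct_capital = round_half_up(100 * mean(sub$capital)),
      stringsAsFactors = FALSE)
  }
  out <- rbind(row_for("male", cohort[cohort$sex == "male", , drop = FALSE]),
               row_for("female", cohort[cohort$sex == "female", , drop = FALSE]),
               row_for("total", cohort))
  rownames(out) <- NULL
  out
}

#' Assemble the per-proband covariate/outcome table for yield regression
#'
#' Age groups are half-open `[0,12)`, `[12,18)`, `[18,52]` with childhood
#' (0-12) as the reference level; the group is always derived from age,
#' never stored independently.
#'
#' @param probands Data frame with `proband_id`, `sex`, `age`, `care`,
#'   `capital`, `congenital`, `neurological`, `immune` and `strategy`.
#' @param results Per-proband results data frame with `proband_id` and
#'   `informative`.
#' @param phenotypes Optional phenotype term table (`proband_id`, `hpo_id`).
#' @param ontology Required with `phenotypes`; used to count affected
#'   systems.
#' @param breaks Age-group boundaries (lower edges plus the upper bound).
#' @return Data frame with one row per proband including `age_group` and
#'   `n_systems`.
#' @export
build_cohort_table <- function(probands, results, phenotypes = NULL,
                               ontology = NULL, breaks = c(0, 12, 18, 52)) {
  out <- probands
  out$informative <- results$informative[match(out$proband_id,
                                               results$proband_id)]
  labels <- sprintf("%g-%g", breaks[-length(breaks)], breaks[-1L])
  out$age_group <- cut(out$age, breaks = breaks, labels = labels,
                       right = FALSE, include.lowest = TRUE)
  if (!is.null(phenotypes)) {
    stopifnot(!is.null(ontology))
    out$n_systems <- vapply(out$proband_id, function(p) {
      count_affected_systems(
        phenotypes$hpo_id[phenotypes$proband_id == p], ontology)$n_systems
    }, integer(1))
  } else if (!"n_systems" %in% names(out)) {
    out$n_systems <- NA_integer_
  }
  out
}

#' @noRd
.or_rows <- function(fit, model_tag, variable) {
  cf <- summary(fit)$coefficients
  terms <- setdiff(rownames(cf), "(Intercept)")
  if (length(terms) == 0L) {  # covariate constant or aliased: nothing fit
    return(data.frame(model = model_tag, variable = variable,
                      term = variable, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_,
                      note = "covariate dropped (constant or collinear)",
                      stringsAsFactors = FALSE))
  }
  est <- cf[terms, "Estimate"]
  se <- cf[terms, "Std. Error"]
  p <- cf[terms, "Pr(>|z|)"]
  sep <- any(abs(est) > 15) || any(se > 15)
  data.frame(
    model = model_tag, variable = variable, term = terms,
    or = exp(est), ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se), p = p,
    note = if (sep) "possible separation: estimates unreliable" else "",
    stringsAsFactors = FALSE)
}

#' Bivariate and multivariate logistic models of diagnostic yield
#'
#' One bivariate binomial model per covariate (sex, age in years, age
#' group, type of care, number of affected systems, and the congenital /
#' neurological / immune criteria flags) plus one multivariate model with
#' all of them, fitted with `stats::glm(family = binomial())`. Odds ratios
#' are exponentiated coefficients with Wald 95% confidence intervals.
#' Degenerate inputs (a single outcome class, perfect separation) are
#' reported as failures in the `note` column rather than raised.
#'
#' @param cohort Cohort table from [build_cohort_table()].
#' @return Data frame with `model`, `variable`, `term`, `or`, `ci_low`,
#'   `ci_high`, `p`, `note`.
#' @export
fit_yield_models <- function(cohort) {
  df <- data.frame(
    informative = as.integer(cohort$informative),
    sex_male = as.integer(cohort$sex == "male"),
    age = cohort$age,
    age_group = stats::relevel(factor(cohort$age_group),
                               ref = levels(factor(cohort$age_group))[1L]),
    private_care = as.integer(cohort$care == "private"),
    n_systems = cohort$n_systems,
    congenital = as.integer(cohort$congenital),
    neurological = as.integer(cohort$neurological),
    immune = as.integer(cohort$immune))
  if (length(unique(df$informative)) < 2L) {
    return(data.frame(model = "bivariate", variable = "(outcome)",
                      term = "(outcome)", or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_,
                      note = "outcome has a single class; models not fit",
                      stringsAsFactors = FALSE))
  }
  covs <- c("sex_male", "age", "age_group", "private_care", "n_systems",
            "congenital", "neurological", "immune")
  rows <- list()
  for (v in covs) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(stats::reformulate(v, "informative"),
                                  data = df, family = stats::binomial())),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = "bivariate", variable = v, term = v, or = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        note = conditionMessage(fit), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- .or_rows(fit, "bivariate", v)
    }
  }
  multi <- tryCatch(
    suppressWarnings(stats::glm(stats::reformulate(covs, "informative"),
                                data = df, family = stats::binomial())),
    error = function(e) e)
  if (inherits(multi, "error")) {
    rows[[length(rows) + 1L]] <- data.frame(
      model = "multivariate", variable = "(all)", term = "(all)",
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
      note = conditionMessage(multi), stringsAsFactors = FALSE)
  } else {
    rows[[length(rows) + 1L]] <- .or_rows(multi, "multivariate", "(all)")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
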