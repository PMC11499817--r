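# Technical, consequence, frequency and cohort-recurrence filters. Each
# filter is a pure function of its inputs and returns pass/fail decisions
# plus an audit trace. MAF comparisons take the maximum across sources
# (exclusion if any database exceeds the bound); absent frequencies and
# counts default to zero at filter time so that novel variants survive.

#' @noRd
.max_maf <- function(annotations) {
  m <- as.matrix(annotations[, .MAF_COLS, drop = FALSE])
  m[is.na(m)] <- 0
  apply(m, 1L, max)
}

#' @noRd
.zero_na <- function(x) ifelse(is.na(x), 0, x)

#' Technical filter: read support and consequence class
#'
#' Fails when the proband depth is below `cfg$min_depth` (unknown depth is
#' conservative: it fails) or when the consequence is in the excluded set.
#' CNV records carry no read-depth semantics and bypass the depth rule but
#' not the consequence rule.
#'
#' @param depth Proband read depth (integer, `NA` = unknown).
#' @param consequence Consequence token.
#' @param is_cnv Logical; CNV records bypass the depth rule.
#' @param cfg A [filter_config()].
#' @return Data frame with `pass`, `reason` (`"depth"`, `"depth unknown"`,
#'   `"consequence"` or `""`) and `value`.
#' @export
technical_filter <- function(depth, consequence, is_cnv = FALSE,
                             cfg = filter_config()) {
  n <- max(length(depth), length(consequence), length(is_cnv))
  depth <- rep_len(depth, n); consequence <- rep_len(consequence, n)
  is_cnv <- rep_len(is_cnv, n)
  depth_unknown <- !is_cnv & is.na(depth)
  depth_fail <- !is_cnv & !is.na(depth) & depth < cfg$min_depth
  cons_fail <- consequence %in% cfg$excluded_consequences
  pass <- !depth_unknown & !depth_fail & !cons_fail
  reason <- rep("", n)
  reason[cons_fail] <- "consequence"
  reason[depth_fail] <- "depth"
  reason[depth_unknown] <- "depth unknown"
  value <- ifelse(reason == "consequence", consequence,
                  ifelse(reason != "", as.character(depth), ""))
  data.frame(pass = pass, reason = reason, value = value,
             stringsAsFactors = FALSE)
}

#' Recessive-model frequency filter
#'
#' Fails when the maximum MAF across sources exceeds
#' `cfg$recessive_maf_max`, or when the combined ExAC homozygous +
#' hemizygous count reaches `cfg$recessive_homhemi_max + 1`. Comparison on
#' MAF is strict: a MAF exactly at the bound passes. Absent sources count as
#' frequency 0.
#'
#' @param annotations Annotation rows (one per variant).
#' @param cfg A [filter_config()].
#' @return Data frame with `pass`, `reason` (`"maf"`, `"homhemi"` or `""`)
#'   and `value`.
#' @export
recessive_frequency_filter <- function(annotations, cfg = filter_config()) {
  maf <- .max_maf(annotations)
  homhemi <- .zero_na(annotations$hom_exac) + .zero_na(annotations$hemi_exac)
  maf_fail <- maf > cfg$recessive_maf_max
  hh_fail <- cfg$apply_recessive_homhemi &
    homhemi > cfg$recessive_homhemi_max
  is_cnv <- !is.na(annotations$variant_class) &
    annotations$variant_class == "CNV"
  maf_fail[is_cnv] <- FALSE; hh_fail[is_cnv] <- FALSE
  pass <- !maf_fail & !hh_fail
  reason <- rep("", nrow(annotations))
  reason[hh_fail] <- "homhemi"
  reason[maf_fail] <- "maf"
  value <- ifelse(reason == "maf", as.character(maf),
                  ifelse(reason == "homhemi", as.character(homhemi), ""))
  data.frame(pass = pass, reason = reason, value = value,
             stringsAsFactors = FALSE)
}

#' Dominant-model frequency filter
#'
#' Fails when the maximum MAF across sources exceeds `cfg$dominant_maf_max`,
#' or when the gnomAD or internal-database allele count exceeds
#' `cfg$dominant_allele_count_max`. Absent counts default to zero.
#'
#' @inheritParams recessive_frequency_filter
#' @return Data frame with `pass`, `reason` (`"maf"`, `"allele_count"` or
#'   `""`) and `value`.
#' @export
dominant_frequency_filter <- function(annotations, cfg = filter_config()) {
  maf <- .max_maf(annotations)
  ac <- pmax(.zero_na(annotations$ac_gnomad), .zero_na(annotations$ac_internal))
  maf_fail <- maf > cfg$dominant_maf_max
  ac_fail <- ac > cfg$dominant_allele_count_max
  is_cnv <- !is.na(annotations$variant_class) &
    annotations$variant_class == "CNV"
  maf_fail[is_cnv] <- FALSE; ac_fail[is_cnv] <- FALSE
  pass <- !maf_fail & !ac_fail
  reason <- rep("", nrow(annotations))
  reason[ac_fail] <- "allele_count"
  reason[maf_fail] <- "maf"
  value <- ifelse(reason == "maf", as.character(maf),
                  ifelse(reason == "allele_count", as.character(ac), ""))
  data.frame(pass = pass, reason = reason, value = value,
             stringsAsFactors = FALSE)
}

#' Index which unrelated probands carry each variant
#'
#' Members of the same family never count as unrelated, so recurrence is
#' counted over distinct families.
#'
#' @param genotypes Long genotype table with a `family_id` column (or a
#'   `sample_id -> family_id` mapping supplied via `families`).
#' @param families Family table from [read_pedigree()]; only proband
#'   genotypes enter the index.
#' @return Data frame of distinct (`key`, `proband_id`, `family_id`) carrier
#'   triples.
#' @export
build_cohort_index <- function(genotypes, families) {
  pro <- genotypes[genotypes$sample_id %in% families$proband_id, , drop = FALSE]
  pro <- pro[carries_alt(pro$a1, pro$a2, pro$missing), , drop = FALSE]
  fam <- families$family_id[match(pro$sample_id, families$proband_id)]
  idx <- data.frame(key = pro$key, proband_id = pro$sample_id,
                    family_id = fam, stringsAsFactors = FALSE)
  idx <- idx[!duplicated(idx), , drop = FALSE]
  # per-key count of distinct carrier families, computed once for the cohort
  pairs <- idx[!duplicated(idx[, c("key", "family_id")]), , drop = FALSE]
  counts <- table(pairs$key)
  attr(idx, "family_counts") <- stats::setNames(as.integer(counts),
                                                names(counts))
  idx
}

#' Cohort-recurrence filter
#'
#' Fails when a variant key is carried by two or more unrelated cohort
#' participants (counting the current proband).
#'
#' @param keys Variant keys to test.
#' @param cohort_index Index from [build_cohort_index()].
#' @param cfg A [filter_config()].
#' @return Data frame with `pass` and `value` (number of distinct carrier
#'   families).
#' @export
cohort_recurrence_filter <- function(keys, cohort_index,
                                     cfg = filter_config()) {
  if (is.null(cohort_index) || nrow(cohort_index) == 0L) {
    return(data.frame(pass = rep(TRUE, length(keys)),
                      value = rep(0L, length(keys))))
  }
  counts <- attr(cohort_index, "family_counts")
  if (is.null(counts)) {
    pairs <- unique(cohort_index[, c("key", "family_id")])
    counts <- table(pairs$key)
  }
  n_fam <- as.integer(counts[keys])
  n_fam[is.na(n_fam)] <- 0L
  data.frame(pass = n_fam <= cfg$cohort_recurrence_max, value = n_fam)
}

#' Apply all stated filters for one family, per inheritance model
#'
#' Produces three surviving key sets: recessive-eligible and
#' dominant-eligible autosomal variants, and X-eligible variants. X-linked
#' candidates are screened with the recessive thresholds for
#' hemizygous/homozygous proband genotypes and with the dominant thresholds
#' for heterozygous (female) genotypes. CNV records skip the SNV frequency
#' filters (no MAF semantics) and are screened by the technical consequence
#' rule and cohort recurrence only. Variants lacking any annotation are
#' excluded with reason `"unannotated"`.
#'
#' @param family One-row family data frame.
#' @param variants,genotypes Tables as produced by [read_vcf()] (plus CNV
#'   rows from [cnv_records()] if any).
#' @param annotations Annotation table; reduced to one row per key via
#'   [select_annotation()].
#' @param cfg A [filter_config()].
#' @param cohort_index Optional index from [build_cohort_index()]; `NULL`
#'   skips the recurrence filter.
#' @return List with `recessive`, `dominant`, `xlinked` (character key
#'   sets) and `trace` (data frame `key`, `filter`, `decision`, `value`,
#'   `model`).
#' @export
apply_filters <- function(family, variants, genotypes, annotations,
                          cfg = filter_config(), cohort_index = NULL) {
  pid <- family$proband_id
  pg <- genotypes[genotypes$sample_id == pid, , drop = FALSE]
  pg <- pg[carries_alt(pg$a1, pg$a2, pg$missing), , drop = FALSE]
  empty <- list(recessive = character(0), dominant = character(0),
                xlinked = character(0),
                trace = data.frame(key = character(0), filter = character(0),
                                   decision = character(0), value = character(0),
                                   model = character(0), stringsAsFactors = FALSE))
  if (nrow(pg) == 0L) return(empty)
  vv <- variants[match(pg$key, variants$key), , drop = FALSE]
  ann <- select_annotation(annotations)
  ai <- match(pg$key, ann$key)
  trace <- list()
  push <- function(key, filter, decision, value, model) {
    if (length(key) == 0L) return(invisible())
    trace[[length(trace) + 1L]] <<- data.frame(
      key = key, filter = filter, decision = decision,
      value = as.character(value), model = model, stringsAsFactors = FALSE)
  }
  unann <- is.na(ai)
  if (any(unann)) {
    push(pg$key[unann], "annotation", "fail", "unannotated", "all")
  }
  keep <- !unann
  if (!any(keep)) {
    out <- empty
    out$trace <- do.call(rbind, trace)
    return(out)
  }
  pg <- pg[keep, , drop = FALSE]
  vv <- vv[keep, , drop = FALSE]
  a <- ann[ai[keep], , drop = FALSE]
  is_cnv <- vv$variant_class == "CNV"

  tech <- technical_filter(pg$depth, a$consequence, is_cnv, cfg)
  push(pg$key, "technical", ifelse(tech$pass, "pass", "fail"),
       ifelse(tech$pass, "", paste(tech$reason, tech$value)), "technical")

  rec <- recessive_frequency_filter(a, cfg)
  push(pg$key, "recessive_frequency", ifelse(rec$pass, "pass", "fail"),
       ifelse(rec$pass, "", paste(rec$reason, rec$value)), "AR")
  dom <- dominant_frequency_filter(a, cfg)
  push(pg$key, "dominant_frequency", ifelse(dom$pass, "pass", "fail"),
       ifelse(dom$pass, "", paste(dom$reason, dom$value)), "AD")

  if (!is.null(cohort_index)) {
    recur <- cohort_recurrence_filter(pg$key, cohort_index, cfg)
  } else {
    recur <- data.frame(pass = rep(TRUE, nrow(pg)), value = 0L)
  }
  push(pg$key, "cohort_recurrence", ifelse(recur$pass, "pass", "fail"),
       recur$value, "all")

  on_x <- is_x_chrom(vv$chrom)
  if (!is.null(cfg$par_regions) && any(on_x)) {
    par <- cfg$par_regions
    for (j in which(on_x)) {
      hit <- par$chrom == vv$chrom[j] & vv$pos[j] >= par$start &
        vv$pos[j] <= par$end
      if (any(hit)) on_x[j] <- FALSE  # pseudoautosomal: treat as autosomal
    }
  }
  zyg <- zygosity_of(pg$a1, pg$a2, pg$missing)
  base <- tech$pass & recur$pass
  recessive <- pg$key[base & !on_x & rec$pass]
  dominant <- pg$key[base & !on_x & dom$pass]
  # X model: recessive thresholds for hem/hom genotypes, dominant for het
  x_rule <- ifelse(zyg %in% c("hem", "hom"), rec$pass, dom$pass)
  xlinked <- pg$key[base & on_x & x_rule]
  push(pg$key[on_x], "xl_frequency",
       ifelse(x_rule[on_x], "pass", "fail"),
       ifelse(zyg[on_x] %in% c("hem", "hom"), "recessive-rule", "dominant-rule"),
       "XL")

  list(recessive = recessive, dominant = dominant, xlinked = xlinked,
       trace = do.call(rbind, trace))
}

#' Export a filter trace as TSV
#'
#' @param trace Trace data frame from [apply_filters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
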