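# Shared domain vocabulary, genotype parsing, variant identity and the
# filter configuration used by every downstream stage.

.CONSEQUENCES <- c(
  "missense", "nonsense", "frameshift", "inframe_indel", "splice_site",
  "deep_intronic", "near_splice_intronic", "synonymous", "utr5", "utr3",
  "intergenic", "cnv_gain", "cnv_loss"
)

# Lower rank = more damaging. Used to pick one representative transcript
# annotation per variant when several are available.
.CONSEQUENCE_RANK <- stats::setNames(
  seq_len(13L),
  c("frameshift", "nonsense", "splice_site", "cnv_loss", "missense",
    "inframe_indel", "cnv_gain", "near_splice_intronic", "utr5", "utr3",
    "synonymous", "deep_intronic", "intergenic")
)

.ACMG <- c("P", "LP", "VUS", "LB", "B")

.MAF_COLS <- c("maf_cmg", "maf_esp5400", "maf_1000g", "maf_gnomad",
               "maf_exac", "maf_internal")

#' Consequence vocabulary accepted by the annotation table
#'
#' @return Character vector of valid consequence tokens.
#' @export
consequence_vocabulary <- function() .CONSEQUENCES

#' Five-tier ACMG interpretation classes
#'
#' @return Character vector `c("P","LP","VUS","LB","B")`, ordered from
#'   pathogenic to benign.
#' @export
acmg_classes <- function() .ACMG

#' @noRd
is_x_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "23")
}

#' Parse a VCF genotype field into a genotype call
#'
#' Handles diploid calls (`"0/1"`, `"1|1"`), single-allele hemizygous calls
#' (`"1"`, as produced for male X chromosomes) and missing genotypes
#' (`"./."`, `"."`). A genotype with any missing allele is treated as
#' missing, never as homozygous reference.
#'
#' @param gt_field Genotype string following VCF GT syntax.
#' @param depth_field Read depth as printed in the DP field; `NA` or `"."`
#'   records the depth as unknown.
#' @param sample_id Optional sample identifier carried along for reporting.
#' @return An object of class `genotype_call`: a list with `sample_id`,
#'   `alleles` (integer vector, length 0 when missing, 1 for hemizygous,
#'   2 for diploid), `phased`, `depth`, `ploidy` and `missing`.
#' @examples
#' parse_genotype("0/1", "35")
#' parse_genotype("1", "20")   # hemizygous male X call
#' parse_genotype("./.", "0")  # missing
#' @export
parse_genotype <- function(gt_field, depth_field = NA, sample_id = NA_character_) {
  if (length(gt_field) != 1L || is.na(gt_field)) {
    stop("parse_genotype() expects a single non-NA GT string", call. = FALSE)
  }
  gt <- trimws(gt_field)
  if (!grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt)) {
    stop(sprintf("malformed GT field '%s'", gt_field), call. = FALSE)
  }
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1L]]
  missing <- any(parts == ".")
  alleles <- if (missing) integer(0) else as.integer(parts)
  depth <- suppressWarnings(as.integer(depth_field))
  if (length(depth) != 1L) depth <- NA_integer_
  if (!is.na(depth) && depth < 0L) {
    stop(sprintf("negative depth '%s'", depth_field), call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, alleles = alleles,
         phased = phased && !missing, depth = depth,
         ploidy = length(parts), missing = missing),
    class = "genotype_call"
  )
}

#' Format a genotype call back into VCF GT syntax
#'
#' Inverse of [parse_genotype()]: `parse_genotype(format_genotype(x))`
#' recovers `x` for every valid call.
#'
#' @param call A `genotype_call`.
#' @return A GT string.
#' @export
format_genotype <- function(call) {
  stopifnot(inherits(call, "genotype_call"))
  if (call$missing) {
    return(paste(rep(".", call$ploidy), collapse = "/"))
  }
  paste(call$alleles, collapse = if (call$phased) "|" else "/")
}

# Vectorised GT parser used by the VCF reader. Returns parallel vectors.
#' @noRd
.parse_gt_vec <- function(gts) {
  gts <- ifelse(is.na(gts), ".", trimws(gts))
  bad <- !grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gts)
  if (any(bad)) {
    stop(sprintf("malformed GT field '%s'", gts[which(bad)[1L]]), call. = FALSE)
  }
  phased <- grepl("|", gts, fixed = TRUE)
  parts <- strsplit(gts, "[/|]")
  a1 <- vapply(parts, function(p) p[1L], character(1))
  a2 <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
               character(1))
  missing <- a1 == "." | (!is.na(a2) & a2 == ".")
  list(
    a1 = ifelse(missing, NA_integer_, suppressWarnings(as.integer(a1))),
    a2 = ifelse(missing, NA_integer_, suppressWarnings(as.integer(a2))),
    phased = phased & !missing,
    missing = missing
  )
}

#' Zygosity label for decomposed bi-allelic genotypes
#'
#' @param a1,a2 Integer allele indices (0 reference, 1 alternate); `a2` is
#'   `NA` for hemizygous single-allele calls.
#' @param missing Logical; `TRUE` marks a missing genotype.
#' @return Character vector with values `"missing"`, `"homref"`, `"het"`,
#'   `"hom"`, `"hem_ref"` or `"hem"`.
#' @export
zygosity_of <- function(a1, a2, missing = is.na(a1) & is.na(a2)) {
  n <- max(length(a1), length(a2), length(missing))
  a1 <- rep_len(a1, n); a2 <- rep_len(a2, n); missing <- rep_len(missing, n)
  out <- rep(NA_character_, n)
  out[missing] <- "missing"
  hemi <- !missing & is.na(a2)
  out[hemi & a1 >= 1L] <- "hem"
  out[hemi & a1 == 0L] <- "hem_ref"
  dip <- !missing & !is.na(a2)
  out[dip & a1 == 0L & a2 == 0L] <- "homref"
  out[dip & a1 >= 1L & a2 >= 1L] <- "hom"
  out[dip & xor(a1 >= 1L, a2 >= 1L)] <- "het"
  out
}

#' Carrier status of a decomposed genotype
#' @noRd
carries_alt <- function(a1, a2, missing) {
  !missing & ((!is.na(a1) & a1 >= 1L) | (!is.na(a2) & a2 >= 1L))
}

#' Variant identity key
#'
#' SNVs and indels are keyed by `(chrom, pos, ref, alt)`; CNV intervals by
#' `(chrom, start, end, dosage)`. Homozygous and heterozygous occurrences of
#' the same variant share one key, so a homozygote counts as a single
#' distinct variant. Coordinates are 1-based inclusive, as in VCF.
#'
#' @param v Data frame of variant records with columns `chrom`, `pos`,
#'   `ref`, `alt`, `variant_class` and, for CNV rows, `cnv_start`,
#'   `cnv_end`, `cnv_dosage`.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(v) {
  stopifnot(is.data.frame(v))
  if (nrow(v) == 0L) return(character(0))
  vc <- if ("variant_class" %in% names(v)) v$variant_class else rep("SNV", nrow(v))
  key <- sprintf("%s:%d:%s>%s", v$chrom, as.integer(v$pos), v$ref, v$alt)
  is_cnv <- !is.na(vc) & vc == "CNV"
  if (any(is_cnv)) {
    key[is_cnv] <- sprintf("%s:%d-%d:%s", v$chrom[is_cnv],
                           as.integer(v$cnv_start[is_cnv]),
                           as.integer(v$cnv_end[is_cnv]),
                           v$cnv_dosage[is_cnv])
  }
  key
}

#' Derive the family analysis strategy from parent availability
#'
#' `trio` when both parents are available, `duo` with exactly one, `solo`
#' with none. The strategy is always derived, never set independently.
#'
#' @param mother_id,father_id Parent sample identifiers; `NA` (or `"0"`)
#'   marks an unavailable parent.
#' @return Character vector in `c("trio","duo","solo")`.
#' @export
derive_strategy <- function(mother_id, father_id) {
  m <- !is.na(mother_id) & mother_id != "0" & mother_id != ""
  f <- !is.na(father_id) & father_id != "0" & father_id != ""
  ifelse(m & f, "trio", ifelse(m | f, "duo", "solo"))
}

#' Filter thresholds for variant triage
#'
#' Defaults encode the study protocol: proband read depth below 3 excluded;
#' synonymous, deep intronic, intergenic and UTR consequences excluded;
#' recessive-model variants excluded at MAF > 0.005 in any population source
#' or at a combined ExAC homozygous + hemizygous count of 10 or greater;
#' dominant-model variants excluded at MAF > 0.001 or at an allele count
#' greater than 5 in gnomAD or the internal database; variants seen in two
#' or more unrelated cohort participants excluded.
#'
#' @param min_depth Minimum proband read depth (reads).
#' @param recessive_maf_max Maximum MAF tolerated under the recessive model.
#' @param recessive_homhemi_max Maximum tolerated ExAC homozygous +
#'   hemizygous count (exclusion at `recessive_homhemi_max + 1` and above).
#' @param dominant_maf_max Maximum MAF tolerated under the dominant model.
#' @param dominant_allele_count_max Maximum tolerated allele count in
#'   gnomAD and the internal database under the dominant model.
#' @param cohort_recurrence_max Maximum number of unrelated cohort probands
#'   (including the current one) that may carry a variant.
#' @param excluded_consequences Consequence tokens removed by the technical
#'   filter.
#' @param deep_intronic_bp Distance from the nearest exon boundary (bp)
#'   beyond which an intronic variant is labelled deep intronic by
#'   annotation producers; documented convention, not applied as a
#'   positional filter here because consequences arrive pre-tokenised.
#' @param apply_recessive_homhemi Whether the ExAC homozygous/hemizygous
#'   rule is applied (it is, by default, in both analysis phases).
#' @param min_term_overlap Minimum number of shared HPO terms (after
#'   ancestor expansion) for a gene to enter a proband's virtual panel;
#'   0 yields the phenotypically unbiased panel of all mapped genes.
#' @param require_parent_depth_for_denovo Require parental depth >=
#'   `min_depth` at a site before asserting a de novo origin.
#' @param par_regions Optional data frame (`chrom`, `start`, `end`) of
#'   pseudoautosomal regions treated as autosomal.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 3L,
                          recessive_maf_max = 0.005,
                          recessive_homhemi_max = 9L,
                          dominant_maf_max = 0.001,
                          dominant_allele_count_max = 5L,
                          cohort_recurrence_max = 1L,
                          excluded_consequences = c("synonymous", "deep_intronic",
                                                    "intergenic", "utr5", "utr3"),
                          deep_intronic_bp = 20L,
                          apply_recessive_homhemi = TRUE,
                          min_term_overlap = 1L,
                          require_parent_depth_for_denovo = TRUE,
                          par_regions = NULL) {
  num <- c(min_depth = min_depth, recessive_maf_max = recessive_maf_max,
           recessive_homhemi_max = recessive_homhemi_max,
           dominant_maf_max = dominant_maf_max,
           dominant_allele_count_max = dominant_allele_count_max,
           cohort_recurrence_max = cohort_recurrence_max,
           deep_intronic_bp = deep_intronic_bp,
           min_term_overlap = min_term_overlap)
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("all filter thresholds must be finite and non-negative", call. = FALSE)
  }
  bad <- setdiff(excluded_consequences, .CONSEQUENCES)
  if (length(bad)) {
    stop(sprintf("unknown consequence token(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(min_depth = as.integer(min_depth),
         recessive_maf_max = recessive_maf_max,
         recessive_homhemi_max = as.integer(recessive_homhemi_max),
         dominant_maf_max = dominant_maf_max,
         dominant_allele_count_max = as.integer(dominant_allele_count_max),
         cohort_recurrence_max = as.integer(cohort_recurrence_max),
         excluded_consequences = excluded_consequences,
         deep_intronic_bp = as.integer(deep_intronic_bp),
         apply_recessive_homhemi = isTRUE(apply_recessive_homhemi),
         min_term_overlap = as.integer(min_term_overlap),
         require_parent_depth_for_denovo = isTRUE(require_parent_depth_for_denovo),
         par_regions = par_regions),
    class = "filter_config"
  )
}

#' Pick one representative annotation per variant key
#'
#' When a variant annotates to several transcripts, the most damaging
#' consequence wins; ties are broken by transcript identifier (ascending).
#'
#' @param annotations Annotation table as returned by [read_annotations()].
#' @return The input reduced to one row per `key`.
#' @export
select_annotation <- function(annotations) {
  if (isTRUE(attr(annotations, "selected"))) return(annotations)
  if (nrow(annotations) == 0L) return(annotations)
  rank <- .CONSEQUENCE_RANK[annotations$consequence]
  tx <- ifelse(is.na(annotations$transcript), "~", annotations$transcript)
  ord <- order(annotations$key, rank, tx)
  ann <- annotations[ord, , drop = FALSE]
  ann <- ann[!duplicated(ann$key), , drop = FALSE]
  attr(ann, "selected") <- TRUE
  ann
}
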