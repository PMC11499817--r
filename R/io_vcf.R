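# Multi-sample VCF reading/writing. Parsing is delegated to vcfR; this
# layer decomposes multi-allelic sites into bi-allelic records and reshapes
# genotypes into the long table used by the filtering and inheritance
# stages.

#' Read a multi-sample VCF into variant and genotype tables
#'
#' Sites with several ALT alleles are decomposed into one bi-allelic record
#' per alternate allele; within each decomposed record, allele indices equal
#' to the record's alternate map to 1 and all other alleles (reference or a
#' different alternate) map to 0, so genotype semantics are per-allele
#' carrier status. Missing genotypes stay missing. A missing DP format field
#' records depth as unknown, which the technical filter treats as failing.
#'
#' @param path Path to a VCF v4.2 file with GT (required) and DP fields.
#' @return A list with
#'   `variants` (data frame: `key`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class`, `cnv_start`, `cnv_end`, `cnv_dosage`),
#'   `genotypes` (data frame: `key`, `sample_id`, `a1`, `a2`, `phased`,
#'   `depth`, `missing`) and `samples` (roster in file order).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {  # single-record files come back as a vector
    fixm <- matrix(fixm, nrow = 1L, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1L]
  if (nrow(fix) == 0L) {
    return(list(variants = .empty_variants(), genotypes = .empty_genotypes(),
                samples = samples))
  }
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt, function(x) "GT" %in% x, logical(1)))) {
    stop(sprintf("%s: GT format field is required on every record", path),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  has_dp <- all(vapply(fmt, function(x) "DP" %in% x, logical(1)))
  if (has_dp) {
    dp <- vcfR::extract.gt(v, element = "DP")
  } else {
    dp <- matrix(NA_character_, nrow = nrow(fix), ncol = length(samples))
    warning(sprintf("%s: DP absent; depths recorded as unknown", path),
            call. = FALSE)
  }
  gt <- matrix(gt, nrow = nrow(fix)); dp <- matrix(dp, nrow = nrow(fix))

  var_rows <- list(); gt_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    parsed <- .parse_gt_vec(gt[i, ])
    depth_i <- suppressWarnings(as.integer(dp[i, ]))
    for (ai in seq_along(alts)) {
      ref <- fix$REF[i]; alt <- alts[ai]
      vc <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV" else "INDEL"
      key <- sprintf("%s:%d:%s>%s", fix$CHROM[i], as.integer(fix$POS[i]), ref, alt)
      remap <- function(a) ifelse(is.na(a), NA_integer_,
                                  ifelse(a == ai, 1L, 0L))
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        key = key, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = ref, alt = alt, variant_class = vc,
        cnv_start = NA_integer_, cnv_end = NA_integer_,
        cnv_dosage = NA_character_, stringsAsFactors = FALSE)
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        key = key, sample_id = samples,
        a1 = remap(parsed$a1), a2 = remap(parsed$a2),
        phased = parsed$phased, depth = depth_i,
        missing = parsed$missing, stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, var_rows)
  if (anyDuplicated(variants$key)) {
    stop(sprintf("%s: duplicate variant key '%s'", path,
                 variants$key[duplicated(variants$key)][1L]), call. = FALSE)
  }
  list(variants = variants, genotypes = do.call(rbind, gt_rows),
       samples = samples)
}

#' @noRd
.empty_variants <- function() {
  data.frame(key = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             variant_class = character(0), cnv_start = integer(0),
             cnv_end = integer(0), cnv_dosage = character(0),
             stringsAsFactors = FALSE)
}

#' @noRd
.empty_genotypes <- function() {
  data.frame(key = character(0), sample_id = character(0), a1 = integer(0),
             a2 = integer(0), phased = logical(0), depth = integer(0),
             missing = logical(0), stringsAsFactors = FALSE)
}

#' Write variant and genotype tables as a VCF v4.2 file
#'
#' CNV interval records are carried in a separate table (see [read_cnv()])
#' and are skipped here. Genotypes are emitted as `GT:DP`.
#'
#' @param variants,genotypes Tables in the layout produced by [read_vcf()].
#' @param samples Sample roster defining column order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, samples, path) {
  snv <- variants[variants$variant_class != "CNV", , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(nrow(snv))
  if (nrow(snv) > 0L) {
    gsplit <- split(genotypes, genotypes$key)
    for (i in seq_len(nrow(snv))) {
      g <- gsplit[[snv$key[i]]]
      g <- g[match(samples, g$sample_id), , drop = FALSE]
      gt_str <- ifelse(
        g$missing,
        ifelse(is.na(g$a2) & !g$missing, ".", "./."),
        ifelse(is.na(g$a2), as.character(g$a1),
               paste0(g$a1, ifelse(g$phased, "|", "/"), g$a2)))
      gt_str[g$missing] <- "./."
      dp_str <- ifelse(is.na(g$depth), ".", as.character(g$depth))
      body[i] <- paste(c(snv$chrom[i], snv$pos[i], ".", snv$ref[i],
                         snv$alt[i], ".", "PASS", ".", "GT:DP",
                         paste(gt_str, dp_str, sep = ":")), collapse = "\t")
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}
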