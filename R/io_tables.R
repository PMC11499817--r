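# Tabular input formats: PED pedigrees, the annotation transport TSV, the
# CNV interval TSV, proband phenotype terms, the gene-disease-inheritance
# map and report writing. All readers reject malformed rows with file/line
# provenance rather than silently coercing.

.INHERITANCE_MODES <- c("AD", "AR", "XLD", "XLR", "XL", "DD")

#' @noRd
.io_stop <- function(path, row, msg) {
  stop(sprintf("%s (row %s): %s", path, row, msg), call. = FALSE)
}

#' @noRd
.num_or_na <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", ".", "NA")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' @noRd
.chr_or_na <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", ".", "NA", "-")] <- NA_character_
  x
}

#' Read a 6-column PED pedigree into a family table
#'
#' Parent identifiers of `"0"` mean the parent is absent; the analysis
#' strategy (trio/duo/solo) is derived from parent availability and is never
#' stored independently. The proband of each family is the affected
#' individual that is not itself a parent within the family.
#'
#' @param path PED file (family, individual, father, mother, sex, phenotype),
#'   whitespace-delimited; sex coded 1 = male / 2 = female, phenotype
#'   2 = affected.
#' @return Data frame with one row per family: `family_id`, `proband_id`,
#'   `mother_id`, `father_id`, `sex`, `strategy`, `mother_affected`,
#'   `father_affected`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6L) {
    stop(sprintf("%s: expected 6 PED columns, found %d", path, ncol(ped)),
         call. = FALSE)
  }
  names(ped) <- c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype")
  out <- list()
  for (fid in unique(ped$family_id)) {
    fam <- ped[ped$family_id == fid, , drop = FALSE]
    parents <- unique(c(fam$father_id, fam$mother_id))
    parents <- parents[parents != "0"]
    missing_parents <- setdiff(parents, fam$individual_id)
    if (length(missing_parents)) {
      .io_stop(path, fid, sprintf(
        "parent id '%s' does not reference an individual in the family",
        missing_parents[1L]))
    }
    affected <- fam$individual_id[fam$phenotype == "2"]
    probands <- setdiff(affected, parents)
    if (length(probands) == 0L) {
      .io_stop(path, fid, "no affected proband in family")
    }
    if (length(probands) > 1L) {
      warning(sprintf("%s: family %s has %d affected non-parents; using '%s'",
                      path, fid, length(probands), probands[1L]), call. = FALSE)
    }
    pr <- fam[fam$individual_id == probands[1L], , drop = FALSE]
    if (!pr$sex %in% c("1", "2")) {
      .io_stop(path, fid, sprintf("proband '%s' has unknown sex; X-linked analysis requires sex",
                                  pr$individual_id))
    }
    mother <- if (pr$mother_id == "0") NA_character_ else pr$mother_id
    father <- if (pr$father_id == "0") NA_character_ else pr$father_id
    aff <- function(id) !is.na(id) &&
      fam$phenotype[fam$individual_id == id] == "2"
    out[[length(out) + 1L]] <- data.frame(
      family_id = fid, proband_id = pr$individual_id,
      mother_id = mother, father_id = father,
      sex = if (pr$sex == "1") "male" else "female",
      strategy = derive_strategy(mother, father),
      mother_affected = aff(mother), father_affected = aff(father),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read the variant annotation transport table
#'
#' A neutral TSV stands in for platform-internal annotation stores. Required
#' columns: `chrom`, `pos`, `ref`, `alt`, `gene`, `transcript`,
#' `consequence`, `hgvs_c`, `hgvs_p`, `cadd`, the six per-source frequency
#' columns `maf_cmg`, `maf_esp5400`, `maf_1000g`, `maf_gnomad`, `maf_exac`,
#' `maf_internal`, the count columns `ac_gnomad`, `ac_internal`, `hom_exac`,
#' `hemi_exac`, and the interpretation columns `clinvar_id`,
#' `clinvar_class`, `class_platform`, `class_varsome`, `class_franklin`.
#' Absent numeric cells are parsed as `NA` (absent), never as zero; the
#' filtering layer decides the zero default.
#'
#' @param path TSV path with a header row.
#' @return Data frame with one row per (variant, transcript), keyed by
#'   `key`, carrying `.row` (source row) and a `source` attribute for
#'   provenance.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  required <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
                "consequence", "hgvs_c", "hgvs_p", "cadd", .MAF_COLS,
                "ac_gnomad", "ac_internal", "hom_exac", "hemi_exac",
                "clinvar_id", "clinvar_class", "class_platform",
                "class_varsome", "class_franklin")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!tab$consequence %in% .CONSEQUENCES)
  if (length(bad)) {
    .io_stop(path, bad[1L] + 1L, sprintf(
      "unknown consequence '%s'; accepted: %s", tab$consequence[bad[1L]],
      paste(.CONSEQUENCES, collapse = ", ")))
  }
  for (col in c("clinvar_class", "class_platform", "class_varsome",
                "class_franklin")) {
    tab[[col]] <- .chr_or_na(tab[[col]])
    bad <- which(!is.na(tab[[col]]) & !tab[[col]] %in% .ACMG)
    if (length(bad)) {
      .io_stop(path, bad[1L] + 1L, sprintf(
        "invalid ACMG class '%s' in column %s; accepted: %s",
        tab[[col]][bad[1L]], col, paste(.ACMG, collapse = ", ")))
    }
  }
  out <- data.frame(
    chrom = tab$chrom, pos = as.integer(tab$pos), ref = tab$ref,
    alt = tab$alt, gene = tab$gene,
    transcript = .chr_or_na(tab$transcript),
    consequence = tab$consequence,
    hgvs_c = .chr_or_na(tab$hgvs_c), hgvs_p = .chr_or_na(tab$hgvs_p),
    cadd = .num_or_na(tab$cadd), stringsAsFactors = FALSE)
  for (col in .MAF_COLS) out[[col]] <- .num_or_na(tab[[col]])
  for (col in c("ac_gnomad", "ac_internal", "hom_exac", "hemi_exac")) {
    out[[col]] <- .num_or_na(tab[[col]])
  }
  out$clinvar_id <- .chr_or_na(tab$clinvar_id)
  out$clinvar_class <- tab$clinvar_class
  out$class_platform <- tab$class_platform
  out$class_varsome <- tab$class_varsome
  out$class_franklin <- tab$class_franklin
  bad_maf <- which(apply(as.matrix(out[, .MAF_COLS]), 1L,
                         function(x) any(!is.na(x) & (x < 0 | x > 1))))
  if (length(bad_maf)) {
    .io_stop(path, bad_maf[1L] + 1L, "MAF outside [0, 1]")
  }
  out$variant_class <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L,
                              "SNV", "INDEL")
  out$key <- variant_key(out)
  out$.row <- seq_len(nrow(out)) + 1L
  attr(out, "source") <- path
  out
}

#' Keys present in the annotation table but absent from a variant set
#'
#' @param annotations Annotation table.
#' @param variants Variant table with a `key` column.
#' @return Character vector of orphan keys.
#' @export
annotation_orphans <- function(annotations, variants) {
  setdiff(unique(annotations$key), variants$key)
}

#' Read pre-called CNV interval records
#'
#' CNVs arrive as platform output in a BED-like TSV; calling is out of
#' scope. Coordinates are 1-based inclusive. Columns: `family_id`, `chrom`,
#' `start`, `end`, `dosage` (DEL/DUP), `genes` (semicolon-separated symbols
#' overlapped), `carriers` (semicolon-separated sample ids), plus the
#' classification columns `clinvar_id`, `clinvar_class`, `class_platform`,
#' `class_varsome`, `class_franklin`.
#'
#' @param path TSV path.
#' @return Data frame of CNV records with a `key` column.
#' @export
read_cnv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  required <- c("family_id", "chrom", "start", "end", "dosage", "genes",
                "carriers", "clinvar_id", "clinvar_class", "class_platform",
                "class_varsome", "class_franklin")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    family_id = tab$family_id, chrom = tab$chrom,
    cnv_start = as.integer(tab$start), cnv_end = as.integer(tab$end),
    cnv_dosage = toupper(tab$dosage), genes = tab$genes,
    carriers = tab$carriers,
    clinvar_id = .chr_or_na(tab$clinvar_id),
    clinvar_class = .chr_or_na(tab$clinvar_class),
    class_platform = .chr_or_na(tab$class_platform),
    class_varsome = .chr_or_na(tab$class_varsome),
    class_franklin = .chr_or_na(tab$class_franklin),
    stringsAsFactors = FALSE)
  bad <- which(!out$cnv_dosage %in% c("DEL", "DUP"))
  if (length(bad)) .io_stop(path, bad[1L] + 1L, "dosage must be DEL or DUP")
  bad <- which(out$cnv_end <= out$cnv_start)
  if (length(bad)) .io_stop(path, bad[1L] + 1L, "CNV end must exceed start")
  out$variant_class <- "CNV"
  out$pos <- out$cnv_start
  out$ref <- NA_character_; out$alt <- NA_character_
  out$key <- variant_key(out)
  out
}

#' Convert CNV interval records into variant/genotype/annotation rows
#'
#' Each carrier receives a heterozygous call, except male X-chromosome
#' carriers, which are hemizygous. One annotation row is emitted per
#' overlapped gene, with consequence `cnv_loss` or `cnv_gain`; CNVs carry no
#' population-frequency semantics, so all frequency fields are absent.
#'
#' @param cnv Data frame from [read_cnv()].
#' @param families Family table from [read_pedigree()] (used to sex carriers).
#' @return List with `variants`, `genotypes` and `annotations` rows that can
#'   be appended to the SNV/indel tables.
#' @export
cnv_records <- function(cnv, families) {
  if (nrow(cnv) == 0L) {
    return(list(variants = .empty_variants(), genotypes = .empty_genotypes(),
                annotations = NULL))
  }
  sex_of <- c(
    stats::setNames(families$sex, families$proband_id),
    stats::setNames(rep("female", nrow(families)), families$mother_id),
    stats::setNames(rep("male", nrow(families)), families$father_id))
  sex_of <- sex_of[!is.na(names(sex_of))]
  variants <- data.frame(
    key = cnv$key, chrom = cnv$chrom, pos = cnv$cnv_start,
    ref = NA_character_, alt = NA_character_, variant_class = "CNV",
    cnv_start = cnv$cnv_start, cnv_end = cnv$cnv_end,
    cnv_dosage = cnv$cnv_dosage,
    family_id = cnv$family_id, stringsAsFactors = FALSE)
  gt_rows <- list(); ann_rows <- list()
  for (i in seq_len(nrow(cnv))) {
    carriers <- strsplit(cnv$carriers[i], ";", fixed = TRUE)[[1L]]
    carriers <- trimws(carriers[carriers != ""])
    # family members not listed as carriers were screened by the CNV
    # caller, so they receive explicit reference calls (de novo assessment)
    fam <- families[families$family_id == cnv$family_id[i], , drop = FALSE]
    members <- unique(stats::na.omit(c(carriers, fam$proband_id,
                                       fam$mother_id, fam$father_id)))
    is_carrier <- members %in% carriers
    hemi <- is_x_chrom(cnv$chrom[i]) &
      !is.na(sex_of[members]) & sex_of[members] == "male"
    gt_rows[[i]] <- data.frame(
      key = cnv$key[i], sample_id = members,
      a1 = ifelse(is_carrier, 1L, 0L),
      a2 = ifelse(hemi, NA_integer_, 0L),
      phased = FALSE, depth = NA_integer_, missing = FALSE,
      family_id = cnv$family_id[i], stringsAsFactors = FALSE)
    genes <- strsplit(cnv$genes[i], ";", fixed = TRUE)[[1L]]
    genes <- trimws(genes[genes != ""])
    if (length(genes) == 0L) genes <- NA_character_
    ann_rows[[i]] <- data.frame(
      chrom = cnv$chrom[i], pos = cnv$cnv_start[i], ref = NA_character_,
      alt = NA_character_, gene = genes, transcript = NA_character_,
      consequence = if (cnv$cnv_dosage[i] == "DEL") "cnv_loss" else "cnv_gain",
      hgvs_c = NA_character_, hgvs_p = NA_character_, cadd = NA_real_,
      maf_cmg = NA_real_, maf_esp5400 = NA_real_, maf_1000g = NA_real_,
      maf_gnomad = NA_real_, maf_exac = NA_real_, maf_internal = NA_real_,
      ac_gnomad = NA_real_, ac_internal = NA_real_, hom_exac = NA_real_,
      hemi_exac = NA_real_, clinvar_id = cnv$clinvar_id[i],
      clinvar_class = cnv$clinvar_class[i],
      class_platform = cnv$class_platform[i],
      class_varsome = cnv$class_varsome[i],
      class_franklin = cnv$class_franklin[i],
      variant_class = "CNV", key = cnv$key[i], .row = NA_integer_,
      stringsAsFactors = FALSE)
  }
  list(variants = variants, genotypes = do.call(rbind, gt_rows),
       annotations = do.call(rbind, ann_rows))
}

#' Read proband phenotype terms
#'
#' @param path Two-column TSV (`proband_id`, `hpo_id`), one term per row,
#'   with a header.
#' @param ontology Optional [read_ontology()] object; unknown term ids are
#'   rejected at load when provided.
#' @return Data frame `proband_id`, `hpo_id`.
#' @export
read_phenotypes <- function(path, ontology = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(c("proband_id", "hpo_id"), names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(ontology)) {
    bad <- which(!tab$hpo_id %in% ontology$ids)
    if (length(bad)) {
      .io_stop(path, bad[1L] + 1L,
               sprintf("unknown HPO term '%s'", tab$hpo_id[bad[1L]]))
    }
  }
  tab[, c("proband_id", "hpo_id")]
}

#' Read the gene-disease-inheritance map
#'
#' @param path TSV with columns `gene`, `omim_id`, `label`, `inheritance`
#'   (semicolon-separated tokens among AD, AR, XLD, XLR, XL, DD) and
#'   `hpo_terms` (semicolon-separated HPO ids). A gene may have multiple
#'   entries.
#' @return Data frame with those columns.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(c("gene", "omim_id", "label", "inheritance",
                            "hpo_terms"), names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    toks <- trimws(strsplit(tab$inheritance[i], "[;,]")[[1L]])
    toks <- toks[toks != ""]
    if (length(toks) == 0L) .io_stop(path, i + 1L, "empty inheritance mode")
    bad <- setdiff(toks, .INHERITANCE_MODES)
    if (length(bad)) {
      .io_stop(path, i + 1L, sprintf("unknown inheritance mode '%s'", bad[1L]))
    }
  }
  tab
}

#' @noRd
mode_tokens <- function(inheritance) {
  toks <- trimws(strsplit(inheritance, "[;,]")[[1L]])
  toks[toks != ""]
}

#' Write machine- and human-readable result reports
#'
#' Emits a TSV (one row per informative candidate; probands without
#' candidates get a single row with empty variant fields) and, optionally, a
#' JSON document with one section per proband.
#'
#' @param results Per-proband results data frame (from [run_cohort()] or
#'   [informative_results()]).
#' @param candidates Candidate data frame with `proband_id`, `gene`,
#'   `hgvs_c`, `zygosity`, `origin`, `model` or `mode`, `class` columns.
#' @param path Output TSV path.
#' @param json_path Optional output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, candidates, path, json_path = NULL) {
  cols <- c("proband_id", "gene", "hgvs_c", "zygosity", "origin", "mode",
            "class", "omim_id", "category")
  rows <- list()
  for (i in seq_len(nrow(results))) {
    pid <- results$proband_id[i]
    cc <- candidates[candidates$proband_id == pid, , drop = FALSE]
    if (nrow(cc) == 0L) {
      row <- data.frame(proband_id = pid, gene = NA, hgvs_c = NA,
                        zygosity = NA, origin = NA, mode = NA, class = NA,
                        omim_id = NA, category = results$category[i],
                        stringsAsFactors = FALSE)
    } else {
      row <- data.frame(
        proband_id = pid, gene = cc$gene,
        hgvs_c = if ("hgvs_c" %in% names(cc)) cc$hgvs_c else NA,
        zygosity = cc$zygosity, origin = cc$origin,
        mode = if ("mode" %in% names(cc)) cc$mode else NA,
        class = cc$class,
        omim_id = if ("omim_id" %in% names(cc)) cc$omim_id else NA,
        category = results$category[i], stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = length(cols), nrow = 0L)), cols)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    sections <- lapply(seq_len(nrow(results)), function(i) {
      pid <- results$proband_id[i]
      list(proband_id = pid,
           strategy = results$strategy[i],
           category = results$category[i],
           informative = results$informative[i],
           candidates = candidates[candidates$proband_id == pid, , drop = FALSE])
    })
    jsonlite::write_json(sections, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read a strategy/outcome analysis table
#'
#' @param path TSV with columns `analysis_id`, `proband_id`, `strategy`
#'   (CES, ES-Solo, ES-Duo, ES-Trio) and `informative` (0/1). Re-sequenced
#'   probands contribute one row per analysis.
#' @return Data frame with `informative` as logical.
#' @export
read_strategy_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("analysis_id", "proband_id", "strategy",
                            "informative"), names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!tab$strategy %in% c("CES", "ES-Solo", "ES-Duo", "ES-Trio"))
  if (length(bad)) {
    .io_stop(path, bad[1L] + 1L,
             sprintf("unknown strategy label '%s'", tab$strategy[bad[1L]]))
  }
  tab$informative <- as.logical(as.integer(tab$informative))
  tab
}
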