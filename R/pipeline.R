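# End-to-end orchestration: filters -> stepwise inheritance models ->
# consensus interpretation + phenotype consistency -> clinical category,
# per family and across a cohort.

#' Run the full prioritization for one family
#'
#' @param family One-row family data frame ([read_pedigree()] row).
#' @param variants,genotypes Variant/genotype tables covering this family
#'   (SNV/indel rows from [read_vcf()] plus CNV rows from [cnv_records()]).
#' @param annotations Annotation table.
#' @param phenotypes Phenotype term table (`proband_id`, `hpo_id`).
#' @param gene_map Gene-disease map.
#' @param ontology An `hpo_ontology`.
#' @param cfg A [filter_config()].
#' @param cohort_index Optional cohort recurrence index.
#' @return A `result_record` augmented with `proband_id`, `family_id`,
#'   `strategy`, the full candidate table and the filter trace.
#' @export
run_family <- function(family, variants, genotypes, annotations, phenotypes,
                       gene_map, ontology, cfg = filter_config(),
                       cohort_index = NULL) {
  filtered <- apply_filters(family, variants, genotypes, annotations, cfg,
                            cohort_index)
  cands <- run_stepwise(family, filtered, variants, genotypes, annotations,
                        cfg)
  terms <- phenotypes$hpo_id[phenotypes$proband_id == family$proband_id]
  if (nrow(cands) > 0L) {
    cc <- .consensus_classes(cands)
    cands$class <- cc$class
    cands$class_source <- cc$class_source
    genes <- unique(cands$gene)
    cons <- stats::setNames(vector("list", length(genes)), genes)
    for (g in genes) {
      cons[[g]] <- phenotype_consistent(g, terms, gene_map, ontology, cfg)
    }
    cands$consistent <- vapply(cands$gene,
                               function(g) cons[[g]]$consistent, logical(1))
    cands$mode <- vapply(cands$gene, function(g) {
      if (cons[[g]]$consistent) cons[[g]]$entry$inheritance else NA_character_
    }, character(1))
    cands$omim_id <- vapply(cands$gene, function(g) {
      if (cons[[g]]$consistent) cons[[g]]$entry$omim_id else NA_character_
    }, character(1))
    panel <- build_virtual_panel(terms, gene_map, ontology, cfg)
    cands$in_panel <- cands$gene %in% panel$gene
  } else {
    cands$class <- character(0); cands$class_source <- character(0)
    cands$consistent <- logical(0); cands$mode <- character(0)
    cands$omim_id <- character(0); cands$in_panel <- logical(0)
  }
  rec <- classify_result(cands, cfg)
  rec$proband_id <- family$proband_id
  rec$family_id <- family$family_id
  rec$strategy <- family$strategy
  rec$all_candidates <- cands
  rec$trace <- filtered$trace
  rec
}

#' Run the prioritization across a cohort
#'
#' Variant and genotype tables must carry a `family_id` column (the
#' synthetic generator and the per-family VCF reader both produce it). The
#' cohort recurrence index is built from all probands before any family is
#' analyzed.
#'
#' @param bundle List with `families`, `variants`, `genotypes`,
#'   `annotations`, optional `cnv`, `phenotypes`, `gene_map`, `ontology`
#'   (as produced by [simulate_cohort()] or assembled from the readers).
#' @param cfg A [filter_config()].
#' @return List of class `rudx_results`: `results` (per-proband data
#'   frame), `records` (list of `result_record`s) and `candidates`
#'   (informative candidates across the cohort, with `proband_id`).
#' @export
run_cohort <- function(bundle, cfg = filter_config()) {
  families <- bundle$families
  variants <- bundle$variants
  genotypes <- bundle$genotypes
  annotations <- bundle$annotations
  if (!is.null(bundle$cnv) && nrow(bundle$cnv) > 0L) {
    cr <- cnv_records(bundle$cnv, families)
    variants <- rbind(variants[, names(cr$variants), drop = FALSE],
                      cr$variants)
    genotypes <- rbind(genotypes[, names(cr$genotypes), drop = FALSE],
                       cr$genotypes)
    ann_cols <- intersect(names(annotations), names(cr$annotations))
    annotations <- rbind(annotations[, ann_cols, drop = FALSE],
                         cr$annotations[, ann_cols, drop = FALSE])
  }
  if (!"family_id" %in% names(variants) || !"family_id" %in% names(genotypes)) {
    stop("cohort variants/genotypes require a family_id column", call. = FALSE)
  }
  cohort_index <- build_cohort_index(genotypes, families)
  annotations <- select_annotation(annotations)  # once, for every family
  # one pass of split() instead of a full-table scan per family
  vsplit <- split(variants, variants$family_id)
  gsplit <- split(genotypes, genotypes$family_id)
  ann_fam <- variants$family_id[match(annotations$key, variants$key)]
  asplit <- split(annotations, ann_fam)
  records <- list(); res_rows <- list(); cand_rows <- list()
  for (i in seq_len(nrow(families))) {
    fam <- families[i, , drop = FALSE]
    fv <- vsplit[[fam$family_id]]
    fg <- gsplit[[fam$family_id]]
    if (is.null(fv)) fv <- variants[0, , drop = FALSE]
    if (is.null(fg)) fg <- genotypes[0, , drop = FALSE]
    fa <- asplit[[fam$family_id]]
    if (is.null(fa)) fa <- annotations[0, , drop = FALSE]
    attr(fa, "selected") <- TRUE
    rec <- run_family(fam, fv, fg, fa, bundle$phenotypes,
                      bundle$gene_map, bundle$ontology, cfg, cohort_index)
    records[[fam$proband_id]] <- rec
    res_rows[[i]] <- data.frame(
      proband_id = fam$proband_id, family_id = fam$family_id,
      strategy = fam$strategy, category = rec$category,
      informative = rec$informative,
      n_candidates = nrow(rec$all_candidates), stringsAsFactors = FALSE)
    if (nrow(rec$candidates) > 0L) {
      cc <- rec$candidates
      cc$proband_id <- fam$proband_id
      cand_rows[[length(cand_rows) + 1L]] <- cc
    }
  }
  structure(
    list(results = do.call(rbind, res_rows),
         records = records,
         candidates = if (length(cand_rows)) do.call(rbind, cand_rows) else NULL),
    class = "rudx_results")
}
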