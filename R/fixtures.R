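# Bundled fixtures: the published informative-variant table (one row per
# informative variant, 47 probands / 55 variants) and the per-analysis
# strategy/outcome table (113 analyses in 103 probands). Both ship as
# plain TSV under inst/extdata and feed the cohort-level tallies.

#' Read the bundled informative-variant table
#'
#' One row per informative variant with gene, transcript, HGVS, zygosity,
#' parental origin, consensus interpretation, ClinVar id (empty when the
#' variant is not listed in ClinVar) and the matched OMIM phenotype with its
#' inheritance mode. SNVs/indels are keyed by gene + cDNA change and CNVs by
#' their interval, so a homozygote counts as one distinct variant.
#'
#' @param path TSV path; defaults to the bundled fixture.
#' @return Candidate data frame ready for [classify_result()] and
#'   [variant_tallies()]: `proband_id`, `key`, `gene`, `class`, `zygosity`,
#'   `origin`, `mode`, `consistent`, `variant_class`, `clinvar_id`,
#'   `hgvs_c`, `omim_id`, `sex`, `age`.
#' @export
read_informative_table <- function(path = system.file(
  "extdata", "informative_variants.tsv", package = "rudx")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  zyg_map <- c(Het = "het", Hom = "hom", Hem = "hem")
  bad <- which(!tab$zygosity %in% names(zyg_map))
  if (length(bad)) .io_stop(path, bad[1L] + 1L, "zygosity must be Het/Hom/Hem")
  bad <- which(!tab$origin %in% c("de_novo", "maternal", "paternal",
                                  "biparental", "unknown"))
  if (length(bad)) .io_stop(path, bad[1L] + 1L, "invalid origin")
  bad <- which(!tab$interpretation %in% .ACMG)
  if (length(bad)) .io_stop(path, bad[1L] + 1L, "invalid interpretation class")
  is_cnv <- tab$variant_class == "CNV"
  key <- paste0(tab$gene, ":", tab$hgvs_c)
  key[is_cnv] <- sprintf("%s:%d-%d:%s", tab$chrom[is_cnv],
                         as.integer(tab$cnv_start[is_cnv]),
                         as.integer(tab$cnv_end[is_cnv]),
                         tab$cnv_dosage[is_cnv])
  data.frame(
    proband_id = tab$patient_id, key = key, gene = tab$gene,
    class = tab$interpretation, zygosity = unname(zyg_map[tab$zygosity]),
    origin = tab$origin, mode = tab$omim_inheritance, consistent = TRUE,
    variant_class = tab$variant_class,
    clinvar_id = .chr_or_na(tab$clinvar_id),
    hgvs_c = .chr_or_na(tab$hgvs_c), omim_id = .chr_or_na(tab$omim_id),
    sex = tab$sex, age = .num_or_na(tab$age_years),
    stringsAsFactors = FALSE)
}

#' Categorize every proband of an informative-variant table
#'
#' Runs [classify_result()] per proband (the fixture's genes are, by
#' construction, phenotype-consistent) and assembles cohort-style outputs.
#'
#' @param tbl Table from [read_informative_table()].
#' @param cfg A [filter_config()].
#' @return List with `results` (per-proband data frame), `records` (list of
#'   `result_record`s) and `candidates` (the input table, for
#'   [variant_tallies()]).
#' @export
informative_results <- function(tbl, cfg = filter_config()) {
  probands <- unique(tbl$proband_id)
  records <- list(); rows <- list()
  for (p in probands) {
    cand <- tbl[tbl$proband_id == p, , drop = FALSE]
    rec <- classify_result(cand, cfg)
    rec$proband_id <- p
    records[[p]] <- rec
    rows[[length(rows) + 1L]] <- data.frame(
      proband_id = p, strategy = NA_character_, category = rec$category,
      informative = rec$informative, stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, rows), records = records, candidates = tbl)
}

#' Path of the bundled strategy/outcome analysis table
#'
#' @return Path to the TSV read by [read_strategy_table()].
#' @export
strategy_table_path <- function() {
  system.file("extdata", "strategy_analyses.tsv", package = "rudx")
}
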