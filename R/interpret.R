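# Consensus ACMG interpretation per variant and per-proband clinical
# categorization (solved / suggestive / partially informative /
# uninformative).

.CATEGORY_RANK <- c(uninformative = 0L, partially_informative = 1L,
                    suggestive = 2L, solved = 3L)

#' Consensus ACMG class across interpretation resources
#'
#' The ClinVar class, when present, is returned verbatim. Otherwise the most
#' common class among the other resources is chosen; modal ties resolve to
#' VUS (a clinically conservative, deterministic tie-break).
#'
#' @param clinvar_class ClinVar class or `NA`.
#' @param resource_classes Character vector of up to three classes from
#'   independent interpretation resources (`NA`s ignored).
#' @return List with `class`, `source` (`"clinvar"`, `"majority"` or
#'   `"tie_rule"`) and `inputs`.
#' @export
consensus_class <- function(clinvar_class, resource_classes) {
  resource_classes <- resource_classes[!is.na(resource_classes)]
  inputs <- list(clinvar = clinvar_class, resources = resource_classes)
  if (!is.na(clinvar_class)) {
    stopifnot(clinvar_class %in% .ACMG)
    return(list(class = clinvar_class, source = "clinvar", inputs = inputs))
  }
  if (length(resource_classes) == 0L) {
    stop("unclassifiable: no interpretation available", call. = FALSE)
  }
  stopifnot(all(resource_classes %in% .ACMG))
  counts <- table(resource_classes)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) {
    list(class = top, source = "majority", inputs = inputs)
  } else {
    list(class = "VUS", source = "tie_rule", inputs = inputs)
  }
}

# Vectorised, non-strict variant used by the pipeline: candidates with no
# interpretation at all get class NA (they can never be informative).
#' @noRd
.consensus_classes <- function(cands) {
  n <- nrow(cands)
  cls <- rep(NA_character_, n); src <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- c(cands$class_platform[i], cands$class_varsome[i],
             cands$class_franklin[i])
    if (is.na(cands$clinvar_class[i]) && all(is.na(res))) next
    cc <- consensus_class(cands$clinvar_class[i], res)
    cls[i] <- cc$class; src[i] <- cc$source
  }
  data.frame(class = cls, class_source = src, stringsAsFactors = FALSE)
}

#' @noRd
.mode_group <- function(mode) {
  ifelse(grepl("^XL", mode), "XL", ifelse(mode == "AR", "AR", "AD"))
}

# Category of a single gene's informative candidates under its matched
# inheritance mode. `rows` carries class, zygosity, origin.
#' @noRd
.gene_category <- function(rows, mode) {
  plp <- rows$class %in% c("P", "LP")
  hom <- rows$zygosity == "hom"
  hem <- rows$zygosity == "hem"
  if (mode %in% c("AD", "DD", "XLD")) {
    return(if (any(plp)) "solved" else "suggestive")
  }
  if (mode %in% c("XLR", "XL")) {
    if (any(hem | hom)) {
      return(if (any(plp & (hem | hom))) "solved" else "suggestive")
    }
    # heterozygous-only finding under a recessive X condition: one allele
    return("partially_informative")
  }
  # AR: two alleles in trans required; a homozygote counts as two
  if (any(hom)) {
    return(if (any(plp & hom)) "solved" else "suggestive")
  }
  if (nrow(rows) >= 2L) {
    org <- rows$origin
    trans_pair <- function(i, j) {
      !(org[i] %in% c("maternal", "paternal") && identical(org[i], org[j]))
    }
    pairs <- which(upper.tri(matrix(TRUE, nrow(rows), nrow(rows))), arr.ind = TRUE)
    any_trans <- FALSE; any_plp_pair <- FALSE
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      if (!trans_pair(i, j)) next
      any_trans <- TRUE
      if (plp[i] && plp[j]) any_plp_pair <- TRUE
    }
    if (any_trans) {
      return(if (any_plp_pair) "solved" else "suggestive")
    }
  }
  "partially_informative"
}

#' Categorize a proband's candidates into a clinical result
#'
#' Implements the interpretation rules: (i) only P/LP/VUS candidates in
#' phenotype-consistent genes are informative (LB/B are dropped; no
#' informative candidate means uninformative); (ii) genotype completeness
#' follows the matched inheritance mode — AR needs two alleles in trans
#' (a homozygote counts as two), AD/XLD need one, XLR needs the hemizygous
#' or homozygous allele; (iii) solved requires the mode's requirement to be
#' met entirely by P/LP alleles (a recessive genotype mixing P/LP with VUS
#' is suggestive, not solved); (iv) a recessive-matched gene with a single
#' informative allele is partially informative; (v) everything else
#' informative is suggestive. With informative candidates in several genes
#' the proband's category is the maximum over genes and all contributing
#' genes are reported.
#'
#' @param candidates Data frame with columns `gene`, `class`, `zygosity`
#'   (`"het"`, `"hom"`, `"hem"`), `origin`, `consistent` (logical) and
#'   `mode` (matched inheritance mode; the first token is used).
#' @param cfg A [filter_config()].
#' @return List of class `result_record`: `category`, `informative`,
#'   `genes` (per-gene detail data frame) and `candidates` (the informative
#'   subset).
#' @export
classify_result <- function(candidates, cfg = filter_config()) {
  required <- c("gene", "class", "zygosity", "origin", "consistent", "mode")
  missing_cols <- setdiff(required, names(candidates))
  if (length(missing_cols)) {
    stop(sprintf("candidates lack consistency evaluation column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  inf <- candidates[!is.na(candidates$class) &
                      candidates$class %in% c("P", "LP", "VUS") &
                      candidates$consistent %in% TRUE, , drop = FALSE]
  if (nrow(inf) == 0L) {
    return(structure(list(category = "uninformative", informative = FALSE,
                          genes = data.frame(gene = character(0),
                                             mode = character(0),
                                             category = character(0)),
                          candidates = inf),
                     class = "result_record"))
  }
  genes <- unique(inf$gene)
  gene_cat <- character(length(genes)); gene_mode <- character(length(genes))
  for (i in seq_along(genes)) {
    rows <- inf[inf$gene == genes[i], , drop = FALSE]
    mode <- mode_tokens(rows$mode[1L])[1L]
    gene_mode[i] <- mode
    gene_cat[i] <- .gene_category(rows, mode)
  }
  best <- which.max(.CATEGORY_RANK[gene_cat])
  structure(
    list(category = gene_cat[best], informative = TRUE,
         genes = data.frame(gene = genes, mode = gene_mode,
                            mode_group = .mode_group(gene_mode),
                            category = gene_cat, stringsAsFactors = FALSE),
         candidates = inf),
    class = "result_record")
}
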