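# HPO-driven virtual gene panels, phenotype-consistency checks and the
# organ-system grouping (depth-1 branches under the phenotypic-abnormality
# root) used for the cohort covariates.

#' Map an HPO term to its organ system(s)
#'
#' Systems are the depth-1 children of the phenotypic-abnormality root; a
#' term maps to every system that is an ancestor of (or equal to) it.
#' Multi-parent terms may map to several systems. Terms not under the root
#' map to the empty set (with a warning unless `quiet`).
#'
#' @param term Term identifier.
#' @param ontology An `hpo_ontology`.
#' @param quiet Suppress the not-under-root warning.
#' @return Character vector of system term ids.
#' @export
term_to_systems <- function(term, ontology, quiet = FALSE) {
  systems <- ontology$children[[ontology$root]]
  anc <- hpo_ancestors(ontology, term, include_self = TRUE)
  hit <- intersect(systems, anc)
  if (length(hit) == 0L && !quiet) {
    warning(sprintf("term '%s' is not under the phenotypic-abnormality root",
                    term), call. = FALSE)
  }
  hit
}

#' Count the organ systems affected in a proband
#'
#' Union of [term_to_systems()] over the proband's terms; deterministic and
#' invariant to term order.
#'
#' @param terms Character vector of the proband's HPO term ids.
#' @param ontology An `hpo_ontology`.
#' @return List with `systems` (sorted character vector) and `n_systems`.
#' @export
count_affected_systems <- function(terms, ontology) {
  systems <- character(0)
  for (t in unique(terms)) {
    systems <- union(systems, term_to_systems(t, ontology, quiet = TRUE))
  }
  list(systems = sort(systems), n_systems = length(systems))
}

# Ancestor expansion used for panel overlap: the term itself plus every
# ancestor strictly below the phenotypic-abnormality root. The root itself
# never counts as a match (a root match is vacuous).
#' @noRd
.expand_terms <- function(terms, ontology) {
  out <- character(0)
  for (t in unique(terms)) {
    if (!t %in% ontology$ids) next
    out <- union(out, hpo_ancestors(ontology, t, include_self = TRUE))
  }
  setdiff(out, ontology$root)
}

#' Build a phenotype-driven virtual gene panel
#'
#' Genes whose disease-entry HPO terms share at least `cfg$min_term_overlap`
#' terms with the proband's terms after ancestor expansion (both sides
#' expanded to all ancestors below the phenotypic-abnormality root). With
#' `min_term_overlap = 0` the panel is phenotypically unbiased and contains
#' every mapped gene, which implements the second, unbiased analysis pass.
#'
#' @param terms Proband HPO term ids.
#' @param gene_map Gene-disease map from [read_gene_map()].
#' @param ontology An `hpo_ontology`.
#' @param cfg A [filter_config()].
#' @return Data frame `gene`, `omim_id`, `inheritance`, `overlap`, ranked by
#'   overlap descending, gene symbol ascending on ties; one row per
#'   qualifying disease entry.
#' @export
build_virtual_panel <- function(terms, gene_map, ontology,
                                cfg = filter_config()) {
  pexp <- .expand_terms(terms, ontology)
  overlap <- integer(nrow(gene_map))
  for (i in seq_len(nrow(gene_map))) {
    gterms <- trimws(strsplit(gene_map$hpo_terms[i], ";", fixed = TRUE)[[1L]])
    gexp <- .expand_terms(gterms[gterms != ""], ontology)
    overlap[i] <- length(intersect(pexp, gexp))
  }
  keep <- overlap >= cfg$min_term_overlap
  out <- data.frame(gene = gene_map$gene[keep],
                    omim_id = gene_map$omim_id[keep],
                    inheritance = gene_map$inheritance[keep],
                    overlap = overlap[keep], stringsAsFactors = FALSE)
  out[order(-out$overlap, out$gene), , drop = FALSE]
}

#' Is a gene consistent with a proband's phenotype?
#'
#' True when the gene has at least one disease entry sharing at least one
#' expanded HPO term with the proband (or `cfg$min_term_overlap` terms when
#' that is higher). The matched entry, with its inheritance mode, is
#' returned for result categorization. The set-overlap rule formalizes an
#' expert-review judgement; see the methods vignette.
#'
#' @param gene Gene symbol.
#' @param terms Proband HPO term ids.
#' @param gene_map Gene-disease map.
#' @param ontology An `hpo_ontology`.
#' @param cfg A [filter_config()].
#' @return List with `consistent` (logical), `entry` (matched gene-map row
#'   or `NULL`), `overlap` and `reason` (set when inconsistent).
#' @export
phenotype_consistent <- function(gene, terms, gene_map, ontology,
                                 cfg = filter_config()) {
  entries <- gene_map[gene_map$gene == gene, , drop = FALSE]
  if (nrow(entries) == 0L) {
    return(list(consistent = FALSE, entry = NULL, overlap = 0L,
                reason = "gene not in map"))
  }
  # consistency always demands a real shared term, even in unbiased mode
  threshold <- max(1L, cfg$min_term_overlap)
  pexp <- .expand_terms(terms, ontology)
  best <- 0L; best_i <- NA_integer_
  for (i in seq_len(nrow(entries))) {
    gterms <- trimws(strsplit(entries$hpo_terms[i], ";", fixed = TRUE)[[1L]])
    ov <- length(intersect(pexp, .expand_terms(gterms[gterms != ""], ontology)))
    if (ov > best) { best <- ov; best_i <- i }
  }
  if (best >= threshold) {
    list(consistent = TRUE, entry = entries[best_i, , drop = FALSE],
         overlap = best, reason = "")
  } else {
    list(consistent = FALSE, entry = NULL, overlap = best,
         reason = "insufficient term overlap")
  }
}
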