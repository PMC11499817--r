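# Minimal OBO 1.2 ontology reader and the ancestor queries used by the
# phenotype module. Only [Term] stanzas with id/name/is_a are consumed;
# obsolete terms are dropped. No installed R package parses OBO, so the
# stanza reader is implemented here.

#' Read an OBO 1.2 ontology file
#'
#' @param path OBO file path.
#' @param root Identifier of the phenotypic-abnormality root. Defaults to
#'   `HP:0000118` when present, otherwise the unique parentless term.
#' @return An object of class `hpo_ontology`: list with `ids`, `labels`
#'   (named by id), `parents` and `children` (named lists of character
#'   vectors), `root`, and `disconnected` (terms with no path to the root).
#' @export
read_ontology <- function(path, root = NULL) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) {
    stop(sprintf("%s: no [Term] stanzas found", path), call. = FALSE)
  }
  stanza_breaks <- c(term_starts, length(lines) + 1L)
  ids <- character(0); labels <- character(0)
  parents <- list()
  for (s in seq_along(term_starts)) {
    chunk <- lines[(stanza_breaks[s] + 1L):(stanza_breaks[s + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\[", chunk)]
    get1 <- function(tag) {
      hit <- grep(paste0("^", tag, ":"), chunk, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      trimws(sub(paste0("^", tag, ":"), "", hit[1L]))
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) next
    isa <- grep("^is_a:", chunk, value = TRUE)
    isa <- trimws(sub("!.*$", "", sub("^is_a:", "", isa)))
    ids <- c(ids, id)
    labels <- c(labels, get1("name"))
    parents[[id]] <- isa
  }
  names(labels) <- ids
  build_ontology(ids, labels, parents, root = root, source = path)
}

#' Assemble an ontology object from term/edge vectors
#'
#' @param ids Term identifiers.
#' @param labels Named character vector of term labels.
#' @param parents Named list: term id -> character vector of `is_a` parents.
#' @param root Root term id; see [read_ontology()].
#' @param source Provenance string.
#' @return An `hpo_ontology` object.
#' @export
build_ontology <- function(ids, labels, parents, root = NULL, source = NA) {
  parents <- lapply(parents, function(p) intersect(p, ids))
  parents <- parents[intersect(names(parents), ids)]
  for (id in setdiff(ids, names(parents))) parents[[id]] <- character(0)
  # cycle detection (Kahn's algorithm on is_a edges)
  indeg <- vapply(parents, length, integer(1))
  queue <- names(indeg)[indeg == 0L]
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  seen <- 0L
  remaining <- indeg
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[cur]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    cyc <- names(remaining)[remaining > 0L]
    stop(sprintf("ontology contains a cycle involving: %s",
                 paste(utils::head(cyc, 5L), collapse = ", ")), call. = FALSE)
  }
  if (is.null(root)) {
    root <- if ("HP:0000118" %in% ids) "HP:0000118" else {
      parentless <- names(parents)[vapply(parents, length, integer(1)) == 0L]
      if (length(parentless) != 1L) {
        stop("cannot determine the phenotypic-abnormality root; pass `root`",
             call. = FALSE)
      }
      parentless
    }
  }
  if (!root %in% ids) {
    stop(sprintf("root term '%s' not present in ontology", root), call. = FALSE)
  }
  ont <- structure(
    list(ids = ids, labels = labels, parents = parents, children = children,
         root = root, source = source),
    class = "hpo_ontology")
  reach <- .descendants(ont, root)
  ont$disconnected <- setdiff(ids, c(root, reach))
  ont
}

#' @noRd
.descendants <- function(ont, term) {
  out <- character(0); queue <- ont$children[[term]]
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (cur %in% out) next
    out <- c(out, cur)
    queue <- c(queue, ont$children[[cur]])
  }
  out
}

#' Ancestor closure of an ontology term
#'
#' Follows `is_a` edges upward; multi-parent terms contribute every path.
#'
#' @param ontology An `hpo_ontology`.
#' @param term Term identifier.
#' @param include_self Include `term` itself in the result.
#' @return Character vector of ancestor term ids.
#' @export
hpo_ancestors <- function(ontology, term, include_self = FALSE) {
  if (!term %in% ontology$ids) {
    stop(sprintf("unknown term '%s'", term), call. = FALSE)
  }
  out <- character(0); queue <- ontology$parents[[term]]
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (cur %in% out) next
    out <- c(out, cur)
    queue <- c(queue, ontology$parents[[cur]])
  }
  if (include_self) out <- c(term, out)
  out
}

#' Write an ontology as an OBO 1.2 file
#'
#' @param ontology An `hpo_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  out <- c("format-version: 1.2", "")
  for (id in ontology$ids) {
    out <- c(out, "[Term]", sprintf("id: %s", id),
             sprintf("name: %s", ontology$labels[[id]]))
    for (p in ontology$parents[[id]]) {
      out <- c(out, sprintf("is_a: %s ! %s", p, ontology$labels[[p]]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
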