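# Organ-system grouping, virtual panels and phenotype consistency.

test_that("term_to_systems maps through the hierarchy, including DAG fan-out", {
  ont <- demo_ontology()
  # single-lineage leaf maps to its one branch
  expect_identical(term_to_systems("HP:0202001", ont), "HP:0100002")
  # the multi-parent leaf maps to both branches
  expect_setequal(term_to_systems("HP:0201003", ont),
                  c("HP:0100001", "HP:0100002"))
  # a system term maps to itself
  expect_identical(term_to_systems("HP:0100005", ont), "HP:0100005")
  # the root is not under any system
  expect_warning(out <- term_to_systems("HP:0000118", ont), "not under")
  expect_length(out, 0L)
})

test_that("term_to_systems equals brute-force reachability on every fixture term", {
  ont <- demo_ontology()
  reach <- oracle_ancestors(ont)
  systems <- ont$children[[ont$root]]
  for (id in setdiff(ont$ids, ont$root)) {
    want <- intersect(systems, c(id, ont$ids[reach[id, ]]))
    expect_setequal(term_to_systems(id, ont, quiet = TRUE), want)
  }
})

test_that("count_affected_systems is a union, order-invariant and monotone", {
  ont <- demo_ontology()
  expect_equal(count_affected_systems(character(0), ont)$n_systems, 0L)
  one_branch <- c("HP:0203001", "HP:0203002", "HP:0203003")
  expect_equal(count_affected_systems(one_branch, ont)$n_systems, 1L)
  terms <- c("HP:0201001", "HP:0204002", "HP:0207003")
  expect_identical(count_affected_systems(terms, ont),
                   count_affected_systems(rev(terms), ont))
  s1 <- count_affected_systems(terms[1:2], ont)$n_systems
  s2 <- count_affected_systems(terms, ont)$n_systems
  expect_gte(s2, s1)
})

test_that("virtual panel membership matches brute-force overlap on the fixture map", {
  ont <- demo_ontology()
  gm <- demo_gene_map(50L)
  cfg <- filter_config()
  terms <- c("HP:0201001", "HP:0201002", "HP:0205001")
  panel <- build_virtual_panel(terms, gm$map, ont, cfg)
  # brute force: expand both sides, count shared terms below the root
  expand <- function(ts) {
    out <- character(0)
    for (t in ts) out <- union(out, hpo_ancestors(ont, t, include_self = TRUE))
    setdiff(out, ont$root)
  }
  pexp <- expand(terms)
  want <- character(0)
  for (i in seq_len(nrow(gm$map))) {
    gterms <- strsplit(gm$map$hpo_terms[i], ";")[[1]]
    if (length(intersect(pexp, expand(gterms))) >= cfg$min_term_overlap) {
      want <- c(want, gm$map$gene[i])
    }
  }
  expect_setequal(panel$gene, want)
  # ranking: overlap descending, gene ascending on ties
  expect_true(all(diff(panel$overlap) <= 0))
  # a proband covering an entry's terms puts that gene in the panel
  full <- strsplit(gm$map$hpo_terms[1], ";")[[1]]
  expect_true(gm$map$gene[1] %in% build_virtual_panel(full, gm$map, ont, cfg)$gene)
  # disjoint branches, no shared ancestor below the root: gene absent
  other <- build_virtual_panel("HP:0205001", gm$map, ont, cfg)
  branch5_genes <- gm$map$gene[grepl("HP:0205", gm$map$hpo_terms)]
  expect_true(all(other$gene %in% branch5_genes))
})

test_that("min_term_overlap = 0 yields the phenotypically unbiased panel", {
  ont <- demo_ontology()
  gm <- demo_gene_map(50L)
  panel <- build_virtual_panel(character(0), gm$map, ont,
                               filter_config(min_term_overlap = 0L))
  expect_setequal(panel$gene, gm$map$gene)
})

test_that("phenotype consistency returns the matched entry and is monotone", {
  ont <- demo_ontology()
  gm <- demo_gene_map(50L)
  cfg <- filter_config()
  g <- gm$map$gene[1]
  gterms <- strsplit(gm$map$hpo_terms[1], ";")[[1]]
  hit <- phenotype_consistent(g, gterms[1], gm$map, ont, cfg)
  expect_true(hit$consistent)
  expect_identical(hit$entry$inheritance, gm$map$inheritance[1])
  miss <- phenotype_consistent("NOT_A_GENE", gterms, gm$map, ont, cfg)
  expect_false(miss$consistent)
  expect_identical(miss$reason, "gene not in map")
  # adding terms never flips a consistent gene to inconsistent
  set.seed(4)
  all_leaves <- grep("^HP:02", ont$ids, value = TRUE)
  for (rep in 1:10) {
    base <- sample(all_leaves, 3)
    before <- phenotype_consistent(g, base, gm$map, ont, cfg)$consistent
    after <- phenotype_consistent(g, c(base, sample(all_leaves, 4)),
                                  gm$map, ont, cfg)$consistent
    if (before) expect_true(after)
  }
})
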