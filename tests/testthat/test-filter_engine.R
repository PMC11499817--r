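# The four stated filter rules, their boundary behaviour, the recurrence
# index, and the oracle-equivalence / monotonicity properties.

test_that("technical filter enforces read support and consequence classes", {
  cfg <- filter_config()
  expect_false(technical_filter(2L, "missense", cfg = cfg)$pass)   # < 3 reads
  expect_true(technical_filter(3L, "missense", cfg = cfg)$pass)    # boundary
  expect_false(technical_filter(50L, "synonymous", cfg = cfg)$pass)
  r <- technical_filter(NA_integer_, "missense", cfg = cfg)
  expect_false(r$pass)
  expect_equal(r$reason, "depth unknown")
  # CNVs bypass the depth rule but not the consequence rule
  expect_true(technical_filter(NA_integer_, "cnv_loss", is_cnv = TRUE,
                               cfg = cfg)$pass)
  expect_false(technical_filter(NA_integer_, "synonymous", is_cnv = TRUE,
                                cfg = cfg)$pass)
  for (cons in c("deep_intronic", "intergenic", "utr5", "utr3")) {
    expect_false(technical_filter(50L, cons, cfg = cfg)$pass, info = cons)
  }
  expect_true(technical_filter(50L, "near_splice_intronic", cfg = cfg)$pass)
})

test_that("recessive frequency filter: strict MAF bound and combined hom+hemi count", {
  cfg <- filter_config()
  expect_false(recessive_frequency_filter(test_ann("chr1:1:A>G", maf = 0.01),
                                          cfg)$pass)
  expect_true(recessive_frequency_filter(
    test_ann("chr1:1:A>G", maf = NA), cfg)$pass)          # absent = 0
  expect_true(recessive_frequency_filter(
    test_ann("chr1:1:A>G", maf = 0.005), cfg)$pass)       # 'greater than' is strict
  expect_false(recessive_frequency_filter(
    test_ann("chr1:1:A>G", maf = 0.004, hom_exac = 10), cfg)$pass)
  expect_false(recessive_frequency_filter(                 # counts combine
    test_ann("chr1:1:A>G", maf = 0, hom_exac = 5, hemi_exac = 5), cfg)$pass)
  expect_true(recessive_frequency_filter(
    test_ann("chr1:1:A>G", hom_exac = 9), cfg)$pass)
  # a single high-frequency source triggers exclusion (max across sources)
  a <- test_ann("chr1:1:A>G", maf = 0)
  a$maf_esp5400 <- 0.02
  expect_false(recessive_frequency_filter(a, cfg)$pass)
})

test_that("dominant frequency filter: MAF and allele-count bounds", {
  cfg <- filter_config()
  expect_false(dominant_frequency_filter(test_ann("chr1:1:A>G", maf = 0.002),
                                         cfg)$pass)
  expect_false(dominant_frequency_filter(test_ann("chr1:1:A>G", ac = 6),
                                         cfg)$pass)
  expect_true(dominant_frequency_filter(
    test_ann("chr1:1:A>G", maf = 0.0005, ac = 5), cfg)$pass)  # at the bounds
  a <- test_ann("chr1:1:A>G")
  a$ac_internal <- 6
  expect_false(dominant_frequency_filter(a, cfg)$pass)
})

test_that("cohort recurrence counts unrelated families only", {
  cfg <- filter_config()
  idx <- data.frame(key = c("k1", "k2", "k2", "k3", "k3"),
                    proband_id = c("A", "A", "B", "A", "A2"),
                    family_id = c("F1", "F1", "F2", "F1", "F1"))
  r <- cohort_recurrence_filter(c("k1", "k2", "k3", "k9"), idx, cfg)
  expect_identical(r$pass, c(TRUE, FALSE, TRUE, TRUE))  # k3: same family twice

  # enumerate all family-relatedness configurations on a 6-proband cohort
  # and compare with a brute-force pairwise unrelatedness check
  set.seed(9)
  for (rep in 1:20) {
    fams <- sample(c("F1", "F2", "F3"), 6, replace = TRUE)
    carriers <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    idx <- data.frame(key = "k", proband_id = sprintf("P%d", which(carriers)),
                      family_id = fams[carriers])
    expected <- length(unique(fams[carriers])) <= 1L
    got <- cohort_recurrence_filter("k", idx, cfg)$pass
    expect_identical(got, expected)
  }
})

test_that("apply_filters isolates a planted de novo among failing background", {
  set.seed(2)
  n <- 200
  keys <- sprintf("chr%d:%d:A>G", sample(1:22, n, TRUE), sample.int(1e7, n))
  keys <- unique(keys)
  variants <- do.call(rbind, lapply(keys, test_variant))
  ann <- do.call(rbind, lapply(keys, function(k) {
    test_ann(k, gene = k, maf = runif(1, 0.01, 0.5))  # all fail on MAF
  }))
  gt <- do.call(rbind, lapply(keys, function(k) rbind(
    test_gt(k, "P1", 0, 1), test_gt(k, "M1", 0, 1), test_gt(k, "F1", 0, 0))))
  planted <- "chr5:99999999:A>G"
  variants <- rbind(variants, test_variant(planted))
  ann <- rbind(ann, test_ann(planted, gene = "CAUSE", maf = 0))
  gt <- rbind(gt, test_gt(planted, "P1", 0, 1), test_gt(planted, "M1", 0, 0),
              test_gt(planted, "F1", 0, 0))
  fam <- test_family()
  out <- apply_filters(fam, variants, gt, ann)
  expect_identical(out$dominant, planted)
  expect_identical(out$recessive, planted)
  # every excluded variant has a trace row with its triggering value
  failed <- setdiff(keys, planted)
  traced <- unique(out$trace$key[out$trace$decision == "fail"])
  expect_setequal(traced, failed)

  empty <- apply_filters(fam, variants[0, ], gt[0, ], ann)
  expect_length(empty$recessive, 0L)
  expect_length(empty$dominant, 0L)
  expect_length(empty$xlinked, 0L)
})

test_that("apply_filters matches the brute-force oracle variant by variant", {
  for (seed in c(11, 12, 13)) {
    cohort <- random_filter_cohort(400, seed)
    got <- apply_filters(cohort$family, cohort$variants, cohort$genotypes,
                         cohort$annotations)
    want <- oracle_filter_sets(cohort$family, cohort$variants,
                               cohort$genotypes, cohort$annotations,
                               filter_config())
    expect_setequal(got$recessive, want$recessive)
    expect_setequal(got$dominant, want$dominant)
    expect_setequal(got$xlinked, want$xlinked)
  }
})

test_that("tightening thresholds never adds a variant to a surviving set", {
  cohort <- random_filter_cohort(300, 21)
  base_cfg <- filter_config()
  base <- apply_filters(cohort$family, cohort$variants, cohort$genotypes,
                        cohort$annotations, base_cfg)
  set.seed(22)
  for (rep in 1:8) {
    cfg <- filter_config(
      min_depth = base_cfg$min_depth + sample(0:5, 1),
      recessive_maf_max = base_cfg$recessive_maf_max * runif(1),
      recessive_homhemi_max = sample(0:base_cfg$recessive_homhemi_max, 1),
      dominant_maf_max = base_cfg$dominant_maf_max * runif(1),
      dominant_allele_count_max = sample(0:base_cfg$dominant_allele_count_max, 1))
    tight <- apply_filters(cohort$family, cohort$variants, cohort$genotypes,
                           cohort$annotations, cfg)
    expect_true(all(tight$recessive %in% base$recessive))
    expect_true(all(tight$dominant %in% base$dominant))
    expect_true(all(tight$xlinked %in% base$xlinked))
  }
})

test_that("filters are deterministic and unannotated variants are traced", {
  cohort <- random_filter_cohort(100, 31)
  ann <- cohort$annotations[-1, ]  # drop one annotation
  a <- apply_filters(cohort$family, cohort$variants, cohort$genotypes, ann)
  b <- apply_filters(cohort$family, cohort$variants, cohort$genotypes, ann)
  expect_identical(a, b)
  orphan <- cohort$annotations$key[1]
  tr <- a$trace[a$trace$key == orphan, ]
  expect_identical(tr$value, "unannotated")
  expect_false(orphan %in% c(a$recessive, a$dominant, a$xlinked))
})
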