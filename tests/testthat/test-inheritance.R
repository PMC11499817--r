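# De novo detection, recessive/dominant/X-linked candidate generation and
# the stepwise review order.

gt_call <- function(a1, a2 = NA_integer_, missing = FALSE, depth = 30L) {
  list(a1 = as.integer(a1), a2 = as.integer(a2), missing = missing,
       depth = as.integer(depth))
}

test_that("detect_de_novo assigns origins from parental carrier status", {
  p <- gt_call(0, 1)
  expect_identical(detect_de_novo(p, gt_call(0, 0), gt_call(0, 0)), "de_novo")
  expect_identical(detect_de_novo(p, gt_call(0, 1), gt_call(0, 0)), "maternal")
  expect_identical(detect_de_novo(p, gt_call(0, 0), gt_call(0, 1)), "paternal")
  expect_identical(detect_de_novo(gt_call(1, 1), gt_call(0, 1), gt_call(0, 1)),
                   "biparental")
  # missing parent genotype is never de novo
  expect_identical(detect_de_novo(p, gt_call(NA, NA, missing = TRUE),
                                  gt_call(0, 0)), "unknown")
  # low parental depth blocks the de novo assertion (dropout guard)
  expect_identical(detect_de_novo(p, gt_call(0, 0, depth = 1), gt_call(0, 0)),
                   "unknown")
  expect_identical(
    detect_de_novo(p, gt_call(0, 0, depth = 1), gt_call(0, 0),
                   filter_config(require_parent_depth_for_denovo = FALSE)),
    "de_novo")
})

test_that("compound heterozygotes require trans configuration in trios", {
  fam <- test_family()
  k1 <- "chr1:100:A>G"; k2 <- "chr1:200:A>G"
  variants <- rbind(test_variant(k1), test_variant(k2))
  ann <- rbind(test_ann(k1, gene = "TK2"), test_ann(k2, gene = "TK2"))
  gts_trans <- rbind(
    test_gt(k1, "P1", 0, 1), test_gt(k1, "M1", 0, 1), test_gt(k1, "F1", 0, 0),
    test_gt(k2, "P1", 0, 1), test_gt(k2, "M1", 0, 0), test_gt(k2, "F1", 0, 1))
  cands <- candidates_recessive(fam, c(k1, k2), variants, gts_trans, ann)
  expect_equal(nrow(cands), 2L)
  expect_setequal(cands$model, "AR_comphet")
  expect_setequal(cands$origin, c("maternal", "paternal"))
  # pairs are symmetric and never pair a variant with itself
  expect_identical(cands$partner_key, rev(cands$key))
  expect_false(any(cands$partner_key == cands$key))

  # both maternal: cis, no pair
  gts_cis <- rbind(
    test_gt(k1, "P1", 0, 1), test_gt(k1, "M1", 0, 1), test_gt(k1, "F1", 0, 0),
    test_gt(k2, "P1", 0, 1), test_gt(k2, "M1", 0, 1), test_gt(k2, "F1", 0, 0))
  expect_equal(nrow(candidates_recessive(fam, c(k1, k2), variants, gts_cis,
                                         ann)), 0L)

  # solo: unphased pair is emitted and flagged
  solo <- test_family(mother = NA, father = NA)
  gts_solo <- rbind(test_gt(k1, "P1", 0, 1), test_gt(k2, "P1", 0, 1))
  cands <- candidates_recessive(solo, c(k1, k2), variants, gts_solo, ann)
  expect_equal(nrow(cands), 2L)
  expect_setequal(cands$origin, "unknown")
  expect_setequal(cands$note, "unphased")
})

test_that("a parental deletion CNV pairs with a hemizygous point variant in trans", {
  # the apparent homozygote pattern: paternal SNV exposed by a maternal deletion
  fam <- test_family(sex = "female")
  snv <- "chr10:50000000:A>G"
  del <- "chr10:49383876-52383915:DEL"
  variants <- rbind(test_variant(snv),
                    test_variant(del, variant_class = "CNV",
                                 cnv_start = 49383876, cnv_end = 52383915,
                                 cnv_dosage = "DEL"))
  variants$chrom <- "chr10"
  ann <- rbind(test_ann(snv, gene = "ERCC6"),
               test_ann(del, gene = "ERCC6", consequence = "cnv_loss",
                        variant_class = "CNV"))
  gts <- rbind(
    test_gt(snv, "P1", 1, 1), test_gt(snv, "M1", 0, 0), test_gt(snv, "F1", 0, 1),
    test_gt(del, "P1", 1, 0, depth = NA), test_gt(del, "M1", 1, 0, depth = NA),
    test_gt(del, "F1", 0, 0, depth = NA))
  cands <- candidates_recessive(fam, c(snv, del), variants, gts, ann)
  expect_equal(nrow(cands), 2L)
  expect_setequal(cands$model, "AR_comphet")
  expect_identical(cands$zygosity[cands$key == snv], "hem")
  expect_identical(cands$origin[cands$key == snv], "paternal")
  expect_identical(cands$origin[cands$key == del], "maternal")

  # without the deletion, the same pattern is a Mendelian error and excluded
  cands2 <- candidates_recessive(fam, snv, variants, gts, ann)
  expect_equal(nrow(cands2), 0L)
  expect_equal(attr(cands2, "mendel_excluded"), 1L)
})

test_that("dominant candidates label origin and flag unaffected-parent inheritance", {
  k <- "chr17:500:A>G"
  variants <- test_variant(k)
  ann <- test_ann(k, gene = "NOG")
  gts <- rbind(test_gt(k, "P1", 0, 1), test_gt(k, "M1", 0, 0),
               test_gt(k, "F1", 0, 1))
  aff <- test_family(father_affected = TRUE)
  cands <- candidates_dominant(aff, k, variants, gts, ann)
  expect_identical(cands$origin, "paternal")
  expect_identical(cands$note, "")
  unaff <- test_family(father_affected = FALSE)
  cands <- candidates_dominant(unaff, k, variants, gts, ann)
  expect_identical(cands$note, "inherited-from-unaffected")

  # homozygous-alt autosomal genotypes belong to AR, not AD
  gts_hom <- rbind(test_gt(k, "P1", 1, 1), test_gt(k, "M1", 0, 1),
                   test_gt(k, "F1", 0, 1))
  expect_equal(nrow(candidates_dominant(unaff, k, variants, gts_hom, ann)), 0L)
})

test_that("X-linked candidates follow proband sex and zygosity", {
  k <- "chrX:860:A>G"
  variants <- test_variant(k); variants$chrom <- "chrX"
  ann <- test_ann(k, gene = "KDM5C")
  # male hemizygous, carrier mother -> XLR maternal
  male <- test_family(sex = "male")
  gts <- rbind(test_gt(k, "P1", 1), test_gt(k, "M1", 0, 1),
               test_gt(k, "F1", 0))
  cands <- candidates_x_linked(male, k, variants, gts, ann)
  expect_identical(cands$model, "XLR")
  expect_identical(cands$origin, "maternal")
  # male hemizygous, absent in mother (trio-confirmed) -> de novo
  gts_dn <- rbind(test_gt(k, "P1", 1), test_gt(k, "M1", 0, 0),
                  test_gt(k, "F1", 0))
  expect_identical(candidates_x_linked(male, k, variants, gts_dn, ann)$origin,
                   "de_novo")
  # female heterozygous de novo -> XLD
  female <- test_family(sex = "female")
  gts_f <- rbind(test_gt(k, "P1", 0, 1), test_gt(k, "M1", 0, 0),
                 test_gt(k, "F1", 0))
  cands <- candidates_x_linked(female, k, variants, gts_f, ann)
  expect_identical(cands$model, "XLD")
  expect_identical(cands$origin, "de_novo")
  # female homozygous -> XLR
  gts_hom <- rbind(test_gt(k, "P1", 1, 1), test_gt(k, "M1", 0, 1),
                   test_gt(k, "F1", 1))
  expect_identical(candidates_x_linked(female, k, variants, gts_hom,
                                       ann)$model, "XLR")
})

test_that("stepwise review lists AR before AD before XL and dedups across models", {
  fam <- test_family(sex = "male")
  k_ar <- "chr2:100:A>G"; k_ad <- "chr3:100:A>G"; k_x <- "chrX:100:A>G"
  variants <- rbind(test_variant(k_ar), test_variant(k_ad), test_variant(k_x))
  ann <- rbind(test_ann(k_ar, gene = "GA"), test_ann(k_ad, gene = "GB"),
               test_ann(k_x, gene = "GX"))
  gts <- rbind(
    test_gt(k_ar, "P1", 1, 1), test_gt(k_ar, "M1", 0, 1), test_gt(k_ar, "F1", 0, 1),
    test_gt(k_ad, "P1", 0, 1), test_gt(k_ad, "M1", 0, 0), test_gt(k_ad, "F1", 0, 0),
    test_gt(k_x, "P1", 1), test_gt(k_x, "M1", 0, 1), test_gt(k_x, "F1", 0))
  filtered <- apply_filters(fam, variants, gts, ann)
  cands <- run_stepwise(fam, filtered, variants, gts, ann)
  expect_identical(cands$model, c("AR_hom", "AD", "XLR"))
  expect_identical(cands$origin[cands$model == "AD"], "de_novo")
  expect_equal(anyDuplicated(cands$key), 0L)

  # solo strategy never asserts de novo anywhere in the candidate list
  solo <- test_family(mother = NA, father = NA, sex = "male")
  gts_solo <- gts[gts$sample_id == "P1", ]
  filtered <- apply_filters(solo, variants, gts_solo, ann)
  cands <- run_stepwise(solo, filtered, variants, gts_solo, ann)
  expect_false(any(cands$origin == "de_novo"))
})

test_that("trio candidates are Mendelian-consistent unless flagged de novo", {
  sim <- simulate_cohort(simulation_config(
    n_families = 15, strategy_counts = c(trio = 15, duo = 0, solo = 0, ces = 0),
    background_n = 50), seed = 17)
  res <- run_cohort(sim)
  for (rec in res$records) {
    cands <- rec$all_candidates
    if (nrow(cands) == 0L) next
    expect_true(all(cands$origin %in%
                      c("de_novo", "maternal", "paternal", "biparental")))
    for (j in seq_len(nrow(cands))) {
      if (cands$origin[j] == "de_novo") next
      fam <- sim$families[sim$families$proband_id == rec$proband_id, ]
      side <- c(maternal = fam$mother_id, paternal = fam$father_id)
      parents <- switch(cands$origin[j],
                        maternal = side["maternal"],
                        paternal = side["paternal"],
                        biparental = side)
      g <- sim$genotypes[sim$genotypes$key == cands$key[j] &
                           sim$genotypes$sample_id %in% parents, ]
      cg <- rbind(g, if (!is.null(sim$cnv)) {
        cr <- cnv_records(sim$cnv, sim$families)
        cr$genotypes[cr$genotypes$key == cands$key[j] &
                       cr$genotypes$sample_id %in% parents, ]
      })
      expect_true(all(carries_alt(cg$a1, cg$a2, cg$missing)),
                  info = cands$key[j])
    }
  }
})
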