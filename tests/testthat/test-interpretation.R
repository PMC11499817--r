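# Consensus interpretation and clinical result categorization.

mk_cand <- function(gene, class, zygosity = "het", origin = "de_novo",
                    mode = "AD", consistent = TRUE) {
  data.frame(gene = gene, class = class, zygosity = zygosity, origin = origin,
             mode = mode, consistent = consistent, stringsAsFactors = FALSE)
}

test_that("consensus interpretation prefers ClinVar, then the modal resource class", {
  cc <- consensus_class("P", c("VUS", "VUS", "LB"))
  expect_identical(cc$class, "P")
  expect_identical(cc$source, "clinvar")
  cc <- consensus_class(NA, c("LP", "LP", "VUS"))
  expect_identical(cc$class, "LP")
  expect_identical(cc$source, "majority")
  cc <- consensus_class(NA, c("P", "LP", "VUS"))   # three-way tie
  expect_identical(cc$class, "VUS")
  expect_identical(cc$source, "tie_rule")
  cc <- consensus_class(NA, c("B", "B"))
  expect_identical(cc$class, "B")
  expect_error(consensus_class(NA, c(NA, NA)), "unclassifiable")
})

test_that("classification reproduces the category definitions", {
  # de novo het LP in an AD-matched gene -> solved
  r <- classify_result(mk_cand("TCF4", "LP"))
  expect_identical(r$category, "solved")
  # single het VUS in an AR-matched gene -> partially informative
  r <- classify_result(mk_cand("ANK3", "VUS", origin = "de_novo", mode = "AR"))
  expect_identical(r$category, "partially_informative")
  expect_true(r$informative)
  # AR compound heterozygote mixing P and VUS -> suggestive, not solved
  r <- classify_result(rbind(
    mk_cand("TK2", "P", origin = "maternal", mode = "AR"),
    mk_cand("TK2", "VUS", origin = "paternal", mode = "AR")))
  expect_identical(r$category, "suggestive")
  # homozygous P in an AR-matched gene -> solved
  r <- classify_result(mk_cand("ABAT", "P", zygosity = "hom",
                               origin = "biparental", mode = "AR"))
  expect_identical(r$category, "solved")
  expect_identical(r$genes$mode_group, "AR")
  # hemizygous P under XLR -> solved; hemizygous VUS -> suggestive
  expect_identical(classify_result(mk_cand("KDM5C", "P", zygosity = "hem",
                                           origin = "maternal",
                                           mode = "XLR"))$category, "solved")
  expect_identical(classify_result(mk_cand("KDM5C", "VUS", zygosity = "hem",
                                           origin = "maternal",
                                           mode = "XLR"))$category, "suggestive")
  # LB/B candidates are never informative
  r <- classify_result(mk_cand("G1", "LB"))
  expect_identical(r$category, "uninformative")
  expect_false(r$informative)
  # inconsistent gene is uninformative regardless of class
  r <- classify_result(mk_cand("G1", "P", consistent = FALSE))
  expect_identical(r$category, "uninformative")
  # cis-only AR pair stays partially informative (one haplotype)
  r <- classify_result(rbind(
    mk_cand("G1", "P", origin = "maternal", mode = "AR"),
    mk_cand("G1", "P", origin = "maternal", mode = "AR")))
  expect_identical(r$category, "partially_informative")
  # dual-diagnosis pattern: the maximum category over genes wins
  r <- classify_result(rbind(
    mk_cand("G1", "VUS", mode = "AD"),
    mk_cand("G2", "P", mode = "AD")))
  expect_identical(r$category, "solved")
  expect_equal(nrow(r$genes), 2L)
  expect_error(classify_result(data.frame(gene = "G1")), "consistency")
})

test_that("category is total and monotone under class upgrades", {
  rank <- c(uninformative = 0, partially_informative = 1, suggestive = 2,
            solved = 3)
  upgrade <- c(VUS = "LP", LP = "P", P = "P")
  set.seed(6)
  for (rep in 1:40) {
    n <- sample(1:3, 1)
    cand <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_cand("G1",
              class = sample(c("P", "LP", "VUS", "LB"), 1),
              zygosity = sample(c("het", "hom", "hem"), 1),
              origin = sample(c("de_novo", "maternal", "paternal", "unknown"), 1),
              mode = sample(c("AD", "AR", "XLR", "XLD"), 1))
    }))
    cand$mode <- cand$mode[1]  # one matched entry per gene
    before <- classify_result(cand)$category
    expect_true(before %in% names(rank))
    cand2 <- cand
    cand2$class <- ifelse(cand$class %in% names(upgrade),
                          upgrade[cand$class], cand$class)
    after <- classify_result(cand2)$category
    expect_gte(rank[after], rank[before])
  }
})

test_that("the fixture cohort is fully informative with the published solved split", {
  fx <- informative_results(read_informative_table())
  expect_true(all(fx$results$informative))
  expect_equal(sum(fx$results$category == "uninformative"), 0L)
  split <- solved_split(fx$records)
  expect_equal(split$n_solved, 31L)
  expect_equal(split$AD, 23L)
  expect_equal(split$AR, 4L)
  expect_equal(split$XL, 4L)
})
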