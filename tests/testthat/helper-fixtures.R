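# Shared fixture builders and independent oracles used across test files.

# One-row family table.
test_family <- function(proband = "P1", mother = "M1", father = "F1",
                        sex = "male", family_id = "FAM1",
                        mother_affected = FALSE, father_affected = FALSE) {
  data.frame(family_id = family_id, proband_id = proband,
             mother_id = mother, father_id = father, sex = sex,
             strategy = derive_strategy(mother, father),
             mother_affected = mother_affected,
             father_affected = father_affected, stringsAsFactors = FALSE)
}

# Annotation row with benign defaults; override via ...
test_ann <- function(key, gene = "G1", consequence = "missense",
                     transcript = "NM_1.1", cadd = 25, maf = 0, ac = 0,
                     hom_exac = 0, hemi_exac = 0, clinvar_id = NA,
                     clinvar_class = NA, resources = NA,
                     variant_class = "SNV") {
  chrom <- sub(":.*", "", key)
  pos <- suppressWarnings(as.integer(sub("^[^:]+:(\\d+).*", "\\1", key)))
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
             transcript = transcript, consequence = consequence,
             hgvs_c = NA_character_, hgvs_p = NA_character_, cadd = cadd,
             maf_cmg = maf, maf_esp5400 = maf, maf_1000g = maf,
             maf_gnomad = maf, maf_exac = maf, maf_internal = 0,
             ac_gnomad = ac, ac_internal = 0, hom_exac = hom_exac,
             hemi_exac = hemi_exac,
             clinvar_id = as.character(clinvar_id),
             clinvar_class = as.character(clinvar_class),
             class_platform = as.character(resources),
             class_varsome = as.character(resources),
             class_franklin = as.character(resources),
             variant_class = variant_class, key = key,
             stringsAsFactors = FALSE)
}

# Variant row matching a key "chrom:pos:ref>alt" or CNV fields.
test_variant <- function(key, variant_class = "SNV", cnv_start = NA,
                         cnv_end = NA, cnv_dosage = NA, family_id = "FAM1") {
  chrom <- sub(":.*", "", key)
  pos <- suppressWarnings(as.integer(sub("^[^:]+:(\\d+).*", "\\1", key)))
  data.frame(key = key, chrom = chrom, pos = pos, ref = "A", alt = "G",
             variant_class = variant_class,
             cnv_start = as.integer(cnv_start), cnv_end = as.integer(cnv_end),
             cnv_dosage = as.character(cnv_dosage), family_id = family_id,
             stringsAsFactors = FALSE)
}

test_gt <- function(key, sample, a1, a2 = NA_integer_, depth = 30L,
                    missing = FALSE, family_id = "FAM1") {
  data.frame(key = key, sample_id = sample, a1 = as.integer(a1),
             a2 = as.integer(a2), phased = FALSE, depth = as.integer(depth),
             missing = missing, family_id = family_id, stringsAsFactors = FALSE)
}

# Independent brute-force re-implementation of the five stated filter
# rules, evaluated one variant at a time. Deliberately literal and separate
# from the vectorised implementation.
oracle_filter_sets <- function(family, variants, genotypes, annotations,
                               cfg, cohort_index = NULL) {
  recessive <- character(0); dominant <- character(0); xlinked <- character(0)
  pid <- family$proband_id
  for (i in seq_len(nrow(variants))) {
    key <- variants$key[i]
    g <- genotypes[genotypes$key == key & genotypes$sample_id == pid, ]
    if (nrow(g) == 0L || g$missing) next
    alt_carrier <- (!is.na(g$a1) && g$a1 >= 1) || (!is.na(g$a2) && g$a2 >= 1)
    if (!alt_carrier) next
    a <- annotations[annotations$key == key, ]
    if (nrow(a) == 0L) next
    a <- a[1L, ]
    is_cnv <- variants$variant_class[i] == "CNV"
    # rule 1: read support (CNVs exempt)
    if (!is_cnv && (is.na(g$depth) || g$depth < cfg$min_depth)) next
    # rule 2: excluded consequence classes
    if (a$consequence %in% cfg$excluded_consequences) next
    # rule 5: cohort recurrence over unrelated families
    if (!is.null(cohort_index)) {
      fams <- unique(cohort_index$family_id[cohort_index$key == key])
      if (length(fams) > cfg$cohort_recurrence_max) next
    }
    mafs <- c(a$maf_cmg, a$maf_esp5400, a$maf_1000g, a$maf_gnomad,
              a$maf_exac, a$maf_internal)
    mafs[is.na(mafs)] <- 0
    hh <- sum(c(a$hom_exac, a$hemi_exac), na.rm = TRUE)
    # rule 3: recessive thresholds
    rec_ok <- is_cnv ||
      (max(mafs) <= cfg$recessive_maf_max &&
         (!cfg$apply_recessive_homhemi || hh < cfg$recessive_homhemi_max + 1))
    # rule 4: dominant thresholds
    acs <- c(a$ac_gnomad, a$ac_internal)
    acs[is.na(acs)] <- 0
    dom_ok <- is_cnv ||
      (max(mafs) <= cfg$dominant_maf_max &&
         max(acs) <= cfg$dominant_allele_count_max)
    on_x <- sub("^chr", "", variants$chrom[i]) %in% c("X", "23")
    zyg <- zygosity_of(g$a1, g$a2, g$missing)
    if (on_x) {
      ok <- if (zyg %in% c("hem", "hom")) rec_ok else dom_ok
      if (ok) xlinked <- c(xlinked, key)
    } else {
      if (rec_ok) recessive <- c(recessive, key)
      if (dom_ok) dominant <- c(dominant, key)
    }
  }
  list(recessive = recessive, dominant = dominant, xlinked = xlinked)
}

# Brute-force ancestor closure by boolean matrix powering.
oracle_ancestors <- function(ontology) {
  n <- length(ontology$ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ontology$ids, ontology$ids))
  for (id in ontology$ids) {
    for (p in ontology$parents[[id]]) adj[id, p] <- TRUE
  }
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# Random annotated variant set spanning the filter thresholds.
random_filter_cohort <- function(n, seed) {
  set.seed(seed)
  chrom <- sample(c(sprintf("chr%d", 1:22), "chrX"), n, replace = TRUE)
  pos <- sample.int(1e8, n)
  keys <- sprintf("%s:%d:A>G", chrom, pos)
  variants <- do.call(rbind, lapply(keys, test_variant))
  variants$chrom <- chrom; variants$pos <- pos
  ann <- do.call(rbind, lapply(seq_len(n), function(i) {
    test_ann(keys[i],
             gene = sprintf("G%03d", i),
             consequence = sample(consequence_vocabulary()[1:11], 1),
             maf = sample(c(0, 0.0005, 0.001, 0.005, 0.008, 0.02), 1),
             ac = sample(c(0, 3, 5, 6, 20), 1),
             hom_exac = sample(c(0, 4, 9, 10, 12), 1))
  }))
  zyg <- sample(c("het", "hom", "hem"), n, replace = TRUE,
                prob = c(0.6, 0.3, 0.1))
  a1 <- ifelse(zyg == "het", 0L, 1L)
  a2 <- ifelse(zyg == "hem", NA_integer_, 1L)
  depth <- sample(c(0L, 2L, 3L, 10L, 50L), n, replace = TRUE,
                  prob = c(.05, .1, .15, .3, .4))
  genotypes <- data.frame(key = keys, sample_id = "P1", a1 = a1, a2 = a2,
                          phased = FALSE, depth = depth, missing = FALSE,
                          family_id = "FAM1", stringsAsFactors = FALSE)
  fam <- test_family(mother = NA, father = NA, sex = "male")
  list(family = fam, variants = variants, genotypes = genotypes,
       annotations = ann)
}
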