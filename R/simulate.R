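# Synthetic-cohort generator. Produces families, variant tables, CNV calls,
# annotations, phenotype terms and ground truth with the statistical
# structure the pipeline assumes: planted causal variants satisfy the filter
# rules for their inheritance mode, background variants are constructed to
# fail at least one stated rule or to sit in a gene with no disease
# association, and parental genotypes are Mendelian-consistent except at
# planted de novo sites.

#' A miniature phenotype ontology fixture
#'
#' Deterministic ontology with a phenotypic-abnormality root, 12 organ-system
#' branches (depth-1 children of the root) and three leaf terms per branch;
#' one leaf has a second parent in a different branch to exercise DAG
#' fan-out. Real HPO files are drop-in replacements via [read_ontology()].
#'
#' @return An `hpo_ontology` with 49 terms.
#' @export
demo_ontology <- function() {
  root <- "HP:0000118"
  sys_labels <- c("nervous system", "cardiovascular system", "skeletal system",
                  "immune system", "eye", "ear", "growth",
                  "head and neck", "genitourinary system",
                  "digestive system", "integument", "metabolism/homeostasis")
  ids <- root
  labels <- c("Phenotypic abnormality")
  parents <- list()
  parents[[root]] <- character(0)
  for (b in seq_along(sys_labels)) {
    sid <- sprintf("HP:01000%02d", b)
    ids <- c(ids, sid)
    labels <- c(labels, sprintf("Abnormality of the %s", sys_labels[b]))
    parents[[sid]] <- root
    for (k in 1:3) {
      lid <- sprintf("HP:02%02d%03d", b, k)
      ids <- c(ids, lid)
      labels <- c(labels, sprintf("%s finding %d", sys_labels[b], k))
      parents[[lid]] <- sid
    }
  }
  # DAG fan-out: one leaf also belongs to the cardiovascular branch
  parents[["HP:0201003"]] <- c(parents[["HP:0201003"]], "HP:0100002")
  names(labels) <- ids
  build_ontology(ids, labels, parents, root = root, source = "demo")
}

#' A deterministic gene-disease-inheritance map fixture
#'
#' @param n_genes Number of genes (default 50). Genes cycle over autosomal
#'   dominant, autosomal recessive and X-linked modes; X-linked genes are
#'   placed on chrX. Each gene carries the three leaf terms of one ontology
#'   branch.
#' @return List with `map` (the [read_gene_map()]-shaped table) and `loci`
#'   (data frame `gene`, `chrom`, `start` used to place variants).
#' @export
demo_gene_map <- function(n_genes = 50L) {
  idx <- seq_len(n_genes)
  inheritance <- rep("AD", n_genes)
  inheritance[idx > 22 & idx <= 36] <- "AR"
  inheritance[idx > 36 & idx <= 41] <- "XLR"
  inheritance[idx > 41 & idx <= 46] <- "XLD"
  inheritance[idx > 46] <- "AR"
  chrom <- sprintf("chr%d", ((idx - 1L) %% 22L) + 1L)
  chrom[inheritance %in% c("XLR", "XLD")] <- "chrX"
  start <- 5e6 + idx * 3e6
  branch <- ((idx - 1L) %% 12L) + 1L
  hpo <- vapply(branch, function(b) {
    paste(sprintf("HP:02%02d%03d", b, 1:3), collapse = ";")
  }, character(1))
  gene <- sprintf("GENE%02d", idx)
  list(
    map = data.frame(gene = gene, omim_id = as.character(600000L + idx),
                     label = sprintf("Disorder %02d", idx),
                     inheritance = inheritance, hpo_terms = hpo,
                     stringsAsFactors = FALSE),
    loci = data.frame(gene = gene, chrom = chrom, start = start,
                      branch = branch, stringsAsFactors = FALSE))
}

#' Simulation settings for the synthetic cohort
#'
#' Defaults encode the emulated study conditions: a 103-family cohort with
#' 71 trios, 7 duos, 19 exome solos and 6 clinical-exome-only solos; 300
#' background variants surviving annotation per exome; a 0.456 probability
#' of a planted causal variant per proband; a planted-mode mix dominated by
#' dominant de novo variants with recessive, X-linked and CNV causes; a
#' planted-class mix over P/LP/VUS; a 0.473 probability that a planted
#' variant is ClinVar-listed; and a per-proband affected-system count on
#' 2..11 with median 6.
#'
#' @param n_families Number of families.
#' @param strategy_counts Named integer vector (`trio`, `duo`, `solo`,
#'   `ces`); scaled to `n_families` by largest remainder when they do not
#'   already sum to it. The `ces` arm is a proband-only clinical-exome solo.
#' @param background_n Background variants per exome.
#' @param planted_prob Probability that a proband carries a planted cause.
#' @param mode_probs Named probabilities over planted modes
#'   (`AD_denovo`, `AD_inherited`, `AR_hom`, `AR_comphet`, `XLR`, `XLD`,
#'   `CNV`).
#' @param class_probs Named probabilities over planted classes (P, LP, VUS).
#' @param clinvar_prob Probability a planted variant is ClinVar-listed.
#' @param background_mix Named probabilities over background construction
#'   classes: `common_maf` (fails both frequency rules), `excluded_consequence`,
#'   `low_depth`, `rare_unmapped` (passes filters but sits in an unmapped
#'   gene, so it can never be informative).
#' @param system_count_probs Distribution of the per-proband affected-system
#'   count (names `2`..`11`).
#' @param n_genes Genes in the fixture gene map.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 103L,
                              strategy_counts = c(trio = 71L, duo = 7L,
                                                  solo = 19L, ces = 6L),
                              background_n = 300L,
                              planted_prob = 0.456,
                              mode_probs = c(AD_denovo = 0.48,
                                             AD_inherited = 0.08,
                                             AR_hom = 0.12, AR_comphet = 0.08,
                                             XLR = 0.08, XLD = 0.08,
                                             CNV = 0.08),
                              class_probs = c(P = 0.30, LP = 0.30, VUS = 0.40),
                              clinvar_prob = 0.473,
                              background_mix = c(common_maf = 0.35,
                                                 excluded_consequence = 0.40,
                                                 low_depth = 0.10,
                                                 rare_unmapped = 0.15),
                              system_count_probs = c(`2` = 0.05, `3` = 0.08,
                                                     `4` = 0.12, `5` = 0.15,
                                                     `6` = 0.20, `7` = 0.15,
                                                     `8` = 0.10, `9` = 0.07,
                                                     `10` = 0.05, `11` = 0.03),
                              n_genes = 50L) {
  for (p in list(mode_probs, class_probs, background_mix, system_count_probs)) {
    if (abs(sum(p) - 1) > 1e-8) {
      stop("probability vectors must sum to 1", call. = FALSE)
    }
  }
  if (planted_prob < 0 || planted_prob > 1 || clinvar_prob < 0 ||
      clinvar_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_families < 1L || background_n < 0L) {
    stop("n_families must be >= 1 and background_n >= 0", call. = FALSE)
  }
  structure(list(n_families = as.integer(n_families),
                 strategy_counts = strategy_counts,
                 background_n = as.integer(background_n),
                 planted_prob = planted_prob, mode_probs = mode_probs,
                 class_probs = class_probs, clinvar_prob = clinvar_prob,
                 background_mix = background_mix,
                 system_count_probs = system_count_probs,
                 n_genes = as.integer(n_genes)),
            class = "simulation_config")
}

#' @noRd
.allocate_counts <- function(weights, n) {
  if (sum(weights) == n) return(as.integer(weights))
  raw <- weights / sum(weights) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' @noRd
.sample1 <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  sample(x, 1L, prob = prob)
}

#' Simulate a synthetic rare-disease cohort
#'
#' The seed fully determines the output. Planted variants are constructed to
#' survive every filter applicable to their mode; background variants fail
#' at least one stated rule or sit in an unmapped gene. Parental genotypes
#' are Mendelian-consistent at every non-planted site.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return List of class `rudx_sim` with `families`, `probands`, `variants`,
#'   `genotypes`, `annotations`, `cnv`, `phenotypes`, `gene_map`,
#'   `gene_loci`, `ontology`, `truth`, `config`, `seed`. Feed it directly to
#'   [run_cohort()] or write files with [write_cohort()].
#' @export
simulate_cohort <- function(cfg = simulation_config(), seed = 1L) {
  set.seed(seed)
  ont <- demo_ontology()
  gm <- demo_gene_map(cfg$n_genes)
  map <- gm$map; loci <- gm$loci
  systems <- seq_len(12L)
  leaf <- function(b, k) sprintf("HP:02%02d%03d", b, k)

  counts <- .allocate_counts(cfg$strategy_counts, cfg$n_families)
  strategies <- sample(rep(names(cfg$strategy_counts), counts))
  bases <- c("A", "C", "G", "T")
  excl_cons <- c("synonymous", "deep_intronic", "intergenic", "utr5", "utr3")
  good_cons <- c("missense", "nonsense", "frameshift", "splice_site")

  fam_rows <- list(); pro_rows <- list(); var_blocks <- list()
  gt_blocks <- list(); ann_blocks <- list(); cnv_rows <- list()
  phe_rows <- list(); truth_rows <- list()
  clinvar_counter <- 0L

  ann_row <- function(chrom, pos, ref, alt, gene, consequence, cadd,
                      maf = 0, ac = 0, clinvar = FALSE, class = NA) {
    res_class <- if (is.na(class) || clinvar) NA_character_ else class
    data.frame(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      gene = gene, transcript = sprintf("NM_%s.1", gene),
      consequence = consequence, hgvs_c = NA_character_,
      hgvs_p = NA_character_, cadd = cadd,
      maf_cmg = maf, maf_esp5400 = maf, maf_1000g = maf, maf_gnomad = maf,
      maf_exac = maf, maf_internal = 0, ac_gnomad = ac, ac_internal = 0,
      hom_exac = 0, hemi_exac = 0,
      clinvar_id = if (clinvar) {
        clinvar_counter <<- clinvar_counter + 1L
        sprintf("CV%06d", clinvar_counter)
      } else NA_character_,
      clinvar_class = if (clinvar) class else NA_character_,
      class_platform = res_class, class_varsome = res_class,
      class_franklin = res_class, stringsAsFactors = FALSE)
  }

  for (i in seq_len(cfg$n_families)) {
    fid <- sprintf("FAM%04d", i)
    pid <- sprintf("P%04d", i)
    arm <- strategies[i]
    strategy <- if (arm == "ces") "solo" else arm
    mid <- if (strategy == "trio" || (strategy == "duo" && i %% 2L == 0L)) {
      paste0(pid, "_m")
    } else NA_character_
    did <- if (strategy == "trio" || (strategy == "duo" && i %% 2L == 1L)) {
      paste0(pid, "_f")
    } else NA_character_

    planted <- stats::runif(1) < cfg$planted_prob
    mode <- if (planted) {
      .sample1(names(cfg$mode_probs), cfg$mode_probs)
    } else NA_character_
    sex <- if (planted && mode == "XLR") "male" else
      if (planted && mode == "XLD") "female" else
        .sample1(c("male", "female"))

    planted_class <- NA_character_; planted_gene <- NA_character_
    planted_keys <- character(0); mother_affected <- FALSE
    father_affected <- FALSE
    fam_vars <- list(); fam_gts <- list(); fam_anns <- list()

    # genotype emitters -----------------------------------------------------
    gt_line <- function(key, sample, a1, a2, depth = 30L) {
      data.frame(key = key, sample_id = sample, a1 = a1, a2 = a2,
                 phased = FALSE, depth = as.integer(depth), missing = FALSE,
                 family_id = fid, stringsAsFactors = FALSE)
    }
    add_snv <- function(chrom, pos, ref, alt, gts, ann) {
      key <- sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
      fam_vars[[length(fam_vars) + 1L]] <<- data.frame(
        key = key, chrom = chrom, pos = as.integer(pos), ref = ref,
        alt = alt, variant_class = ifelse(nchar(ref) == 1L & nchar(alt) == 1L,
                                          "SNV", "INDEL"),
        cnv_start = NA_integer_, cnv_end = NA_integer_,
        cnv_dosage = NA_character_, family_id = fid, stringsAsFactors = FALSE)
      for (g in gts) fam_gts[[length(fam_gts) + 1L]] <<- g(key)
      ann$chrom <- chrom; ann$pos <- as.integer(pos)
      ann$ref <- ref; ann$alt <- alt
      ann$key <- key
      fam_anns[[length(fam_anns) + 1L]] <<- ann
      key
    }
    # diploid autosomal genotypes by carrier pattern
    gt_pattern <- function(p_a, m_a = NULL, f_a = NULL, depths = 30L) {
      gts <- list(function(key) gt_line(key, pid, p_a[1L], p_a[2L], depths))
      if (!is.na(mid) && !is.null(m_a)) {
        gts <- c(gts, function(key) gt_line(key, mid, m_a[1L], m_a[2L], depths))
      }
      if (!is.na(did) && !is.null(f_a)) {
        gts <- c(gts, function(key) gt_line(key, did, f_a[1L], f_a[2L], depths))
      }
      gts
    }

    # ---- planted cause -----------------------------------------------------
    if (planted) {
      planted_class <- .sample1(names(cfg$class_probs), cfg$class_probs)
      in_clinvar <- stats::runif(1) < cfg$clinvar_prob
      pick_gene <- function(modes) {
        cand <- loci$gene[map$inheritance %in% modes]
        .sample1(cand)
      }
      if (mode %in% c("AD_denovo", "AD_inherited", "CNV")) {
        planted_gene <- pick_gene("AD")
      } else if (mode %in% c("AR_hom", "AR_comphet")) {
        planted_gene <- pick_gene("AR")
      } else {
        planted_gene <- pick_gene(mode)
      }
      gl <- loci[loci$gene == planted_gene, , drop = FALSE]
      base_pos <- gl$start + 2e5 + i  # unique per family: no cohort recurrence
      cons <- .sample1(good_cons)
      cadd <- stats::runif(1, 25, 35)
      mk_ann <- function(pos, cons2 = cons) {
        ann_row(gl$chrom, pos, "A", "G", planted_gene, cons2, cadd,
                clinvar = in_clinvar, class = planted_class)
      }
      if (mode == "AD_denovo") {
        planted_keys <- add_snv(gl$chrom, base_pos, "A", "G",
                                gt_pattern(c(0L, 1L), c(0L, 0L), c(0L, 0L)),
                                mk_ann(base_pos))
      } else if (mode == "AD_inherited") {
        from_mother <- if (!is.na(mid) && !is.na(did)) i %% 2L == 0L else !is.na(mid)
        m_a <- if (from_mother) c(0L, 1L) else c(0L, 0L)
        f_a <- if (from_mother) c(0L, 0L) else c(0L, 1L)
        if (from_mother && !is.na(mid)) mother_affected <- TRUE
        if (!from_mother && !is.na(did)) father_affected <- TRUE
        planted_keys <- add_snv(gl$chrom, base_pos, "A", "G",
                                gt_pattern(c(0L, 1L), m_a, f_a),
                                mk_ann(base_pos))
      } else if (mode == "AR_hom") {
        planted_keys <- add_snv(gl$chrom, base_pos, "A", "G",
                                gt_pattern(c(1L, 1L), c(0L, 1L), c(0L, 1L)),
                                mk_ann(base_pos))
      } else if (mode == "AR_comphet") {
        k1 <- add_snv(gl$chrom, base_pos, "A", "G",
                      gt_pattern(c(0L, 1L), c(0L, 1L), c(0L, 0L)),
                      mk_ann(base_pos))
        k2 <- add_snv(gl$chrom, base_pos + 5000L, "C", "T",
                      gt_pattern(c(0L, 1L), c(0L, 0L), c(0L, 1L)),
                      mk_ann(base_pos + 5000L))
        planted_keys <- c(k1, k2)
      } else if (mode == "XLR") {
        # male proband hemizygous, carrier mother, hemizygous-reference father
        gts <- list(function(key) gt_line(key, pid, 1L, NA_integer_))
        if (!is.na(mid)) gts <- c(gts, function(key) gt_line(key, mid, 0L, 1L))
        if (!is.na(did)) gts <- c(gts, function(key) gt_line(key, did, 0L, NA_integer_))
        planted_keys <- add_snv(gl$chrom, base_pos, "A", "G", gts,
                                mk_ann(base_pos))
      } else if (mode == "XLD") {
        gts <- list(function(key) gt_line(key, pid, 0L, 1L))
        if (!is.na(mid)) gts <- c(gts, function(key) gt_line(key, mid, 0L, 0L))
        if (!is.na(did)) gts <- c(gts, function(key) gt_line(key, did, 0L, NA_integer_))
        planted_keys <- add_snv(gl$chrom, base_pos, "A", "G", gts,
                                mk_ann(base_pos))
      } else if (mode == "CNV") {
        res_class <- if (in_clinvar) NA_character_ else planted_class
        cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
          family_id = fid, chrom = gl$chrom, cnv_start = gl$start,
          cnv_end = gl$start + 2e5 + i, cnv_dosage = .sample1(c("DEL", "DUP")),
          genes = planted_gene, carriers = pid,
          clinvar_id = if (in_clinvar) {
            clinvar_counter <- clinvar_counter + 1L
            sprintf("CV%06d", clinvar_counter)
          } else NA_character_,
          clinvar_class = if (in_clinvar) planted_class else NA_character_,
          class_platform = res_class, class_varsome = res_class,
          class_franklin = res_class, stringsAsFactors = FALSE)
        cnv_rows[[length(cnv_rows)]]$variant_class <- "CNV"
        cnv_rows[[length(cnv_rows)]]$pos <- cnv_rows[[length(cnv_rows)]]$cnv_start
        cnv_rows[[length(cnv_rows)]]$ref <- NA_character_
        cnv_rows[[length(cnv_rows)]]$alt <- NA_character_
        cnv_rows[[length(cnv_rows)]]$key <- variant_key(cnv_rows[[length(cnv_rows)]])
        planted_keys <- cnv_rows[[length(cnv_rows)]]$key
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        proband_id = pid, keys = paste(planted_keys, collapse = ";"),
        mode = mode, class = planted_class, gene = planted_gene,
        expected_category = if (planted_class %in% c("P", "LP")) "solved"
        else "suggestive", stringsAsFactors = FALSE)
    }

    # ---- background variants ----------------------------------------------
    nb <- cfg$background_n
    if (nb > 0L) {
      cls <- sample(names(cfg$background_mix), nb, replace = TRUE,
                    prob = cfg$background_mix)
      chrom <- sprintf("chr%d", sample(1:22, nb, replace = TRUE))
      pos <- sample.int(2e8, nb)
      ref <- sample(bases, nb, replace = TRUE)
      alt <- vapply(ref, function(r) .sample1(setdiff(bases, r)), character(1))
      cons <- ifelse(cls == "excluded_consequence",
                     sample(excl_cons, nb, replace = TRUE), "missense")
      maf <- ifelse(cls == "common_maf", stats::runif(nb, 0.01, 0.5),
                    stats::runif(nb, 0, 0.005))
      depth <- ifelse(cls == "low_depth", sample(0:2, nb, replace = TRUE), 30L)
      gene <- ifelse(cls == "rare_unmapped",
                     sprintf("BG%04d_%d", sample.int(9999L, nb, replace = TRUE), i),
                     sprintf("BGC%04d_%d", sample.int(9999L, nb, replace = TRUE), i))
      key <- sprintf("%s:%d:%s>%s", chrom, pos, ref, alt)
      keep <- !duplicated(key)
      fam_vars[[length(fam_vars) + 1L]] <- data.frame(
        key = key[keep], chrom = chrom[keep], pos = pos[keep],
        ref = ref[keep], alt = alt[keep], variant_class = "SNV",
        cnv_start = NA_integer_, cnv_end = NA_integer_,
        cnv_dosage = NA_character_, family_id = fid, stringsAsFactors = FALSE)
      # proband het; in trios one parent transmits (Mendelian-consistent)
      n2 <- sum(keep)
      from_mother <- sample(c(TRUE, FALSE), n2, replace = TRUE)
      gt_block <- data.frame(
        key = key[keep], sample_id = pid, a1 = 0L, a2 = 1L, phased = FALSE,
        depth = as.integer(depth[keep]), missing = FALSE, family_id = fid,
        stringsAsFactors = FALSE)
      if (!is.na(mid)) {
        gt_block <- rbind(gt_block, data.frame(
          key = key[keep], sample_id = mid, a1 = 0L,
          a2 = ifelse(from_mother, 1L, 0L), phased = FALSE, depth = 30L,
          missing = FALSE, family_id = fid, stringsAsFactors = FALSE))
      }
      if (!is.na(did)) {
        gt_block <- rbind(gt_block, data.frame(
          key = key[keep], sample_id = did, a1 = 0L,
          a2 = ifelse(from_mother & !is.na(mid), 0L, 1L), phased = FALSE,
          depth = 30L, missing = FALSE, family_id = fid,
          stringsAsFactors = FALSE))
      }
      fam_gts[[length(fam_gts) + 1L]] <- gt_block
      bg_ann <- data.frame(
        chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
        alt = alt[keep], gene = gene[keep],
        transcript = sprintf("NM_%s.1", gene[keep]), consequence = cons[keep],
        hgvs_c = NA_character_, hgvs_p = NA_character_,
        cadd = stats::runif(n2, 0, 20),
        maf_cmg = maf[keep], maf_esp5400 = maf[keep], maf_1000g = maf[keep],
        maf_gnomad = maf[keep], maf_exac = maf[keep], maf_internal = 0,
        ac_gnomad = 0, ac_internal = 0, hom_exac = 0, hemi_exac = 0,
        clinvar_id = NA_character_, clinvar_class = NA_character_,
        class_platform = NA_character_, class_varsome = NA_character_,
        class_franklin = NA_character_, key = key[keep],
        stringsAsFactors = FALSE)
      fam_anns[[length(fam_anns) + 1L]] <- bg_ann
    }

    # ---- phenotype terms ---------------------------------------------------
    n_sys <- as.integer(.sample1(names(cfg$system_count_probs),
                                 cfg$system_count_probs))
    if (planted) {
      gb <- loci$branch[loci$gene == planted_gene]
      gene_terms <- sample(sprintf("HP:02%02d%03d", gb, 1:3), 2L)
      other <- sample(setdiff(systems, gb), n_sys - 1L)
      terms <- c(gene_terms, vapply(other, function(b) leaf(b, sample.int(3L, 1L)),
                                    character(1)))
    } else {
      chosen <- sample(systems, n_sys)
      terms <- vapply(chosen, function(b) leaf(b, sample.int(3L, 1L)),
                      character(1))
    }
    phe_rows[[length(phe_rows) + 1L]] <- data.frame(
      proband_id = pid, hpo_id = unique(terms), stringsAsFactors = FALSE)

    fam_rows[[i]] <- data.frame(
      family_id = fid, proband_id = pid, mother_id = mid, father_id = did,
      sex = sex, strategy = strategy, mother_affected = mother_affected,
      father_affected = father_affected, stringsAsFactors = FALSE)
    pro_rows[[i]] <- data.frame(
      proband_id = pid, family_id = fid, sex = sex,
      age = round(stats::rbeta(1, 1.2, 5) * 52, 1),
      care = .sample1(c("public", "private"), c(0.72, 0.28)),
      capital = stats::runif(1) < 0.85,
      congenital = stats::runif(1) < 0.75,
      neurological = stats::runif(1) < 0.70,
      immune = stats::runif(1) < 0.20,
      strategy = strategy, arm = if (arm == "ces") "CES" else "ES",
      stringsAsFactors = FALSE)
    if (length(fam_vars)) {
      var_blocks[[length(var_blocks) + 1L]] <- do.call(rbind, fam_vars)
    }
    if (length(fam_gts)) {
      gt_blocks[[length(gt_blocks) + 1L]] <- do.call(rbind, fam_gts)
    }
    if (length(fam_anns)) {
      ann_blocks[[length(ann_blocks) + 1L]] <- do.call(rbind, fam_anns)
    }
  }

  annotations <- do.call(rbind, ann_blocks)
  annotations$variant_class <- ifelse(
    nchar(annotations$ref) == 1L & nchar(annotations$alt) == 1L, "SNV", "INDEL")
  annotations$.row <- seq_len(nrow(annotations))
  structure(
    list(families = do.call(rbind, fam_rows),
         probands = do.call(rbind, pro_rows),
         variants = do.call(rbind, var_blocks),
         genotypes = do.call(rbind, gt_blocks),
         annotations = annotations,
         cnv = if (length(cnv_rows)) do.call(rbind, cnv_rows) else NULL,
         phenotypes = do.call(rbind, phe_rows),
         gene_map = map, gene_loci = loci, ontology = ont,
         truth = if (length(truth_rows)) do.call(rbind, truth_rows) else
           data.frame(proband_id = character(0), keys = character(0),
                      mode = character(0), class = character(0),
                      gene = character(0), expected_category = character(0)),
         config = cfg, seed = seed),
    class = "rudx_sim")
}

#' Write a simulated cohort as the pipeline's external file formats
#'
#' Emits one multi-sample VCF per family, a cohort PED, the annotation TSV,
#' the CNV TSV, the phenotype TSV, the gene-map TSV, the ontology OBO, a
#' proband covariate TSV and the truth TSV. Every file round-trips through
#' the package readers.
#'
#' @param sim A `rudx_sim` from [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ped_rows <- list()
  for (i in seq_len(nrow(sim$families))) {
    fam <- sim$families[i, , drop = FALSE]
    samples <- stats::na.omit(c(fam$proband_id, fam$mother_id, fam$father_id))
    fv <- sim$variants[sim$variants$family_id == fam$family_id, , drop = FALSE]
    fg <- sim$genotypes[sim$genotypes$family_id == fam$family_id, , drop = FALSE]
    write_vcf(fv, fg, samples, file.path(outdir, paste0(fam$family_id, ".vcf")))
    sexcode <- if (fam$sex == "male") "1" else "2"
    ped_rows[[length(ped_rows) + 1L]] <- c(
      fam$family_id, fam$proband_id,
      ifelse(is.na(fam$father_id), "0", fam$father_id),
      ifelse(is.na(fam$mother_id), "0", fam$mother_id), sexcode, "2")
    if (!is.na(fam$mother_id)) {
      ped_rows[[length(ped_rows) + 1L]] <- c(
        fam$family_id, fam$mother_id, "0", "0", "2",
        if (fam$mother_affected) "2" else "1")
    }
    if (!is.na(fam$father_id)) {
      ped_rows[[length(ped_rows) + 1L]] <- c(
        fam$family_id, fam$father_id, "0", "0", "1",
        if (fam$father_affected) "2" else "1")
    }
  }
  ped <- do.call(rbind, ped_rows)
  utils::write.table(ped, file.path(outdir, "cohort.ped"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ann <- sim$annotations
  ann$.row <- NULL; ann$variant_class <- NULL; ann$key <- NULL
  utils::write.table(ann, file.path(outdir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(sim$cnv)) {
    cnv <- sim$cnv[, c("family_id", "chrom", "cnv_start", "cnv_end",
                       "cnv_dosage", "genes", "carriers", "clinvar_id",
                       "clinvar_class", "class_platform", "class_varsome",
                       "class_franklin")]
    names(cnv)[3:5] <- c("start", "end", "dosage")
    utils::write.table(cnv, file.path(outdir, "cnv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  utils::write.table(sim$phenotypes, file.path(outdir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$gene_map, file.path(outdir, "gene_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$probands, file.path(outdir, "probands.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_obo(sim$ontology, file.path(outdir, "ontology.obo"))
  invisible(outdir)
}

#' Read a written cohort directory back into a pipeline bundle
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A bundle list compatible with [run_cohort()].
#' @export
read_cohort_dir <- function(dir) {
  families <- read_pedigree(file.path(dir, "cohort.ped"))
  ontology <- read_ontology(file.path(dir, "ontology.obo"))
  var_blocks <- list(); gt_blocks <- list()
  for (i in seq_len(nrow(families))) {
    fid <- families$family_id[i]
    vcf <- read_vcf(file.path(dir, paste0(fid, ".vcf")))
    vcf$variants$family_id <- fid
    vcf$genotypes$family_id <- fid
    var_blocks[[i]] <- vcf$variants
    gt_blocks[[i]] <- vcf$genotypes
  }
  cnv_path <- file.path(dir, "cnv.tsv")
  list(families = families,
       variants = do.call(rbind, var_blocks),
       genotypes = do.call(rbind, gt_blocks),
       annotations = read_annotations(file.path(dir, "annotations.tsv")),
       cnv = if (file.exists(cnv_path)) read_cnv(cnv_path) else NULL,
       phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv"), ontology),
       gene_map = read_gene_map(file.path(dir, "gene_map.tsv")),
       probands = utils::read.delim(file.path(dir, "probands.tsv"),
                                    stringsAsFactors = FALSE),
       truth = utils::read.delim(file.path(dir, "truth.tsv"),
                                 stringsAsFactors = FALSE),
       ontology = ontology)
}

#' Compare pipeline results against the generator's ground truth
#'
#' @param results A `rudx_results` from [run_cohort()].
#' @param truth Truth table from a `rudx_sim`.
#' @return List with `recall` (fraction of planted probands whose planted
#'   variant keys all appear among their candidates), `by_mode` (per-mode
#'   recall data frame), `category_agreement` (fraction of planted probands
#'   whose category equals the expected one) and `confusion`
#'   (expected x observed category table).
#' @export
evaluate_against_truth <- function(results, truth) {
  if (!all(truth$proband_id %in% results$results$proband_id)) {
    stop("truth records reference probands absent from the results",
         call. = FALSE)
  }
  if (nrow(truth) == 0L) {
    return(list(recall = NA_real_, by_mode = NULL,
                category_agreement = NA_real_, confusion = NULL))
  }
  hit <- logical(nrow(truth)); obs_cat <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    rec <- results$records[[truth$proband_id[i]]]
    keys <- strsplit(truth$keys[i], ";", fixed = TRUE)[[1L]]
    hit[i] <- all(keys %in% rec$all_candidates$key)
    obs_cat[i] <- rec$category
  }
  by_mode <- stats::aggregate(hit, by = list(mode = truth$mode),
                              FUN = function(x) mean(x))
  names(by_mode)[2L] <- "recall"
  by_mode$n <- as.integer(table(truth$mode)[by_mode$mode])
  list(recall = mean(hit), by_mode = by_mode,
       category_agreement = mean(obs_cat == truth$expected_category),
       confusion = table(expected = truth$expected_category,
                         observed = obs_cat))
}
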