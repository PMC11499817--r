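# Stepwise candidate generation under the autosomal recessive (homozygous +
# compound heterozygous), autosomal dominant and X-linked models, with trio
# de novo detection, degraded gracefully for duos and solos. A de novo call
# additionally requires parental read depth at the site, guarding against
# allele dropout mimicking de novo.

#' @noRd
.as_gt <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "genotype_call")) {
    a <- x$alleles
    return(list(a1 = if (length(a) >= 1L) a[1L] else NA_integer_,
                a2 = if (length(a) >= 2L) a[2L] else NA_integer_,
                missing = x$missing, depth = x$depth))
  }
  list(a1 = x$a1, a2 = x$a2, missing = isTRUE(x$missing), depth = x$depth)
}

#' @noRd
.gt_carries <- function(g) {
  !is.null(g) && !g$missing && carries_alt(g$a1, g$a2, g$missing)
}

#' Parental origin of a proband allele in a trio
#'
#' A variant is de novo when the proband carries an alternate allele absent
#' from both parental genotypes; otherwise the origin is assigned by which
#' parent(s) carry the allele. A missing parental genotype (or, when
#' `cfg$require_parent_depth_for_denovo` is set, a parental depth below
#' `cfg$min_depth`) yields `"unknown"`, never `"de_novo"`.
#'
#' @param proband,mother,father Genotype calls (from [parse_genotype()]) or
#'   lists with `a1`, `a2`, `missing`, `depth`.
#' @param cfg A [filter_config()].
#' @param is_cnv CNV records carry no read-depth semantics, so the parental
#'   depth guard is skipped for them.
#' @return One of `"de_novo"`, `"maternal"`, `"paternal"`, `"biparental"`,
#'   `"unknown"`.
#' @export
detect_de_novo <- function(proband, mother, father, cfg = filter_config(),
                           is_cnv = FALSE) {
  p <- .as_gt(proband); m <- .as_gt(mother); f <- .as_gt(father)
  if (is.null(p) || p$missing || !.gt_carries(p)) {
    stop("detect_de_novo() requires a proband genotype carrying an alternate allele",
         call. = FALSE)
  }
  if (is.null(m) || is.null(f) || m$missing || f$missing) return("unknown")
  mc <- .gt_carries(m); fc <- .gt_carries(f)
  if (mc && fc) return("biparental")
  if (mc) return("maternal")
  if (fc) return("paternal")
  if (!is_cnv && cfg$require_parent_depth_for_denovo) {
    ok <- !is.na(m$depth) && m$depth >= cfg$min_depth &&
      !is.na(f$depth) && f$depth >= cfg$min_depth
    if (!ok) return("unknown")
  }
  "de_novo"
}

#' @noRd
.geno_of <- function(genotypes, key, sample) {
  if (is.na(sample)) return(NULL)
  i <- which(genotypes$key == key & genotypes$sample_id == sample)
  if (length(i) == 0L) return(NULL)
  as.list(genotypes[i[1L], c("a1", "a2", "missing", "depth")])
}

# Origin assignment that degrades with the family strategy: duos label a
# variant absent from the single available parent as unknown (never de
# novo); solos are always unknown.
#' @noRd
.assign_origin <- function(family, key, genotypes, cfg, is_cnv = FALSE) {
  p <- .geno_of(genotypes, key, family$proband_id)
  if (family$strategy == "solo") return(list(origin = "unknown", note = ""))
  m <- .geno_of(genotypes, key, family$mother_id)
  f <- .geno_of(genotypes, key, family$father_id)
  if (family$strategy == "trio") {
    if (is.null(m) || is.null(f) || m$missing || f$missing) {
      return(list(origin = "unknown", note = "parental genotype missing"))
    }
    return(list(origin = detect_de_novo(p, m, f, cfg, is_cnv), note = ""))
  }
  # duo
  avail <- if (!is.na(family$mother_id)) m else f
  side <- if (!is.na(family$mother_id)) "maternal" else "paternal"
  if (is.null(avail) || avail$missing) {
    return(list(origin = "unknown", note = "parental genotype missing"))
  }
  if (.gt_carries(avail)) return(list(origin = side, note = ""))
  list(origin = "unknown", note = "absent in available parent")
}

#' @noRd
.new_candidates <- function() {
  data.frame(key = character(0), gene = character(0), model = character(0),
             origin = character(0), zygosity = character(0),
             partner_key = character(0), note = character(0),
             stringsAsFactors = FALSE)
}

#' @noRd
.cand_row <- function(key, gene, model, origin, zygosity,
                      partner_key = NA_character_, note = "") {
  data.frame(key = key, gene = gene, model = model, origin = origin,
             zygosity = zygosity, partner_key = partner_key, note = note,
             stringsAsFactors = FALSE)
}

#' Recessive-model candidates: homozygotes and compound heterozygotes
#'
#' Homozygous-alternate proband genotypes become `AR_hom` candidates. Two
#' distinct heterozygous variants in one gene form an `AR_comphet` pair when
#' their parental origins establish a trans configuration (one maternal, one
#' paternal) in trios; in duos and solos same-gene pairs are emitted
#' unphased with a note. A heterozygous deletion CNV from one parent that
#' spans a gene pairs with a variant of that gene from the other parent (the
#' proband is effectively hemizygous); the same pattern rescues an apparent
#' homozygote whose second allele is a deletion. Mendelian-error homozygotes
#' (a confidently genotyped non-carrier parent, no deletion rescue) are
#' excluded and counted in the `mendel_excluded` attribute.
#'
#' @param family One-row family data frame.
#' @param keys Recessive-eligible variant keys from [apply_filters()].
#' @param variants,genotypes Variant/genotype tables.
#' @param annotations One annotation row per key ([select_annotation()]).
#' @param cfg A [filter_config()].
#' @return Candidate data frame (`key`, `gene`, `model`, `origin`,
#'   `zygosity`, `partner_key`, `note`).
#' @export
candidates_recessive <- function(family, keys, variants, genotypes,
                                 annotations, cfg = filter_config()) {
  out <- list(); mendel_excluded <- 0L
  if (length(keys) == 0L) {
    res <- .new_candidates(); attr(res, "mendel_excluded") <- 0L
    return(res)
  }
  vv <- variants[match(keys, variants$key), , drop = FALSE]
  ann <- annotations[match(keys, annotations$key), , drop = FALSE]
  pg <- genotypes[genotypes$sample_id == family$proband_id &
                    genotypes$key %in% keys, , drop = FALSE]
  pg <- pg[match(keys, pg$key), , drop = FALSE]
  zyg <- zygosity_of(pg$a1, pg$a2, pg$missing)
  is_cnv <- vv$variant_class == "CNV"
  is_del <- is_cnv & vv$cnv_dosage == "DEL"
  trio <- family$strategy == "trio"

  # --- homozygous (or autosomal hemizygous-by-deletion) candidates -------
  for (j in which(zyg %in% c("hom", "hem") & !is_cnv)) {
    key <- keys[j]; gene <- ann$gene[j]
    m <- .geno_of(genotypes, key, family$mother_id)
    f <- .geno_of(genotypes, key, family$father_id)
    mc <- .gt_carries(m); fc <- .gt_carries(f)
    if (trio && !is.null(m) && !is.null(f) && !m$missing && !f$missing &&
        xor(mc, fc)) {
      # one parent confidently lacks the allele: deletion rescue or Mendel error
      noncarrier_side <- if (mc) "paternal" else "maternal"
      carrier_side <- if (mc) "maternal" else "paternal"
      noncarrier_id <- if (mc) family$father_id else family$mother_id
      rescue <- NA_character_
      for (k in which(is_del)) {
        if (vv$chrom[k] == vv$chrom[j] &&
            vv$pos[j] >= vv$cnv_start[k] && vv$pos[j] <= vv$cnv_end[k]) {
          cg <- .geno_of(genotypes, keys[k], noncarrier_id)
          pgk <- .geno_of(genotypes, keys[k], family$proband_id)
          if (.gt_carries(cg) && .gt_carries(pgk)) { rescue <- keys[k]; break }
        }
      }
      if (!is.na(rescue)) {
        out[[length(out) + 1L]] <- .cand_row(
          key, gene, "AR_comphet", carrier_side, "hem", rescue,
          "hemizygous-by-deletion")
        out[[length(out) + 1L]] <- .cand_row(
          rescue, gene, "AR_comphet", noncarrier_side, "het", key,
          "deletion partner")
      } else {
        mendel_excluded <- mendel_excluded + 1L
      }
      next
    }
    orig <- .assign_origin(family, key, genotypes, cfg)
    origin <- if (trio && mc && fc) "biparental" else orig$origin
    out[[length(out) + 1L]] <- .cand_row(key, gene, "AR_hom", origin,
                                         zyg[j], note = orig$note)
  }

  # --- compound heterozygotes --------------------------------------------
  het_idx <- which(zyg == "het" & !is_cnv)
  del_idx <- which(is_del & zyg %in% c("het", "hem"))
  items <- list()
  for (j in het_idx) {
    orig <- .assign_origin(family, keys[j], genotypes, cfg)
    items[[length(items) + 1L]] <- list(key = keys[j], gene = ann$gene[j],
                                        origin = orig$origin, zygosity = "het",
                                        pos = vv$pos[j], chrom = vv$chrom[j])
  }
  if (length(items)) {
    genes <- unique(vapply(items, `[[`, character(1), "gene"))
    for (g in genes) {
      gi <- items[vapply(items, function(x) identical(x$gene, g), logical(1))]
      # deletion CNVs spanning any of this gene's variants join the gene group
      for (k in del_idx) {
        span_hit <- any(vapply(gi, function(x) {
          x$chrom == vv$chrom[k] && x$pos >= vv$cnv_start[k] &&
            x$pos <= vv$cnv_end[k]
        }, logical(1)))
        if (span_hit) {
          orig <- .assign_origin(family, keys[k], genotypes, cfg, is_cnv = TRUE)
          gi[[length(gi) + 1L]] <- list(key = keys[k], gene = g,
                                        origin = orig$origin,
                                        zygosity = zyg[k],
                                        pos = vv$pos[k], chrom = vv$chrom[k])
        }
      }
      if (length(gi) < 2L) next
      origins <- vapply(gi, `[[`, character(1), "origin")
      trans_ok <- function(o1, o2) {
        if (trio) {
          a <- o1 %in% c("maternal", "paternal", "biparental") &&
            o2 %in% c("maternal", "paternal", "biparental")
          a && !(o1 == "maternal" && o2 == "maternal") &&
            !(o1 == "paternal" && o2 == "paternal")
        } else {
          # unphased: only a known-cis pair (same single parent) is excluded
          !(o1 %in% c("maternal", "paternal") && identical(o1, o2))
        }
      }
      partner <- rep(NA_character_, length(gi))
      for (x in seq_along(gi)) {
        for (y in seq_along(gi)) {
          if (x == y) next
          if (trans_ok(origins[x], origins[y])) { partner[x] <- gi[[y]]$key; break }
        }
      }
      for (x in which(!is.na(partner))) {
        out[[length(out) + 1L]] <- .cand_row(
          gi[[x]]$key, g, "AR_comphet", origins[x], gi[[x]]$zygosity,
          partner[x], if (trio) "" else "unphased")
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .new_candidates()
  res <- res[!duplicated(res[, c("key", "model")]), , drop = FALSE]
  attr(res, "mendel_excluded") <- mendel_excluded
  res
}

#' Dominant-model candidates
#'
#' Heterozygous proband variants on autosomes. In trios the parental origin
#' is labelled; a variant inherited from an unaffected parent is retained
#' but flagged for review.
#'
#' @inheritParams candidates_recessive
#' @param keys Dominant-eligible variant keys.
#' @return Candidate data frame.
#' @export
candidates_dominant <- function(family, keys, variants, genotypes,
                                annotations, cfg = filter_config()) {
  if (length(keys) == 0L) return(.new_candidates())
  ann <- annotations[match(keys, annotations$key), , drop = FALSE]
  vv <- variants[match(keys, variants$key), , drop = FALSE]
  pg <- genotypes[genotypes$sample_id == family$proband_id &
                    genotypes$key %in% keys, , drop = FALSE]
  pg <- pg[match(keys, pg$key), , drop = FALSE]
  zyg <- zygosity_of(pg$a1, pg$a2, pg$missing)
  out <- list()
  for (j in which(zyg == "het")) {
    orig <- .assign_origin(family, keys[j], genotypes, cfg,
                           is_cnv = vv$variant_class[j] == "CNV")
    note <- orig$note
    if (orig$origin == "maternal" && isFALSE(family$mother_affected)) {
      note <- "inherited-from-unaffected"
    }
    if (orig$origin == "paternal" && isFALSE(family$father_affected)) {
      note <- "inherited-from-unaffected"
    }
    out[[length(out) + 1L]] <- .cand_row(keys[j], ann$gene[j], "AD",
                                         orig$origin, "het", note = note)
  }
  if (length(out)) do.call(rbind, out) else .new_candidates()
}

#' X-linked candidates
#'
#' Male hemizygous variants become XLR candidates (maternal when the mother
#' carries the allele, de novo when a trio confirms its absence); female
#' heterozygous variants become XLD candidates and female homozygotes XLR.
#'
#' @inheritParams candidates_recessive
#' @param keys X-eligible variant keys.
#' @return Candidate data frame.
#' @export
candidates_x_linked <- function(family, keys, variants, genotypes,
                                annotations, cfg = filter_config()) {
  if (length(keys) == 0L) return(.new_candidates())
  if (!family$sex %in% c("male", "female")) {
    stop("proband sex is required for X-linked analysis", call. = FALSE)
  }
  ann <- annotations[match(keys, annotations$key), , drop = FALSE]
  vv <- variants[match(keys, variants$key), , drop = FALSE]
  pg <- genotypes[genotypes$sample_id == family$proband_id &
                    genotypes$key %in% keys, , drop = FALSE]
  pg <- pg[match(keys, pg$key), , drop = FALSE]
  zyg <- zygosity_of(pg$a1, pg$a2, pg$missing)
  out <- list()
  for (j in seq_along(keys)) {
    key <- keys[j]; gene <- ann$gene[j]
    is_cnv <- vv$variant_class[j] == "CNV"
    if (family$sex == "male") {
      if (!zyg[j] %in% c("hem", "hom")) next
      m <- .geno_of(genotypes, key, family$mother_id)
      if (.gt_carries(m)) {
        origin <- "maternal"
      } else if (family$strategy == "trio" && !is.null(m) && !m$missing &&
                 (is_cnv || !cfg$require_parent_depth_for_denovo ||
                  (!is.na(m$depth) && m$depth >= cfg$min_depth))) {
        origin <- "de_novo"
      } else {
        origin <- "unknown"
      }
      out[[length(out) + 1L]] <- .cand_row(key, gene, "XLR", origin, "hem")
    } else {
      if (zyg[j] == "het") {
        orig <- .assign_origin(family, key, genotypes, cfg, is_cnv)
        out[[length(out) + 1L]] <- .cand_row(key, gene, "XLD", orig$origin,
                                             "het", note = orig$note)
      } else if (zyg[j] == "hom") {
        orig <- .assign_origin(family, key, genotypes, cfg, is_cnv)
        out[[length(out) + 1L]] <- .cand_row(key, gene, "XLR", orig$origin,
                                             "hom", note = orig$note)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else .new_candidates()
}

#' Stepwise candidate generation: AR, then AD, then XL
#'
#' Candidates are concatenated in the stated review order (autosomal
#' recessive first, then autosomal dominant, then X-linked), with de novo
#' occurrences flagged by their `origin`. A variant eligible under two
#' models is kept under the first model in the order, with the alternative
#' recorded in `alt_model`. Within each model block candidates are ranked by
#' CADD descending (absent CADD last), ties broken by (chrom, pos); CADD is
#' never a hard filter.
#'
#' @param family One-row family data frame.
#' @param filtered Output of [apply_filters()].
#' @param variants,genotypes Variant/genotype tables.
#' @param annotations Full annotation table (representative transcript is
#'   selected internally).
#' @param cfg A [filter_config()].
#' @return Candidate data frame with annotation columns merged in.
#' @export
run_stepwise <- function(family, filtered, variants, genotypes, annotations,
                         cfg = filter_config()) {
  ann <- select_annotation(annotations)
  ar <- candidates_recessive(family, filtered$recessive, variants, genotypes,
                             ann, cfg)
  ad <- candidates_dominant(family, filtered$dominant, variants, genotypes,
                            ann, cfg)
  xl <- candidates_x_linked(family, filtered$xlinked, variants, genotypes,
                            ann, cfg)
  rank_block <- function(b) {
    if (nrow(b) == 0L) return(b)
    a <- ann[match(b$key, ann$key), , drop = FALSE]
    v <- variants[match(b$key, variants$key), , drop = FALSE]
    cadd <- ifelse(is.na(a$cadd), -Inf, a$cadd)
    b[order(-cadd, v$chrom, v$pos), , drop = FALSE]
  }
  blocks <- list(rank_block(ar), rank_block(ad), rank_block(xl))
  cands <- do.call(rbind, blocks)
  if (nrow(cands) == 0L) {
    cands$alt_model <- character(0)
  } else {
    dup <- duplicated(cands$key)
    alt <- stats::setNames(rep(NA_character_, length(unique(cands$key))),
                           unique(cands$key))
    for (k in cands$key[dup]) alt[k] <- cands$model[dup & cands$key == k][1L]
    cands <- cands[!dup, , drop = FALSE]
    cands$alt_model <- unname(alt[cands$key])
  }
  if (family$strategy == "solo" && any(cands$origin == "de_novo")) {
    stop("internal error: de novo origin asserted in a solo family")
  }
  a <- ann[match(cands$key, ann$key), , drop = FALSE]
  v <- variants[match(cands$key, variants$key), , drop = FALSE]
  cands$consequence <- a$consequence
  cands$cadd <- a$cadd
  cands$hgvs_c <- a$hgvs_c
  cands$clinvar_id <- a$clinvar_id
  cands$clinvar_class <- a$clinvar_class
  cands$class_platform <- a$class_platform
  cands$class_varsome <- a$class_varsome
  cands$class_franklin <- a$class_franklin
  cands$variant_class <- v$variant_class
  cands$chrom <- v$chrom
  cands$pos <- v$pos
  rownames(cands) <- NULL
  cands
}
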