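## Trio, cross-platform and long-read consistency procedures.

# genotype of one sample at one locus as a sorted integer vector (may be
# length 0 = not genotyped)
calls_at <- function(calls, sample, locus) {
  sort(calls$cgl[calls$sample == sample & calls$locus == locus])
}

is_het <- function(g) length(unique(g)) == 2L

# can the child multiset be split into one allele from each parent?
autosomal_consistent <- function(child, mother, father) {
  if (length(child) == 1L)  # lenient single-allele rule
    return(child %in% c(mother, father))
  for (i in seq_along(child)) {
    a <- child[i]; b <- child[-i]
    if ((a %in% mother && b %in% father) ||
        (a %in% father && b %in% mother)) return(TRUE)
  }
  FALSE
}

#' Mendelian consistency of a trio's genotype calls
#'
#' An autosomal locus is consistent when the child's genotype can be
#' explained as one allele present in the mother plus one present in the
#' father. For a male child, the X allele must appear among the mother's
#' X alleles and the Y allele among the father's. Stringency tiers
#' restrict which loci are evaluated: `parents_het` requires both parents
#' heterozygous, `all_het` the whole trio, `all_het_distinct` additionally
#' requires the three genotypes to be pairwise different — tiers designed
#' to avoid trivially consistent configurations. Loci lacking a genotype
#' in a required member are unevaluated and excluded from the denominator.
#'
#' @param calls data.frame of calls (`sample`, `locus`, `cgl`) covering
#'   the trio.
#' @param mother,father,child Sample ids.
#' @param child_sex `"M"` or `"F"`.
#' @param loci Locus table with `locus` and `chrom`.
#' @param tier One of `"all"`, `"parents_het"`, `"all_het"`,
#'   `"all_het_distinct"`.
#' @return List: `per_locus` (data.frame `locus`, `status` in
#'   consistent/inconsistent/unevaluated), `summary` (counts and
#'   `consistent_pct` over evaluated loci), `tier`.
#' @export
mendelian_check <- function(calls, mother, father, child, child_sex,
                            loci,
                            tier = c("all", "parents_het", "all_het",
                                     "all_het_distinct")) {
  tier <- match.arg(tier)
  stopifnot(child_sex %in% c("M", "F"))
  ctype <- setNames(chrom_type(loci$chrom), loci$locus)
  ids <- sort(unique(loci$locus))
  status <- character(length(ids))
  cm <- calls[calls$sample == mother, ]
  cf <- calls[calls$sample == father, ]
  cc <- calls[calls$sample == child, ]
  gm_l <- split(cm$cgl, cm$locus)
  gf_l <- split(cf$cgl, cf$locus)
  gc_l <- split(cc$cgl, cc$locus)
  get0i <- function(lst, k) { v <- lst[[k]]; if (is.null(v)) integer(0)
                              else sort(v) }
  for (i in seq_along(ids)) {
    l <- ids[i]
    k <- as.character(l)
    ct <- ctype[[k]]
    gm <- get0i(gm_l, k)
    gf <- get0i(gf_l, k)
    gc <- get0i(gc_l, k)
    if (ct == "Y" && child_sex == "F") { status[i] <- "unevaluated"; next }
    if (ct == "X" && child_sex == "M") {
      if (!length(gc) || !length(gm)) { status[i] <- "unevaluated"; next }
      status[i] <- if (all(gc %in% gm)) "consistent" else "inconsistent"
      next
    }
    if (ct == "Y") {  # male child
      if (!length(gc) || !length(gf)) { status[i] <- "unevaluated"; next }
      status[i] <- if (all(gc %in% gf)) "consistent" else "inconsistent"
      next
    }
    # autosome (and female-child X, which follows the autosomal rule
    # with the father contributing his single X allele)
    if (!length(gc) || !length(gm) || !length(gf)) {
      status[i] <- "unevaluated"; next
    }
    keep <- switch(tier,
      all = TRUE,
      parents_het = is_het(gm) && is_het(gf),
      all_het = is_het(gm) && is_het(gf) && is_het(gc),
      all_het_distinct = is_het(gm) && is_het(gf) && is_het(gc) &&
        !identical(gm, gf) && !identical(gm, gc) && !identical(gf, gc))
    if (!keep) { status[i] <- "unevaluated"; next }
    status[i] <- if (autosomal_consistent(gc, gm, gf)) "consistent"
                 else "inconsistent"
  }
  per_locus <- data.frame(locus = ids, status = status,
                          stringsAsFactors = FALSE)
  n_c <- sum(status == "consistent")
  n_i <- sum(status == "inconsistent")
  n_u <- sum(status == "unevaluated")
  list(per_locus = per_locus,
       summary = data.frame(
         consistent = n_c, inconsistent = n_i, unevaluated = n_u,
         consistent_pct = if (n_c + n_i > 0) 100 * n_c / (n_c + n_i)
                          else NA_real_),
       tier = tier)
}

#' Non-reference allele consistency between two platforms
#'
#' Jaccard-style agreement between two call sets for the same individual
#' sequenced at different read lengths. Loci are restricted to those
#' genotyped in both sets and VNTR (non-reference) in at least one. Over
#' the non-reference alleles only, alleles are kept only when they lie
#' within the detectable CGL range at the shorter read length (alleles
#' only the longer reads could see are excluded from both sets); the
#' statistic is |intersection| / |union|.
#'
#' @param calls_a,calls_b data.frames of calls (`sample` column ignored;
#'   single sample assumed).
#' @param read_length_a,read_length_b Read lengths of the two sets.
#' @param loci Locus table with `locus`, `pattern_length`, `ref_copies`.
#' @param min_copies Detection floor (default 1.9).
#' @return List: `ratio` (`NA` when the union is empty), `n_intersection`,
#'   `n_union`, `n_loci` evaluated.
#' @export
platform_consistency <- function(calls_a, calls_b, read_length_a,
                                 read_length_b, loci, min_copies = 1.9) {
  shorter <- min(read_length_a, read_length_b)
  common <- intersect(unique(calls_a$locus), unique(calls_b$locus))
  has_nonref <- function(calls, l) any(calls$cgl[calls$locus == l] != 0L)
  vntr <- common[vapply(common, function(l)
    has_nonref(calls_a, l) || has_nonref(calls_b, l), logical(1))]
  allele_set <- function(calls) {
    x <- calls[calls$locus %in% vntr & calls$cgl != 0L, ]
    if (!nrow(x)) return(character(0))
    pl <- loci$pattern_length[match(x$locus, loci$locus)]
    rc <- loci$ref_copies[match(x$locus, loci$locus)]
    keep <- cgl_detectable(x$cgl, pl, rc, shorter, min_copies)
    unique(paste(x$locus[keep], x$cgl[keep]))
  }
  sa <- allele_set(calls_a)
  sb <- allele_set(calls_b)
  u <- union(sa, sb)
  i <- intersect(sa, sb)
  list(ratio = if (length(u)) length(i) / length(u) else NA_real_,
       n_intersection = length(i), n_union = length(u),
       n_loci = length(vntr))
}

#' Validate predicted alleles against long-read copy numbers
#'
#' For each predicted allele, the allele copy number (reference copies +
#' CGL) is compared with wraparound-alignment copy counts measured on
#' long reads assigned to the locus. The allele is validated when at
#' least one read's copy number lies within `tolerance` of the
#' prediction. Loci without covering long reads are unevaluated.
#'
#' @param calls data.frame of predicted calls (`locus`, `cgl`).
#' @param long_reads Named list: locus id -> character vector of long
#'   read sequences spanning the locus.
#' @param ref A `vntr_reference` (or any locus table wrapper with
#'   `pattern`, `ref_copies`).
#' @param tolerance Copy tolerance (default 0.25).
#' @param scoring [scoring_scheme()].
#' @return List: `per_allele` (data.frame `locus`, `cgl`,
#'   `predicted_copies`, `best_read_copies`, `validated`, `evaluated`),
#'   `allele_rate` (fraction of evaluated alleles validated),
#'   `locus_rate` (fraction of evaluated loci with all alleles
#'   validated).
#' @export
longread_validate <- function(calls, long_reads, ref, tolerance = 0.25,
                              scoring = scoring_scheme()) {
  loci <- ref$loci
  rows <- list()
  copies_cache <- list()
  for (i in seq_len(nrow(calls))) {
    l <- calls$locus[i]
    li <- loci[loci$locus == l, ]
    pred <- li$ref_copies + calls$cgl[i]
    key <- as.character(l)
    reads <- long_reads[[key]]
    if (is.null(reads) || !length(reads)) {
      rows[[i]] <- data.frame(locus = l, cgl = calls$cgl[i],
                              predicted_copies = pred,
                              best_read_copies = NA_real_,
                              validated = NA, evaluated = FALSE)
      next
    }
    if (is.null(copies_cache[[key]])) {
      copies_cache[[key]] <- vapply(reads, function(r)
        wraparound_align(r, li$pattern, scoring)$copies, numeric(1),
        USE.NAMES = FALSE)
    }
    rc <- copies_cache[[key]]
    diff <- abs(rc - pred)
    best <- rc[which.min(diff)]
    rows[[i]] <- data.frame(locus = l, cgl = calls$cgl[i],
                            predicted_copies = pred,
                            best_read_copies = best,
                            validated = min(diff) <= tolerance + 1e-9,
                            evaluated = TRUE)
  }
  per_allele <- do.call(rbind, rows)
  rownames(per_allele) <- NULL
  ev <- per_allele[per_allele$evaluated, ]
  allele_rate <- if (nrow(ev)) mean(ev$validated) else NA_real_
  locus_ok <- tapply(ev$validated, ev$locus, all)
  locus_rate <- if (length(locus_ok)) mean(locus_ok) else NA_real_
  list(per_allele = per_allele, allele_rate = allele_rate,
       locus_rate = locus_rate)
}
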