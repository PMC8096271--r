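## Cohort-level summaries over multi-filtered genotypes.

#' Classify VNTR loci as common, private or intermediate
#'
#' A locus is *common* when samples carrying a non-reference allele number
#' at least `ceiling(common_frac * n)` and *private* when they number at
#' most `floor(private_frac * n)` (but at least one). For n = 2504 the
#' ceiling/floor conventions give the familiar thresholds of 126 and 25
#' samples. Only VNTR-flagged loci are classified.
#'
#' @param cohort A [vntr_cohort()] (multi-filtered).
#' @param common_frac,private_frac Fractions in (0,1), defaults 0.05 and
#'   0.01.
#' @return data.frame `locus`, `carriers`, `label` (common / private /
#'   intermediate) over VNTR loci.
#' @export
classify_common_private <- function(cohort, common_frac = 0.05,
                                    private_frac = 0.01) {
  stopifnot(inherits(cohort, "vntr_cohort"))
  if (common_frac <= 0 || common_frac >= 1 ||
      private_frac <= 0 || private_frac >= 1)
    stop("fractions must lie in (0,1)")
  n <- nrow(cohort$samples)
  if (n < 1L) stop("cohort has no samples")
  calls <- cohort$calls
  nonref <- calls[calls$cgl != 0L, ]
  carriers <- tapply(nonref$sample, nonref$locus,
                     function(s) length(unique(s)))
  vntr <- classify_vntr_loci(cohort)
  vloci <- vntr$locus[vntr$is_vntr]
  cnt <- as.integer(carriers[as.character(vloci)])
  cnt[is.na(cnt)] <- 0L
  hi <- as.integer(ceiling(common_frac * n))
  lo <- as.integer(floor(private_frac * n))
  label <- ifelse(cnt >= hi, "common",
                  ifelse(cnt >= 1L & cnt <= lo, "private", "intermediate"))
  data.frame(locus = vloci, carriers = cnt, label = label,
             stringsAsFactors = FALSE)
}

#' Per-sample heterozygous VNTR percentage
#'
#' For each sample: 100 x (loci with two distinct called alleles) /
#' (denominator loci). The default denominator is the sample's own VNTR
#' loci — loci where the sample carries at least one non-reference allele
#' — a carrier-restricted proxy for heterozygosity appropriate when
#' allele discovery is read-length limited. `"genotyped"` uses all loci
#' the sample was genotyped at.
#'
#' @param cohort A [vntr_cohort()].
#' @param denominator `"vntr"` (default) or `"genotyped"`.
#' @return data.frame `sample`, `het_loci`, `denom_loci`, `het_pct`
#'   (`NA` when the denominator is zero).
#' @export
heterozygosity_fraction <- function(cohort,
                                    denominator = c("vntr", "genotyped")) {
  stopifnot(inherits(cohort, "vntr_cohort"))
  denominator <- match.arg(denominator)
  calls <- cohort$calls
  by_sample <- split(calls, calls$sample)
  out <- lapply(cohort$samples$sample, function(s) {
    cs <- by_sample[[s]]
    if (is.null(cs)) cs <- calls[0, ]
    n_alleles <- tapply(cs$cgl, cs$locus, function(x) length(unique(x)))
    has_nonref <- tapply(cs$cgl, cs$locus, function(x) any(x != 0L))
    het <- n_alleles == 2L
    denom <- if (denominator == "vntr") has_nonref else rep(TRUE,
                                                            length(het))
    het_n <- sum(het & denom)
    denom_n <- sum(denom)
    data.frame(sample = s, het_loci = het_n, denom_loci = denom_n,
               het_pct = if (denom_n > 0) 100 * het_n / denom_n else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Copies-gained/lost spectrum of a cohort
#'
#' Counts every non-reference allele occurrence (per sample, per locus)
#' by its CGL value and totals losses and gains.
#'
#' @param cohort A [vntr_cohort()].
#' @return List: `histogram` (data.frame `cgl`, `count`), `losses`,
#'   `gains`, `ratio` (losses/gains, 1 decimal; `NA` when there are no
#'   gains).
#' @export
copy_spectrum <- function(cohort) {
  stopifnot(inherits(cohort, "vntr_cohort"))
  cgl <- cohort$calls$cgl[cohort$calls$cgl != 0L]
  hist <- as.data.frame(table(cgl = cgl), stringsAsFactors = FALSE)
  if (nrow(hist)) {
    hist$cgl <- as.integer(hist$cgl)
    names(hist)[2] <- "count"
  } else hist <- data.frame(cgl = integer(0), count = integer(0))
  losses <- sum(cgl < 0L)
  gains <- sum(cgl > 0L)
  ratio <- if (gains > 0) round(losses / gains, 1) else NA_real_
  list(histogram = hist, losses = losses, gains = gains, ratio = ratio)
}

#' Fractions of loci where copy gains/losses are observable
#'
#' Gain fraction: share of loci where an allele with one extra copy still
#' fits within a read (array plus 10 bp flanks). Loss fraction: share of
#' loci whose reference copy number is at least `min_copies + 1`, so the
#' allele remaining after losing one copy stays above the repeat-finder
#' detection floor (with the default floor of 1.8 copies the reference
#' needs 2.8 copies).
#'
#' @param loci Locus table with `pattern_length` and `ref_copies`.
#' @param read_length Read length (bp).
#' @param min_copies Detection floor in pattern copies (default 1.8).
#' @param min_flank Minimum flank per side (default 10 bp).
#' @return List `gain_frac`, `loss_frac`.
#' @export
detectable_fractions <- function(loci, read_length, min_copies = 1.8,
                                 min_flank = 10) {
  gain <- is_genotypable(loci$pattern_length * (loci$ref_copies + 1),
                         read_length, min_flank)
  loss <- loci$ref_copies >= min_copies + 1 - 1e-9
  list(gain_frac = mean(gain), loss_frac = mean(loss))
}

#' Compare tumor and normal genotypes from one individual
#'
#' Reports per-tissue heterozygous VNTR percentages, somatic alleles
#' (present in the tumor, absent in the normal), loss-of-heterozygosity
#' events (heterozygous in normal, single-allele in tumor) and loci with
#' apparent loss of both alleles (genotyped in normal, absent in tumor).
#'
#' @param normal,tumor [vntr_cohort()]s for the two tissues (one sample
#'   each, same locus universe).
#' @return List `het_normal`, `het_tumor` (percentages), `somatic`
#'   (data.frame `locus`, `cgl`), `loh` (locus vector), `both_loss`
#'   (locus vector).
#' @export
compare_tumor_normal <- function(normal, tumor) {
  stopifnot(inherits(normal, "vntr_cohort"), inherits(tumor, "vntr_cohort"))
  hn <- heterozygosity_fraction(normal)$het_pct[1]
  ht <- heterozygosity_fraction(tumor)$het_pct[1]
  nc <- normal$calls; tc <- tumor$calls
  nk <- paste(nc$locus, nc$cgl); tk <- paste(tc$locus, tc$cgl)
  somatic <- tc[!(tk %in% nk), c("locus", "cgl")]
  rownames(somatic) <- NULL
  n_allele_n <- tapply(nc$cgl, nc$locus, function(x) length(unique(x)))
  n_allele_t <- tapply(tc$cgl, tc$locus, function(x) length(unique(x)))
  het_n <- as.integer(names(n_allele_n)[n_allele_n == 2L])
  single_t <- as.integer(names(n_allele_t)[n_allele_t == 1L])
  loh <- intersect(het_n, single_t)
  both_loss <- setdiff(unique(nc$locus), unique(tc$locus))
  list(het_normal = hn, het_tumor = ht, somatic = somatic,
       loh = loh, both_loss = sort(both_loss))
}

#' Overlap loci with annotation feature intervals
#'
#' Flags, for each locus, whether it overlaps each feature class by at
#' least one base. All intervals are 0-based half-open on a shared
#' coordinate system; inputs need not be sorted.
#'
#' @param loci data.frame `locus`, `chrom`, `start`, `end`.
#' @param features Named list of data.frames (`chrom`, `start`, `end`),
#'   one per feature class.
#' @return data.frame: `locus` plus one logical column per feature class.
#' @export
overlap_annotations <- function(loci, features) {
  stopifnot(is.list(features), !is.null(names(features)))
  to_gr <- function(df) {
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$start + 1L,
                                            end = df$end))
  }
  lg <- to_gr(loci)
  out <- data.frame(locus = loci$locus)
  for (cls in names(features)) {
    fg <- to_gr(features[[cls]])
    hits <- GenomicRanges::countOverlaps(lg, fg, minoverlap = 1L)
    out[[cls]] <- hits > 0L
  }
  out
}
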