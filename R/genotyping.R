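## Per-sample allele calling: read observations -> CGL calls with support.

#' Cohort of per-sample allele calls
#'
#' Container tying together per-allele calls (long format), sample
#' metadata and the locus table. All cohort-level statistics operate on
#' this class.
#'
#' @param calls data.frame `sample`, `locus`, `cgl` (integer copies
#'   gained/lost), `sp` (supporting reads).
#' @param samples data.frame `sample`, `sex` and optional `population`,
#'   `read_length`, `coverage`.
#' @param loci Locus table (as in a `vntr_reference`): needs `locus`,
#'   `chrom`, `pattern_length`, `ref_copies`; `start`, `end`, `pattern`
#'   are carried when present.
#' @return A `vntr_cohort`.
#' @export
vntr_cohort <- function(calls, samples, loci) {
  stopifnot(all(c("sample", "locus", "cgl", "sp") %in% names(calls)),
            all(c("sample", "sex") %in% names(samples)),
            all(c("locus", "chrom", "pattern_length", "ref_copies") %in%
                  names(loci)))
  if (!all(calls$sample %in% samples$sample))
    stop("calls reference samples missing from the metadata")
  if (!all(calls$locus %in% loci$locus))
    stop("calls reference loci missing from the locus table")
  structure(list(calls = calls, samples = samples, loci = loci),
            class = "vntr_cohort")
}

#' @export
print.vntr_cohort <- function(x, ...) {
  cat(sprintf("vntr_cohort: %d samples, %d loci, %d allele calls\n",
              nrow(x$samples), nrow(x$loci), nrow(x$calls)))
  invisible(x)
}

#' Extract per-read repeat copy observations for reference loci
#'
#' Desk-scale read-to-locus matching: for each locus the last bases of its
#' left flank and the first bases of its right flank act as anchor probes.
#' A read (either strand) containing both probes in order yields the
#' sequence between them as the tandem array; its copy number is measured
#' by wraparound alignment against the locus pattern. Flank context beyond
#' the probe is verified up to 50 bp at the identity threshold, so reads
#' from near-identical dispersed families are rejected.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector.
#' @param ref A `vntr_reference`.
#' @param probe_len Anchor probe length (bp).
#' @param max_mismatch Mismatches tolerated in each probe match.
#' @param min_flank,max_flank Flank verification window (bp).
#' @param min_identity Minimum flank identity.
#' @param min_copies Minimum pattern copies for an observation.
#' @param scoring [scoring_scheme()] for the wraparound alignment.
#' @return data.frame `locus`, `read`, `copies` (fractional).
#' @export
extract_read_observations <- function(reads, ref, probe_len = 12L,
                                      max_mismatch = 0L, min_flank = 10L,
                                      max_flank = 50L, min_identity = 0.9,
                                      min_copies = 1.9,
                                      scoring = scoring_scheme()) {
  if (!methods::is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads)) && length(reads))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  loci <- ref$loci
  out <- list()
  strands <- list(fwd = reads,
                  rev = if (length(reads))
                    Biostrings::reverseComplement(reads)
                  else reads)
  for (i in seq_len(nrow(loci))) {
    li <- loci[i, ]
    pl <- substring(li$flank_left, nchar(li$flank_left) - probe_len + 1L)
    pr <- substring(li$flank_right, 1L, probe_len)
    for (st in names(strands)) {
      rs <- strands[[st]]
      if (!length(rs)) next
      hits_l <- Biostrings::vmatchPattern(pl, rs,
                                          max.mismatch = max_mismatch)
      idx <- which(lengths(hits_l) > 0)
      for (r in idx) {
        rseq <- as.character(rs[[r]])
        ml <- hits_l[[r]]
        mr <- Biostrings::matchPattern(pr, rs[[r]],
                                       max.mismatch = max_mismatch)
        if (!length(mr)) next
        # earliest left anchor, then first right anchor after it
        e <- min(IRanges::end(ml))
        starts_r <- IRanges::start(mr)
        starts_r <- starts_r[starts_r > e]
        if (!length(starts_r)) next
        s <- min(starts_r)
        # verify extended flank context (up to max_flank where available)
        avail_l <- e - probe_len            # read bases left of the probe
        nl <- min(avail_l + probe_len, nchar(li$flank_left), max_flank)
        read_fl <- substring(rseq, e - nl + 1L, e)
        lref <- substring(li$flank_left, nchar(li$flank_left) - nl + 1L)
        if (nl < min_flank || string_identity(read_fl, lref) < min_identity)
          next
        avail_r <- nchar(rseq) - (s - 1L) - probe_len + 1L
        nr <- min(probe_len + max(avail_r, 0L), nchar(li$flank_right),
                  nchar(rseq) - s + 1L, max_flank)
        read_fr <- substring(rseq, s, s + nr - 1L)
        rref <- substring(li$flank_right, 1L, nr)
        if (nr < min_flank || string_identity(read_fr, rref) < min_identity)
          next
        seg <- substring(rseq, e + 1L, s - 1L)
        if (!nzchar(seg)) next
        aln <- wraparound_align(seg, li$pattern, scoring)
        cp <- aln$copies
        if (cp < min_copies) next
        out[[length(out) + 1L]] <- data.frame(
          locus = li$locus, read = names(rs)[r], copies = cp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(locus = integer(0), read = character(0),
                      copies = numeric(0)))
  res <- do.call(rbind, out)
  # one observation per (read, locus); a read claimed by several loci is
  # ambiguous (indistinguishable families) and dropped entirely
  res <- res[!duplicated(paste(res$read, res$locus)), ]
  n_loci_per_read <- ave(res$locus, res$read,
                         FUN = function(x) length(unique(x)))
  res <- res[n_loci_per_read == 1, ]
  rownames(res) <- NULL
  res
}

#' Encode observed copies as copies gained/lost (CGL)
#'
#' `CGL = observed_copies - round(ref_copies)` (halves rounded away from
#' zero); [decode_cgl()] is the exact inverse.
#'
#' @param observed_copies Integer observed copy number(s).
#' @param ref_copies Reference copy number (possibly fractional).
#' @return Integer CGL.
#' @export
#' @examples
#' encode_cgl(3, 2)  # +1
#' encode_cgl(2, 7)  # -5
encode_cgl <- function(observed_copies, ref_copies) {
  as.integer(observed_copies - rnd_half_up(ref_copies))
}

#' @rdname encode_cgl
#' @param cgl Integer CGL value(s).
#' @export
decode_cgl <- function(cgl, ref_copies) {
  as.integer(cgl + rnd_half_up(ref_copies))
}

#' Call alleles from per-read copy observations
#'
#' Rounds each read's fractional copy number to the nearest integer and
#' emits one allele per copy value supported by at least `min_support`
#' reads. A locus with no supported allele is omitted (not genotyped,
#' which is distinct from a reference genotype).
#'
#' @param obs data.frame `locus`, `copies` (from
#'   [extract_read_observations()]).
#' @param loci Locus table with `locus` and `ref_copies`.
#' @param min_support Minimum supporting reads per allele (default 2).
#' @return data.frame `locus`, `cgl`, `sp`.
#' @export
call_genotypes <- function(obs, loci, min_support = 2L) {
  if (!nrow(obs))
    return(data.frame(locus = integer(0), cgl = integer(0),
                      sp = integer(0)))
  obs$int_copies <- as.integer(rnd_half_up(obs$copies))
  agg <- stats::aggregate(list(sp = obs$int_copies),
                          by = list(locus = obs$locus,
                                    copies = obs$int_copies),
                          FUN = length)
  agg <- agg[agg$sp >= min_support, ]
  rc <- loci$ref_copies[match(agg$locus, loci$locus)]
  out <- data.frame(locus = agg$locus,
                    cgl = encode_cgl(agg$copies, rc),
                    sp = as.integer(agg$sp))
  out <- out[order(out$locus, out$cgl), ]
  rownames(out) <- NULL
  out
}

#' Genotype one sample from reads
#'
#' Convenience wrapper: [extract_read_observations()] then
#' [call_genotypes()], tagging calls with the sample id.
#'
#' @param reads Reads for one sample.
#' @param ref A `vntr_reference`.
#' @param sample Sample id recorded in the calls.
#' @param min_support Minimum supporting reads per allele.
#' @param ... Passed to [extract_read_observations()].
#' @return data.frame `sample`, `locus`, `cgl`, `sp`.
#' @export
genotype_sample <- function(reads, ref, sample, min_support = 2L, ...) {
  obs <- extract_read_observations(reads, ref, ...)
  calls <- call_genotypes(obs, ref$loci, min_support)
  if (nrow(calls)) cbind(sample = sample, calls, stringsAsFactors = FALSE)
  else data.frame(sample = character(0), locus = integer(0),
                  cgl = integer(0), sp = integer(0))
}

expected_allele_count <- function(chrom, sex) {
  ct <- chrom_type(chrom)
  ifelse(ct == "A", 2L,
         ifelse(ct == "X", ifelse(sex == "M", 1L, 2L),
                ifelse(sex == "M", 1L, 0L)))
}

#' Remove per-sample loci with too many alleles ("multis")
#'
#' A per-sample locus call with more distinct alleles than the expected
#' number of chromosome copies (2 on autosomes; 2/1 on X for
#' females/males; 0/1 on Y) indicates an artifact or segmental
#' duplication and is removed, per sample, and reported.
#'
#' @param cohort A [vntr_cohort()].
#' @return List: `cohort` (filtered) and `multis` (data.frame `sample`,
#'   `locus`, `n_alleles`, `expected`).
#' @export
filter_multis <- function(cohort) {
  stopifnot(inherits(cohort, "vntr_cohort"))
  calls <- cohort$calls
  if (!nrow(calls))
    return(list(cohort = cohort,
                multis = data.frame(sample = character(0),
                                    locus = integer(0),
                                    n_alleles = integer(0),
                                    expected = integer(0))))
  chrom <- cohort$loci$chrom[match(calls$locus, cohort$loci$locus)]
  sex <- cohort$samples$sex[match(calls$sample, cohort$samples$sample)]
  key <- paste(calls$sample, calls$locus)
  n_alleles <- ave(calls$cgl, key, FUN = length)
  expected <- expected_allele_count(chrom, sex)
  bad <- n_alleles > expected
  multis <- unique(data.frame(sample = calls$sample[bad],
                              locus = calls$locus[bad],
                              n_alleles = as.integer(n_alleles[bad]),
                              expected = as.integer(expected[bad]),
                              stringsAsFactors = FALSE))
  rownames(multis) <- NULL
  cohort$calls <- calls[!bad, ]
  rownames(cohort$calls) <- NULL
  list(cohort = cohort, multis = multis)
}

#' Flag VNTR loci in a multi-filtered cohort
#'
#' A TR locus is a VNTR if any remaining allele different from the
#' reference (CGL != 0) is observed in any sample. Adding samples can
#' only add flags, never remove them.
#'
#' @param cohort A [vntr_cohort()] (already multi-filtered).
#' @return data.frame `locus`, `is_vntr` for every locus in the cohort's
#'   locus table.
#' @export
classify_vntr_loci <- function(cohort) {
  stopifnot(inherits(cohort, "vntr_cohort"))
  vntr <- unique(cohort$calls$locus[cohort$calls$cgl != 0L])
  data.frame(locus = cohort$loci$locus,
             is_vntr = cohort$loci$locus %in% vntr)
}
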