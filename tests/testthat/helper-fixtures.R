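# Fixture builders (everything generated in code; no data files).

# minimal reference wrapper around a hand-built locus table (no genome);
# sufficient for all cohort-level operations
make_loci_ref <- function(n, chrom = "chr1", pattern = "ACGTACG",
                          ref_copies = 3, spacing = 21000L) {
  plen <- nchar(pattern)
  loci <- data.frame(
    locus = seq_len(n), chrom = rep_len(chrom, n),
    start = (seq_len(n) - 1L) * spacing,
    end = (seq_len(n) - 1L) * spacing +
      as.integer(round(plen * ref_copies)),
    pattern = pattern, pattern_length = plen,
    ref_copies = rep_len(ref_copies, n),
    flank_left = strrep("A", 50), flank_right = strrep("C", 50),
    indistinguishable = FALSE, family = NA_integer_,
    canonical = canonical_pattern(pattern), stringsAsFactors = FALSE)
  structure(list(loci = loci, genome = NULL), class = "vntr_reference")
}

# quick cohort from explicit per-sample allele lists:
# genotypes = list(sample = list(`locus` = c(cgl, ...)))
make_cohort <- function(genotypes, loci_ref, sex = NULL,
                        population = NULL) {
  samples <- names(genotypes)
  rows <- list()
  for (s in samples) {
    for (l in names(genotypes[[s]])) {
      cgl <- genotypes[[s]][[l]]
      if (!length(cgl)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, locus = as.integer(l), cgl = as.integer(cgl),
        sp = 5L, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(0), locus = integer(0),
               cgl = integer(0), sp = integer(0))
  meta <- data.frame(sample = samples,
                     sex = if (is.null(sex)) "F" else sex,
                     stringsAsFactors = FALSE)
  if (!is.null(population)) meta$population <- population
  vntr_cohort(calls, meta, loci_ref$loci)
}

# small end-to-end simulation config: loci whose arrays (and one-copy
# gains) stay well inside a 150 bp read, so spanning-read support for
# every detectable allele is near-certain at 30x (see methods vignette)
recovery_config <- function(n_samples = 2L, n_loci = 30L) {
  sim_config(n_populations = 1L, samples_per_population = n_samples,
             n_loci = n_loci, pattern_length_range = c(7L, 10L),
             ref_copies_range = c(2, 3.5), allele_cgl_range = c(-1L, 1L),
             mono_frac = 0.2, nonref_beta = c(2, 2))
}
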