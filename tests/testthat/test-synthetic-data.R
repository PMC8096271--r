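test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_populations = 2, samples_per_population = 5,
                    n_loci = 15, pattern_length_range = c(7, 20),
                    ref_copies_range = c(2, 4))
  r1 <- generate_reference(cfg, seed = 5)
  r2 <- generate_reference(cfg, seed = 5)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$loci, r2$loci)
  t1 <- sample_cohort(r1, cfg, seed = 6)
  t2 <- sample_cohort(r2, cfg, seed = 6)
  expect_identical(t1$genotypes, t2$genotypes)
  rd1 <- synthesize_reads(t1, r1, "S0001", 100, 10, 0.01, seed = 7)
  rd2 <- synthesize_reads(t2, r2, "S0001", 100, 10, 0.01, seed = 7)
  expect_identical(as.character(rd1), as.character(rd2))
  genes <- simulate_genes(r1, loci = 1:5)
  e1 <- simulate_expression(t1, genes, n_hidden_factors = 2, seed = 8)
  e2 <- simulate_expression(t2, genes, n_hidden_factors = 2, seed = 8)
  expect_identical(e1$tpm, e2$tpm)
  # different seeds differ
  r3 <- generate_reference(cfg, seed = 9)
  expect_false(identical(as.character(r1$genome),
                         as.character(r3$genome)))
})

test_that("degenerate configurations produce empty outputs", {
  cfg <- sim_config(n_populations = 1, samples_per_population = 1,
                    n_loci = 0)
  ref <- generate_reference(cfg, seed = 1)
  expect_equal(nrow(ref$loci), 0)
  expect_equal(length(ref$genome), 0)

  cfg2 <- sim_config(n_populations = 1, samples_per_population = 1,
                     n_loci = 5, pattern_length_range = c(7, 10),
                     ref_copies_range = c(2, 3))
  ref2 <- generate_reference(cfg2, seed = 2)
  tr <- sample_cohort(ref2, cfg2, seed = 3)
  rd <- synthesize_reads(tr, ref2, "S0001", 100, 0, 0, seed = 4)
  expect_equal(length(rd), 0)

  # single sample, single population: every autosomal locus diploid
  expect_equal(nrow(tr$samples), 1)
  expect_true(all(!is.na(tr$genotypes$a1) & !is.na(tr$genotypes$a2)))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(pattern_length_range = c(5, 20)), "7-126")
  expect_error(sim_config(pattern_length_range = c(7, 200)), "7-126")
  expect_error(sim_config(error_rate = 1.5), "probabilities")
  expect_error(sim_config(coverage = -1), "coverage")
  expect_error(sim_config(marker_allele_spec = data.frame(locus = 1)),
               "marker_allele_spec")
  cfg <- sim_config(n_loci = 4,
                    marker_allele_spec = data.frame(
                      locus = 99L, cgl = 1L, population = "POP1",
                      f_in = .4, f_out = .05))
  ref <- generate_reference(sim_config(n_loci = 4), seed = 1)
  expect_error(sample_cohort(ref, cfg, seed = 1), "unknown locus")
  expect_error(generate_reference(
    sim_config(n_loci = 50, genome_length = 100), seed = 1),
    "without overlap")
})

test_that("indistinguishable fraction and flank structure are as configured", {
  cfg <- sim_config(n_populations = 1, samples_per_population = 1,
                    n_loci = 100, pattern_length_range = c(7, 20),
                    ref_copies_range = c(2, 4),
                    indistinguishable_frac = 0.16)
  ref <- generate_reference(cfg, seed = 42)
  expect_equal(sum(ref$loci$indistinguishable), 16)
  # family members share the pattern
  fams <- split(ref$loci$pattern[ref$loci$indistinguishable],
                ref$loci$family[ref$loci$indistinguishable])
  for (f in fams) expect_equal(length(unique(f)), 1)
  # loci do not overlap
  for (ch in unique(ref$loci$chrom)) {
    l <- ref$loci[ref$loci$chrom == ch, ]
    l <- l[order(l$start), ]
    if (nrow(l) > 1) expect_true(all(diff(l$start) > 0) &&
                                   all(l$start[-1] >= l$end[-nrow(l)]))
  }
})

test_that("planted marker frequencies hit their targets within 3 SE", {
  cfg <- sim_config(n_populations = 2, samples_per_population = 2000,
                    n_loci = 6,
                    marker_allele_spec = data.frame(
                      locus = 1L, cgl = 1L, population = "POP1",
                      f_in = 0.4, f_out = 0.05))
  ref <- generate_reference(sim_config(n_loci = 6), seed = 21)
  tr <- sample_cohort(ref, cfg, seed = 22)
  g <- tr$genotypes[tr$genotypes$locus == 1L, ]
  pop <- tr$samples$population[match(g$sample, tr$samples$sample)]
  hap_freq <- function(rows) mean(c(rows$a1, rows$a2) == 1L, na.rm = TRUE)
  f_in_hat <- hap_freq(g[pop == "POP1", ])
  f_out_hat <- hap_freq(g[pop == "POP2", ])
  se <- function(f, n) sqrt(f * (1 - f) / (2 * n))
  expect_lt(abs(f_in_hat - 0.4), 3 * se(0.4, 2000))
  expect_lt(abs(f_out_hat - 0.05), 3 * se(0.05, 2000))
  # carrier fraction approximately 1 - (1 - f)^2
  carrier <- mean((g$a1 == 1L | g$a2 == 1L)[pop == "POP1"])
  expect_lt(abs(carrier - (1 - 0.6^2)), 0.04)
})

test_that("trio generation is Mendelian by construction at rate zero", {
  ref <- make_loci_ref(200)
  cfg <- sim_config(n_populations = 1, samples_per_population = 2,
                    n_loci = 200, mono_frac = 0, nonref_beta = c(2, 2))
  tr <- sample_cohort(ref, cfg, seed = 31)
  # S0001 is M, S0002 is F under the alternating sex rule
  tr2 <- generate_trio(tr, ref, mother = "S0002", father = "S0001",
                       child_id = "KID", child_sex = "F",
                       mutation_rate = 0, seed = 32)
  calls <- truth_as_calls(tr2)
  rep <- mendelian_check(calls, mother = "S0002", father = "S0001",
                         child = "KID", child_sex = "F",
                         loci = ref$loci, tier = "all")
  expect_equal(rep$summary$inconsistent, 0)
  expect_equal(rep$summary$consistent_pct, 100)

  # enumeration example: mother {0,+1}, father {-2,-2} -> child in
  # {{0,-2},{+1,-2}}
  ref1 <- make_loci_ref(1)
  base <- structure(list(
    samples = data.frame(sample = c("M0", "F0"),
                         population = "POP1", sex = c("F", "M")),
    genotypes = data.frame(sample = c("M0", "F0"), locus = 1L,
                           a1 = c(0L, -2L), a2 = c(1L, -2L))),
    class = "vntr_truth")
  seen <- character(0)
  for (s in 1:12) {
    kid <- generate_trio(base, ref1, "M0", "F0", "K", "M", 0, seed = s)
    g <- kid$genotypes[kid$genotypes$sample == "K", ]
    seen <- c(seen, paste(sort(c(g$a1, g$a2)), collapse = ","))
  }
  expect_true(all(seen %in% c("-2,0", "-2,1")))
  expect_equal(sort(unique(seen)), c("-2,0", "-2,1"))
})

test_that("read counts follow the coverage expectation within 1%", {
  cfg <- sim_config(n_populations = 1, samples_per_population = 1,
                    n_loci = 40, pattern_length_range = c(7, 15),
                    ref_copies_range = c(2, 4))
  ref <- generate_reference(cfg, seed = 51)
  tr <- sample_cohort(ref, cfg, seed = 52)
  g_len <- sum(Biostrings::width(ref$genome))
  for (cov in c(30, 60)) {
    rd <- synthesize_reads(tr, ref, "S0001", 100, cov, 0, seed = 53)
    expected <- cov * g_len / 100
    expect_lt(abs(length(rd) - expected) / expected, 0.01)
  }
})

test_that("sex chromosomes are haploid as appropriate", {
  cfg <- sim_config(n_populations = 1, samples_per_population = 4,
                    n_loci = 40, x_frac = 0.2, y_frac = 0.1,
                    pattern_length_range = c(7, 15),
                    ref_copies_range = c(2, 4))
  ref <- generate_reference(cfg, seed = 61)
  tr <- sample_cohort(ref, cfg, seed = 62)
  ct <- setNames(ifelse(ref$loci$chrom == "chrX", "X",
                        ifelse(ref$loci$chrom == "chrY", "Y", "A")),
                 ref$loci$locus)
  g <- tr$genotypes
  g$ct <- ct[as.character(g$locus)]
  g$sex <- tr$samples$sex[match(g$sample, tr$samples$sample)]
  expect_true(all(!is.na(g$a2[g$ct == "A"])))
  expect_true(all(is.na(g$a2[g$ct == "X" & g$sex == "M"])))
  expect_true(all(!is.na(g$a2[g$ct == "X" & g$sex == "F"])))
  expect_true(all(g$sex[g$ct == "Y"] == "M"))  # no female Y rows
  expect_true(all(is.na(g$a2[g$ct == "Y"])))
})

test_that("expression generator plants effects, covariates and hidden factors", {
  ref <- make_loci_ref(10)
  cfg <- sim_config(n_populations = 2, samples_per_population = 100,
                    n_loci = 10, mono_frac = 0, nonref_beta = c(2, 2),
                    allele_cgl_range = c(-1L, 0L))
  tr <- sample_cohort(ref, cfg, seed = 71)
  genes <- simulate_genes(ref)
  spec <- data.frame(gene = "GENE_1", locus = 1L, effect = 2.0)
  ex <- simulate_expression(tr, genes, eqtl_effect_spec = spec,
                            n_hidden_factors = 1, noise_sd = 0.3,
                            seed = 72)
  expect_equal(dim(ex$tpm), c(10L, 200L))
  expect_equal(dim(ex$hidden), c(200L, 1L))
  expect_true(all(ex$tpm >= 0))
  # carrier shift visible in raw log2 expression of the planted gene
  g <- tr$genotypes[tr$genotypes$locus == 1L, ]
  carrier <- g$sample[g$a1 != 0L | g$a2 != 0L]
  y <- log2(ex$tpm["GENE_1", ] + 1)
  idx <- colnames(ex$tpm) %in% carrier
  expect_gt(mean(y[idx]) - mean(y[!idx]), 1.5)
  # unknown gene/locus in the effect spec is an error
  expect_error(simulate_expression(
    tr, genes, eqtl_effect_spec = data.frame(gene = "NOPE", locus = 1L,
                                             effect = 1), seed = 1),
    "unknown gene")
})
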