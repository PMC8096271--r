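test_that("Mendelian consistency handles worked trio examples and tiers", {
  ref <- make_loci_ref(5)
  co <- make_cohort(list(
    M = list(`1` = c(0L, -1L), `2` = c(0L, 1L), `3` = c(0L, 1L),
             `4` = c(0L, 0L), `5` = c(2L, 3L)),
    F = list(`1` = c(1L, 2L), `2` = c(2L, -1L), `3` = c(0L, 1L),
             `4` = c(1L, 2L)),
    C = list(`1` = c(0L, 1L), `2` = c(2L, 2L), `3` = c(0L, 1L),
             `4` = 1L)), ref,
    sex = c("F", "M", "M"))
  rep_all <- mendelian_check(co$calls, "M", "F", "C", "M", ref$loci,
                             tier = "all")
  st <- setNames(rep_all$per_locus$status, rep_all$per_locus$locus)
  expect_equal(st[["1"]], "consistent")     # 0 from M, +1 from F
  expect_equal(st[["2"]], "inconsistent")   # +2 absent in mother
  expect_equal(st[["3"]], "consistent")
  expect_equal(st[["4"]], "consistent")     # lenient single-allele rule
  expect_equal(st[["5"]], "unevaluated")    # father/child not genotyped
  expect_equal(rep_all$summary$consistent +
                 rep_all$summary$inconsistent +
                 rep_all$summary$unevaluated, 5)

  # parents_het drops loci with a homozygous parent (locus 4: mother hom)
  rep_ph <- mendelian_check(co$calls, "M", "F", "C", "M", ref$loci,
                            tier = "parents_het")
  st_ph <- setNames(rep_ph$per_locus$status, rep_ph$per_locus$locus)
  expect_equal(st_ph[["4"]], "unevaluated")
  expect_equal(st_ph[["1"]], "consistent")
  # all_het additionally requires a heterozygous child (locus 2 child hom)
  rep_ah <- mendelian_check(co$calls, "M", "F", "C", "M", ref$loci,
                            tier = "all_het")
  expect_equal(rep_ah$per_locus$status[rep_ah$per_locus$locus == 2L],
               "unevaluated")
  # all_het_distinct drops locus 3 (all genotypes identical)
  rep_ad <- mendelian_check(co$calls, "M", "F", "C", "M", ref$loci,
                            tier = "all_het_distinct")
  expect_equal(rep_ad$per_locus$status[rep_ad$per_locus$locus == 3L],
               "unevaluated")
  expect_error(mendelian_check(co$calls, "M", "F", "C", "M", ref$loci,
                               tier = "bogus"))
})

test_that("male-child X and Y alleles follow the parental-origin rules", {
  ref <- make_loci_ref(3)
  ref$loci$chrom <- c("chrX", "chrY", "chr1")
  co <- make_cohort(list(
    M = list(`1` = c(0L, -1L), `3` = c(0L, 0L)),
    F = list(`1` = 1L, `2` = -2L, `3` = c(0L, 1L)),
    C = list(`1` = -1L, `2` = -2L, `3` = c(0L, 1L))), ref,
    sex = c("F", "M", "M"))
  rep <- mendelian_check(co$calls, "M", "F", "C", "M", ref$loci)
  st <- setNames(rep$per_locus$status, rep$per_locus$locus)
  expect_equal(st[["1"]], "consistent")   # X allele present in mother
  expect_equal(st[["2"]], "consistent")   # Y allele present in father
  # X allele seen only in the father is inconsistent for a son
  co2 <- make_cohort(list(
    M = list(`1` = c(0L, -1L)), F = list(`1` = 1L),
    C = list(`1` = 1L)), ref, sex = c("F", "M", "M"))
  rep2 <- mendelian_check(co2$calls, "M", "F", "C", "M", ref$loci)
  expect_equal(rep2$per_locus$status[rep2$per_locus$locus == 1L],
               "inconsistent")
})

test_that("de novo mutation rate is recovered from trio inconsistencies", {
  # all-reference parents: every de novo change is detectably
  # inconsistent, so the flagged fraction estimates the rate
  n_loci <- 5000L
  ref <- make_loci_ref(n_loci)
  cfg <- sim_config(n_populations = 1, samples_per_population = 2,
                    n_loci = n_loci, mono_frac = 1)
  tr <- sample_cohort(ref, cfg, seed = 61)
  rate <- 0.01
  tr2 <- generate_trio(tr, ref, mother = "S0002", father = "S0001",
                       child_id = "K", child_sex = "F",
                       mutation_rate = rate, seed = 62)
  calls <- truth_as_calls(tr2)
  rep <- mendelian_check(calls, "S0002", "S0001", "K", "F", ref$loci)
  n_eval <- rep$summary$consistent + rep$summary$inconsistent
  obs <- rep$summary$inconsistent / n_eval
  se <- sqrt(rate * (1 - rate) / n_eval)
  expect_lt(abs(obs - rate), 3 * se)
})

test_that("platform consistency is a detectability-restricted Jaccard ratio", {
  loci <- data.frame(locus = 1:4, chrom = "chr1",
                     pattern_length = c(10L, 10L, 10L, 30L),
                     ref_copies = c(4, 4, 4, 4))
  # every locus genotyped in both sets (reference calls where no
  # non-reference allele was seen)
  a <- data.frame(sample = "S", locus = c(1L, 2L, 3L, 4L),
                  cgl = c(-1L, 1L, 0L, 1L), sp = 5L)
  b <- data.frame(sample = "S", locus = c(1L, 2L, 3L, 4L),
                  cgl = c(0L, 1L, -2L, 0L), sp = 5L)
  # worked example: {(1,-1),(2,+1)} vs {(2,+1),(3,-2)} -> 1/3;
  # (4,+1) needs 30*5+20 = 170 bp and is excluded at 150 bp
  pc <- platform_consistency(a, b, 250, 150, loci)
  expect_equal(pc$ratio, 1 / 3)
  expect_equal(pc$n_union, 3)
  # identical non-reference call sets give 1
  pc1 <- platform_consistency(a, a, 150, 150, loci)
  expect_equal(pc1$ratio, 1)
  # symmetry after restriction
  pc_ab <- platform_consistency(a, b, 250, 150, loci)
  pc_ba <- platform_consistency(b, a, 150, 250, loci)
  expect_equal(pc_ab$ratio, pc_ba$ratio)
  expect_gte(pc_ab$ratio, 0); expect_lte(pc_ab$ratio, 1)
  # empty union is undefined
  ref_only <- data.frame(sample = "S", locus = 1L, cgl = 0L, sp = 5L)
  expect_true(is.na(platform_consistency(ref_only, ref_only, 150, 150,
                                         loci)$ratio))
})

test_that("platform consistency matches a set-arithmetic oracle on simulations", {
  set.seed(71)
  loci <- data.frame(locus = 1:30, chrom = "chr1", pattern_length = 7L,
                     ref_copies = 5)
  for (rep in 1:10) {
    mk <- function() {
      n <- sample(5:15, 1)
      data.frame(sample = "S", locus = sample(1:30, n),
                 cgl = sample(c(-2L, -1L, 0L, 1L), n, TRUE), sp = 5L)
    }
    a <- mk(); b <- mk()
    pc <- platform_consistency(a, b, 150, 150, loci)
    common <- intersect(a$locus, b$locus)
    vntr <- common[vapply(common, function(l)
      any(a$cgl[a$locus == l] != 0) || any(b$cgl[b$locus == l] != 0),
      logical(1))]
    sa <- unique(paste(a$locus, a$cgl)[a$locus %in% vntr & a$cgl != 0])
    sb <- unique(paste(b$locus, b$cgl)[b$locus %in% vntr & b$cgl != 0])
    want <- if (length(union(sa, sb)))
      length(intersect(sa, sb)) / length(union(sa, sb)) else NA_real_
    expect_equal(pc$ratio, want)
  }
})

test_that("long-read validation applies the quarter-copy rule", {
  ref <- make_loci_ref(2, pattern = "ACGTACGTTG", ref_copies = 4)
  calls <- data.frame(sample = "S", locus = c(1L, 2L), cgl = 0L, sp = 5L)
  pat <- ref$loci$pattern[1]
  mk_read <- function(copies)
    paste0(strrep("A", 30), build_array(pat, copies), strrep("C", 30))
  # 4.2 copies observed: |4.2 - 4.0| = 0.2 <= 0.25 -> validated
  lr <- list(`1` = mk_read(4.2), `2` = mk_read(4.3))
  v <- longread_validate(calls, lr, ref)
  expect_true(v$per_allele$validated[v$per_allele$locus == 1L])
  expect_false(v$per_allele$validated[v$per_allele$locus == 2L])
  expect_equal(v$allele_rate, 0.5)
  # rate is monotone non-decreasing in tolerance
  rates <- vapply(c(0.1, 0.25, 0.35, 1), function(tol)
    longread_validate(calls, lr, ref, tolerance = tol)$allele_rate,
    numeric(1))
  expect_true(all(diff(rates) >= 0))
  # loci without covering reads are unevaluated
  v2 <- longread_validate(calls, list(`1` = mk_read(4)), ref)
  expect_false(v2$per_allele$evaluated[v2$per_allele$locus == 2L])
})

test_that("error-free long reads validate every true allele", {
  cfg <- recovery_config(n_samples = 1, n_loci = 12)
  ref <- generate_reference(cfg, seed = 81)
  tr <- sample_cohort(ref, cfg, seed = 82)
  calls <- truth_as_calls(tr)
  lr <- synthesize_long_reads(tr, ref, "S0001", n_per_locus = 2,
                              seed = 83)
  v <- longread_validate(calls, lr, ref)
  ev <- v$per_allele[v$per_allele$evaluated, ]
  expect_true(all(ev$validated))
  expect_equal(v$allele_rate, 1)
  expect_equal(v$locus_rate, 1)
})
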