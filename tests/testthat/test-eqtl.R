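test_that("gene-VNTR pairing respects the 10 kb window and overlap", {
  genes <- data.frame(gene = c("G1", "G2", "G3", "G4"),
                      chrom = "chr1",
                      start = c(20000L, 35101L, 5000L, 90000L),
                      end = c(21000L, 36101L, 5100L, 91000L))
  loci <- data.frame(locus = 1:2, chrom = "chr1",
                     start = c(25000L, 5050L), end = c(25100L, 5060L))
  pr <- pair_genes_vntrs(genes, loci)
  key <- paste(pr$gene, pr$locus)
  expect_true("G1 1" %in% key)       # 4 kb upstream
  expect_false("G2 1" %in% key)      # gap of 10 001 bp
  expect_true("G3 2" %in% key)       # locus inside the gene
  expect_equal(pr$distance[pr$gene == "G3"], 0L)
  expect_false("G4 1" %in% key)
  # boundary: exactly 10 kb gap is paired
  genes_b <- data.frame(gene = "GB", chrom = "chr1", start = 35100L,
                        end = 36000L)
  pr_b <- pair_genes_vntrs(genes_b, loci[1, ])
  expect_equal(nrow(pr_b), 1)
  expect_equal(pr_b$distance, 10000L)
})

test_that("genotype classes apply the other rule and size filters", {
  samples <- sprintf("S%03d", 1:445)
  mk_calls <- function(n00, n01, sp_locus = 1L) {
    rows <- list()
    for (i in seq_len(n00))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples[i], locus = sp_locus, cgl = 0L, sp = 5L)
    for (i in seq_len(n01)) {
      s <- samples[n00 + i]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, locus = sp_locus, cgl = c(0L, 1L), sp = 5L)
    }
    do.call(rbind, rows)
  }
  # {0: 200, 0/+1: 150, other: 95} -> retained (a reference-only call
  # is the single-allele genotype "0")
  cl <- build_genotype_classes(mk_calls(200, 150), 1L, samples)
  expect_false(is.null(cl))
  expect_equal(sort(unname(as.integer(cl$counts))), c(95L, 150L, 200L))
  expect_true("other" %in% levels(cl$classes))
  expect_equal(unname(cl$counts[["0"]]), 200L)
  # {0/0: 430, 0/+1: 15} -> excluded (a class below 20)
  expect_null(build_genotype_classes(mk_calls(430, 15), 1L, samples))
  # {0/0: 425, other: 20} -> excluded (needs 3 classes with other)
  expect_null(build_genotype_classes(mk_calls(425, 0), 1L, samples))
  # fully genotyped two-class locus is retained without other
  cl2 <- build_genotype_classes(mk_calls(295, 150), 1L, samples)
  expect_false(is.null(cl2))
  expect_false("other" %in% levels(cl2$classes))
})

test_that("residualization is exact, orthogonal and equivariant", {
  set.seed(31)
  n <- 60
  cov <- data.frame(sex = rep(c("M", "F"), n / 2),
                    pc1 = rnorm(n), pc2 = rnorm(n))
  X <- vntrscope:::covariate_matrix(cov)
  # expression that is an exact linear function of the covariates
  beta <- matrix(rnorm(3 * ncol(X)), 3)
  expr <- t(cbind(1, X) %*% t(cbind(rnorm(3), beta)))
  colnames(expr) <- sprintf("S%02d", 1:n)
  rownames(expr) <- paste0("G", 1:3)
  res <- residualize(expr, cov)
  expect_lt(max(abs(res)), 1e-8)
  # residuals orthogonal to every design column
  noisy <- expr + matrix(rnorm(3 * n), 3)
  res2 <- residualize(noisy, cov)
  expect_lt(max(abs(cor(t(res2), X))), 1e-8)
  # consistent permutation of samples permutes residuals
  perm <- sample(n)
  res_p <- residualize(noisy[, perm], cov[perm, ])
  expect_equal(res_p, res2[, perm])
  # rank deficiency errors name the collinear column
  cov_bad <- cov; cov_bad$dup <- cov$pc1
  expect_error(residualize(noisy, cov_bad), "dup")
  # missing covariates error lists samples
  cov_na <- cov; cov_na$pc1[3] <- NA
  expect_error(residualize(noisy, cov_na), "S03")
})

test_that("hidden factors recover planted structure and obey the stopping rule", {
  ref <- make_loci_ref(5)
  cfg <- sim_config(n_populations = 2, samples_per_population = 80,
                    n_loci = 5)
  tr <- sample_cohort(ref, cfg, seed = 41)
  genes <- data.frame(gene = paste0("G", 1:200))
  # a single planted batch factor is recovered almost exactly
  ex1 <- simulate_expression(tr, genes, n_hidden_factors = 1,
                             noise_sd = 0.3, seed = 43)
  hf1 <- estimate_hidden_factors(log2(ex1$tpm + 1), ex1$covariates,
                                 max_k = 4)
  expect_gt(max(abs(cor(hf1, ex1$hidden))), 0.9)
  # two planted factors: PCA may rotate within their span, so check
  # that the span of the accepted factors explains each truth factor
  ex <- simulate_expression(tr, genes, n_hidden_factors = 2,
                            noise_sd = 0.3, seed = 42)
  log2m <- log2(ex$tpm + 1)
  hf <- estimate_hidden_factors(log2m, ex$covariates, max_k = 4)
  expect_gte(ncol(hf), 2)
  for (j in 1:2) {
    fit <- stats::lm.fit(cbind(1, hf), ex$hidden[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((ex$hidden[, j] -
                                            mean(ex$hidden[, j]))^2)
    expect_gt(r2, 0.8)
  }
  # corr_cutoff zero accepts nothing
  hf0 <- estimate_hidden_factors(log2m, ex$covariates, max_k = 4,
                                 corr_cutoff = 0)
  expect_equal(ncol(hf0), 0)
  # cap respected
  hf1 <- estimate_hidden_factors(log2m, ex$covariates, max_k = 1)
  expect_equal(ncol(hf1), 1)
})

test_that("ANOVA F equals the squared two-sample t statistic", {
  set.seed(51)
  for (rep in 1:10) {
    n1 <- sample(20:40, 1); n2 <- sample(20:40, 1)
    y <- c(rnorm(n1, 0), rnorm(n2, 0.5))
    grp <- factor(rep(c("a", "b"), c(n1, n2)))
    res_mat <- matrix(y, 1, dimnames = list("G1", NULL))
    scan <- anova_scan(res_mat,
                       data.frame(gene = "G1", locus = 1L),
                       list(`1` = list(classes = grp,
                                       counts = table(grp))),
                       fdr = 0.05)
    tt <- stats::t.test(y ~ grp, var.equal = TRUE)$statistic
    expect_equal(scan$tested$f, unname(tt)^2, tolerance = 1e-10)
  }
  # identical value multisets in both classes: means equal, F = 0
  v <- rnorm(50)
  y0 <- c(v, v)
  grp0 <- factor(rep(c("a", "b"), each = 50))
  scan0 <- anova_scan(matrix(y0, 1, dimnames = list("G1", NULL)),
                      data.frame(gene = "G1", locus = 1L),
                      list(`1` = list(classes = grp0,
                                      counts = table(grp0))))
  expect_lt(scan0$tested$f, 1e-12)
  expect_gt(scan0$tested$p, 0.999)
})

test_that("planted effects are recovered with the expected magnitude", {
  set.seed(61)
  power_hits <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    n <- 450
    grp <- factor(rep(c("0/0", "0/-1", "-1/-1"), c(150, 200, 100)))
    shift <- ifelse(grp == "0/0", 0, 1.0)  # carrier shift, 1 log2 unit
    y <- shift + rnorm(n, 0, 0.5)
    y <- y - mean(y)
    scan <- anova_scan(matrix(y, 1, dimnames = list("G1", NULL)),
                       data.frame(gene = "G1", locus = 1L),
                       list(`1` = list(classes = grp,
                                       counts = table(grp))))
    if (scan$tested$q < 0.05) power_hits <- power_hits + 1L
    expect_lt(abs(scan$tested$max_mean_diff - 1.0), 0.25)
  }
  expect_gte(power_hits / reps, 0.9)
})

test_that("null scans control discoveries under BH", {
  set.seed(71)
  n <- 200
  grp <- factor(rep(c("0/0", "0/-1"), each = n / 2))
  n_pairs <- 300L
  res_mat <- matrix(rnorm(n_pairs * n), n_pairs,
                    dimnames = list(paste0("G", seq_len(n_pairs)), NULL))
  pairs <- data.frame(gene = paste0("G", seq_len(n_pairs)),
                      locus = seq_len(n_pairs))
  classings <- setNames(rep(list(list(classes = grp,
                                      counts = table(grp))), n_pairs),
                        as.character(seq_len(n_pairs)))
  scan <- anova_scan(res_mat, pairs, classings)
  expect_lte(nrow(scan$significant), 0.05 * n_pairs)
})

test_that("full synthetic scan recovers planted pairs with controlled FDR", {
  n_pairs <- 1071L
  n_effect <- 193L
  ref <- make_loci_ref(n_pairs)
  cfg <- sim_config(n_populations = 2, samples_per_population = 223,
                    n_loci = n_pairs,
                    marker_allele_spec = marker_panel(
                      n_populations = 1, n_per_pop = n_pairs,
                      f_in = 0.4, f_out = 0.4, cgl_values = -1L))
  tr <- sample_cohort(ref, cfg, seed = 81)
  genes <- simulate_genes(ref, gap = 500L)
  effect_loci <- seq_len(n_effect)
  spec <- data.frame(gene = sprintf("GENE_%d", effect_loci),
                     locus = effect_loci, effect = 1.0)
  ex <- simulate_expression(tr, genes, eqtl_effect_spec = spec,
                            n_hidden_factors = 2, noise_sd = 0.5,
                            seed = 82)
  co <- vntr_cohort(truth_as_calls(tr), tr$samples, ref$loci)
  out <- eqtl_scan(co, genes, ex$tpm, ex$covariates, max_hidden = 5)
  # every gene pairs with exactly its adjacent locus
  expect_equal(nrow(out$pairs), n_pairs)
  hits <- out$significant
  truth_keys <- paste(spec$gene, spec$locus)
  hit_keys <- paste(hits$gene, hits$locus)
  sensitivity <- mean(truth_keys %in% hit_keys)
  fdp <- if (nrow(hits)) mean(!(hit_keys %in% truth_keys)) else 0
  expect_gte(sensitivity, 0.9)
  expect_lte(fdp, 0.1)
})
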