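## Simulation configuration and RNG hygiene.

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Simulation configuration for the synthetic VNTR cohort generator
#'
#' Bundles every knob of the generator. Defaults describe the study
#' conditions used throughout the package's tests: a five-population
#' diploid cohort of 200 samples each, 400 minisatellite loci with pattern
#' sizes 7-126 bp and reference copy numbers 2-10, and allele copy-number
#' changes expressed as integer copies gained/lost (CGL) in -5..+3.
#'
#' Background allele frequencies: a fraction `mono_frac` of loci are
#' monomorphic for the reference; at the rest the per-haplotype
#' non-reference frequency is drawn from `Beta(nonref_beta[1],
#' nonref_beta[2])`. A non-reference haplotype is a copy loss with
#' probability `loss_bias` (copy losses outnumber gains roughly 1.8:1 in
#' human cohorts) and its magnitude is truncated-geometric with parameter
#' `geom_p`, clamped so every allele retains at least one pattern copy.
#' The true allele-frequency law of human minisatellites is unknown; this
#' stand-in is fully configurable.
#'
#' @param n_populations Number of populations.
#' @param samples_per_population Diploid samples per population.
#' @param n_loci Number of reference TR loci.
#' @param pattern_length_range Repeat unit length range in bp (7-126).
#' @param ref_copies_range Reference copy number range (real).
#' @param allele_cgl_range Integer CGL range for simulated alleles.
#' @param marker_allele_spec `NULL` or a data.frame with columns `locus`,
#'   `cgl`, `population`, `f_in`, `f_out`: population-specific marker
#'   alleles planted at haplotype frequency `f_in` inside the target
#'   population and `f_out` elsewhere.
#' @param read_length Read length in bp for read synthesis.
#' @param coverage Fold coverage for read synthesis.
#' @param error_rate Per-base substitution error probability.
#' @param trio_mutation_rate Per-locus probability of a de novo +-1 CGL
#'   change in a simulated child.
#' @param eqtl_effect_spec `NULL` or a data.frame with columns `gene`,
#'   `locus`, `effect`: planted expression shifts (log2 units) applied to
#'   carriers of any non-reference allele at the locus.
#' @param n_hidden_factors Hidden (batch-like) expression factors.
#' @param mono_frac,nonref_beta,loss_bias,geom_p Background allele
#'   frequency model (see Details).
#' @param x_frac,y_frac Fraction of loci placed on chrX / chrY.
#' @param indistinguishable_frac Fraction of loci flagged as members of
#'   dispersed, near-identical repeat families.
#' @param flank Flank length stored per locus (bp).
#' @param spacer Random spacer between loci in the synthetic genome (bp).
#' @param genome_length Optional total genome length; error if the loci
#'   cannot be placed without overlap within it.
#' @param noise_sd Residual Gaussian noise SD for expression (log2 units).
#' @param seed Optional default seed carried in the config.
#' @return A `sim_config` object (validated named list).
#' @export
sim_config <- function(n_populations = 5L,
                       samples_per_population = 200L,
                       n_loci = 400L,
                       pattern_length_range = c(7L, 126L),
                       ref_copies_range = c(2.0, 10.0),
                       allele_cgl_range = c(-5L, 3L),
                       marker_allele_spec = NULL,
                       read_length = 150L,
                       coverage = 30,
                       error_rate = 0,
                       trio_mutation_rate = 0,
                       eqtl_effect_spec = NULL,
                       n_hidden_factors = 0L,
                       mono_frac = 0.36,
                       nonref_beta = c(0.4, 3),
                       loss_bias = 0.64,
                       geom_p = 0.5,
                       x_frac = 0,
                       y_frac = 0,
                       indistinguishable_frac = 0,
                       flank = 50L,
                       spacer = 60L,
                       genome_length = NULL,
                       noise_sd = 0.5,
                       seed = NULL) {
  cfg <- list(n_populations = as.integer(n_populations),
              samples_per_population = as.integer(samples_per_population),
              n_loci = as.integer(n_loci),
              pattern_length_range = as.integer(pattern_length_range),
              ref_copies_range = as.numeric(ref_copies_range),
              allele_cgl_range = as.integer(allele_cgl_range),
              marker_allele_spec = marker_allele_spec,
              read_length = as.integer(read_length),
              coverage = coverage,
              error_rate = error_rate,
              trio_mutation_rate = trio_mutation_rate,
              eqtl_effect_spec = eqtl_effect_spec,
              n_hidden_factors = as.integer(n_hidden_factors),
              mono_frac = mono_frac,
              nonref_beta = nonref_beta,
              loss_bias = loss_bias,
              geom_p = geom_p,
              x_frac = x_frac,
              y_frac = y_frac,
              indistinguishable_frac = indistinguishable_frac,
              flank = as.integer(flank),
              spacer = as.integer(spacer),
              genome_length = genome_length,
              noise_sd = noise_sd,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_populations >= 0, cfg$samples_per_population >= 0,
            cfg$n_loci >= 0)
  if (cfg$pattern_length_range[1] < 7L || cfg$pattern_length_range[2] > 126L ||
      cfg$pattern_length_range[1] > cfg$pattern_length_range[2])
    stop("pattern lengths must lie within 7-126 bp")
  if (cfg$ref_copies_range[1] < 1 ||
      cfg$ref_copies_range[1] > cfg$ref_copies_range[2])
    stop("ref_copies_range must be an increasing pair with minimum >= 1")
  probs <- c(cfg$error_rate, cfg$trio_mutation_rate, cfg$mono_frac,
             cfg$loss_bias, cfg$geom_p, cfg$x_frac, cfg$y_frac,
             cfg$indistinguishable_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (cfg$coverage < 0) stop("coverage must be non-negative")
  if (!is.null(cfg$marker_allele_spec)) {
    ms <- cfg$marker_allele_spec
    need <- c("locus", "cgl", "population", "f_in", "f_out")
    if (!all(need %in% names(ms)))
      stop("marker_allele_spec needs columns ", paste(need, collapse = ", "))
    if (any(ms$f_in < 0 | ms$f_in > 1 | ms$f_out < 0 | ms$f_out > 1))
      stop("marker frequencies must lie in [0,1]")
  }
  invisible(cfg)
}

#' Marker allele panel for population-specific simulations
#'
#' Convenience builder for `marker_allele_spec`: assigns `n_per_pop`
#' distinct loci to each population round-robin over the first
#' `n_per_pop * n_populations` loci, with the marker CGL cycling through
#' `cgl_values`.
#'
#' @param n_populations Number of populations (labels `POP1..POPk`).
#' @param n_per_pop Marker alleles per population (default 50).
#' @param f_in,f_out In-/out-of-population haplotype frequencies
#'   (defaults 0.4 and 0.05).
#' @param cgl_values CGL values cycled over markers.
#' @param first_locus Id of the first marker locus (default 1).
#' @return A data.frame suitable for [sim_config()]'s
#'   `marker_allele_spec`.
#' @export
marker_panel <- function(n_populations = 5L, n_per_pop = 50L,
                         f_in = 0.4, f_out = 0.05,
                         cgl_values = c(-2L, -1L, 1L, 2L),
                         first_locus = 1L) {
  n <- n_populations * n_per_pop
  data.frame(
    locus = seq.int(first_locus, length.out = n),
    cgl = rep_len(cgl_values, n),
    population = rep(paste0("POP", seq_len(n_populations)), each = n_per_pop),
    f_in = f_in, f_out = f_out)
}
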