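# Synthetic beta matrices with known truth, so the whole audit pipeline is
# testable offline. The generator states a world and sticks to it: SNP probes
# are fully methylated CpGs destroyed by a D allele (beta modes ~1 / ~0.5 / ~0
# for CC / CD / DD, a clipped-Normal stand-in for array chemistry), genotypes
# are drawn under HWE at a per-probe MAF, background probes have high/low/mid
# baselines with no genotype structure, and one trait probe mimics the
# AHRR smoking locus.

#' Simulation configuration
#'
#' Defaults mirror the published cohort: 111 samples (so the
#' `ceiling(0.95 * n) = 106` candidacy arithmetic is exercised at the printed
#' scale), genotype beta modes 0.97 / 0.50 / 0.03 (heterozygote at exactly
#' half signal), per-cell noise SD 0.03. `maf_range` spans (0.05, 0.5) so
#' that the audit's observed MAF floor emerges from the homozygote-count and
#' HWE filters rather than being built into the generator. The cleaned input
#' matrices the audit targets are complete, so `missing_rate` defaults to 0;
#' raise it to test robustness.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_snp_probes planted SNP-affected probes (>= 0).
#' @param n_background_probes non-genetic probes (>= 0).
#' @param maf_range length-2 D-allele (minor) frequency range, within
#'   (0, 0.5\].
#' @param genotype_means beta means for (CC, CD, DD); must be strictly
#'   decreasing.
#' @param beta_sd per-cell Normal noise SD (> 0); betas are clipped to \[0,1\].
#' @param missing_rate fraction of cells set to `NA`, in \[0,1).
#' @param smoking_prevalence fraction of samples labelled smokers.
#' @param smoking_means beta means (nonsmoker, smoker) at the trait probe.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 111L,
                              n_snp_probes = 500L,
                              n_background_probes = 5000L,
                              maf_range = c(0.05, 0.5),
                              genotype_means = c(0.97, 0.50, 0.03),
                              beta_sd = 0.03,
                              missing_rate = 0,
                              smoking_prevalence = 0.5,
                              smoking_means = c(0.85, 0.45),
                              seed = NULL) {
  fail <- function(field, msg) stop("invalid config field '", field, "': ",
                                    msg, call. = FALSE)
  if (!(n_samples >= 2)) fail("n_samples", "need at least 2 samples")
  if (n_snp_probes < 0) fail("n_snp_probes", "must be >= 0")
  if (n_background_probes < 0) fail("n_background_probes", "must be >= 0")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    fail("maf_range", "need (low, high) within (0, 0.5]")
  if (length(genotype_means) != 3L ||
      !(genotype_means[3] < genotype_means[2] &&
        genotype_means[2] < genotype_means[1]))
    fail("genotype_means", "need mu_DD < mu_CD < mu_CC")
  if (!(beta_sd > 0)) fail("beta_sd", "must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) fail("missing_rate", "must be in [0,1)")
  if (smoking_prevalence < 0 || smoking_prevalence > 1)
    fail("smoking_prevalence", "must be in [0,1]")
  if (length(smoking_means) != 2L) fail("smoking_means", "need (nonsmoker, smoker)")
  structure(list(n_samples = as.integer(n_samples),
                 n_snp_probes = as.integer(n_snp_probes),
                 n_background_probes = as.integer(n_background_probes),
                 maf_range = as.numeric(maf_range),
                 genotype_means = as.numeric(genotype_means),
                 beta_sd = beta_sd, missing_rate = missing_rate,
                 smoking_prevalence = smoking_prevalence,
                 smoking_means = as.numeric(smoking_means),
                 seed = seed),
            class = "simulation_config")
}

# background baseline mixture: mostly fully methylated or unmethylated CpGs,
# a minority of intermediate (e.g. imprinted / heterogeneous-tissue) sites
BG_CLASSES <- c(high = 0.9, low = 0.1, mid = 0.5)
BG_WEIGHTS <- c(high = 0.4, low = 0.4, mid = 0.2)
BG_BASELINE_SD <- 0.05

.clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# betas for SNP probes given an integer D-allele dose matrix (0/1/2)
.snp_betas <- function(dose, config) {
  mu <- array(config$genotype_means[dose + 1L], dim(dose))
  .clip01(array(rnorm(length(mu), mu, config$beta_sd), dim(dose)))
}

.apply_missing <- function(m, rate) {
  if (rate > 0) m[runif(length(m)) < rate] <- NA_real_
  m
}

#' Simulate a beta matrix with full truth tables
#'
#' Per SNP probe, a true MAF is drawn uniformly from `maf_range` and each
#' sample's genotype from HWE proportions; beta is Normal around the genotype
#' mean, clipped to \[0,1\]. Background probes get a per-probe baseline mean
#' from a high/low/mid mixture, no genotype structure. One trait probe,
#' `cg05575921`, takes its mean from each sample's smoking label. Identical
#' config and seed give identical output.
#'
#' @param config a [simulation_config].
#' @return list of class `methylaudit_sim` with elements `beta` (a
#'   [beta_matrix]), `truth` (list: `probes` data.frame with class /
#'   true MAF / background baseline, `genotypes` character matrix for SNP
#'   probes, `samples` data.frame with smoking labels), and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))

  snp_ids <- if (config$n_snp_probes) sprintf("snp%04d", seq_len(config$n_snp_probes)) else character()
  bg_ids <- if (config$n_background_probes) sprintf("bg%05d", seq_len(config$n_background_probes)) else character()
  trait_id <- "cg05575921"

  # SNP block: genotype = D-allele dose ~ Binomial(2, maf), i.e. HWE
  maf <- runif(length(snp_ids), config$maf_range[1], config$maf_range[2])
  dose <- matrix(rbinom(length(snp_ids) * n, 2L, rep(maf, n)),
                 nrow = length(snp_ids), ncol = n,
                 dimnames = list(snp_ids, sample_ids))
  snp_beta <- .snp_betas(dose, config)

  # background block
  bg_class <- sample(names(BG_CLASSES), length(bg_ids), replace = TRUE,
                     prob = BG_WEIGHTS)
  bg_baseline <- .clip01(rnorm(length(bg_ids), BG_CLASSES[bg_class],
                               BG_BASELINE_SD))
  bg_beta <- .clip01(matrix(rnorm(length(bg_ids) * n, rep(bg_baseline, n),
                                  config$beta_sd),
                            nrow = length(bg_ids), ncol = n))

  # trait block
  smoker <- runif(n) < config$smoking_prevalence
  trait_mu <- ifelse(smoker, config$smoking_means[2], config$smoking_means[1])
  trait_beta <- matrix(.clip01(rnorm(n, trait_mu, config$beta_sd)), nrow = 1L)

  beta <- rbind(snp_beta, bg_beta, trait_beta)
  dimnames(beta) <- list(c(snp_ids, bg_ids, trait_id), sample_ids)
  beta <- .apply_missing(beta, config$missing_rate)

  genotypes <- array(GENOTYPE_LEVELS[dose + 1L], dim(dose), dimnames(dose))
  probes <- data.frame(
    probe_id = rownames(beta),
    class = c(rep("snp", length(snp_ids)), rep("background", length(bg_ids)),
              "trait"),
    true_maf = c(maf, rep(NA_real_, length(bg_ids)), NA_real_),
    baseline = c(rep(NA_real_, length(snp_ids)), bg_baseline, NA_real_),
    stringsAsFactors = FALSE)

  structure(list(beta = beta_matrix(beta),
                 truth = list(probes = probes,
                              genotypes = genotypes,
                              samples = data.frame(sample_id = sample_ids,
                                                   smoker = smoker,
                                                   stringsAsFactors = FALSE)),
                 config = config),
            class = "methylaudit_sim")
}

#' Re-assay the same individuals
#'
#' Generates a second beta matrix for the individuals of a previous
#' [simulate_dataset()] call: true genotypes, background baselines and
#' smoking labels are carried over, noise and missingness are drawn fresh,
#' and a fraction `per_call_error` of (SNP probe, sample) genotype cells is
#' flipped to a random other genotype before beta generation — emulating a
#' second array run of the same cohort with some call error.
#'
#' @param truth the `truth` element of a `methylaudit_sim` (or the whole sim).
#' @param config the matching [simulation_config].
#' @param per_call_error fraction of genotype cells flipped, in \[0,1).
#' @param seed optional RNG seed for the re-assay.
#' @return a `methylaudit_sim` sharing the same individuals.
#' @export
resample_individuals <- function(truth, config = NULL, per_call_error = 0,
                                 seed = NULL) {
  if (inherits(truth, "methylaudit_sim")) {
    if (is.null(config)) config <- truth$config
    truth <- truth$truth
  }
  stopifnot(inherits(config, "simulation_config"))
  if (per_call_error < 0 || per_call_error >= 1)
    stop("per_call_error must be in [0,1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  geno <- truth$genotypes
  dose <- array(match(geno, GENOTYPE_LEVELS) - 1L, dim(geno), dimnames(geno))
  if (per_call_error > 0 && length(dose)) {
    flip <- which(runif(length(dose)) < per_call_error)
    # replace each flipped dose by one of the two other values
    dose[flip] <- (dose[flip] + sample(1:2, length(flip), replace = TRUE)) %% 3L
  }
  snp_beta <- .snp_betas(dose, config)

  bg <- truth$probes[truth$probes$class == "background", , drop = FALSE]
  n <- nrow(truth$samples)
  bg_beta <- .clip01(matrix(rnorm(nrow(bg) * n, rep(bg$baseline, n),
                                  config$beta_sd),
                            nrow = nrow(bg), ncol = n))
  trait_mu <- ifelse(truth$samples$smoker, config$smoking_means[2],
                     config$smoking_means[1])
  trait_beta <- matrix(.clip01(rnorm(n, trait_mu, config$beta_sd)), nrow = 1L)

  beta <- rbind(snp_beta, bg_beta, trait_beta)
  dimnames(beta) <- list(c(rownames(geno), bg$probe_id, "cg05575921"),
                         truth$samples$sample_id)
  beta <- .apply_missing(beta, config$missing_rate)

  new_truth <- truth
  new_truth$genotypes <- array(GENOTYPE_LEVELS[dose + 1L], dim(dose),
                               dimnames(dose))
  structure(list(beta = beta_matrix(beta), truth = new_truth,
                 config = config),
            class = "methylaudit_sim")
}
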