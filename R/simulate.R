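#' Configuration for the synthetic SILAC/comparative generator
#'
#' The generator emulates the measurement model of a pooled-channel SILAC
#' RBP-capture experiment. Each protein has a captured intensity
#' (`abundance`) and a true RNA-bound fraction `f`, so its RNA-bound signal is
#' `S = abundance * f` and its free-protein noise is `N = abundance * (1 - f)`.
#' Free protein partitions between the crosslinked and non-crosslinked
#' channels in proportion `noise_partition` (default 1:1, the equal
#' noise-partitioning assumption that holds when the labeled cell populations
#' are mixed before extraction), giving expected channel intensities
#' `E[CL] = S + N * noise_partition` and `E[nCL] = N * (1 - noise_partition)`.
#' Replicates receive multiplicative lognormal noise with coefficient of
#' variation `replicate_cv` (mean-preserving); cells below `detection_floor`
#' are recorded missing; contaminant spike-ins are appended and flagged.
#'
#' Defaults describe a LEAP-like high-specificity capture: 2,000 proteins, 30%
#' RBPs with Beta(2.5, 1.5)-distributed bound fractions, lognormal captured
#' abundances spanning several orders of magnitude, 3 replicates at 20%
#' replicate CV, and non-RBP free-protein recovery at 10% of abundance.
#'
#' @param n_proteins Number of (non-contaminant) proteins.
#' @param rbp_fraction Fraction of proteins that are true RBPs.
#' @param bound_shape1,bound_shape2 Beta parameters of the RBP bound-fraction
#'   distribution.
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of captured
#'   intensity (arbitrary intensity units).
#' @param background_free_protein Free-protein intensity of non-RBPs as a
#'   fraction of their abundance (models method-dependent noise recovery).
#' @param replicate_cv Multiplicative replicate noise CV.
#' @param n_replicates Replicates per channel/condition.
#' @param detection_floor Intensity below which a cell is recorded missing.
#' @param noise_partition Fraction of free protein recovered in the CL channel
#'   (default 0.5 = equal partitioning).
#' @param n_contaminants Number of contaminant spike-in rows.
#' @param condition_labels Labels of the two comparative conditions.
#' @param seed Integer seed; identical (config, seed) pairs produce
#'   bit-identical tables.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 2000, rbp_fraction = 0.3,
                             bound_shape1 = 2.5, bound_shape2 = 1.5,
                             abundance_meanlog = log(1e7),
                             abundance_sdlog = 1.5,
                             background_free_protein = 0.1,
                             replicate_cv = 0.2, n_replicates = 3,
                             detection_floor = 5e4, noise_partition = 0.5,
                             n_contaminants = 10,
                             condition_labels = c("DMSO", "HT"),
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_proteins >= 1, rbp_fraction >= 0, rbp_fraction <= 1,
            bound_shape1 > 0, bound_shape2 > 0, replicate_cv >= 0,
            n_replicates >= 1, noise_partition >= 0, noise_partition <= 1,
            background_free_protein >= 0)
  structure(cfg, class = "generator_config")
}

# mean-preserving multiplicative lognormal noise
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

simulate_truth <- function(config) {
  n <- config$n_proteins
  is_rbp <- seq_len(n) <= round(n * config$rbp_fraction)
  f <- ifelse(is_rbp,
              stats::rbeta(n, config$bound_shape1, config$bound_shape2), 0)
  abundance <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  truth <- tibble::tibble(
    protein_id = sprintf("SYN%05d", seq_len(n)),
    true_abundance = abundance,
    true_bound_fraction = f,
    is_rbp = is_rbp,
    is_contaminant = FALSE,
    occupancy_shift = 0
  )
  if (config$n_contaminants > 0) {
    cont <- tibble::tibble(
      protein_id = sprintf("CONT_KRT%02d_HUMAN", seq_len(config$n_contaminants)),
      true_abundance = stats::rlnorm(config$n_contaminants,
                                     config$abundance_meanlog,
                                     config$abundance_sdlog),
      true_bound_fraction = 0,
      is_rbp = FALSE,
      is_contaminant = TRUE,
      occupancy_shift = 0
    )
    truth <- rbind(truth, cont)
  }
  truth
}

# per-protein signal and noise intensities implied by the truth table
truth_sn <- function(truth, config) {
  S <- truth$true_abundance * truth$true_bound_fraction
  N <- ifelse(truth$is_rbp,
              truth$true_abundance * (1 - truth$true_bound_fraction),
              truth$true_abundance * config$background_free_protein)
  N[truth$is_contaminant] <- truth$true_abundance[truth$is_contaminant]
  list(S = S, N = N)
}

noisy_channel <- function(expected, config) {
  n_rep <- config$n_replicates
  m <- matrix(rep(expected, n_rep), ncol = n_rep) *
    matrix(ln_noise(length(expected) * n_rep, config$replicate_cv), ncol = n_rep)
  m[m < config$detection_floor] <- NA_real_
  m
}

#' Simulate a pooled-channel SILAC RBP-capture experiment
#'
#' Draws a protein population from `config`, forms expected channel
#' intensities under the generator's measurement model (see
#' [generator_config()]), adds replicate noise and missingness, and returns
#' the intensity table together with the generative truth for
#' parameter-recovery testing. With `replicate_cv = 0` and no missingness,
#' [compute_signal_profiles()] recovers `pct_bound` equal to
#' `100 * true_bound_fraction` exactly.
#'
#' @param config A [generator_config()].
#' @return A list with `table` (an [intensity_table()] with `CL` and `nCL`
#'   groups) and `truth` (a tibble of per-protein generative parameters).
#' @export
generate_silac <- function(config = generator_config()) {
  with_seed(config$seed, {
    truth <- simulate_truth(config)
    sn <- truth_sn(truth, config)
    e_cl <- sn$S + sn$N * config$noise_partition
    e_ncl <- sn$N * (1 - config$noise_partition)
    cl <- noisy_channel(e_cl, config)
    ncl <- noisy_channel(e_ncl, config)
    m <- cbind(cl, ncl)
    n_rep <- config$n_replicates
    samples <- data.frame(
      sample_id = c(sprintf("CL_%d", seq_len(n_rep)),
                    sprintf("nCL_%d", seq_len(n_rep))),
      group = rep(c("CL", "nCL"), each = n_rep),
      replicate = rep(seq_len(n_rep), 2),
      stringsAsFactors = FALSE
    )
    proteins <- data.frame(
      protein_id = truth$protein_id,
      gene_name = truth$protein_id,
      unique_peptides = pmax(1L, as.integer(round(
        2 + log10(pmax(truth$true_abundance, 1)) ))),
      contaminant_flag = truth$is_contaminant,
      stringsAsFactors = FALSE
    )
    list(table = intensity_table(m, proteins, samples), truth = truth)
  })
}

#' Simulate a comparative (two-condition) RBP-capture experiment
#'
#' Emulates the comparative design: label-free input (total protein) and
#' clRNP (RNA-bound protein) fractions for two conditions. A random subset of
#' RBPs receives a log2 shift of their RNA-bound quantity `S` in the treatment
#' condition (`occupancy_shift` in the truth table); input fractions reflect
#' total abundance and are unshifted, so occupancy-specific changes are
#' distinguishable from abundance-driven ones by construction. A companion
#' SILAC table drawn from the same truth (control state) is returned for S/N
#' gating.
#'
#' @param config A [generator_config()].
#' @param shifted_fraction Fraction of RBPs (with `S > 0`) given an occupancy
#'   shift.
#' @param shift_log2 The log2 shift applied to `S` in the treatment condition.
#' @return A list with `input` and `clrnp` intensity tables (groups =
#'   `config$condition_labels`), `silac` (companion SILAC table), and `truth`.
#' @export
generate_comparative <- function(config = generator_config(),
                                 shifted_fraction = 0.05, shift_log2 = 1) {
  stopifnot(shifted_fraction >= 0, shifted_fraction <= 1)
  with_seed(config$seed, {
    truth <- simulate_truth(config)
    sn <- truth_sn(truth, config)
    eligible <- which(truth$is_rbp & sn$S > 0)
    n_shift <- round(length(eligible) * shifted_fraction)
    shifted <- sample(eligible, n_shift)
    truth$occupancy_shift[shifted] <- shift_log2

    labels <- config$condition_labels
    n_rep <- config$n_replicates
    make_table <- function(e_ctrl, e_treat) {
      m <- cbind(noisy_channel(e_ctrl, config), noisy_channel(e_treat, config))
      samples <- data.frame(
        sample_id = c(sprintf("%s_%d", labels[1], seq_len(n_rep)),
                      sprintf("%s_%d", labels[2], seq_len(n_rep))),
        group = rep(labels, each = n_rep),
        replicate = rep(seq_len(n_rep), 2),
        stringsAsFactors = FALSE
      )
      proteins <- data.frame(
        protein_id = truth$protein_id,
        gene_name = truth$protein_id,
        unique_peptides = pmax(2L, as.integer(round(
          2 + log10(pmax(truth$true_abundance, 1)) ))),
        contaminant_flag = truth$is_contaminant,
        stringsAsFactors = FALSE
      )
      intensity_table(m, proteins, samples)
    }
    # input: total protein, shift-free
    input <- make_table(truth$true_abundance, truth$true_abundance)
    # clRNP: the captured fraction, RNA-bound signal plus residual free protein
    e_ctrl <- sn$S + sn$N
    e_treat <- sn$S * 2^truth$occupancy_shift + sn$N
    clrnp <- make_table(e_ctrl, e_treat)
    # companion SILAC experiment in the control state
    cl <- noisy_channel(sn$S + sn$N * config$noise_partition, config)
    ncl <- noisy_channel(sn$N * (1 - config$noise_partition), config)
    silac_samples <- data.frame(
      sample_id = c(sprintf("CL_%d", seq_len(n_rep)),
                    sprintf("nCL_%d", seq_len(n_rep))),
      group = rep(c("CL", "nCL"), each = n_rep),
      replicate = rep(seq_len(n_rep), 2),
      stringsAsFactors = FALSE
    )
    silac <- intensity_table(cbind(cl, ncl),
                             data.frame(
                               protein_id = truth$protein_id,
                               gene_name = truth$protein_id,
                               unique_peptides = 2L,
                               contaminant_flag = truth$is_contaminant,
                               stringsAsFactors = FALSE
                             ),
                             silac_samples)
    list(input = input, clrnp = clrnp, silac = silac, truth = truth)
  })
}
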