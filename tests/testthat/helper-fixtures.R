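# Builders for small in-code fixtures.

# SILAC table from explicit CL / nCL replicate matrices (proteins x reps)
make_silac_table <- function(cl, ncl, protein_id = NULL, unique_peptides = 3L,
                             contaminant_flag = FALSE) {
  cl <- rbind(cl); ncl <- rbind(ncl)
  n <- nrow(cl)
  if (is.null(protein_id)) protein_id <- sprintf("P%03d", seq_len(n))
  proteins <- data.frame(
    protein_id = protein_id, gene_name = protein_id,
    unique_peptides = rep_len(unique_peptides, n),
    contaminant_flag = rep_len(contaminant_flag, n),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = c(sprintf("CL_%d", seq_len(ncol(cl))),
                  sprintf("nCL_%d", seq_len(ncol(ncl)))),
    group = rep(c("CL", "nCL"), c(ncol(cl), ncol(ncl))),
    replicate = c(seq_len(ncol(cl)), seq_len(ncol(ncl))),
    stringsAsFactors = FALSE
  )
  intensity_table(cbind(cl, ncl), proteins, samples)
}

# two-condition label-free table from per-condition matrices
make_comparative_table <- function(a, b, groups = c("DMSO", "HT"),
                                   protein_id = NULL, unique_peptides = 3L) {
  a <- rbind(a); b <- rbind(b)
  n <- nrow(a)
  if (is.null(protein_id)) protein_id <- sprintf("P%03d", seq_len(n))
  proteins <- data.frame(
    protein_id = protein_id, gene_name = protein_id,
    unique_peptides = rep_len(unique_peptides, n),
    contaminant_flag = FALSE, stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = c(sprintf("%s_%d", groups[1], seq_len(ncol(a))),
                  sprintf("%s_%d", groups[2], seq_len(ncol(b)))),
    group = rep(groups, c(ncol(a), ncol(b))),
    replicate = c(seq_len(ncol(a)), seq_len(ncol(b))),
    stringsAsFactors = FALSE
  )
  intensity_table(cbind(a, b), proteins, samples)
}

# constant signal profiles for proteins with given log2(S/N) via SPI choice:
# S/N = s2n  =>  CL/nCL = 2*s2n + 1
profiles_from_s2n <- function(s2n, scale = 1e6) {
  ncl <- rep(scale, length(s2n))
  cl <- (2 * s2n + 1) * ncl
  x <- make_silac_table(matrix(rep(cl, 3), ncol = 3),
                        matrix(rep(ncl, 3), ncol = 3))
  compute_signal_profiles(x)
}

# literal step-up definition, independent of stats::p.adjust:
# q_i = min over sorted p_(j) >= p_i of min(1, m * p_(j) / j)
bh_brute_force <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    j <- which(sp >= pi)
    min(1, min(m * sp[j] / j))
  }, numeric(1))
}

expect_permutation <- function(ranks, n) {
  expect_setequal(ranks, seq_len(n))
}
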