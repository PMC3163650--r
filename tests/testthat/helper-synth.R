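# Small configurations used across test files.

# Tiny noiseless configuration: all nuisance effects off, no planted DE.
cfg_clean <- function(seed = 1, n_probes = 96, ...) {
  synth_config(seed = seed, n_probes = n_probes, n_subarrays = 4,
               n_arrays_per_region = 4, n_de_probes = 0,
               dye_bias_amplitude = 0, subarray_sd = 0, noise_sd = 0,
               sc_noise_sd = 0, sc_scale_sd = 0, cp_sd = 0, ...)
}

# Small noisy configuration with planted effects.
cfg_small <- function(seed = 1, ...) {
  synth_config(seed = seed, n_probes = 480, n_subarrays = 4,
               n_arrays_per_region = 6, n_de_probes = 20, ...)
}

# One-sample |t| statistic used by brute-force permutation oracles.
abs_t <- function(x) abs(mean(x)) / (sd(x) / sqrt(length(x)))

# Plain-R brute-force step-down maxT over an explicit sign matrix.
# Enumerates flips with nested loops, independent of the package kernel.
brute_maxt <- function(m, S) {
  tobs <- apply(m, 1, abs_t)
  ordA <- order(tobs)
  cnt <- numeric(nrow(m))
  for (b in seq_len(nrow(S))) {
    run <- -Inf
    for (j in ordA) {
      tb <- abs_t(m[j, ] * S[b, ])
      run <- max(run, tb)
      if (run >= tobs[j]) cnt[j] <- cnt[j] + 1
    }
  }
  p <- (1 + cnt) / (1 + nrow(S))  # add-one convention
  o <- order(tobs, decreasing = TRUE)
  p[o] <- cummax(p[o])
  pmin(p, 1)
}

all_sign_rows <- function(n) as.matrix(expand.grid(rep(list(c(-1, 1)), n)))

# Toy two-exon plus-strand gene model: exon1 101..150, exon2 201..260,
# promoter 100 bp, DER 50 bp, CDS spanning mRNA 11..100.
toy_model <- function(cds_seq = NULL) {
  gene_model(chrom = "chrT", strand = "+",
             exons = tibble::tibble(start = c(101, 201), end = c(150, 260)),
             promoter_span = 100, der_span = 50,
             cds_start = 11L, cds_len = 90L, cds_seq = cds_seq)
}
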