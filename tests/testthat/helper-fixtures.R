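# Shared fixtures: small simulation configs and hand-built tables.

# a compact two-platform scenario for fast pipeline tests
tiny_config <- function(seed = 1, n_samples = 40, n_assays = 4,
                        angle_a = 0.19, angle_b = 0.30,
                        noise_a = 0.10, noise_b = 0.10,
                        fail_rate = 0.05, invalid_rate = 0.01) {
  pa <- platform_profile("alpha", gain = 2, angle_a11 = angle_a,
                         angle_a22 = pi / 2 - angle_a,
                         noise_sd = noise_a, fail_rate = fail_rate,
                         invalid_rate = invalid_rate,
                         ntc_center = c(0.2, 0.2), ntc_sd = 0.03)
  pb <- platform_profile("beta", gain = 3, angle_a11 = angle_b,
                         angle_a22 = pi / 2 - angle_b,
                         noise_sd = noise_b, fail_rate = fail_rate,
                         invalid_rate = invalid_rate,
                         ntc_center = c(0.3, 0.3), ntc_sd = 0.045)
  sim_config(list(pa, pb), n_samples = n_samples, n_ntc = 2,
             n_assays = n_assays, maf = 0.35, seed = seed)
}

# one noiseless platform: every called well sits exactly on its centroid
noiseless_config <- function(seed = 1, n_samples = 60, n_assays = 2,
                             gain = 2.5, angle_a11 = 0.25) {
  p <- platform_profile("pure", gain = gain, angle_a11 = angle_a11,
                        angle_a22 = pi / 2 - angle_a11, noise_sd = 0,
                        fail_rate = 0, invalid_rate = 0,
                        ntc_center = c(0.5, 0.4), ntc_sd = 0)
  sim_config(list(p), n_samples = n_samples, n_ntc = 2,
             n_assays = n_assays, maf = 0.4, seed = seed)
}

# oracle call table derived from the planted truth of one experiment
truth_calls <- function(exp, platform_id) {
  tr <- exp$truth
  oc <- tr[[paste0("outcome_", platform_id)]]
  lab <- ifelse(oc == "called", tr$true_genotype,
                ifelse(oc == "failed", "FAILED", "INVALID"))
  data.frame(sample_id = tr$sample_id, assay_id = tr$assay_id,
             platform_id = platform_id, label = lab,
             quality = ifelse(oc == "called", 1, NA_real_),
             stringsAsFactors = FALSE)
}

# hand-built call table with given per-platform label counts
calls_with_counts <- function(platform_id, n_called, n_failed,
                              n_invalid) {
  lab <- c(rep("A11", n_called), rep("FAILED", n_failed),
           rep("INVALID", n_invalid))
  n <- length(lab)
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             assay_id = "ASSAY01", platform_id = platform_id,
             label = lab,
             quality = ifelse(lab == "A11", 0.99, NA_real_),
             stringsAsFactors = FALSE)
}
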