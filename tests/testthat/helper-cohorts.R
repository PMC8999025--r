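# shared cohort builders for the statistical tests

block_truth <- function(within_r, between_r = 0.3)
  make_block_correlation(within_r = within_r, between_r = between_r)

# paired cohort of oxy-Hb recordings (no optical forward model), returning
# per-subject pre/post connectivity matrices
cohort_cor_mats <- function(n, truth_pre, truth_post, duration_s, seed,
                            noise = noise_spec(), fs = 7.4074) {
  coh <- generate_paired_cohort(n, truth_pre, truth_post,
                                duration_s = duration_s, fs = fs,
                                noise = noise, seed = seed)
  list(pre = lapply(coh$subjects, function(s) cor_matrix(s$pre)),
       post = lapply(coh$subjects, function(s) cor_matrix(s$post)))
}
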