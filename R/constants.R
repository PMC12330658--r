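# Canonical covariate column order used across the package.  Every variant
# table carries exactly these six covariates, in this order, plus gene_id
# and optional label/score columns.
COVARIATE_NAMES <- c("AF", "LOEUF", "CCR", "FDR_TADA_DD", "obs_lof", "exp_lof")
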