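# Covariate profiles: label-conditional sampling distributions for the six
# covariates used by ClassDn.  De novo variants have lower allele frequency,
# lower LOEUF, higher CCR, lower FDR_TADA_DD, lower obs_lof and higher
# exp_lof than inherited variants; the default parameters put roughly one
# standardized mean difference between the classes per covariate.

#' Construct a distribution specification
#'
#' @param family one of `"lnorm_trunc"` (log-normal truncated above),
#'   `"beta_scaled"` (Beta rescaled to `[0, max]`), `"norm_trunc"`
#'   (normal truncated to `[lower, upper]`), `"pois"`, `"gamma"`.
#' @param ... family parameters (see `sample_dist`).
#' @return A list of class `dist_spec`.
#' @export
dist_spec <- function(family, ...) {
  structure(c(list(family = family), list(...)), class = "dist_spec")
}

# Inverse-CDF samplers so that truncation is exact (no rejection loops).
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    lnorm_trunc = {
      pmax <- plnorm(spec$upper, spec$meanlog, spec$sdlog)
      qlnorm(runif(n, 0, pmax), spec$meanlog, spec$sdlog)
    },
    beta_scaled = spec$max * rbeta(n, spec$shape1, spec$shape2),
    norm_trunc = {
      lo <- pnorm(spec$lower, spec$mean, spec$sd)
      hi <- pnorm(spec$upper, spec$mean, spec$sd)
      qnorm(runif(n, lo, hi), spec$mean, spec$sd)
    },
    pois = rpois(n, spec$lambda),
    gamma = rgamma(n, shape = spec$shape, rate = spec$rate),
    stop("unknown distribution family: ", spec$family)
  )
}

#' Construct a covariate profile
#'
#' A profile holds the label-conditional sampling distributions for one
#' covariate: one distribution for de novo variants and one for inherited
#' variants.
#'
#' @param name covariate name, one of `AF`, `LOEUF`, `CCR`, `FDR_TADA_DD`,
#'   `obs_lof`, `exp_lof`.
#' @param denovo,inherited `dist_spec` objects for the two inheritance
#'   classes.
#' @return A list of class `covariate_profile`.
#' @export
covariate_profile <- function(name, denovo, inherited) {
  if (!name %in% COVARIATE_NAMES)
    stop("unknown covariate name: ", name)
  structure(list(name = name, denovo = denovo, inherited = inherited),
            class = "covariate_profile")
}

#' Default covariate profiles
#'
#' Label-conditional distributions for the six ClassDn covariates.  Choices
#' respect the legal ranges (AF in \[0, 0.001\] after the ultra-rare filter,
#' CCR percentile in \[0, 100\], FDR in \[0, 1\], obs_lof a count,
#' exp_lof positive) and separate the classes in the directions seen in
#' family data: de novo variants are rarer, fall in more constrained genes
#' (lower LOEUF, fewer observed LoF against a larger expectation) and in more
#' constrained regions (higher CCR), and in genes already implicated in
#' developmental delay (lower FDR_TADA_DD).
#'
#' @return Named list of six `covariate_profile` objects.
#' @examples
#' prof <- covariate_profiles()
#' names(prof)
#' @export
covariate_profiles <- function() {
  list(
    AF = covariate_profile("AF",
      denovo    = dist_spec("lnorm_trunc", meanlog = log(2e-6), sdlog = 1.2, upper = 0.001),
      inherited = dist_spec("lnorm_trunc", meanlog = log(8e-5), sdlog = 1.2, upper = 0.001)),
    LOEUF = covariate_profile("LOEUF",
      denovo    = dist_spec("beta_scaled", shape1 = 2, shape2 = 6, max = 2),
      inherited = dist_spec("beta_scaled", shape1 = 4, shape2 = 4, max = 2)),
    CCR = covariate_profile("CCR",
      denovo    = dist_spec("norm_trunc", mean = 75, sd = 25, lower = 0, upper = 100),
      inherited = dist_spec("norm_trunc", mean = 45, sd = 25, lower = 0, upper = 100)),
    FDR_TADA_DD = covariate_profile("FDR_TADA_DD",
      denovo    = dist_spec("beta_scaled", shape1 = 1.5, shape2 = 4.5, max = 1),
      inherited = dist_spec("beta_scaled", shape1 = 4.5, shape2 = 1.5, max = 1)),
    obs_lof = covariate_profile("obs_lof",
      denovo    = dist_spec("pois", lambda = 3),
      inherited = dist_spec("pois", lambda = 12)),
    exp_lof = covariate_profile("exp_lof",
      denovo    = dist_spec("gamma", shape = 8, rate = 0.4),
      inherited = dist_spec("gamma", shape = 8, rate = 0.8))
  )
}

# Draw an n x 6 covariate matrix conditional on per-variant labels.
sample_covariates <- function(labels, profiles) {
  n <- length(labels)
  out <- matrix(NA_real_, n, length(COVARIATE_NAMES),
                dimnames = list(NULL, COVARIATE_NAMES))
  idx_dn <- which(labels == 1L)
  idx_in <- which(labels == 0L)
  for (nm in COVARIATE_NAMES) {
    p <- profiles[[nm]]
    if (is.null(p)) stop("profiles must cover covariate ", nm)
    if (length(idx_dn)) out[idx_dn, nm] <- sample_dist(p$denovo, length(idx_dn))
    if (length(idx_in)) out[idx_in, nm] <- sample_dist(p$inherited, length(idx_in))
  }
  as.data.frame(out)
}
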