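#' Planted-effect specification for synthetic cohorts
#'
#' Describes the signal covariates of a simulated cohort: each row names a
#' variable, its kind, its planted log-effects on the cured-fraction
#' parameter (`alpha`, acting on `theta`) and on the event dynamics
#' (`beta`, acting on `H`), and a distribution parameter `par` (prevalence
#' for `binary`, minor allele frequency for `genotype012`, standard
#' deviation for `continuous`).
#'
#' @param name Variable names.
#' @param kind `"binary"`, `"genotype012"` or `"continuous"` (recycled).
#' @param alpha,beta Planted log-effects (recycled; the empty/null spec is
#'   `signal_spec()` with no arguments).
#' @param par Distribution parameter (recycled; defaults: prevalence 0.5,
#'   MAF 0.3, sd 1).
#' @return A tibble with one row per signal variable.
#' @export
signal_spec <- function(name = character(0), kind = "binary", alpha = 0,
                        beta = 0, par = NA_real_) {
  if (!length(name)) {
    return(tibble::tibble(name = character(0), kind = character(0),
                          alpha = numeric(0), beta = numeric(0),
                          par = numeric(0)))
  }
  out <- tibble::tibble(name = name, kind = rep_len(kind, length(name)),
                        alpha = rep_len(alpha, length(name)),
                        beta = rep_len(beta, length(name)),
                        par = rep_len(par, length(name)))
  stopifnot(all(out$kind %in% c("binary", "genotype012", "continuous")),
            all(is.finite(out$alpha)), all(is.finite(out$beta)))
  defaults <- c(binary = 0.5, genotype012 = 0.3, continuous = 1)
  out$par <- ifelse(is.na(out$par), defaults[out$kind], out$par)
  out
}

#' Hardy-Weinberg noise genotypes
#'
#' For each of `p` pseudo-SNPs a minor allele frequency `q` is drawn
#' uniformly on `maf_range`, then `n` genotypes are drawn i.i.d. with the
#' Hardy-Weinberg probabilities `((1-q)^2, 2q(1-q), q^2)` for 0/1/2
#' alternative alleles.  These are the non-informative variables used to
#' drown the signal in the high-dimensional benchmarks.
#'
#' @param n Number of subjects.
#' @param p Number of noise SNPs.
#' @param maf_range Range for the uniform MAF draw; must lie in
#'   `(0, 0.5]`.  The default (0.25, 0.4) keeps every noise SNP past the
#'   common-variant MAF filter.
#' @param seed Optional integer seed.
#' @param prefix Column-name prefix.
#' @return An `n` x `p` tibble of 0/1/2 genotypes (kind `genotype012`).
#' @export
generate_noise_snps <- function(n, p, maf_range = c(0.25, 0.4), seed = NULL,
                                prefix = "snp") {
  stopifnot(n >= 1, p >= 1, length(maf_range) == 2,
            maf_range[1] <= maf_range[2])
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("generate_noise_snps: maf_range must lie in (0, 0.5]")
  }
  draw <- function() {
    q <- stats::runif(p, maf_range[1], maf_range[2])
    matrix(stats::rbinom(n * p, 2L, rep(q, each = n)), n, p)
  }
  g <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  colnames(g) <- sprintf("%s%0*d", prefix, max(4, nchar(p)), seq_len(p))
  tibble::as_tibble(g)
}

#' Simulate a cure-model cohort with planted signal covariates
#'
#' Draws the covariates of `spec`, forms the per-subject linear predictors
#' `eta_alpha = sum(alpha_k x_k)` and `eta_beta = sum(beta_k x_k)`, and
#' simulates outcomes from the Poisson-clone mechanism with clone mean
#' `theta0 * exp(eta_alpha)` and dynamics `H0(t) * exp(eta_beta)`, censored
#' administratively at `horizon`.  Optionally appends Hardy-Weinberg noise
#' genotypes.
#'
#' @param n Number of subjects.
#' @param spec A [signal_spec()] (the empty spec gives a pure-null cohort).
#' @param theta0 Baseline clone mean; baseline cured fraction is
#'   `exp(-theta0)`.
#' @param h0 Baseline hazard (parametric, for inversion).
#' @param horizon Administrative censoring time (12-month analogue);
#'   `Inf` disables censoring.
#' @param dropout Optional rate of independent uniform dropout on
#'   `(0, horizon)`: each subject is additionally censored at a
#'   `U(0, horizon)` time with this probability.
#' @param n_noise Number of appended noise SNPs.
#' @param maf_range MAF range for the noise SNPs.
#' @param seed Optional integer seed.
#' @param latent Export the latent clone count (`n_clones` column; test
#'   oracles only).
#' @return A [as_cohort()] cohort with `time`, `event` and the predictors.
#' @export
generate_cure_cohort <- function(n, spec = signal_spec(), theta0 = log(2),
                                 h0 = weibull_hazard(), horizon = Inf,
                                 dropout = 0, n_noise = 0,
                                 maf_range = c(0.25, 0.4), seed = NULL,
                                 latent = FALSE) {
  stopifnot(n >= 1, is.data.frame(spec), theta0 > 0,
            dropout >= 0, dropout <= 1)
  draw <- function() {
    covs <- lapply(seq_len(nrow(spec)), function(k) {
      switch(spec$kind[k],
        binary = stats::rbinom(n, 1L, spec$par[k]),
        genotype012 = stats::rbinom(n, 2L, spec$par[k]),
        continuous = stats::rnorm(n, 0, spec$par[k]))
    })
    X <- if (length(covs)) do.call(cbind, covs) else
      matrix(0, n, 0)
    eta_a <- if (ncol(X)) drop(X %*% spec$alpha) else rep(0, n)
    eta_b <- if (ncol(X)) drop(X %*% spec$beta) else rep(0, n)
    censor <- rep(horizon, n)
    if (dropout > 0 && is.finite(horizon)) {
      hit <- stats::runif(n) < dropout
      censor[hit] <- stats::runif(sum(hit), 0, horizon)
    }
    out <- simulate_promotion_times(theta0 * exp(eta_a), eta_b, h0,
                                    censor, latent = latent)
    if (nrow(spec)) {
      colnames(X) <- spec$name
      out <- dplyr::bind_cols(out, tibble::as_tibble(X))
    }
    if (n_noise > 0) {
      out <- dplyr::bind_cols(out,
        generate_noise_snps(n, n_noise, maf_range))
    }
    out
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  kinds <- stats::setNames(spec$kind, spec$name)
  if (n_noise > 0) {
    snp_cols <- setdiff(names(out), c("time", "event", "n_clones",
                                      spec$name))
    kinds <- c(kinds, stats::setNames(rep("genotype012", length(snp_cols)),
                                      snp_cols))
  }
  co <- as_cohort(out[, setdiff(names(out), "n_clones")], kinds = kinds)
  if (latent) co$n_clones_latent <- out$n_clones
  co
}

# Variable layout of the PBC-like fixture: 17 covariates mimicking the
# Mayo PBC trial panel (quartile-coded labs, binaries, ordered edema and
# stage), with heterogeneous planted effects on a shared linear predictor.
pbc_like_layout <- function() {
  tibble::tribble(
    ~name,        ~kind,        ~coef, ~par,
    "trt",        "binary",      0.00, 0.49,
    "age_q",      "continuous",  0.48, NA,
    "sex",        "binary",     -0.32, 0.88,
    "ascites",    "binary",      1.44, 0.08,
    "hepato",     "binary",      0.48, 0.51,
    "spiders",    "binary",      0.48, 0.29,
    "edema",      "ordered3",    0.80, NA,
    "bili_q",     "continuous",  1.04, NA,
    "chol_q",     "continuous",  0.16, NA,
    "albumin_q",  "continuous", -0.72, NA,
    "copper_q",   "continuous",  0.56, NA,
    "alk_q",      "continuous",  0.16, NA,
    "ast_q",      "continuous",  0.32, NA,
    "trig_q",     "continuous",  0.00, NA,
    "platelet_q", "continuous", -0.16, NA,
    "protime_q",  "continuous",  0.56, NA,
    "stage",      "continuous",  0.64, NA)
}

#' PBC-like high-dimensional benchmark cohort
#'
#' A synthetic stand-in for the 312-patient randomised subset of the Mayo
#' Primary Biliary Cirrhosis trial as used in tree-ensemble benchmarks:
#' 17 covariates (quartile-coded laboratory values, binaries, ordered
#' edema and histologic stage) with heterogeneous planted effects, event
#' and censoring levels calibrated to the PBC trial's roughly 40% death /
#' 60% censoring split, optionally augmented with Hardy-Weinberg noise
#' genotypes via `n_noise`.  The real PBC data are not bundled; this
#' fixture reproduces the design (dimensions, variable kinds, censoring
#' level), not the joint distribution of the original covariates.
#'
#' Outcomes follow the Poisson-clone cure mechanism with clone mean
#' `theta0 * exp(L)` and dynamics `H0(t) * exp(0.4 L)`, where `L` is the
#' centred linear predictor over the signal covariates.
#'
#' @param n Number of subjects (default 312).
#' @param n_noise Number of appended noise SNPs (0 for the bare fixture;
#'   the full-scale benchmark design uses 50,000).
#' @param seed Optional integer seed.
#' @param maf_range MAF range for the noise SNPs.
#' @return A [as_cohort()] cohort with `time`, `event` and 17 + `n_noise`
#'   predictors.
#' @export
generate_pbc_like <- function(n = 312, n_noise = 0, seed = NULL,
                              maf_range = c(0.25, 0.4)) {
  lay <- pbc_like_layout()
  theta0 <- 0.45   # calibrated: ~40% events at the 1-unit horizon
  draw <- function() {
    covs <- lapply(seq_len(nrow(lay)), function(k) {
      switch(lay$kind[k],
        binary = stats::rbinom(n, 1L, lay$par[k]),
        ordered3 = sample.int(3L, n, replace = TRUE,
                              prob = c(0.84, 0.10, 0.06)),
        continuous = sample.int(4L, n, replace = TRUE))
    })
    X <- do.call(cbind, covs)
    colnames(X) <- lay$name
    # centre on the design means so L has mean ~0 by construction
    mu <- ifelse(lay$kind == "binary", lay$par,
                 ifelse(lay$kind == "ordered3", 1.22, 2.5))
    L <- drop(sweep(X, 2, mu) %*% lay$coef)
    out <- simulate_promotion_times(theta0 * exp(L), 0.4 * L,
                                    weibull_hazard(), censor_time = 1)
    dplyr::bind_cols(out, tibble::as_tibble(X))
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  kinds <- stats::setNames(lay$kind, lay$name)
  if (n_noise > 0) {
    snps <- generate_noise_snps(n, n_noise, maf_range,
                                seed = if (is.null(seed)) NULL else
                                  seed + 1L)
    kinds <- c(kinds, stats::setNames(rep("genotype012", n_noise),
                                      names(snps)))
    out <- dplyr::bind_cols(out, snps)
  }
  as_cohort(out, kinds = kinds)
}
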