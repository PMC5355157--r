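# Seeded generators for multi-study case-control expression data,
# correlated gene blocks with negative hubs, and proportional-hazards
# survival cohorts. Every generator is a pure function of its arguments
# including the seed, and returns the planted truth alongside the data.

new_sim_truth <- function(de_features = setNames(numeric(0), character(0)),
                          block_assignments = integer(0),
                          negative_hubs = character(0),
                          signature_genes = character(0),
                          signature_betas = numeric(0),
                          ...) {
  structure(list(de_features = de_features,
                 block_assignments = block_assignments,
                 negative_hubs = negative_hubs,
                 signature_genes = signature_genes,
                 signature_betas = signature_betas,
                 ...),
            class = "sim_truth")
}

#' Simulate a tumor/normal case-control expression study
#'
#' Generates a log2-scale features x samples matrix. Background features
#' are a per-feature baseline (uniform on 4-12 log2 units, the typical
#' microarray intensity range) plus Gaussian noise in both classes. A
#' fraction `de_fraction` of features is planted as differentially
#' expressed: the tumor mean is shifted by a signed log2 fold change with
#' magnitude `effect_lfc` plus an exponential excess (mean 0.25), the sign
#' up/down with equal probability. The planted count is
#' `floor(n_features * de_fraction)`, with the fractional remainder
#' resolved by one seeded Bernoulli draw.
#'
#' @param n_features,n_tumor,n_normal Dimensions (all >= 1).
#' @param de_fraction Fraction of features planted as DE, in \[0, 1\].
#' @param effect_lfc Minimum |log2 fold change| of planted features (> 0).
#' @param noise_sd Within-class Gaussian noise standard deviation (> 0).
#' @param seed Integer seed; identical seed gives bit-identical output.
#' @return List with `matrix` (an [expr_matrix]) and `truth` (a
#'   `sim_truth` whose `de_features` is a named vector of planted signed
#'   log2 fold changes).
#' @export
simulate_case_control <- function(n_features, n_tumor, n_normal,
                                  de_fraction = 0.1, effect_lfc = 1.5,
                                  noise_sd = 0.3, seed) {
  stopifnot(n_features >= 1)
  if (n_tumor < 1 || n_normal < 1) stop("sample counts must be positive")
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  stopifnot(effect_lfc > 0, noise_sd > 0)
  with_seed(seed, {
    fid <- sprintf("g%05d", seq_len(n_features))
    baseline <- setNames(runif(n_features, 4, 12), fid)
    n_de <- floor(n_features * de_fraction)
    rem <- n_features * de_fraction - n_de
    if (rem > 0 && runif(1) < rem) n_de <- n_de + 1
    de_idx <- if (n_de > 0) sort(sample.int(n_features, n_de)) else integer(0)
    lfc <- numeric(0)
    if (n_de > 0) {
      sign <- sample(c(-1, 1), n_de, replace = TRUE)
      lfc <- setNames(sign * (effect_lfc + rexp(n_de, rate = 4)),
                      fid[de_idx])
    }
    truth <- new_sim_truth(
      de_features = lfc,
      block_assignments = setNames(rep(0L, n_features), fid),
      baseline = baseline, noise_sd = noise_sd, effect_lfc = effect_lfc)
    mat <- .draw_case_control(truth, n_tumor, n_normal, shift = NULL,
                              sample_prefix = "")
    list(matrix = mat, truth = truth)
  })
}

# Draw one study from a shared truth; `shift` is an optional per-feature
# batch offset added to both classes.
.draw_case_control <- function(truth, n_tumor, n_normal, shift = NULL,
                               sample_prefix = "") {
  fid <- names(truth$baseline)
  nf <- length(fid)
  ns <- n_tumor + n_normal
  mu <- truth$baseline
  if (!is.null(shift)) mu <- mu + shift
  vals <- matrix(rnorm(nf * ns, sd = truth$noise_sd), nf, ns) + mu
  cls <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  if (length(truth$de_features))
    vals[match(names(truth$de_features), fid), cls == "tumor"] <-
      vals[match(names(truth$de_features), fid), cls == "tumor",
           drop = FALSE] + truth$de_features
  dimnames(vals) <- list(fid, paste0(sample_prefix,
                                     c(paste0("tumor_", seq_len(n_tumor)),
                                       paste0("normal_", seq_len(n_normal)))))
  expr_matrix(vals, sample_class = cls)
}

#' Simulate several case-control studies sharing one DE truth
#'
#' Each study shares the planted differential-expression truth (identical
#' features, effect sizes, and signs) but receives its own additive
#' per-feature baseline shift -- a simple batch effect -- drawn with
#' standard deviation `study_shift_sd`, plus an independent noise
#' realization. This makes cross-study consensus non-trivial while keeping
#' the direction of every planted effect consistent.
#'
#' @param k_studies Number of studies (>= 2).
#' @param shared_truth `sim_truth` from [simulate_case_control()].
#' @param per_study_sizes List of length `k_studies` of `c(n_tumor,
#'   n_normal)` pairs.
#' @param study_shift_sd SD of the per-study per-feature baseline shift
#'   (0 = studies differ only by noise realization).
#' @param seed Integer seed.
#' @return List of [expr_matrix] objects, one per study.
#' @export
simulate_multistudy <- function(k_studies, shared_truth, per_study_sizes,
                                study_shift_sd = 0.5, seed) {
  stopifnot(k_studies >= 2, inherits(shared_truth, "sim_truth"))
  if (length(per_study_sizes) == 0) stop("empty study size list")
  if (length(per_study_sizes) != k_studies)
    stop("per_study_sizes must have one entry per study")
  nf <- length(shared_truth$baseline)
  with_seed(seed, {
    lapply(seq_len(k_studies), function(s) {
      sz <- per_study_sizes[[s]]
      shift <- if (study_shift_sd > 0) rnorm(nf, 0, study_shift_sd)
               else rep(0, nf)
      .draw_case_control(shared_truth, sz[1], sz[2], shift = shift,
                         sample_prefix = sprintf("s%d_", s))
    })
  })
}

#' Simulate correlated gene blocks with negative-hub genes
#'
#' Features inside a block follow a one-factor Gaussian model: each block
#' has a latent per-sample factor, and members load on it with
#' `sqrt(within_rho)`, giving pairwise population correlation
#' `within_rho`. Background features are independent noise. Each negative
#' hub loads on the factor of `hub_block` with a negative weight chosen so
#' its population correlation with block members is `hub_rho` (this
#' requires `|hub_rho| <= sqrt(within_rho)`). All features sit on a log2
#' baseline of 7 with unit marginal variance.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param n_background Number of independent background features.
#' @param within_rho Within-block pairwise correlation, in (0, 1).
#' @param n_samples Number of samples.
#' @param n_negative_hubs Number of anti-correlated hub genes.
#' @param hub_rho Target hub-to-member correlation (< 0 when hubs exist).
#' @param hub_block Index of the block the hubs oppose.
#' @param seed Integer seed.
#' @return List with `matrix` ([expr_matrix]) and `truth` (`sim_truth`
#'   with `block_assignments` and `negative_hubs`; hubs and background are
#'   assigned block 0).
#' @export
simulate_correlated_blocks <- function(block_sizes, n_background,
                                       within_rho, n_samples,
                                       n_negative_hubs = 0, hub_rho = -0.7,
                                       hub_block = 1, seed) {
  stopifnot(length(block_sizes) >= 1, all(block_sizes >= 2),
            n_background >= 0, n_samples >= 2)
  if (!(within_rho > 0 && within_rho < 1))
    stop("within_rho must be in (0, 1)")
  if (n_negative_hubs > 0) {
    if (abs(hub_rho) >= 1) stop("|hub_rho| must be < 1")
    if (hub_rho >= 0) stop("hub_rho must be negative when hubs are requested")
    if (abs(hub_rho) > sqrt(within_rho))
      stop("|hub_rho| cannot exceed sqrt(within_rho) under the one-factor model")
    if (hub_block < 1 || hub_block > length(block_sizes))
      stop("hub_block out of range")
  }
  nb <- length(block_sizes)
  with_seed(seed, {
    factors <- matrix(rnorm(nb * n_samples), nb, n_samples)
    rows <- list()
    assign <- integer(0)
    for (b in seq_len(nb)) {
      k <- block_sizes[b]
      load <- sqrt(within_rho)
      m <- load * matrix(factors[b, ], k, n_samples, byrow = TRUE) +
        sqrt(1 - within_rho) * matrix(rnorm(k * n_samples), k, n_samples)
      rownames(m) <- sprintf("b%d_g%03d", b, seq_len(k))
      rows[[length(rows) + 1]] <- m
      assign <- c(assign, setNames(rep(b, k), rownames(m)))
    }
    if (n_negative_hubs > 0) {
      a <- hub_rho / sqrt(within_rho)
      m <- a * matrix(factors[hub_block, ], n_negative_hubs, n_samples,
                      byrow = TRUE) +
        sqrt(1 - a^2) * matrix(rnorm(n_negative_hubs * n_samples),
                               n_negative_hubs, n_samples)
      rownames(m) <- sprintf("hub_g%03d", seq_len(n_negative_hubs))
      rows[[length(rows) + 1]] <- m
      assign <- c(assign, setNames(rep(0L, n_negative_hubs), rownames(m)))
    }
    if (n_background > 0) {
      m <- matrix(rnorm(n_background * n_samples), n_background, n_samples)
      rownames(m) <- sprintf("bg_g%03d", seq_len(n_background))
      rows[[length(rows) + 1]] <- m
      assign <- c(assign, setNames(rep(0L, n_background), rownames(m)))
    }
    vals <- do.call(rbind, rows) + 7
    colnames(vals) <- sprintf("s%04d", seq_len(n_samples))
    truth <- new_sim_truth(
      block_assignments = assign,
      negative_hubs = if (n_negative_hubs > 0)
        grep("^hub_", names(assign), value = TRUE) else character(0),
      hub_block = hub_block, within_rho = within_rho, hub_rho = hub_rho)
    list(matrix = expr_matrix(vals), truth = truth)
  })
}

#' Simulate survival outcomes under a Weibull proportional-hazards model
#'
#' Event times are drawn from a Weibull baseline with the per-patient
#' hazard multiplied by `exp(lp)`, where the linear predictor
#' `lp = sum_g beta_g * x_g` is centered across the cohort (centering only
#' rescales the baseline; hazard ratios are unchanged). Censoring is
#' independent exponential, with rate solved numerically so the expected
#' censored fraction over the drawn event times equals `censor_rate`.
#' Recorded time is the minimum of event and censoring time; ties count as
#' events.
#'
#' @param expression An [expr_matrix] over the cohort patients.
#' @param signature_genes Genes driving the hazard (must be rows of
#'   `expression`); may be empty for a null cohort.
#' @param signature_betas True log-hazard coefficients, one per gene.
#' @param baseline_shape,baseline_scale Weibull shape and scale (> 0);
#'   time units are arbitrary but consistent (defaults roughly resemble
#'   relapse times in years).
#' @param censor_rate Target censored fraction, in \[0, 1).
#' @param seed Integer seed.
#' @param covariates Optional clinical covariate data.frame attached to
#'   the cohort (not used in generation).
#' @return A [survival_cohort]; its `truth` attribute records the planted
#'   genes and betas.
#' @export
simulate_survival <- function(expression, signature_genes, signature_betas,
                              baseline_shape = 1.5, baseline_scale = 5,
                              censor_rate = 0.3, seed, covariates = NULL) {
  stopifnot(inherits(expression, "expr_matrix"),
            baseline_shape > 0, baseline_scale > 0)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (length(signature_genes) != length(signature_betas))
    stop("signature_genes and signature_betas lengths differ")
  miss <- setdiff(signature_genes, expression$feature_ids)
  if (length(miss))
    stop("signature genes not in expression matrix: ",
         paste(miss, collapse = ", "))
  n <- ncol(expression$values)
  with_seed(seed, {
    lp <- if (length(signature_genes))
      colSums(expression$values[signature_genes, , drop = FALSE] *
                signature_betas)
    else rep(0, n)
    lp <- lp - mean(lp)
    u <- runif(n)
    T <- baseline_scale * (-log(u) * exp(-lp))^(1 / baseline_shape)
    if (censor_rate == 0) {
      time <- T
      event <- rep(1, n)
    } else {
      # E[censored] = mean(P(C < T | T)) = mean(1 - exp(-lambda T))
      f <- function(loglam) mean(1 - exp(-exp(loglam) * T)) - censor_rate
      lam <- exp(uniroot(f, c(-30, 30))$root)
      C <- rexp(n, lam)
      event <- as.numeric(T <= C)
      time <- pmin(T, C)
    }
    cohort <- survival_cohort(time, event, expression, covariates)
    attr(cohort, "truth") <- new_sim_truth(
      signature_genes = as.character(signature_genes),
      signature_betas = setNames(as.numeric(signature_betas),
                                 signature_genes))
    cohort
  })
}
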