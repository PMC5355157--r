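h_model <- function(genes, betas, cutpoint = 0) {
  structure(list(genes = genes, beta_mean = setNames(betas, genes),
                 cutpoint = cutpoint),
            class = "signature_model")
}

test_that("prognostic score is exact linear arithmetic", {
  v <- matrix(c(2, 1), 2, 1, dimnames = list(c("a", "b"), "p1"))
  m <- expr_matrix(v)
  expect_equal(unname(prognostic_score(m, h_model(c("a", "b"), c(0.5, -0.5)))),
               0.5)
  expect_equal(unname(prognostic_score(m, h_model(c("a", "b"), c(0, 0)))), 0)
  # doubling one gene's expression moves the score by beta_g * x_g exactly
  v2 <- v; v2["a", ] <- 4
  s1 <- prognostic_score(m, h_model(c("a", "b"), c(0.5, -0.5)))
  s2 <- prognostic_score(expr_matrix(v2), h_model(c("a", "b"), c(0.5, -0.5)))
  expect_equal(unname(s2 - s1), 0.5 * 2)
  expect_error(prognostic_score(m, h_model(c("a", "zz"), c(1, 1))),
               "missing")
})

test_that("test-set forest: k=1 row count and summary self-consistency", {
  mat <- h_noise_matrix(8, 300, seed = 101)
  genes <- mat$feature_ids[1:3]
  coh <- h_survival_cohort(mat, genes, c(0.8, 0.8, -0.8), seed = 102)
  plan1 <- make_splits(300, 200, 1, seed = 103)
  m <- fit_signature_betas(mat, coh, genes, plan1)
  ft1 <- evaluate_test_sets(mat, coh, m, plan1)
  expect_equal(nrow(ft1$rows), 1)

  plan <- make_splits(300, 200, 12, seed = 104)
  m <- fit_signature_betas(mat, coh, genes, plan)
  ft <- evaluate_test_sets(mat, coh, m, plan)
  ok <- ft$rows[ft$rows$ok, ]
  expect_equal(ft$frac_ci_crossing_1,
               mean(ok$ci_low <= 1 & ok$ci_high >= 1))
  expect_true(all(ok$ci_low <= ok$hr & ok$hr <= ok$ci_high))
})

test_that("external validation separates planted risk groups", {
  mat <- h_noise_matrix(10, 1000, seed = 105)
  genes <- mat$feature_ids[1:3]
  coh <- h_survival_cohort(mat, genes, c(0.7, -0.7, 0.5), seed = 106)
  # model trained on an independent cohort with the same hazard structure
  mat_tr <- h_noise_matrix(10, 400, seed = 107)
  coh_tr <- h_survival_cohort(mat_tr, genes, c(0.7, -0.7, 0.5), seed = 108)
  plan <- make_splits(400, 300, 5, seed = 109)
  model <- fit_signature_betas(mat_tr, coh_tr, genes, plan)
  rep <- validate_external(mat, coh, model)
  expect_lt(rep$logrank_p, 0.01)
  expect_gt(rep$cox_hr, 1)
  # the high-score group does worse throughout follow-up
  tq <- quantile(coh$time, c(0.25, 0.5))
  expect_true(all(km_survival_at(rep$km_high, tq) <
                    km_survival_at(rep$km_low, tq)))
  # groups are equal sized at the cohort median
  expect_lte(abs(sum(rep$group == "high") - sum(rep$group == "low")), 1)
})

test_that("refitting betas on the scoring cohort matches a direct forced fit", {
  mat <- h_noise_matrix(6, 300, seed = 110)
  genes <- mat$feature_ids[1:2]
  coh <- h_survival_cohort(mat, genes, c(0.6, -0.6), seed = 111)
  model <- h_model(genes, c(99, 99))    # transferred betas are overridden
  rep <- validate_external(mat, coh, model, refit_betas = TRUE)
  direct <- cox_fit(t(mat$values[genes, ]), coh$time, coh$event)
  expect_equal(rep$betas_used, direct$beta, tolerance = 1e-10)
})

test_that("multivariate forced entry adjusts the score for covariates", {
  mat <- h_noise_matrix(6, 1000, seed = 112)
  genes <- mat$feature_ids[1:2]
  coh <- h_survival_cohort(mat, genes, c(0.7, -0.7), seed = 113)
  sc <- prognostic_score(mat, h_model(genes, c(0.7, -0.7)))
  set.seed(114)
  z <- scale(sc)[, 1]
  conf <- 0.3 * z + sqrt(1 - 0.09) * rnorm(1000)   # r ~ 0.3 with the score
  covs <- data.frame(age = conf,
                     stage = factor(sample(c("I", "II", "III"), 1000, TRUE),
                                    levels = c("I", "II", "III")),
                     er = rbinom(1000, 1, 0.6))
  tab <- multivariate_validate(sc, covs, coh$time, coh$event)
  sg <- tab[tab$term == "score_group", ]
  expect_gt(sg$ci_low, 1)      # score effect survives adjustment
  expect_equal(sum(grepl("^stage", tab$term)), 2)  # stage I is reference

  # single numeric covariate reduces exactly to cox_fit
  tab1 <- multivariate_validate(sc, covs["er"], coh$time, coh$event,
                                cutpoint = NULL)
  direct <- cox_fit(cbind(score_group = sc, er = covs$er),
                    coh$time, coh$event)
  expect_equal(tab1$beta, unname(direct$beta), tolerance = 1e-12)

  # collinear dummies are reported by name
  covs$dup <- covs$er
  expect_error(multivariate_validate(sc, covs, coh$time, coh$event),
               "collinear.*dup")
})

test_that("null covariates rarely reach significance alongside the score", {
  cross <- vapply(1:10, function(s) {
    mat <- h_noise_matrix(4, 400, seed = 500 + s)
    coh <- h_survival_cohort(mat, mat$feature_ids[1], 0.7, seed = 600 + s)
    sc <- prognostic_score(mat, h_model(mat$feature_ids[1], 0.7))
    set.seed(700 + s)
    covs <- data.frame(a = rnorm(400), b = rnorm(400))
    tab <- multivariate_validate(sc, covs, coh$time, coh$event)
    tab <- tab[tab$term != "score_group", ]
    all(tab$ci_low <= 1 & tab$ci_high >= 1)
  }, logical(1))
  expect_gte(mean(cross), 0.8)
})

test_that("subtype stratification: single subtype equals the plain analysis", {
  mat <- h_noise_matrix(4, 300, seed = 115)
  coh <- h_survival_cohort(mat, mat$feature_ids[1], 0.8, seed = 116)
  sc <- prognostic_score(mat, h_model(mat$feature_ids[1], 0.8))
  one <- subtype_stratified(sc, rep("lumA", 300), coh$time, coh$event,
                            mode = "global-cut")
  grp <- ifelse(sc > median(sc), "high", "low")
  lr <- logrank_test(coh$time, coh$event, grp)
  expect_equal(one$logrank_p, lr$p)
  expect_equal(one$chi2, lr$chi2)
})

test_that("stratification modes agree where the signature acts, and the
           inert subtype stays null", {
  mat <- h_noise_matrix(4, 600, seed = 117)
  g <- mat$feature_ids[1]
  subtype <- rep(c("active", "inert"), each = 300)
  # hazard driven by the gene only in the active subtype
  lp <- ifelse(subtype == "active", 0.9, 0) * scale(mat$values[g, ])[, 1]
  with_seed(118, {
    T <- 5 * (-log(runif(600)) * exp(-lp))^(1 / 1.5)
    C <- rexp(600, 0.1)
  })
  time <- pmin(T, C); event <- as.numeric(T <= C)
  coh_mat <- mat
  sc <- prognostic_score(coh_mat, h_model(g, 0.9))
  for (mode in c("global-cut", "within-subtype")) {
    res <- subtype_stratified(sc, subtype, time, event, mode = mode)
    expect_lt(res$logrank_p[res$subtype == "active"], 0.01)
    expect_gt(res$logrank_p[res$subtype == "inert"], 0.05)
  }
  # undersized subtypes are skipped with a warning
  expect_warning(
    res <- subtype_stratified(sc, c("tiny", rep("big", 599)), time, event,
                              mode = "within-subtype"),
    "skipped")
  expect_true(res$skipped[res$subtype == "tiny"])
})
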