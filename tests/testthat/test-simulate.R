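test_that("generators are pure functions of their arguments and seed", {
  a <- simulate_case_control(200, 10, 12, seed = 7)
  b <- simulate_case_control(200, 10, 12, seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a$matrix$values,
    simulate_case_control(200, 10, 12, seed = 8)$matrix$values))

  blk1 <- simulate_correlated_blocks(c(10, 8), 20, 0.7, 50, seed = 9)
  blk2 <- simulate_correlated_blocks(c(10, 8), 20, 0.7, 50, seed = 9)
  expect_identical(blk1, blk2)

  coh1 <- simulate_survival(a$matrix, "g00001", 0.5, seed = 3)
  coh2 <- simulate_survival(a$matrix, "g00001", 0.5, seed = 3)
  expect_identical(coh1$time, coh2$time)
})

test_that("planted DE bookkeeping: counts, effect floor, sign balance", {
  s0 <- simulate_case_control(500, 10, 10, de_fraction = 0, seed = 1)
  expect_length(s0$truth$de_features, 0)

  s1 <- simulate_case_control(1000, 10, 10, de_fraction = 0.1, seed = 2)
  expect_length(s1$truth$de_features, 100)   # floor(1000 * 0.1), no remainder
  expect_true(all(abs(s1$truth$de_features) >= 1.5))
  expect_true(all(names(s1$truth$de_features) %in% s1$matrix$feature_ids))

  # planted shift is realized in the class means
  lfc <- s1$truth$de_features[1]
  g <- names(lfc)
  tum <- s1$matrix$sample_class == "tumor"
  d <- mean(s1$matrix$values[g, tum]) - mean(s1$matrix$values[g, !tum])
  expect_equal(d, unname(lfc), tolerance = 0.5)

  expect_error(simulate_case_control(100, 0, 5, seed = 1), "positive")
  expect_error(simulate_case_control(100, 5, 5, de_fraction = 1.2, seed = 1),
               "de_fraction")
})

test_that("multi-study panels share truth but differ by batch and noise", {
  sim <- simulate_case_control(300, 20, 20, de_fraction = 0.1, seed = 11)
  sizes <- list(c(40, 7), c(42, 143), c(5, 5), c(72, 36))
  studies <- simulate_multistudy(4, sim$truth, sizes, study_shift_sd = 0.5,
                                 seed = 12)
  expect_length(studies, 4)
  for (i in 1:4) {
    expect_equal(sum(studies[[i]]$sample_class == "tumor"), sizes[[i]][1])
    expect_equal(sum(studies[[i]]$sample_class == "normal"), sizes[[i]][2])
    expect_identical(studies[[i]]$feature_ids, sim$matrix$feature_ids)
  }
  # with no batch shift, per-feature means stay near the shared baseline
  flat <- simulate_multistudy(2, sim$truth, list(c(30, 30), c(30, 30)),
                              study_shift_sd = 0, seed = 13)
  nrm <- flat[[1]]$sample_class == "normal"
  expect_lt(max(abs(rowMeans(flat[[1]]$values[, nrm]) -
                      sim$truth$baseline)), 0.5)
  expect_error(simulate_multistudy(2, sim$truth, list(), seed = 1), "empty")
})

test_that("correlated blocks realize the one-factor correlation structure", {
  blk <- simulate_correlated_blocks(c(20), 30, within_rho = 0.8,
                                    n_samples = 500, seed = 14)
  members <- names(blk$truth$block_assignments)[
    blk$truth$block_assignments == 1]
  rho <- cor(t(blk$matrix$values[members, ]), method = "spearman")
  expect_gt(mean(rho[upper.tri(rho)]), 0.7)
  expect_lt(mean(rho[upper.tri(rho)]), 0.9)

  hub <- simulate_correlated_blocks(c(20), 10, 0.8, 400,
                                    n_negative_hubs = 7, hub_rho = -0.7,
                                    seed = 15)
  expect_length(hub$truth$negative_hubs, 7)
  expect_true(all(hub$truth$block_assignments[hub$truth$negative_hubs] == 0))
  mem <- names(hub$truth$block_assignments)[hub$truth$block_assignments == 1]
  for (h in hub$truth$negative_hubs) {
    r <- cor(hub$matrix$values[h, ], t(hub$matrix$values[mem, ]))
    expect_gte(mean(r < 0), 0.5)
  }
  expect_error(simulate_correlated_blocks(c(10), 5, 0.5, 50,
                                          n_negative_hubs = 1, hub_rho = -1.2,
                                          seed = 1), "hub_rho")
  expect_error(simulate_correlated_blocks(c(10), 5, 0.5, 50,
                                          n_negative_hubs = 1, hub_rho = 0.5,
                                          seed = 1), "negative")
  expect_error(simulate_correlated_blocks(c(10), 5, 0.25, 50,
                                          n_negative_hubs = 1, hub_rho = -0.9,
                                          seed = 1), "sqrt")
})

test_that("survival generator honors censoring and the hazard model", {
  mat <- h_noise_matrix(5, 400, seed = 16)
  full <- simulate_survival(mat, character(0), numeric(0),
                            censor_rate = 0, seed = 17)
  expect_true(all(full$event == 1))
  expect_true(all(full$time > 0))

  cens <- simulate_survival(mat, character(0), numeric(0),
                            censor_rate = 0.4, seed = 18)
  expect_lt(abs(mean(1 - cens$event) - 0.4), 0.08)

  # planted effect shifts event times in the right direction
  g <- mat$feature_ids[1]
  coh <- simulate_survival(mat, g, 0.9, censor_rate = 0.2, seed = 19)
  hi <- mat$values[g, ] > median(mat$values[g, ])
  expect_lt(median(coh$time[hi]), median(coh$time[!hi]))

  expect_error(simulate_survival(mat, c("a", "b"), 0.5, seed = 1), "length")
  expect_error(simulate_survival(mat, "nope", 0.5, seed = 1), "not in")
  expect_error(simulate_survival(mat, g, 0.5, censor_rate = 1, seed = 1),
               "censor_rate")
})

test_that("container validation enforces the cohort invariants", {
  mat <- h_noise_matrix(3, 10, seed = 20)
  expect_error(survival_cohort(c(rep(1, 9), -1), rep(1, 10), mat),
               "positive")
  expect_error(survival_cohort(rep(1, 10), c(rep(1, 9), 2), mat), "0/1")
  expect_error(survival_cohort(rep(1, 5), rep(1, 5), mat), "match")
  v <- mat$values; v[1, 1] <- NA
  expect_error(expr_matrix(v), "missing")
  expect_error(expr_matrix(rbind(mat$values, mat$values)), "duplicate")
})
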