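# Accuracy estimators: definitions, limits, bias-correction identities,
# CV2* failure modes.

test_that("true accuracy is the Pearson correlation", {
  u <- c(1.2, -0.3, 0.5, 2.0)
  expect_equal(true_accuracy(u, u), 1)
  expect_equal(true_accuracy(u, -u), -1)
  v <- c(0.7, 0.1, -0.2, 1.1)
  # hand-computed from the definition
  num <- sum((u - mean(u)) * (v - mean(v)))
  den <- sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(true_accuracy(u, v), num / den)
  expect_warning(res <- true_accuracy(c(1, 1, 1), v[1:3]), "zero variance")
  expect_true(is.na(res))
  expect_error(true_accuracy(1:2, 1:2), "at least 3")
})

test_that("naive accuracy divides by h (and optionally h^2)", {
  set.seed(61)
  u <- rnorm(50); y <- u + rnorm(50)
  expect_equal(naive_accuracy(u, y, 1), cor(u, y))
  expect_equal(naive_accuracy(u, y, 0.25), cor(u, y) / 0.5)
  expect_equal(naive_accuracy(u, y, 0.25, h_power = 1), cor(u, y) / 0.25)
  expect_lt(abs(naive_accuracy(u, sample(y), 0.25)), 0.5)
})

test_that("the h-correction makes the naive estimator consistent when rho_R = 0", {
  K <- simulate_breeding_grm(200, 20, 500, seed = 62)
  arch <- genetic_architecture(0.2, 0.6, 0.6, 0)   # no residual correlation
  ids <- grm_ids(K)
  part <- partition(ids[1:20], ids[21:200])
  blocks <- conditional_blocks(K, part)
  Koo <- unclass(K)[part$train_ids, part$train_ids]
  eig <- grm_eigen(Koo)
  res <- t(vapply(1:400, function(r) {
    rep1 <- simulate_traits(K, arch, make_draws(200, 700 + r))
    ufit <- blup_univariate_fixed(rep1$Y[part$train_ids, 1], Koo,
                                  arch$G[1, 1], arch$R[1, 1], eig = eig)
    p <- predict_single(ufit, blocks)
    c(naive = naive_accuracy(p, rep1$Y[part$test_ids, 1], 0.2),
      true = true_accuracy(p, rep1$U[part$test_ids, 1]))
  }, numeric(2)))
  dif <- res[, 1] - res[, 2]
  expect_lt(abs(mean(dif)), 3 * sd(dif) / sqrt(nrow(res)) + 0.02)
})

test_that("bias correction vanishes when either correlation is zero", {
  K <- rand_pd(20, seed = 63)
  ids <- rownames(K)
  part <- partition(ids[1:5], ids[6:20])
  blocks <- conditional_blocks(K, part)
  set.seed(63)
  u3 <- rnorm(5); y1 <- rnorm(5)
  for (pars in list(c(0, 0.4), c(0.4, 0))) {
    cv <- build_covariances(0.3, 0.5, pars[1], pars[2])
    b <- semiparametric_bias(fixed_fit(cv$G, cv$R), blocks, u3, y1)
    expect_identical(b$bias_cov, 0)
    expect_identical(b$bias_hat, 0)
  }
  # sign follows g12 * r12
  cv <- build_covariances(0.3, 0.5, 0.5, -0.5)
  expect_lt(semiparametric_bias(fixed_fit(cv$G, cv$R), blocks,
                                u3, y1)$bias_cov, 0)
  cv <- build_covariances(0.3, 0.5, 0.5, 0.5)
  expect_gt(semiparametric_bias(fixed_fit(cv$G, cv$R), blocks,
                                u3, y1)$bias_cov, 0)
})

test_that("analytic bias matches the Monte-Carlo covariance gap with true components", {
  K <- simulate_breeding_grm(150, 15, 500, seed = 64)
  ids <- grm_ids(K)
  part <- partition(ids[1:30], ids[31:150])
  blocks <- conditional_blocks(K, part)
  arch <- genetic_architecture(0.2, 0.6, 0.6, -0.6)
  Koo <- unclass(K)[part$train_ids, part$train_ids]
  eig <- grm_eigen(Koo)
  diffs <- vapply(1:2000, function(r) {
    rep1 <- simulate_traits(K, arch, make_draws(150, r))
    bfit <- blup_with_fixed_components(rep1$Y[part$train_ids, ], Koo,
                                       arch$G, arch$R, mu = c(0, 0),
                                       eig = eig)
    u3 <- predict_cv2(bfit, blocks, rep1$Y[part$test_ids, 2])
    cov(u3, rep1$Y[part$test_ids, 1]) - cov(u3, rep1$U[part$test_ids, 1])
  }, numeric(1))
  analytic <- semiparametric_bias(fixed_fit(arch$G, arch$R), blocks,
                                  seq_len(30), seq_len(30))$bias_cov
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - analytic), 3 * mc_se)
})

test_that("semiparametric correction moves the estimate in the right direction", {
  K <- rand_pd(25, seed = 65)
  ids <- rownames(K)
  part <- partition(ids[1:6], ids[7:25])
  blocks <- conditional_blocks(K, part)
  set.seed(65)
  u3 <- rnorm(6); y1 <- rnorm(6)
  raw <- cor(u3, y1)
  # zero bias: reduces to the naive estimator
  cv0 <- build_covariances(0.2, 0.6, 0, 0.3)
  b0 <- semiparametric_bias(fixed_fit(cv0$G, cv0$R), blocks, u3, y1)
  expect_equal(semiparametric_accuracy(raw, b0, 0.2),
               naive_accuracy(u3, y1, 0.2))
  # opposing correlations: negative bias, corrected > naive
  cvn <- build_covariances(0.2, 0.6, 0.6, -0.6)
  bn <- semiparametric_bias(fixed_fit(cvn$G, cvn$R), blocks, u3, y1)
  expect_gt(semiparametric_accuracy(raw, bn, 0.2),
            naive_accuracy(u3, y1, 0.2))
  # aligned correlations: corrected < naive
  cvp <- build_covariances(0.2, 0.6, 0.6, 0.6)
  bp <- semiparametric_bias(fixed_fit(cvp$G, cvp$R), blocks, u3, y1)
  expect_lt(semiparametric_accuracy(raw, bp, 0.2),
            naive_accuracy(u3, y1, 0.2))
})

test_that("full-data EBVs converge to truth as residual variance vanishes", {
  K <- simulate_breeding_grm(60, 6, 300, seed = 66)
  arch <- genetic_architecture(1 - 1e-6, 1 - 1e-6, 0.3, 0)
  rep1 <- simulate_traits(K, arch, make_draws(60, 11))
  test <- grm_ids(K)[1:6]
  u_tilde <- full_data_ebv_predictand(rep1$Y, K, test)
  expect_gt(cor(u_tilde, rep1$U[test, 1]), 0.98)
})

test_that("scoring against full-data EBVs overstates accuracy", {
  K <- simulate_breeding_grm(120, 12, 400, seed = 67)
  arch <- genetic_architecture(0.2, 0.6, 0.6, 0.3)
  ids <- grm_ids(K)
  part <- partition(ids[1:12], ids[13:120])
  blocks <- conditional_blocks(K, part)
  Koo <- unclass(K)[part$train_ids, part$train_ids]
  eig_oo <- grm_eigen(Koo)
  eig_full <- grm_eigen(K)
  res <- t(vapply(1:40, function(r) {
    rep1 <- simulate_traits(K, arch, make_draws(120, 300 + r))
    bfit <- blup_with_fixed_components(rep1$Y[part$train_ids, ], Koo,
                                       arch$G, arch$R, eig = eig_oo)
    p <- predict_cv1(bfit, blocks)
    u_tilde <- full_data_ebv_predictand(rep1$Y, K, part$test_ids,
                                        eig = eig_full)
    c(ebv = cor(p, u_tilde), true = true_accuracy(p, rep1$U[part$test_ids, 1]))
  }, numeric(2)))
  expect_gt(mean(res[, "ebv"]), mean(res[, "true"]))
})

test_that("parametric accuracy recovers a perfect index and rejects noise", {
  K <- simulate_breeding_grm(300, 30, 600, seed = 68)
  arch <- genetic_architecture(0.4, 0.4, 0, 0)
  accs <- t(vapply(1:12, function(r) {
    rep1 <- simulate_traits(K, arch, make_draws(300, 40 + r))
    u <- rep1$U[, 1]; y <- rep1$Y[, 1]
    set.seed(r)
    c(perfect = parametric_accuracy(u, y, K),
      noise = parametric_accuracy(rnorm(300), y, K))
  }, numeric(2)))
  expect_gt(mean(accs[, "perfect"], na.rm = TRUE), 0.9)
  expect_lt(abs(mean(accs[, "noise"], na.rm = TRUE)), 0.15)
})

test_that("CV2* with unrelated surrogates estimates ~zero accuracy", {
  # block-diagonal GRM: surrogates genetically unrelated to test lines
  set.seed(69)
  n <- 200
  K <- matrix(0, n, n)
  K[1:100, 1:100] <- unclass(rand_pd(100, seed = 70))
  K[101:n, 101:n] <- unclass(rand_pd(100, seed = 71))
  K <- grm(K)
  ids <- grm_ids(K)
  arch <- genetic_architecture(0.3, 0.6, 0.6, 0)
  vals <- vapply(1:150, function(r) {
    rep1 <- simulate_traits(K, arch, make_draws(n, 600 + r))
    u3 <- rep1$U[ids[1:20], 1] + rnorm(20, sd = 0.1)  # a good predictor
    y_x1 <- rep1$Y[ids[101:120], 1]                   # unrelated surrogates
    cv2star_accuracy(u3, y_x1, 0.3, design = "relative")
  }, numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.02)
})

test_that("clone-design CV2* is nearly unbiased, slightly conservative", {
  K <- simulate_breeding_grm(150, 15, 500, seed = 72)
  arch <- genetic_architecture(0.2, 0.6, 0.6, -0.6)
  ids <- grm_ids(K)
  part <- partition(ids[1:15], ids[16:150])
  blocks <- conditional_blocks(K, part)
  Koo <- unclass(K)[part$train_ids, part$train_ids]
  eig <- grm_eigen(Koo)
  res <- t(vapply(1:300, function(r) {
    rep1 <- simulate_traits(K, arch, make_draws(150, r))
    rep1 <- make_clone_phenotypes(rep1, part, seed = 5000 + r)
    bfit <- blup_with_fixed_components(rep1$Y[part$train_ids, ], Koo,
                                       arch$G, arch$R, mu = c(0, 0),
                                       eig = eig)
    u3 <- predict_cv2(bfit, blocks, rep1$Y_a[part$test_ids, 2])
    c(est = cv2star_accuracy(u3, rep1$Y_b[part$test_ids, 1], 0.2, "clone"),
      true = true_accuracy(u3, rep1$U[part$test_ids, 1]))
  }, numeric(2)))
  gap <- mean(res[, "est"]) - mean(res[, "true"])
  # close to unbiased...
  expect_lt(abs(gap), 0.1)
  # ...and not optimistic beyond Monte-Carlo error
  expect_lt(gap, 3 * sd(res[, "est"] - res[, "true"]) / sqrt(nrow(res)))
})

test_that("estimators are invariant to common location shifts", {
  set.seed(73)
  u <- rnorm(20); y <- rnorm(20)
  expect_equal(naive_accuracy(u + 5, y - 2, 0.3), naive_accuracy(u, y, 0.3))
  expect_equal(cv2star_accuracy(u + 5, y - 2, 0.3, "clone"),
               cv2star_accuracy(u, y, 0.3, "clone"))
})
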