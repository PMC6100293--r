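test_that("descending-activity split sends ranks 1, 4, 7, ... to the test set", {
  set.seed(1)
  seqs <- sample(enumerate_candidates(), 91)
  df <- data.frame(sequence = seqs, activity = runif(91), stringsAsFactors = FALSE)
  sp <- split_train_test(df)
  expect_identical(nrow(sp$train), 60L)
  expect_identical(nrow(sp$test), 31L)
  # the most active peptide is always a test peptide
  expect_identical(sp$all$subset[1], "test")
  expect_true(all(diff(sp$all$activity) <= 0))
  expect_identical(which(sp$all$subset == "test"), as.integer(seq(1, 91, by = 3)))

  df3 <- data.frame(sequence = c("AAA", "CCC", "GGG"), activity = c(0.2, 0.9, 0.5))
  sp3 <- split_train_test(df3)
  expect_identical(sp3$test$sequence, "CCC")
  expect_identical(nrow(sp3$train), 2L)

  df6 <- data.frame(sequence = paste0(LETTERS[c(1, 3, 4, 5, 6, 7)], "AA"),
                    activity = 6:1)
  sp6 <- split_train_test(df6)
  expect_identical(which(sp6$all$subset == "test"), c(1L, 4L))

  # ties broken by sequence lexicographic order
  dft <- data.frame(sequence = c("CCC", "AAA", "BBB"), activity = c(1, 1, 1))
  spt <- split_train_test(dft)
  expect_identical(spt$all$sequence, c("AAA", "BBB", "CCC"))
  expect_identical(spt$test$sequence, "AAA")

  expect_warning(split_train_test(df3[1:2, ]), "fewer than 3")
  expect_error(split_train_test(rbind(df3, df3)), "duplicate")
})

test_that("MLR recovers exact linear responses to machine precision", {
  X <- autoscale(make_X(30, 2, seed = 4))$X
  y <- as.vector(X %*% c(0.5, -0.25))
  fit <- fit_mlr(X, y)
  expect_equal(unname(fit$coefficients), c(0.5, -0.25), tolerance = 1e-12)
  # standardized simple regression: coefficient equals the Pearson correlation
  d <- make_linear_data(n = 50, p = 1, support = 1, beta = 1,
                        noise_sd = 0.5, seed = 6)
  f1 <- fit_mlr(d$X, d$y)
  expect_equal(unname(f1$coefficients), unname(cor(d$X[, 1], d$y)),
               tolerance = 1e-12)
})

test_that("MLR coefficients fall within 3 OLS standard errors of the truth", {
  set.seed(42)
  n <- 60
  X <- autoscale(make_X(n, 7, seed = 42))$X
  beta <- c(0.5, -0.3, 0.8, 0.2, -0.6, 0.4, -0.1)
  y <- as.vector(X %*% beta) + rnorm(n, 0, 0.1)
  fit <- fit_mlr(X, y)
  # independent standard errors from the OLS covariance
  resid <- y - as.vector(X %*% fit$coefficients)
  sigma2 <- sum(resid^2) / (n - 7)
  se <- sqrt(diag(solve(crossprod(X))) * sigma2)
  expect_true(all(abs(fit$coefficients - beta) <= 3 * se))
})

test_that("MLR rejects singular designs naming collinear variables", {
  X <- autoscale(make_X(20, 3, seed = 8))$X
  X <- cbind(X, x4 = X[, 1])
  y <- rnorm(20)
  expect_error(fit_mlr(X, y), "x4")
})

test_that("PLS with all components equals MLR on full-rank designs", {
  d <- make_linear_data(n = 40, p = 5, support = c(1, 4), beta = c(1, -0.5),
                        noise_sd = 0.3, seed = 14)
  mlr <- fit_mlr(d$X, d$y)
  pls <- fit_pls(d$X, d$y, ncomp = 5)
  expect_equal(pls$coefficients, mlr$coefficients, tolerance = 1e-8)
})

test_that("PLS on rank-one designs predicts identically for any component count", {
  set.seed(15)
  t <- rnorm(30)
  X <- outer(t, c(1, 2, -1))
  colnames(X) <- paste0("x", 1:3)
  y <- 2 * t + rnorm(30, 0, 0.1)
  p1 <- fit_pls(X, y, ncomp = 1)
  p3 <- fit_pls(X, y, ncomp = 3)
  expect_equal(predict(p1, X), predict(p3, X), tolerance = 1e-10)
  expect_identical(p3$hyperparameters$ncomp, 1L)  # deflation exhausts rank
})

test_that("PLS predictions match the mixOmics reference implementation", {
  d <- make_linear_data(n = 35, p = 6, support = c(2, 5), beta = c(1.2, -0.7),
                        noise_sd = 0.4, seed = 21)
  for (a in c(1, 2, 3)) {
    ours <- fit_pls(d$X, d$y, ncomp = a)
    ref <- mixOmics::pls(d$X, d$y, ncomp = a, scale = FALSE, mode = "regression")
    ref_pred <- predict(ref, d$X)$predict[, 1, a]
    expect_equal(unname(predict(ours, d$X)), unname(ref_pred),
                 tolerance = 1e-6, label = paste("ncomp", a))
  }
})

test_that("SVR with a heavy slack penalty stays near the epsilon tube", {
  d <- make_linear_data(n = 50, p = 3, support = 2, beta = 1,
                        noise_sd = 0, seed = 33)
  fit <- fit_svr(d$X, d$y, seed = 1, cost = 1e4, gamma = c(0.1, 1),
                 epsilon = 0.05)
  err <- abs(predict(fit, d$X) - d$y)
  # finite-cost SVR trades slack against flatness, so exact containment is
  # not guaranteed; with cost 1e4 any tube violation must be tiny
  expect_lt(max(err), 0.05 + 0.005)
  expect_gte(mean(err <= 0.05 + 1e-6), 0.5)
})

test_that("SVR and RF are deterministic given a seed", {
  d <- make_linear_data(n = 40, p = 5, support = 1, beta = 1,
                        noise_sd = 0.3, seed = 17)
  s1 <- fit_svr(d$X, d$y, seed = 5)
  s2 <- fit_svr(d$X, d$y, seed = 5)
  expect_identical(predict(s1, d$X), predict(s2, d$X))
  expect_identical(s1$hyperparameters[c("cost", "gamma", "epsilon")],
                   s2$hyperparameters[c("cost", "gamma", "epsilon")])
  r1 <- fit_rf(d$X, d$y, seed = 5)
  r2 <- fit_rf(d$X, d$y, seed = 5)
  expect_identical(predict(r1, d$X), predict(r2, d$X))
})

test_that("RF fits a strong univariate signal closely", {
  set.seed(3)
  X <- matrix(rnorm(400), 400, 1, dimnames = list(NULL, "x1"))
  y <- X[, 1]
  fit <- fit_rf(X, y, seed = 3)
  expect_gt(cor(predict(fit, X), y)^2, 0.95)
  expect_error(fit_rf(X, rep(1, 400)), "zero variance")
})

test_that("LOO PRESS equals the hat-matrix closed form for MLR", {
  d <- make_linear_data(n = 25, p = 4, support = c(1, 3), beta = c(1, -0.5),
                        noise_sd = 0.5, seed = 19)
  fit <- fit_mlr(d$X, d$y)
  loo <- loo_q2(fit, d$X, d$y)
  # independent closed form: PRESS = sum((e_i / (1 - h_ii))^2)
  H <- d$X %*% solve(crossprod(d$X)) %*% t(d$X)
  e <- d$y - as.vector(d$X %*% fit$coefficients)
  press_hat <- sum((e / (1 - diag(H)))^2)
  expect_equal(loo$press, press_hat, tolerance = 1e-10)
  expect_equal(loo$q2, 1 - press_hat / sum((d$y - mean(d$y))^2),
               tolerance = 1e-10)
})

test_that("cross-validation is exact on noiseless data and penalizes noise fits", {
  Xs <- autoscale(make_X(30, 3, seed = 25))$X
  y <- as.vector(Xs %*% c(1, -0.5, 0.25))
  fit <- fit_mlr(Xs, y)
  loo <- loo_q2(fit, Xs, y)
  expect_lt(loo$press, 1e-20)
  expect_equal(loo$q2, 1, tolerance = 1e-10)
  kf <- kfold_q2(fit, Xs, y, k = 5, seed = 2)
  expect_equal(kf$q2, 1, tolerance = 1e-10)
  # response independent of the predictor: held-out Q2 is negative
  set.seed(26)
  yn <- rnorm(30)
  fitn <- fit_mlr(Xs[, 1, drop = FALSE], yn)
  expect_lt(loo_q2(fitn, Xs[, 1, drop = FALSE], yn)$q2, 0)
})

test_that("k = n fold validation reproduces leave-one-out", {
  d <- make_linear_data(n = 18, p = 3, support = 2, beta = 1,
                        noise_sd = 0.4, seed = 27)
  fit <- fit_mlr(d$X, d$y)
  loo <- loo_q2(fit, d$X, d$y)
  kf <- kfold_q2(fit, d$X, d$y, k = 18, seed = 99)
  expect_equal(kf$q2, loo$q2, tolerance = 1e-12)
  # seeds are carried in the result so fold draws are reportable
  k1 <- kfold_q2(fit, d$X, d$y, k = 4, seed = 1)
  k2 <- kfold_q2(fit, d$X, d$y, k = 4, seed = 2)
  expect_identical(k1$seed, 1L)
  expect_identical(k2$seed, 2L)
})

test_that("the F statistic formula reproduces published-scale arithmetic", {
  # R2 = 0.893 with n = 60, m = 7 gives F close to 61.7 (within 0.5%)
  expect_equal(f_statistic(0.893, 60, 7), 61.745, tolerance = 0.005)
  expect_identical(f_statistic(1, 60, 7), Inf)
  expect_equal(f_statistic(0.5, 12, 2), (0.5 / 2) / (0.5 / 9))
})

test_that("model_metrics bundles training, LOO, k-fold and test statistics", {
  gen <- generate_peptide_dataset(ground_truth(seed = 3, n_peptides = 60),
                                  properties = default_properties(m = 20))
  sp <- split_train_test(gen$peptides)
  props <- default_properties(m = 20)
  Xtr <- encode_peptides(sp$train$sequence, props)
  Xte <- encode_peptides(sp$test$sequence, props)
  sc <- autoscale(Xtr, sp$train$activity)
  sel <- stepwise_select(sc$X, sc$y)
  fit <- fit_mlr(sc$X[, sel$selected, drop = FALSE], sc$y, scaling = sc$params)
  fit <- model_metrics(fit, Xtr, sp$train$activity, Xte, sp$test$activity,
                       ks = c(4, 6), seed = 1)
  m <- fit$metrics
  expect_identical(m$n, nrow(sp$train))
  expect_identical(m$m, length(sel$selected))
  expect_true(m$R2_train >= 0 && m$R2_train <= 1)
  expect_true(all(c(m$Q2_loo, m$Q2_kfold) <= 1))
  # Q2/PRESS consistency: 1 - Q2 = PRESS / SS_total exactly
  sst <- sum((sp$train$activity - mean(sp$train$activity))^2)
  expect_equal(1 - m$Q2_loo, m$PRESS / sst, tolerance = 1e-12)
  # R2_train recomputed from predictions matches the stored metric
  expect_equal(m$R2_train,
               cor(predict(fit, Xtr), sp$train$activity)^2, tolerance = 1e-12)
  expect_identical(m$n_test, nrow(sp$test))
  # perfect fit: SD 0, F infinite
  Xs <- autoscale(make_X(20, 2, seed = 1))$X
  yp <- as.vector(Xs %*% c(1, 1))
  fp <- model_metrics(fit_mlr(Xs, yp), Xs, yp)
  expect_equal(fp$metrics$SD, 0, tolerance = 1e-10)
  expect_identical(fp$metrics$F, Inf)
})

test_that("linear predictions scale with a constant rescaling of activity units", {
  gen <- generate_peptide_dataset(ground_truth(seed = 5, n_peptides = 40),
                                  properties = default_properties(m = 15))
  props <- default_properties(m = 15)
  X <- encode_peptides(gen$peptides$sequence, props)
  y <- gen$peptides$activity
  for (c0 in c(2, 10)) {
    sc1 <- autoscale(X, y)
    sc2 <- autoscale(X, c0 * y)
    vars <- colnames(sc1$X)[1:4]
    f1 <- fit_mlr(sc1$X[, vars], sc1$y, scaling = sc1$params)
    f2 <- fit_mlr(sc2$X[, vars], sc2$y, scaling = sc2$params)
    expect_equal(predict(f2, X), c0 * predict(f1, X), tolerance = 1e-10)
  }
})
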