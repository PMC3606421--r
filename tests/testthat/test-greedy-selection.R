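test_that("initialization matches the empty-set closed form", {
  X <- rbind(c(1L, 0L), c(2L, 1L))
  st <- init_selection(X, c(1, -1), lambda = 2)
  expect_equal(st$a, c(0.5, -0.5))
  expect_equal(st$d, c(0.5, 0.5))
  expect_equal(st$C, t(X) / 2)
  expect_error(init_selection(rbind(c(1L, NA)), c(1, -1), 1), "impute")
})

test_that("candidate evaluation reproduces the hand-derived update chain", {
  X <- matrix(c(1L, -1L), nrow = 1)
  st <- init_selection(X, c(1, -1), 1)
  # u = (1/3, -1/3), a~ = (1/3, -1/3), d~ = (2/3, 2/3) -> LOO-MSE 1/4
  expect_equal(evaluate_candidate(st, 1), 0.25)
  expect_error(evaluate_candidate(st, 2), "out of range")
  st2 <- commit_feature(st, 1)
  expect_error(evaluate_candidate(st2, 1), "already selected")
})

test_that("an all-zero feature leaves the criterion and state unchanged", {
  inst <- rand_instance(5, 12, 21)
  X <- rbind(inst$X, 0L)
  st <- init_selection(X, inst$y, 1)
  base_mse <- loo_mse(rls_dual_state(matrix(0, 0, 12), inst$y, 1), inst$y)
  expect_equal(evaluate_candidate(st, 6), base_mse)
  st2 <- commit_feature(st, 6)
  expect_equal(st2$a, st$a)
  expect_equal(st2$d, st$d)
  expect_equal(st2$C, st$C)
})

test_that("candidate scores equal from-scratch LOO-MSE of the enlarged set", {
  for (seed in 1:8) {
    inst <- rand_instance(12, 15, seed + 40)
    st <- init_selection(inst$X, inst$y, 1)
    pick <- select_next(st)
    st <- commit_feature(st, pick$feature)
    for (i in setdiff(seq_len(12), st$S)[1:4]) {
      expect_equal(evaluate_candidate(st, i),
                   dense_loo_mse(inst$X, c(st$S, i), inst$y, 1),
                   tolerance = 1e-9)
    }
  }
})

test_that("ties break toward the smallest feature index", {
  inst <- rand_instance(4, 10, 5)
  X <- rbind(inst$X[1, ], inst$X)      # rows 1 and 2 identical
  st <- init_selection(X, inst$y, 1)
  m1 <- evaluate_candidate(st, 1)
  m2 <- evaluate_candidate(st, 2)
  expect_identical(m1, m2)
  # make row 1/2 the winner by boosting y alignment is not needed: if the
  # duplicate pair wins, index 1 must be returned; otherwise check directly
  mse <- vapply(1:5, function(i) evaluate_candidate(st, i), numeric(1))
  expect_identical(select_next(st)$feature, which.min(mse))
  # single-feature problem returns feature 1 regardless of quality
  one <- init_selection(matrix(0L, 1, 10), inst$y, 1)
  expect_identical(select_next(one)$feature, 1L)
})

test_that("committed state matches dense reconstruction of G at every step", {
  inst <- rand_instance(10, 14, 99)
  X <- inst$X; y <- inst$y
  st <- init_selection(X, y, lambda = 0.5)
  for (step in 1:4) {
    st <- commit_feature(st, select_next(st)$feature)
    Xs <- X[st$S, , drop = FALSE]; storage.mode(Xs) <- "double"
    G <- solve(crossprod(Xs) + 0.5 * diag(ncol(X)))
    expect_lt(max(abs(st$a - drop(G %*% y))), 1e-9)
    expect_lt(max(abs(st$d - diag(G))), 1e-9)
    expect_lt(max(abs(st$C - G %*% t(X))), 1e-9)
    # candidate denominators 1 + X_i C_{:,i} never drop below 1
    expect_true(all(1 + colSums(st$C * t(X)) >= 1 - 1e-9))
  }
})

test_that("greedy, space-efficient and naive wrapper select identically", {
  for (seed in 1:12) {
    n <- sample(15:40, 1)
    m <- sample(10:30, 1)
    inst <- rand_instance(n, m, seed + 700)
    g <- greedy_rls(inst$X, inst$y, 1, 5)
    se <- greedy_rls_space_efficient(inst$X, inst$y, 1, 5, block_size = 7L)
    nv <- naive_wrapper(inst$X, inst$y, 1, 5)
    expect_identical(g$trace$feature, se$trace$feature)
    expect_identical(g$trace$feature, nv$trace$feature)
    expect_lt(max(abs(g$trace$loo_mse - se$trace$loo_mse)), 1e-8)
    expect_lt(max(abs(g$trace$loo_mse - nv$trace$loo_mse)), 1e-8)
  }
  # the explicit-retraining inner loop gives the same answer (double oracle)
  inst <- rand_instance(12, 12, 1234)
  g <- greedy_rls(inst$X, inst$y, 1, 3)
  nv2 <- naive_wrapper(inst$X, inst$y, 1, 3, loo = "explicit")
  expect_identical(g$trace$feature, nv2$trace$feature)
  expect_lt(max(abs(g$trace$loo_mse - nv2$trace$loo_mse)), 1e-8)
})

test_that("per-step LOO-MSE equals a from-scratch model on the committed set", {
  inst <- rand_instance(20, 18, 31)
  g <- greedy_rls(inst$X, inst$y, 1, 6)
  for (step in 1:6) {
    expect_equal(g$trace$loo_mse[step],
                 dense_loo_mse(inst$X, g$trace$feature[1:step], inst$y, 1),
                 tolerance = 1e-9)
  }
  # and the final predictor obeys w = X_S a
  Xs <- inst$X[g$trace$feature, , drop = FALSE]
  storage.mode(Xs) <- "double"
  a <- rls_dual_state(Xs, inst$y, 1)$a
  expect_lt(max(abs(g$predictor$w - drop(Xs %*% a))), 1e-9)
})

test_that("k = 0 yields an empty trace and an all-zero predictor", {
  inst <- rand_instance(5, 8, 2)
  g <- greedy_rls(inst$X, inst$y, 1, 0)
  expect_identical(nrow(g$trace), 0L)
  expect_equal(predict(g$predictor, inst$X), rep(0, 8))
  expect_error(greedy_rls(inst$X, inst$y, 1, 6), "k must be")
})

test_that("SVD cache columns match the stored cache matrix columnwise", {
  inst <- rand_instance(15, 12, 55)
  lam <- 2
  st <- init_selection(inst$X, inst$y, lam)
  sest <- greedysnp:::se_state(inst$X, inst$y, lam)
  # empty set: c = X_i / lambda
  expect_equal(se_cache_column(sest, inst$X, 3), inst$X[3, ] / lam)
  # after 3 commits
  for (j in 1:3) st <- commit_feature(st, select_next(st)$feature)
  sest$S <- st$S
  sest <- greedysnp:::se_refresh_svd(sest, inst$X)
  for (i in c(1, 7, 15)) {
    expect_lt(max(abs(se_cache_column(sest, inst$X, i) - st$C[, i])), 1e-9)
  }
  # zero feature gives a zero column
  X0 <- rbind(inst$X, 0L)
  sest0 <- greedysnp:::se_state(X0, inst$y, lam)
  expect_equal(se_cache_column(sest0, X0, 16), rep(0, 12))
})

test_that("space-efficient variant never materializes an m x n cache", {
  inst <- rand_instance(400, 50, 8)
  se_allocation_tracker(TRUE)
  se <- greedy_rls_space_efficient(inst$X, inst$y, 1, 4, block_size = 32L)
  widest <- se_allocation_tracker()
  se_allocation_tracker(FALSE)
  expect_lte(widest, 32L)          # auxiliary blocks bounded by block_size
  expect_lt(widest, nrow(inst$X))  # strictly narrower than the feature count
  g <- greedy_rls(inst$X, inst$y, 1, 4)
  expect_identical(se$trace$feature, g$trace$feature)
  expect_lt(max(abs(se$trace$loo_mse - g$trace$loo_mse)), 1e-8)
})

test_that("selection under bias mode matches the naive wrapper with a constant feature", {
  for (seed in c(3, 17)) {
    inst <- rand_instance(20, 15, seed + 900)
    g <- greedy_rls(inst$X, inst$y, 1, 4, bias = TRUE)
    se <- greedy_rls_space_efficient(inst$X, inst$y, 1, 4, bias = TRUE)
    nv <- naive_wrapper(inst$X, inst$y, 1, 4, bias = TRUE)
    expect_identical(g$trace$feature, nv$trace$feature)
    expect_identical(g$trace$feature, se$trace$feature)
    expect_lt(max(abs(g$trace$loo_mse - nv$trace$loo_mse)), 1e-8)
    # trace only reports genuine features
    expect_true(all(g$trace$feature <= nrow(inst$X)))
  }
})

test_that("a strong planted feature is selected first", {
  set.seed(64)
  m <- 60
  X <- matrix(rbinom(30 * m, 2L, 0.3), nrow = 30)
  y <- sample(c(-1, 1), m, replace = TRUE)
  X[12, ] <- as.integer(y + 1)  # scaled copy of the labels
  g <- greedy_rls(X, y, 1, 1)
  expect_identical(g$trace$feature[1], 12L)
  # brute-force argmin agrees
  mses <- vapply(1:30, function(i) dense_loo_mse(X, i, y, 1), numeric(1))
  expect_identical(which.min(mses), 12L)
})
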