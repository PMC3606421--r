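# Shared fixture builders. Everything is generated in code at test time.

# random genotype-like instance: X in {0,1,2}^{n x m}, y in {-1,+1}^m
rand_instance <- function(n, m, seed, maf_range = c(0.1, 0.5)) {
  set.seed(seed)
  maf <- runif(n, maf_range[1], maf_range[2])
  X <- matrix(rbinom(n * m, 2L, rep(maf, m)), nrow = n, ncol = m)
  y <- sample(c(-1, 1), m, replace = TRUE)
  # guard against one-class draws
  if (length(unique(y)) == 1L) y[1] <- -y[1]
  list(X = X, y = y)
}

# small valid dataset with optional missing entries
tiny_dataset <- function(n = 10, m = 8, seed = 1, missing = 0) {
  inst <- rand_instance(n, m, seed)
  X <- inst$X
  if (missing > 0) {
    set.seed(seed + 1000)
    holes <- sample(length(X), missing)
    X[holes] <- NA_integer_
  }
  genotype_dataset(X, inst$y)
}

# independent brute-force oracle for the 3x2 exact test: plain choose()
# arithmetic over the full grid of case-column cells, no log-gamma
fisher_3x2_bruteforce <- function(tab) {
  r <- rowSums(tab)
  cases <- sum(tab[, 1])
  N <- sum(tab)
  prob_of <- function(x0, x1, x2)
    choose(r[1], x0) * choose(r[2], x1) * choose(r[3], x2) / choose(N, cases)
  p_obs <- prob_of(tab[1, 1], tab[2, 1], tab[3, 1])
  total <- 0
  for (x0 in 0:r[1]) for (x1 in 0:r[2]) {
    x2 <- cases - x0 - x1
    if (x2 < 0 || x2 > r[3]) next
    p <- prob_of(x0, x1, x2)
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  min(total, 1)
}

# dense from-scratch LOO-MSE for a feature set (the selection oracle)
dense_loo_mse <- function(X, S, y, lambda, bias = FALSE) {
  Xs <- X[S, , drop = FALSE]
  if (bias) Xs <- rbind(Xs, rep(1, ncol(X)))
  storage.mode(Xs) <- "double"
  loo_mse(rls_dual_state(Xs, y, lambda), y)
}
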