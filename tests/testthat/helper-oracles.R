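# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package: plain loops, direct
# textbook formulas.

# direct-formula Pearson correlation (zero-variance convention: 0)
pearson_oracle <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# exhaustive-neighbor ReliefF (all instances, k hits / k misses per class,
# prior-weighted misses, range-normalized diff, Manhattan distance)
relieff_oracle <- function(x, y, k) {
  n <- nrow(x)
  m <- ncol(x)
  y <- factor(y)
  rngs <- apply(x, 2, function(col) diff(range(col)))
  difff <- function(f, i, j) {
    if (rngs[f] == 0) 0 else abs(x[i, f] - x[j, f]) / rngs[f]
  }
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dmat[i, j] <- sum(vapply(seq_len(m), function(f) difff(f, i, j), numeric(1)))
    }
  }
  priors <- table(y) / n
  W <- numeric(m)
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    for (cl in levels(y)) {
      pool <- which(y == cl)
      if (cl == ci) pool <- setdiff(pool, i)
      nb <- pool[order(dmat[i, pool], pool)][seq_len(k)]
      for (f in seq_len(m)) {
        s <- sum(vapply(nb, function(j) difff(f, i, j), numeric(1)))
        if (cl == ci) {
          W[f] <- W[f] - s / (n * k)
        } else {
          W[f] <- W[f] + (priors[[cl]] / (1 - priors[[ci]])) * s / (n * k)
        }
      }
    }
  }
  W
}

# naive greedy MWMR: recomputes every candidate's redundancy from scratch at
# every step
greedy_oracle <- function(x, w_raw, alpha, k, target = "pool",
                          aggregate = "mean", normalize = TRUE) {
  m <- ncol(x)
  if (normalize) {
    rng <- range(w_raw)
    w_use <- if (rng[1] == rng[2]) rep(0, m) else (w_raw - rng[1]) / diff(rng)
  } else {
    w_use <- w_raw
  }
  remaining <- seq_len(m)
  sel <- integer(0)
  for (step in seq_len(k)) {
    if (step == 1L) {
      score <- w_use[remaining]
    } else {
      r <- vapply(remaining, function(j) {
        others <- if (target == "selected") sel else setdiff(remaining, j)
        if (length(others) == 0) return(0)
        vals <- vapply(others, function(o) abs(pearson_oracle(x[, j], x[, o])),
                       numeric(1))
        switch(aggregate, mean = mean(vals), max = max(vals), min = min(vals))
      }, numeric(1))
      score <- alpha * w_use[remaining] - (1 - alpha) * r
    }
    j <- remaining[order(-score, -w_raw[remaining], remaining)][1]
    sel <- c(sel, j)
    remaining <- setdiff(remaining, j)
  }
  sel
}

# dominant eigenvector of K Y Y' — the fixed point of the first KPLS score
# iteration
kpls_first_score_oracle <- function(Kc, Yc) {
  M <- Kc %*% tcrossprod(Yc)
  e <- eigen(M)
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sqrt(sum(v^2))
}

# direct Fisher score formula (population class variances)
fisher_oracle <- function(x, y) {
  y <- factor(y)
  mu <- colMeans(x)
  num <- den <- numeric(ncol(x))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    nc <- length(rows)
    muc <- colMeans(x[rows, , drop = FALSE])
    varc <- colMeans((x[rows, , drop = FALSE] -
                        matrix(muc, nc, ncol(x), byrow = TRUE))^2)
    num <- num + nc * (muc - mu)^2
    den <- den + nc * varc
  }
  num / den
}

# small labeled dataset for quick checks
toy_data <- function(n_per_class = 8, m_noise = 3, seed = 42, sep = 6) {
  withr::with_seed(seed, {
    y <- rep(c("a", "b"), each = n_per_class)
    f1 <- rnorm(2 * n_per_class) + ifelse(y == "a", 0, sep)
    noise <- matrix(rnorm(2 * n_per_class * m_noise), ncol = m_noise)
    d <- tibble::tibble(class = factor(y), f1 = f1)
    for (j in seq_len(m_noise)) d[[paste0("n", j)]] <- noise[, j]
    d
  })
}
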