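test_that("pearson_r closed forms and direct-formula agreement", {
  withr::with_seed(3, a <- rnorm(6))
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -2 * a + 7), -1)
  expect_equal(pearson_r(a, rep(2, 6)), 0)          # zero-variance convention
  withr::with_seed(4, b <- rnorm(6))
  expect_equal(pearson_r(a, b), pearson_oracle(a, b), tolerance = 1e-14)
  expect_error(pearson_r(a, b[1:3]), "length")
})

test_that("redundancy_score aggregates |r| over the selected set", {
  withr::with_seed(6, {
    cand <- rnorm(12)
    s1 <- rnorm(12)
    s2 <- rnorm(12)
  })
  expect_equal(redundancy_score(cand, NULL), 0)
  expect_equal(redundancy_score(cand, matrix(numeric(0), 12, 0)), 0)
  expect_equal(redundancy_score(cand, cbind(cand), aggregate = "max"), 1)
  r1 <- abs(pearson_oracle(cand, s1))
  r2 <- abs(pearson_oracle(cand, s2))
  sel <- cbind(s1, s2)
  expect_equal(redundancy_score(cand, sel, "mean"), mean(c(r1, r2)))
  expect_equal(redundancy_score(cand, sel, "max"), max(r1, r2))
  expect_equal(redundancy_score(cand, sel, "min"), min(r1, r2))
})

test_that("alpha = 1 reduces the greedy order to descending weights exactly", {
  for (seed in 1:3) {
    d <- synth_benchmark(n_per_class = 8, n_noise = 6, seed = seed)
    w <- relieff_weights(d, k_neighbors = 3)
    for (target in c("pool", "selected")) {
      sel <- mwmr_select(d, w, alpha = 1, k = 9, redundancy_target = target)
      expect_equal(sel$features, w$feature[order(w$rank)],
                   label = sprintf("seed %d target %s", seed, target))
    }
  }
})

test_that("k = 1 returns the single top-weighted feature for any alpha", {
  d <- synth_benchmark(n_per_class = 8, n_noise = 4, seed = 5)
  w <- relieff_weights(d, k_neighbors = 3)
  top <- w$feature[w$rank == 1]
  for (a in c(0, 0.3, 1)) {
    expect_equal(selected_features(mwmr_select(d, w, alpha = a, k = 1)), top)
  }
})

# fixture with an exact duplicate of the top feature plus uncorrelated
# candidates; informative structure is explicit so expected behavior is
# derivable by hand
duplicated_fixture <- function(seed = 8, n = 30) {
  withr::with_seed(seed, {
    f1 <- c(rnorm(n / 2, 0), rnorm(n / 2, 6))
    tibble::tibble(
      class = factor(rep(c("a", "b"), each = n / 2)),
      f1 = f1,
      dup = f1,                               # |r| = 1 with f1
      u1 = rnorm(n), u2 = rnorm(n), u3 = rnorm(n)
    )
  })
}

test_that("under selected-set redundancy a duplicate is deferred while uncorrelated candidates remain", {
  d <- duplicated_fixture(n = 60)
  # weights favour f1 then dup; uncorrelated candidates have smaller weights.
  # At small alpha the unit redundancy to the selected twin dominates the
  # criterion; at larger alpha the weight term can legitimately win once mean
  # aggregation dilutes the twin's |r| = 1, so the guarantee is a small-alpha one.
  w <- setNames(c(1, 0.99, 0.5, 0.4, 0.3), names(d)[-1])
  for (a in c(0, 0.1)) {
    sel <- mwmr_select(d, w, alpha = a, k = 4, redundancy_target = "selected")
    expect_equal(sel$features[1], "f1")
    expect_false("dup" %in% sel$features[1:4])
  }
  # with max aggregation the duplicate's redundancy stays 1 and it is deferred
  # whenever a zero-redundancy candidate with sufficient weight remains
  for (a in c(0.2, 0.4)) {
    sel <- mwmr_select(d, w, alpha = a, k = 4, redundancy_target = "selected",
                       aggregate = "max")
    expect_false("dup" %in% sel$features)
  }
  # at alpha = 1 the duplicate is picked second, by weight alone
  sel1 <- mwmr_select(d, w, alpha = 1, k = 2, redundancy_target = "selected")
  expect_equal(sel1$features, c("f1", "dup"))
})

test_that("greedy selection matches the naive recomputed-criterion oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 14
      m <- sample(6:12, 1)
      x <- matrix(rnorm(n * m), n)
      colnames(x) <- paste0("v", seq_len(m))
      w_raw <- runif(m, -0.2, 1)
    })
    d <- tibble::as_tibble(x)
    k <- min(4, m)
    for (target in c("pool", "selected")) {
      for (agg in c("mean", "max", "min")) {
        sel <- mwmr_select(d, setNames(w_raw, colnames(x)), alpha = 0.4, k = k,
                           label_col = "none", redundancy_target = target,
                           aggregate = agg)
        oracle <- greedy_oracle(x, w_raw, alpha = 0.4, k = k, target = target,
                                aggregate = agg)
        expect_equal(sel$features, colnames(x)[oracle],
                     label = sprintf("seed %d %s/%s", seed, target, agg))
      }
    }
  }
})

test_that("selection is invariant to feature-column permutation up to names", {
  d <- synth_benchmark(n_per_class = 8, n_noise = 6, seed = 12)
  w <- relieff_weights(d, k_neighbors = 3)
  sel <- mwmr_select(d, w, alpha = 0.3, k = 4)
  withr::with_seed(99, perm <- c(1, 1 + sample(ncol(d) - 1)))
  dp <- d[, perm]
  wp <- relieff_weights(dp, k_neighbors = 3)
  selp <- mwmr_select(dp, wp, alpha = 0.3, k = 4)
  expect_setequal(selp$features, sel$features)
})

test_that("m = k returns all features and a well-formed trace", {
  d <- synth_benchmark(n_per_class = 6, n_noise = 2, seed = 14)
  w <- relieff_weights(d, k_neighbors = 2)
  sel <- mwmr_select(d, w, alpha = 0.5, k = 5)
  expect_setequal(sel$features, names(d)[-1])
  expect_equal(sel$trace$pool_size, 5:1)          # pool shrinks by one per step
  expect_equal(sel$trace$step, 1:5)
  expect_equal(anyDuplicated(sel$features), 0L)
})

test_that("the full pipeline selects the informative features on the benchmark", {
  d <- synth_benchmark(seed = 31)
  fit <- kpls_mwmr(d, alpha = 0.3, k = 3)
  expect_setequal(selected_features(fit), c("f1", "f2", "f3"))
  expect_equal(fit$selection$method, "kpls-mwmr")
  # deterministic end to end
  fit2 <- kpls_mwmr(d, alpha = 0.3, k = 3)
  expect_identical(fit$selection$trace, fit2$selection$trace)
})

test_that("pipeline endpoint behavior on a duplicated-column dataset", {
  d <- duplicated_fixture(seed = 20, n = 40)
  # alpha = 1: ranking is by pipeline weight alone, duplicate allowed next to
  # its twin; alpha = 0 (selected-set redundancy): duplicate deferred
  fit1 <- kpls_mwmr(d, alpha = 1, k = 2, k_neighbors = 5)
  w <- fit1$weights
  expect_equal(selected_features(fit1), w$feature[order(w$rank)][1:2])
  fit0 <- kpls_mwmr(d, alpha = 0, k = 4, k_neighbors = 5,
                    redundancy_target = "selected")
  first <- selected_features(fit0)[1]
  twin <- if (first %in% c("f1", "dup")) setdiff(c("f1", "dup"), first) else NA
  expect_false(is.na(twin))
  expect_false(twin %in% selected_features(fit0))
})

test_that("stage failures carry the stage name", {
  d <- synth_benchmark(n_per_class = 5, n_noise = 2, seed = 3)
  expect_error(kpls_mwmr(d, label_col = "nope", k = 2), "kpls")
  expect_error(kpls_mwmr(d, k = 2, width = -1), "width")
})
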