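test_that("Cohen's kappa closed forms", {
  expect_equal(cohens_kappa(matrix(c(40, 10, 10, 40), 2, byrow = TRUE)), 0.6)
  expect_equal(cohens_kappa(diag(c(7, 9, 4))), 1)
  expect_warning(k0 <- cohens_kappa(matrix(c(10, 0, 0, 0), 2)), "degenerate")
  expect_equal(k0, 0)
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
})

test_that("kappa of marginal-matching random predictions is near zero", {
  vals <- withr::with_seed(123, {
    replicate(200, {
      truth <- sample(c("a", "b", "c"), 90, replace = TRUE, prob = c(.5, .3, .2))
      pred <- sample(c("a", "b", "c"), 90, replace = TRUE, prob = c(.5, .3, .2))
      cohens_kappa(confusion_matrix(truth, pred, classes = c("a", "b", "c")))
    })
  })
  expect_lt(abs(mean(vals)), 0.02)   # null distribution centered at 0
})

test_that("macro-F1 closed forms and label symmetry", {
  expect_equal(macro_f1(diag(c(5, 5))), 1)
  # balanced binary, everything predicted as the first class
  cm <- matrix(c(10, 0, 10, 0), 2, byrow = TRUE)
  expect_equal(macro_f1(cm), 1 / 3)     # F1 = 2/3 and 0
  # relabeling invariance
  perm <- c(2, 1)
  cm2 <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  expect_equal(macro_f1(cm2), macro_f1(cm2[perm, perm]))
})

test_that("stratified folds partition samples with balanced class proportions", {
  y <- factor(rep(c("a", "b", "c"), times = c(30, 20, 10)))
  folds <- kplsmwmr:::stratified_folds(y, 5, seed = 42)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 60L)
  for (f in 1:5) {
    tab <- table(y[folds == f])
    expect_equal(as.numeric(tab), c(6, 4, 2))   # exact per-class balance here
  }
  expect_identical(folds, kplsmwmr:::stratified_folds(y, 5, seed = 42))
  expect_error(kplsmwmr:::stratified_folds(factor(c("a", "a", "b")), 3, 1),
               "fewer folds|fewer than")
})

test_that("a perfectly separated toy problem scores accuracy 1 in every fold", {
  withr::with_seed(10, {
    d <- tibble::tibble(
      class = factor(rep(c("a", "b"), each = 20)),
      f1 = c(rnorm(20, -10, 0.1), rnorm(20, 10, 0.1)),
      f2 = rnorm(40)
    )
  })
  cv <- cross_validate(d, features = "f1", n_folds = 5, n_repeats = 2, seed = 3)
  expect_true(all(cv$folds$accuracy == 1))
  expect_true(all(cv$folds$kappa == 1))
  expect_true(all(cv$folds$macro_f1 == 1))
  g <- glance(cv)
  expect_equal(g$mean_accuracy, 1)
  expect_equal(g$sd_accuracy, 0)
})

test_that("stored metrics re-derive exactly from the stored confusion matrices", {
  d <- synth_benchmark(n_per_class = 20, n_noise = 5, seed = 18)
  cv <- cross_validate(d, features = c("f4", "f5"),   # noise only: imperfect
                       n_folds = 4, n_repeats = 2, seed = 5)
  for (i in seq_len(nrow(cv$folds))) {
    cm <- cv$folds$confusion[[i]]
    expect_identical(cv$folds$accuracy[i], sum(diag(cm)) / sum(cm))
    expect_identical(cv$folds$kappa[i], cohens_kappa(cm))
    expect_identical(cv$folds$macro_f1[i], macro_f1(cm))
  }
  g <- glance(cv)
  expect_equal(g$mean_accuracy, mean(cv$folds$accuracy), tolerance = 1e-12)
  # same seed => identical report
  cv2 <- cross_validate(d, features = c("f4", "f5"),
                        n_folds = 4, n_repeats = 2, seed = 5)
  expect_identical(cv$folds$accuracy, cv2$folds$accuracy)
  expect_identical(cv$folds$confusion, cv2$folds$confusion)
})

test_that("within-fold selection never sees held-out rows", {
  d <- synth_benchmark(n_per_class = 10, n_noise = 4, seed = 25)
  d$rowid <- seq_len(nrow(d)) * 1.0     # numeric id feature for instrumentation
  seen <- list()
  sel_fun <- function(train) {
    seen[[length(seen) + 1L]] <<- train$rowid
    c("f1", "f2")
  }
  cv <- cross_validate(d, selector = sel_fun, n_folds = 5, n_repeats = 1,
                       seed = 2, mode = "within_fold")
  expect_length(seen, 5L)
  all_ids <- d$rowid
  held_out <- lapply(seen, function(s) setdiff(all_ids, s))
  # the five held-out sets partition the samples exactly once
  expect_setequal(unlist(held_out), all_ids)
  expect_equal(sum(lengths(held_out)), length(all_ids))
  for (i in seq_along(seen)) {
    expect_length(intersect(seen[[i]], held_out[[i]]), 0)
  }
})

test_that("evaluation guards: bad modes, unknown features, empty selection", {
  d <- synth_benchmark(n_per_class = 10, n_noise = 2, seed = 2)
  expect_error(cross_validate(d, mode = "within_fold"), "selector")
  expect_error(cross_validate(d, mode = "select_once"), "features")
  expect_error(cross_validate(d, features = "zzz"), "unknown")
  expect_error(cross_validate(d, features = "f1", n_folds = 1), "n_folds")
})

test_that("alpha sweep tabulates one row per alpha with sane accuracies", {
  d <- synth_benchmark(n_per_class = 15, n_noise = 10, seed = 8)
  sw <- alpha_sweep(d, alphas = c(0.9, 0.3), k = 2, n_folds = 3, n_repeats = 1,
                    seed = 4, k_neighbors = 5)
  expect_equal(sw$alpha, c(0.3, 0.9))             # sorted ascending
  expect_true(all(sw$mean_accuracy >= 0 & sw$mean_accuracy <= 1))
  # a singleton sweep reproduces a direct select-once evaluation
  fit <- kpls_mwmr(d, alpha = 0.3, k = 2, k_neighbors = 5)
  cv <- cross_validate(d, features = selected_features(fit), n_folds = 3,
                       n_repeats = 1, seed = 4)
  expect_equal(sw$mean_accuracy[sw$alpha == 0.3], glance(cv)$mean_accuracy)
  expect_error(alpha_sweep(d, alphas = c(-0.2, 0.5), k = 2), "alphas")
})
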