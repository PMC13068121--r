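test_that("1-NN imputation copies from the nearest training row", {
  train <- rbind(A = c(1, 2, 3), C = c(10, 20, 30))
  colnames(train) <- c("x", "y", "z")
  model <- fit_preprocess(train)
  q <- matrix(c(1, 2, NA), 1, dimnames = list("B", c("x", "y", "z")))
  expect_equal(unname(impute_1nn(q, model)[1, ]), c(1, 2, 3))
  full <- matrix(c(4, 5, 6), 1, dimnames = list("D", c("x", "y", "z")))
  expect_equal(unname(impute_1nn(full, model)[1, ]), c(4, 5, 6))
})

test_that("equidistant neighbours break ties toward the smaller row index", {
  train <- rbind(r1 = c(0, 5), r2 = c(2, 1), r3 = c(-2, 9))
  colnames(train) <- c("u", "v")
  model <- fit_preprocess(train)
  # query (1, NA): r2 and r3 are at |u| distance 1 and 3; r1 at 1 -> tie
  q <- matrix(c(1, NA), 1, dimnames = list("q", c("u", "v")))
  # distances on u alone: r1 -> 1, r2 -> 1, r3 -> 3; tie r1/r2 -> r1 wins
  expect_equal(unname(impute_1nn(q, model)[1, "v"]), 5)
})

test_that("imputation matches the exhaustive oracle on masked matrices", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(5:10, 1); p <- sample(3:5, 1)
    train <- matrix(round(rnorm(n * p), 2), n, p,
                    dimnames = list(NULL, paste0("c", 1:p)))
    if (rep %% 3 == 0) train[sample(length(train), 2)] <- NA
    q <- matrix(round(rnorm(4 * p), 2), 4, p,
                dimnames = list(NULL, paste0("c", 1:p)))
    q[cbind(1:4, sample(p, 4, replace = TRUE))] <- NA
    ok_rows <- rowSums(!is.na(train)) > 0
    train <- train[ok_rows, , drop = FALSE]
    if (nrow(train) < 2) next
    model <- fit_preprocess(train)
    expect_equal(impute_1nn(q, model), oracle_impute(q, train),
                 ignore_attr = TRUE)
  }
})

test_that("imputation errors are specific", {
  train <- rbind(c(1, 2), c(3, 4)); colnames(train) <- c("a", "b")
  model <- fit_preprocess(train)
  q <- matrix(NA_real_, 1, 2, dimnames = list("q", c("a", "b")))
  expect_error(impute_1nn(q, model), "no observed value")
})

test_that("winsorization replaces outliers with in-range training extremes", {
  train <- matrix(c(rep(0, 10), 100), ncol = 1,
                  dimnames = list(NULL, "m"))
  model <- suppressWarnings(fit_preprocess(train))  # winsorized range is 0
  mu <- mean(train); s <- sd(train)
  expect_equal(model$winsor_upper[["m"]], mu + 2 * s)
  w <- winsorize(train, model)
  expect_equal(unname(w[11, 1]), 0)  # largest in-range observed value
  # in-range data pass through
  mid <- matrix(c(-5, 0, 5), ncol = 1, dimnames = list(NULL, "m"))
  model2 <- fit_preprocess(mid)
  expect_equal(unname(winsorize(mid, model2)[, 1]), c(-5, 0, 5))
  # all outputs inside the bounds
  set.seed(2)
  tr <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  m3 <- fit_preprocess(tr)
  new <- matrix(rnorm(30, sd = 5), 10, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  w3 <- winsorize(new, m3)
  for (j in 1:3) {
    expect_true(all(w3[, j] >= m3$winsor_lower[j] - 1e-12))
    expect_true(all(w3[, j] <= m3$winsor_upper[j] + 1e-12))
  }
})

test_that("range normalization divides by the training range", {
  train <- matrix(c(-50, 0, 50), ncol = 1, dimnames = list(NULL, "m"))
  model <- fit_preprocess(train)
  expect_equal(unname(normalize_range(train, model)[, 1]),
               c(-0.5, 0, 0.5))
  cons <- cbind(m = c(-50, 0, 50), k = c(1, 1, 1))
  mc <- suppressWarnings(fit_preprocess(cons))
  expect_warning(out <- normalize_range(cons, mc), "zero-range")
  expect_equal(colnames(out), "m")
})

test_that("standardization centers and scales by training statistics", {
  train <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "m"))
  model <- fit_preprocess(train)
  expect_equal(unname(standardize(train, model)[, 1]), c(-1, 0, 1))
  held <- matrix(2, 1, 1, dimnames = list(NULL, "m"))
  expect_equal(unname(standardize(held, model)[1, 1]), 0)
  # affine invariance: fitting on a*x + b reproduces the z-scores
  a <- 3.7; b <- -2
  model2 <- fit_preprocess(a * train + b)
  expect_equal(unname(standardize(a * held + b, model2)),
               unname(standardize(held, model)))
})

test_that("every stage is idempotent for a fitted model", {
  set.seed(5)
  tr <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  model <- fit_preprocess(tr)
  x <- matrix(rnorm(10, sd = 3), 5, 2, dimnames = list(NULL, c("a", "b")))
  x[2, 1] <- NA
  once <- apply_preprocess(x, model)
  expect_equal(standardize(once, model), once)
  expect_equal(winsorize(once, model), once)
  w <- winsorize(impute_1nn(x, model), model)
  expect_equal(winsorize(w, model), w)
  nrm <- normalize_range(w, model)
  expect_equal(normalize_range(nrm, model), nrm)
})

test_that("the fitted model never sees held-out rows", {
  lst <- make_feature_matrix(n = 16, p = 3, delta = 1, seed = 9)
  pm_full <- fit_preprocess(lst$X[-1, , drop = FALSE])
  mutated <- lst$X
  mutated[1, ] <- mutated[1, ] + 100
  pm_mut <- fit_preprocess(mutated[-1, , drop = FALSE])
  expect_identical(pm_full, pm_mut)
})
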