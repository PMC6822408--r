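make_nf <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(cd_n = runif(n), sk_n = runif(n), co_n = runif(n))
}

test_that("least squares recovers exact linear data and rejects degenerate designs", {
  nf <- make_nf(12, seed = 2)
  counts <- 3 * nf$cd_n + 2
  m <- fit_count_model(nf, counts, terms = "cd")
  expect_equal(m$coefficients, 3, tolerance = 1e-9)
  expect_equal(m$intercept, 2, tolerance = 1e-9)
  expect_equal(m$fit_r2, 1, tolerance = 1e-9)
  expect_lt(m$fit_rmse, 1e-9)
  const <- fit_count_model(nf, rep(5, 12), terms = "cd")
  expect_equal(const$coefficients, 0, tolerance = 1e-9)
  expect_equal(const$intercept, 5, tolerance = 1e-9)
  bad <- nf; bad$sk_n <- bad$cd_n
  expect_error(fit_count_model(bad, counts, terms = c("cd", "sk")),
               "rank-deficient")
})

test_that("multivariate fit matches the explicit normal-equation solution", {
  nf <- make_nf(10, seed = 7)
  set.seed(8)
  counts <- round(runif(10, 50, 250))
  m <- fit_count_model(nf, counts)
  X <- cbind(1, nf$cd_n, nf$sk_n, nf$co_n)
  beta <- solve(t(X) %*% X, t(X) %*% counts)
  expect_equal(c(m$intercept, m$coefficients), as.numeric(beta),
               tolerance = 1e-8)
})

test_that("prediction rounds half away from zero and clamps only the reported count", {
  m <- count_model("cd", 1, 0)
  pr <- predict_count(m, data.frame(cd_n = 0.5))
  expect_equal(pr$gn_raw, 0.5)
  expect_equal(pr$gn_count, 1)
  neg <- predict_count(count_model("cd", 1, -17.031), data.frame(cd_n = 0))
  expect_equal(neg$gn_raw, -17.031)   # raw value unclamped
  expect_equal(neg$gn_count, 0)
  expect_error(predict_count(m, data.frame(sk_n = 1)), "missing model term")
})

test_that("evaluation metrics follow their definitions", {
  perfect <- evaluate_model(c(100, 150, 200), c(100, 150, 200))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$accuracy_pct, 100)
  at_mean <- evaluate_model(rep(150, 3), c(100, 150, 200))
  expect_equal(at_mean$r2, 0)
  expect_warning(ex <- evaluate_model(c(100, 90), c(100, 100)),
                 "zero variance")
  expect_equal(ex$rmse, 7.0711, tolerance = 1e-4)
  expect_equal(ex$accuracy_pct, 95)
  expect_true(is.na(ex$r2))  # R2 undefined for constant truths
})

test_that("evaluation is invariant to permuting the prediction-truth pairs", {
  set.seed(5)
  truths <- round(runif(20, 60, 220))
  preds <- truths + round(rnorm(20, 0, 6))
  perm <- sample(20)
  a <- evaluate_model(preds, truths)
  b <- evaluate_model(preds[perm], truths[perm])
  expect_equal(a[c("r2", "rmse", "accuracy_pct")],
               b[c("r2", "rmse", "accuracy_pct")])
})

test_that("the multivariate fit is never worse in-sample than its nested univariate fits", {
  nf <- make_nf(30, seed = 11)
  set.seed(12)
  counts <- round(200 * nf$cd_n + 20 * nf$sk_n + rnorm(30, 0, 5)) + 30
  full <- fit_count_model(nf, counts)
  for (tm in c("cd", "sk", "co"))
    expect_lte(full$fit_rmse, fit_count_model(nf, counts, terms = tm)$fit_rmse)
})

test_that("the printed-model registry holds all eight groups with exact coefficients", {
  reg <- printed_models()
  expect_length(reg, 8)
  isc <- reg[["indica.scanner.C"]]
  expect_equal(isc$coefficients, c(363.72, 10.50, -13.48))
  expect_equal(isc$intercept, 5.348)
  jcb <- reg[["japonica.camera.B"]]
  expect_equal(jcb$coefficients, c(500.64, 188.62, -205.06))
  expect_equal(jcb$intercept, -5.477)
  expect_true(all(vapply(reg, function(m) length(m$coefficients), 0L) == 3L))
})

test_that("count models survive a JSON round-trip", {
  ft <- data.frame(cd = c(0.1, 0.5), sk = c(0.01, 0.04), co = c(0.05, 0.09))
  st <- fit_normalizer(ft)
  m <- count_model(c("cd", "sk"), c(300, 5), 2.5,
                   group = list(subspecies = "indica"), norm_stats = st)
  f <- tempfile(fileext = ".json")
  write_count_model(m, f)
  m2 <- read_count_model(f)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$terms, m$terms)
  expect_equal(m2$norm_stats$cd, st$cd)
  unlink(f)
})
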