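test_that("the published model reproduces its printed coefficients", {
  m <- published_model()
  b <- coef(m)
  expect_length(b, 7L)                       # intercept + 6 descriptors
  expect_equal(unname(b["(Intercept)"]), -30.7139)
  expect_equal(unname(b["chi_m"]), -0.9132)
  expect_setequal(setdiff(names(b), "(Intercept)"), pka_descriptor_names)

  expect_equal(predict(m, zero_descriptors(0)), -30.7139)
  expect_equal(predict(m, zero_descriptors(1)), -30.7139 + 3.0608)

  # unit sensitivity in delta_e is the printed coefficient
  x0 <- zero_descriptors(0)
  x1 <- x0; x1$delta_e <- 1
  expect_equal(predict(m, x1) - predict(m, x0), 0.1074)

  # affine map: f(x1) + f(x2) - f(0) = f(x1 + x2) at base_t = 0
  set.seed(7)
  r1 <- zero_descriptors(0); r2 <- zero_descriptors(0)
  for (nm in setdiff(pka_descriptor_names, "base_t")) {
    r1[[nm]] <- rnorm(1); r2[[nm]] <- rnorm(1)
  }
  r12 <- r1; for (nm in pka_descriptor_names) r12[[nm]] <- r1[[nm]] + r2[[nm]]
  expect_equal(predict(m, r1) + predict(m, r2) - predict(m, x0),
               predict(m, r12))

  expect_error(predict(m, data.frame(delta_e = 1)), "missing descriptor")
})

test_that("noiseless synthetic data is recovered exactly", {
  d <- linear_dataset(n = 40, noise_sd = 0, seed = 11)
  fit <- qsar_fit(pka_exp ~ delta_e + delta_hl_gap + chi_m +
                    npsa_percent + delta_alie_n + base_t, data = d)
  beta_true <- attr(d, "beta")
  expect_equal(unname(coef(fit)[names(beta_true)]), unname(beta_true),
               tolerance = 1e-8)
  expect_equal(unname(coef(fit)["(Intercept)"]), attr(d, "intercept"),
               tolerance = 1e-8)
  st <- fit$statistics
  expect_equal(st$r2, 1, tolerance = 1e-12)
  expect_equal(st$rmse, 0, tolerance = 1e-8)
  expect_equal(st$mae, 0, tolerance = 1e-8)
  expect_equal(st$q2_loo, 1, tolerance = 1e-10)
})

test_that("fit preconditions and rank checks are enforced", {
  d <- linear_dataset(n = 30, noise_sd = 0.1, seed = 2)
  small <- d[1:7, ]   # n = k + 1 for 6 descriptors
  expect_error(qsar_fit(pka_exp ~ delta_e + delta_hl_gap + chi_m +
                          npsa_percent + delta_alie_n + base_t,
                        data = small),
               "more than k \\+ 1")
  d$dup <- d$delta_e * 2
  expect_error(qsar_fit(pka_exp ~ delta_e + dup, data = d), "dup")
})

test_that("OLS matches the normal-equations oracle on random designs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:50, 1)
    p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- rnorm(n)
    fit <- qsar_fit(x = as.data.frame(X), y = y)
    expect_equal(unname(coef(fit)), ols_oracle(cbind(1, X), y),
                 tolerance = 1e-8)
  }
})

test_that("fit statistics obey their defining identities", {
  d <- linear_dataset(n = 60, noise_sd = 0.4, seed = 33)
  fit <- qsar_fit(pka_exp ~ delta_e + delta_hl_gap + chi_m +
                    npsa_percent + delta_alie_n + base_t, data = d)
  st <- fit$statistics
  n <- st$n; k <- st$k
  res <- residuals(fit)
  sse <- sum(res^2)
  expect_equal(st$f_statistic,
               (st$r2 / k) / ((1 - st$r2) / (n - k - 1)))
  expect_equal(st$s, sqrt(sse / (n - k - 1)))
  expect_equal(st$rmse, sqrt(sse / n))
  expect_lte(st$mae, st$rmse)
  expect_lte(st$q2_loo, st$r2)
  expect_equal(st$stability, st$r2 - st$q2_loo)
  expect_lte(st$r2, 1)
})

test_that("hat-matrix LOO equals naive refitting", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(60), 20, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- X %*% c(1, -2, 0.5) + rnorm(20, sd = 0.3)
    expect_equal(loo_q2(as.data.frame(X), as.vector(y)),
                 loo_q2_naive(as.data.frame(X), as.vector(y)),
                 tolerance = 1e-10)
  }
})

test_that("permuted responses destroy cross-validated predictivity", {
  set.seed(314)
  n <- 30
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 * X$a - X$b + rnorm(n, sd = 0.2)
  neg <- 0
  for (r in 1:100) {
    q2 <- loo_q2(X, sample(y))
    if (q2 <= 0) neg <- neg + 1
  }
  expect_gte(neg, 90)
})

test_that("correlation screening flags collinear descriptor pairs", {
  set.seed(5)
  x <- data.frame(a = rnorm(50), b = rnorm(50))
  x$dup <- x$a
  sc <- correlation_screen(x)
  expect_equal(sc$cap, 0.7744)
  expect_true(any(sc$flagged$var1 == "a" & sc$flagged$var2 == "dup"))
  expect_equal(sc$r["a", "dup"], 1)

  # near-orthogonal random columns are never flagged at the default cap
  for (seed in 1:20) {
    set.seed(seed)
    xr <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
    expect_equal(nrow(correlation_screen(xr)$flagged), 0L)
  }

  xz <- data.frame(a = rnorm(10), z = rep(1, 10))
  scz <- correlation_screen(xz)
  expect_true(is.na(scz$r["a", "z"]))
  expect_equal(nrow(scz$flagged), 0L)
})

test_that("all-subsets selection recovers a planted descriptor pair", {
  hits <- 0
  for (r in 1:100) {
    set.seed(1000 + r)
    n <- 60
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- paste0("d", 1:6)
    y0 <- 2 * X$d2 - 1.5 * X$d5
    y <- y0 + rnorm(n, sd = 0.1 * sd(y0))
    top <- select_descriptors(X, y, max_k = 2)[1, ]
    if (identical(top$subset, "d2,d5")) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("selection handles the intercept-only edge and column order", {
  set.seed(9)
  X <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  y <- X$a + rnorm(30, sd = 0.1)
  none <- select_descriptors(X, y, max_k = 0)
  expect_equal(none$subset, "(none)")
  expect_equal(none$r2, 0)

  full <- select_descriptors(X, y, max_k = 2)
  shuffled <- select_descriptors(X[, c("c", "a", "b")], y, max_k = 2)
  expect_equal(full$subset, shuffled$subset)
  expect_equal(full$q2_loo, shuffled$q2_loo)

  big <- as.data.frame(matrix(rnorm(30 * 21), 30, 21))
  expect_error(select_descriptors(big, rnorm(30), 2), "pre-filter")
})

test_that("models serialize to JSON and back", {
  d <- linear_dataset(n = 40, noise_sd = 0.2, seed = 8)
  fit <- qsar_fit(pka_exp ~ delta_e + chi_m + base_t, data = d)
  f <- tempfile(fileext = ".json")
  write_qsar_model(fit, f)
  back <- read_qsar_model(f)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$statistics$r2, fit$statistics$r2)
  expect_equal(predict(back, d[1:3, ]), predict(fit, d[1:3, ]))
})
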