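test_that("Moran's I matches hand evaluation of the double sum", {
  w2 <- distance_weights(c(0, 100), 100)
  expect_equal(morans_i(c(1, -1), w2), -1)
  w3 <- distance_weights(c(100, 200, 300), 100)
  expect_equal(morans_i(c(1, 2, 3), w3), 0)  # middle deviation is zero
  expect_error(morans_i(c(2, 2, 2), w3), "constant")
  expect_error(morans_i(c(1, 2), distance_weights(c(0, 500), 100)), "no neighbor")
})

test_that("Moran's I equals the brute-force oracle on random inputs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:25, 1)
    pos <- sort(runif(n, 0, 1000))
    x <- rnorm(n)
    d <- runif(1, 50, 400)
    w <- distance_weights(pos, d, step = d)
    if (w$S == 0) next
    expect_equal(morans_i(x, w), morans_i_bruteforce(x, w$W), tolerance = 1e-12)
  }
})

test_that("Moran's I agrees with an independent library implementation", {
  skip_if_not_installed("ape")
  set.seed(3)
  # ape::Moran.I row-normalizes its weights unconditionally, so compare on a
  # ring where every band has the same number of neighbors: normalization is
  # then a uniform rescale and the raw-weight statistic coincides with ape's
  n <- 37
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, (i %% n) + 1] <- 1
    W[(i %% n) + 1, i] <- 1
  }
  ring <- structure(list(W = W, S = sum(W), positions = seq_len(n)),
                    class = "band_weights")
  for (rep in 1:5) {
    x <- rnorm(n)
    expect_equal(morans_i(x, ring),
                 ape::Moran.I(x, W, scaled = FALSE)$observed,
                 tolerance = 1e-12)
  }
})

test_that("permutation null of Moran's I is centred on -1/(n-1)", {
  set.seed(8)
  n <- 30
  pos <- seq_len(n) * 100
  w <- distance_weights(pos, 100)
  x <- rnorm(n)
  perms <- replicate(999, morans_i(sample(x), w))
  e0 <- -1 / (n - 1)
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - e0), 3 * se)
})

test_that("correlograms use regular 100-m distance classes on 100-m bands", {
  sch <- make_equal_elevation_bands(1350, 5050, 100)
  set.seed(21)
  res <- rnorm(37)
  cg <- correlogram(res, sch$mid, step = 100, max_lag = 8, n_perm = 99, seed = 2L)
  expect_equal(cg$class_m, seq(100, 800, by = 100))
  expect_equal(cg$n_pairs, 37 - seq_len(8))
  # perfect gradient: strong positive autocorrelation at lag 1
  cg2 <- correlogram(sch$mid, sch$mid, step = 100, max_lag = 3, n_perm = 99, seed = 2L)
  expect_gt(cg2$morans_i[1], 0.5)
  expect_lt(cg2$p_value[1], 0.05)
})

test_that("white-noise residuals stay inside the permutation envelope", {
  sch <- make_equal_elevation_bands(1350, 5050, 100)
  hits <- 0L
  total <- 0L
  for (rep in 1:10) {
    set.seed(rep + 400)
    res <- rnorm(37)
    cg <- correlogram(res, sch$mid, step = 100, max_lag = 6,
                      n_perm = 199, seed = rep)
    hits <- hits + sum(cg$p_value <= 0.05)
    total <- total + nrow(cg)
  }
  # ~5 % false positives expected; allow a generous margin
  expect_lt(hits / total, 0.15)
})

test_that("polynomial OLS reproduces exact lines, parabolas and the normal equations", {
  x <- seq(1, 20)
  f1 <- suppressWarnings(fit_polynomial(2 * x + 1, x, 1L))  # exact fit
  expect_equal(unname(f1$coef["S"]), 2)
  expect_equal(unname(f1$coef["C"]), 1)
  expect_equal(f1$r2, 1)
  f2 <- suppressWarnings(fit_polynomial(-x^2 + 4 * x, x, 2L))
  expect_equal(unname(f2$coef["Q"]), -1)
  expect_equal(unname(f2$coef["S"]), 4)
  expect_equal(unname(f2$coef["C"]), 0, tolerance = 1e-10)
  set.seed(12)
  y <- rnorm(25)
  xr <- rnorm(25)
  f <- fit_polynomial(y, xr, 2L)
  X <- cbind(1, xr, xr^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)  # normal-equation oracle
  expect_equal(unname(f$coef[c("C", "S", "Q")]), unname(drop(beta)),
               tolerance = 1e-8)
  expect_error(fit_polynomial(y, rep(1, 25), 1L), "degenerate")
})

test_that("SAR with lambda near zero reduces to OLS", {
  sim <- simulate_sar(37, beta = c(2, 0.5), lambda = 0, sigma = 1, seed = 31L)
  fs <- fit_polynomial(sim$y, sim$x, 1L, engine = "SAR", weights = sim$weights)
  fo <- fit_polynomial(sim$y, sim$x, 1L, engine = "OLS")
  expect_lt(abs(fs$lambda), 2 * fs$lambda_se)
  expect_equal(unname(fs$coef), unname(fo$coef), tolerance = 0.05)
  expect_gte(fs$loglik, fo$loglik - 1e-8)  # ML nesting
  expect_true(fs$r2 >= 0 && fs$r2 <= 1)
  expect_lt(abs(fs$r2 - fo$r2), 0.05)
})

test_that("SAR recovers a known spatial coefficient and whitens residuals", {
  lambdas <- numeric(60)
  reduced <- logical(60)
  for (i in seq_len(60)) {
    sim <- simulate_sar(37, beta = c(1, 0.3), lambda = 0.6, sigma = 1, seed = i)
    fs <- fit_polynomial(sim$y, sim$x, 1L, engine = "SAR", weights = sim$weights)
    fo <- fit_polynomial(sim$y, sim$x, 1L, engine = "OLS")
    lambdas[i] <- fs$lambda
    reduced[i] <- abs(morans_i(residuals(fs), sim$weights)) <
      abs(morans_i(residuals(fo), sim$weights))
  }
  expect_lt(abs(mean(lambdas) - 0.6), 0.1)
  expect_gte(mean(reduced), 0.9)
})

test_that("SAR pseudo-R2 uses trend plus signal and stays in [0, 1]", {
  sim <- simulate_sar(37, beta = c(0, 1), lambda = 0.5, sigma = 1, seed = 77L)
  f <- fit_polynomial(sim$y, sim$x, 1L, engine = "SAR", weights = sim$weights)
  expect_true(f$r2 >= 0 && f$r2 <= 1)
  expect_gte(f$r2, f$r2_trend - 1e-8)
  # hand-recompute the prediction
  Wr <- sim$weights$W / pmax(rowSums(sim$weights$W), 1)
  trend <- f$coef["C"] + f$coef["S"] * sim$x
  yhat <- trend + f$lambda * drop(Wr %*% (sim$y - trend))
  expect_equal(f$r2, cor(sim$y, yhat)^2, tolerance = 1e-10)
})

test_that("order selection prefers simplicity within 2 AICc units", {
  mk <- function(order, aicc_val) {
    structure(list(order = order, engine = "OLS", response_name = "S",
                   predictor_name = "x", n_used = 30L, aicc = aicc_val,
                   selected = FALSE),
              class = "band_fit")
  }
  expect_equal(select_order(mk(1L, 50), mk(2L, 45))$order, 2L)
  expect_equal(select_order(mk(1L, 50), mk(2L, 49))$order, 1L)
  expect_equal(select_order(mk(1L, 50), mk(2L, 50))$order, 1L)
  # symmetric in argument order and idempotent
  expect_equal(select_order(mk(2L, 45), mk(1L, 50))$order, 2L)
  sel <- select_order(mk(1L, 50), mk(2L, 45))
  expect_true(sel$selected)
  bad <- mk(2L, 45)
  bad$n_used <- 20L
  expect_error(select_order(mk(1L, 50), bad), "not comparable")
  expect_error(select_order(mk(1L, 50), mk(1L, 45)), "order-1 and one order-2")
})

test_that("method comparison flags the larger pseudo-R2 per cell", {
  fits <- expand.grid(group = c("S", "G"), predictor = c("MAT", "MDE"),
                      richness_kind = c("obs", "cor1", "cor2"),
                      stringsAsFactors = FALSE)
  fits$r2 <- c(
    0.9, 0.9, 0.9, 0.9,        # obs
    0.4, 0.7, 0.5, 0.5,        # cor1
    0.6, 0.5, 0.8, 0.5         # cor2
  )
  cmp <- compare_methods(fits)
  w <- attr(cmp, "wins")
  expect_equal(unname(w[["method2"]]), 2L)
  expect_equal(unname(w[["method1"]]), 1L)
  expect_equal(unname(w[["tie"]]), 1L)
  expect_true(all(is.na(cmp$winner[cmp$richness_kind == "obs"])))
})
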