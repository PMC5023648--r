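#' Spatial neighbor weights for bands along the elevational axis
#'
#' Bands are treated as observations along a single geographic axis. Two
#' constructors are provided: `distance_weights()` connects pairs whose
#' positions (normally band mid-elevations) lie in a distance class
#' `(d - step/2, d + step/2]`, which on 100-m equal-elevation bands yields
#' the classes 100 m, 200 m, ...; `rank_weights()` connects each band to its
#' ordinal neighbors `i - 1` and `i + 1`, the natural choice for equal-area
#' bands whose mid-elevations are irregularly spaced (a fixed metre radius
#' would isolate the wide bands).
#'
#' @param positions Numeric positions of the bands (m).
#' @param distance Target distance class d (m).
#' @param step Class width (m); defaults to `distance` so the first class
#'   spans `(d/2, 3d/2]`.
#' @return An object of class `band_weights`: list with the raw binary
#'   symmetric matrix `W`, the link count `S = sum(W)`, and `positions`.
#' @export
distance_weights <- function(positions, distance, step = distance) {
  n <- length(positions)
  if (n < 2) stop_invalid("need at least 2 positions")
  dmat <- abs(outer(positions, positions, "-"))
  W <- (dmat > distance - step / 2 & dmat <= distance + step / 2) * 1
  diag(W) <- 0
  structure(list(W = W, S = sum(W), positions = positions),
            class = "band_weights")
}

#' @rdname distance_weights
#' @param n Number of bands.
#' @export
rank_weights <- function(n, positions = seq_len(n)) {
  if (n < 2) stop_invalid("need at least 2 bands")
  W <- matrix(0, n, n)
  idx <- seq_len(n - 1)
  W[cbind(idx, idx + 1)] <- 1
  W[cbind(idx + 1, idx)] <- 1
  structure(list(W = W, S = sum(W), positions = positions),
            class = "band_weights")
}

#' @export
print.band_weights <- function(x, ...) {
  cat(sprintf("<band_weights> n = %d, links S = %d\n", nrow(x$W), x$S))
  invisible(x)
}

# Row-standardize a binary neighbor matrix; isolated rows stay all-zero.
row_standardize <- function(W) {
  rs <- rowSums(W)
  sweep(W, 1, pmax(rs, 1), "/") * (rs > 0)
}

#' Moran's I spatial autocorrelation coefficient
#'
#' `I = (n / S) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' over the raw binary weights of one distance class, where `S` is the number
#' of links. Positive values mean neighbors are more alike than chance,
#' negative less alike; the null expectation is `-1 / (n - 1)`.
#'
#' @param values Per-band numeric values (typically model residuals).
#' @param weights A `band_weights` object (raw binary links).
#' @return Moran's I.
#' @export
morans_i <- function(values, weights) {
  stopifnot(inherits(weights, "band_weights"))
  n <- length(values)
  if (n < 2 || n != nrow(weights$W)) {
    stop_invalid("values (length %d) must match the weights dimension (%d)",
                 n, nrow(weights$W))
  }
  if (weights$S == 0) stop_invalid("no neighbor pairs at this distance class")
  dev <- values - mean(values)
  denom <- sum(dev^2)
  if (denom == 0) stop_invalid("constant values: Moran's I undefined")
  (n / weights$S) * sum(weights$W * outer(dev, dev)) / denom
}

#' Moran's I correlogram with permutation tests
#'
#' Computes Moran's I at distance classes `step, 2 step, ...` and a
#' two-sided permutation p-value per class (values randomly reassigned to
#' positions, extremeness measured around the null expectation
#' `-1/(n-1)`). Classes with no pairs are omitted with a warning.
#'
#' @param residuals Per-band numeric values.
#' @param positions Band positions (m), strictly increasing.
#' @param step Distance class width (m); classes are its multiples.
#' @param max_lag Number of classes; default covers the span of positions.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutations.
#' @return A `correlogram`: data frame with `class_m`, `morans_i`, `n_pairs`,
#'   `p_value`.
#' @export
correlogram <- function(residuals, positions, step = 100, max_lag = NULL,
                        n_perm = 999L, seed = 1L) {
  if (is.unsorted(positions, strictly = TRUE)) {
    stop_invalid("positions must be strictly increasing")
  }
  n <- length(residuals)
  if (n != length(positions)) stop_invalid("residuals and positions differ in length")
  if (is.null(max_lag)) {
    max_lag <- floor((max(positions) - min(positions)) / step)
  }
  e0 <- -1 / (n - 1)
  perms <- with_seed(seed, replicate(n_perm, sample(residuals)))
  rows <- vector("list", max_lag)
  dropped <- 0L
  for (k in seq_len(max_lag)) {
    w <- distance_weights(positions, k * step, step)
    if (w$S == 0) {
      dropped <- dropped + 1L
      next
    }
    i_obs <- morans_i(residuals, w)
    i_perm <- apply(perms, 2, morans_i, weights = w)
    p <- (1 + sum(abs(i_perm - e0) >= abs(i_obs - e0))) / (n_perm + 1)
    rows[[k]] <- data.frame(class_m = k * step, morans_i = i_obs,
                            n_pairs = w$S / 2, p_value = p)
  }
  if (dropped > 0) {
    warning(sprintf("%d distance class(es) had no pairs and were omitted", dropped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop_invalid("no distance class has any pair")
  rownames(out) <- NULL
  structure(out, class = c("correlogram", "data.frame"),
            n = n, expectation = e0, n_perm = n_perm)
}

#' @export
plot.correlogram <- function(x, ...) {
  plot(x$class_m, x$morans_i, type = "b", pch = 19,
       xlab = "distance class (m)", ylab = "Moran's I", ...)
  graphics::abline(h = attr(x, "expectation"), lty = 2)
  invisible(x)
}

new_band_fit <- function(fields) {
  structure(fields, class = "band_fit")
}

#' Polynomial regression of band richness on a predictor
#'
#' Fits a first- or second-order polynomial of one predictor (elevation,
#' MAT, MAP or the MDE prediction) to a per-band response, by OLS or by a
#' simultaneous autoregressive (SAR) error model. Coefficients are reported
#' in the field's Q/S/C convention: quadratic, slope, constant. Bands with
#' missing response (e.g. dropped zero-richness bands) are excluded and
#' counted.
#'
#' @param y Per-band response.
#' @param x Per-band predictor.
#' @param order Polynomial order, 1 or 2.
#' @param engine `"OLS"` or `"SAR"`.
#' @param weights A `band_weights` object; required for `engine = "SAR"`.
#'   When responses contain missing bands the weights must already be built
#'   on the analyzed subset.
#' @param response_name,predictor_name Labels carried into the result.
#' @return An object of class `band_fit` with coefficients `Q` (order 2
#'   only), `S`, `C`, their standard errors and p-values, `r2` (adjusted R^2
#'   for OLS, pseudo-R^2 for SAR), a model `p_value`, `aicc`
#'   (K = order + 2 for OLS, order + 3 for SAR), and residuals/fitted values.
#' @export
fit_polynomial <- function(y, x, order = 1L, engine = c("OLS", "SAR"),
                           weights = NULL, response_name = deparse(substitute(y)),
                           predictor_name = deparse(substitute(x))) {
  engine <- match.arg(engine)
  if (!order %in% c(1L, 2L)) stop_invalid("order must be 1 or 2")
  use <- is.finite(y) & is.finite(x)
  n_dropped <- sum(!use)
  y <- y[use]
  x <- x[use]
  n <- length(y)
  if (n < order + 2) stop_invalid("need at least %d usable bands, got %d", order + 2, n)
  if (length(unique(x)) <= order) stop_invalid("degenerate predictor: too few distinct values")
  X <- if (order == 2L) cbind(x = x, x2 = x^2) else cbind(x = x)
  if (engine == "OLS") {
    fit <- stats::lm(y ~ X)
    sm <- summary(fit)
    ll <- as.numeric(stats::logLik(fit))
    cf <- stats::coef(fit)
    se <- sm$coefficients[, 2]
    cp <- sm$coefficients[, 4]
    ord_names <- if (order == 2L) c("C", "S", "Q") else c("C", "S")
    names(cf) <- names(se) <- names(cp) <- ord_names
    p <- unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                          lower.tail = FALSE))
    new_band_fit(list(
      response_name = response_name, predictor_name = predictor_name,
      order = order, engine = "OLS",
      coef = cf[rev(ord_names)], se = se[rev(ord_names)],
      coef_p = cp[rev(ord_names)],
      r2 = sm$adj.r.squared, p_value = p,
      loglik = ll, aicc = aicc(ll, n, order + 2L),
      lambda = NA_real_, lambda_se = NA_real_,
      n_used = n, n_dropped = n_dropped,
      residuals = unname(stats::residuals(fit)),
      fitted = unname(stats::fitted(fit)),
      x = x, y = y, selected = FALSE
    ))
  } else {
    if (is.null(weights)) stop_invalid("engine = 'SAR' requires `weights`")
    fit <- fit_sar_error(y, X, weights)
    fit$response_name <- response_name
    fit$predictor_name <- predictor_name
    fit$order <- order
    fit$n_dropped <- n_dropped
    fit
  }
}

#' Simultaneous autoregressive error model by profile maximum likelihood
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ iid N(0, sigma^2)`,
#' with `W` the row-standardized neighbor matrix. For a candidate `lambda`
#' the model is a GLS whose whitened form `(I - lambda W) y` regresses on
#' `(I - lambda W) X`; the log-likelihood adds the Jacobian
#' `sum(log(1 - lambda e_i))` over the eigenvalues `e_i` of `W`, and
#' `lambda` is profiled out by one-dimensional optimization on (-1, 1).
#' With `lambda = 0` the fit reduces exactly to OLS. The pseudo-R^2 is the
#' squared Pearson correlation between `y` and the full SAR prediction
#' `X beta + lambda W (y - X beta)` (trend plus spatial signal); the
#' trend-only version is reported alongside. The model p-value is a
#' likelihood-ratio test against the intercept-only SAR model on the same
#' weights.
#'
#' @param y Response vector.
#' @param X Numeric matrix of predictors, without an intercept column (one
#'   is added internally).
#' @param weights A `band_weights` object (raw binary; standardized
#'   internally).
#' @return A `band_fit` with `engine = "SAR"`, spatial coefficient `lambda`
#'   and its profile-likelihood standard error, coefficients named Q/S/C
#'   when `X` holds polynomial terms, `r2` (pseudo-R^2), `r2_trend`, AICc
#'   with `K = ncol(X) + 3` (coefficients, intercept is counted in X + 1,
#'   lambda, sigma^2), and whitened residuals.
#' @export
fit_sar_error <- function(y, X, weights) {
  stopifnot(inherits(weights, "band_weights"))
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(weights$W) != n) {
    stop_invalid("y, X and weights must agree in dimension")
  }
  if (n < ncol(X) + 3) stop_invalid("too few observations for a SAR fit")
  if (all(rowSums(weights$W) == 0)) stop_invalid("all bands are isolated in the weights")
  Wr <- row_standardize(weights$W)
  ev <- Re(eigen(Wr, only.values = TRUE)$values)
  lo <- if (min(ev) < 0) max(-0.999, 1 / min(ev) + 1e-6) else -0.999
  hi <- if (max(ev) > 0) min(0.999, 1 / max(ev) - 1e-6) else 0.999
  Xf <- cbind(`(Intercept)` = 1, X)
  profile_ll <- function(lambda) {
    A <- diag(n) - lambda * Wr
    ys <- A %*% y
    Xs <- A %*% Xf
    qr_ <- qr(Xs)
    beta <- qr.coef(qr_, ys)
    rss <- sum((ys - Xs %*% beta)^2)
    if (!is.finite(rss) || rss <= 0) return(-Inf)
    -n / 2 * (log(2 * pi * rss / n) + 1) + sum(log(pmax(1 - lambda * ev, 1e-300)))
  }
  opt <- stats::optimize(profile_ll, c(lo, hi), maximum = TRUE, tol = 1e-9)
  lambda <- opt$maximum
  ll <- opt$objective
  if (!is.finite(ll)) {
    stop_invalid("SAR optimizer failed: non-finite likelihood on (%.3f, %.3f)", lo, hi)
  }
  A <- diag(n) - lambda * Wr
  ys <- drop(A %*% y)
  Xs <- A %*% Xf
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  xtx_inv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  z <- beta / se
  cp <- 2 * stats::pnorm(-abs(z))
  # profile-likelihood observed information for lambda
  h <- 1e-4 * max(1, abs(lambda))
  d2 <- (profile_ll(lambda + h) - 2 * ll + profile_ll(lambda - h)) / h^2
  lambda_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  trend <- drop(Xf %*% beta)
  signal <- lambda * drop(Wr %*% (y - trend))
  yhat <- trend + signal
  r2 <- stats::cor(y, yhat)^2
  r2_trend <- stats::cor(y, trend)^2
  K <- ncol(Xf) + 2L
  # LR test against the intercept-only SAR model on the same weights
  p_model <- if (ncol(X) >= 1) {
    ll0 <- stats::optimize(function(l) {
      A0 <- diag(n) - l * Wr
      y0 <- A0 %*% y
      X0 <- A0 %*% matrix(1, n, 1)
      b0 <- qr.coef(qr(X0), y0)
      rss0 <- sum((y0 - X0 %*% b0)^2)
      if (!is.finite(rss0) || rss0 <= 0) return(-Inf)
      -n / 2 * (log(2 * pi * rss0 / n) + 1) + sum(log(pmax(1 - l * ev, 1e-300)))
    }, c(lo, hi), maximum = TRUE, tol = 1e-9)$objective
    stats::pchisq(2 * (ll - ll0), df = ncol(X), lower.tail = FALSE)
  } else NA_real_
  cname <- c("C", "S", if (ncol(X) >= 2) "Q")
  if (ncol(Xf) == length(cname)) {
    names(beta) <- names(se) <- names(cp) <- cname
    ord <- rev(cname)
  } else {
    ord <- names(beta)
  }
  new_band_fit(list(
    response_name = NA_character_, predictor_name = NA_character_,
    order = ncol(X), engine = "SAR",
    coef = beta[ord], se = se[ord], coef_p = cp[ord],
    r2 = r2, r2_trend = r2_trend, p_value = p_model,
    loglik = ll, aicc = aicc(ll, n, K),
    lambda = lambda, lambda_se = lambda_se,
    n_used = n, n_dropped = 0L,
    residuals = unname(fit$residuals),
    fitted = yhat,
    x = X, y = y, selected = FALSE
  ))
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("<band_fit> %s ~ poly(%s, %d), engine %s\n",
              x$response_name, x$predictor_name, x$order, x$engine))
  cf <- format(signif(x$coef, 4))
  cat("  coefficients:", paste(names(x$coef), cf, sep = " = ", collapse = ", "), "\n")
  if (x$engine == "SAR") {
    cat(sprintf("  lambda = %.3f (SE %.3f), pseudo-R2 = %.4f\n",
                x$lambda, x$lambda_se, x$r2))
  } else {
    cat(sprintf("  adj R2 = %.4f\n", x$r2))
  }
  cat(sprintf("  p = %.3g, AICc = %.2f, n = %d (%d dropped)%s\n",
              x$p_value, x$aicc, x$n_used, x$n_dropped,
              if (isTRUE(x$selected)) " [selected]" else ""))
  invisible(x)
}

#' @export
coef.band_fit <- function(object, ...) object$coef

#' @export
residuals.band_fit <- function(object, ...) object$residuals

#' @export
fitted.band_fit <- function(object, ...) object$fitted

#' Choose between first- and second-order polynomial fits by AICc
#'
#' The lower-AICc fit wins only when it beats the rival by at least 2 AICc
#' units; otherwise the two are considered equally supported and the
#' first-order fit is selected for simplicity.
#'
#' @param fit1,fit2 `band_fit` objects of orders 1 and 2 (either argument
#'   order) on the same response, predictor, engine and band subset.
#' @return The selected fit with `selected = TRUE` and a `delta_aicc` field.
#' @export
select_order <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "band_fit"), inherits(fit2, "band_fit"))
  if (!setequal(c(fit1$order, fit2$order), c(1L, 2L))) {
    stop_invalid("select_order() needs one order-1 and one order-2 fit")
  }
  same <- function(f) identical(fit1[[f]], fit2[[f]])
  if (!same("engine") || !same("response_name") || !same("predictor_name") ||
      fit1$n_used != fit2$n_used) {
    stop_invalid("fits are not comparable (different response, predictor, engine or subset)")
  }
  o1 <- if (fit1$order == 1L) fit1 else fit2
  o2 <- if (fit1$order == 2L) fit1 else fit2
  delta <- abs(o1$aicc - o2$aicc)
  best <- if (delta >= 2 && o2$aicc < o1$aicc) o2 else o1
  best$selected <- TRUE
  best$delta_aicc <- delta
  best
}

#' Compare the two area-correction methods by SAR pseudo-R^2
#'
#' For every richness group and predictor, the area-correction method whose
#' selected SAR model has the larger pseudo-R^2 is judged to preserve that
#' abiotic signal better.
#'
#' @param fits A data frame with columns `group` (richness variable),
#'   `predictor`, `richness_kind` (`"obs"`, `"cor1"`, `"cor2"`) and `r2`.
#' @return A `method_comparison`: the input in long format plus a `winner`
#'   column on the corrected rows (`"method1"`, `"method2"` or `"tie"`,
#'   repeated within each group x predictor cell), with a `wins` attribute
#'   counting cells won by each method.
#' @export
compare_methods <- function(fits) {
  req <- c("group", "predictor", "richness_kind", "r2")
  if (!all(req %in% names(fits))) {
    stop_invalid("fits must have columns %s", paste(req, collapse = ", "))
  }
  fits$winner <- NA_character_
  cells <- unique(fits[, c("group", "predictor")])
  for (i in seq_len(nrow(cells))) {
    sel <- fits$group == cells$group[i] & fits$predictor == cells$predictor[i]
    r1 <- fits$r2[sel & fits$richness_kind == "cor1"]
    r2v <- fits$r2[sel & fits$richness_kind == "cor2"]
    if (length(r1) == 1 && length(r2v) == 1) {
      fits$winner[sel & fits$richness_kind %in% c("cor1", "cor2")] <-
        if (r1 > r2v) "method1" else if (r2v > r1) "method2" else "tie"
    }
  }
  wins <- table(factor(
    fits$winner[fits$richness_kind == "cor2"],
    levels = c("method1", "method2", "tie")
  ))
  structure(fits, class = c("method_comparison", "data.frame"), wins = wins)
}

#' @export
print.method_comparison <- function(x, ...) {
  w <- attr(x, "wins")
  cat(sprintf("<method_comparison> %d cells: method1 wins %d, method2 wins %d, ties %d\n",
              sum(w), w[["method1"]], w[["method2"]], w[["tie"]]))
  NextMethod()
}
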