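# Small fixtures built in code: a toy grid with known cell elevations, a
# default synthetic mountain, and hand-written checklists.

toy_grid <- function(elev, cell_area = 900, domain = range(elev)) {
  structure(
    list(elev = matrix(as.integer(elev), nrow = 1), cell_area = cell_area,
         domain = as.numeric(domain), mat = NULL, map = NULL),
    class = "elevation_grid"
  )
}

default_mountain <- function(seed = 1L, grid_shape = c(60L, 60L), ...) {
  p <- mountain_params(seed = seed, grid_shape = grid_shape, ...)
  generate_climate(generate_elevation_grid(p), p)
}

toy_checklist <- function(species, genus, family, lifeform, elev_min, elev_max,
                          domain = c(1350, 5050)) {
  df <- data.frame(species = species, genus = genus, family = family,
                   lifeform = lifeform, elev_min = elev_min,
                   elev_max = elev_max, stringsAsFactors = FALSE)
  class(df) <- c("checklist", "data.frame")
  attr(df, "domain") <- domain
  df
}

# A random valid checklist for property tests.
random_checklist <- function(n, domain = c(0, 1000), seed = 1L) {
  set.seed(seed)
  span <- diff(domain)
  r <- runif(n, 0, span)
  r[runif(n) < 0.2] <- 0
  m <- runif(n, domain[1] + r / 2, domain[2] - r / 2)
  ng <- max(1L, n %/% 3L)
  gid <- sample.int(ng, n, replace = TRUE)
  fam <- sample.int(max(1L, ng %/% 4L), ng, replace = TRUE)
  toy_checklist(
    species = sprintf("sp%03d", seq_len(n)),
    genus = sprintf("g%03d", gid),
    family = sprintf("f%02d", fam[gid]),
    lifeform = sample(c("tree", "shrub", "herb"), n, replace = TRUE),
    elev_min = m - r / 2, elev_max = m + r / 2,
    domain = domain
  )
}

# Brute-force Moran's I: a literal double loop over Eq.-style sums,
# independent of the vectorized implementation.
morans_i_bruteforce <- function(x, W) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * (x[i] - xbar) * (x[j] - xbar)
    }
  }
  (n / sum(W)) * num / sum((x - xbar)^2)
}

# Simulate an error-SAR process y = X beta + u, u = lambda W u + eps,
# on row-standardized rank-adjacency weights.
simulate_sar <- function(n, beta, lambda, sigma = 1, seed = 1L) {
  set.seed(seed)
  x <- seq_len(n)
  X <- cbind(1, x)
  w <- rank_weights(n)
  Wr <- w$W / pmax(rowSums(w$W), 1)
  eps <- rnorm(n, 0, sigma)
  u <- solve(diag(n) - lambda * Wr, eps)
  list(y = drop(X %*% beta + u), x = x, weights = w)
}
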