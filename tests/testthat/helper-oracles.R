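# Independent oracles used across tests. These are deliberately naive and
# share no code with the package internals.

# ordinary least squares via the normal equations
ols_oracle <- function(x, y) {
  x1 <- cbind(1, as.matrix(x))
  as.numeric(solve(crossprod(x1), crossprod(x1, y)))
}

# the lasso objective the solver claims to minimize, on the internally
# standardized scale (matching lasso_fit with standardize = TRUE)
lasso_objective <- function(x, y, beta_std, b0_std, lambda) {
  xs <- scale(x, scale = apply(x, 2, function(v) sqrt(mean((v - mean(v))^2))))
  r <- (y - mean(y)) - xs %*% beta_std
  sum(r^2) / (2 * length(y)) + lambda * sum(abs(beta_std))
}

# quadratic-programming-style brute force: split beta = bp - bn, bp, bn >= 0,
# smooth objective, box-constrained BFGS; operates on the standardized scale
qp_lasso_oracle <- function(x, y, lambda) {
  xs <- scale(x, scale = apply(x, 2, function(v) sqrt(mean((v - mean(v))^2))))
  yc <- y - mean(y)
  n <- length(y); p <- ncol(xs)
  fn <- function(par) {
    b <- par[1:p] - par[p + 1:p]
    sum((yc - xs %*% b)^2) / (2 * n) + lambda * sum(par)
  }
  gr <- function(par) {
    b <- par[1:p] - par[p + 1:p]
    g <- -as.numeric(crossprod(xs, yc - xs %*% b)) / n
    c(g + lambda, -g + lambda)
  }
  fit <- optim(rep(0, 2 * p), fn, gr, method = "L-BFGS-B",
               lower = 0, control = list(maxit = 2000, factr = 1e4))
  fit$par[1:p] - fit$par[p + 1:p]
}

# random design with exactly orthonormal columns under the 1/n inner product
orthonormal_design <- function(n, p) {
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  q * sqrt(n)
}

# a small raw panel shared by several test files
tiny_panel <- function(n = 250, seed = 99, truth = true_network()) {
  simulate_cohort(generator_config(n_participants = n, seed = seed,
                                   true_network = truth))
}

# construct a clpn_network by hand (for evaluation-module tests)
fake_network <- function(mat, covariates = "age", wave_pair = c(1, 2)) {
  nodes <- rownames(mat)
  structure(list(wave_pair = wave_pair, nodes = nodes, matrix = mat,
                 covariate_effects = matrix(0, length(covariates), length(nodes),
                                            dimnames = list(covariates, nodes)),
                 covariates = covariates, n_used = 100L, rule = "min"),
            class = "clpn_network")
}
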