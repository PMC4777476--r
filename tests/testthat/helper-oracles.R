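# Independent oracles used to cross-check the package's own implementations.

# Benjamini-Hochberg acceptance via R's canonical adjusted-p implementation.
oracle_bh <- function(p, q) stats::p.adjust(p, method = "BH") <= q

# Trapezoidal area under the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Direct likelihood maximisation with Nelder-Mead from several starts; the
# brute-force reference for IRLS on tiny instances.
oracle_logit_ml <- function(x, y) {
  X <- cbind(1, as.matrix(x))
  nll <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  best <- NULL
  for (start in list(rep(0, ncol(X)), rep(0.5, ncol(X)), rep(-0.5, ncol(X)))) {
    fit <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$par
}

# Moran's I from its definition, written independently of the package.
oracle_morans_i <- function(values, lon, lat, radius) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((lon[i] - lon[j])^2 + (lat[i] - lat[j])^2)
    if (d <= radius) { num <- num + z[i] * z[j]; s0 <- s0 + 1 }
  }
  (n / s0) * num / sum(z^2)
}

# A small deterministic logistic dataset for reuse across tests.
make_logit_data <- function(n = 400, beta0 = -1, beta1 = 1.5, seed = 42) {
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    y <- stats::rbinom(n, 1, stats::plogis(beta0 + beta1 * x))
    list(x = matrix(x, ncol = 1, dimnames = list(NULL, "x1")), y = y)
  })
}
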