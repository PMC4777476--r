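#' Fit a binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression for a 0/1 response, written as a
#' small self-contained engine so that every downstream stage (stepwise
#' selection, screening, trend-surface fitting, variation partitioning) runs
#' on one well-understood fitter with explicit convergence and separation
#' diagnostics.
#'
#' The design matrix is the numeric matrix (or data frame) of non-intercept
#' terms; an intercept column is always prepended internally. Convergence is
#' declared when the largest absolute coefficient update falls below `tol`
#' (default 1e-8) or after `max_iter` iterations. Complete or
#' quasi-complete separation is detected as coefficient divergence
#' (some |beta| > 15 while the likelihood is still improving) and reported via
#' the `separation` flag rather than as an error, because univariate screening
#' legitimately encounters quasi-separated columns.
#'
#' @param x numeric matrix or data frame of predictor columns (no intercept);
#'   may have zero columns for an intercept-only model.
#' @param y binary response vector (0/1), same length as `nrow(x)`.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the coefficient update.
#'
#' @return an object of class `"geofav_logit"`: a list with elements
#'   `terms` (term names, intercept first), `beta`, `se`, `z`, `p_value`
#'   (Wald tests), `log_lik`, `null_log_lik`, `n`, `n1`, `n0`, `df` (number of
#'   estimated coefficients), `converged`, `separation`, `entry_order`
#'   (filled by [stepwise()]; `NA` otherwise) and `fitted` (in-sample
#'   probabilities).
#'
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "x1"))
#' y <- rbinom(200, 1, plogis(-1 + 1.5 * x[, 1]))
#' m <- fit_logistic(x, y)
#' coef(m)
#' @export
fit_logistic <- function(x, y, max_iter = 50L, tol = 1e-8) {
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y have different numbers of rows")
  if (anyNA(x) || anyNA(y)) stop("missing values in design or response")
  if (any(!is.finite(x))) stop("non-finite values in design matrix")
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("response has a single class; both classes required")

  if (ncol(x) > 0 && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  n <- nrow(X)

  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design; aliased columns: ", paste(bad, collapse = ", "))
  }

  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  improving <- TRUE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X, XtW %*% z),
      error = function(e) stop("IRLS normal equations singular: ", conditionMessage(e))
    )
    beta_new <- drop(beta_new)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll_new <- .binom_loglik(y, stats::plogis(drop(X %*% beta)))
    improving <- (ll_new - ll_old) > 1e-8
    ll_old <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }

  mu <- stats::plogis(drop(X %*% beta))
  log_lik <- .binom_loglik(y, mu)
  separation <- (max(abs(beta)) > 15) && (improving || !converged)

  # observed (= expected) information at the MLE
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(X * w) %*% X
  vcv <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcv), 0))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  p_null <- n1 / n
  null_log_lik <- n1 * log(p_null) + n0 * log(1 - p_null)

  structure(list(
    terms = colnames(X),
    beta = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(zval, colnames(X)),
    p_value = stats::setNames(pval, colnames(X)),
    log_lik = log_lik,
    null_log_lik = null_log_lik,
    n = n, n1 = n1, n0 = n0,
    df = p,
    converged = converged,
    separation = separation,
    entry_order = stats::setNames(rep(NA_integer_, p - 1L),
                                  colnames(X)[-1L][seq_len(max(p - 1L, 0L))]),
    fitted = mu
  ), class = "geofav_logit")
}

.binom_loglik <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-15), 1 - 1e-15)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' @export
coef.geofav_logit <- function(object, ...) object$beta

#' @export
logLik.geofav_logit <- function(object, ...) {
  structure(object$log_lik, df = object$df, class = "logLik")
}

#' @export
print.geofav_logit <- function(x, ...) {
  cat("Logistic model (IRLS):", length(x$terms) - 1L, "term(s),",
      "n =", x$n, sprintf("(%d/%d presences/absences)\n", x$n1, x$n0))
  tab <- data.frame(beta = x$beta, se = x$se, p = x$p_value)
  print(round(tab, 4))
  cat(sprintf("logLik %.3f (null %.3f)  AIC %.2f  Nagelkerke R2 %.4f\n",
              x$log_lik, x$null_log_lik, model_aic(x), nagelkerke_r2(x)))
  if (!x$converged) cat("warning: IRLS did not converge\n")
  if (x$separation) cat("warning: separation detected (diverging coefficients)\n")
  invisible(x)
}

#' Predict probabilities from a fitted logistic model
#'
#' @param object a `"geofav_logit"` model.
#' @param newdata data frame or matrix containing every non-intercept term of
#'   the model as a column. If omitted, in-sample fitted probabilities are
#'   returned.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor (logit).
#' @param ... unused.
#' @return numeric vector of probabilities (or logits).
#' @export
predict.geofav_logit <- function(object, newdata = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    return(stats::qlogis(object$fitted))
  }
  terms <- setdiff(object$terms, "(Intercept)")
  missing_terms <- setdiff(terms, colnames(newdata))
  if (length(missing_terms))
    stop("newdata lacks model term(s): ", paste(missing_terms, collapse = ", "))
  X <- cbind(1, as.matrix(as.data.frame(newdata, check.names = FALSE)[, terms, drop = FALSE]))
  eta <- drop(X %*% object$beta)
  if (type == "link") eta else stats::plogis(eta)
}

#' Likelihood-ratio test between nested logistic models
#'
#' Compares two models fitted to the same data, the reduced model's terms a
#' subset of the full model's, with a chi-squared test on twice the
#' log-likelihood difference.
#'
#' @param full,reduced fitted `"geofav_logit"` models on identical data.
#' @return a list with `statistic`, `df` and `p_value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "geofav_logit"), inherits(reduced, "geofav_logit"))
  if (!all(reduced$terms %in% full$terms))
    stop("models are not nested: reduced terms must be a subset of full terms")
  if (full$n != reduced$n || full$n1 != reduced$n1)
    stop("models were fitted to different data")
  stat <- max(2 * (full$log_lik - reduced$log_lik), 0)
  df <- full$df - reduced$df
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Nagelkerke's pseudo-R-squared (deviance explained)
#'
#' R2 = \[1 - exp(2(ll0 - ll)/n)\] / \[1 - exp(2 ll0 / n)\], where ll is the
#' maximised log-likelihood, ll0 the intercept-only log-likelihood and n the
#' number of observations.
#'
#' @param model a fitted `"geofav_logit"` model.
#' @return numeric value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(model) {
  stopifnot(inherits(model, "geofav_logit"))
  if (model$n == 0) stop("model has no observations")
  cox_snell <- 1 - exp(2 * (model$null_log_lik - model$log_lik) / model$n)
  max_cs <- 1 - exp(2 * model$null_log_lik / model$n)
  cox_snell / max_cs
}

#' Akaike Information Criterion of a fitted logistic model
#'
#' AIC = 2k - 2 logLik with k the number of estimated coefficients including
#' the intercept.
#'
#' @param model a fitted `"geofav_logit"` model.
#' @return numeric AIC value.
#' @export
model_aic <- function(model) {
  stopifnot(inherits(model, "geofav_logit"))
  2 * model$df - 2 * model$log_lik
}
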