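#' Benjamini-Hochberg false-discovery-rate step-up acceptance
#'
#' Given a vector of p-values, returns a logical flag per item marking which
#' are accepted when the false discovery rate is controlled at `q`. The
#' step-up rule sorts the p-values ascending, finds the largest i with
#' p(i) <= i * q / m, and accepts every item whose p-value does not exceed
#' that p(i); if no i qualifies, nothing is accepted.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q target false discovery rate in (0, 1).
#' @return logical vector, `TRUE` where the item is accepted.
#' @examples
#' bh_fdr(c(0.001, 0.04, 0.2), q = 0.05)  # only the first survives
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  p_values <= ps[max(ok)]
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j is the coefficient of determination of
#' an ordinary least-squares regression of column j on the remaining columns.
#' Used as the multicollinearity diagnostic on the terms of a final combined
#' model.
#'
#' @param x numeric matrix or data frame with at least two columns, each with
#'   nonzero variance.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(as.data.frame(x, check.names = FALSE))
  if (ncol(x) < 2) stop("vif needs at least two columns")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1))
  stats::setNames(out, colnames(x))
}

#' Forward-backward stepwise logistic regression
#'
#' Selects terms by significance testing with likelihood-ratio tests.
#' Each cycle first tries a forward step: among candidates not in the model,
#' the one with the smallest likelihood-ratio p-value enters if that p-value
#' is below `p_enter` (ties broken by the larger deviance reduction, then by
#' candidate order). It then tries a backward step: the included term with
#' the largest removal p-value leaves if that p-value exceeds `p_remove`.
#' Selection stops when neither step fires. Candidates whose addition makes
#' the design rank-deficient (e.g. duplicated columns) are skipped.
#'
#' @param candidates data frame or matrix of candidate term columns.
#' @param y binary response (0/1).
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10); must be >= `p_enter` to
#'   prevent cycling.
#' @param direction `"both"` for forward-backward, `"backward"` to start from
#'   the full model and only eliminate.
#' @return a `"geofav_logit"` model with `entry_order` filled and an extra
#'   element `trace`: a data frame logging every attempted step with its
#'   p-value.
#' @export
stepwise <- function(candidates, y, p_enter = 0.05, p_remove = 0.10,
                     direction = c("both", "backward")) {
  direction <- match.arg(direction)
  candidates <- as.data.frame(candidates, check.names = FALSE)
  if (p_enter > p_remove) stop("p_enter must be <= p_remove (prevents cycling)")
  cand_names <- colnames(candidates)
  trace <- list()
  note <- function(action, term, p) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = length(trace) + 1L, action = action, term = term,
      p_value = p, stringsAsFactors = FALSE)
  }

  refit <- function(terms) {
    fit_logistic(candidates[, terms, drop = FALSE], y)
  }

  included <- character(0)
  entry_rank <- integer(0)
  if (direction == "backward") {
    # start from the largest full-rank subset, in declared order
    for (nm in cand_names) {
      ok <- tryCatch({ refit(c(included, nm)); TRUE },
                     error = function(e) FALSE)
      if (ok) included <- c(included, nm)
    }
    entry_rank <- stats::setNames(seq_along(included), included)
  }
  current <- refit(included)

  max_cycles <- 2L * length(cand_names) + 2L
  for (cycle in seq_len(max_cycles)) {
    acted <- FALSE

    if (direction == "both") {
      pool <- setdiff(cand_names, included)
      if (length(pool)) {
        best <- NULL
        for (nm in pool) {
          fit_try <- tryCatch(refit(c(included, nm)), error = function(e) NULL)
          if (is.null(fit_try)) next  # rank-degenerate addition
          lt <- lr_test(fit_try, current)
          dev_red <- 2 * (fit_try$log_lik - current$log_lik)
          if (is.null(best) || lt$p_value < best$p - 1e-12 ||
              (abs(lt$p_value - best$p) <= 1e-12 && dev_red > best$dev + 1e-12)) {
            best <- list(nm = nm, p = lt$p_value, dev = dev_red, fit = fit_try)
          }
        }
        if (!is.null(best) && best$p < p_enter) {
          included <- c(included, best$nm)
          entry_rank[best$nm] <- length(entry_rank) + 1L
          current <- best$fit
          note("add", best$nm, best$p)
          acted <- TRUE
        }
      }
    }

    if (length(included)) {
      worst <- NULL
      for (nm in included) {
        reduced <- refit(setdiff(included, nm))
        lt <- lr_test(current, reduced)
        if (is.null(worst) || lt$p_value > worst$p)
          worst <- list(nm = nm, p = lt$p_value, fit = reduced)
      }
      if (!is.null(worst) && worst$p > p_remove) {
        included <- setdiff(included, worst$nm)
        entry_rank <- entry_rank[names(entry_rank) != worst$nm]
        if (length(entry_rank)) entry_rank[] <- rank(entry_rank)
        current <- worst$fit
        note("drop", worst$nm, worst$p)
        acted <- TRUE
      }
    }

    if (!acted) break
    if (cycle == max_cycles)
      stop("stepwise selection failed to settle (possible cycling); ",
           "check p_enter <= p_remove and candidate collinearity")
  }

  current$entry_order <- stats::setNames(
    as.integer(entry_rank[included]), included)
  current$trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), action = character(0), term = character(0),
               p_value = numeric(0))
  current
}
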