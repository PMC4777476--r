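#' Screen a predictor set by univariate tests under FDR control
#'
#' For each column assigned to `set_name` (quadratic terms included, each
#' tested as a single-term model), computes the likelihood-ratio p-value of
#' the univariate logistic model against the intercept-only model, then
#' applies the Benjamini-Hochberg step-up within the set at rate `q`.
#' Only survivors go forward as stepwise candidates; an empty survivor set is
#' legal and simply contributes no candidates.
#'
#' @param data grid table with predictor columns.
#' @param sets named character vector mapping predictor columns to set names.
#' @param set_name the predictor set to screen.
#' @param presence binary response (0/1).
#' @param q false discovery rate (default 0.05).
#' @return character vector of retained column names (possibly empty), with
#'   the univariate p-values as a `p_value` attribute.
#' @export
screen_predictor_set <- function(data, sets, set_name, presence, q = 0.05) {
  cols <- names(sets)[sets == set_name]
  if (length(cols) == 0) stop("predictor set '", set_name, "' is empty")
  missing_cols <- setdiff(cols, colnames(data))
  if (length(missing_cols))
    stop("column(s) absent from data: ", paste(missing_cols, collapse = ", "))
  null_fit <- fit_logistic(NULL, presence)
  pvals <- vapply(cols, function(nm) {
    fit <- fit_logistic(data[, nm, drop = FALSE], presence)
    lr_test(fit, null_fit)$p_value
  }, numeric(1))
  keep <- bh_fdr(pvals, q)
  structure(cols[keep], p_value = pvals)
}

#' Fit a predictor-set model by stepwise selection over screened columns
#'
#' Forward-backward stepwise logistic regression restricted to the columns
#' that survived FDR screening for one predictor set. An empty retained set
#' yields the intercept-only model.
#'
#' @param data grid table with predictor columns.
#' @param retained column names surviving [screen_predictor_set()].
#' @param presence binary response (0/1).
#' @param p_enter,p_remove stepwise thresholds.
#' @return a `"geofav_logit"` model.
#' @export
fit_predictor_set_model <- function(data, retained, presence,
                                    p_enter = 0.05, p_remove = 0.10) {
  if (length(retained) == 0) return(fit_logistic(NULL, presence))
  stepwise(data[, retained, drop = FALSE], presence,
           p_enter = p_enter, p_remove = p_remove)
}

#' Split cells into training and validation parts
#'
#' Uniform random split without replacement into a training part of size
#' `floor(fraction * n)` and the remainder. The split is redrawn (up to 100
#' times) until both parts contain both classes; with `stratified = TRUE`
#' the split is drawn within each class instead.
#'
#' @param presence binary response (0/1).
#' @param fraction training share in (0, 1); default 0.7.
#' @param seed integer seed.
#' @param stratified draw the split within each class.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(presence, fraction = 0.7, seed = 1L,
                             stratified = FALSE) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n <- length(presence)
  n_train <- floor(fraction * n)
  if (n_train < 1 || n_train >= n) stop("split leaves an empty part")
  draw <- function(s) {
    withr::with_seed(s, {
      if (stratified) {
        idx1 <- which(presence == 1); idx0 <- which(presence == 0)
        k1 <- round(fraction * length(idx1))
        tr <- c(sample(idx1, k1), sample(idx0, n_train - k1))
      } else {
        tr <- sample.int(n, n_train)
      }
      sort(tr)
    })
  }
  for (try in seq_len(100)) {
    train <- draw(as.integer(seed) + (try - 1L) * 131L)
    test <- setdiff(seq_len(n), train)
    ok <- length(unique(presence[train])) == 2 &&
      length(unique(presence[test])) == 2
    if (ok) return(list(train = train, test = test))
  }
  stop("could not produce a split with both classes in both parts")
}

#' Fit the space-included / space-excluded combined model pair
#'
#' Pools the variables retained in the predictor-set models and runs
#' forward-backward stepwise selection twice on the training cells: once
#' with the geographic set's variables among the candidates (the
#' space-included model) and once with them withheld (the space-excluded
#' model). Variance inflation factors are computed on each final model's
#' terms.
#'
#' @param data grid table with predictor columns (including the trend-surface
#'   column when used).
#' @param sets named character vector mapping columns to predictor sets;
#'   the geographic set must be named `"geographic"`.
#' @param set_models named list of predictor-set models (from
#'   [fit_predictor_set_model()]).
#' @param presence binary response (0/1).
#' @param train integer indices of the training cells.
#' @param p_enter,p_remove stepwise thresholds.
#' @return object of class `"geofav_pair"`: list with `space_included`,
#'   `space_excluded` (fitted models), `vif_included`, `vif_excluded`,
#'   `train`, `candidates`.
#' @export
fit_combined_pair <- function(data, sets, set_models, presence, train,
                              p_enter = 0.05, p_remove = 0.10) {
  pool <- unique(unlist(lapply(set_models, function(m)
    setdiff(m$terms, "(Intercept)"))))
  if (length(pool) == 0)
    stop("no predictor-set model retained any variable")
  geog_cols <- intersect(pool, names(sets)[sets == "geographic"])
  pool_excl <- setdiff(pool, geog_cols)

  tr_data <- data[train, , drop = FALSE]
  tr_y <- presence[train]
  inc <- stepwise(tr_data[, pool, drop = FALSE], tr_y,
                  p_enter = p_enter, p_remove = p_remove)
  exc <- if (length(pool_excl)) {
    stepwise(tr_data[, pool_excl, drop = FALSE], tr_y,
             p_enter = p_enter, p_remove = p_remove)
  } else fit_logistic(NULL, tr_y)

  vif_of <- function(m) {
    tt <- setdiff(m$terms, "(Intercept)")
    if (length(tt) >= 2) vif(tr_data[, tt, drop = FALSE]) else
      stats::setNames(rep(NA_real_, length(tt)), tt)
  }
  structure(list(space_included = inc, space_excluded = exc,
                 vif_included = vif_of(inc), vif_excluded = vif_of(exc),
                 train = train, candidates = pool),
            class = "geofav_pair")
}

#' Evaluate a fitted model on held-out cells
#'
#' Computes probabilities on the validation cells, converts them to
#' favourability with the training presence/absence counts (those
#' parameterise the fitted model's prevalence), and reports sensitivity,
#' specificity and CCR at the neutral favourability threshold F >= 0.5
#' together with the AUC of favourability. Deviance explained (Nagelkerke)
#' and AIC describe the training fit itself.
#'
#' @param model a `"geofav_logit"` model fitted on the training cells.
#' @param data grid table with predictor columns.
#' @param presence binary response (0/1) for all cells.
#' @param test integer indices of the validation cells (both classes
#'   required).
#' @param threshold favourability classification threshold (default 0.5, the
#'   neutral value).
#' @return list with `sensitivity`, `specificity`, `ccr`, `auc`,
#'   `deviance_explained`, `aic`.
#' @export
evaluate_model <- function(model, data, presence, test, threshold = 0.5) {
  if (length(test) == 0) stop("empty validation set")
  y <- presence[test]
  if (length(unique(y)) < 2)
    stop("validation cells contain a single class")
  p <- predict(model, data[test, , drop = FALSE])
  f <- favourability(p, model$n1, model$n0)
  cm <- confusion_metrics(f, y, threshold)
  list(sensitivity = cm$sensitivity,
       specificity = cm$specificity,
       ccr = cm$ccr,
       auc = roc_auc(f, y),
       deviance_explained = nagelkerke_r2(model),
       aic = model_aic(model))
}

#' Partition a combined model's explained variation across predictor sets
#'
#' Decomposes the Nagelkerke R-squared of a fitted combined model into pure
#' and shared fractions over the predictor sets represented in the model.
#' For every non-empty subset S of those sets, the model containing exactly
#' the combined model's terms belonging to S is refitted (fixed variable
#' lists — no reselection) on the same cells, giving R2(S). Exclusive
#' fractions follow by inclusion-exclusion (Moebius inversion of the
#' variation lost when sets are removed), so pure fractions are singleton
#' subsets, shared fractions larger subsets, and all fractions sum exactly
#' to the full model's R2. Shared fractions can legitimately be negative
#' (suppression between predictor sets).
#'
#' @param model the combined `"geofav_logit"` model.
#' @param sets named character vector mapping columns to predictor sets.
#' @param data grid table with predictor columns.
#' @param presence binary response for the same cells the model was fitted
#'   on (pass the training rows).
#' @return object of class `"geofav_partition"`: data frame with columns
#'   `sets` (subset label, "+"-joined), `n_sets`, `fraction` and `pct`
#'   (fraction as a percentage of the total), plus attribute `total` (the
#'   full model's R2).
#' @export
variation_partition <- function(model, sets, data, presence) {
  terms <- setdiff(model$terms, "(Intercept)")
  if (length(terms) == 0) stop("intercept-only model cannot be partitioned")
  term_set <- sets[terms]
  if (anyNA(term_set))
    stop("term(s) without a set assignment: ",
         paste(terms[is.na(term_set)], collapse = ", "))
  present <- unique(unname(term_set))
  k <- length(present)

  r2_of <- function(set_subset) {
    tt <- terms[term_set %in% set_subset]
    if (length(tt) == 0) return(0)
    nagelkerke_r2(fit_logistic(data[, tt, drop = FALSE], presence))
  }

  key <- function(s) if (length(s) == 0) "(none)" else paste(sort(s), collapse = "+")
  subsets <- lapply(seq_len(2^k) - 1L, function(m) present[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0])
  r2 <- vapply(subsets, r2_of, numeric(1))
  names(r2) <- vapply(subsets, key, "")
  total <- r2[[length(r2)]]  # full set

  # u(S) = R2(full) - R2(complement of S); fractions by Moebius inversion
  u <- function(s) total - r2[[key(setdiff(present, s))]]
  frac <- numeric(0)
  labels <- character(0)
  sizes <- integer(0)
  for (tset in subsets[-1]) {
    subs_of_t <- lapply(seq_len(2^length(tset)) - 1L, function(m)
      tset[bitwAnd(m, 2^(seq_len(length(tset)) - 1L)) > 0])
    val <- sum(vapply(subs_of_t, function(s)
      (-1)^(length(tset) - length(s)) * u(s), numeric(1)))
    frac <- c(frac, val)
    labels <- c(labels, key(tset))
    sizes <- c(sizes, length(tset))
  }
  out <- data.frame(sets = labels, n_sets = sizes, fraction = frac,
                    pct = 100 * frac / total, stringsAsFactors = FALSE)
  out <- out[order(out$n_sets, out$sets), ]
  rownames(out) <- NULL
  attr(out, "total") <- unname(total)
  class(out) <- c("geofav_partition", class(out))
  out
}

#' Project a fitted model onto a future climate scenario
#'
#' Recomputes probabilities and favourability with the fitted coefficients
#' unchanged, after replacing the current values of climatic predictors with
#' the scenario's values. Quadratic columns (named `<parent>^2`) are
#' recomputed as the square of their shifted parent, never replaced
#' independently; land-use, topographic and geographic (trend-surface) terms
#' are held at their current values — coordinates do not change over time.
#'
#' @param model the fitted combined `"geofav_logit"` model.
#' @param data current grid table.
#' @param scenario a `"geofav_scenario"` (or `NULL` for the current surface).
#' @param sets named character vector mapping columns to predictor sets.
#' @param n1,n0 presence/absence counts parameterising the favourability
#'   transformation (use the full dataset's counts for final maps).
#' @return object of class `"geofav_surface"`: data frame with `cell_id`,
#'   `probability`, `favourability` and attribute `scenario_label`.
#' @export
project_future <- function(model, data, scenario = NULL, sets, n1, n0) {
  newdata <- data
  label <- "current"
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "geofav_scenario"))
    repl <- scenario$replacements
    if (!identical(repl$cell_id, data$cell_id)) {
      idx <- match(data$cell_id, repl$cell_id)
      if (anyNA(idx)) stop("scenario cells do not match the grid")
      repl <- repl[idx, , drop = FALSE]
    }
    repl_cols <- setdiff(colnames(repl), "cell_id")
    for (nm in repl_cols) newdata[[nm]] <- repl[[nm]]
    # recompute quadratic columns from their (possibly shifted) parents
    quad <- grep("\\^2$", colnames(newdata), value = TRUE)
    for (nm in quad) {
      parent <- sub("\\^2$", "", nm)
      if (parent %in% colnames(newdata))
        newdata[[nm]] <- newdata[[parent]]^2
    }
    # every climatic model term must be covered by the scenario
    terms <- setdiff(model$terms, "(Intercept)")
    clim_terms <- terms[!is.na(sets[terms]) & sets[terms] == "climate"]
    needed <- unique(sub("\\^2$", "", clim_terms))
    uncovered <- setdiff(needed, repl_cols)
    if (length(uncovered))
      stop("scenario is missing climatic column(s): ",
           paste(uncovered, collapse = ", "))
    label <- scenario$label
  }
  p <- predict(model, newdata)
  out <- data.frame(cell_id = data$cell_id, probability = p,
                    favourability = favourability(p, n1, n0),
                    stringsAsFactors = FALSE)
  attr(out, "scenario_label") <- label
  class(out) <- c("geofav_surface", class(out))
  out
}

#' Run the full favourability modelling workflow on a grid table
#'
#' End-to-end orchestration for one species: (1) build the trend-surface
#' geographic predictor from cell-centroid coordinates; (2) screen each
#' predictor set under FDR control; (3) fit a stepwise model per set;
#' (4) split cells 70/30, fit the combined space-included and space-excluded
#' models on the training part and evaluate both on the validation part at
#' the neutral favourability threshold; (5) partition each combined model's
#' explained variation across predictor sets; (6) compute current
#' favourability surfaces for all cells and, if scenarios are given, project
#' each model onto them.
#'
#' @param data grid table: `cell_id`, `lon`, `lat`, `presence`, predictor
#'   columns.
#' @param sets named character vector mapping predictor columns to sets
#'   (`climate`, `land_use`, `topography`; the trend-surface column is added
#'   automatically under `geographic`).
#' @param scenarios list of `"geofav_scenario"` objects (may be empty).
#' @param q FDR rate for screening.
#' @param p_enter,p_remove stepwise thresholds.
#' @param split_fraction,split_seed,stratified training-split controls.
#' @param geog_mode `"all-data"` fits the trend surface on every cell before
#'   the split (the conventional data-preparation reading); `"split-safe"`
#'   fits it on the training cells only, avoiding any leakage into the
#'   validation part.
#' @return object of class `"geofav_run"`: list with `geog`, `screened`,
#'   `set_models`, `split`, `pair`, `evaluation` (per model), `partition`
#'   (per model), `surfaces` (current + one per scenario per model), `sets`,
#'   `config`.
#' @export
run_favourability_pipeline <- function(data, sets, scenarios = list(),
                                       q = 0.05, p_enter = 0.05,
                                       p_remove = 0.10,
                                       split_fraction = 0.7, split_seed = 1L,
                                       stratified = FALSE,
                                       geog_mode = c("all-data", "split-safe")) {
  geog_mode <- match.arg(geog_mode)
  required <- c("cell_id", "lon", "lat", "presence")
  missing_cols <- setdiff(required, colnames(data))
  if (length(missing_cols))
    stop("grid table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(data$cell_id)) stop("cell_id values are not unique")
  presence <- data$presence
  if (anyNA(presence) || !all(presence %in% c(0, 1)))
    stop("presence must be binary 0/1 with no missing values")

  split <- split_train_test(presence, fraction = split_fraction,
                            seed = split_seed, stratified = stratified)

  # trend-surface geographic predictor
  if (geog_mode == "all-data") {
    basis <- build_basis(data$lon, data$lat)
    geog <- fit_geog(basis, presence, p_remove = p_remove)
    data$Geog <- geog$values
  } else {
    basis <- build_basis(data$lon[split$train], data$lat[split$train])
    geog <- fit_geog(basis, presence[split$train], p_remove = p_remove)
    data$Geog <- predict_geog(geog, data$lon, data$lat)
  }
  sets <- c(sets, Geog = "geographic")

  set_names <- unique(unname(sets))
  screened <- lapply(stats::setNames(set_names, set_names), function(s)
    screen_predictor_set(data, sets, s, presence, q = q))
  set_models <- lapply(screened, function(cols)
    fit_predictor_set_model(data, cols, presence,
                            p_enter = p_enter, p_remove = p_remove))

  pair <- fit_combined_pair(data, sets, set_models, presence, split$train,
                            p_enter = p_enter, p_remove = p_remove)

  evaluation <- list(
    space_included = evaluate_model(pair$space_included, data, presence,
                                    split$test),
    space_excluded = evaluate_model(pair$space_excluded, data, presence,
                                    split$test))

  partition <- lapply(pair[c("space_included", "space_excluded")], function(m) {
    tt <- setdiff(m$terms, "(Intercept)")
    if (length(tt) == 0) return(NULL)
    tryCatch(variation_partition(m, sets, data[split$train, , drop = FALSE],
                                 presence[split$train]),
             error = function(e) NULL)
  })

  n1 <- sum(presence == 1); n0 <- sum(presence == 0)
  surfaces <- list()
  for (mn in c("space_included", "space_excluded")) {
    m <- pair[[mn]]
    surfaces[[paste0(mn, ".current")]] <-
      project_future(m, data, NULL, sets, n1, n0)
    for (sc in scenarios) {
      surfaces[[paste0(mn, ".", sc$label)]] <-
        project_future(m, data, sc, sets, n1, n0)
    }
  }

  structure(list(geog = geog, screened = screened, set_models = set_models,
                 split = split, pair = pair, evaluation = evaluation,
                 partition = partition, surfaces = surfaces,
                 data = data, sets = sets,
                 config = list(q = q, p_enter = p_enter, p_remove = p_remove,
                               split_fraction = split_fraction,
                               split_seed = split_seed,
                               stratified = stratified,
                               geog_mode = geog_mode)),
            class = "geofav_run")
}

#' @export
print.geofav_run <- function(x, ...) {
  cat("Favourability modelling run:", nrow(x$data), "cells,",
      sum(x$data$presence), "presences\n")
  for (mn in c("space_included", "space_excluded")) {
    m <- x$pair[[mn]]
    ev <- x$evaluation[[mn]]
    cat(sprintf("%s: %d term(s); DE %.3f  AUC %.3f  sens %.3f  spec %.3f  CCR %.3f  AIC %.1f\n",
                mn, length(m$terms) - 1L, ev$deviance_explained, ev$auc,
                ev$sensitivity, ev$specificity, ev$ccr, ev$aic))
  }
  invisible(x)
}
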