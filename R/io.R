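#' Read and write grid tables and scenario tables as CSV
#'
#' The grid CSV carries one row per cell with columns `cell_id`, `lon`,
#' `lat`, `presence`, then one column per predictor (quadratic terms use the
#' `<name>^2` naming convention). A scenario CSV carries `cell_id` plus the
#' climatic columns only. Values round-trip at full double precision.
#'
#' @param path file path.
#' @return `read_grid_csv`: the grid data frame; `read_scenario_csv`: a
#'   `"geofav_scenario"` object.
#' @name grid_io
NULL

#' @rdname grid_io
#' @param data grid data frame to write.
#' @export
write_grid_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_grid_csv <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  data <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("cell_id", "lon", "lat")
  missing_cols <- setdiff(required, colnames(data))
  if (length(missing_cols))
    stop("grid CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  data$cell_id <- as.character(data$cell_id)
  data
}

#' @rdname grid_io
#' @param scenario a `"geofav_scenario"` to write.
#' @export
write_scenario_csv <- function(scenario, path) {
  stopifnot(inherits(scenario, "geofav_scenario"))
  utils::write.csv(scenario$replacements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname grid_io
#' @param label scenario label; defaults to the file name without extension.
#' @export
read_scenario_csv <- function(path, label = NULL) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  repl <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"cell_id" %in% colnames(repl))
    stop("scenario CSV lacks a cell_id column")
  repl$cell_id <- as.character(repl$cell_id)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  structure(list(label = label, replacements = repl),
            class = "geofav_scenario")
}

#' Serialise a fitted logistic model to JSON (and back)
#'
#' Persists coefficients, standard errors, p-values, entry order,
#' log-likelihoods and sample counts so that a fitted model can be reloaded
#' and used for projection without refitting. Values round-trip at full
#' double precision.
#'
#' @param model a `"geofav_logit"` model.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "geofav_logit"))
  obj <- list(terms = model$terms,
              beta = as.list(model$beta),
              se = as.list(model$se),
              p_value = as.list(model$p_value),
              entry_order = as.list(model$entry_order),
              log_lik = model$log_lik,
              null_log_lik = model$null_log_lik,
              n = model$n, n1 = model$n1, n0 = model$n0, df = model$df,
              converged = model$converged, separation = model$separation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  model <- list(
    terms = vapply(obj$terms, as.character, ""),
    beta = num(obj$beta), se = num(obj$se), p_value = num(obj$p_value),
    entry_order = vapply(obj$entry_order, function(v)
      if (is.null(v) || identical(v, "NA") || is.na(v)) NA_integer_
      else as.integer(v), integer(1)),
    log_lik = obj$log_lik, null_log_lik = obj$null_log_lik,
    n = obj$n, n1 = obj$n1, n0 = obj$n0, df = obj$df,
    converged = obj$converged, separation = obj$separation,
    fitted = NULL)
  class(model) <- "geofav_logit"
  model
}

#' Write a favourability surface as CSV
#'
#' Columns: `cell_id`, `probability`, `favourability`, `class` (low / medium
#' / high at the configured cuts), plus a `scenario` column carrying the
#' label.
#'
#' @param surface a `"geofav_surface"` from [project_future()].
#' @param path file path.
#' @param low_cut,high_cut classification cuts (defaults 0.2 / 0.8).
#' @export
write_surface_csv <- function(surface, path, low_cut = 0.2, high_cut = 0.8) {
  stopifnot(inherits(surface, "geofav_surface"))
  out <- as.data.frame(surface)
  out$class <- as.character(
    classify_favourability(out$favourability, low_cut, high_cut))
  out$scenario <- attr(surface, "scenario_label")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
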