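#' Build the trend-surface polynomial basis from cell-centroid coordinates
#'
#' Centres each coordinate on its mean and scales it by its standard
#' deviation, then evaluates the nine monomials X, Y, X2, Y2, X3, Y3, XY,
#' X2Y, XY2. Standardising before taking powers keeps the cubic columns
#' numerically well-conditioned; the centering/scaling constants are stored
#' so the identical basis can be reproduced on new cells.
#'
#' @param lon,lat numeric centroid coordinates (planar units; longitude /
#'   latitude are a labelling convention).
#' @param scaling optional scaling constants from a previous call (list with
#'   `lon_center`, `lon_scale`, `lat_center`, `lat_scale`); when supplied the
#'   stored constants are reused instead of recomputed, so held-out cells get
#'   exactly the basis they would have had jointly.
#' @return object of class `"geofav_tsbasis"`: list with `basis` (n x 9
#'   matrix) and `scaling`.
#' @export
build_basis <- function(lon, lat, scaling = NULL) {
  if (length(lon) != length(lat)) stop("lon and lat differ in length")
  if (anyNA(lon) || anyNA(lat) || any(!is.finite(c(lon, lat))))
    stop("coordinates must be finite")
  if (is.null(scaling)) {
    if (nrow(unique(cbind(lon, lat))) < 3)
      stop("need at least 3 distinct locations")
    scaling <- list(lon_center = mean(lon), lon_scale = stats::sd(lon),
                    lat_center = mean(lat), lat_scale = stats::sd(lat))
    if (scaling$lon_scale == 0 && scaling$lat_scale == 0)
      stop("all cells at a single point")
    if (scaling$lon_scale == 0) scaling$lon_scale <- 1
    if (scaling$lat_scale == 0) scaling$lat_scale <- 1
  }
  X <- (lon - scaling$lon_center) / scaling$lon_scale
  Y <- (lat - scaling$lat_center) / scaling$lat_scale
  basis <- cbind(X = X, Y = Y, X2 = X^2, Y2 = Y^2, X3 = X^3, Y3 = Y^3,
                 XY = X * Y, X2Y = X^2 * Y, XY2 = X * Y^2)
  structure(list(basis = basis, scaling = scaling), class = "geofav_tsbasis")
}

#' Fit the geographic trend-surface variable
#'
#' Fits a logistic regression of presence on the full nine-term polynomial
#' coordinate basis, then backward-eliminates: the retained term with the
#' largest likelihood-ratio removal p-value is dropped while that p-value
#' exceeds `p_remove`, refitting after each drop. The per-cell logit of the
#' final geographic model is the trend-surface variable ("Geog"), a single
#' covariate summarising pure spatial structure in the species' range. If
#' every term is eliminated the variable degenerates to the constant
#' intercept logit and a warning is issued.
#'
#' @param basis a `"geofav_tsbasis"` from [build_basis()].
#' @param presence binary presence vector (0/1).
#' @param p_remove removal threshold for backward elimination (default 0.10).
#' @return object of class `"geofav_geog"`: list with `retained_terms`,
#'   `model` (the final `"geofav_logit"`), `scaling`, and `values` (the
#'   per-cell logit).
#' @export
fit_geog <- function(basis, presence, p_remove = 0.10) {
  stopifnot(inherits(basis, "geofav_tsbasis"))
  model <- stepwise(basis$basis, presence, p_enter = p_remove,
                    p_remove = p_remove, direction = "backward")
  retained <- setdiff(model$terms, "(Intercept)")
  if (length(retained) == 0)
    warning("no geographic term survived backward elimination; ",
            "trend-surface variable is constant")
  values <- predict(model, as.data.frame(basis$basis), type = "link")
  structure(list(retained_terms = retained,
                 model = model,
                 scaling = basis$scaling,
                 values = values),
            class = "geofav_geog")
}

#' Evaluate a fitted trend-surface variable on (new) cells
#'
#' Reconstructs the stored polynomial basis with the stored scaling constants
#' and returns the geographic model's logit, so the variable is exactly
#' reproducible on the original cells and consistently computable on new
#' ones.
#'
#' @param geog a `"geofav_geog"` object from [fit_geog()].
#' @param lon,lat centroid coordinates of the cells to evaluate.
#' @return numeric vector of trend-surface (logit) values.
#' @export
predict_geog <- function(geog, lon, lat) {
  stopifnot(inherits(geog, "geofav_geog"))
  b <- build_basis(lon, lat, scaling = geog$scaling)
  predict(geog$model, as.data.frame(b$basis), type = "link")
}
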