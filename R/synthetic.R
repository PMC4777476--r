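#' Generate a regular grid of cell centroids
#'
#' Lays out `nx` by `ny` square cells over a bounding box and returns their
#' centroid coordinates — the skeleton every synthetic landscape is built on.
#' Coordinates are abstract planar units; no great-circle geometry is used
#' anywhere.
#'
#' @param nx,ny number of cells along x and y (each >= 2).
#' @param extent bounding box `c(xmin, xmax, ymin, ymax)`; default the unit
#'   square.
#' @return data frame with columns `cell_id`, `lon`, `lat` (row-major from
#'   the south-west corner).
#' @export
gen_grid <- function(nx, ny, extent = c(0, 1, 0, 1)) {
  if (nx < 2 || ny < 2) stop("nx and ny must both be >= 2")
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive spans")
  dx <- (extent[2] - extent[1]) / nx
  dy <- (extent[4] - extent[3]) / ny
  xs <- extent[1] + dx * (seq_len(nx) - 0.5)
  ys <- extent[3] + dy * (seq_len(ny) - 0.5)
  g <- expand.grid(lon = xs, lat = ys, KEEP.OUT.ATTRS = FALSE)
  data.frame(cell_id = sprintf("c%04d", seq_len(nrow(g))),
             lon = g$lon, lat = g$lat, stringsAsFactors = FALSE)
}

#' Generate a spatially autocorrelated covariate field on a grid
#'
#' Draws seeded white noise per cell and smooths it with a uniform kernel
#' over all cells within `radius` (Euclidean distance between centroids),
#' then rescales the result to zero mean and the requested marginal
#' variance. Smoothing white noise with a local average is an O(n k)
#' shortcut to a Gaussian-process draw that induces exactly the kind of
#' positive spatial autocorrelation a trend surface must be able to detect;
#' `radius = 0` degenerates to pure white noise.
#'
#' @param grid grid skeleton from [gen_grid()] (columns `lon`, `lat`).
#' @param radius smoothing radius in coordinate units (>= 0).
#' @param variance marginal variance of the returned field (> 0).
#' @param seed integer seed; the same seed and parameters reproduce the field
#'   bit-for-bit.
#' @return numeric vector, one value per grid cell.
#' @export
gen_spatial_field <- function(grid, radius, variance = 1, seed = 1L) {
  if (nrow(grid) == 0) stop("empty grid")
  if (radius < 0) stop("radius must be >= 0")
  if (variance <= 0) stop("variance must be > 0")
  noise <- withr::with_seed(as.integer(seed), stats::rnorm(nrow(grid)))
  if (radius > 0) {
    d2 <- outer(grid$lon, grid$lon, "-")^2 + outer(grid$lat, grid$lat, "-")^2
    W <- d2 <= radius^2
    smoothed <- as.vector(W %*% noise) / rowSums(W)
  } else {
    smoothed <- noise
  }
  centred <- smoothed - mean(smoothed)
  centred / stats::sd(centred) * sqrt(variance)
}

#' Moran's I spatial autocorrelation statistic
#'
#' Standard Moran's I with binary contiguity weights: cells i and j are
#' neighbours when 0 < distance(i, j) <= `neighbour_radius`. Used to verify
#' that generated fields carry the intended spatial structure.
#'
#' @param values numeric vector, one value per cell; must not be constant.
#' @param grid grid skeleton with `lon`, `lat` columns matching `values`.
#' @param neighbour_radius contiguity radius; the default, 1.01 times the
#'   smallest positive inter-centroid gap, gives first-order rook neighbours
#'   on a regular lattice.
#' @return Moran's I.
#' @export
morans_i <- function(values, grid, neighbour_radius = NULL) {
  n <- length(values)
  if (n < 3) stop("need at least 3 cells")
  if (n != nrow(grid)) stop("values and grid differ in length")
  if (stats::sd(values) == 0) stop("Moran's I is undefined for constant values")
  d2 <- outer(grid$lon, grid$lon, "-")^2 + outer(grid$lat, grid$lat, "-")^2
  if (is.null(neighbour_radius)) {
    pos <- sqrt(min(d2[d2 > 0]))
    neighbour_radius <- 1.01 * pos
  }
  W <- (d2 > 0) & (d2 <= neighbour_radius^2)
  s0 <- sum(W)
  if (s0 == 0) stop("no neighbour pairs at this radius")
  z <- values - mean(values)
  (n / s0) * sum(W * outer(z, z)) / sum(z^2)
}

#' Simulate presences from a logistic occurrence process
#'
#' Builds the linear predictor named by `true_coefficients` over the
#' predictor columns, calibrates the intercept by bisection so that the mean
#' generating probability matches `target_prevalence` to within 0.005, and
#' then samples each cell's presence as an independent Bernoulli draw. The
#' generating model thus belongs to the same family the analysis fits, with
#' a controllable species prevalence — the quantity the favourability
#' transformation corrects for.
#'
#' @param predictors data frame of per-cell covariates (may include
#'   coordinate-derived columns).
#' @param true_coefficients named numeric vector of generating slopes; every
#'   name must be a column of `predictors`. The intercept is not given: it is
#'   calibrated from `target_prevalence`.
#' @param target_prevalence intended fraction of presences, in (0, 1).
#' @param seed integer seed for the Bernoulli draws.
#' @return list with `presence` (0/1 vector), `probability` (the generating
#'   probabilities), `intercept` (the calibrated value) and
#'   `true_coefficients`.
#' @export
gen_occurrences <- function(predictors, true_coefficients,
                            target_prevalence = 0.055, seed = 1L) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie in (0, 1)")
  unknown <- setdiff(names(true_coefficients), colnames(predictors))
  if (length(unknown))
    stop("coefficient(s) reference unknown column(s): ",
         paste(unknown, collapse = ", "))
  lp <- if (length(true_coefficients)) {
    as.matrix(predictors[, names(true_coefficients), drop = FALSE]) %*%
      true_coefficients
  } else rep(0, nrow(predictors))
  lp <- drop(lp)

  mean_prob <- function(a) mean(stats::plogis(a + lp))
  lo <- -50; hi <- 50
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    if (abs(mean_prob(mid) - target_prevalence) <= 0.005) break
    if (mean_prob(mid) < target_prevalence) lo <- mid else hi <- mid
  }
  intercept <- mid
  prob <- stats::plogis(intercept + lp)
  presence <- withr::with_seed(as.integer(seed),
                               stats::rbinom(length(prob), 1L, prob))
  list(presence = presence, probability = prob, intercept = intercept,
       true_coefficients = true_coefficients)
}

#' Build a future climate scenario by shifting climatic covariates
#'
#' Produces a scenario table holding the same cells with replacement values
#' for climatic predictors only: `value + delta`, optionally modulated by a
#' south-to-north gradient so the shift is stronger at high latitudes (as
#' warming scenarios typically are). Non-climatic columns are absent from the
#' scenario by construction; quadratic columns are never shifted directly but
#' recomputed from their shifted parent at projection time.
#'
#' @param data grid table containing `cell_id`, `lat` and the climate
#'   columns.
#' @param deltas named numeric vector of additive shifts; names must be a
#'   subset of `climate_cols`.
#' @param climate_cols character vector naming the climate-set columns.
#' @param label scenario label (e.g. `"2080-hadcm3"`).
#' @param gradient if non-zero, the per-cell shift is
#'   `delta * (1 + gradient * (lat - min(lat)) / (max(lat) - min(lat)))`,
#'   i.e. `gradient = 1` doubles the shift at the northern edge relative to
#'   the southern edge.
#' @return object of class `"geofav_scenario"`: list with `label` and
#'   `replacements` (data frame of `cell_id` plus shifted climate columns).
#' @export
gen_future_scenario <- function(data, deltas, climate_cols, label = "future",
                                gradient = 0) {
  bad <- setdiff(names(deltas), climate_cols)
  if (length(bad))
    stop("delta(s) on non-climate column(s): ", paste(bad, collapse = ", "))
  missing_cols <- setdiff(names(deltas), colnames(data))
  if (length(missing_cols))
    stop("column(s) absent from data: ", paste(missing_cols, collapse = ", "))
  mult <- if (gradient != 0) {
    rng <- range(data$lat)
    1 + gradient * (data$lat - rng[1]) / (rng[2] - rng[1])
  } else 1
  repl <- data.frame(cell_id = data$cell_id, stringsAsFactors = FALSE)
  for (nm in names(deltas)) repl[[nm]] <- data[[nm]] + deltas[[nm]] * mult
  structure(list(label = label, replacements = repl),
            class = "geofav_scenario")
}

#' Simulate a complete synthetic landscape
#'
#' One-call generator for a study-shaped dataset: a regular grid; three
#' spatially autocorrelated climate covariates (`Pannual`, `Range`,
#' `Tapr_jul`) with their quadratic terms (`<name>^2` columns); two land-use
#' covariates (`DCP`, `HPd`); one topographic covariate (`Slope`); and a
#' presence/absence response drawn from a logistic process that may combine
#' environmental slopes with a pure spatial (coordinate-polynomial) term.
#' Defaults mirror the statistical shape of a continental 50 km atlas
#' dataset: a 40 x 40 grid and a rare species with prevalence 0.055.
#'
#' @param nx,ny grid dimensions.
#' @param seed master seed; all covariates and the occurrence draw derive
#'   their own seeds from it deterministically.
#' @param radius smoothing radius for covariate fields, in cell widths.
#' @param env_coefficients named numeric vector of environmental generating
#'   slopes (names among the predictor columns).
#' @param spatial_coefficient slope on the standardised latitude coordinate;
#'   a nonzero value creates pure spatial structure in the species' range
#'   that no environmental covariate carries.
#' @param target_prevalence intended fraction of presences.
#' @return list with `data` (data frame: `cell_id`, `lon`, `lat`, `presence`,
#'   predictors), `sets` (named character vector mapping predictor columns to
#'   predictor sets), `truth` (generating parameters, including the
#'   calibrated intercept and per-cell generating probabilities).
#' @export
simulate_landscape <- function(nx = 40, ny = 40, seed = 1L, radius = 5,
                               env_coefficients = c(Pannual = -1, Range = -0.7,
                                                    DCP = 0.8, Slope = -0.5),
                               spatial_coefficient = 0,
                               target_prevalence = 0.055) {
  seed <- as.integer(seed)
  grid <- gen_grid(nx, ny, extent = c(0, nx, 0, ny))
  fields <- c("Pannual", "Range", "Tapr_jul", "DCP", "HPd", "Slope")
  data <- grid
  for (i in seq_along(fields)) {
    data[[fields[i]]] <- gen_spatial_field(grid, radius = radius, variance = 1,
                                           seed = seed + 1000L * i)
  }
  for (nm in c("Pannual", "Range", "Tapr_jul"))
    data[[paste0(nm, "^2")]] <- data[[nm]]^2

  # standardised latitude as the pure spatial driver of the truth
  gen <- data
  gen[[".Ystd"]] <- (data$lat - mean(data$lat)) / stats::sd(data$lat)
  coefs <- env_coefficients
  if (spatial_coefficient != 0) coefs <- c(coefs, .Ystd = spatial_coefficient)
  occ <- gen_occurrences(gen, coefs, target_prevalence = target_prevalence,
                         seed = seed + 777L)
  data$presence <- occ$presence
  pred_cols <- setdiff(colnames(data), c("cell_id", "lon", "lat", "presence"))
  data <- data[, c("cell_id", "lon", "lat", "presence", pred_cols)]

  sets <- c(Pannual = "climate", Range = "climate", Tapr_jul = "climate",
            `Pannual^2` = "climate", `Range^2` = "climate",
            `Tapr_jul^2` = "climate",
            DCP = "land_use", HPd = "land_use", Slope = "topography")
  truth <- list(true_coefficients = c(`(Intercept)` = occ$intercept, coefs),
                field_params = list(radius = radius, variance = 1),
                target_prevalence = target_prevalence,
                seed = seed,
                probability = occ$probability)
  list(data = data, sets = sets, truth = truth)
}
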