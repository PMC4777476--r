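test_that("gen_grid lays out a deterministic lattice of unique cells", {
  g <- gen_grid(2, 2, extent = c(0, 1, 0, 1))
  expect_equal(nrow(g), 4)
  expect_equal(g$lon, c(0.25, 0.75, 0.25, 0.75))
  expect_equal(g$lat, c(0.25, 0.25, 0.75, 0.75))
  big <- gen_grid(40, 40)
  expect_equal(nrow(big), 1600)
  expect_false(anyDuplicated(big$cell_id) > 0)
  expect_identical(gen_grid(7, 5), gen_grid(7, 5))
  expect_error(gen_grid(1, 5), ">= 2")
  expect_error(gen_grid(4, 4, extent = c(1, 0, 0, 1)), "extent")
})

test_that("spatial fields are seeded, variance-calibrated and autocorrelated", {
  g <- gen_grid(20, 20, extent = c(0, 20, 0, 20))
  f1 <- gen_spatial_field(g, radius = 3, variance = 2, seed = 10)
  f2 <- gen_spatial_field(g, radius = 3, variance = 2, seed = 10)
  expect_identical(f1, f2)
  expect_equal(stats::var(f1), 2, tolerance = 1e-10)
  # radius 0: white noise, Moran's I near its null expectation -1/(n-1)
  f0 <- gen_spatial_field(g, radius = 0, variance = 1, seed = 10)
  expect_lt(abs(morans_i(f0, g) - (-1 / (nrow(g) - 1))), 0.1)
  expect_error(gen_spatial_field(g[0, ], 1, 1, 1), "empty")
  expect_error(gen_spatial_field(g, -1, 1, 1), ">= 0")
})

test_that("Moran's I of generated fields is non-decreasing in radius", {
  g <- gen_grid(40, 40, extent = c(0, 40, 0, 40))
  mean_i <- sapply(c(0, 2, 5), function(r) {
    mean(sapply(1:20, function(s)
      morans_i(gen_spatial_field(g, radius = r, variance = 1, seed = s), g)))
  })
  expect_true(all(diff(mean_i) > 0))
  expect_gt(mean_i[3], 0.3)  # radius = 5 cell widths gives strong structure
})

test_that("morans_i matches its definition and known anchors", {
  g <- gen_grid(8, 8, extent = c(0, 8, 0, 8))
  # perfect checkerboard with rook neighbours: I = -1
  chk <- (-1)^(outer(1:8, 1:8, "+"))
  expect_equal(morans_i(as.vector(chk), g), -1, tolerance = 1e-12)
  # values equal to latitude: strong positive autocorrelation
  g20 <- gen_grid(20, 20, extent = c(0, 20, 0, 20))
  expect_gt(morans_i(g20$lat, g20), 0.9)
  # agreement with an independently coded implementation
  withr::with_seed(5, {
    v <- stats::rnorm(nrow(g))
    expect_equal(morans_i(v, g, neighbour_radius = 2.2),
                 oracle_morans_i(v, g$lon, g$lat, 2.2), tolerance = 1e-12)
  })
  expect_error(morans_i(rep(1, nrow(g)), g), "constant")
  expect_error(morans_i(1:2, g[1:2, ]), "at least 3")
})

test_that("occurrence generation calibrates prevalence and links covariates", {
  g <- gen_grid(40, 40, extent = c(0, 40, 0, 40))
  pred <- data.frame(env = gen_spatial_field(g, 3, 1, seed = 2))
  # null model at prevalence 0.5
  occ0 <- gen_occurrences(pred, c(env = 0), target_prevalence = 0.5, seed = 1)
  expect_lt(abs(mean(occ0$probability) - 0.5), 0.005)
  expect_lt(abs(mean(occ0$presence) - 0.5), 3 * sqrt(0.25 / 1600))
  # rare-species calibration: mean generating probability in [0.05, 0.06]
  occ <- gen_occurrences(pred, c(env = 1.2), target_prevalence = 0.055,
                         seed = 1)
  expect_gte(mean(occ$probability), 0.05)
  expect_lte(mean(occ$probability), 0.06)
  # determinism
  occ2 <- gen_occurrences(pred, c(env = 1.2), target_prevalence = 0.055,
                          seed = 1)
  expect_identical(occ$presence, occ2$presence)
  # a strong positive coefficient induces positive point-biserial correlation
  cors <- sapply(1:20, function(s)
    stats::cor(pred$env,
               gen_occurrences(pred, c(env = 1.5), 0.2, seed = s)$presence))
  expect_true(all(cors > 0))
  expect_error(gen_occurrences(pred, c(nope = 1), 0.1, 1), "unknown column")
  expect_error(gen_occurrences(pred, c(env = 1), 1.5, 1), "\\(0, 1\\)")
})

test_that("future scenarios shift climate columns exactly as requested", {
  land <- simulate_landscape(nx = 10, ny = 10, seed = 3)
  clim <- names(land$sets)[land$sets == "climate"]
  # zero delta: identity
  sc0 <- gen_future_scenario(land$data, c(Pannual = 0), clim)
  expect_equal(sc0$replacements$Pannual, land$data$Pannual)
  # additive shift
  sc <- gen_future_scenario(land$data, c(Pannual = 2), clim, label = "2080")
  expect_equal(sc$replacements$Pannual, land$data$Pannual + 2)
  expect_identical(sc$label, "2080")
  expect_identical(colnames(sc$replacements), c("cell_id", "Pannual"))
  # south-to-north gradient doubles the delta at the northern edge
  scg <- gen_future_scenario(land$data, c(Pannual = 2), clim, gradient = 1)
  shift <- scg$replacements$Pannual - land$data$Pannual
  south <- shift[land$data$lat == min(land$data$lat)]
  north <- shift[land$data$lat == max(land$data$lat)]
  expect_equal(mean(north) / mean(south), 2, tolerance = 1e-12)
  expect_error(gen_future_scenario(land$data, c(Slope = 1), clim),
               "non-climate")
})

test_that("simulate_landscape is seed-deterministic with study-shaped output", {
  a <- simulate_landscape(nx = 15, ny = 15, seed = 9, spatial_coefficient = 1)
  b <- simulate_landscape(nx = 15, ny = 15, seed = 9, spatial_coefficient = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$data), 225)
  expect_true(all(a$data$presence %in% c(0, 1)))
  expect_equal(a$data$`Pannual^2`, a$data$Pannual^2)
  expect_setequal(unique(unname(a$sets)), c("climate", "land_use", "topography"))
  expect_lt(abs(mean(a$truth$probability) - 0.055), 0.005)
})
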