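test_that("random fields are deterministic, bounded and autocorrelated", {
  a <- make_random_field(64, 64, correlation_range = 8, seed = 1)
  b <- make_random_field(64, 64, correlation_range = 8, seed = 1)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, make_random_field(64, 64, 8, seed = 2)$values))

  # the generator can mimic an observed bioclim layer range exactly
  r <- make_random_field(32, 32, 4, seed = 3, vmin = 21.75, vmax = 33.65)
  expect_equal(min(r$values), 21.75)
  expect_equal(max(r$values), 33.65)
  expect_true(all(is.finite(r$values)))

  rough <- make_random_field(64, 64, correlation_range = 0.5, seed = 5)
  smooth <- make_random_field(64, 64, correlation_range = 16, seed = 5)
  expect_lt(lag1_cor(rough), lag1_cor(smooth))

  expect_error(make_random_field(4, 64, 8, 1), "at least 8")
  expect_error(make_random_field(64, 64, -1, 1), "positive")
})

test_that("predictor stacks align layers and keep names", {
  specs <- list(list(name = "Bio3", min = 0, max = 1, correlation_range = 4),
                list(name = "Bio7", min = 5, max = 9, correlation_range = 4),
                list(name = "Bio12", min = 0, max = 2, correlation_range = 4),
                list(name = "elev", min = 0, max = 1, correlation_range = 4))
  st <- make_predictor_stack(specs, seed = 1)
  expect_length(st, 4)
  expect_identical(names(st), c("Bio3", "Bio7", "Bio12", "elev"))
  expect_s3_class(st[["Bio7"]], "raster_grid")
  expect_true(rangerisk:::same_grid(st[["Bio3"]], st[["Bio12"]]))

  st2 <- make_predictor_stack(specs, seed = 2)
  expect_false(identical(st[["Bio3"]]$values, st2[["Bio3"]]$values))
  expect_equal(grid_def(st[["Bio3"]]), grid_def(st2[["Bio3"]]))

  specs[[2]]$name <- "Bio3"
  expect_error(make_predictor_stack(specs, seed = 1), "duplicate")
})

test_that("true suitability follows the parametric niche", {
  g <- raster_grid(matrix(seq(0, 100, length.out = 100), 10, 10))
  st <- predictor_stack(list(x = g))
  niche <- virtual_niche(list(x = list(kind = "gaussian", optimum = 50,
                                       breadth = 10)))
  s <- true_suitability(st, niche)
  expect_true(all(s$values >= 0 & s$values <= 1))
  # cell value exactly at the optimum has suitability 1
  g2 <- g; g2$values[1, 1] <- 50
  s2 <- true_suitability(predictor_stack(list(x = g2)), niche)
  expect_equal(s2$values[1, 1], 1.0)

  # product combine: two responses of 0.5 give 0.25
  sqrt_half <- 50 + 10 * sqrt(2 * log(2))  # gaussian response = 0.5 there
  ga <- raster_grid(matrix(sqrt_half, 5, 5))
  two <- predictor_stack(list(x = ga, y = ga))
  niche2 <- virtual_niche(list(
    x = list(kind = "gaussian", optimum = 50, breadth = 10),
    y = list(kind = "gaussian", optimum = 50, breadth = 10)))
  expect_equal(true_suitability(two, niche2)$values[3, 3], 0.25,
               tolerance = 1e-12)

  # negative-slope logistic response is non-increasing along a gradient
  grad <- raster_grid(matrix(seq(0, 1, length.out = 64), 8, 8))
  stg <- predictor_stack(list(x = grad))
  nlog <- virtual_niche(list(x = list(kind = "logistic", inflection = 0.5,
                                      slope = -8)))
  sv <- true_suitability(stg, nlog)$values
  ord <- order(grad$values)
  expect_true(all(diff(sv[ord]) <= 1e-12))

  expect_error(true_suitability(st, virtual_niche(
    list(zz = list(kind = "gaussian", optimum = 0, breadth = 1)))),
    "missing")
})

test_that("presence sampling is suitability-weighted, capped and seeded", {
  vs <- virtual_study(seed = 3, n_presences = 41)
  expect_equal(nrow(vs$occurrences), 41)
  expect_identical(vs$occurrences,
                   virtual_study(seed = 3, n_presences = 41)$occurrences)

  # single positive cell: one record at that cell center, regardless of n
  z <- raster_grid(matrix(0, 10, 10), xmin = 0, ymax = 10)
  z$values[4, 7] <- 0.8
  occ <- sample_presences(z, 5, seed = 1)
  expect_equal(nrow(occ), 1)
  expect_equal(c(occ$lon, occ$lat), c(6.5, 6.5))

  expect_error(sample_presences(raster_grid(matrix(0, 8, 8)), 3, seed = 1),
               "empty support")

  # sampled cells sit in better-than-average habitat (Monte-Carlo)
  suit <- virtual_study(seed = 9)$suitability
  overall <- mean(suit$values)
  hits <- vapply(1:100, function(s) {
    occ <- sample_presences(suit, 20, seed = s)
    st1 <- predictor_stack(list(s = suit))
    mean(extract_at_points(st1, occ)$s) > overall
  }, logical(1))
  expect_true(all(hits))
})

test_that("presence-cell driver values recover the niche optimum", {
  # precondition for downstream parameter recovery: with n >= 30 the
  # Monte-Carlo mean of the presence-cell driver values is within half a
  # breadth of the optimum; individual replicates stay within one breadth
  # (they carry a small warm-ward availability bias, since more of the
  # landscape lies above the cool-tail optimum than below it)
  errs <- vapply(1:20, function(s) {
    vs <- virtual_study(seed = s, n_presences = 30)
    st1 <- predictor_stack(list(bio7 = vs$stack[["bio7"]]))
    mean(extract_at_points(st1, vs$occurrences)$bio7) - 25
  }, numeric(1))
  expect_lte(abs(mean(errs)), 0.5 * 3)
  expect_true(all(abs(errs) <= 3))
})

test_that("climate deltas shift layers exactly and invert", {
  st <- toy_stack()
  expect_equal(apply_climate_delta(st, climate_delta())$layers,
               st$layers)
  shifted <- apply_climate_delta(st, climate_delta(offset = c(a = 3)))
  expect_equal(mean(shifted[["a"]]$values), mean(st[["a"]]$values) + 3)
  expect_equal(shifted[["b"]]$values, st[["b"]]$values)
  expect_equal(grid_def(shifted[["a"]]), grid_def(st[["a"]]))

  both <- climate_delta(offset = c(a = 2), factor = c(a = 1.5))
  inv <- climate_delta(offset = c(a = -2 / 1.5), factor = c(a = 1 / 1.5))
  back <- apply_climate_delta(apply_climate_delta(st, both), inv)
  expect_equal(back[["a"]]$values, st[["a"]]$values, tolerance = 1e-12)

  expect_error(apply_climate_delta(st, climate_delta(offset = c(zz = 1))),
               "missing layer")
  expect_error(climate_delta(factor = c(a = -1)), "positive")

  # pushing a gaussian driver three breadths past its optimum erodes the niche
  vs <- virtual_study(seed = 4)
  fut <- apply_climate_delta(vs$stack, climate_delta(offset = c(bio7 = 9)))
  expect_lt(mean(true_suitability(fut, vs$niche)$values),
            mean(vs$suitability$values))
})

test_that("synthetic land cover hits the forest fraction", {
  grid <- default_grid()
  all_forest <- make_landcover(grid, 1.0, seed = 1)
  expect_true(all(all_forest$values == 1))

  lc <- make_landcover(grid, 0.5, seed = 2)
  expect_identical(lc$values, make_landcover(grid, 0.5, seed = 2)$values)
  nf <- sum(lc$values == 1)
  expect_gte(nf, 4800); expect_lte(nf, 5200)
  expect_true(all(lc$values %in% landcover_classes()))

  expect_error(make_landcover(grid, 0, seed = 1), "forest_fraction")
  expect_error(make_landcover(grid, 1.2, seed = 1), "forest_fraction")
})

test_that("virtual-species scenarios round-trip through disk", {
  vs <- virtual_study(seed = 6, n_presences = 10)
  dir <- withr::local_tempdir()
  write_virtual_species(dir, vs$stack, vs$occurrences, vs$niche, seed = 6)
  st2 <- read_stack(file.path(dir, "stack"))
  expect_equal(names(st2), names(vs$stack))
  expect_equal(st2[["bio7"]]$values, vs$stack[["bio7"]]$values)
  occ2 <- read_occurrences(file.path(dir, "occurrences.csv"))
  expect_equal(occ2$lon, vs$occurrences$lon)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$niche$bio7$optimum, 25)
  expect_equal(truth$seed, 6)
})
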