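test_that("pseudo-absence sampling avoids presences and hits the 10x ratio", {
  vs <- virtual_study(seed = 2, n_presences = 20)
  pa <- sample_pseudo_absences(vs$stack, vs$occurrences, ratio = 10, seed = 4)
  expect_equal(nrow(pa), 200)
  g <- vs$stack[["bio7"]]
  pcells <- cell_of(g, vs$occurrences$lon, vs$occurrences$lat)
  acells <- cell_of(g, pa$lon, pa$lat)
  expect_length(intersect(paste(pcells$row, pcells$col),
                          paste(acells$row, acells$col)), 0)
  expect_identical(pa, sample_pseudo_absences(vs$stack, vs$occurrences,
                                              ratio = 10, seed = 4))
  # requesting more than the landscape holds degrades gracefully
  expect_warning(
    big <- sample_pseudo_absences(vs$stack, vs$occurrences, ratio = 1000,
                                  seed = 1),
    "eligible")
  expect_equal(nrow(big), 100 * 100 - 20)
})

test_that("train/test split is stratified, disjoint and exhaustive", {
  tab <- data.frame(label = rep(c(1, 0), c(10, 100)), x = rnorm(110))
  sp <- split_train_test(tab, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 77)
  expect_equal(sum(sp$train$label), 7)
  expect_equal(nrow(sp$train) + nrow(sp$test), 110)
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(tab)))

  tab100 <- data.frame(label = rep(c(1, 0), 50), x = rnorm(100))
  sp100 <- split_train_test(tab100, 0.7, seed = 2)
  expect_equal(nrow(sp100$train), 70)
  expect_equal(nrow(sp100$test), 30)

  expect_error(split_train_test(data.frame(label = c(1, 0, 0), x = 1:3)),
               "at least 2")
})

test_that("every member family learns a separable problem and is seeded", {
  set.seed(2)
  n <- 300
  x <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  tab <- data.frame(label = rep(c(0, 1), each = n / 2), x = x,
                    noise = rnorm(n))
  sp <- split_train_test(tab, 0.7, seed = 3)
  for (fam in c("glm", "gam", "rf", "brt")) {
    m <- fit_member(fam, sp$train, c("x", "noise"), seed = 11,
                    hyper = fast_hyper[[fam]] %||% list())
    p <- predict_member(m, sp$test)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(auc_stat(p, sp$test$label), 0.9)
    m2 <- fit_member(fam, sp$train, c("x", "noise"), seed = 11,
                     hyper = fast_hyper[[fam]] %||% list())
    expect_equal(p, predict_member(m2, sp$test), tolerance = 1e-12)
  }
})

test_that("with no signal every family predicts about the prevalence", {
  set.seed(6)
  tab <- data.frame(label = rbinom(200, 1, 0.25), x = rep(1, 200),
                    y = rep(2, 200))
  # constant predictors carry no information
  for (fam in c("glm", "rf", "brt")) {
    m <- fit_member(fam, tab, c("x", "y"), seed = 1,
                    hyper = fast_hyper[[fam]] %||% list())
    p <- predict_member(m, tab)
    expect_equal(mean(p), mean(tab$label), tolerance = 0.05)
  }
})

test_that("ensemble weights follow floored, normalized TSS", {
  mk <- function(fam) structure(list(family = fam, failed = FALSE),
                                class = "sdm_member")
  ens <- build_ensemble(list(mk("glm"), mk("rf")), c(0.6, 0.2))
  expect_equal(ens$weights, c(0.75, 0.25))
  expect_equal(build_ensemble(list(mk("glm")), 0.4)$weights, 1)
  ens2 <- build_ensemble(list(mk("glm"), mk("rf")), c(0.5, -0.1))
  expect_equal(ens2$weights, c(1, 0))
  expect_warning(ens3 <- build_ensemble(list(mk("a"), mk("b")),
                                        c(-0.2, -0.5)), "equal weights")
  expect_equal(ens3$weights, c(0.5, 0.5))
  expect_error(build_ensemble(list(), numeric(0)), "no usable")
})

test_that("ensemble prediction is a convex combination and maps stacks", {
  vs <- virtual_study(seed = 5, n_presences = 25)
  pa <- sample_pseudo_absences(vs$stack, vs$occurrences, seed = 1)
  tab <- build_sample_table(vs$stack, vs$occurrences, pa)
  m <- ensemble_sdm(tab, seed = 7, hyper = fast_hyper)
  expect_equal(sum(m$weights), 1)

  nd <- tab[1:40, ]
  member_p <- vapply(m$members, predict_member, numeric(40), newdata = nd)
  ens_p <- predict(m, nd)
  expect_true(all(ens_p >= apply(member_p, 1, min) - 1e-12))
  expect_true(all(ens_p <= apply(member_p, 1, max) + 1e-12))

  surf <- predict(m, vs$stack)
  expect_s3_class(surf, "raster_grid")
  expect_true(all(surf$values >= 0 & surf$values <= 1, na.rm = TRUE))
  # nodata in a layer propagates into the surface
  st2 <- vs$stack
  st2$layers$bio7$values[1, 1] <- NA
  expect_true(is.na(predict(m, st2)$values[1, 1]))

  # determinism of the full fit
  m2 <- ensemble_sdm(tab, seed = 7, hyper = fast_hyper)
  expect_equal(predict(m2, vs$stack)$values, surf$values, tolerance = 1e-12)
})

test_that("marginal response is flat for an ignored predictor and bounded", {
  set.seed(8)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  tab <- data.frame(label = rbinom(n, 1, plogis(2.5 * x1)), x1 = x1, x2 = x2)
  m <- ensemble_sdm(tab, variables = c("x1", "x2"), families = "glm",
                    seed = 1)
  r2 <- marginal_response(m, "x2", grid_points = 30)
  r1 <- marginal_response(m, "x1", grid_points = 30)
  expect_gt(diff(range(r1$probability)), 0.5)
  # the uninformative predictor's curve is much flatter than the driver's
  expect_lt(diff(range(r2$probability)),
            0.4 * diff(range(r1$probability)))
  expect_true(all(r1$probability >= 0 & r1$probability <= 1))
  expect_error(marginal_response(m, "zz"), "retained")
})

test_that("stack averaging is exact and order-invariant", {
  st <- toy_stack(seed = 1)
  same <- average_stacks(list(st, st))
  expect_equal(same$layers$a$values, st$layers$a$values)

  c10 <- predictor_stack(list(z = raster_grid(matrix(10, 8, 8))))
  c20 <- predictor_stack(list(z = raster_grid(matrix(20, 8, 8))))
  expect_true(all(average_stacks(list(c10, c20))[["z"]]$values == 15))
  expect_equal(average_stacks(list(c10, c20))[["z"]]$values,
               average_stacks(list(c20, c10))[["z"]]$values)
  expect_error(average_stacks(list(st, c10)), "different layer names")
})
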