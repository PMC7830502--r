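#' Sample pseudo-absence background points
#'
#' Draws cell centers uniformly at random, without replacement, from the
#' non-nodata cells of the stack that do not contain a presence record
#' (optionally also excluding cells within a chebyshev buffer of any
#' presence cell). The default ratio of ten background points per
#' presence follows common presence/pseudo-absence practice.
#'
#' @param stack a [predictor_stack].
#' @param presences an [occurrence_set].
#' @param ratio background points per presence (>= 1).
#' @param seed integer RNG seed.
#' @param exclusion_buffer_cells cells around each presence to exclude
#'   (0 = plain random background).
#' @return data.frame with `lon`, `lat`; warns and returns all eligible
#'   cells when fewer are available than requested.
#' @export
sample_pseudo_absences <- function(stack, presences, ratio = 10, seed = 1,
                                   exclusion_buffer_cells = 0) {
  if (ratio < 1) stop("ratio must be at least 1")
  g <- stack[[names(stack)[1]]]
  d <- grid_def(g)
  ok <- !is.na(g$values)
  for (n in names(stack)) ok <- ok & !is.na(stack[[n]]$values)
  pres <- cell_of(d, presences$lon, presences$lat)
  pres <- pres[!is.na(pres$row), , drop = FALSE]
  b <- exclusion_buffer_cells
  for (i in seq_len(nrow(pres))) {
    rows <- max(1, pres$row[i] - b):min(d$nrow, pres$row[i] + b)
    cols <- max(1, pres$col[i] - b):min(d$ncol, pres$col[i] + b)
    ok[rows, cols] <- FALSE
  }
  eligible <- which(ok)  # column-major cell index
  want <- ratio * nrow(presences)
  if (length(eligible) < want) {
    warning("only ", length(eligible), " eligible background cells; ",
            "requested ", want)
    pick <- eligible
  } else pick <- with_seed(seed, sample(eligible, want))
  row <- (pick - 1L) %% d$nrow + 1L
  col <- (pick - 1L) %/% d$nrow + 1L
  cc <- cell_centers(d)
  data.frame(lon = cc$x[col], lat = cc$y[row])
}

#' Stratified train/test split
#'
#' @param table sample table with a binary `label` column.
#' @param train_fraction fraction of rows assigned to training
#'   (default 0.7).
#' @param seed integer RNG seed.
#' @param stratified preserve class proportions within rounding.
#' @return list with `train` and `test` data.frames (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed = 1,
                             stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (min(table(table$label)) < 2)
    stop("each class needs at least 2 rows to split")
  idx_train <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(split(seq_len(nrow(table)), table$label), function(ix)
        sample(ix, round(train_fraction * length(ix)))))
    } else sample(seq_len(nrow(table)), round(train_fraction * nrow(table)))
  })
  list(train = table[sort(idx_train), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), idx_train), , drop = FALSE])
}

# Default member hyperparameters; conventional SDM practice, all
# overridable through the `hyper` argument of ensemble_sdm().
default_hyper <- function() list(
  gam = list(k = 8),
  rf = list(ntree = 500),
  brt = list(nrounds = 1000, eta = 0.01, max_depth = 3, subsample = 0.5)
)

#' Fit a single ensemble member
#'
#' Family contracts: `glm` = logistic regression with linear + quadratic
#' terms per predictor; `gam` = logistic additive model with a thin-plate
#' smooth per predictor (basis size capped by the data); `rf` = random
#' forest class-probability model; `brt` = stochastic gradient-boosted
#' trees with logistic loss. All fits are seeded and all predictions are
#' probabilities in `[0, 1]`. On failure a family-specific fallback is
#' tried once; if that also fails the member is flagged failed (and is
#' later excluded from the ensemble with a warning).
#'
#' @param family one of `"glm"`, `"gam"`, `"rf"`, `"brt"`.
#' @param train training sample table (`label` + predictor columns).
#' @param variables predictor column names.
#' @param seed integer RNG seed.
#' @param hyper named list of hyperparameter overrides for this family.
#' @return object of class `sdm_member`.
#' @export
fit_member <- function(family = c("glm", "gam", "rf", "brt"), train,
                       variables, seed = 1, hyper = list()) {
  family <- match.arg(family)
  if (length(unique(train$label)) < 2)
    stop("training data must contain both classes")
  hp <- utils::modifyList(default_hyper()[[family]] %||% list(), hyper)
  # a table with no varying predictor carries no signal: degenerate to the
  # training prevalence for every family (tree learners cannot split it)
  if (all(vapply(train[variables], function(v) length(unique(v)) == 1,
                 logical(1))))
    return(structure(list(family = family, variables = variables,
                          seed = seed, hyper = hp, failed = FALSE,
                          fit = structure(list(p = mean(train$label)),
                                          class = "prevalence_model")),
                     class = "sdm_member"))
  fit <- tryCatch(fit_member_impl(family, train, variables, seed, hp),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    fb <- fallback_hyper(family, hp)
    fit <- tryCatch(fit_member_impl(family, train, variables, seed, fb),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("member ", family, " failed to fit: ", conditionMessage(fit))
      return(structure(list(family = family, variables = variables,
                            seed = seed, failed = TRUE),
                       class = "sdm_member"))
    }
    hp <- fb
  }
  structure(list(family = family, fit = fit, variables = variables,
                 seed = seed, hyper = hp, failed = FALSE),
            class = "sdm_member")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fallback_hyper <- function(family, hp) {
  switch(family,
         gam = utils::modifyList(hp, list(k = 4)),
         brt = utils::modifyList(hp, list(nrounds = 200, max_depth = 2)),
         rf = utils::modifyList(hp, list(ntree = 200)),
         hp)
}

fit_member_impl <- function(family, train, variables, seed, hp) {
  y <- train$label
  switch(family,
    glm = {
      terms <- paste(vapply(variables, function(v)
        sprintf("%s + I(%s^2)", v, v), character(1)), collapse = " + ")
      f <- stats::as.formula(paste("label ~", terms))
      with_seed(seed, suppressWarnings(
        stats::glm(f, data = train, family = stats::binomial())))
    },
    gam = {
      k <- hp$k
      sm <- vapply(variables, function(v) {
        kk <- max(3, min(k, length(unique(train[[v]])) - 1))
        sprintf("s(%s, k = %d)", v, kk)
      }, character(1))
      f <- stats::as.formula(paste("label ~", paste(sm, collapse = " + ")))
      with_seed(seed, suppressWarnings(
        mgcv::gam(f, data = train, family = stats::binomial())))
    },
    rf = with_seed(seed, randomForest::randomForest(
      x = train[variables], y = factor(y, levels = c(0, 1)),
      ntree = hp$ntree)),
    brt = {
      dm <- xgboost::xgb.DMatrix(as.matrix(train[variables]), label = y)
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, subsample = hp$subsample,
                      nthread = 1, seed = seed),
        data = dm, nrounds = hp$nrounds, verbose = 0))
    })
}

#' Predict probabilities from one member
#'
#' @param member an `sdm_member`.
#' @param newdata data.frame containing the member's predictor columns.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_member <- function(member, newdata) {
  if (isTRUE(member$failed)) stop("cannot predict from a failed member")
  if (inherits(member$fit, "prevalence_model"))
    return(rep(member$fit$p, nrow(newdata)))
  p <- switch(member$family,
    glm = stats::predict(member$fit, newdata = newdata, type = "response"),
    gam = as.numeric(mgcv::predict.gam(member$fit, newdata = newdata,
                                       type = "response")),
    rf = stats::predict(member$fit, newdata = newdata[member$variables],
                        type = "prob")[, "1"],
    brt = stats::predict(member$fit,
                         xgboost::xgb.DMatrix(
                           as.matrix(newdata[member$variables]))))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Combine fitted members into a TSS-weighted ensemble
#'
#' Weight of member i is `max(TSS_i, 0) / sum_j max(TSS_j, 0)` — members
#' with non-positive skill get zero weight. If every member has TSS <= 0
#' the weights fall back to equal with a warning.
#'
#' @param members list of `sdm_member` objects (failed members are
#'   dropped with a warning).
#' @param member_tss numeric vector of held-out TSS values, one per
#'   member.
#' @return list with `members` and `weights` (summing to 1).
#' @export
build_ensemble <- function(members, member_tss) {
  ok <- !vapply(members, function(m) isTRUE(m$failed), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " failed member(s) excluded from ensemble")
    members <- members[ok]; member_tss <- member_tss[ok]
  }
  if (!length(members)) stop("no usable ensemble members")
  w <- pmax(member_tss, 0)
  if (sum(w) == 0) {
    warning("all members have non-positive TSS; using equal weights")
    w <- rep(1, length(members))
  }
  list(members = members, weights = w / sum(w))
}

#' Fit a TSS-weighted ensemble habitat-suitability model
#'
#' The central fitting function: splits the presence/pseudo-absence
#' sample into training and evaluation portions, fits the requested
#' member families on the training portion, scores members on the
#' held-out portion (each member's TSS maximized over thresholds
#' there), and combines them into an ensemble weighted by held-out True
#' Skill Statistic. Binarization thresholds (minimum
#' training presence, maximum training sensitivity plus specificity) are
#' derived from ensemble predictions on the training rows, as their
#' names imply; discrimination metrics (AUC, TSS) are reported on the
#' held-out rows.
#'
#' @param data sample table with binary `label` and predictor columns
#'   (see [build_sample_table()]).
#' @param variables predictor columns to use (default: all numeric
#'   columns except `lon`, `lat`, `label`).
#' @param families member families to fit.
#' @param train_fraction fraction of rows used for fitting (default
#'   0.7, evaluation on the remaining 0.3).
#' @param replicates replicate fits per family with distinct seeds
#'   (default 1).
#' @param seed integer master seed.
#' @param hyper named list of per-family hyperparameter overrides, e.g.
#'   `list(rf = list(ntree = 100))`.
#' @return object of class `ensemble_sdm` with components `members`,
#'   `weights`, `variables`, `evaluation` (held-out ensemble metrics),
#'   `thresholds` (`mtp`, `mtss`, `fixed_05`), `member_metrics`
#'   (data.frame), `train`, `test`, `seed`.
#' @export
ensemble_sdm <- function(data, variables = NULL,
                         families = c("glm", "gam", "rf", "brt"),
                         train_fraction = 0.7, replicates = 1, seed = 1,
                         hyper = list()) {
  if (is.null(variables))
    variables <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                         c("lon", "lat", "label"))
  if (!length(variables)) stop("no predictor variables")
  sp <- split_train_test(data, train_fraction, seed = stage_seed(seed, "split"))
  train <- sp$train; test <- sp$test
  specs <- expand.grid(family = families, replicate = seq_len(replicates),
                       stringsAsFactors = FALSE)
  members <- lapply(seq_len(nrow(specs)), function(i) {
    fam <- specs$family[i]
    s <- stage_seed(seed, paste0("member:", fam, ":", specs$replicate[i]))
    fit_member(fam, train, variables, seed = s, hyper = hyper[[fam]] %||% list())
  })
  usable <- !vapply(members, function(m) isTRUE(m$failed), logical(1))
  member_eval <- lapply(members, function(m) {
    if (isTRUE(m$failed)) return(NULL)
    tr_scores <- predict_member(m, train)
    te_scores <- predict_member(m, test)
    mtss <- find_mtss(te_scores, test$label)
    ev <- evaluate_scores(te_scores, test$label, mtss$threshold)
    list(mtp = find_mtp(tr_scores[train$label == 1]),
         mtss = mtss$threshold, eval = ev)
  })
  tss_vec <- vapply(member_eval, function(e)
    if (is.null(e)) -Inf else e$eval$tss, numeric(1))
  ens <- build_ensemble(members, tss_vec)
  keep <- which(usable)
  member_eval <- member_eval[keep]
  # ensemble scores
  w <- ens$weights
  ens_score <- function(tbl) {
    p <- vapply(ens$members, predict_member, numeric(nrow(tbl)), newdata = tbl)
    as.numeric(p %*% w)
  }
  tr_scores <- ens_score(train)
  te_scores <- ens_score(test)
  mtss <- find_mtss(tr_scores, train$label)
  thresholds <- list(mtp = find_mtp(tr_scores[train$label == 1]),
                     mtss = mtss$threshold, fixed_05 = 0.5)
  evaluation <- evaluate_scores(te_scores, test$label, mtss$threshold)
  mm <- data.frame(
    model = c(vapply(ens$members, `[[`, character(1), "family"), "ensemble"),
    AUC = c(vapply(member_eval, function(e) e$eval$auc, numeric(1)),
            evaluation$auc),
    TSS = c(vapply(member_eval, function(e) e$eval$tss, numeric(1)),
            evaluation$tss),
    MTSS = c(vapply(member_eval, `[[`, numeric(1), "mtss"),
             thresholds$mtss),
    MTP = c(vapply(member_eval, `[[`, numeric(1), "mtp"), thresholds$mtp),
    weight = c(w, NA_real_))
  structure(list(members = ens$members, weights = w, variables = variables,
                 evaluation = evaluation, thresholds = thresholds,
                 member_metrics = mm, train = train, test = test,
                 families = families, seed = seed),
            class = "ensemble_sdm")
}

#' @export
print.ensemble_sdm <- function(x, ...) {
  cat("TSS-weighted ensemble habitat-suitability model\n")
  cat(sprintf("  members: %s\n",
              paste(sprintf("%s (w=%.2f)",
                            vapply(x$members, `[[`, character(1), "family"),
                            x$weights), collapse = ", ")))
  cat(sprintf("  predictors: %s\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("  held-out AUC %.3f, TSS %.3f (n train %d, test %d)\n",
              x$evaluation$auc, x$evaluation$tss, nrow(x$train), nrow(x$test)))
  cat(sprintf("  thresholds: MTP %.3f, MTSS %.3f, fixed 0.50\n",
              x$thresholds$mtp, x$thresholds$mtss))
  invisible(x)
}

#' @export
summary.ensemble_sdm <- function(object, ...) {
  print(object)
  cat("\nPer-member held-out metrics:\n")
  print(object$member_metrics, row.names = FALSE, digits = 3)
  invisible(object$member_metrics)
}

#' @export
weights.ensemble_sdm <- function(object, ...) {
  stats::setNames(object$weights,
                  vapply(object$members, `[[`, character(1), "family"))
}

#' Predict ensemble suitability
#'
#' For a data.frame, returns the per-row weighted mean of member
#' probabilities (a convex combination, so always within the members'
#' range). For a [predictor_stack], evaluates every cell and returns a
#' suitability [raster_grid], propagating nodata from any layer.
#'
#' @param object an `ensemble_sdm`.
#' @param newdata data.frame with predictor columns, or a
#'   `predictor_stack` containing every retained variable.
#' @param ... unused.
#' @return numeric vector or `raster_grid` of probabilities in `[0, 1]`.
#' @export
predict.ensemble_sdm <- function(object, newdata, ...) {
  if (inherits(newdata, "predictor_stack")) {
    missing <- setdiff(object$variables, names(newdata))
    if (length(missing))
      stop("stack lacks retained layer(s): ", paste(missing, collapse = ", "))
    g <- newdata[[object$variables[1]]]
    d <- grid_def(g)
    cols <- lapply(object$variables, function(n) as.vector(newdata[[n]]$values))
    df <- as.data.frame(stats::setNames(cols, object$variables))
    ok <- stats::complete.cases(df)
    out <- rep(NA_real_, nrow(df))
    if (any(ok)) out[ok] <- predict(object, df[ok, , drop = FALSE])
    g$values <- matrix(out, d$nrow, d$ncol)
    return(g)
  }
  p <- vapply(object$members, predict_member, numeric(nrow(newdata)),
              newdata = newdata)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  as.numeric(p %*% object$weights)
}

#' Marginal response curve
#'
#' Ensemble suitability over a sequence of values of one predictor, all
#' other predictors held at their training-set mean.
#'
#' @param object an `ensemble_sdm`.
#' @param variable retained predictor name.
#' @param grid_points number of evaluation points spanning the observed
#'   range (default 100).
#' @return data.frame with `value` and `probability`.
#' @export
marginal_response <- function(object, variable, grid_points = 100) {
  if (!variable %in% object$variables)
    stop("'", variable, "' is not a retained variable")
  tr <- object$train
  vals <- seq(min(tr[[variable]]), max(tr[[variable]]),
              length.out = grid_points)
  nd <- as.data.frame(lapply(tr[object$variables], function(col)
    rep(mean(col), grid_points)))
  nd[[variable]] <- vals
  data.frame(value = vals, probability = predict(object, nd))
}

#' Permutation variable importance
#'
#' For each retained variable, importance is `1 - cor(p, p_perm)` where
#' `p` are ensemble predictions on the table and `p_perm` predictions
#' after permuting that variable's column, averaged over permutations,
#' floored at zero, and normalized to percentages summing to 100.
#'
#' @param object an `ensemble_sdm`.
#' @param table evaluation table (default: the model's full sample).
#' @param n_permutations permutations per variable (default 10).
#' @param seed integer RNG seed.
#' @return named numeric vector of percentages summing to 100.
#' @export
variable_importance <- function(object, table = NULL, n_permutations = 10,
                                seed = 1) {
  if (is.null(table)) table <- rbind(object$train, object$test)
  base <- predict(object, table)
  if (stats::sd(base) == 0) {
    warning("constant ensemble predictions; importance undefined, ",
            "returning zeros")
    return(stats::setNames(rep(0, length(object$variables)),
                           object$variables))
  }
  raw <- with_seed(seed, vapply(object$variables, function(v) {
    drops <- vapply(seq_len(n_permutations), function(i) {
      tb <- table
      tb[[v]] <- sample(tb[[v]])
      p <- predict(object, tb)
      if (stats::sd(p) == 0) 1 else 1 - stats::cor(base, p)
    }, numeric(1))
    mean(drops)
  }, numeric(1)))
  raw <- pmax(raw, 0)
  if (sum(raw) == 0) {
    warning("all permutation importances are zero")
    return(stats::setNames(raw, object$variables))
  }
  100 * raw / sum(raw)
}

#' Plot response curves of an ensemble model
#'
#' @param x an `ensemble_sdm`.
#' @param variables which predictors to plot (default: all retained).
#' @param grid_points points per curve.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the list of response data.frames.
#' @export
plot.ensemble_sdm <- function(x, variables = x$variables, grid_points = 100,
                              ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(variables)))
  on.exit(graphics::par(old))
  out <- lapply(variables, function(v) {
    r <- marginal_response(x, v, grid_points)
    graphics::plot(r$value, r$probability, type = "l", xlab = v,
                   ylab = "suitability", ylim = c(0, 1), ...)
    r
  })
  names(out) <- variables
  invisible(out)
}

#' Write member and ensemble metrics to CSV
#'
#' Columns `model,AUC,TSS,MTSS,MTP,weight`.
#' @param object an `ensemble_sdm`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_model_metrics <- function(object, path) {
  utils::write.csv(object$member_metrics, path, row.names = FALSE)
  invisible(path)
}
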