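#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression of predictor j on all the others. A perfectly collinear
#' predictor is reported as `Inf` rather than raising an error.
#'
#' @param table data.frame containing the predictor columns.
#' @param variables character vector of column names (>= 2).
#' @return named numeric vector of VIFs (all >= 1).
#' @export
compute_vif <- function(table, variables) {
  if (length(variables) < 2) stop("need at least two variables")
  if (nrow(table) <= length(variables))
    stop("need more rows than variables")
  X <- as.matrix(table[variables])
  vif <- vapply(seq_along(variables), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((X[, j] - mean(X[, j]))^2)
    if (ss_tot == 0) return(Inf)  # constant column
    r2 <- 1 - ss_res / ss_tot
    if (r2 >= 1 - 1e-12) Inf else max(1, 1 / (1 - r2))
  }, numeric(1))
  names(vif) <- variables
  vif
}

#' Collinearity-driven predictor selection
#'
#' Two-stage iterative filter, recomputing statistics after every
#' removal: (a) while any predictor pair has `|Pearson r| > r_max`,
#' remove the member of the most-correlated pair with the larger VIF;
#' (b) while any VIF exceeds `vif_max`, remove the largest-VIF
#' predictor. Ties are broken by removing the lexicographically later
#' name, making the procedure deterministic.
#'
#' @param table data.frame of predictor columns.
#' @param variables columns to consider (default: all numeric columns
#'   except `lon`, `lat`, `label`).
#' @param vif_max VIF cutoff (default 5).
#' @param r_max absolute pairwise correlation cutoff (default 0.75).
#' @return object of class `collinearity_report`: list with `vif`
#'   (final VIFs of retained variables), `removed` (data.frame of name,
#'   reason, value), `retained`.
#' @export
select_predictors <- function(table, variables = NULL, vif_max = 5,
                              r_max = 0.75) {
  if (vif_max <= 0 || r_max <= 0) stop("thresholds must be positive")
  if (is.null(variables))
    variables <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                         c("lon", "lat", "label"))
  keep <- variables
  removed <- data.frame(name = character(0), reason = character(0),
                        value = numeric(0))
  drop_one <- function(name, reason, value) {
    keep <<- setdiff(keep, name)
    removed <<- rbind(removed, data.frame(name = name, reason = reason,
                                          value = value))
  }
  # stage (a): pairwise correlation rule
  while (length(keep) >= 2) {
    C <- abs(stats::cor(as.matrix(table[keep])))
    diag(C) <- 0
    C[is.na(C)] <- 0  # constant columns: leave to the VIF stage
    if (max(C) <= r_max) break
    ij <- which(C == max(C), arr.ind = TRUE)[1, ]
    pair <- sort(keep[ij])
    vif <- tryCatch(compute_vif(table, keep), error = function(e) {
      stats::setNames(rep(1, length(keep)), keep)
    })
    # remove larger VIF; tie -> lexicographically later name
    worse <- if (vif[pair[1]] > vif[pair[2]]) pair[1]
    else if (vif[pair[2]] > vif[pair[1]]) pair[2]
    else pair[2]
    drop_one(worse, "correlation", max(C))
  }
  # stage (b): VIF rule
  while (length(keep) >= 2) {
    vif <- compute_vif(table, keep)
    if (max(vif) <= vif_max) break
    worst <- max(vif)
    cand <- sort(names(vif)[vif == worst])
    drop_one(cand[length(cand)], "vif", worst)
  }
  if (length(keep) < 2)
    warning("fewer than two predictors survive collinearity filtering")
  final_vif <- if (length(keep) >= 2) compute_vif(table, keep)
  else stats::setNames(rep(1, length(keep)), keep)
  structure(list(vif = final_vif, removed = removed, retained = keep,
                 vif_max = vif_max, r_max = r_max),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("collinearity filter (VIF <= %g, |r| <= %g)\n",
              x$vif_max, x$r_max))
  cat("  retained:", paste(sprintf("%s (VIF %.2f)", x$retained,
                                   x$vif[x$retained]), collapse = ", "), "\n")
  if (nrow(x$removed))
    cat("  removed: ", paste(sprintf("%s (%s %.2f)", x$removed$name,
                                     x$removed$reason, x$removed$value),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a collinearity report to CSV
#'
#' Columns `variable,vif,status,reason`.
#' @param report a `collinearity_report`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_collinearity_report <- function(report, path) {
  kept <- data.frame(variable = report$retained,
                     vif = unname(report$vif[report$retained]),
                     status = "retained", reason = "")
  drop <- if (nrow(report$removed))
    data.frame(variable = report$removed$name, vif = NA_real_,
               status = "removed", reason = report$removed$reason)
  else NULL
  utils::write.csv(rbind(kept, drop), path, row.names = FALSE)
  invisible(path)
}
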