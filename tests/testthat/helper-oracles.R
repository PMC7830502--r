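# Independent oracles used across tests. These deliberately use naive
# enumeration / closed forms, never the package's own code paths.

# AUC by exhaustive presence-absence pair counting (ties = 0.5).
auc_pair_oracle <- function(scores, labels) {
  p <- scores[labels == 1]; a <- scores[labels == 0]
  tot <- 0
  for (x in p) for (y in a)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(p) * length(a))
}

# MTSS by brute-force sweep over every unique score.
mtss_sweep_oracle <- function(scores, labels) {
  cand <- sort(unique(scores))
  best_t <- NA; best <- -Inf
  for (t in cand) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    if (sens + spec - 1 > best + 1e-12) { best <- sens + spec - 1; best_t <- t }
  }
  list(threshold = best_t, tss = best)
}

# VIF from the diagonal of the inverse correlation matrix.
vif_inverse_oracle <- function(X) {
  R <- stats::cor(X)
  diag(solve(R))
}

# AOO by a naive double loop over cells.
aoo_loop_oracle <- function(binary) {
  v <- binary$values
  n <- 0
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
    if (!is.na(v[i, j]) && v[i, j] == 1) n <- n + 1
  n
}

# Lag-1 spatial autocorrelation: Pearson r between horizontally and
# vertically adjacent cells, pooled.
lag1_cor <- function(grid) {
  v <- grid$values
  h <- stats::cor(as.vector(v[, -ncol(v)]), as.vector(v[, -1]))
  w <- stats::cor(as.vector(v[-nrow(v), ]), as.vector(v[-1, ]))
  (h + w) / 2
}

# Shoelace polygon area for a vertex ring (n x 2).
shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Convex hull area of a point set via grDevices::chull + shoelace.
convex_hull_area <- function(pts) {
  h <- grDevices::chull(pts)
  shoelace_area(pts[h, , drop = FALSE])
}

# A small deterministic stack used by several tests.
toy_stack <- function(seed = 42, nrow = 30, ncol = 30) {
  grid <- default_grid(nrow = nrow, ncol = ncol)
  make_predictor_stack(
    list(list(name = "a", min = 0, max = 1, correlation_range = 4),
         list(name = "b", min = 10, max = 20, correlation_range = 4)),
    grid = grid, seed = seed)
}

# Fast ensemble hyperparameters for unit tests (not the study defaults).
fast_hyper <- list(rf = list(ntree = 100), brt = list(nrounds = 100))

`%||%` <- function(a, b) if (is.null(a)) b else a
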