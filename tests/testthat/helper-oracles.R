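# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (loops, enumeration) and must stay free of
# the package's own code paths.

# percentile with linear interpolation between order statistics
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# AUC by exhaustive positive/negative pair comparison, half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Spearman rho from the rank-based Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  stats::cor(rx, ry)
}

# exhaustive threshold scan maximizing (sens+spec)/2; ties -> lower cut
oracle_best_cut <- function(x, labels, direction) {
  ux <- sort(unique(x))
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  best <- NULL
  for (thr in cuts) {
    pred <- if (direction == "low") as.integer(x <= thr)
            else as.integer(x >= thr)
    sens <- 100 * sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- 100 * sum(pred == 0 & labels == 0) / sum(labels == 0)
    acc <- (sens + spec) / 2
    if (is.null(best) || acc > best$acc + 1e-12)
      best <- list(thr = thr, acc = acc)
  }
  best
}

# per-frame mean over mask voxels, plain loops
oracle_mask_mean_curve <- function(conc4d, mask) {
  nt <- dim(conc4d)[4]
  out <- numeric(nt)
  idx <- which(mask, arr.ind = TRUE)
  for (f in seq_len(nt)) {
    s <- 0
    for (r in seq_len(nrow(idx)))
      s <- s + conc4d[idx[r, 1], idx[r, 2], idx[r, 3], f]
    out[f] <- s / nrow(idx)
  }
  out
}

# trapezoid rule by explicit loop
oracle_trapz <- function(y, dx) {
  s <- 0
  for (i in seq_len(length(y) - 1)) s <- s + dx * (y[i] + y[i + 1]) / 2
  s
}

oracle_cumtrapz <- function(y, dx) {
  out <- numeric(length(y))
  for (i in seq_len(length(y) - 1))
    out[i + 1] <- out[i] + dx * (y[i] + y[i + 1]) / 2
  out
}

# linear-interpolated delayed copy of a sampled curve (zero before start)
oracle_shift <- function(y, dt, s) {
  n <- length(y)
  t <- (seq_len(n) - 1) * dt
  out <- stats::approx(t, y, xout = t - s, rule = 1)$y
  out[is.na(out)] <- 0
  out
}
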