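#' The published logistic hemorrhage-risk score
#'
#' The fixed-coefficient model reported from the trial cohort:
#' `score = 1.75 - 9.526 * cbv_p10 + 2.7924 * k2_p90`, predicting
#' parenchymal hemorrhage when the score is at or above -1.45. The sign of
#' the CBV coefficient is negative (the printed formula's "1.75 to 9.526" is
#' a typeset minus): low lesion CBV raises risk, which is also required for
#' the worked example patient (CBV10 0.40, K2_90 0.32) to classify as PH.
#'
#' @return a `ph_logistic` model object.
#' @export
published_logistic <- function() {
  structure(list(intercept = 1.75,
                 coefficients = c(cbv_p10 = -9.526, k2_p90 = 2.7924),
                 threshold = -1.45, fitted = FALSE),
            class = "ph_logistic")
}

# raw published score; also used by the synthetic generator's label modes
logistic_score_value <- function(cbv_p10, k2_p90) {
  1.75 - 9.526 * cbv_p10 + 2.7924 * k2_p90
}

#' Score and classify a patient record with a logistic model
#'
#' @param record named list / one-row data.frame holding the model's
#'   features.
#' @param model a `ph_logistic` (default: the published model).
#' @return list with `score` and `label` (1 = PH; a score exactly at the
#'   threshold counts as PH).
#' @export
logistic_score <- function(record, model = published_logistic()) {
  stopifnot(inherits(model, "ph_logistic"))
  feats <- names(model$coefficients)
  for (f in feats) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1 || !is.finite(as.numeric(v)))
      stop("missing or non-finite feature: ", f, call. = FALSE)
  }
  x <- vapply(feats, function(f) as.numeric(record[[f]]), numeric(1))
  score <- unname(model$intercept + sum(model$coefficients * x))
  list(score = score, label = as.integer(score >= model$threshold))
}

#' The published two-threshold classification tree
#'
#' From the trial's recursive-partitioning analysis: 10th percentile CBV at
#' 0.47 and 90th percentile K2 at 0.28. The published rule covers two of the
#' four threshold quadrants (low CBV + high K2 predicts PH; high CBV + low
#' K2 predicts no PH); the `policy` resolves the two mixed quadrants —
#' `"logistic_fallback"` (default) defers to the published logistic score,
#' `"root_cbv"` uses the CBV split alone, `"majority"` predicts the
#' cohort-majority class (no PH).
#'
#' @param policy mixed-quadrant policy tag.
#' @return a `ph_tree` model object (`type = "published"`).
#' @export
published_tree <- function(policy = c("logistic_fallback", "root_cbv",
                                      "majority")) {
  policy <- match.arg(policy)
  structure(list(type = "published", cbv_thr = 0.47, k2_thr = 0.28,
                 policy = policy),
            class = "ph_tree")
}

#' Predict with a classification tree
#'
#' @param record named list / one-row data.frame of features.
#' @param model a `ph_tree`, either the published two-threshold rule or a
#'   fitted recursive-partitioning tree.
#' @return predicted label (1 = PH). Feature values exactly at a split
#'   threshold take the PH-side branch for the published thresholds
#'   (CBV `< 0.47` / K2 `>= 0.28` predict PH) and the `>=` branch in
#'   fitted trees.
#' @export
tree_predict <- function(record, model = published_tree()) {
  stopifnot(inherits(model, "ph_tree"))
  if (model$type == "published") {
    cbv <- as.numeric(record[["cbv_p10"]]); k2 <- as.numeric(record[["k2_p90"]])
    if (!is.finite(cbv) || !is.finite(k2))
      stop("missing or non-finite feature for tree prediction", call. = FALSE)
    low_cbv <- cbv < model$cbv_thr
    high_k2 <- k2 >= model$k2_thr
    if (low_cbv && high_k2) return(1L)
    if (!low_cbv && !high_k2) return(0L)
    switch(model$policy,
      logistic_fallback = logistic_score(record)$label,
      root_cbv = as.integer(low_cbv),
      majority = 0L,
      stop("unknown mixed-quadrant policy: ", model$policy, call. = FALSE))
  } else {
    node <- model$root
    while (!node$leaf) {
      x <- as.numeric(record[[node$feature]])
      if (!is.finite(x))
        stop("missing or non-finite feature: ", node$feature, call. = FALSE)
      node <- if (x < node$threshold) node$left else node$right
    }
    node$label
  }
}

gini_impurity <- function(pos, n) {
  p <- pos / n
  2 * p * (1 - p)
}

# best (feature, threshold) over all midpoints; deterministic tie-breaks:
# first feature in candidate order, then lowest threshold
best_split <- function(data, candidates, y, min_leaf) {
  n <- length(y)
  parent <- gini_impurity(sum(y), n)
  best <- NULL
  for (f in candidates) {
    x <- data[[f]]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    distinct <- which(diff(xs) > 0)             # split after these positions
    if (length(distinct) == 0) next
    nl <- distinct
    posl <- cumsum(ys)[distinct]
    nr <- n - nl
    posr <- sum(ys) - posl
    ok <- nl >= min_leaf & nr >= min_leaf
    if (!any(ok)) next
    dec <- parent - (nl * gini_impurity(posl, nl) +
                       nr * gini_impurity(posr, nr)) / n
    dec[!ok] <- -Inf
    k <- which.max(dec)                          # first max = lowest threshold
    pos <- distinct[k]
    if (dec[k] > 1e-12 && (is.null(best) || dec[k] > best$decrease + 1e-12)) {
      best <- list(feature = f, threshold = (xs[pos] + xs[pos + 1]) / 2,
                   decrease = dec[k])
    }
  }
  best
}

leaf_node <- function(y) {
  # majority label; ties go to the negative (no-PH) class
  list(leaf = TRUE, label = as.integer(sum(y) * 2 > length(y)),
       n = length(y), n_pos = sum(y))
}

grow_tree <- function(data, candidates, y, depth, max_depth, min_leaf) {
  if (depth >= max_depth || length(unique(y)) < 2 || length(y) < 2 * min_leaf)
    return(leaf_node(y))
  sp <- best_split(data, candidates, y, min_leaf)
  if (is.null(sp)) return(leaf_node(y))
  left <- data[[sp$feature]] < sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(data[left, , drop = FALSE], candidates, y[left],
                        depth + 1, max_depth, min_leaf),
       right = grow_tree(data[!left, , drop = FALSE], candidates, y[!left],
                         depth + 1, max_depth, min_leaf))
}

#' Fit a classification tree by binary recursive partitioning
#'
#' Greedy exhaustive search: at each node every candidate feature and every
#' midpoint between consecutive sorted distinct values is scored by Gini
#' impurity decrease; the best split (ties: earlier feature in `candidates`,
#' then lower threshold) recurses until `max_depth` or `min_leaf`. Records
#' with the feature exactly at a fitted threshold follow the `>=` branch.
#'
#' @param data data.frame containing `candidates` and `label_col`.
#' @param candidates character vector of feature columns, in priority order.
#' @param max_depth maximum tree depth (default 2, the published model's).
#' @param min_leaf minimum records per leaf (default 5).
#' @param label_col binary outcome column (default `"ph_label"`).
#' @return a `ph_tree` (`type = "fitted"`) with the node structure in
#'   `$root`; [tree_thresholds()] lists the split thresholds per feature.
#' @export
fit_tree <- function(data, candidates, max_depth = 2, min_leaf = 5,
                     label_col = "ph_label") {
  y <- data[[label_col]]
  stopifnot(nrow(data) >= 10, all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) {
    root <- leaf_node(y)
  } else {
    root <- grow_tree(data[, candidates, drop = FALSE], candidates, y,
                      0L, max_depth, min_leaf)
  }
  structure(list(type = "fitted", root = root, policy = NA_character_,
                 candidates = candidates, max_depth = max_depth,
                 min_leaf = min_leaf),
            class = "ph_tree")
}

#' Split thresholds of a fitted tree, by feature
#' @param model a fitted `ph_tree`.
#' @return named list mapping feature name to vector of thresholds.
#' @export
tree_thresholds <- function(model) {
  stopifnot(inherits(model, "ph_tree"), model$type == "fitted")
  out <- list()
  walk <- function(node) {
    if (node$leaf) return(invisible())
    out[[node$feature]] <<- c(out[[node$feature]], node$threshold)
    walk(node$left); walk(node$right)
  }
  walk(model$root)
  out
}

# IRLS on a standardized design: |beta| > 30 per standardized unit signals
# (quasi-)separation; coefficients stay at the last stable iterate
irls_logistic <- function(X, y, tol = 1e-8, max_iter = 100) {
  beta <- rep(0, ncol(X))
  separated <- FALSE
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    XtWX <- crossprod(X, X * w)
    new_beta <- tryCatch(drop(solve(XtWX, crossprod(X, w * z))),
                         error = function(e) NULL)
    if (is.null(new_beta) || max(abs(new_beta)) > 30) {
      separated <- TRUE
      break
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  cov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, length(beta)) else sqrt(diag(cov))
  pval <- 2 * stats::pnorm(-abs(beta / se))
  list(beta = beta, se = se, p = pval, cov = cov, converged = converged,
       separated = separated)
}

#' Backward-stepwise logistic regression (IRLS + Wald elimination)
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (convergence when the largest coefficient change falls below 1e-8, at
#' most 100 iterations), followed by backward elimination: while any
#' remaining variable has Wald p-value above `alpha`, the one with the
#' largest p-value is dropped and the model refit. Constant or collinear
#' candidates are dropped up front with a warning; perfect separation is
#' flagged (coefficients kept at the last stable iterate) rather than
#' raised.
#'
#' @param data data.frame with candidate columns and `label_col`.
#' @param candidates character vector of candidate predictor columns (the
#'   analysis supports the 14 trial candidates: 6 imaging + 8 clinical).
#' @param alpha retention significance level (default 0.05).
#' @param label_col binary outcome column.
#' @return a `ph_logistic` with `fitted = TRUE`, retained `coefficients`,
#'   Wald `se` and `p_values`, a training-data `threshold` on the linear
#'   score chosen to maximize (sensitivity+specificity)/2, and flags
#'   `separation`/`dropped_degenerate`.
#' @export
fit_logistic_backward <- function(data, candidates, alpha = 0.05,
                                  label_col = "ph_label") {
  y <- data[[label_col]]
  stopifnot(nrow(data) >= 10, all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("both labels must be present", call. = FALSE)

  degenerate <- candidates[vapply(candidates, function(f) {
    v <- data[[f]]
    !is.numeric(v) || stats::sd(v) == 0 || anyNA(v)
  }, logical(1))]
  if (length(degenerate) > 0)
    warning("dropping degenerate candidate(s): ",
            paste(degenerate, collapse = ", "))
  vars <- setdiff(candidates, degenerate)

  # fit on per-variable standardized predictors (conditioning; the
  # separation guard is then in log-odds-per-SD units); results are mapped
  # back to the raw scale afterwards. Wald p-values are scale-invariant.
  mu <- vapply(vars, function(f) mean(data[[f]]), numeric(1))
  sdev <- vapply(vars, function(f) stats::sd(data[[f]]), numeric(1))
  separated <- FALSE
  repeat {
    Xs <- cbind(`(Intercept)` = 1,
                scale(as.matrix(data[, vars, drop = FALSE]),
                      center = mu[vars], scale = sdev[vars]))
    fit <- irls_logistic(Xs, y)
    separated <- separated || fit$separated
    if (length(vars) == 0) break
    pv <- fit$p[-1]
    worst <- which.max(pv)
    if (is.finite(pv[worst]) && pv[worst] > alpha) {
      vars <- vars[-worst]
    } else if (anyNA(pv)) {
      vars <- vars[-which(is.na(pv))[1]]          # rank-deficient survivor
    } else break
  }

  # back-transform: beta_raw = T beta_std, cov_raw = T cov_std T'
  k <- length(vars)
  Tm <- diag(1 + k)
  if (k > 0) {
    Tm[1, 1 + seq_len(k)] <- -mu[vars] / sdev[vars]
    diag(Tm)[1 + seq_len(k)] <- 1 / sdev[vars]
  }
  beta <- drop(Tm %*% fit$beta)
  names(beta) <- c("(Intercept)", vars)
  se_raw <- if (is.null(fit$cov)) rep(NA_real_, 1 + k) else
    sqrt(diag(Tm %*% fit$cov %*% t(Tm)))
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, vars, drop = FALSE]))
  score <- drop(X %*% beta)
  thr <- if (length(unique(score)) > 1) {
    optimal_threshold(score, y, direction = "high")$threshold
  } else 0
  structure(list(intercept = unname(beta[1]), coefficients = beta[-1],
                 se = stats::setNames(se_raw, names(beta)),
                 p_values = stats::setNames(fit$p, names(beta)),
                 threshold = thr, fitted = TRUE, converged = fit$converged,
                 separation = separated, dropped_degenerate = degenerate),
            class = "ph_logistic")
}

#' Confusion counts and balanced-accuracy report
#'
#' The trial's accuracy conventions: sensitivity = 100*TP/(TP+FN),
#' specificity = 100*TN/(TN+FP), overall accuracy = their arithmetic mean,
#' and (when scores are supplied) AUC by the rank / Mann-Whitney formulation
#' with half-credit for ties.
#'
#' @param predictions binary predicted labels (or `NULL` when `counts` is
#'   given).
#' @param labels binary true labels.
#' @param scores optional continuous scores for AUC.
#' @param counts optional named vector/list with `tp`, `fn`, `tn`, `fp`,
#'   bypassing `predictions`.
#' @return a `ph_eval` list: `counts` (tp/fn/tn/fp) and `report`
#'   (`sensitivity`, `specificity`, `overall_accuracy` in percent — `NA`
#'   when a class is absent — and `auc`).
#' @export
evaluate <- function(predictions = NULL, labels = NULL, scores = NULL,
                     counts = NULL) {
  if (is.null(counts)) {
    stopifnot(length(predictions) == length(labels),
              all(predictions %in% c(0, 1)), all(labels %in% c(0, 1)))
    counts <- c(tp = sum(predictions == 1 & labels == 1),
                fn = sum(predictions == 0 & labels == 1),
                tn = sum(predictions == 0 & labels == 0),
                fp = sum(predictions == 1 & labels == 0))
  } else {
    counts <- unlist(counts)[c("tp", "fn", "tn", "fp")]
    stopifnot(all(counts >= 0))
  }
  npos <- counts[["tp"]] + counts[["fn"]]
  nneg <- counts[["tn"]] + counts[["fp"]]
  sens <- if (npos > 0) 100 * counts[["tp"]] / npos else NA_real_
  spec <- if (nneg > 0) 100 * counts[["tn"]] / nneg else NA_real_
  auc <- if (!is.null(scores) && !is.null(labels)) auc_scores(scores, labels)
         else NA_real_
  structure(list(counts = as.list(counts),
                 report = list(sensitivity = sens, specificity = spec,
                               overall_accuracy = mean(c(sens, spec)),
                               auc = auc)),
            class = "ph_eval")
}

#' Area under the ROC curve (rank formulation)
#' @param scores continuous scores, higher = more PH-like.
#' @param labels binary labels.
#' @return AUC in `[0, 1]`, with half-credit for tied scores.
#' @export
auc_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Optimal single-feature threshold by balanced accuracy
#'
#' Scans every midpoint between consecutive sorted distinct feature values
#' and returns the cut maximizing (sensitivity+specificity)/2 — the
#' Youden-equivalent operating point. Ties go to the lower threshold.
#' Values exactly at the threshold count as the PH side.
#'
#' @param x feature values.
#' @param labels binary labels.
#' @param direction `"low"` if low values predict PH (CBV, ADC) or
#'   `"high"` if high values do (K2).
#' @return list with `threshold` (`NA` with `flag = "constant_feature"` for
#'   a constant feature), `direction`, and the `ph_eval` of the chosen cut.
#' @export
optimal_threshold <- function(x, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(labels), all(labels %in% c(0, 1)))
  ux <- sort(unique(x))
  if (length(ux) < 2)
    return(list(threshold = NA_real_, direction = direction, eval = NULL,
                flag = "constant_feature"))
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  best <- NULL
  for (thr in cuts) {                            # ascending: ties keep lower
    pred <- if (direction == "low") as.integer(x <= thr) else as.integer(x >= thr)
    ev <- evaluate(pred, labels)
    acc <- ev$report$overall_accuracy
    if (is.null(best) || acc > best$acc + 1e-12)
      best <- list(thr = thr, acc = acc, eval = ev)
  }
  list(threshold = best$thr, direction = direction, eval = best$eval,
       flag = NULL)
}

#' Pairwise Spearman correlations of the lesion features
#'
#' Rank-based correlation with average ranks for ties, for each pair of the
#' three percentile features (or any supplied columns). A constant column
#' yields `NA` for its pairs.
#'
#' @param data data.frame holding the feature columns.
#' @param features columns to correlate (default the three lesion features).
#' @return data.frame with columns `feature_a`, `feature_b`, `rho`.
#' @export
feature_correlations <- function(data,
                                 features = c("cbv_p10", "adc_p10", "k2_p90")) {
  stopifnot(nrow(data) >= 3, all(features %in% names(data)))
  pairs <- utils::combn(features, 2)
  rho <- apply(pairs, 2, function(fp) {
    x <- data[[fp[1]]]; y <- data[[fp[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  })
  data.frame(feature_a = pairs[1, ], feature_b = pairs[2, ], rho = rho)
}
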