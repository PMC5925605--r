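#' Rank-based AUC of a single feature
#'
#' Area under the ROC curve via the Mann-Whitney U statistic: the
#' probability that a random tumor value exceeds a random normal value,
#' ties counted 1/2 (average ranks).
#'
#' @param values per-sample numeric values.
#' @param labels per-sample class: logical/0-1 (TRUE/1 = tumor) or
#'   `"normal"`/`"tumor"` strings.
#' @return AUC in `[0, 1]`, tumor-high oriented.
#' @export
probe_auc <- function(values, labels) {
  y <- .binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("normal", "tumor"))) {
      stop("labels must be 'normal'/'tumor' or binary")
    }
    as.integer(labels == "tumor")
  } else {
    y <- as.integer(labels)
    if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
    y
  }
}

#' Staged feature selection for the diagnostic panel
#'
#' Three stages, mirroring the marker-panel construction: (1) drop
#' significant probes whose genomic position falls inside any recurrent
#' copy-number interval; (2) keep only fully differentiating probes --
#' rank AUC exactly `auc_keep` in either orientation (`max(U, 1 - U)`,
#' so perfect hypo-direction separation also counts); (3) greedy
#' redundancy pruning in a deterministic order (decreasing `|delta_beta|`,
#' ties by probe id): a probe is kept only when its squared Pearson
#' correlation with every already-kept probe is at most `r2_cut`.
#'
#' @param dmps DMP table from [call_dmps()] (only `significant` probes are
#'   considered).
#' @param cnv_regions recurrent CNV intervals (`chrom`, `start`, `end`);
#'   may be empty.
#' @param manifest probe manifest (for probe positions).
#' @param beta probe x sample beta matrix.
#' @param labels per-sample class labels.
#' @param auc_keep required AUC (default 1.00, exact).
#' @param r2_cut maximum squared correlation among kept probes
#'   (default 0.90).
#' @return character vector of kept probe ids (iteration order); errors
#'   name the stage that emptied the candidate set.
#' @export
select_features <- function(dmps, cnv_regions, manifest, beta, labels,
                            auc_keep = 1.0, r2_cut = 0.9) {
  if (nrow(dmps) == 0) stop("empty DMP table")
  cand <- dmps[dmps$significant, , drop = FALSE]
  if (nrow(cand) == 0) stop("stage 0: no significant probes to select from")

  pos <- manifest[match(cand$probe_id, manifest$probe_id), c("chrom", "pos")]
  in_cnv <- rep(FALSE, nrow(cand))
  if (!is.null(cnv_regions) && nrow(cnv_regions) > 0) {
    lv <- union(unique(pos$chrom), unique(cnv_regions$chrom))
    pg <- GenomicRanges::GRanges(factor(pos$chrom, levels = lv),
                                 IRanges::IRanges(pos$pos, pos$pos))
    in_cnv <- IRanges::overlapsAny(pg, .seg_granges(cnv_regions, lv))
  }
  cand <- cand[!in_cnv, , drop = FALSE]
  if (nrow(cand) == 0) stop("stage 1 (CNV exclusion): no probes left")

  auc <- vapply(cand$probe_id, function(p) {
    a <- probe_auc(beta[p, ], labels)
    max(a, 1 - a)
  }, numeric(1))
  cand <- cand[auc == auc_keep, , drop = FALSE]
  if (nrow(cand) == 0) stop("stage 2 (AUC filter): no probes left")

  ord <- order(-abs(cand$delta_beta), cand$probe_id)
  ids <- cand$probe_id[ord]
  kept <- character(0)
  for (p in ids) {
    if (length(kept) == 0) {
      kept <- p
      next
    }
    r2 <- cor(beta[p, ], t(beta[kept, , drop = FALSE]))^2
    if (all(r2 <= r2_cut)) kept <- c(kept, p)
  }
  if (length(kept) == 0) stop("stage 3 (redundancy pruning): no probes left")
  kept
}

# Soft-threshold operator.
soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# IRLS + cyclic coordinate descent on already-standardized columns
# (compiled core). Returns b0/b on the standardized scale; warm-startable.
.lasso_core <- function(Xs, y, lambda, b0, b, max_iter = 200L, tol = 1e-7) {
  .lasso_core_cpp(Xs, as.integer(y), lambda, b0, b, as.integer(max_iter), tol)
}

# Warm-started regularization path over a decreasing lambda grid on
# standardized columns; returns a p x length(grid) coefficient matrix and
# intercept vector (standardized scale).
.lasso_path <- function(Xs, y, lambdas, max_iter = 40L, tol = 1e-5) {
  p <- ncol(Xs)
  B <- matrix(0, p, length(lambdas))
  b0s <- numeric(length(lambdas))
  b0 <- qlogis(mean(y))
  b <- rep(0, p)
  for (li in order(lambdas, decreasing = TRUE)) {
    fit <- .lasso_core(Xs, y, lambdas[li], b0, b, max_iter, tol)
    b0 <- fit$b0
    b <- fit$b
    B[, li] <- b
    b0s[li] <- b0
  }
  list(b0 = b0s, B = B)
}

# Penalized logistic objective on the standardized scale:
# (1/n) * sum deviance/2-free log-loss + lambda * sum |beta|.
.lasso_objective <- function(Xs, y, b0, b, lambda) {
  eta <- as.vector(b0 + Xs %*% b)
  # numerically stable log(1 + exp(eta)) - y*eta
  ll <- mean(ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta)
  ll + lambda * sum(abs(b))
}

#' L1-regularized logistic regression by coordinate descent
#'
#' Minimizes `(1/n) * logistic log-loss + lambda * ||coef||_1` on
#' internally standardized columns (mean 0, sd 1 with an `1/n`
#' denominator), intercept unpenalized, via iteratively reweighted least
#' squares with cyclic coordinate descent and soft-thresholding. Returned
#' coefficients are back-transformed to the input (beta) scale so new
#' samples can be scored from raw beta values.
#'
#' @param X sample x feature matrix (features in columns, named).
#' @param y binary response (0/1 or normal/tumor labels).
#' @param lambda non-negative penalty.
#' @param max_iter maximum outer iterations (default 200).
#' @param tol convergence threshold on the maximum standardized
#'   coefficient change (default 1e-7).
#' @return a panel model: list with `probe_ids`, `intercept`,
#'   `coefficients` (input scale), `lambda`, `standardization` (per-feature
#'   mean/sd), `threshold` (0.5), `objective`, and `converged`.
#' @export
lasso_logistic_fit <- function(X, y, lambda, max_iter = 200L, tol = 1e-7) {
  y <- .binary_labels(y)
  if (lambda < 0) stop("lambda must be non-negative")
  mu <- colMeans(X)
  sds <- sqrt(colMeans(X^2) - mu^2)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) dropped")
    X <- X[, keep, drop = FALSE]
    mu <- mu[keep]
    sds <- sds[keep]
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  fit <- .lasso_core(Xs, y, lambda, qlogis(mean(y)), rep(0, ncol(X)),
                     max_iter, tol)
  if (!fit$converged) {
    stop("coordinate descent did not converge in ", max_iter,
         " IRLS iterations (lambda = ", lambda, ", p = ", ncol(X), ")")
  }
  b0 <- fit$b0
  b <- fit$b
  coef_orig <- b / sds
  intercept <- b0 - sum(b * mu / sds)
  structure(list(
    probe_ids = colnames(X),
    intercept = intercept,
    coefficients = setNames(coef_orig, colnames(X)),
    lambda = lambda,
    standardization = data.frame(probe_id = colnames(X), mean = mu, sd = sds,
                                 stringsAsFactors = FALSE),
    threshold = 0.5,
    objective = .lasso_objective(Xs, y, b0, b, lambda),
    converged = fit$converged
  ), class = "panel_model")
}

#' Karush-Kuhn-Tucker residuals of a fitted panel model
#'
#' On the standardized scale the subgradient conditions require
#' `|gradient_j| <= lambda` for zero coefficients and
#' `gradient_j = -sign(coef_j) * lambda` for active ones. Returns the
#' per-feature gradient `(1/n) * X_std' (p - y)` for inspection/testing.
#'
#' @param model fitted panel model.
#' @param X,y the training data used at fit time.
#' @return named numeric vector of gradients (standardized scale).
#' @export
kkt_residuals <- function(model, X, y) {
  y <- .binary_labels(y)
  X <- X[, model$probe_ids, drop = FALSE]
  st <- model$standardization
  Xs <- sweep(sweep(X, 2, st$mean), 2, st$sd, "/")
  eta <- model$intercept + as.vector(X %*% model$coefficients)
  prob <- plogis(eta)
  setNames(as.vector(crossprod(Xs, prob - y)) / nrow(X), model$probe_ids)
}

#' Smallest penalty that zeroes every coefficient
#'
#' @param X sample x feature matrix.
#' @param y binary response.
#' @return `lambda_max = max_j |(1/n) X_std_j' (y - mean(y))|`.
#' @export
lambda_max <- function(X, y) {
  y <- .binary_labels(y)
  mu <- colMeans(X)
  sds <- sqrt(colMeans(X^2) - mu^2)
  sds[sds == 0] <- Inf
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  max(abs(crossprod(Xs, y - mean(y)) / nrow(X)))
}

#' Choose the LASSO penalty by repeated cross-validation
#'
#' Repeated stratified k-fold cross-validation: fold assignment is
#' re-randomized `n_rep` times; held-out misclassification at the 0.5
#' probability threshold is averaged over all repetitions, and the largest
#' lambda attaining the minimum mean error is returned (parsimony
#' tie-break). A repetition whose folds lose a class is re-drawn (logged
#' via message).
#'
#' @param X sample x feature matrix.
#' @param y binary response.
#' @param n_rep fold-assignment repetitions (default 25; the full-scale
#'   analysis uses 1000).
#' @param n_folds folds per repetition (default 5, >= 2).
#' @param lambda_grid decreasing penalty grid; default 50 log-spaced
#'   values over 3 decades down from `lambda_max`.
#' @param seed RNG seed.
#' @return list with `lambda` (selected), `lambda_grid`, `cv_error` (mean
#'   misclassification per grid point).
#' @export
select_lambda <- function(X, y, n_rep = 25L, n_folds = 5L,
                          lambda_grid = NULL, seed = 1L) {
  y <- .binary_labels(y)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (is.null(lambda_grid)) {
    lmax <- lambda_max(X, y)
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 50))
  }
  n <- nrow(X)
  errs <- matrix(NA_real_, length(lambda_grid), n_rep)
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      for (attempt in 1:20) {
        fold <- integer(n)
        for (cls in unique(y)) {
          idx <- which(y == cls)
          fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
        }
        ok <- all(vapply(seq_len(n_folds), function(f) {
          length(unique(y[fold != f])) == 2
        }, logical(1)))
        if (ok) break
        message("re-drawing fold assignment (repetition ", r,
                "): a training fold lost a class")
      }
      miss <- matrix(NA_real_, length(lambda_grid), n)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        te <- !tr
        if (!any(te)) next
        Xtr <- X[tr, , drop = FALSE]
        mu <- colMeans(Xtr)
        sds <- sqrt(colMeans(Xtr^2) - mu^2)
        sds[sds == 0] <- Inf               # constant-in-fold feature inert
        Xtr_s <- sweep(sweep(Xtr, 2, mu), 2, sds, "/")
        Xte_s <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sds, "/")
        path <- .lasso_path(Xtr_s, y[tr], lambda_grid)
        eta <- sweep(Xte_s %*% path$B, 2, path$b0, "+")
        miss[, te] <- t((eta > 0) != (y[te] == 1))
      }
      errs[, r] <- rowMeans(miss, na.rm = TRUE)
    }
  })
  cv_error <- rowMeans(errs)
  best <- min(cv_error)
  lambda <- max(lambda_grid[cv_error <= best + 1e-12])
  list(lambda = lambda, lambda_grid = lambda_grid, cv_error = cv_error)
}

#' Score samples with a fitted panel model
#'
#' `score = logistic(intercept + sum coef * beta)`; a sample is classed
#' tumor when its score strictly exceeds the model threshold (a score of
#' exactly 0.5 is classed normal).
#'
#' @param model fitted panel model.
#' @param beta probe x sample beta matrix containing every model probe.
#' @return data.frame `sample_id`, `score` (in (0,1)), `class`.
#' @export
predict_scores <- function(model, beta) {
  missing <- setdiff(model$probe_ids, rownames(beta))
  if (length(missing) > 0) {
    stop("model probes absent from beta matrix: ",
         paste(missing, collapse = ", "))
  }
  B <- beta[model$probe_ids, , drop = FALSE]
  if (any(B < 0 | B > 1)) stop("beta values out of [0, 1]")
  eta <- model$intercept + as.vector(crossprod(B, model$coefficients))
  score <- plogis(eta)
  data.frame(
    sample_id = colnames(beta) %||% as.character(seq_along(score)),
    score = score,
    class = ifelse(score > model$threshold, "tumor", "normal"),
    stringsAsFactors = FALSE
  )
}

#' Classification performance report
#'
#' Confusion counts at the threshold plus sensitivity, specificity,
#' accuracy and the rank AUC of the scores.
#'
#' @param scores per-sample probability scores.
#' @param true_labels per-sample truth.
#' @param threshold classification cut-off (default 0.5, strict `>` for
#'   tumor).
#' @return list with `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`,
#'   `accuracy`, `auc`, and the per-sample `scores` echoed back. With a
#'   single-class truth the undefined metrics are `NA`.
#' @export
evaluate_panel <- function(scores, true_labels, threshold = 0.5) {
  y <- .binary_labels(true_labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (length(unique(y)) == 2) probe_auc(scores, y) else NA_real_
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(y),
       auc = auc,
       scores = data.frame(score = scores, truth = y))
}

#' Train the minimal CpG diagnostic panel end to end
#'
#' Feature selection ([select_features()]), penalty choice
#' ([select_lambda()]) and the final L1-regularized logistic fit, keeping
#' only probes with nonzero coefficients in the reported panel size.
#'
#' @inheritParams select_features
#' @param n_rep,n_folds cross-validation settings (see [select_lambda()]).
#' @param seed RNG seed.
#' @return fitted panel model with an added `selected_features` element
#'   (the post-pruning candidate list) and `n_active` (nonzero
#'   coefficients).
#' @export
train_panel <- function(dmps, cnv_regions, manifest, beta, labels,
                        auc_keep = 1.0, r2_cut = 0.9, n_rep = 25L,
                        n_folds = 5L, seed = 1L) {
  feats <- select_features(dmps, cnv_regions, manifest, beta, labels,
                           auc_keep, r2_cut)
  X <- t(beta[feats, , drop = FALSE])
  sel <- select_lambda(X, labels, n_rep = n_rep, n_folds = n_folds,
                       seed = seed)
  model <- lasso_logistic_fit(X, labels, sel$lambda)
  model$selected_features <- feats
  model$cv <- sel[c("lambda_grid", "cv_error")]
  model$n_active <- sum(model$coefficients != 0)
  model
}
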