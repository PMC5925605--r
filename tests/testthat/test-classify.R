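test_that("rank AUC equals brute-force pair counting", {
  # perfect separation and pure ties
  expect_equal(probe_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(probe_auc(rep(5, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_equal(probe_auc(c(10, 11, 1, 2), c(1, 1, 0, 0)), 1)

  pair_count <- function(v, y) {
    t <- v[y == 1]; n <- v[y == 0]
    s <- 0
    for (a in t) for (b in n) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(t) * length(n))
  }
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    v <- sample(round(rnorm(n), 1))   # rounded -> ties occur
    expect_equal(probe_auc(v, y), pair_count(v, y))
  }
  expect_error(probe_auc(1:4, rep(1, 4)), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  v <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  expect_equal(probe_auc(v, y),
               as.numeric(suppressMessages(pROC::auc(y, v,
                                                     direction = "<"))))
})

# A small hand-built selection scenario.
selection_fixture <- function() {
  man <- manual_manifest(c(100, 5000, 9000, 13000, 17000))
  groups <- group_labels(5, 5)
  beta <- rbind(
    p001 = c(0.1, 0.12, 0.11, 0.09, 0.10, 0.6, 0.62, 0.61, 0.60, 0.63),  # in CNV
    p002 = c(0.1, 0.12, 0.11, 0.09, 0.10, 0.55, 0.58, 0.57, 0.56, 0.59), # clean, AUC 1
    p003 = c(0.1, 0.12, 0.50, 0.09, 0.10, 0.45, 0.58, 0.57, 0.20, 0.59), # AUC < 1
    p004 = c(0.12, 0.14, 0.13, 0.11, 0.12, 0.57, 0.60, 0.59, 0.58, 0.61), # = p002 + 0.02
    p005 = c(0.95, 0.70, 0.90, 0.65, 0.85, 0.45, 0.20, 0.40, 0.15, 0.35) # hypo direction
  )
  colnames(beta) <- paste0("S", 1:10)
  dmps <- data.frame(
    probe_id = rownames(beta),
    p_adj = 1e-5,
    delta_beta = rowMeans(beta[, 6:10]) - rowMeans(beta[, 1:5]),
    significant = TRUE,
    stringsAsFactors = FALSE
  )
  cnv <- data.frame(chrom = "chr1", start = 50, end = 150,
                    direction = "gain", stringsAsFactors = FALSE)
  list(man = man, beta = beta, dmps = dmps, cnv = cnv, groups = groups)
}

test_that("feature selection applies CNV, AUC and redundancy stages in order", {
  fx <- selection_fixture()
  kept <- select_features(fx$dmps, fx$cnv, fx$man, fx$beta, fx$groups)
  # p001 excluded at stage 1 (inside CNV) despite AUC 1
  expect_false("p001" %in% kept)
  # p003 excluded at stage 2 (AUC < 1)
  expect_false("p003" %in% kept)
  # p004 strongly correlated with p002: the lower-|delta| one is pruned
  expect_true("p002" %in% kept)
  expect_false("p004" %in% kept)
  # hypo-direction perfect separation is kept (direction-agnostic AUC)
  expect_true("p005" %in% kept)
  # iteration order: decreasing |delta_beta|
  expect_equal(kept, kept[order(-abs(fx$dmps$delta_beta[match(kept, fx$dmps$probe_id)]))])

  # staged errors name the failing stage
  no_sig <- fx$dmps; no_sig$significant <- FALSE
  expect_error(select_features(no_sig, fx$cnv, fx$man, fx$beta, fx$groups),
               "stage 0")
  all_cnv <- data.frame(chrom = "chr1", start = 1, end = 1e6,
                        stringsAsFactors = FALSE)
  expect_error(select_features(fx$dmps, all_cnv, fx$man, fx$beta, fx$groups),
               "stage 1")
  expect_error(select_features(fx$dmps[fx$dmps$probe_id == "p003", ], fx$cnv,
                               fx$man, fx$beta, fx$groups), "stage 2")
})

test_that("the null-model threshold and descent properties hold", {
  set.seed(41)
  X <- matrix(rbeta(30 * 4, 2, 5), 30, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(30, 1, 0.4)
  lmax <- lambda_max(X, y)
  fit <- lasso_logistic_fit(X, y, lmax * 1.0001)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-6)

  # below lambda_max at least one coefficient activates
  fit2 <- lasso_logistic_fit(X, y, lmax * 0.5)
  obj_null <- methylforge:::.lasso_objective(
    scale(X, scale = apply(X, 2, function(c) sqrt(mean(c^2) - mean(c)^2))),
    y, qlogis(mean(y)), rep(0, 4), lmax * 0.5)
  expect_lte(fit2$objective, obj_null + 1e-10)

  expect_error(lasso_logistic_fit(X, cbind(1, 2, 3), 0.1), "binary")
  expect_error(lasso_logistic_fit(X, y, -1), "non-negative")

  # constant features are dropped with a warning
  Xc <- cbind(X, const = 1)
  expect_warning(fc <- lasso_logistic_fit(Xc, y, 0.1), "constant")
  expect_false("const" %in% fc$probe_ids)
})

test_that("the fit satisfies the KKT conditions and matches glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(42)
  X <- matrix(rbeta(40 * 6, 2, 5), 40, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(X[, 1] + X[, 2] + rnorm(40, 0, 0.3) > 1)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  lam <- 0.03
  fit <- lasso_logistic_fit(X, y, lam)
  kkt <- kkt_residuals(fit, X, y)
  act <- fit$coefficients != 0
  if (any(!act)) expect_lte(max(abs(kkt[!act])), lam + 1e-4)
  if (any(act)) expect_lt(max(abs(abs(kkt[act]) - lam)), 1e-4)

  g <- glmnet::glmnet(X, y, family = "binomial", lambda = lam,
                      standardize = TRUE, thresh = 1e-12)
  expect_equal(unname(fit$coefficients),
               as.vector(stats::coef(g))[-1], tolerance = 1e-3)
  expect_equal(fit$intercept, as.vector(stats::coef(g))[1], tolerance = 1e-3)
})

test_that("objective matches an independent proximal-gradient oracle", {
  # ISTA: same objective, entirely different optimizer
  ista <- function(Xs, y, lambda, steps = 60000, lr = 0.05) {
    n <- nrow(Xs); p <- ncol(Xs)
    b0 <- 0; b <- rep(0, p)
    for (s in seq_len(steps)) {
      eta <- b0 + Xs %*% b
      pr <- plogis(eta)
      gb0 <- mean(pr - y)
      gb <- as.vector(crossprod(Xs, pr - y)) / n
      b0 <- b0 - lr * gb0
      b <- b - lr * gb
      b <- sign(b) * pmax(abs(b) - lr * lambda, 0)
    }
    list(b0 = b0, b = b)
  }
  set.seed(43)
  X <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(20, 1, plogis(X[, 1] - X[, 2]))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  mu <- colMeans(X); sds <- sqrt(colMeans(X^2) - mu^2)
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  for (lam in c(0.02, 0.08)) {
    fit <- lasso_logistic_fit(X, y, lam)
    ref <- ista(Xs, y, lam)
    obj_ref <- methylforge:::.lasso_objective(Xs, y, ref$b0, ref$b, lam)
    expect_lt(abs(fit$objective - obj_ref), 1e-6)
  }
})

test_that("active-set size is non-increasing along increasing lambda", {
  set.seed(44)
  X <- matrix(rnorm(35 * 8), 35, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rbinom(35, 1, plogis(X[, 1]))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  lmax <- lambda_max(X, y)
  grid <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 25))
  nnz <- vapply(grid, function(l) {
    sum(lasso_logistic_fit(X, y, l)$coefficients != 0)
  }, numeric(1))
  # grid is decreasing, so nnz should be non-decreasing; tolerate rare
  # single-probe swaps near ties
  violations <- sum(diff(nnz) < 0)
  expect_lte(violations, 1)
})

test_that("cross-validated lambda selection behaves on signal and noise", {
  set.seed(45)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rbeta(n * 5, 2, 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[y == 1, 1] <- X[y == 1, 1] + 2   # one informative, fully separating
  sel <- select_lambda(X, y, n_rep = 8, seed = 9)
  expect_equal(min(sel$cv_error), 0)
  fit <- lasso_logistic_fit(X, y, sel$lambda)
  expect_gte(sum(fit$coefficients != 0), 1)

  # pure noise: error near the minority prevalence, null model selected
  set.seed(46)
  Xn <- matrix(rbeta(n * 5, 2, 5), n, 5, dimnames = dimnames(X))
  yn <- rep(c(0, 1), c(26, 14))
  seln <- select_lambda(Xn, yn, n_rep = 8, seed = 10)
  expect_lt(abs(min(seln$cv_error) - 14 / 40), 0.1)
  expect_equal(seln$lambda, max(seln$lambda_grid))

  # halving the grid moves the choice by at most one coarse step
  lmax <- lambda_max(X, y)
  g50 <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 50))
  g25 <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 25))
  l50 <- select_lambda(X, y, n_rep = 6, lambda_grid = g50, seed = 11)$lambda
  l25 <- select_lambda(X, y, n_rep = 6, lambda_grid = g25, seed = 11)$lambda
  step25 <- abs(diff(log(g25)))[1]
  expect_lte(abs(log(l50) - log(l25)), step25 + 1e-9)
})

test_that("scoring is deterministic, strict at 0.5, and guards inputs", {
  model <- structure(list(
    probe_ids = c("p1", "p2"),
    intercept = 0,
    coefficients = setNames(c(0, 0), c("p1", "p2")),
    lambda = 0.1,
    standardization = data.frame(probe_id = c("p1", "p2"), mean = 0, sd = 1),
    threshold = 0.5
  ), class = "panel_model")
  beta <- matrix(c(0.2, 0.8, 0.4, 0.6), 2,
                 dimnames = list(c("p1", "p2"), c("A", "B")))
  sc <- predict_scores(model, beta)
  expect_equal(sc$score, c(0.5, 0.5))
  expect_equal(sc$class, c("normal", "normal"))   # exact 0.5 is normal

  # saturation toward 1 with a large intercept
  model$intercept <- 50
  expect_equal(predict_scores(model, beta)$score, c(1, 1), tolerance = 1e-12)

  # rescoring identical input reproduces scores bit for bit
  model$coefficients <- setNames(c(3, -2), c("p1", "p2"))
  expect_identical(predict_scores(model, beta), predict_scores(model, beta))

  expect_error(predict_scores(model, beta[1, , drop = FALSE]), "p2")
  bad <- beta; bad[1, 1] <- 1.2
  expect_error(predict_scores(model, bad), "out of")
})

test_that("evaluation reproduces confusion arithmetic exactly", {
  # 225 of 234 tumors correct, 88 of 90 non-tumors correct
  scores <- c(rep(0.9, 225), rep(0.1, 9), rep(0.1, 88), rep(0.9, 2))
  truth <- rep(c(1, 0), c(234, 90))
  ev <- evaluate_panel(scores, truth)
  expect_equal(ev$tp, 225); expect_equal(ev$fn, 9)
  expect_equal(ev$tn, 88); expect_equal(ev$fp, 2)
  expect_equal(ev$sensitivity, 225 / 234)
  expect_equal(round(ev$sensitivity, 2), 0.96)
  expect_equal(ev$specificity, 88 / 90)
  expect_equal(round(ev$specificity, 2), 0.98)
  expect_equal(ev$accuracy, (225 + 88) / 324)
  expect_equal(ev$tp + ev$fn + ev$tn + ev$fp, length(truth))

  perfect <- evaluate_panel(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)

  one_class <- evaluate_panel(c(0.9, 0.8), c(1, 1))
  expect_true(is.na(one_class$specificity))
  expect_true(is.na(one_class$auc))
})
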