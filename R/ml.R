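# Internal projection and classifier engines for the biomarker harness.
# Deliberately small, vectorized implementations of the four named
# projections (none / PCA / FastICA / RBF kernel PCA) and four classifiers
# (AdaBoost stumps / k-NN / random forest / linear SVM). All stochastic
# steps consume the caller's RNG stream, so seeding the bootstrap iteration
# seeds the whole fit. Every classifier exposes a probability-like score in
# [0, 1]; margin-based classifiers use a logistic link over the decision
# value so scores can be thresholded at 0.5.

PROJECTIONS <- c("none", "pca", "ica", "kpca")
CLASSIFIERS <- c("adaboost", "knn", "rf", "svm")

fit_projection <- function(type, X, n_components = NULL) {
  n_components <- n_components %||% min(ncol(X), nrow(X) - 1L)
  n_components <- max(1L, min(n_components, ncol(X), nrow(X) - 1L))
  switch(type,
    none = list(type = "none"),
    pca = {
      ctr <- colMeans(X)
      pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      k <- min(n_components, ncol(pr$rotation))
      list(type = "pca", center = ctr, rotation = pr$rotation[, seq_len(k), drop = FALSE])
    },
    ica = fit_fastica(X, n_components),
    kpca = fit_kpca(X, n_components),
    tcsp_error("tcsp_parameter_error", sprintf("unknown projection: %s", type))
  )
}

apply_projection <- function(proj, X) {
  switch(proj$type,
    none = X,
    pca = sweep(X, 2L, proj$center) %*% proj$rotation,
    ica = sweep(X, 2L, proj$center) %*% proj$unmixing,
    kpca = project_kpca(proj, X)
  )
}

# FastICA, symmetric decorrelation, logcosh contrast. Random init from the
# current RNG stream; sign fixed so each component's largest loading is
# positive (determinism).
fit_fastica <- function(X, n_components, max_iter = 200L, tol = 1e-6) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  cv <- stats::cov(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  k <- min(n_components, sum(pos))
  K <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(k)]), k)
  Z <- Xc %*% K
  W <- matrix(stats::rnorm(k * k), k, k)
  sym_decorr <- function(W) {
    sv <- svd(W)
    sv$u %*% t(sv$v)
  }
  W <- sym_decorr(W)
  n <- nrow(Z)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% W
    G <- tanh(WX)
    W1 <- crossprod(Z, G) / n - W %*% diag(colMeans(1 - G^2), k)
    W1 <- sym_decorr(W1)
    if (max(abs(abs(colSums(W1 * W)) - 1)) < tol) {
      W <- W1
      break
    }
    W <- W1
  }
  unmixing <- K %*% W
  flip <- apply(unmixing, 2L, function(v) sign(v[which.max(abs(v))]))
  unmixing <- sweep(unmixing, 2L, ifelse(flip == 0, 1, flip), "*")
  list(type = "ica", center = ctr, unmixing = unmixing)
}

# RBF kernel PCA with gamma = 1/p; train-kernel centering reused at
# projection time.
fit_kpca <- function(X, n_components) {
  gamma <- 1 / ncol(X)
  D2 <- as.matrix(stats::dist(X))^2
  K <- exp(-gamma * D2)
  n <- nrow(K)
  ones <- matrix(1 / n, n, n)
  Kc <- K - ones %*% K - K %*% ones + ones %*% K %*% ones
  eg <- eigen(Kc, symmetric = TRUE)
  keep <- which(eg$values > 1e-8)
  k <- min(n_components, length(keep))
  if (k < 1L) k <- 1L
  idx <- seq_len(k)
  alphas <- eg$vectors[, idx, drop = FALSE] %*%
    diag(1 / sqrt(pmax(eg$values[idx], 1e-12)), k)
  list(type = "kpca", X_train = X, gamma = gamma, K_train = K,
       alphas = alphas, col_means = colMeans(K), total_mean = mean(K))
}

project_kpca <- function(proj, X) {
  Xtr <- proj$X_train
  d2 <- outer(rowSums(X^2), rowSums(Xtr^2), "+") - 2 * X %*% t(Xtr)
  Kt <- exp(-proj$gamma * pmax(d2, 0))
  n <- nrow(Xtr)
  Ktc <- sweep(Kt, 2L, proj$col_means) -
    matrix(rowMeans(Kt), nrow(Kt), n) + proj$total_mean
  Ktc %*% proj$alphas
}

fit_classifier <- function(type, X, y, params = list()) {
  switch(type,
    knn = list(type = "knn", X = X, y = y, k = params$k %||% 5L),
    svm = fit_linear_svm(X, y, C = params$C %||% 1),
    adaboost = fit_adaboost(X, y, n_stumps = params$n_stumps %||% 50L),
    rf = fit_forest(X, y, n_tree = params$n_tree %||% 64L,
                    max_depth = params$max_depth %||% 4L),
    tcsp_error("tcsp_parameter_error", sprintf("unknown classifier: %s", type))
  )
}

predict_score <- function(clf, X) {
  switch(clf$type,
    knn = predict_knn(clf, X),
    svm = stats::plogis(cbind(X, 1) %*% clf$w)[, 1L],
    adaboost = stats::plogis(2 * predict_adaboost_margin(clf, X)),
    rf = predict_forest(clf, X)
  )
}

predict_knn <- function(clf, X) {
  k <- max(1L, min(clf$k, nrow(clf$X)))
  d2 <- outer(rowSums(X^2), rowSums(clf$X^2), "+") - 2 * X %*% t(clf$X)
  apply(d2, 1L, function(d) mean(clf$y[order(d)[seq_len(k)]]))
}

# Hinge-loss linear SVM via dual coordinate descent; bias absorbed as a
# constant augmented feature.
fit_linear_svm <- function(X, y, C = 1, max_iter = 2000L, tol = 1e-8) {
  Xa <- cbind(X, 1)
  yy <- ifelse(y > 0.5, 1, -1)
  fit <- .svm_dcd(Xa, yy, C, tol, as.integer(max_iter))
  list(type = "svm", w = fit$w)
}

# Discrete AdaBoost over depth-1 decision stumps.
fit_adaboost <- function(X, y, n_stumps = 50L) {
  yy <- ifelse(y > 0.5, 1, -1)
  n <- nrow(X)
  wts <- rep(1 / n, n)
  stumps <- list()
  for (t in seq_len(n_stumps)) {
    st <- best_stump(X, yy, wts)
    if (is.null(st)) break
    pred <- stump_predict(st, X)
    err <- sum(wts[pred != yy])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5) break
    st$alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- st
    wts <- wts * exp(-st$alpha * yy * pred)
    wts <- wts / sum(wts)
    if (err <= 1e-9) break
  }
  if (!length(stumps)) {
    # no discriminating stump: fall back to the weighted majority class
    stumps <- list(list(feature = 1L, threshold = -Inf, polarity = 1,
                        alpha = 0.5 * sign(sum(wts * yy) + 1e-12)))
  }
  list(type = "adaboost", stumps = stumps)
}

best_stump <- function(X, yy, wts) {
  total_w <- sum(wts)
  total_wneg <- sum(wts[yy == -1])
  best <- NULL
  best_err <- Inf
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xv <- X[ord, j]
    cum_wpos <- cumsum(wts[ord] * (yy[ord] == 1))
    cum_wneg <- cumsum(wts[ord] * (yy[ord] == -1))
    splits <- which(diff(xv) > 0)
    if (!length(splits)) next
    # polarity +1 predicts +1 right of the threshold:
    # err = w(+1 on left) + w(-1 on right)
    err_gt <- cum_wpos[splits] + (total_wneg - cum_wneg[splits])
    err_lt <- total_w - err_gt
    for (dir in c(1, -1)) {
      errs <- if (dir == 1) err_gt else err_lt
      i <- which.min(errs)
      if (errs[i] < best_err) {
        best_err <- errs[i]
        best <- list(feature = j,
                     threshold = (xv[splits[i]] + xv[splits[i] + 1L]) / 2,
                     polarity = dir)
      }
    }
  }
  best
}

stump_predict <- function(st, X) {
  st$polarity * ifelse(X[, st$feature] > st$threshold, 1, -1)
}

predict_adaboost_margin <- function(clf, X) {
  m <- numeric(nrow(X))
  for (st in clf$stumps) m <- m + st$alpha * stump_predict(st, X)
  m
}

# Random forest: CART trees on bootstrap resamples, Gini splits over a
# random feature subset per node, leaf value = positive-class fraction.
fit_forest <- function(X, y, n_tree = 64L, max_depth = 4L, min_node = 2L) {
  mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  trees <- lapply(seq_len(n_tree), function(t) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_tree(X[idx, , drop = FALSE], y[idx], depth = 0L,
              max_depth = max_depth, min_node = min_node, mtry = mtry)
  })
  list(type = "rf", trees = trees)
}

grow_tree <- function(X, y, depth, max_depth, min_node, mtry) {
  if (depth >= max_depth || nrow(X) < 2L * min_node || length(unique(y)) == 1L) {
    return(list(leaf = TRUE, value = mean(y)))
  }
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- NULL
  best_imp <- Inf
  for (j in feats) {
    ord <- order(X[, j])
    xv <- X[ord, j]
    yv <- y[ord]
    n <- length(yv)
    cum_pos <- cumsum(yv)
    splits <- which(diff(xv) > 0)
    splits <- splits[splits >= min_node & (n - splits) >= min_node]
    if (!length(splits)) next
    nl <- splits
    nr <- n - splits
    pl <- cum_pos[splits] / nl
    pr <- (cum_pos[n] - cum_pos[splits]) / nr
    imp <- nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)
    i <- which.min(imp)
    if (imp[i] < best_imp) {
      best_imp <- imp[i]
      best <- list(feature = j, threshold = (xv[splits[i]] + xv[splits[i] + 1L]) / 2)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, value = mean(y)))
  left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1L,
                        max_depth, min_node, mtry),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1L,
                         max_depth, min_node, mtry))
}

predict_tree <- function(node, newdata) {
  if (node$leaf) return(rep(node$value, nrow(newdata)))
  out <- numeric(nrow(newdata))
  left <- newdata[, node$feature] <= node$threshold
  if (any(left)) out[left] <- predict_tree(node$left, newdata[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(node$right, newdata[!left, , drop = FALSE])
  out
}

predict_forest <- function(clf, X) {
  rowMeans(vapply(clf$trees, predict_tree, numeric(nrow(X)), newdata = X))
}
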