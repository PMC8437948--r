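#' Classifier specification
#'
#' Six classifier families for severity classification: error-correcting
#' output codes over binary SVMs (`ecoc_svm`), Gaussian naive Bayes
#' (`nb`), k-nearest neighbours (`knn`), random forest with 100 bagged
#' trees (`rf`), multiclass AdaBoost of depth-1 trees (`adaboost`), and a
#' four-layer fully connected network trained with Adam on cross-entropy
#' (`dnn`: hidden sizes 256-128-64, batch 32, learning rate 0.001, 200
#' epochs).
#'
#' @param kind one of `"ecoc_svm"`, `"nb"`, `"knn"`, `"rf"`,
#'   `"adaboost"`, `"dnn"`.
#' @param ... hyperparameter overrides: `svm_kernel`, `svm_cost`, `knn_k`,
#'   `rf_n_trees`, `ab_n_estimators`, `dnn_hidden`, `dnn_batch`, `dnn_lr`,
#'   `dnn_epochs`.
#' @param seed RNG seed; training and prediction are deterministic given
#'   it.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("rf", "knn", "nb", "ecoc_svm",
                                     "adaboost", "dnn"),
                            ..., seed = 1L) {
  kind <- match.arg(kind)
  hp <- list(svm_kernel = "radial", svm_cost = 1, knn_k = 5L,
             rf_n_trees = 100L, ab_n_estimators = 100L,
             dnn_hidden = c(256L, 128L, 64L), dnn_batch = 32L,
             dnn_lr = 0.001, dnn_epochs = 200L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(hp))
  if (length(unknown)) stop("unknown hyperparameters: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  hp[names(dots)] <- dots
  counts <- c(hp$knn_k, hp$rf_n_trees, hp$ab_n_estimators, hp$dnn_batch,
              hp$dnn_epochs, hp$dnn_hidden)
  if (any(counts < 1)) stop("counts must be positive", call. = FALSE)
  structure(c(list(kind = kind, seed = as.integer(seed)), hp),
            class = "classifier_spec")
}

check_training_labels <- function(y) {
  if (!is.factor(y)) y <- factor(y)
  if (any(table(y) == 0))
    stop("class missing from training data: ",
         paste(levels(y)[table(y) == 0], collapse = ", "), call. = FALSE)
  y
}

#' Train a severity classifier
#'
#' @param spec a [classifier_spec()].
#' @param X numeric feature matrix (samples x features), already
#'   standardised (see [cross_validate()], which z-scores from the
#'   training fold only).
#' @param y class labels; every level must be present.
#' @return object of class `severity_model`.
#' @export
train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  y <- check_training_labels(y)
  fit <- withr::with_seed(spec$seed, switch(spec$kind,
    nb = e1071::naiveBayes(X, y),
    rf = randomForest::randomForest(X, y, ntree = spec$rf_n_trees),
    knn = list(X = X, y = y),
    ecoc_svm = fit_ecoc_svm(X, y, spec),
    adaboost = fit_adaboost(X, y, spec$ab_n_estimators),
    dnn = fit_mlp(X, y, hidden = spec$dnn_hidden, epochs = spec$dnn_epochs,
                  batch = spec$dnn_batch, lr = spec$dnn_lr)
  ))
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 levels = levels(y), p = ncol(X)),
            class = "severity_model")
}

#' Predict severity labels
#' @param object a `severity_model`.
#' @param newdata numeric matrix with the same columns as at training.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.severity_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  lv <- object$levels
  out <- withr::with_seed(object$spec$seed + 1L, switch(object$kind,
    nb = as.character(predict(object$fit, X)),
    rf = as.character(predict(object$fit, X)),
    knn = as.character(class::knn(object$fit$X, X, object$fit$y,
                                  k = min(object$spec$knn_k,
                                          nrow(object$fit$X)))),
    ecoc_svm = predict_ecoc_svm(object$fit, X),
    adaboost = predict_adaboost(object$fit, X),
    dnn = predict_mlp(object$fit, X)
  ))
  factor(out, levels = lv)
}

# --- ECOC-SVM: one-vs-one coding matrix, min-loss (Hamming) decoding ----

fit_ecoc_svm <- function(X, y, spec) {
  lv <- levels(y)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    idx <- y %in% pr
    yy <- factor(as.character(y[idx]), levels = pr)
    e1071::svm(X[idx, , drop = FALSE], yy, kernel = spec$svm_kernel,
               cost = spec$svm_cost, scale = FALSE)
  })
  # coding matrix: rows classes, cols pairs; +1 first class, -1 second
  M <- matrix(0, length(lv), length(pairs), dimnames = list(lv, NULL))
  for (j in seq_along(pairs)) {
    M[pairs[[j]][1], j] <- 1
    M[pairs[[j]][2], j] <- -1
  }
  list(fits = fits, pairs = pairs, M = M, levels = lv)
}

predict_ecoc_svm <- function(fit, X) {
  b <- vapply(seq_along(fit$fits), function(j) {
    pr <- as.character(predict(fit$fits[[j]], X))
    ifelse(pr == fit$pairs[[j]][1], 1, -1)
  }, numeric(nrow(X)))
  b <- matrix(b, nrow = nrow(X))
  loss <- b %*% t(fit$M)  # agreement score per class (0 entries ignored)
  fit$levels[max.col(loss, ties.method = "first")]
}

# --- AdaBoost (SAMME) over depth-1 rpart trees ---------------------------

fit_adaboost <- function(X, y, n_estimators) {
  K <- nlevels(y)
  n <- nrow(X)
  df <- data.frame(.y = y, X, check.names = FALSE)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0)
  for (t in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(fit, X) {
  df <- as.data.frame(X)
  votes <- matrix(0, nrow(X), length(fit$levels),
                  dimnames = list(NULL, fit$levels))
  for (t in seq_along(fit$stumps)) {
    pred <- as.character(predict(fit$stumps[[t]], df, type = "class"))
    votes[cbind(seq_len(nrow(X)), match(pred, fit$levels))] <-
      votes[cbind(seq_len(nrow(X)), match(pred, fit$levels))] + fit$alphas[t]
  }
  fit$levels[max.col(votes, ties.method = "first")]
}

# --- Four-layer fully connected network (Adam, cross-entropy) ------------

relu <- function(x) pmax(x, 0)

fit_mlp <- function(X, y, hidden = c(256, 128, 64), epochs = 200, batch = 32,
                    lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  K <- nlevels(y)
  sizes <- c(ncol(X), hidden, K)
  nl <- length(sizes) - 1L
  W <- list(); b <- list()
  for (l in seq_len(nl)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  n <- nrow(X)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1, n)]
      xb <- X[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
      # forward
      acts <- list(xb)
      for (l in seq_len(nl)) {
        z <- acts[[l]] %*% W[[l]] + rep(b[[l]], each = nrow(xb))
        acts[[l + 1]] <- if (l < nl) relu(z) else z
      }
      z <- acts[[nl + 1]]
      z <- z - apply(z, 1, max)
      pr <- exp(z) / rowSums(exp(z))
      delta <- (pr - yb) / nrow(xb)
      step <- step + 1L
      for (l in rev(seq_len(nl))) {
        gW <- t(acts[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  list(W = W, b = b, levels = levels(y))
}

predict_mlp <- function(fit, X) {
  a <- as.matrix(X)
  nl <- length(fit$W)
  for (l in seq_len(nl)) {
    z <- a %*% fit$W[[l]] + rep(fit$b[[l]], each = nrow(a))
    a <- if (l < nl) relu(z) else z
  }
  fit$levels[max.col(a, ties.method = "first")]
}
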