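#' Seven classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity, precision, F1, Matthews
#' correlation coefficient (generalised multiclass form) and Cohen's
#' kappa.  Rows of the matrix are reference classes, columns predicted
#' classes.  For a 2x2 matrix the first class is treated as positive and
#' sensitivity/specificity/precision/F1 follow the classic binary
#' definitions; for more classes they are macro-averaged one-vs-rest.
#'
#' @param cm square numeric confusion matrix (rows = truth).
#' @param average `"auto"` (binary for 2x2, macro otherwise), `"macro"`,
#'   or `"binary"`.
#' @return named numeric vector: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `mcc`, `kappa`.
#' @export
compute_metrics <- function(cm, average = c("auto", "macro", "binary")) {
  average <- match.arg(average)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2)
    stop("confusion matrix must be square with >= 2 classes", call. = FALSE)
  if (any(cm < 0) || sum(cm) == 0)
    stop("confusion matrix must be non-negative and non-empty", call. = FALSE)
  n <- sum(cm)
  K <- nrow(cm)
  acc <- sum(diag(cm)) / n
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  sens_k <- safe_div(tp, tp + fn)
  spec_k <- safe_div(tn, tn + fp)
  prec_k <- safe_div(tp, tp + fp)
  f1_k <- safe_div(2 * prec_k * sens_k, prec_k + sens_k)
  f1_k[is.na(f1_k) & !is.na(sens_k)] <- 0  # prec+sens = 0
  if (average == "auto") average <- if (K == 2) "binary" else "macro"
  if (average == "binary") {
    if (K != 2) stop("binary averaging needs a 2x2 matrix", call. = FALSE)
    sens <- sens_k[1]; spec <- spec_k[1]; prec <- prec_k[1]; f1 <- f1_k[1]
  } else {
    sens <- mean(sens_k, na.rm = TRUE); spec <- mean(spec_k, na.rm = TRUE)
    prec <- mean(prec_k, na.rm = TRUE); f1 <- mean(f1_k, na.rm = TRUE)
  }
  t_k <- rowSums(cm); p_k <- colSums(cm)
  num <- n * sum(diag(cm)) - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  mcc <- if (den > 0) num / den else 0
  pe <- sum(t_k * p_k) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  c(accuracy = acc, sensitivity = unname(sens), specificity = unname(spec),
    precision = unname(prec), f1 = unname(f1), mcc = mcc, kappa = kappa)
}

#' Cross-validation configuration
#'
#' @param k_folds number of folds (default 5).
#' @param repeats number of repetitions of the whole k-fold scheme
#'   (default 10).
#' @param stratified stratify folds by class (default TRUE).
#' @param seed RNG seed for fold assignment.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k_folds = 5, repeats = 10, stratified = TRUE, seed = 1L) {
  stopifnot(k_folds >= 2, repeats >= 1)
  structure(list(k_folds = as.integer(k_folds), repeats = as.integer(repeats),
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_config")
}

stratified_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      if (length(idx) < k)
        stop("stratification infeasible: class '", lv, "' has ",
             length(idx), " < ", k, " members", call. = FALSE)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Features are z-scored inside each training fold (constant columns get
#' unit scale) and the same transform is applied to the test fold; an
#' optional feature-selection hook runs either inside each training fold
#' (no leakage) or once on the whole data.
#'
#' @param spec a [classifier_spec()].
#' @param X numeric feature matrix with column names.
#' @param y class labels (factor); every class needs at least `k_folds`
#'   members.
#' @param cv a [cv_config()].
#' @param select_fun optional `function(X, y)` returning the feature
#'   names to keep.
#' @param selection_scope `"fold"` (default; selection re-run inside each
#'   training fold) or `"whole"` (once on all data).
#' @return object of class `eval_report`: list with `per_fold` (tibble of
#'   the seven metrics per repeat/fold), `confusions` (list of confusion
#'   matrices), `aggregate` (tibble metric/mean/sd), `spec`, `cv`.
#' @export
cross_validate <- function(spec, X, y, cv = cv_config(), select_fun = NULL,
                           selection_scope = c("fold", "whole")) {
  selection_scope <- match.arg(selection_scope)
  X <- as.matrix(X)
  y <- check_training_labels(y)
  lv <- levels(y)
  whole_sel <- NULL
  if (!is.null(select_fun) && selection_scope == "whole")
    whole_sel <- select_fun(X, y)
  rows <- list(); cms <- list()
  withr::with_seed(cv$seed, {
    for (r in seq_len(cv$repeats)) {
      fold <- stratified_folds(y, cv$k_folds, cv$stratified)
      for (f in seq_len(cv$k_folds)) {
        tr <- fold != f; te <- !tr
        mu <- colMeans(X[tr, , drop = FALSE])
        sg <- apply(X[tr, , drop = FALSE], 2, sd)
        sg[sg == 0 | is.na(sg)] <- 1
        Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
        Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
        keep <- colnames(X)
        if (!is.null(whole_sel)) keep <- whole_sel
        else if (!is.null(select_fun)) keep <- select_fun(Xtr, y[tr])
        Xtr <- Xtr[, keep, drop = FALSE]; Xte <- Xte[, keep, drop = FALSE]
        model <- train_classifier(spec, Xtr, y[tr])
        pred <- predict(model, Xte)
        cm <- table(factor(y[te], levels = lv), factor(pred, levels = lv))
        cm <- matrix(as.numeric(cm), length(lv), length(lv),
                     dimnames = list(lv, lv))
        cms[[length(cms) + 1L]] <- cm
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rep = r, fold = f,
          !!!as.list(compute_metrics(cm, average = "macro")))
      }
    }
  })
  per_fold <- dplyr::bind_rows(rows)
  agg <- tidyr::pivot_longer(per_fold, -c("rep", "fold"),
                             names_to = "metric", values_to = "value")
  agg <- dplyr::summarise(dplyr::group_by(agg, .data$metric),
                          mean = mean(.data$value), sd = sd(.data$value),
                          .groups = "drop")
  structure(list(per_fold = per_fold, confusions = cms, aggregate = agg,
                 spec = spec, cv = cv),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d-fold x %d repeats\n", x$spec$kind,
              x$cv$k_folds, x$cv$repeats))
  print(as.data.frame(x$aggregate), row.names = FALSE)
  invisible(x)
}

combo_columns <- function(fm_names, combo) {
  pref <- c(texture = "tex.", color = "col.", spectrum = "spec.")
  parts <- if (combo == "full") names(pref) else strsplit(combo, "+", fixed = TRUE)[[1]]
  unlist(lapply(pref[parts], function(p) fm_names[startsWith(fm_names, p)]),
         use.names = FALSE)
}

#' Feature-combination grid experiment
#'
#' Evaluates classifiers over a grid of dataset variants and the seven
#' feature combinations (texture, color, spectrum, their pairs, full),
#' reporting one headline metric per cell (default F1, macro-averaged
#' and mean over folds/repeats).  Cells that fail evaluate to `NaN` with
#' a warning.
#'
#' @param feature_matrices named list of feature-matrix tibbles from
#'   [extract_matrix()], one per dataset variant (e.g. `A`, `B`,
#'   `A+patches`).
#' @param classifiers character vector of classifier kinds.
#' @param combos character vector of feature combinations; default all
#'   seven.
#' @param cv a [cv_config()].
#' @param metric headline metric name (default `"f1"`).
#' @param seed seed passed to each classifier spec.
#' @return tibble with columns `dataset`, `classifier`, `combo`, `value`.
#' @export
run_experiment <- function(feature_matrices,
                           classifiers = c("rf", "knn"),
                           combos = c("texture", "color", "spectrum",
                                      "texture+color", "texture+spectrum",
                                      "color+spectrum", "full"),
                           cv = cv_config(), metric = "f1", seed = 1L) {
  rows <- list()
  for (ds in names(feature_matrices)) {
    xy <- feature_xy(feature_matrices[[ds]])
    for (combo in combos) {
      cols <- combo_columns(colnames(xy$X), combo)
      for (clf in classifiers) {
        val <- tryCatch({
          rep_ <- cross_validate(classifier_spec(clf, seed = seed),
                                 xy$X[, cols, drop = FALSE], xy$y, cv)
          rep_$aggregate$mean[rep_$aggregate$metric == metric]
        }, error = function(e) {
          warning(sprintf("cell %s/%s/%s failed: %s", ds, clf, combo,
                          conditionMessage(e)), call. = FALSE)
          NaN
        })
        rows[[length(rows) + 1L]] <- tibble::tibble(
          dataset = ds, classifier = clf, combo = combo, value = val)
      }
    }
  }
  dplyr::bind_rows(rows)
}
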