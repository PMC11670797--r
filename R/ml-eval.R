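#' Principal-component scores of a data matrix
#'
#' Projects the column-centered matrix onto its leading principal
#' components, ordered by non-increasing explained variance. Centering only
#' (no variance scaling) is the default convention throughout the package;
#' scale beforehand if desired.
#'
#' @param X numeric matrix (`P` rows of observations).
#' @param n_components number of components, in `1..min(P, ncol(X))`.
#' @param scale. logical; standardize columns to unit variance first
#'   (zero-variance columns are left unscaled rather than producing NaN).
#' @return `P x n_components` score matrix with attributes `rotation`
#'   (loadings), `center`, `scale` (the divisors used, or `NULL`) and
#'   `sdev` (all singular-value-derived standard deviations).
#' @export
pca_scores <- function(X, n_components, scale. = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  m <- min(nrow(X), ncol(X))
  if (n_components < 1L || n_components > m)
    stop("n_components must lie in 1..min(P, F) = ", m, call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sdv <- NULL
  if (isTRUE(scale.)) {
    sdv <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
    sdv[sdv == 0] <- 1
    Xc <- sweep(Xc, 2L, sdv, `/`)
  }
  sv <- svd(Xc, nu = n_components, nv = n_components)
  scores <- sweep(sv$u, 2L, sv$d[seq_len(n_components)], `*`)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  attr(scores, "rotation") <- sv$v
  attr(scores, "center") <- ctr
  attr(scores, "scale") <- sdv
  attr(scores, "sdev") <- sv$d / sqrt(max(1L, nrow(X) - 1L))
  scores
}

# ---- internal classifier plumbing -----------------------------------------

algo_names <- c("KNN", "NB", "DT", "LDA", "SVM", "RF")

default_opts <- function(opts = list()) {
  utils::modifyList(list(knn_k = 5L, svm_kernel = "linear", svm_cost = 1,
                         rf_ntree = 100L),
                    opts)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic per-cell seed below 2^31
cell_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  s <- 0
  for (v in ix) s <- (s * 131 + as.numeric(v)) %% 2147483629
  as.integer(s) + 1L
}

# train one classifier and predict labels for the test block
train_predict <- function(algorithm, train_x, train_y, test_x, opts) {
  lev <- levels(train_y)
  as_df <- function(m) {
    df <- as.data.frame(m)
    names(df) <- paste0("V", seq_len(ncol(df)))
    df
  }
  pred <- switch(algorithm,
    KNN = class::knn(train_x, test_x, cl = train_y,
                     k = min(opts$knn_k, nrow(train_x))),
    NB = {
      fit <- e1071::naiveBayes(as_df(train_x), train_y)
      stats::predict(fit, as_df(test_x), type = "class")
    },
    DT = {
      df <- as_df(train_x); df$.y <- train_y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      stats::predict(fit, as_df(test_x), type = "class")
    },
    LDA = {
      fit <- suppressWarnings(MASS::lda(train_x, grouping = train_y))
      stats::predict(fit, test_x)$class
    },
    SVM = {
      fit <- e1071::svm(train_x, train_y, kernel = opts$svm_kernel,
                        cost = opts$svm_cost, scale = FALSE)
      stats::predict(fit, test_x)
    },
    RF = {
      fit <- randomForest::randomForest(train_x, train_y, ntree = opts$rf_ntree)
      stats::predict(fit, test_x)
    },
    stop("unknown algorithm '", algorithm, "'; available: ",
         paste(algo_names, collapse = ", "), call. = FALSE)
  )
  factor(as.character(pred), levels = lev)
}

# stratified fold assignment: every class spread across all folds
make_folds <- function(labels, k, seed) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  fold <- integer(length(labels))
  with_seed(cell_seed(seed, 1L), {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      if (length(idx) < k)
        stop("class '", cl, "' has fewer members (", length(idx),
             ") than folds (", k, "); stratification impossible", call. = FALSE)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# per-fold train/test score blocks, optionally via fold-local PCA
fold_blocks <- function(features, fold, n_components, pca_per_fold,
                        pca_scale = FALSE) {
  k <- max(fold)
  if (is.null(n_components)) {
    lapply(seq_len(k), function(f)
      list(train = features[fold != f, , drop = FALSE],
           test = features[fold == f, , drop = FALSE]))
  } else if (!pca_per_fold) {
    sc <- pca_scores(features, n_components, scale. = pca_scale)
    lapply(seq_len(k), function(f)
      list(train = sc[fold != f, , drop = FALSE],
           test = sc[fold == f, , drop = FALSE]))
  } else {
    lapply(seq_len(k), function(f) {
      tr <- features[fold != f, , drop = FALSE]
      te <- features[fold == f, , drop = FALSE]
      sc <- pca_scores(tr, n_components, scale. = pca_scale)
      proj <- sweep(te, 2L, attr(sc, "center"))
      if (!is.null(attr(sc, "scale")))
        proj <- sweep(proj, 2L, attr(sc, "scale"), `/`)
      list(train = matrix(sc, nrow(sc), ncol(sc)),
           test = proj %*% attr(sc, "rotation"))
    })
  }
}

# ---- cross-validated evaluation -------------------------------------------

#' Stratified k-fold cross-validation of one classifier
#'
#' Splits the signals into `k` stratified folds; each fold serves once as
#' the test set, so every signal is predicted exactly once. When
#' `n_components` is given, PCA is fit on each training fold and the test
#' fold is projected onto it (no leakage); `pca_per_fold = FALSE` restores
#' the simpler fit-once-on-all-data variant for comparability.
#'
#' @param features numeric matrix `P x F`.
#' @param labels binary labels, length `P`.
#' @param algorithm one of `"KNN"`, `"NB"`, `"DT"`, `"LDA"`, `"SVM"`, `"RF"`.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling fold assignment and any classifier
#'   randomness.
#' @param n_components optional number of principal components to classify
#'   on; `NULL` uses the raw features.
#' @param pca_per_fold fit PCA inside each training fold (default) or once
#'   on all data.
#' @param pca_scale standardize feature columns to unit variance before
#'   PCA (see [pca_scores()]).
#' @param opts list of classifier options (`knn_k`, `svm_kernel`,
#'   `svm_cost`, `rf_ntree`).
#' @return List with `confusion` (pooled over folds), `fold_accuracy`
#'   (length `k`), `mean_accuracy`, and `predictions` in input order.
#' @export
kfold_cv <- function(features, labels, algorithm = "KNN", k = 5L, seed = 1L,
                     n_components = NULL, pca_per_fold = TRUE,
                     pca_scale = FALSE, opts = list()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  algorithm <- match.arg(algorithm, algo_names)
  opts <- default_opts(opts)
  fold <- make_folds(labels, k, seed)
  blocks <- fold_blocks(features, fold, n_components, pca_per_fold, pca_scale)
  lev <- sort(unique(labels))
  y <- factor(labels, levels = lev)
  preds <- factor(rep(NA_character_, length(labels)), levels = lev)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    p <- with_seed(cell_seed(seed, f, match(algorithm, algo_names)),
                   train_predict(algorithm, blocks[[f]]$train, y[!te],
                                 blocks[[f]]$test, opts))
    preds[te] <- p
    fold_acc[f] <- mean(p == y[te])
  }
  list(confusion = confusion(labels, as.character(preds), positive = lev[1L]),
       fold_accuracy = fold_acc,
       mean_accuracy = mean(fold_acc),
       predictions = as.character(preds))
}

#' Cross-validated metric reports for a set of classifiers
#'
#' Runs [kfold_cv()] for each requested algorithm and derives the
#' six-metric report from the pooled confusion counts; the per-fold mean
#' accuracy is attached alongside.
#'
#' @inheritParams kfold_cv
#' @param algorithms subset of `c("KNN", "NB", "DT", "LDA", "SVM", "RF")`.
#' @return Named list of [compute_metrics()] reports, each carrying
#'   attributes `mean_accuracy` and `fold_accuracy`.
#' @export
run_algorithms <- function(features, labels, algorithms = algo_names, k = 5L,
                           seed = 1L, n_components = NULL, pca_per_fold = TRUE,
                           pca_scale = FALSE, opts = list()) {
  bad <- setdiff(algorithms, algo_names)
  if (length(bad))
    stop("unknown algorithm(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(algo_names, collapse = ", "), call. = FALSE)
  features <- as.matrix(features)
  labels <- as.character(labels)
  opts <- default_opts(opts)
  # the fold split and (possibly expensive) fold-wise PCA are shared across
  # algorithms; predictions then match kfold_cv() exactly
  fold <- make_folds(labels, k, seed)
  blocks <- fold_blocks(features, fold, n_components, pca_per_fold, pca_scale)
  lev <- sort(unique(labels))
  y <- factor(labels, levels = lev)
  out <- lapply(algorithms, function(a) {
    preds <- factor(rep(NA_character_, length(labels)), levels = lev)
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      te <- fold == f
      p <- with_seed(cell_seed(seed, f, match(a, algo_names)),
                     train_predict(a, blocks[[f]]$train, y[!te],
                                   blocks[[f]]$test, opts))
      preds[te] <- p
      fold_acc[f] <- mean(p == y[te])
    }
    rep <- suppressWarnings(
      compute_metrics(confusion(labels, as.character(preds), positive = lev[1L])))
    attr(rep, "mean_accuracy") <- mean(fold_acc)
    attr(rep, "fold_accuracy") <- fold_acc
    rep
  })
  names(out) <- algorithms
  out
}

#' Accuracy sweep over the number of principal components
#'
#' For each component count `1..pc_max`, classifies on that many PCA scores
#' with every requested algorithm under stratified k-fold CV, reporting the
#' mean per-fold accuracy. Per-fold PCA is computed once at `pc_max` and
#' reused: the leading components of a fold's PCA do not change when fewer
#' are requested.
#'
#' @inheritParams run_algorithms
#' @param pc_max largest component count (default 36).
#' @return A data frame of class `sweep_table` with column `PC` and one
#'   accuracy column per algorithm, in the fixed order KNN, NB, DT, LDA,
#'   SVM, RF (restricted to those requested).
#' @export
sweep_pcs <- function(features, labels, algorithms = algo_names, pc_max = 36L,
                      k = 5L, seed = 1L, pca_per_fold = TRUE,
                      pca_scale = FALSE, opts = list()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  algorithms <- algo_names[algo_names %in% algorithms]
  if (length(algorithms) == 0L) stop("no known algorithm requested", call. = FALSE)
  if (pc_max > min(nrow(features), ncol(features)))
    stop("pc_max exceeds min(P, F)", call. = FALSE)
  opts <- default_opts(opts)
  fold <- make_folds(labels, k, seed)
  blocks <- fold_blocks(features, fold, pc_max, pca_per_fold, pca_scale)
  lev <- sort(unique(labels))
  y <- factor(labels, levels = lev)
  acc <- matrix(NA_real_, pc_max, length(algorithms),
                dimnames = list(NULL, algorithms))
  for (n in seq_len(pc_max)) {
    for (a in seq_along(algorithms)) {
      fa <- numeric(k)
      for (f in seq_len(k)) {
        te <- fold == f
        p <- with_seed(cell_seed(seed, f, match(algorithms[a], algo_names), n),
                       train_predict(algorithms[a],
                                     blocks[[f]]$train[, seq_len(n), drop = FALSE],
                                     y[!te],
                                     blocks[[f]]$test[, seq_len(n), drop = FALSE],
                                     opts))
        fa[f] <- mean(p == y[te])
      }
      acc[n, a] <- mean(fa)
    }
  }
  out <- data.frame(PC = seq_len(pc_max), acc, check.names = FALSE)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' KNN accuracy grid over neighbor count and component count
#'
#' Cross-validated KNN accuracy for every combination of the neighbor
#' parameter and the number of principal components, sharing the per-fold
#' PCA across cells.
#'
#' @inheritParams sweep_pcs
#' @param k_neighbors_range vector of neighbor counts.
#' @param pc_range vector of principal-component counts.
#' @param folds number of CV folds.
#' @return Matrix of class `knn_grid`, rows `k=<neighbors>`, columns
#'   `PC=<components>`.
#' @export
knn_grid <- function(features, labels, k_neighbors_range = 1:10,
                     pc_range = 1:36, folds = 5L, seed = 1L,
                     pca_per_fold = TRUE, pca_scale = FALSE) {
  stopifnot(length(k_neighbors_range) > 0L, length(pc_range) > 0L)
  features <- as.matrix(features)
  labels <- as.character(labels)
  fold <- make_folds(labels, folds, seed)
  blocks <- fold_blocks(features, fold, max(pc_range), pca_per_fold, pca_scale)
  lev <- sort(unique(labels))
  y <- factor(labels, levels = lev)
  grid <- matrix(NA_real_, length(k_neighbors_range), length(pc_range),
                 dimnames = list(paste0("k=", k_neighbors_range),
                                 paste0("PC=", pc_range)))
  for (ki in seq_along(k_neighbors_range)) {
    for (ni in seq_along(pc_range)) {
      n <- pc_range[ni]
      fa <- numeric(folds)
      for (f in seq_len(folds)) {
        te <- fold == f
        p <- with_seed(cell_seed(seed, f, k_neighbors_range[ki], n),
                       train_predict("KNN",
                                     blocks[[f]]$train[, seq_len(n), drop = FALSE],
                                     y[!te],
                                     blocks[[f]]$test[, seq_len(n), drop = FALSE],
                                     default_opts(list(knn_k = k_neighbors_range[ki]))))
        fa[f] <- mean(p == y[te])
      }
      grid[ki, ni] <- mean(fa)
    }
  }
  class(grid) <- c("knn_grid", "matrix", "array")
  grid
}
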