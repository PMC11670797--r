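# small separable two-cloud fixture
two_clouds <- function(P = 60, F = 8, gap = 10, seed = 5) {
  set.seed(seed)
  X <- matrix(rnorm(P * F), P, F)
  lab <- rep(c("a", "b"), each = P / 2)
  X[lab == "b", 1] <- X[lab == "b", 1] + gap
  list(X = X, lab = lab)
}

test_that("pca_scores have orthogonal columns and non-increasing variance", {
  set.seed(8)
  X <- matrix(rnorm(40 * 10), 40, 10) %*% diag(c(5, 3, rep(1, 8)))
  sc <- pca_scores(X, 5)
  G <- crossprod(sc)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  v <- apply(sc, 2, var)
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(diff(attr(sc, "sdev")) <= 1e-12))
})

test_that("a single varying column yields its own variance as the score variance", {
  X <- cbind(c(1, 2, 3, 4, 5), rep(2, 5), rep(-1, 5))
  sc <- pca_scores(X, 1)
  expect_equal(var(sc[, 1]), var(X[, 1]))
})

test_that("pca_scores validates the requested component count", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(pca_scores(X, 0), "n_components")
  expect_error(pca_scores(X, 5), "n_components")
})

test_that("kfold_cv predicts each signal exactly once and nails separable clouds", {
  d <- two_clouds()
  cv <- kfold_cv(d$X, d$lab, algorithm = "KNN", k = 5, seed = 3,
                 opts = list(knn_k = 1))
  expect_equal(cv$mean_accuracy, 1)
  expect_length(cv$predictions, nrow(d$X))
  expect_false(anyNA(cv$predictions))
  cc <- cv$confusion
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, nrow(d$X))
})

test_that("permuted labels sit at chance across seeds", {
  d <- two_clouds(P = 100, gap = 10)
  set.seed(1234)
  accs <- vapply(1:20, function(s) {
    perm <- sample(d$lab)
    kfold_cv(d$X, perm, algorithm = "KNN", k = 5, seed = s)$mean_accuracy
  }, numeric(1))
  # mean over 20 runs of 100 predictions within 3 binomial SEs of 0.5
  se <- sqrt(0.25 / (100 * 20))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 1e-12)
})

test_that("stratification failure is reported", {
  d <- two_clouds(P = 8)
  expect_error(kfold_cv(d$X, d$lab, k = 5, seed = 1), "stratification")
})

test_that("run_algorithms scores all six classifiers on separable data", {
  d <- two_clouds()
  reps <- run_algorithms(d$X, d$lab, k = 5, seed = 2)
  expect_named(reps, c("KNN", "NB", "DT", "LDA", "SVM", "RF"))
  for (a in names(reps)) expect_gte(reps[[a]]$acc, 0.95)
  # determinism: identical rerun
  reps2 <- run_algorithms(d$X, d$lab, k = 5, seed = 2)
  expect_identical(lapply(reps, unclass), lapply(reps2, unclass))
  # single algorithm request
  one <- run_algorithms(d$X, d$lab, algorithms = "NB", k = 5, seed = 2)
  expect_length(one, 1)
  expect_error(run_algorithms(d$X, d$lab, algorithms = "QDA"), "unknown algorithm")
})

test_that("sweep_pcs mirrors the table layout and saturates on separable data", {
  d <- two_clouds()
  tab <- sweep_pcs(d$X, d$lab, pc_max = 4, k = 5, seed = 6)
  expect_s3_class(tab, "sweep_table")
  expect_equal(names(tab), c("PC", "KNN", "NB", "DT", "LDA", "SVM", "RF"))
  expect_equal(tab$PC, 1:4)
  expect_true(all(tab$DT >= 0.95))
  expect_true(all(tab$RF >= 0.95))
  expect_true(all(as.matrix(tab[, -1]) >= 0) && all(as.matrix(tab[, -1]) <= 1))

  one_row <- sweep_pcs(d$X, d$lab, algorithms = "KNN", pc_max = 1, k = 5, seed = 6)
  expect_equal(nrow(one_row), 1)
})

test_that("knn_grid covers the requested surface deterministically", {
  d <- two_clouds()
  g1 <- knn_grid(d$X, d$lab, k_neighbors_range = c(1, 3), pc_range = 1:3,
                 folds = 5, seed = 9)
  expect_equal(dim(g1), c(2, 3))
  expect_gte(g1["k=1", "PC=1"], 0.95)
  g2 <- knn_grid(d$X, d$lab, k_neighbors_range = c(1, 3), pc_range = 1:3,
                 folds = 5, seed = 9)
  expect_identical(unclass(g1), unclass(g2))
})

test_that("per-fold PCA and fit-once PCA both classify separable clouds", {
  d <- two_clouds()
  for (per_fold in c(TRUE, FALSE)) {
    cv <- kfold_cv(d$X, d$lab, algorithm = "SVM", k = 5, seed = 4,
                   n_components = 2, pca_per_fold = per_fold)
    expect_gte(cv$mean_accuracy, 0.95)
  }
})
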