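test_that("PCA conserves variance and reconstructs the centered data", {
  set.seed(3)
  m <- matrix(rbinom(25 * 12, 1, 0.5), 25, 12)
  rownames(m) <- sprintf("s%02d", 1:25)
  pca <- pca_fit(m)
  # total eigenvalue mass equals total column variance
  expect_equal(sum(pca$eig), sum(apply(m, 2, var)))
  # full reconstruction
  centered <- scale(m, scale = FALSE)
  rec <- pca$scores %*% t(pca$rotation)
  expect_lt(max(abs(rec - centered)), 1e-8)
  expect_true(all(diff(pca$cum_var) >= -1e-12))
  expect_true(all(diff(pca$eig) <= 1e-8))
  # orthogonal centered columns keep their variances as eigenvalues
  o <- cbind(c(3, -3, 0, 0), c(0, 0, 1, -1))
  rownames(o) <- sprintf("o%d", 1:4)
  p2 <- pca_fit(o)
  expect_equal(sort(p2$eig, decreasing = TRUE)[1:2],
               sort(apply(o, 2, var), decreasing = TRUE))
  expect_error(pca_fit(matrix(1, 5, 3)), "zero-variance")
})

test_that("BIC cluster detection finds blobs and respects k-means monotonicity", {
  centers3 <- diag(10, 3, 2)
  m3 <- blob_matrix(30, centers3, d = 100, sigma = 0.1, seed = 42)
  cl3 <- find_clusters(pca_fit(m3), 1:8, n_pcs = 80, seed = 1)
  expect_equal(cl3$best_k, 3L)
  expect_true(all(diff(cl3$bic$W) <= 1e-6))  # W nonincreasing in K
  expect_equal(length(unique(cl3$labels)), 3L)

  m1 <- blob_matrix(90, matrix(0, 1, 2), d = 100, sigma = 0.1, seed = 43)
  cl1 <- find_clusters(pca_fit(m1), 1:8, n_pcs = 80, seed = 1)
  expect_equal(cl1$best_k, 1L)

  # deterministic under a fixed seed
  cl3b <- find_clusters(pca_fit(m3), 1:8, n_pcs = 80, seed = 1)
  expect_identical(cl3$bic, cl3b$bic)
})

test_that("discriminant axes obey the rank bound and separate disjoint clouds", {
  m <- blob_matrix(20, diag(10, 2, 2), d = 30, sigma = 0.5, seed = 9)
  labs <- rep(c("a", "b"), each = 20)
  pca <- pca_fit(m)
  fit <- dapc_fit(pca, labs, n_pcs = 10)
  expect_equal(fit$n_da, 1L)  # K - 1 axes for two groups
  expect_equal(sum(fit$eig > 1e-8), 1L)
  expect_equal(unname(glance(fit)$train_accuracy), 1)
  # LD axes are orthonormal in the within-group metric
  fit3 <- dapc_fit(pca_fit(blob_matrix(15, diag(8, 3, 3), d = 30, seed = 10)),
                   rep(c("a", "b", "c"), each = 15), n_pcs = 10)
  expect_equal(fit3$n_da, 2L)
  expect_true(all(fit3$eig >= 0))
})

test_that("the Fisher axis matches a brute-force two-group ratio maximiser", {
  set.seed(12)
  m <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 2), 20, 2))
  m[, 2] <- m[, 2] * 3
  rownames(m) <- sprintf("s%02d", 1:40)
  labs <- rep(c("a", "b"), each = 20)
  pca <- pca_fit(m)
  fit <- dapc_fit(pca, labs, n_pcs = 2)

  # brute force: scan directions on the unit circle for max between/within
  s <- pca$scores[, 1:2]
  ratio <- function(theta) {
    v <- c(cos(theta), sin(theta))
    proj <- drop(s %*% v)
    mg <- tapply(proj, labs, mean)
    b <- sum(table(labs) * (mg - mean(proj))^2)
    w <- sum((proj - mg[labs])^2)
    b / w
  }
  thetas <- seq(0, pi, length.out = 2000)
  v_best <- c(cos(thetas[which.max(vapply(thetas, ratio, 1))]),
              sin(thetas[which.max(vapply(thetas, ratio, 1))]))
  v_fit <- fit$axes[, 1] / sqrt(sum(fit$axes[, 1]^2))
  expect_gt(abs(sum(v_best * v_fit)), 0.999)  # same direction up to sign

  # independent cross-check against MASS::lda scalings
  skip_if_not_installed("MASS")
  ld <- MASS::lda(s, grouping = labs)
  v_mass <- ld$scaling[, 1] / sqrt(sum(ld$scaling[, 1]^2))
  expect_gt(abs(sum(v_mass * v_fit)), 0.999)
})

test_that("cross-validation is deterministic, perfect on separable data, chance on noise", {
  m <- blob_matrix(20, diag(10, 2, 2), d = 30, sigma = 0.2, seed = 14)
  labs <- rep(c("a", "b"), each = 20)
  xv <- dapc_xval(m, labs, pc_grid = c(1, 3, 5), reps = 10, seed = 5)
  expect_true(all(xv$results$mean_success == 1))
  xv2 <- dapc_xval(m, labs, pc_grid = c(1, 3, 5), reps = 10, seed = 5)
  expect_identical(xv$results, xv2$results)
  expect_equal(xv$recommended, 1L)  # ties resolved toward fewer PCs

  # labels unrelated to any structure drop success to chance level
  set.seed(6)
  noise <- matrix(rnorm(40 * 30), 40, 30,
                  dimnames = list(sprintf("n%02d", 1:40)))
  xv_null <- dapc_xval(noise, labs, pc_grid = 3, reps = 30, seed = 7)
  expect_lt(abs(xv_null$results$mean_success - 0.5), 0.2)
})

test_that("subset re-analysis re-derives columns and recovers substructure", {
  sim <- simulate_panel(sim_config(
    n_samples = 90, n_loci = 15, k_subpop = 3, f_subpop = 0.3,
    origins = tibble::tibble(label = c("A", "B", "C"),
                             size = c(30L, 30L, 30L), subpop = 1:3,
                             f = rep(0.02, 3)),
    admix_frac = 0, missing_rate = 0, seed = 33))
  gt <- sim$table
  # full-set subset is just the full analysis
  full <- dapc_subset(gt, sample_ids(gt), k_range = 1:6, n_pcs = 60, seed = 2)
  expect_equal(n_samples(full$table), 90L)
  expect_equal(full$clusters$best_k, 3L)

  # a single true cluster yields K = 1 and no discriminant fit
  ids_a <- sample_ids(gt)[sim$truth$subpop == 1]
  sub_a <- dapc_subset(gt, ids_a, k_range = 1:5, seed = 2)
  expect_equal(sub_a$clusters$best_k, 1L)
  expect_null(sub_a$dapc)
  # alleles private to other subpopulations drop out of the encoding
  expect_lt(ncol(sub_a$bm$x), ncol(full$bm$x))
})
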