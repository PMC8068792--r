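#' Principal component analysis of allele-presence data
#'
#' Column-centred (optionally scaled) PCA of the 0/1 matrix, after
#' mean-imputation of masked cells — the dimension-reduction step in front
#' of cluster detection and discriminant analysis. Eigenvalues are the
#' variances of the score axes; cumulative variance fractions are reported
#' per retained-axis count.
#'
#' @param bm An [allele_presence()] encoding or numeric matrix.
#' @param center,scale Column centring (always recommended) and scaling
#'   (off by default for binary data).
#' @return An `ssr_pca`: list with `scores`, `rotation`, `eig`
#'   (eigenvalues, descending), `center`, `scale`, `cum_var`
#'   (cumulative variance fractions), `samples`.
#' @export
pca_fit <- function(bm, center = TRUE, scale = FALSE) {
  samples <- if (inherits(bm, "ssr_binary")) bm$samples else NULL
  m <- if (inherits(bm, "ssr_binary")) impute_binary(bm) else as.matrix(bm)
  if (nrow(m) < 2L) abort("need at least two samples")
  keep <- apply(m, 2, function(v) var(v) > 0)
  if (!any(keep)) abort("zero-variance matrix: no polymorphic column")
  if (scale) m <- m[, keep, drop = FALSE]
  p <- prcomp(m, center = center, scale. = scale)
  eig <- p$sdev^2
  structure(list(
    scores = p$x, rotation = p$rotation, eig = eig,
    center = if (center) p$center else NULL,
    scale = if (scale) p$scale else NULL,
    cum_var = cumsum(eig) / sum(eig),
    samples = samples
  ), class = "ssr_pca")
}

#' @export
print.ssr_pca <- function(x, ...) {
  cat(sprintf("<ssr_pca> %d samples, %d axes; first axis %.1f%% of variance\n",
              nrow(x$scores), length(x$eig), 100 * x$eig[1] / sum(x$eig)))
  invisible(x)
}

# project new rows of the original column space onto a fitted PCA
pca_project <- function(pca, m) {
  m <- as.matrix(m)
  if (!is.null(pca$center)) m <- sweep(m, 2, pca$center)
  if (!is.null(pca$scale)) m <- sweep(m, 2, pca$scale, "/")
  m %*% pca$rotation
}

#' Detect clusters on PCA scores by BIC-guided k-means
#'
#' The sequential-k-means cluster-detection step of DAPC: for each `K` in
#' `k_range`, run k-means on the first `n_pcs` score axes (best of
#' `n_restarts` restarts by within-cluster sum of squares `W_K`) and score
#' it with `BIC(K) = N log(W_K / N) + K log(N)`; the supported number of
#' clusters minimises BIC. Deterministic given `seed` (restart seeds are
#' derived from it).
#'
#' @param pca An [pca_fit()] object.
#' @param k_range Candidate cluster counts (default `1:10`).
#' @param n_pcs Number of retained principal components.
#' @param n_restarts k-means restarts per K.
#' @param seed Integer seed.
#' @return An `ssr_clusters`: list with `bic` (tibble `K`, `W`, `BIC`),
#'   `best_k`, `labels` (integer cluster per sample at the best K),
#'   `n_pcs`, `seed`. `tidy()` returns the BIC tibble.
#' @export
find_clusters <- function(pca, k_range = 1:10, n_pcs, n_restarts = 10, seed = 1) {
  stopifnot(inherits(pca, "ssr_pca"))
  if (n_pcs > ncol(pca$scores)) abort("n_pcs exceeds available axes")
  s <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  N <- nrow(s)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > N) abort("K cannot exceed the number of samples")

  fit_one <- function(K) {
    if (K == 1L) {
      W <- sum(scale(s, scale = FALSE)^2)
      return(list(W = W, labels = rep(1L, N)))
    }
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(seed * 1000L + K * 100L + r)
      km <- tryCatch(
        kmeans(s, centers = K, nstart = 1, iter.max = 50),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) abort(sprintf("k-means failed for K = %d", K))
    list(W = best$tot.withinss, labels = best$cluster)
  }

  fits <- lapply(k_range, fit_one)
  W <- vapply(fits, `[[`, numeric(1), "W")
  BIC <- N * log(pmax(W, .Machine$double.eps) / N) + k_range * log(N)
  best_i <- which.min(BIC)
  structure(list(
    bic = tibble::tibble(K = k_range, W = W, BIC = BIC),
    best_k = k_range[best_i],
    labels = fits[[best_i]]$labels,
    n_pcs = n_pcs, seed = seed,
    samples = pca$samples
  ), class = "ssr_clusters")
}

#' @export
print.ssr_clusters <- function(x, ...) {
  cat(sprintf("<ssr_clusters> best K = %d (BIC over K in {%s}, %d PCs)\n",
              x$best_k, paste(range(x$bic$K), collapse = ".."), x$n_pcs))
  invisible(x)
}

#' @rdname find_clusters
#' @param x An `ssr_clusters` object.
#' @param ... Unused.
#' @export
tidy.ssr_clusters <- function(x, ...) x$bic

#' Fisher discriminant axes on retained principal components
#'
#' The discriminant step of DAPC: on the first `n_pcs` PCA score axes,
#' finds the linear axes maximising between-group over within-group
#' variance (generalised eigenproblem solved by within-whitening, so the
#' axes are orthogonal in the within-group metric). Prediction assigns a
#' sample to the nearest group centroid in discriminant space, with
#' Gaussian posterior weights.
#'
#' @param pca An [pca_fit()] object.
#' @param labels Group label per sample.
#' @param n_pcs Retained principal components.
#' @param n_da Retained discriminant axes (default `min(K - 1, n_pcs)`).
#' @param ridge Trace-scaled ridge added to a (near-)singular within-group
#'   scatter, with a warning.
#' @return An `ssr_dapc`: list with `eig` (discriminant eigenvalues),
#'   `axes` (PC-space loadings of each LD axis), `ld` (sample scores on LD
#'   axes), `centroids`, `labels`, `n_pcs`, `n_da`, `prior`, plus the
#'   fitted `pca`. Use [predict.ssr_dapc()] for new samples.
#' @export
dapc_fit <- function(pca, labels, n_pcs, n_da = NULL, ridge = 1e-8) {
  stopifnot(inherits(pca, "ssr_pca"))
  labels <- as.character(labels)
  if (length(labels) != nrow(pca$scores)) abort("one label per sample required")
  groups <- split(seq_along(labels), labels)
  K <- length(groups)
  if (K < 2L) abort("need at least two groups")
  if (n_pcs < 1L || n_pcs > ncol(pca$scores)) abort("invalid n_pcs")
  s <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  N <- nrow(s)

  centroids_pc <- do.call(rbind, lapply(groups, function(g) {
    colMeans(s[g, , drop = FALSE])
  }))
  grand <- colMeans(s)
  # within / between covariance (MLE normalisation; only the ratio matters)
  W <- matrix(0, n_pcs, n_pcs)
  for (g in seq_along(groups)) {
    cs <- sweep(s[groups[[g]], , drop = FALSE], 2, centroids_pc[g, ])
    W <- W + crossprod(cs)
  }
  W <- W / N
  B <- matrix(0, n_pcs, n_pcs)
  for (g in seq_along(groups)) {
    d <- centroids_pc[g, ] - grand
    B <- B + length(groups[[g]]) * tcrossprod(d)
  }
  B <- B / N

  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) < ridge * sum(diag(W)) / n_pcs) {
    warn("within-group scatter near-singular; ridge regularisation applied")
    W <- W + ridge * (sum(diag(W)) / n_pcs + .Machine$double.eps) * diag(n_pcs)
    ew <- eigen(W, symmetric = TRUE)
  }
  w_half_inv <- ew$vectors %*% diag(1 / sqrt(ew$values), n_pcs) %*% t(ew$vectors)
  eb <- eigen(w_half_inv %*% B %*% w_half_inv, symmetric = TRUE)
  max_da <- min(K - 1L, n_pcs)
  if (is.null(n_da)) n_da <- max_da
  n_da <- min(n_da, max_da)
  axes <- w_half_inv %*% eb$vectors[, seq_len(n_da), drop = FALSE]
  colnames(axes) <- paste0("LD", seq_len(n_da))

  ld <- sweep(s, 2, grand) %*% axes
  centroids <- sweep(centroids_pc, 2, grand) %*% axes
  rownames(centroids) <- names(groups)

  structure(list(
    eig = pmax(eb$values[seq_len(max_da)], 0), axes = axes, ld = ld,
    centroids = centroids, labels = labels, groups = names(groups),
    n_pcs = n_pcs, n_da = n_da,
    prior = lengths(groups) / N, grand = grand, pca = pca
  ), class = "ssr_dapc")
}

#' @export
print.ssr_dapc <- function(x, ...) {
  cat(sprintf("<ssr_dapc> %d groups, %d PCs -> %d discriminant axes\n",
              length(x$groups), x$n_pcs, x$n_da))
  cat("discriminant eigenvalues:", signif(x$eig, 4), "\n")
  invisible(x)
}

#' Predict group membership from a DAPC fit
#'
#' @param object An `ssr_dapc` fit.
#' @param newdata New samples: a numeric matrix in the original column
#'   space of the training [pca_fit()] (e.g. rows of an allele-presence
#'   matrix over the same columns), an `ssr_binary`, or `NULL` for the
#'   training samples.
#' @param ... Unused.
#' @return A tibble with `group` (nearest centroid in LD space) and one
#'   posterior-weight column per group (Gaussian kernel on LD distance,
#'   weighted by group priors).
#' @export
predict.ssr_dapc <- function(object, newdata = NULL, ...) {
  ld <- if (is.null(newdata)) {
    object$ld
  } else {
    m <- if (inherits(newdata, "ssr_binary")) impute_binary(newdata) else as.matrix(newdata)
    pcs <- pca_project(object$pca, m)[, seq_len(object$n_pcs), drop = FALSE]
    sweep(pcs, 2, object$grand) %*% object$axes
  }
  d2 <- vapply(seq_len(nrow(object$centroids)), function(g) {
    rowSums(sweep(ld, 2, object$centroids[g, ])^2)
  }, numeric(nrow(ld)))
  d2 <- matrix(d2, nrow = nrow(ld))
  logw <- sweep(-d2 / 2, 2, log(object$prior), `+`)
  logw <- logw - apply(logw, 1, max)
  post <- exp(logw) / rowSums(exp(logw))
  colnames(post) <- object$groups
  out <- tibble::tibble(group = object$groups[apply(d2, 1, which.min)])
  dplyr::bind_cols(out, tibble::as_tibble(post))
}

#' @export
tidy.ssr_dapc <- function(x, ...) {
  ld <- tibble::as_tibble(x$ld, .name_repair = "minimal")
  names(ld) <- colnames(x$axes)
  dplyr::bind_cols(tibble::tibble(sample = rownames(x$pca$scores) %||%
                                    as.character(seq_len(nrow(ld))),
                                  group = x$labels), ld)
}

#' @export
glance.ssr_dapc <- function(x, ...) {
  self <- predict(x)
  tibble::tibble(n_groups = length(x$groups), n_pcs = x$n_pcs, n_da = x$n_da,
                 train_accuracy = mean(self$group == x$labels))
}

#' Cross-validate the number of retained principal components
#'
#' Repeated stratified holdout: for every candidate `n_pcs`, refit the PCA
#' and discriminant axes on the training part and score the held-out
#' samples by predicted-group accuracy. The recommended `n_pcs` maximises
#' mean accuracy (ties broken toward fewer PCs).
#'
#' @param bm An [allele_presence()] encoding or numeric matrix.
#' @param labels Group label per sample (each group needs >= 2 members).
#' @param pc_grid Candidate retained-PC counts.
#' @param reps Holdout repetitions.
#' @param holdout Held-out fraction per group (default 0.1).
#' @param seed Integer seed.
#' @return An `ssr_xval`: list with `results` (tibble `n_pcs`,
#'   `mean_success`, `sd_success`), `recommended` (n_pcs), `reps`,
#'   `holdout`. `tidy()` returns the results tibble.
#' @export
dapc_xval <- function(bm, labels, pc_grid, reps = 30, holdout = 0.1, seed = 1) {
  m <- if (inherits(bm, "ssr_binary")) impute_binary(bm) else as.matrix(bm)
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) abort("one label per sample required")
  groups <- split(seq_along(labels), labels)
  if (any(lengths(groups) < 2L)) abort("every group needs >= 2 members")
  pc_grid <- sort(unique(as.integer(pc_grid)))

  set.seed(seed)
  success <- matrix(NA_real_, reps, length(pc_grid),
                    dimnames = list(NULL, pc_grid))
  for (r in seq_len(reps)) {
    hold <- unlist(lapply(groups, function(g) {
      n_h <- max(1L, floor(holdout * length(g)))
      if (n_h >= length(g)) abort("holdout would empty a training group")
      sample(g, n_h)
    }), use.names = FALSE)
    train <- setdiff(seq_len(nrow(m)), hold)
    pca_tr <- pca_fit(m[train, , drop = FALSE])
    for (j in seq_along(pc_grid)) {
      p <- pc_grid[j]
      if (p > ncol(pca_tr$scores)) next
      fit <- dapc_fit(pca_tr, labels[train], n_pcs = p)
      pred <- predict(fit, m[hold, , drop = FALSE])
      success[r, j] <- mean(pred$group == labels[hold])
    }
  }
  res <- tibble::tibble(
    n_pcs = pc_grid,
    mean_success = colMeans(success, na.rm = TRUE),
    sd_success = apply(success, 2, sd, na.rm = TRUE)
  )
  best <- res$n_pcs[which.max(res$mean_success)]  # which.max ties -> fewer PCs
  structure(list(results = res, recommended = best, reps = reps,
                 holdout = holdout, seed = seed),
            class = "ssr_xval")
}

#' @export
print.ssr_xval <- function(x, ...) {
  cat(sprintf("<ssr_xval> recommended n_pcs = %d (%d reps, %.0f%% holdout)\n",
              x$recommended, x$reps, 100 * x$holdout))
  invisible(x)
}

#' @rdname dapc_xval
#' @param x An `ssr_xval` object.
#' @param ... Unused.
#' @export
tidy.ssr_xval <- function(x, ...) x$results

#' Re-run the DAPC pipeline on a sample subset
#'
#' Restricts the panel to a subset, re-derives the allele-presence columns
#' (alleles absent from the subset drop out), refits the PCA, re-detects
#' clusters by BIC and fits the discriminant axes at the detected K — the
#' standard drill-down when a broad cluster hides substructure.
#'
#' @param x A [genotype_tbl()].
#' @param samples Character vector of sample ids (>= 4).
#' @param k_range,n_pcs,n_restarts,seed Passed to [find_clusters()];
#'   `n_pcs = NULL` retains axes covering 90% of variance (capped at
#'   N - 2).
#' @return A list with `table` (the subset panel), `bm`, `pca`,
#'   `clusters` (`ssr_clusters`), and `dapc` (`ssr_dapc`, `NULL` when one
#'   cluster is detected).
#' @export
dapc_subset <- function(x, samples, k_range = 1:10, n_pcs = NULL,
                        n_restarts = 10, seed = 1) {
  stopifnot(inherits(x, "ssr_genotype_tbl"))
  if (length(samples) < 4L) abort("subset must contain at least 4 samples")
  sub <- subset_samples(x, samples)
  bm <- allele_presence(sub)
  pca <- pca_fit(bm)
  if (is.null(n_pcs)) {
    n_pcs <- min(which(pca$cum_var >= 0.9)[1], nrow(pca$scores) - 2L)
    n_pcs <- max(1L, n_pcs)
  }
  k_range <- k_range[k_range <= n_samples(sub) - 1L]
  cl <- find_clusters(pca, k_range = k_range, n_pcs = n_pcs,
                      n_restarts = n_restarts, seed = seed)
  fit <- if (cl$best_k >= 2L) dapc_fit(pca, cl$labels, n_pcs = n_pcs) else NULL
  list(table = sub, bm = bm, pca = pca, clusters = cl, dapc = fit)
}
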