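#' Admixture-model Bayesian clustering of allele-presence data
#'
#' A simplified admixture-model Gibbs sampler operating directly on the 0/1
#' allele-presence matrix: each sample `i` owns admixture proportions `q_i`
#' over `K` clusters; each (sample, column) cell draws its cluster of
#' origin from `q_i` and its 0/1 value from that cluster's allele-presence
#' frequency `f_kj`. Priors are `Dirichlet(alpha)` on `q` and
#' `Beta(beta, beta)` on `f`. This is a deliberately lean desk-scale model
#' of the same generative idea as admixture-based clustering programs —
#' one binary observation per allele column, no correlated-frequencies or
#' linkage model — and its output is the posterior-mean `q` and `f` after
#' relabelling each recorded draw against the first one (greedy L2
#' matching of `f` rows), plus the thinned marginal log-likelihood trace.
#'
#' Defaults are desk-scale (`burn_in = 1000`, `n_iter = 10000`); the
#' reference field protocol for production runs on real panels is a burn-in
#' of 50,000 followed by 500,000 iterations with 3 runs per `K`.
#'
#' @param bm An [allele_presence()] encoding or 0/1 matrix (NA = masked).
#' @param K Number of clusters (>= 1).
#' @param burn_in,n_iter,thin Burn-in sweeps, post-burn-in sweeps, and
#'   recording interval.
#' @param seed Integer seed (R RNG) for exact reproducibility.
#' @param alpha,beta Dirichlet and Beta prior parameters.
#' @return An `ssr_structure` object: list with `K`, `q` (N x K
#'   posterior-mean admixture proportions, rows on the simplex), `f`
#'   (K x M cluster frequencies in (0,1)), `lnl_trace`, `lnPD`
#'   (see [estimate_lnPD()]), `config`, and `samples`.
#' @examples
#' sim <- simulate_panel(sim_config(n_samples = 30, n_loci = 8, seed = 3))
#' run <- structure_admixture(allele_presence(sim$table), K = 2,
#'                            burn_in = 100, n_iter = 400, seed = 1)
#' head(run$q)
#' @export
structure_admixture <- function(bm, K, burn_in = 1000, n_iter = 10000,
                                thin = 10, seed = NULL, alpha = 1, beta = 1) {
  if (K < 1) abort("K must be >= 1")
  samples <- NULL
  if (inherits(bm, "ssr_binary")) {
    samples <- bm$samples
    m <- bm$x
    m[bm$missing] <- NA_integer_
  } else {
    m <- as.matrix(bm)
  }
  storage.mode(m) <- "integer"
  if (all(is.na(m))) abort("all cells are masked")
  if (!all(m %in% c(0L, 1L, NA_integer_))) abort("matrix must be 0/1 (NA = masked)")
  if (!is.null(seed)) set.seed(seed)
  fit <- gibbs_admixture_cpp(m, as.integer(K), as.integer(burn_in),
                             as.integer(n_iter), as.integer(thin),
                             alpha, beta)
  rownames(fit$q) <- rownames(m)
  run <- structure(list(
    K = as.integer(K), q = fit$q, f = fit$f, lnl_trace = fit$lnl_trace,
    config = list(burn_in = burn_in, n_iter = n_iter, thin = thin,
                  seed = seed, alpha = alpha, beta = beta),
    samples = samples
  ), class = "ssr_structure")
  run$lnPD <- estimate_lnPD(run)
  run
}

#' @export
print.ssr_structure <- function(x, ...) {
  cat(sprintf("<ssr_structure> K = %d, %d samples, ln P(D) = %.2f (%d recorded draws)\n",
              x$K, nrow(x$q), x$lnPD, length(x$lnl_trace)))
  invisible(x)
}

#' Model-evidence estimate ln P(D | K)
#'
#' The standard harmonic-style estimator used for admixture-model model
#' selection: `mean(lnL) - var(lnL) / 2` over the recorded log-likelihood
#' trace (variance with the n-1 denominator).
#'
#' @param run An `ssr_structure` fit, or a numeric log-likelihood trace.
#' @return The estimate, a single number.
#' @examples
#' estimate_lnPD(c(-10, -12))  # mean -11, var 2 -> -12
#' @export
estimate_lnPD <- function(run) {
  trace <- if (inherits(run, "ssr_structure")) run$lnl_trace else as.numeric(run)
  if (length(trace) < 2L) abort("need at least 2 recorded log-likelihood values")
  mean(trace) - var(trace) / 2
}

#' Run the admixture sampler over a grid of K
#'
#' Repeats [structure_admixture()] for each `K` in `k_range`, `n_runs`
#' independent runs per `K` (run seeds derived as `seed + run_index`), and
#' collects the evidence estimates feeding [evanno()].
#'
#' @inheritParams structure_admixture
#' @param k_range Integer vector of K values (e.g. `1:11`).
#' @param n_runs Independent runs per K (>= 2 for Evanno's sd).
#' @return An `ssr_structure_scan`: list with `lnPD` (tibble `K`, `run`,
#'   `lnPD`), `runs` (nested list of fits indexed `[[as.character(K)]][[run]]`),
#'   and the call configuration.
#' @export
structure_scan <- function(bm, k_range = 1:11, n_runs = 3, burn_in = 1000,
                           n_iter = 10000, thin = 10, seed = 1,
                           alpha = 1, beta = 1) {
  k_range <- sort(unique(as.integer(k_range)))
  runs <- list()
  rows <- list()
  run_index <- 0L
  for (K in k_range) {
    runs[[as.character(K)]] <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      run_index <- run_index + 1L
      fit <- structure_admixture(bm, K, burn_in = burn_in, n_iter = n_iter,
                                 thin = thin, seed = seed + run_index,
                                 alpha = alpha, beta = beta)
      runs[[as.character(K)]][[r]] <- fit
      rows[[run_index]] <- tibble::tibble(K = K, run = r, lnPD = fit$lnPD)
    }
  }
  structure(list(lnPD = dplyr::bind_rows(rows), runs = runs,
                 config = list(k_range = k_range, n_runs = n_runs, seed = seed)),
            class = "ssr_structure_scan")
}

#' @export
print.ssr_structure_scan <- function(x, ...) {
  cat(sprintf("<ssr_structure_scan> K in {%s}, %d runs per K\n",
              paste(x$config$k_range, collapse = ", "), x$config$n_runs))
  print(evanno(x))
  invisible(x)
}

#' Evanno delta-K table for admixture model selection
#'
#' From per-run evidence estimates `L(K)` over a consecutive range of `K`:
#' `L'(K)` is the first difference of mean `L`, `|L''(K)|` its absolute
#' second difference, and `Delta K` is the mean over runs of
#' `|L_r(K+1) - 2 L_r(K) + L_r(K-1)|` (runs paired by index) divided by
#' the run-to-run sd of `L(K)`. The peak of `Delta K` over interior `K`
#' marks the supported number of clusters.
#'
#' @param x An `ssr_structure_scan`, or a data frame with columns `K`,
#'   `run`, `lnPD`.
#' @return An `ssr_evanno` tibble: `K`, `mean_L`, `sd_L`, `L_prime`,
#'   `L_second`, `delta_K`, with attribute `best_k` (argmax of `delta_K`;
#'   `NA` if undefined everywhere). A zero sd makes that K's `delta_K`
#'   `NA` (undefined sentinel).
#' @export
evanno <- function(x) {
  tbl <- if (inherits(x, "ssr_structure_scan")) x$lnPD else tibble::as_tibble(x)
  stopifnot(all(c("K", "run", "lnPD") %in% names(tbl)))
  ks <- sort(unique(tbl$K))
  if (length(ks) < 3L) abort("Evanno's method needs at least 3 consecutive K values")
  if (any(diff(ks) != 1L)) abort("K values must be consecutive")
  runs <- sort(unique(tbl$run))
  if (length(runs) < 2L) abort("need >= 2 runs per K for the sd")
  L <- matrix(NA_real_, length(ks), length(runs),
              dimnames = list(ks, runs))
  for (i in seq_len(nrow(tbl))) {
    L[as.character(tbl$K[i]), as.character(tbl$run[i])] <- tbl$lnPD[i]
  }
  if (anyNA(L)) abort("every K must have the same set of runs")
  mean_L <- rowMeans(L)
  sd_L <- apply(L, 1, sd)
  n <- length(ks)
  L_prime <- c(NA, diff(mean_L))
  L_second <- rep(NA_real_, n)
  delta_K <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    sec <- L[i + 1, ] - 2 * L[i, ] + L[i - 1, ]
    L_second[i] <- abs(mean_L[i + 1] - 2 * mean_L[i] + mean_L[i - 1])
    delta_K[i] <- if (sd_L[i] > 0) mean(abs(sec)) / sd_L[i] else NA_real_
  }
  out <- tibble::tibble(K = ks, mean_L = mean_L, sd_L = sd_L,
                        L_prime = L_prime, L_second = L_second,
                        delta_K = delta_K)
  best <- if (all(is.na(delta_K))) NA_integer_ else ks[which.max(delta_K)]
  structure(out, best_k = best,
            class = c("ssr_evanno", class(tibble::tibble())))
}

#' @rdname evanno
#' @export
best_k <- function(x) {
  stopifnot(inherits(x, "ssr_evanno"))
  attr(x, "best_k")
}

#' Assign samples to clusters from admixture proportions
#'
#' Each sample is labelled with its largest-`q` cluster (ties broken
#' toward the lowest cluster index); samples whose largest membership
#' coefficient is `<= threshold` are flagged as genetically admixed.
#'
#' @param q An N x K matrix of admixture proportions (rows on the simplex),
#'   or an `ssr_structure` fit.
#' @param threshold Membership coefficient above which a sample is
#'   considered assigned (default 0.8; `q = 0.8` exactly is admixed).
#' @return A tibble with columns `sample` (if names available), `cluster`
#'   (integer), `q_max`, `admixed` (logical).
#' @export
assign_membership <- function(q, threshold = 0.8) {
  if (inherits(q, "ssr_structure")) q <- q$q
  q <- as.matrix(q)
  if (nrow(q) == 0L) abort("empty q matrix")
  if (any(abs(rowSums(q) - 1) > 1e-6)) abort("q rows must sum to 1")
  cl <- apply(q, 1, which.max)  # which.max ties -> lowest index
  qmax <- q[cbind(seq_len(nrow(q)), cl)]
  out <- tibble::tibble(cluster = as.integer(cl), q_max = qmax,
                        admixed = qmax <= threshold)
  if (!is.null(rownames(q))) out <- dplyr::bind_cols(
    tibble::tibble(sample = rownames(q)), out)
  out
}

#' Tidy an admixture fit into long format
#'
#' @param x An `ssr_structure` object.
#' @param ... Unused.
#' @return A long tibble: `sample`, `pop` (if known), `cluster`, `q`.
#' @export
tidy.ssr_structure <- function(x, ...) {
  q <- x$q
  ids <- rownames(q) %||% as.character(seq_len(nrow(q)))
  out <- tibble::tibble(
    sample = rep(ids, x$K),
    cluster = rep(seq_len(x$K), each = nrow(q)),
    q = as.vector(q)
  )
  if (!is.null(x$samples)) {
    out$pop <- x$samples$pop[match(out$sample, x$samples$sample)]
    out <- out[, c("sample", "pop", "cluster", "q")]
  }
  out
}

#' @export
glance.ssr_structure <- function(x, ...) {
  memb <- assign_membership(x)
  tibble::tibble(K = x$K, lnPD = x$lnPD,
                 n_samples = nrow(x$q),
                 n_admixed = sum(memb$admixed),
                 n_recorded = length(x$lnl_trace))
}
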