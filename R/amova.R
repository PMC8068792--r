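#' Pairwise squared Euclidean distances on allele-presence data
#'
#' Distances feeding the molecular variance decomposition: squared Euclidean
#' distance between 0/1 allele-presence rows, which equals the count of
#' allele mismatches when there is no missing data. Masked cells are
#' mean-imputed per column first; columns with no observation at all are
#' dropped with a warning.
#'
#' @param bm An [allele_presence()] encoding (or a plain numeric matrix,
#'   samples in rows).
#' @return A symmetric matrix of squared distances with zero diagonal,
#'   sample ids as dimnames.
#' @export
dist_squared <- function(bm) {
  m <- if (inherits(bm, "ssr_binary")) impute_binary(bm) else as.matrix(bm)
  if (nrow(m) < 2L) abort("need at least two samples")
  d2 <- as.matrix(dist(m, method = "euclidean"))^2
  dimnames(d2) <- list(rownames(m), rownames(m))
  d2
}

# Sum over unordered within-set pairs of d2, divided by set size:
# the AMOVA "sum of squares" contribution of one stratum.
ss_of_set <- function(d2, idx) {
  if (length(idx) < 2L) return(0)
  sum(d2[idx, idx]) / (2 * length(idx))
}

# PhiPT (and components) from a squared-distance matrix and a list of
# index groups. Core shared by amova() and its permutation loop.
phipt_from_d2 <- function(d2, groups) {
  N <- nrow(d2)
  k <- length(groups)
  n_g <- lengths(groups)
  ss_total <- sum(d2) / (2 * N)
  ss_within <- sum(vapply(groups, function(g) ss_of_set(d2, g), numeric(1)))
  ss_among <- ss_total - ss_within
  df_among <- k - 1L
  df_within <- N - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(n_g^2) / N) / (k - 1)
  va <- max(0, (ms_among - ms_within) / n0)
  vw <- ms_within
  phi <- if (va + vw <= 0) 0 else va / (va + vw)
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       df_among = df_among, df_within = df_within,
       ms_among = ms_among, ms_within = ms_within,
       n0 = n0, va = va, vw = vw, phipt = phi)
}

#' Variance components from printed AMOVA mean squares
#'
#' Recovers the estimated among-group variance component, PhiPT and gene
#' flow from a one-way AMOVA's mean squares and group sizes — the chain
#' `n0 = (N - sum(n_g^2)/N) / (k-1)`, `Va = (MS_among - MS_within) / n0`
#' (truncated at 0), `Vw = MS_within`, `PhiPT = Va / (Va + Vw)`,
#' `Nm = (1 - PhiPT) / (2 PhiPT)`. Useful for auditing published AMOVA
#' tables, where MS values and stratum sizes are printed but the variance
#' components must be re-derived.
#'
#' @param ms_among,ms_within Mean squares among and within groups.
#' @param sizes Integer vector of group sizes.
#' @return A tibble with columns `n0`, `va`, `vw`, `phipt`, `nm`,
#'   `pct_among`, `pct_within` (percentages of total estimated variance).
#' @examples
#' amova_components(80.296, 26.329, c(29, 42, 48, 122, 60, 41, 140))
#' @export
amova_components <- function(ms_among, ms_within, sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 2L || any(sizes <= 0)) abort("need >= 2 positive group sizes")
  N <- sum(sizes)
  k <- length(sizes)
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  va <- max(0, (ms_among - ms_within) / n0)
  vw <- ms_within
  phi <- phipt(va, vw)
  tibble::tibble(
    n0 = n0, va = va, vw = vw, phipt = phi, nm = nm_from_phipt(phi),
    pct_among = 100 * va / (va + vw), pct_within = 100 * vw / (va + vw)
  )
}

#' PhiPT from variance components
#'
#' The AMOVA analogue of Fst for binary/haploid data: the among-group
#' fraction of the total estimated molecular variance, `Va / (Va + Vw)`.
#'
#' @param va Among-group variance component (>= 0).
#' @param vw Within-group variance component.
#' @return PhiPT in `[0, 1]`.
#' @export
phipt <- function(va, vw) {
  if (va < 0) abort("Va must be nonnegative (truncate at 0 first)")
  if (va + vw <= 0) abort("Va + Vw must be positive")
  va / (va + vw)
}

#' Gene flow Nm from PhiPT
#'
#' The haploid/binary-data island-model transform
#' `Nm = (1 - Phi) / (2 Phi)` (effective migrants per generation).
#' For diploid codominant data the analogous transform divides by 4; the
#' binary transform is the one consistent with allele-presence coding and
#' is the default throughout the package.
#'
#' @param phi PhiPT in `(0, 1]`.
#' @param data_type `"binary"` (default, divisor 2) or `"codominant"`
#'   (divisor 4).
#' @return Nm; `Inf` when `phi <= 0` (no differentiation, unbounded flow).
#' @examples
#' nm_from_phipt(0.290)
#' @export
nm_from_phipt <- function(phi, data_type = c("binary", "codominant")) {
  data_type <- match.arg(data_type)
  div <- if (data_type == "binary") 2 else 4
  ifelse(phi <= 0, Inf, (1 - phi) / (div * phi))
}

#' One-way distance-based AMOVA with PhiPT permutation test
#'
#' Partitions the total squared-distance variation among and within groups:
#' `SS_total = sum_{i<j} d2_ij / N`, `SS_within = sum_g sum_{i<j in g}
#' d2_ij / n_g`, mean squares by their degrees of freedom (`k-1` and
#' `N-k`), variance components via the weighted average group size `n0`,
#' PhiPT as the among fraction, and the gene-flow transform. Significance
#' of PhiPT is assessed by uniformly permuting sample labels (group sizes
#' fixed) and recomputing PhiPT; `p = (#{Phi_perm >= Phi_obs} + 1) /
#' (n_perm + 1)`.
#'
#' @param bm An [allele_presence()] encoding, a plain 0/1 matrix, or a
#'   precomputed squared-distance matrix (`is_dist = TRUE`).
#' @param group Character vector of group labels, one per sample. Defaults
#'   to the panel's population labels when `bm` is an `ssr_binary`.
#' @param n_perm Number of label permutations (0 skips the test).
#' @param seed Integer seed making the permutation stream reproducible.
#' @param is_dist Set `TRUE` when `bm` is already a squared-distance matrix.
#' @return An `ssr_amova` object; see [tidy.ssr_amova()] and
#'   [glance.ssr_amova()] for the table and one-row summary.
#' @examples
#' sim <- simulate_panel(sim_config(n_samples = 40, n_loci = 6, seed = 2))
#' fit <- amova(allele_presence(sim$table), n_perm = 99, seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
amova <- function(bm, group = NULL, n_perm = 999, seed = NULL, is_dist = FALSE) {
  if (inherits(bm, "ssr_binary")) {
    if (is.null(group)) group <- bm$samples$pop
    d2 <- dist_squared(bm)
  } else if (is_dist) {
    d2 <- as.matrix(bm)
    if (!isTRUE(all.equal(d2, t(d2), tolerance = 1e-8)) || any(d2 < -1e-12)) {
      abort("`bm` must be a symmetric nonnegative squared-distance matrix")
    }
  } else {
    d2 <- dist_squared(bm)
  }
  if (is.null(group)) abort("`group` labels are required")
  group <- as.character(group)
  if (length(group) != nrow(d2)) abort("one group label per sample required")
  groups <- split(seq_along(group), group)
  if (length(groups) < 2L) abort("need at least two groups")
  if (any(lengths(groups) == 0L)) abort("empty group")

  comp <- phipt_from_d2(d2, groups)
  degenerate <- comp$ss_total <= .Machine$double.eps

  p_value <- NA_real_
  perm_phi <- NULL
  if (n_perm > 0) {
    if (degenerate) {
      p_value <- 1
    } else {
      if (!is.null(seed)) set.seed(seed)
      obs <- comp$phipt
      perm_phi <- vapply(seq_len(n_perm), function(i) {
        lab <- sample(group)
        phipt_from_d2(d2, split(seq_along(lab), lab))$phipt
      }, numeric(1))
      p_value <- (sum(perm_phi >= obs) + 1) / (n_perm + 1)
    }
  }

  structure(list(
    table = tibble::tibble(
      source = c("Among groups", "Within groups", "Total"),
      df = c(comp$df_among, comp$df_within, comp$df_among + comp$df_within),
      SS = c(comp$ss_among, comp$ss_within, comp$ss_total),
      MS = c(comp$ms_among, comp$ms_within, NA_real_),
      est_var = c(comp$va, comp$vw, comp$va + comp$vw),
      pct = 100 * c(comp$va, comp$vw, comp$va + comp$vw) /
        max(comp$va + comp$vw, .Machine$double.eps)
    ),
    n0 = comp$n0, phipt = comp$phipt,
    nm = nm_from_phipt(comp$phipt),
    p_value = p_value, n_perm = n_perm, seed = seed,
    group_sizes = lengths(groups), perm_phipt = perm_phi
  ), class = "ssr_amova")
}

#' @export
print.ssr_amova <- function(x, ...) {
  cat("One-way distance-based AMOVA\n")
  tbl <- x$table
  tbl$SS <- round(tbl$SS, 3); tbl$MS <- round(tbl$MS, 3)
  tbl$est_var <- round(tbl$est_var, 3); tbl$pct <- round(tbl$pct)
  print(as.data.frame(tbl), row.names = FALSE)
  stars <- if (is.na(x$p_value)) "" else if (x$p_value < 0.001) " ***"
    else if (x$p_value < 0.01) " **" else if (x$p_value < 0.05) " *" else ""
  cat(sprintf("PhiPT = %.3f%s  Nm = %.3f", x$phipt, stars, x$nm))
  if (!is.na(x$p_value)) {
    cat(sprintf("  (p = %.4g, %d permutations)", x$p_value, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' Tidy an AMOVA fit
#'
#' @param x An `ssr_amova` object.
#' @param ... Unused.
#' @return The decomposition table as a tibble (`source`, `df`, `SS`, `MS`,
#'   `est_var`, `pct`).
#' @export
tidy.ssr_amova <- function(x, ...) x$table

#' One-row summary of an AMOVA fit
#'
#' @param x An `ssr_amova` object.
#' @param ... Unused.
#' @return A tibble with `phipt`, `nm`, `p_value`, `n0`, `n_groups`,
#'   `n_samples`, `n_perm`.
#' @export
glance.ssr_amova <- function(x, ...) {
  tibble::tibble(
    phipt = x$phipt, nm = x$nm, p_value = x$p_value, n0 = x$n0,
    n_groups = length(x$group_sizes), n_samples = sum(x$group_sizes),
    n_perm = x$n_perm
  )
}

#' Pairwise PhiPT and gene-flow matrices
#'
#' Runs a one-way AMOVA on every unordered pair of groups (distances
#' restricted to the pair's samples) and assembles the conventional
#' report: PhiPT above the diagonal, Nm below, plus a permutation p-value
#' per pair.
#'
#' @inheritParams amova
#' @return An `ssr_pairwise` object: list with `phipt_nm` (square matrix,
#'   PhiPT above / Nm below the diagonal), `p_values` (symmetric matrix)
#'   and `pairs` (long tibble: `group1`, `group2`, `phipt`, `nm`,
#'   `p_value`). Groups with fewer than 2 samples are skipped with a
#'   warning. `tidy()` returns the long tibble.
#' @export
pairwise_phipt <- function(bm, group = NULL, n_perm = 999, seed = NULL) {
  if (inherits(bm, "ssr_binary") && is.null(group)) group <- bm$samples$pop
  if (is.null(group)) abort("`group` labels are required")
  group <- as.character(group)
  d2 <- dist_squared(bm)
  if (length(group) != nrow(d2)) abort("one group label per sample required")

  sizes <- table(group)
  usable <- names(sizes)[sizes >= 2]
  skipped <- setdiff(names(sizes), usable)
  if (length(skipped)) {
    warn(paste0("skipping group(s) with < 2 samples: ", paste(skipped, collapse = ", ")))
  }
  if (length(usable) < 2L) abort("need at least two groups with >= 2 samples")
  g_levels <- usable

  mat <- matrix(NA_real_, length(g_levels), length(g_levels),
                dimnames = list(g_levels, g_levels))
  pmat <- mat
  pairs <- utils::combn(g_levels, 2, simplify = FALSE)
  long <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    idx <- which(group %in% pr)
    fit <- amova(d2[idx, idx], group[idx], n_perm = n_perm,
                 seed = if (is.null(seed)) NULL else seed + i, is_dist = TRUE)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   phipt = fit$phipt, nm = fit$nm, p_value = fit$p_value)
  })
  long <- dplyr::bind_rows(long)
  for (i in seq_len(nrow(long))) {
    mat[long$group1[i], long$group2[i]] <- long$phipt[i]  # above diagonal
    mat[long$group2[i], long$group1[i]] <- long$nm[i]     # below diagonal
    pmat[long$group1[i], long$group2[i]] <- long$p_value[i]
    pmat[long$group2[i], long$group1[i]] <- long$p_value[i]
  }
  structure(list(phipt_nm = mat, p_values = pmat, pairs = long),
            class = "ssr_pairwise")
}

#' @export
print.ssr_pairwise <- function(x, ...) {
  cat("Pairwise PhiPT (above diagonal) / Nm (below diagonal)\n")
  print(round(x$phipt_nm, 3))
  invisible(x)
}

#' @rdname pairwise_phipt
#' @param x An `ssr_pairwise` object.
#' @param ... Unused.
#' @export
tidy.ssr_pairwise <- function(x, ...) x$pairs
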