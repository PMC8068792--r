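#' Binary allele-presence encoding of an SSR panel
#'
#' Converts a multi-allelic codominant panel into the 0/1 sample x allele
#' matrix on which distances, AMOVA, the admixture sampler and DAPC all
#' operate. One column per (locus, allele) pair observed anywhere in the
#' panel; a cell is 1 when the sample carries at least one copy of that
#' allele (dosage discarded, the standard treatment for autotetraploid SSR
#' data). Columns belonging to a missing genotype are flagged in a mask and
#' never counted as observed zeros.
#'
#' @param x A [genotype_tbl()].
#' @return An `ssr_binary` object: list with `x` (0/1 matrix, samples in
#'   rows), `missing` (logical matrix, `TRUE` where masked), `columns`
#'   (tibble `locus`, `allele`), and `samples` (tibble `sample`, `pop`).
#' @examples
#' gt <- simulate_panel(sim_config(n_samples = 12, n_loci = 3, seed = 4))$table
#' bm <- allele_presence(gt)
#' dim(bm$x)
#' @export
allele_presence <- function(x) {
  stopifnot(inherits(x, "ssr_genotype_tbl"))
  cols <- lapply(loci(x), function(l) {
    alleles <- sort(unique(unlist(x$alleles[x$locus == l], use.names = FALSE)))
    tibble::tibble(locus = l, allele = alleles)
  })
  cols <- dplyr::bind_rows(cols)
  if (nrow(cols) == 0L) abort("panel has no observed alleles")
  col_key <- paste(cols$locus, cols$allele, sep = "\r")
  samples <- attr(x, "samples")
  n <- nrow(samples)

  mat <- matrix(0L, n, nrow(cols),
                dimnames = list(samples$sample, paste(cols$locus, cols$allele, sep = ".")))
  mask <- matrix(FALSE, n, nrow(cols), dimnames = dimnames(mat))
  row_of <- match(x$sample, samples$sample)
  for (r in seq_len(nrow(x))) {
    a <- x$alleles[[r]]
    if (length(a) == 0L) {
      mask[row_of[r], cols$locus == x$locus[r]] <- TRUE
    } else {
      j <- match(paste(x$locus[r], unique(a), sep = "\r"), col_key)
      mat[row_of[r], j] <- 1L
    }
  }
  structure(list(x = mat, missing = mask, columns = cols, samples = samples),
            class = "ssr_binary")
}

#' @export
print.ssr_binary <- function(x, ...) {
  cat(sprintf("<ssr_binary> %d samples x %d (locus, allele) columns; %.1f%% masked\n",
              nrow(x$x), ncol(x$x), 100 * mean(x$missing)))
  invisible(x)
}

#' @export
as.matrix.ssr_binary <- function(x, ...) x$x

# Mean-impute masked cells column-wise; columns with no observation dropped
# with a warning. Returns a plain numeric matrix.
impute_binary <- function(bm) {
  stopifnot(inherits(bm, "ssr_binary"))
  m <- bm$x * 1.0
  m[bm$missing] <- NA_real_
  obs <- colSums(!is.na(m))
  if (any(obs == 0L)) {
    warn(sprintf("dropping %d column(s) with no observed genotype", sum(obs == 0L)))
    m <- m[, obs > 0L, drop = FALSE]
  }
  mu <- colMeans(m, na.rm = TRUE)
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx)) m[na_idx] <- mu[na_idx[, 2]]
  m
}

#' Estimate null-allele frequency at a diploid locus
#'
#' Brookfield's (1996) estimator 1, `(He - Ho) / (1 + He)`, comparing
#' expected heterozygosity from allele frequencies with the observed
#' heterozygote fraction. Meaningful only for diploid-coded data where
#' heterozygotes are distinguishable; panels coded at higher ploidy (allele
#' presence without dosage) are rejected.
#'
#' @param x A [genotype_tbl()] with `ploidy == 2`.
#' @param locus Locus name; default `NULL` estimates every locus.
#' @return A tibble with columns `locus`, `He`, `Ho`, `null_freq`
#'   (clamped to `[0, 1]`).
#' @export
null_allele_freq <- function(x, locus = NULL) {
  stopifnot(inherits(x, "ssr_genotype_tbl"))
  if (ploidy(x) != 2L) {
    abort("null-allele estimation requires diploid-coded data (ploidy 2)")
  }
  loci_use <- if (is.null(locus)) loci(x) else locus
  rows <- lapply(loci_use, function(l) {
    ac <- allele_counts(x, l)
    He <- 1 - sum(ac$freq^2)
    g <- x[x$locus == l, ]
    g <- g[lengths(g$alleles) > 0L, ]
    # a single recorded call at a diploid locus is treated as a homozygote
    Ho <- mean(vapply(g$alleles, function(a) length(unique(a)) == 2L, logical(1)))
    tibble::tibble(locus = l, He = He, Ho = Ho,
                   null_freq = min(1, max(0, (He - Ho) / (1 + He))))
  })
  dplyr::bind_rows(rows)
}
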