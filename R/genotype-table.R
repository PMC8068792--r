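#' Build a genotype table for a codominant SSR panel
#'
#' The central container of the package: one row per sample x locus, with the
#' observed allele calls (fragment sizes in base pairs) held in a list-column.
#' SSR genotypes in polyploids carry between 1 and `ploidy` distinguishable
#' alleles per locus; allele dosage is generally unresolvable from fragment
#' peaks, so a genotype is the *set* (multiset) of called fragment lengths.
#' A genotype with no recorded allele (an empty integer vector) is MISSING.
#'
#' @param calls A data frame with columns `sample`, `pop`, `locus` and
#'   `alleles`, the latter a list-column of positive integer vectors (length
#'   0 = missing genotype, length at most `ploidy`). One row per
#'   sample-locus combination; every sample must cover every locus.
#' @param ploidy Maximum number of allele calls per genotype (default 4,
#'   autotetraploid presence coding).
#' @param title Panel title carried through to [write_genalex()].
#' @return A `ssr_genotype_tbl`: a tibble with attributes `ploidy`, `title`,
#'   `samples` (tibble of sample id and population in panel order) and
#'   `loci` (character vector in panel order).
#' @examples
#' calls <- tibble::tibble(
#'   sample = rep(c("a", "b"), each = 2),
#'   pop = rep("P1", 4),
#'   locus = rep(c("L1", "L2"), 2),
#'   alleles = list(c(101L, 103L), 200L, 101L, integer(0))
#' )
#' gt <- genotype_tbl(calls, ploidy = 2)
#' n_samples(gt)
#' @export
genotype_tbl <- function(calls, ploidy = 4L, title = "ssrpop panel") {
  stopifnot(is.data.frame(calls))
  need <- c("sample", "pop", "locus", "alleles")
  if (!all(need %in% names(calls))) {
    abort(paste0("`calls` must have columns ", paste(need, collapse = ", ")))
  }
  ploidy <- as.integer(ploidy)
  if (length(ploidy) != 1L || is.na(ploidy) || ploidy < 1L) {
    abort("`ploidy` must be a positive integer")
  }
  calls <- tibble::as_tibble(calls[need])
  calls$sample <- as.character(calls$sample)
  calls$pop <- as.character(calls$pop)
  calls$locus <- as.character(calls$locus)
  if (!is.list(calls$alleles)) abort("`alleles` must be a list-column")
  calls$alleles <- lapply(calls$alleles, function(a) {
    a <- as.integer(a)
    if (anyNA(a)) abort("allele calls must not be NA; use integer(0) for missing")
    if (length(a) > ploidy) {
      abort(sprintf("genotype with %d allele calls exceeds ploidy %d", length(a), ploidy))
    }
    if (any(a <= 0L)) abort("allele calls must be positive integers (fragment sizes)")
    sort(a)
  })

  samples <- dplyr::distinct(calls, .data$sample, .data$pop)
  if (anyDuplicated(samples$sample)) {
    abort("duplicate sample id (or sample listed under two populations)")
  }
  loci <- unique(calls$locus)
  if (anyDuplicated(loci)) abort("duplicate locus name")
  if (nrow(calls) != nrow(samples) * length(loci) ||
      anyDuplicated(calls[c("sample", "locus")])) {
    abort("`calls` must contain exactly one row per sample x locus combination")
  }
  # canonical ordering: samples in first-appearance order, loci within sample
  calls <- calls[order(match(calls$sample, samples$sample),
                       match(calls$locus, loci)), ]
  structure(
    calls,
    class = c("ssr_genotype_tbl", "tbl_df", "tbl", "data.frame"),
    ploidy = ploidy,
    title = as.character(title)[1],
    samples = samples,
    loci = loci
  )
}

#' @export
print.ssr_genotype_tbl <- function(x, ...) {
  cat(sprintf(
    "<ssr_genotype_tbl> %d samples x %d loci (ploidy %d, %d population%s)\n",
    n_samples(x), n_loci(x), ploidy(x), length(unique(pop_labels(x))),
    if (length(unique(pop_labels(x))) == 1L) "" else "s"
  ))
  NextMethod()
}

#' Panel accessors
#'
#' Small helpers reading the panel-level attributes of a
#' [genotype_tbl()]: sample count, locus count and names, ploidy, and
#' per-sample population labels (in panel order).
#'
#' @param x A `ssr_genotype_tbl`.
#' @return `n_samples()`/`n_loci()`/`ploidy()` an integer; `loci()` a
#'   character vector; `sample_ids()` a character vector;
#'   `pop_labels()` a character vector aligned with `sample_ids()`.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
n_samples <- function(x) nrow(attr(x, "samples"))

#' @rdname panel-accessors
#' @export
n_loci <- function(x) length(attr(x, "loci"))

#' @rdname panel-accessors
#' @export
loci <- function(x) attr(x, "loci")

#' @rdname panel-accessors
#' @export
ploidy <- function(x) attr(x, "ploidy")

#' @rdname panel-accessors
#' @export
sample_ids <- function(x) attr(x, "samples")$sample

#' @rdname panel-accessors
#' @export
pop_labels <- function(x) attr(x, "samples")$pop

#' Subset a genotype panel by sample
#'
#' Keeps panel attributes consistent; loci are retained even if they become
#' monomorphic (re-derive the binary encoding with [allele_presence()] to
#' drop alleles absent from the subset).
#'
#' @param x A `ssr_genotype_tbl`.
#' @param samples Character vector of sample ids to keep.
#' @return A `ssr_genotype_tbl` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "ssr_genotype_tbl"))
  samples <- as.character(samples)
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing)) {
    abort(paste0("unknown sample id(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  keep <- x[x$sample %in% samples, , drop = FALSE]
  genotype_tbl(keep, ploidy = ploidy(x), title = attr(x, "title"))
}

#' Tally allele observations at a locus
#'
#' Counts every recorded allele copy (gene copy) at a locus over a group of
#' samples, skipping missing genotypes. Relative frequencies are the `p_i`
#' entering Nei's gene diversity.
#'
#' @param x A `ssr_genotype_tbl`.
#' @param locus Locus name.
#' @param samples Optional character vector restricting the tally to a
#'   sample subset (default: all samples).
#' @return A tibble with columns `locus`, `allele`, `count`, `freq`, sorted
#'   by allele, with attribute `n_obs` (total allele observations).
#' @examples
#' gt <- simulate_panel(sim_config(n_samples = 20, n_loci = 2, seed = 1))$table
#' allele_counts(gt, loci(gt)[1])
#' @export
allele_counts <- function(x, locus, samples = NULL) {
  stopifnot(inherits(x, "ssr_genotype_tbl"))
  if (!locus %in% loci(x)) abort(paste0("unknown locus: ", locus))
  rows <- x[x$locus == locus, ]
  if (!is.null(samples)) {
    if (length(samples) == 0L) abort("empty sample group")
    rows <- rows[rows$sample %in% samples, ]
    if (nrow(rows) == 0L) abort("empty sample group")
  }
  all_calls <- unlist(rows$alleles, use.names = FALSE)
  if (length(all_calls) == 0L) {
    abort(paste0("all genotypes missing at locus ", locus, " in this group"))
  }
  tab <- table(all_calls)
  out <- tibble::tibble(
    locus = locus,
    allele = as.integer(names(tab)),
    count = as.integer(tab)
  )
  out <- out[order(out$allele), ]
  out$freq <- out$count / sum(out$count)
  attr(out, "n_obs") <- sum(out$count)
  out
}

# Genotype-class tally at a locus: one class per distinct allele multiset.
# Missing genotypes excluded. Internal helper shared by the diversity module.
genotype_class_counts <- function(x, locus, samples = NULL) {
  rows <- x[x$locus == locus, ]
  if (!is.null(samples)) rows <- rows[rows$sample %in% samples, ]
  keys <- vapply(rows$alleles, function(a) paste(a, collapse = "/"), character(1))
  keys <- keys[keys != ""]
  if (length(keys) == 0L) return(integer(0))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}
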