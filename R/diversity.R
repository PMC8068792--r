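#' Shannon-Wiener index of a proportion vector
#'
#' Information entropy `-sum(p * log(p))` of class proportions, by default
#' in nats so that it pairs with the exponential form used by the evenness
#' index E5. Zero-probability classes contribute nothing.
#'
#' @param p Nonnegative proportions summing to 1 (tolerance `1e-9`).
#' @param base Logarithm base; default `exp(1)` (nats).
#' @return The entropy, a single nonnegative number.
#' @examples
#' div_shannon(c(0.5, 0.25, 0.25))
#' @export
div_shannon <- function(p, base = exp(1)) {
  if (any(p < 0)) abort("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) abort("proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Nei's gene diversity at one locus
#'
#' Corrected expected heterozygosity `h = n/(n-1) * (1 - sum(p_i^2))`.
#' The small-sample correction's `n` is, by default, the number of gene
#' copies observed at the locus (the standard Nei 1978 usage); setting
#' `n_convention = "distinct_alleles"` reads `n` as the number of distinct
#' alleles instead.
#'
#' @param counts An allele-count tibble from [allele_counts()], or any data
#'   frame with a `count` column of per-allele observation counts.
#' @param n_convention `"gene_copies"` (default) or `"distinct_alleles"`.
#' @return `h` in `[0, 1]`.
#' @examples
#' div_nei_gd(tibble::tibble(count = c(5, 5)))  # (10/9) * 0.5
#' @export
div_nei_gd <- function(counts, n_convention = c("gene_copies", "distinct_alleles")) {
  n_convention <- match.arg(n_convention)
  cnt <- counts$count
  n_obs <- sum(cnt)
  if (n_obs < 2) abort("need at least two allele observations")
  p <- cnt / n_obs
  n <- if (n_convention == "gene_copies") n_obs else length(cnt)
  if (n < 2) return(0)
  h <- (n / (n - 1)) * (1 - sum(p^2))
  min(1, max(0, h))
}

#' Average per-locus gene diversities
#'
#' `GD = mean(h_l)` over loci — the panel-level summary printed alongside
#' per-locus values.
#'
#' @param h Numeric vector of per-locus gene diversities.
#' @return Their arithmetic mean.
#' @export
gd_mean <- function(h) {
  if (length(h) == 0L) abort("no per-locus diversities supplied")
  mean(h)
}

#' Evenness E5 of genotype-class counts
#'
#' `E5 = (1/lambda - 1) / (exp(H) - 1)`, where `1/lambda` is the
#' Stoddart-Taylor index (inverse Simpson) and `H` the Shannon index in
#' nats, both over genotype-class proportions. Equals 1 for perfectly even
#' class abundances (and, by convention, for a single class).
#'
#' @param counts Positive integer counts per genotype class (named or not).
#' @return E5 in `(0, 1]`.
#' @examples
#' div_evenness(c(8, 1, 1))
#' @export
div_evenness <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) abort("all genotype-class counts are zero")
  if (length(counts) == 1L) return(1)
  p <- counts / sum(counts)
  lambda <- sum(p^2)
  H <- div_shannon(p)
  # Hill-number ordering guarantees E5 <= 1; clamp floating-point overshoot
  min(1, ((1 / lambda) - 1) / (exp(H) - 1))
}

# Per-locus summary over a sample subset; shared by locus_table/group_table.
locus_stats_one <- function(x, l, samples = NULL,
                            n_convention = "gene_copies", base = exp(1)) {
  gc <- genotype_class_counts(x, l, samples)
  if (length(gc) == 0L) {
    return(tibble::tibble(locus = l, Na = NA_integer_, Ng = NA_integer_,
                          H = NA_real_, GD = NA_real_, E5 = NA_real_))
  }
  ac <- allele_counts(x, l, samples)
  tibble::tibble(
    locus = l,
    Na = nrow(ac),
    Ng = length(gc),
    H = div_shannon(gc / sum(gc), base = base),
    GD = div_nei_gd(ac, n_convention = n_convention),
    E5 = div_evenness(gc)
  )
}

#' Per-locus diversity table
#'
#' For every locus: number of distinct alleles (`Na`), number of distinct
#' genotype classes (`Ng`, a class being the multiset of allele calls,
#' missing genotypes excluded), Shannon-Wiener index `H` over genotype-class
#' proportions, Nei's corrected gene diversity `GD` over allele frequencies,
#' and evenness `E5` over genotype-class counts. Optionally appends a
#' `mean` row with column means rounded to 2 decimals (report convention);
#' per-locus rows keep full precision.
#'
#' @param x A [genotype_tbl()].
#' @param include_mean Append the rounded mean row (default `TRUE`).
#' @inheritParams div_nei_gd
#' @param base Log base for `H` (default nats).
#' @return A tibble with columns `locus`, `Na`, `Ng`, `H`, `GD`, `E5`.
#' @export
locus_table <- function(x, include_mean = TRUE,
                        n_convention = c("gene_copies", "distinct_alleles"),
                        base = exp(1)) {
  stopifnot(inherits(x, "ssr_genotype_tbl"))
  n_convention <- match.arg(n_convention)
  out <- dplyr::bind_rows(lapply(loci(x), function(l) {
    locus_stats_one(x, l, NULL, n_convention, base)
  }))
  if (include_mean) {
    m <- tibble::tibble(
      locus = "mean",
      Na = round(mean(out$Na), 2), Ng = round(mean(out$Ng), 2),
      H = round(mean(out$H), 2), GD = round(mean(out$GD), 2),
      E5 = round(mean(out$E5), 2)
    )
    out$Na <- as.numeric(out$Na); out$Ng <- as.numeric(out$Ng)
    out <- dplyr::bind_rows(out, m)
  }
  out
}

#' Per-group diversity table
#'
#' Splits the panel by a grouping label (origin, inferred cluster, ...) and
#' reports, per group: sample count `N`, mean and sd over loci of `Na` and
#' `Ng`, and locus-mean `H`, `GD` and `E5`. All groups are summarised over
#' the same locus set; sd uses the sample (n-1) denominator. Groups with
#' fewer than 2 samples are flagged with `NA` diversity values.
#'
#' @param x A [genotype_tbl()].
#' @param group Character vector of group labels, one per sample in panel
#'   order; defaults to the panel's population labels.
#' @inheritParams locus_table
#' @return A tibble with columns `group`, `N`, `Na_mean`, `Na_sd`,
#'   `Ng_mean`, `Ng_sd`, `H`, `GD`, `E5`.
#' @export
group_table <- function(x, group = pop_labels(x),
                        n_convention = c("gene_copies", "distinct_alleles"),
                        base = exp(1)) {
  stopifnot(inherits(x, "ssr_genotype_tbl"))
  n_convention <- match.arg(n_convention)
  group <- as.character(group)
  if (length(group) != n_samples(x)) {
    abort("`group` must supply one label per sample")
  }
  ids <- sample_ids(x)
  dplyr::bind_rows(lapply(unique(group), function(g) {
    members <- ids[group == g]
    if (length(members) < 2L) {
      warn(sprintf("group '%s' has fewer than 2 samples; diversity undefined", g))
      return(tibble::tibble(group = g, N = length(members),
                            Na_mean = NA_real_, Na_sd = NA_real_,
                            Ng_mean = NA_real_, Ng_sd = NA_real_,
                            H = NA_real_, GD = NA_real_, E5 = NA_real_))
    }
    per_locus <- dplyr::bind_rows(lapply(loci(x), function(l) {
      locus_stats_one(x, l, members, n_convention, base)
    }))
    tibble::tibble(
      group = g, N = length(members),
      Na_mean = mean(per_locus$Na), Na_sd = sd(per_locus$Na),
      Ng_mean = mean(per_locus$Ng), Ng_sd = sd(per_locus$Ng),
      H = mean(per_locus$H), GD = mean(per_locus$GD), E5 = mean(per_locus$E5)
    )
  }))
}
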