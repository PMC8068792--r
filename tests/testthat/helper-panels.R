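# Shared fixture builders (all generated in code; nothing stored on disk).

# Minimal hand-written panel: 3 samples x 2 loci, tetraploid coding.
tiny_panel <- function() {
  genotype_tbl(tibble::tibble(
    sample = rep(c("s1", "s2", "s3"), each = 2),
    pop = rep(c("A", "A", "B"), each = 2),
    locus = rep(c("L1", "L2"), 3),
    alleles = list(
      c(173L, 175L, 180L), c(200L, 202L),
      c(173L, 175L), c(202L, 204L),
      c(175L, 180L), integer(0)   # s3 missing at L2
    )
  ), ploidy = 4, title = "tiny")
}

# Two populations with completely disjoint allele sets: every method must
# separate them perfectly.
disjoint_panel <- function(n_per = 15, n_loci = 6, seed = 99) {
  set.seed(seed)
  calls <- list()
  row <- 0L
  for (i in seq_len(2 * n_per)) {
    popi <- if (i <= n_per) 1L else 2L
    for (l in seq_len(n_loci)) {
      row <- row + 1L
      pool <- if (popi == 1L) c(100L, 102L, 104L) else c(300L, 302L, 304L)
      calls[[row]] <- sort(unique(sample(pool, 4, replace = TRUE)))
    }
  }
  genotype_tbl(tibble::tibble(
    sample = rep(sprintf("d%03d", seq_len(2 * n_per)), each = n_loci),
    pop = rep(c("P1", "P2"), each = n_per * n_loci),
    locus = rep(sprintf("L%d", seq_len(n_loci)), 2 * n_per),
    alleles = calls
  ), ploidy = 4)
}

# Spherical Gaussian blobs in d dimensions, centers `spread` apart.
blob_matrix <- function(n_per, centers, d = 100, sigma = 0.1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  m <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * d, sd = sigma), n_per, d), 2,
          c(centers[i, ], rep(0, d - ncol(centers))), "+")
  }))
  rownames(m) <- sprintf("b%03d", seq_len(nrow(m)))
  m
}

ref_csv <- function(name) {
  system.file("extdata", name, package = "ssrpop")
}
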