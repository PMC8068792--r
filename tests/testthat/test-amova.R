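test_that("squared distances equal a brute-force pairwise loop", {
  set.seed(7)
  m <- matrix(rbinom(20 * 30, 1, 0.4), 20, 30)
  rownames(m) <- sprintf("r%02d", 1:20)
  d2 <- dist_squared(m)
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) brute[i, j] <- sum((m[i, ] - m[j, ])^2)
  expect_equal(unname(d2), brute)
  expect_equal(diag(d2), stats::setNames(rep(0, 20), rownames(m)))
  # identical rows at distance zero, one mismatch at distance one
  mm <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 0, 1))
  dd <- dist_squared(mm)
  expect_equal(dd["a", "b"], 0)
  expect_equal(dd["a", "c"], 1)
})

test_that("masked cells are mean-imputed before distances", {
  gt <- genotype_tbl(tibble::tibble(
    sample = rep(c("a", "b", "c"), each = 1), pop = "P", locus = "L1",
    alleles = list(c(1L), c(2L), integer(0))), ploidy = 2)
  bm <- allele_presence(gt)
  d2 <- dist_squared(bm)
  # c's masked cells sit at the column means (0.5, 0.5)
  expect_equal(d2["a", "c"], 0.5)
  expect_equal(d2["a", "b"], 2)
})

test_that("AMOVA sums of squares are additive and scale-equivariant", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(12:30, 1)
    m <- matrix(rbinom(n * 15, 1, runif(1, 0.2, 0.8)), n, 15)
    rownames(m) <- sprintf("s%02d", seq_len(n))
    labs <- sample(c("a", "b", "c"), n, replace = TRUE)
    while (length(unique(labs)) < 2) labs <- sample(c("a", "b", "c"), n, TRUE)
    fit <- amova(m, labs, n_perm = 0)
    tbl <- tidy(fit)
    expect_equal(tbl$SS[1] + tbl$SS[2], tbl$SS[3], tolerance = 1e-6)
    expect_equal(sum(tbl$pct[1:2]), 100)
    expect_gte(fit$phipt, 0); expect_lte(fit$phipt, 1)

    # scaling distances by c scales SS, leaves PhiPT unchanged
    d2 <- dist_squared(m)
    fit_scaled <- amova(5 * d2, labs, n_perm = 0, is_dist = TRUE)
    expect_equal(tidy(fit_scaled)$SS, 5 * tbl$SS)
    expect_equal(fit_scaled$phipt, fit$phipt)
  }
})

test_that("distance AMOVA reproduces classical one-way ANOVA on 1-D data", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(10:25, 1)
    x <- rbinom(n, 1, 0.5)
    labs <- sample(c("g1", "g2", "g3"), n, replace = TRUE)
    while (length(unique(labs)) < 3 || min(table(labs)) < 2) {
      labs <- sample(c("g1", "g2", "g3"), n, replace = TRUE)
    }
    m <- matrix(as.numeric(x), ncol = 1, dimnames = list(sprintf("s%d", 1:n)))
    fit <- amova(m, labs, n_perm = 0)
    aov_fit <- stats::aov(x ~ factor(labs))
    ss <- summary(aov_fit)[[1]][["Sum Sq"]]
    ms <- summary(aov_fit)[[1]][["Mean Sq"]]
    tbl <- tidy(fit)
    expect_equal(tbl$SS[1], ss[1], tolerance = 1e-8)
    expect_equal(tbl$SS[2], ss[2], tolerance = 1e-8)
    expect_equal(tbl$MS[1:2], ms, tolerance = 1e-8)
  }
})

test_that("identical samples give a degenerate AMOVA with PhiPT 0", {
  m <- matrix(1, 8, 5, dimnames = list(sprintf("s%d", 1:8)))
  fit <- amova(m, rep(c("a", "b"), each = 4), n_perm = 99, seed = 1)
  expect_equal(tidy(fit)$SS[3], 0)
  expect_equal(fit$phipt, 0)
  expect_equal(fit$p_value, 1)
})

test_that("variance components from printed mean squares follow the n0 chain", {
  # hand-checkable case: 2 groups of 3 and 6; n0 = (9 - 45/9)/1 = 4
  out <- amova_components(10, 4, c(3, 6))
  expect_equal(out$n0, 4)
  expect_equal(out$va, 1.5)
  expect_equal(out$phipt, 1.5 / 5.5)
  # negative Va truncates to zero
  out0 <- amova_components(1, 4, c(3, 6))
  expect_equal(out0$va, 0)
  expect_equal(out0$phipt, 0)
})

test_that("the gene-flow transform matches the binary-data convention", {
  expect_equal(nm_from_phipt(0.5), 0.5)
  expect_equal(nm_from_phipt(1), 0)
  expect_equal(nm_from_phipt(0), Inf)
  expect_equal(nm_from_phipt(0.2, data_type = "codominant"), 0.8 / 0.8)
  expect_equal(phipt(0.832, 26.329), 0.832 / 27.161)
  expect_error(phipt(-1, 2), "nonnegative")
})

test_that("permutation p-values are deterministic and maximal separation is extreme", {
  gt <- disjoint_panel()
  bm <- allele_presence(gt)
  fit1 <- amova(bm, n_perm = 99, seed = 42)
  fit2 <- amova(bm, n_perm = 99, seed = 42)
  expect_identical(fit1$p_value, fit2$p_value)
  expect_identical(fit1$perm_phipt, fit2$perm_phipt)
  # disjoint allele pools: observed PhiPT beats every permutation
  expect_equal(fit1$p_value, 1 / 100)
})

test_that("pairwise PhiPT matrices are symmetric in content and shaped like the report", {
  sim <- simulate_panel(sim_config(
    n_samples = 45, n_loci = 5, k_subpop = 2,
    origins = tibble::tibble(label = c("A", "B", "C"),
                             size = c(15L, 15L, 15L),
                             subpop = c(1L, 1L, 2L),
                             f = c(0.02, 0.02, 0.2)),
    seed = 17))
  pw <- pairwise_phipt(allele_presence(sim$table), n_perm = 49, seed = 3)
  expect_equal(nrow(pw$pairs), 3L)
  m <- pw$phipt_nm
  # above-diagonal PhiPT and below-diagonal Nm are consistent transforms
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[j, i], nm_from_phipt(m[i, j]))
  }
  # the most diverged origin (largest F, other subpopulation) stands out
  ab <- pw$pairs$phipt[pw$pairs$group1 == "A" & pw$pairs$group2 == "B"]
  ac <- pw$pairs$phipt[pw$pairs$group1 == "A" & pw$pairs$group2 == "C"]
  expect_gt(ac, ab)
  # undersized groups are skipped with a warning
  labs <- c(rep("big", 40), rep("mid", 4), "tiny")
  expect_warning(
    pw2 <- pairwise_phipt(allele_presence(sim$table), labs, n_perm = 0),
    "skipping")
  expect_equal(nrow(pw2$pairs), 1L)
  expect_error(
    suppressWarnings(pairwise_phipt(allele_presence(sim$table),
                                    c(rep("big", 44), "tiny"), n_perm = 0)),
    "at least two groups")
})

test_that("PhiPT increases with simulated divergence", {
  phis <- vapply(c(0.01, 0.05, 0.2), function(f) {
    sim <- simulate_panel(sim_config(
      n_samples = 100, n_loci = 10, k_subpop = 2, f_subpop = f,
      origins = tibble::tibble(label = c("A", "B"), size = c(50L, 50L),
                               subpop = 1:2, f = c(0.01, 0.01)),
      admix_frac = 0, seed = 40))
    amova(allele_presence(sim$table), n_perm = 0)$phipt
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})
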