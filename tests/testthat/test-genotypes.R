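test_that("genotype table validates its invariants", {
  gt <- tiny_panel()
  expect_s3_class(gt, "ssr_genotype_tbl")
  expect_equal(n_samples(gt), 3L)
  expect_equal(n_loci(gt), 2L)
  expect_equal(ploidy(gt), 4L)

  # duplicate sample under two populations rejected
  bad <- tibble::tibble(
    sample = c("a", "a"), pop = c("P", "Q"),
    locus = c("L1", "L2"), alleles = list(1L, 2L))
  expect_error(genotype_tbl(bad, ploidy = 2), "duplicate sample")
  # too many allele calls for the ploidy
  bad2 <- tibble::tibble(sample = "a", pop = "P", locus = "L1",
                         alleles = list(c(1L, 2L, 3L)))
  expect_error(genotype_tbl(bad2, ploidy = 2), "exceeds ploidy")
  # nonpositive allele call
  bad3 <- tibble::tibble(sample = "a", pop = "P", locus = "L1",
                         alleles = list(0L))
  expect_error(genotype_tbl(bad3, ploidy = 2), "positive")
  # incomplete sample x locus grid
  bad4 <- tibble::tibble(sample = c("a", "b"), pop = "P",
                         locus = c("L1", "L2"), alleles = list(1L, 2L))
  expect_error(genotype_tbl(bad4, ploidy = 2), "one row per sample x locus")
})

test_that("GenAlEx writer and reader invert each other", {
  gt <- tiny_panel()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_genalex(gt, f1)
  back <- read_genalex(f1)
  expect_equal(n_samples(back), 3L)
  expect_equal(loci(back), loci(gt))
  expect_equal(back$alleles, gt$alleles)
  # byte-identical round trip on a canonical file
  write_genalex(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  # same property on a generated panel
  sim <- simulate_panel(sim_config(n_samples = 10, n_loci = 3, seed = 5))
  write_genalex(sim$table, f1)
  write_genalex(read_genalex(f1), f2)
  expect_identical(readLines(f1), readLines(f2))

  # missing genotype serialised as all-zero slots
  lines <- strsplit(readLines(f1), ",")
  gt_lines <- read_genalex(f1)
  miss <- which(lengths(gt_lines$alleles) == 0L)
  expect_gt(length(vapply(gt_lines$alleles, length, 1L)), 0)
  w3 <- withr::local_tempfile()
  write_genalex(tiny_panel(), w3)
  s3_row <- strsplit(readLines(w3)[6], ",")[[1]]
  expect_equal(s3_row[7:10], c("0", "0", "0", "0"))  # s3 missing at L2
})

test_that("malformed GenAlEx files are rejected with informative errors", {
  gt <- tiny_panel()
  f <- withr::local_tempfile(fileext = ".csv")
  write_genalex(gt, f)
  lines <- readLines(f)

  # declared sample count disagrees with data rows
  bad <- lines
  bad[1] <- sub("^2,3,", "2,5,", bad[1])
  fb <- withr::local_tempfile()
  writeLines(bad, fb)
  expect_error(read_genalex(fb), "declares 5 samples")

  # duplicated sample id
  bad2 <- c(lines[1:4], lines[4], lines[6])
  writeLines(bad2, fb)
  expect_error(read_genalex(fb), "duplicate sample")

  # ragged data row
  bad3 <- lines
  bad3[5] <- paste0(bad3[5], ",7")
  writeLines(bad3, fb)
  expect_error(read_genalex(fb), "expected .* fields")
})

test_that("empty-locus table cannot be written", {
  empty <- genotype_tbl(tiny_panel()[0, ])
  expect_error(write_genalex(empty, tempfile()), "no loci")
})

test_that("allele presence encoding marks carried alleles and masks missing", {
  gt <- tiny_panel()
  bm <- allele_presence(gt)
  # one column per observed (locus, allele)
  expect_equal(nrow(bm$columns),
               length(unique(unlist(lapply(c("L1", "L2"), function(l)
                 paste(l, unlist(gt$alleles[gt$locus == l])))))))
  # sample with {173,175,180} at L1 -> those columns 1, others 0
  s1 <- bm$x["s1", bm$columns$locus == "L1"]
  expect_equal(unname(s1[as.character(bm$columns$allele[bm$columns$locus == "L1"]) %in%
                           c("173", "175", "180")]), c(1L, 1L, 1L))
  # missing genotype fully masked, never an unmasked all-zero block
  expect_true(all(bm$missing["s3", bm$columns$locus == "L2"]))
  for (s in c("s1", "s2")) {
    for (l in c("L1", "L2")) {
      blk <- bm$columns$locus == l
      expect_true(any(bm$x[s, blk] == 1L) || all(bm$missing[s, blk]))
    }
  }
  # column count equals the sum of per-locus distinct allele counts
  na_sum <- sum(vapply(loci(gt), function(l) nrow(allele_counts(gt, l)), 1L))
  expect_equal(ncol(bm$x), na_sum)
})

test_that("monomorphic locus yields a single all-1 presence column", {
  gt <- genotype_tbl(tibble::tibble(
    sample = c("a", "b"), pop = "P", locus = "L1",
    alleles = list(150L, 150L)), ploidy = 2)
  bm <- allele_presence(gt)
  expect_equal(ncol(bm$x), 1L)
  expect_true(all(bm$x == 1L))
})

test_that("allele counts follow the gene-copy definition and are additive", {
  # genotypes {A,A,B} and {B,B,B} at ploidy 3 -> A:2 B:4, n_obs 6
  gt <- genotype_tbl(tibble::tibble(
    sample = c("a", "b"), pop = "P", locus = "L1",
    alleles = list(c(1L, 1L, 2L), c(2L, 2L, 2L))), ploidy = 3)
  ac <- allele_counts(gt, "L1")
  expect_equal(ac$count, c(2L, 4L))
  expect_equal(attr(ac, "n_obs"), 6L)

  expect_error(allele_counts(gt, "nope"), "unknown locus")
  expect_error(allele_counts(gt, "L1", character(0)), "empty")

  # group with all genotypes missing errors
  gt2 <- genotype_tbl(tibble::tibble(
    sample = c("a", "b"), pop = "P", locus = "L1",
    alleles = list(integer(0), c(5L))), ploidy = 2)
  expect_error(allele_counts(gt2, "L1", samples = "a"), "missing")

  # additivity over disjoint groups
  sim <- simulate_panel(sim_config(n_samples = 30, n_loci = 4, seed = 8))
  ids <- sample_ids(sim$table)
  g1 <- ids[1:12]; g2 <- ids[13:30]
  for (l in loci(sim$table)) {
    whole <- allele_counts(sim$table, l)
    a <- allele_counts(sim$table, l, g1)
    b <- allele_counts(sim$table, l, g2)
    merged <- merge(as.data.frame(a[c("allele", "count")]),
                    as.data.frame(b[c("allele", "count")]),
                    by = "allele", all = TRUE)
    merged[is.na(merged)] <- 0
    expect_equal(whole$count, merged$count.x + merged$count.y)
  }
})

test_that("STRUCTURE export writes ploidy rows with a bijective recode", {
  gt <- tiny_panel()
  f <- withr::local_tempfile()
  rec <- export_structure(gt, f)
  lines <- readLines(f)
  expect_equal(length(lines), 1 + 3 * 4)  # header + ploidy rows per sample
  expect_equal(strsplit(lines[1], " ")[[1]], c("L1", "L2"))
  # missing genotype -> -9 in all slots
  s3 <- do.call(rbind, strsplit(lines[10:13], " "))
  expect_true(all(s3[, 4] == "-9"))
  # recode maps invert cleanly
  for (l in names(rec)) {
    expect_false(anyDuplicated(rec[[l]]) > 0)
    expect_equal(sort(as.integer(names(rec[[l]]))),
                 sort(unique(unlist(gt$alleles[gt$locus == l]))))
  }
})

test_that("null-allele estimator matches its closed form and rejects polyploids", {
  # He = Ho -> 0
  gt_eq <- genotype_tbl(tibble::tibble(
    sample = c("a", "b"), pop = "P", locus = "L1",
    alleles = list(c(1L, 2L), c(1L, 2L))), ploidy = 2)
  expect_equal(null_allele_freq(gt_eq)$null_freq, 0)
  expect_error(null_allele_freq(tiny_panel()), "ploidy 2")

  # He = 0.5, Ho = 0.2 -> 0.3/1.5 = 0.2 (construct frequencies directly)
  # two alleles at 50:50 over 10 gene copies, 1 of 5 samples heterozygous
  gt2 <- genotype_tbl(tibble::tibble(
    sample = letters[1:5], pop = "P", locus = "L1",
    alleles = list(c(1L, 1L), c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 2L))),
    ploidy = 2)
  est <- null_allele_freq(gt2)
  expect_equal(est$He, 0.5)
  expect_equal(est$Ho, 0.2)
  expect_equal(est$null_freq, 0.2)
})

test_that("null-allele estimate recovers an injected null allele", {
  # highly polymorphic diploid locus (the estimator's accurate regime) with
  # a true null allele at frequency r: null heterozygotes look homozygous,
  # null homozygotes fail to amplify (missing genotype)
  set.seed(31)
  n <- 500
  r <- 0.1
  vis <- seq(100L, 118L, by = 2L)              # 10 visible alleles
  freqs <- c(rep((1 - r) / 10, 10), r)
  draws <- replicate(n, sample(c(vis, 9L), 2, replace = TRUE, prob = freqs))
  observed <- lapply(seq_len(n), function(i) {
    g <- draws[, i]
    seen <- g[g != 9L]
    if (length(seen) == 0L) return(integer(0))  # amplification failure
    if (length(seen) == 1L) seen <- rep(seen, 2)
    sort(seen)
  })
  gt <- genotype_tbl(tibble::tibble(
    sample = sprintf("s%03d", 1:n), pop = "P", locus = "L1",
    alleles = observed), ploidy = 2)
  est <- null_allele_freq(gt)$null_freq
  expect_lt(abs(est - r), 0.05)
})
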