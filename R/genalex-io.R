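#' Read a GenAlEx-style codominant SSR genotype file
#'
#' Parses the canonical comma-separated codominant dialect used for SSR
#' panels: row 1 holds `n_loci,n_samples,n_pops,size_pop1,...`; row 2 holds
#' `title,,pop_name1,...`; row 3 is the column header
#' `Sample,Pop,Locus1,,...` with `ploidy` columns per locus (locus name in
#' the first, blanks after); data rows follow, one per sample, allele calls
#' as integer fragment sizes and `0` marking an empty allele slot. A
#' genotype whose slots are all zero is missing.
#'
#' @param path Path to the CSV file.
#' @return A [genotype_tbl()].
#' @seealso [write_genalex()] for the exact inverse.
#' @export
read_genalex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > 3 & lines == "")]
  if (length(lines) < 4) abort("file too short to be a codominant GenAlEx table")
  # keep trailing empty fields (strsplit drops them)
  split_row <- function(i) {
    s <- strsplit(paste0(lines[i], ",\x01"), ",", fixed = TRUE)[[1]]
    s[-length(s)]
  }

  meta <- split_row(1)
  if (length(meta) < 3) abort("line 1: expected n_loci,n_samples,n_pops,...")
  n_loci <- as.integer(meta[1]); n_samp <- as.integer(meta[2]); n_pops <- as.integer(meta[3])
  if (anyNA(c(n_loci, n_samp, n_pops))) abort("line 1: non-integer header counts")
  pop_sizes <- as.integer(meta[seq_len(n_pops) + 3L])
  if (anyNA(pop_sizes)) abort("line 1: missing or non-integer population sizes")

  title_row <- split_row(2)
  title <- title_row[1]
  pop_names <- title_row[seq_len(n_pops) + 2L]
  if (anyNA(pop_names) || any(pop_names == "")) abort("line 2: missing population names")

  header <- split_row(3)
  if (length(header) < 3 || (length(header) - 2L) %% n_loci != 0L) {
    abort(sprintf("line 3: %d genotype columns not divisible by %d loci",
                  length(header) - 2L, n_loci))
  }
  p <- (length(header) - 2L) %/% n_loci
  locus_names <- header[2L + (seq_len(n_loci) - 1L) * p + 1L]
  if (anyDuplicated(locus_names)) abort("line 3: duplicate locus names")

  data_lines <- lines[-(1:3)]
  if (length(data_lines) != n_samp) {
    abort(sprintf("line 1 declares %d samples but file has %d data rows",
                  n_samp, length(data_lines)))
  }
  fields <- lapply(strsplit(paste0(data_lines, ",\x01"), ",", fixed = TRUE),
                   function(s) s[-length(s)])
  bad <- which(lengths(fields) != length(header))
  if (length(bad)) {
    abort(sprintf("data line %d: expected %d fields, found %d",
                  bad[1] + 3L, length(header), lengths(fields)[bad[1]]))
  }
  mat <- do.call(rbind, fields)
  sample_id <- mat[, 1]
  if (anyDuplicated(sample_id)) abort("duplicate sample id in data rows")
  pop <- mat[, 2]
  if (!setequal(unique(pop), pop_names)) {
    abort("data-row populations do not match the populations declared on line 2")
  }
  counted <- as.integer(table(factor(pop, levels = pop_names)))
  if (!identical(counted, pop_sizes)) {
    abort("declared population sizes on line 1 do not match the data rows")
  }

  allele_mat <- suppressWarnings(
    matrix(as.integer(mat[, -(1:2), drop = FALSE]), nrow = n_samp))
  allele_mat[is.na(allele_mat)] <- 0L  # blank cells = empty slots
  if (any(allele_mat < 0L)) abort("negative allele call")

  calls <- tidyr::expand_grid(sample = sample_id, locus = locus_names)
  idx <- cbind(rep(seq_len(n_samp), each = n_loci), rep(seq_len(n_loci), n_samp))
  calls$alleles <- lapply(seq_len(nrow(idx)), function(r) {
    cols <- (idx[r, 2] - 1L) * p + seq_len(p)
    a <- allele_mat[idx[r, 1], cols]
    sort(a[a > 0L])
  })
  calls$pop <- pop[match(calls$sample, sample_id)]
  genotype_tbl(calls, ploidy = p, title = title)
}

#' Write a genotype panel in the canonical GenAlEx-style dialect
#'
#' Emits the exact dialect read by [read_genalex()]; on a file produced by
#' this writer, `write_genalex(read_genalex(f))` is byte-identical.
#' Missing genotypes are serialised as all-zero allele slots; genotypes
#' with fewer than `ploidy` calls are zero-padded on the right.
#'
#' @param x A [genotype_tbl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(x, path) {
  stopifnot(inherits(x, "ssr_genotype_tbl"))
  if (n_loci(x) == 0L) abort("cannot write a panel with no loci")
  p <- ploidy(x)
  samples <- attr(x, "samples")
  pops <- unique(samples$pop)
  sizes <- as.integer(table(factor(samples$pop, levels = pops)))

  line1 <- paste(c(n_loci(x), n_samples(x), length(pops), sizes), collapse = ",")
  line2 <- paste(c(attr(x, "title"), "", pops), collapse = ",")
  header_cells <- unlist(lapply(loci(x), function(l) c(l, rep("", p - 1L))))
  line3 <- paste(c("Sample", "Pop", header_cells), collapse = ",")

  # panel order is already sample-major, locus-minor
  ord <- order(match(samples$pop, pops), match(samples$sample, samples$sample))
  sample_order <- samples$sample[ord]
  rows <- vapply(sample_order, function(s) {
    rows_s <- x[x$sample == s, ]
    rows_s <- rows_s[match(loci(x), rows_s$locus), ]
    cells <- unlist(lapply(rows_s$alleles, function(a) c(a, rep(0L, p - length(a)))))
    paste(c(s, samples$pop[samples$sample == s], cells), collapse = ",")
  }, character(1))

  writeLines(c(line1, line2, line3, rows), path, sep = "\n")
  invisible(path)
}

#' Export a panel in STRUCTURE's multi-row format
#'
#' Writes the whitespace-delimited layout expected by admixture-model
#' clustering programs: a header row of locus names, then `ploidy` rows per
#' individual (`sample_id pop_int allele...`), alleles recoded to
#' consecutive integers per locus (recode maps returned invisibly), and
#' `-9` for missing data. Genotypes with fewer recorded calls than `ploidy`
#' have the surplus rows filled with `-9` (dosage unknown).
#'
#' @param x A [genotype_tbl()].
#' @param path Output path.
#' @return Invisibly, a named list of per-locus recode maps
#'   (`allele -> code`), each a named integer vector.
#' @export
export_structure <- function(x, path) {
  stopifnot(inherits(x, "ssr_genotype_tbl"))
  p <- ploidy(x)
  samples <- attr(x, "samples")
  pop_int <- match(samples$pop, unique(samples$pop))

  recode <- lapply(loci(x), function(l) {
    alleles <- sort(unique(unlist(x$alleles[x$locus == l], use.names = FALSE)))
    stats::setNames(seq_along(alleles), alleles)
  })
  names(recode) <- loci(x)

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(loci(x), collapse = " "), con)
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]
    rows_s <- x[x$sample == s, ]
    rows_s <- rows_s[match(loci(x), rows_s$locus), ]
    slot_mat <- vapply(seq_len(n_loci(x)), function(j) {
      a <- rows_s$alleles[[j]]
      codes <- unname(recode[[j]][as.character(a)])
      c(codes, rep(-9L, p - length(codes)))
    }, integer(p))
    slot_mat <- matrix(slot_mat, nrow = p)
    for (r in seq_len(p)) {
      writeLines(paste(c(s, pop_int[i], slot_mat[r, ]), collapse = " "), con)
    }
  }
  invisible(recode)
}
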