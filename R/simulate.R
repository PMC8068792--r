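#' Configuration for the structured SSR panel generator
#'
#' Describes a germplasm panel with nested population structure: `k_subpop`
#' latent subpopulations diverged from a common ancestral allele pool under
#' the Balding-Nichols F-model, and origin groups (e.g. country of
#' provenance) nested inside the subpopulations with a smaller
#' within-subpopulation divergence. The defaults emulate a genebank potato
#' collection: 482 accessions x 24 SSR loci with 4-20 alleles per locus,
#' autotetraploid presence coding, seven origin groups of sizes
#' (29, 42, 48, 122, 60, 41, 140) of which one (41 accessions, wild-relative
#' like) belongs to a second latent subpopulation, weak differentiation
#' among origins (around 3% of molecular variance), a small admixed
#' fraction, and 2% missing genotypes.
#'
#' @param n_samples,n_loci Panel dimensions.
#' @param allele_range Inclusive range for the per-locus allele count
#'   (drawn uniformly), within `[2, 60]`.
#' @param ploidy Allele calls drawn per genotype (default 4).
#' @param k_subpop Number of latent subpopulations.
#' @param origins Tibble with columns `label`, `size`, `subpop` (1-based
#'   index), `f` (within-subpopulation Balding-Nichols divergence of the
#'   origin from its subpopulation). Sizes must sum to `n_samples`.
#' @param f_subpop Divergence of each subpopulation from the ancestral
#'   pool (scalar or one value per subpopulation).
#' @param admix_frac Fraction of samples receiving admixed ancestry.
#' @param admix_conc Dirichlet concentration for admixed `q` vectors.
#' @param missing_rate Per-genotype missing probability (MCAR).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 482, n_loci = 24, allele_range = c(4, 20),
                       ploidy = 4, k_subpop = 2, origins = NULL,
                       f_subpop = 0.025, admix_frac = 0.07, admix_conc = 1,
                       missing_rate = 0.02, seed = 1) {
  if (is.null(origins)) {
    if (n_samples == 482 && k_subpop == 2) {
      origins <- tibble::tibble(
        label = paste0("O", 1:7),
        size = c(29L, 42L, 48L, 122L, 60L, 41L, 140L),
        subpop = c(1L, 1L, 1L, 1L, 1L, 2L, 1L),
        f = c(rep(0.006, 5), 0.02, 0.006)
      )
    } else {
      # generic default: k_subpop equal-ish origins, one per subpopulation
      sizes <- diff(round(seq(0, n_samples, length.out = k_subpop + 1)))
      origins <- tibble::tibble(
        label = paste0("O", seq_len(k_subpop)),
        size = as.integer(sizes),
        subpop = seq_len(k_subpop),
        f = rep(0.006, k_subpop)
      )
    }
  }
  origins <- tibble::as_tibble(origins)
  stopifnot(all(c("label", "size", "subpop", "f") %in% names(origins)))
  if (sum(origins$size) != n_samples) {
    abort("origin sizes must sum to n_samples")
  }
  if (any(origins$f <= 0 | origins$f >= 1)) abort("origin F must be in (0, 1)")
  f_subpop <- rep_len(f_subpop, k_subpop)
  if (any(f_subpop <= 0 | f_subpop >= 1)) abort("f_subpop must be in (0, 1)")
  if (allele_range[1] < 2 || allele_range[2] > 60 ||
      allele_range[1] > allele_range[2]) {
    abort("allele_range must be within [2, 60]")
  }
  if (!all(origins$subpop %in% seq_len(k_subpop))) {
    abort("origin subpop indices must be in 1..k_subpop")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_loci = as.integer(n_loci),
    allele_range = as.integer(allele_range), ploidy = as.integer(ploidy),
    k_subpop = as.integer(k_subpop), origins = origins,
    f_subpop = f_subpop, admix_frac = admix_frac, admix_conc = admix_conc,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  if (sum(g) <= 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# Balding-Nichols draw: child frequencies around parent p with divergence F
bn_draw <- function(p, f) rdirichlet1(p * (1 - f) / f)

#' Simulate a structured SSR germplasm panel
#'
#' Generates a codominant SSR panel with known truth under a nested
#' Balding-Nichols model: per locus, ancestral allele frequencies are a
#' flat Dirichlet draw over a locus-specific allele count; each latent
#' subpopulation diverges from the ancestral pool with divergence
#' `f_subpop`; each origin group diverges from its subpopulation with its
#' own (smaller) `f`. Most samples draw all `ploidy` allele copies from
#' their origin's frequencies; a fraction `admix_frac` receives a
#' Dirichlet admixture vector `q` over subpopulations and draws each
#' allele copy from the subpopulation selected by `q` (mosaic ancestry).
#' Genotypes go missing completely at random at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A list with `table` (a [genotype_tbl()]) and `truth`: per-locus
#'   allele inventories, ancestral / subpopulation / origin allele
#'   frequencies, per-sample origin, subpopulation and admixture `q`
#'   (N x k_subpop, rows on the simplex).
#' @examples
#' sim <- simulate_panel(sim_config(n_samples = 30, n_loci = 5, seed = 7))
#' sim$table
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  L <- config$n_loci
  K <- config$k_subpop
  org <- config$origins
  n_org <- nrow(org)

  locus_names <- sprintf("L%02d", seq_len(L))
  n_alleles <- sample(seq(config$allele_range[1], config$allele_range[2]),
                      L, replace = TRUE)
  inventory <- lapply(seq_len(L), function(l) {
    base <- sample(100:280, 1)
    as.integer(base + 2 * (seq_len(n_alleles[l]) - 1))
  })
  names(inventory) <- locus_names

  p_anc <- lapply(seq_len(L), function(l) rdirichlet1(rep(1, n_alleles[l])))
  p_sub <- lapply(seq_len(L), function(l) {
    t(vapply(seq_len(K), function(s) bn_draw(p_anc[[l]], config$f_subpop[s]),
             numeric(n_alleles[l])))
  })
  p_org <- lapply(seq_len(L), function(l) {
    t(vapply(seq_len(n_org), function(o) {
      bn_draw(p_sub[[l]][org$subpop[o], ], org$f[o])
    }, numeric(n_alleles[l])))
  })
  names(p_anc) <- names(p_sub) <- names(p_org) <- locus_names

  origin_of <- rep(seq_len(n_org), org$size)
  subpop_of <- org$subpop[origin_of]
  sample_id <- sprintf("S%04d", seq_len(n))

  q <- matrix(0, n, K)
  q[cbind(seq_len(n), subpop_of)] <- 1
  admixed <- runif(n) < config$admix_frac
  if (K > 1 && any(admixed)) {
    for (i in which(admixed)) {
      q[i, ] <- rdirichlet1(rep(config$admix_conc, K))
    }
  }

  calls <- vector("list", n * L)
  miss <- matrix(runif(n * L) < config$missing_rate, n, L)
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      idx <- (i - 1L) * L + l
      if (miss[i, l]) {
        calls[[idx]] <- integer(0)
        next
      }
      copies <- integer(config$ploidy)
      for (cp in seq_len(config$ploidy)) {
        freqs <- if (admixed[i] && K > 1) {
          s <- sample.int(K, 1, prob = q[i, ])
          p_sub[[l]][s, ]
        } else {
          p_org[[l]][origin_of[i], ]
        }
        copies[cp] <- sample(inventory[[l]], 1, prob = freqs)
      }
      calls[[idx]] <- sort(unique(copies))
    }
  }

  tbl <- tibble::tibble(
    sample = rep(sample_id, each = L),
    pop = rep(org$label[origin_of], each = L),
    locus = rep(locus_names, n),
    alleles = calls
  )
  gt <- genotype_tbl(tbl, ploidy = config$ploidy, title = "simulated SSR panel")
  truth <- list(
    inventory = inventory, p_anc = p_anc, p_subpop = p_sub, p_origin = p_org,
    origin = org$label[origin_of], subpop = subpop_of, q = q,
    admixed = admixed, config = config
  )
  list(table = gt, truth = truth)
}

#' Write a self-contained fixture suite from the generator
#'
#' Emits a small (N = 60) and a full-scale (default config) panel in the
#' GenAlEx dialect, the ground truth as JSON, and golden outputs (locus
#' diversity table and AMOVA-by-origin summary) regenerated from the
#' pipeline itself. Byte-identical across calls with the same seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the vector of written paths.
#' @export
emit_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  specs <- list(
    small = sim_config(n_samples = 60, n_loci = 8, k_subpop = 2,
                       origins = tibble::tibble(
                         label = c("O1", "O2", "O3"),
                         size = c(25L, 20L, 15L),
                         subpop = c(1L, 1L, 2L),
                         f = c(0.015, 0.015, 0.10)),
                       seed = seed),
    full = sim_config(seed = seed + 1)
  )
  for (nm in names(specs)) {
    sim <- simulate_panel(specs[[nm]])
    panel_path <- file.path(out_dir, paste0("panel_", nm, ".csv"))
    write_genalex(sim$table, panel_path)
    truth_path <- file.path(out_dir, paste0("truth_", nm, ".json"))
    truth <- sim$truth
    truth$config <- NULL
    jsonlite::write_json(truth, truth_path, digits = 10, auto_unbox = TRUE)
    lt <- locus_table(sim$table)
    lt_path <- file.path(out_dir, paste0("locus_table_", nm, ".csv"))
    utils::write.csv(lt, lt_path, row.names = FALSE)
    fit <- amova(allele_presence(sim$table), n_perm = 99, seed = seed)
    am_path <- file.path(out_dir, paste0("amova_", nm, ".csv"))
    utils::write.csv(tidy(fit), am_path, row.names = FALSE)
    paths <- c(paths, panel_path, truth_path, lt_path, am_path)
  }
  invisible(paths)
}
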