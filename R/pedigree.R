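#' Parse a pedigree cross string into parent names
#'
#' Splits notation like `"Superior x Dejima"` on the cross operator
#' (`x` or `×` as a standalone token) at the top parenthesis level
#' only, so nested crosses such as `"(B x C) x D"` keep `"(B x C)"` as a
#' single opaque parent. Whitespace is collapsed; names are otherwise kept
#' verbatim (no case folding, no fuzzy matching).
#'
#' @param text A single cross string.
#' @return Character vector of parent names in order (length 1 for a
#'   selfed/unknown record).
#' @examples
#' parse_cross("Superior x Dejima")
#' parse_cross("(B x C) x D")
#' @export
parse_cross <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s+", " ", trimws(text))
  if (s == "") abort("empty cross string")
  chars <- strsplit(s, "", fixed = FALSE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  # find top-level " x " / " × " operators
  cuts <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n - 2L) {
    if (depth[i] == 0L && chars[i] == " " &&
        (chars[i + 1L] == "x" || chars[i + 1L] == "×") &&
        chars[i + 2L] == " ") {
      cuts <- c(cuts, i)
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  if (length(cuts) == 0L) return(s)
  starts <- c(1L, cuts + 3L)
  ends <- c(cuts - 1L, n)
  parents <- vapply(seq_along(starts), function(j) {
    trimws(paste(chars[starts[j]:ends[j]], collapse = ""))
  }, character(1))
  parents <- parents[parents != ""]
  if (length(parents) == 0L) abort("empty cross string")
  parents
}

# normalise a pedigree data frame into a list of parent vectors
pedigree_parents <- function(records) {
  if (is.data.frame(records)) {
    stopifnot("pedigree" %in% names(records))
    ped <- as.character(records$pedigree)
  } else {
    ped <- as.character(records)
  }
  lapply(ped, function(s) {
    if (is.na(s) || trimws(s) == "") character(0) else parse_cross(s)
  })
}

#' Parent-usage frequency across pedigrees
#'
#' Counts how often each parent name appears across all pedigree records
#' (every mention counted), ranked by descending count with alphabetical
#' tie-break — the tabular content of a parent-usage word cloud.
#'
#' @param records A data frame with a `pedigree` column (e.g. from
#'   [read_pedigree()]) or a character vector of cross strings. Empty /
#'   `NA` pedigrees are skipped.
#' @return A tibble with columns `parent`, `n`.
#' @examples
#' parent_frequency(c("A x B", "A x C"))
#' @export
parent_frequency <- function(records) {
  parents <- pedigree_parents(records)
  if (length(parents) == 0L) abort("no pedigree records")
  all_p <- unlist(parents, use.names = FALSE)
  if (length(all_p) == 0L) {
    return(tibble::tibble(parent = character(0), n = integer(0)))
  }
  tab <- table(all_p)
  out <- tibble::tibble(parent = names(tab), n = as.integer(tab))
  out[order(-out$n, out$parent), ]
}

#' Parent co-usage network edges
#'
#' Undirected edges between parents named together in the same cross,
#' weighted by the number of crosses in which the pair co-occurs.
#' Single-parent records contribute no edge; self-edges are excluded.
#'
#' @inheritParams parent_frequency
#' @param min_count Drop edges with weight below this (default 1).
#' @return A tibble with columns `parent1`, `parent2`, `weight`
#'   (`parent1 < parent2` alphabetically).
#' @export
cooccurrence_edges <- function(records, min_count = 1) {
  parents <- pedigree_parents(records)
  edges <- list()
  for (p in parents) {
    p <- unique(p)
    if (length(p) < 2L) next
    prs <- combn(sort(p), 2)
    edges[[length(edges) + 1L]] <- tibble::tibble(
      parent1 = prs[1, ], parent2 = prs[2, ])
  }
  if (length(edges) == 0L) {
    return(tibble::tibble(parent1 = character(0), parent2 = character(0),
                          weight = integer(0)))
  }
  out <- dplyr::count(dplyr::bind_rows(edges), .data$parent1, .data$parent2,
                      name = "weight")
  out <- out[out$weight >= min_count, ]
  out[order(-out$weight, out$parent1, out$parent2), ]
}

#' Read a pedigree CSV
#'
#' Expects columns `accession` and `pedigree` (a cross string, possibly
#' empty).
#'
#' @param path CSV path.
#' @return A tibble with those two columns as character.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "pedigree") %in% names(df))) {
    abort("pedigree file needs columns `accession` and `pedigree`")
  }
  tibble::tibble(accession = as.character(df$accession),
                 pedigree = as.character(df$pedigree))
}
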