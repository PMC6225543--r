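#' Wisconsin double standardization of a community matrix
#'
#' Each abundance is divided by its bin (column) maximum, then each
#' sample (row) is divided by its row total, so that rows of the result
#' sum to 1. The zero pattern is preserved.
#'
#' @param m A samples-by-bins community table: either a numeric matrix
#'   with sample row names, or a data frame whose first column is
#'   `sample_id` (as produced by [as_bin_matrix()]); all abundances
#'   non-negative.
#' @return The standardized table in the same form as the input.
#' @examples
#' wisconsin_standardize(matrix(c(2, 1, 0, 4), 2, dimnames = list(c("a", "b"), c("x", "y"))))
#' @export
wisconsin_standardize <- function(m) {
  x <- .as_community_matrix(m)
  if (any(x < 0)) abort("Community matrix must be non-negative.")
  zero_cols <- colSums(x) == 0
  if (any(zero_cols)) {
    abort(sprintf(
      "All-zero bin column(s): %s. Drop empty bins before standardizing.",
      paste(colnames(x)[zero_cols], collapse = ", ")
    ))
  }
  out <- sweep(x, 2, apply(x, 2, max), "/")
  rs <- rowSums(out)
  if (any(rs == 0)) abort("All-zero sample row(s) cannot be row-standardized.")
  out <- sweep(out, 1, rs, "/")
  .restore_community_form(out, m)
}

#' Bray-Curtis dissimilarities between samples
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` for every pair of sample rows:
#' symmetric with zero diagonal, 1 for samples with disjoint support,
#' and values in [0, 1]. A pair of all-zero samples has an undefined
#' dissimilarity and is flagged with a warning (returned as `NaN`).
#'
#' @inheritParams wisconsin_standardize
#' @return A symmetric numeric matrix with sample ids as dimnames.
#' @examples
#' bray_curtis(rbind(a = c(1, 0, 3), b = c(0, 2, 1)))
#' @export
bray_curtis <- function(m) {
  x <- .as_community_matrix(m)
  if (any(x < 0)) abort("Community matrix must be non-negative.")
  zero_rows <- rowSums(x) == 0
  if (sum(zero_rows) >= 2) {
    warn("Pairs of all-zero samples have undefined Bray-Curtis dissimilarity (NaN).")
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  diag(d) <- 0
  d
}

#' Combine per-gene bin matrices into one collective fingerprint
#'
#' Column-wise concatenation of sample-by-bin tables from several genes
#' (e.g. nirK, nirS, nosZ-I, nosZ-II) with gene-prefixed bin ids; values
#' are unchanged and rows follow the first table's sample order.
#'
#' @param tables Named list of wide tibbles, each with a `sample_id`
#'   column and identical sample sets (names are used as prefixes; an
#'   unnamed list is prefixed `gene1`, `gene2`, ...).
#' @return One wide tibble spanning all genes' bins.
#' @export
combine_genes <- function(tables) {
  if (!is.list(tables) || length(tables) == 0) abort("`tables` must be a non-empty list.")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("gene", seq_along(tables))
  }
  purrr::walk(tables, check_columns, cols = "sample_id")
  ref <- tables[[1]]$sample_id
  out <- purrr::imap(tables, function(tab, gene) {
    if (!setequal(tab$sample_id, ref)) {
      abort(sprintf("Sample set of table '%s' differs from the first table.", gene))
    }
    tab <- tab[match(ref, tab$sample_id), , drop = FALSE]
    names(tab)[-1] <- paste(gene, names(tab)[-1], sep = "_")
    tab[, -1, drop = FALSE]
  })
  dplyr::bind_cols(tibble(sample_id = ref), out)
}

.as_community_matrix <- function(m) {
  if (is.data.frame(m)) {
    if ("sample_id" %in% names(m)) {
      x <- as.matrix(m[, setdiff(names(m), "sample_id"), drop = FALSE])
      rownames(x) <- m$sample_id
    } else {
      x <- as.matrix(m)
    }
  } else if (is.matrix(m)) {
    x <- m
  } else {
    abort("`m` must be a matrix or data frame.")
  }
  storage.mode(x) <- "double"
  x
}

.restore_community_form <- function(x, original) {
  if (is.data.frame(original) && "sample_id" %in% names(original)) {
    dplyr::bind_cols(tibble(sample_id = original$sample_id), as_tibble(x))
  } else {
    x
  }
}
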