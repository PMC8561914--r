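#' Read a gene-set collection from a GMT file
#'
#' Parses the tab-separated GMT dialect used by MSigDB exports: one gene set
#' per line, with the set name in the first field, a free-text description
#' (possibly empty or a URL) in the second, and one gene symbol per remaining
#' field. Trailing empty fields are ignored.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: a list of gene sets, each
#'   a list with elements `name`, `description` and `genes` (a character
#'   vector of unique gene symbols, input order preserved).
#' @details Duplicate gene symbols within a line are removed with a warning.
#'   A line with fewer than three fields, or a set name that repeats an
#'   earlier line, is an error.
#' @seealso [write_gmt()], [map_to_features()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("GMT file is empty: ", path)
  }
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    # drop trailing empty fields (common in hand-edited exports)
    while (length(fields) > 0L && !nzchar(fields[length(fields)])) {
      fields <- fields[-length(fields)]
    }
    if (length(fields) < 3L) {
      stop("Malformed GMT line ", i, ": expected at least 3 tab-separated ",
           "fields (name, description, >=1 gene), found ", length(fields))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT line ", i, " (", fields[[1]], "): ",
              sum(duplicated(genes)), " duplicate gene symbol(s) removed")
      genes <- unique(genes)
    }
    if (length(genes) == 0L) {
      stop("Malformed GMT line ", i, ": no gene symbols")
    }
    sets[[i]] <- list(name = fields[[1]], description = fields[[2]],
                      genes = genes)
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets))) {
    stop("Duplicate gene-set name(s) in GMT: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `gene_set_collection` as returned by [read_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), integer(1))
  cat("Gene-set collection:", length(x), "sets, sizes",
      min(sizes), "-", max(sizes), "\n")
  invisible(x)
}

#' Map gene sets onto expression-matrix columns
#'
#' Matches each set's gene symbols against the column labels of an expression
#' matrix by exact, case-sensitive string comparison (no alias resolution),
#' yielding the column-index partition that the per-pathway kernels are built
#' from. A gene may belong to several sets; sets matching no column are
#' retained but flagged so that kernel construction can drop them.
#'
#' @param collection A `gene_set_collection`.
#' @param gene_ids Character vector of the expression matrix's column labels.
#' @return An object of class `feature_partition` with elements:
#'   \describe{
#'     \item{indices}{named list of integer column indices (1-based), one per set;}
#'     \item{n_matched}{named integer vector of matched-gene counts;}
#'     \item{empty}{names of sets that matched no column;}
#'     \item{union_size}{number of distinct columns matched by any set.}
#'   }
#' @export
map_to_features <- function(collection, gene_ids) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!is.character(gene_ids) || length(gene_ids) == 0L) {
    stop("gene_ids must be a nonempty character vector of column labels")
  }
  idx <- lapply(collection, function(s) {
    out <- match(s$genes, gene_ids)
    sort(out[!is.na(out)])
  })
  n_matched <- vapply(idx, length, integer(1))
  empty <- names(idx)[n_matched == 0L]
  if (length(empty) > 0L) {
    warning(length(empty), " gene set(s) matched no expression column and ",
            "will be dropped before kernel construction: ",
            paste(utils::head(empty, 5L), collapse = ", "),
            if (length(empty) > 5L) ", ..." else "")
  }
  structure(list(indices = idx,
                 n_matched = n_matched,
                 empty = empty,
                 union_size = length(unique(unlist(idx)))),
            class = "feature_partition")
}

#' @export
print.feature_partition <- function(x, ...) {
  cat("Feature partition:", length(x$indices), "sets,",
      x$union_size, "distinct columns matched,",
      length(x$empty), "empty\n")
  invisible(x)
}

#' Compute tumour volumes from clinical dimension columns
#'
#' Volume is the product of the three recorded tumour dimensions (length,
#' width, depth, in a common linear unit). Rows with any missing dimension or
#' a non-positive product are marked invalid rather than raising an error;
#' invalid rows are excluded from model fitting downstream.
#'
#' @param table A data frame holding the three dimension columns.
#' @param dims Names of the length/width/depth columns, in that order.
#' @param id_col Optional name of a sample-identifier column; row names are
#'   used when `NULL`.
#' @return A data frame with columns `sample_id`, `length`, `width`, `depth`,
#'   `volume`, `valid`.
#' @export
compute_volumes <- function(table,
                            dims = c("length", "width", "depth"),
                            id_col = NULL) {
  stopifnot(is.data.frame(table), length(dims) == 3L)
  missing_cols <- setdiff(dims, names(table))
  if (length(missing_cols) > 0L) {
    stop("Clinical table lacks dimension column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- if (is.null(id_col)) {
    if (is.null(rownames(table))) as.character(seq_len(nrow(table)))
    else rownames(table)
  } else {
    as.character(table[[id_col]])
  }
  l <- as.numeric(table[[dims[1]]])
  w <- as.numeric(table[[dims[2]]])
  d <- as.numeric(table[[dims[3]]])
  volume <- l * w * d
  valid <- is.finite(volume) & volume > 0
  data.frame(sample_id = ids, length = l, width = w, depth = d,
             volume = volume, valid = valid,
             stringsAsFactors = FALSE, row.names = NULL)
}
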