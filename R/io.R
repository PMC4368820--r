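#' Validate an expression matrix
#'
#' An expression matrix is an ordinary numeric matrix of log2 intensities
#' with unique feature identifiers as row names and unique sample
#' identifiers as column names.  `expression_matrix()` checks the
#' contract every downstream function relies on and returns the matrix
#' unchanged.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   row and column names required, all values finite, at least 2 rows
#'   and 2 columns.
#' @return the validated matrix (invisibly identical to the input).
#' @examples
#' x <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expression_matrix(x)
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires feature row names and sample column names",
         call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("expression matrix must have at least 2 features and 2 samples",
         call. = FALSE)
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature identifiers: ",
         paste(utils::head(dup_f, 5L), collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ",
         paste(utils::head(dup_s, 5L), collapse = ", "), call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at feature '", rownames(values)[bad[1L]],
         "', sample '", colnames(values)[bad[2L]], "'", call. = FALSE)
  }
  values
}

#' Construct a two-cohort design
#'
#' Assigns sample identifiers to a test and a control cohort.  Both
#' cohorts need at least two samples because error variances are
#' estimated from pairwise array comparisons within each cohort.
#'
#' @param test,control character vectors of sample identifiers; disjoint,
#'   each of length >= 2, no duplicates.
#' @return an object of class `cohort_design`, a list with elements
#'   `test` and `control`.
#' @examples
#' cohort_design(c("t1", "t2", "t3"), c("c1", "c2", "c3"))
#' @export
cohort_design <- function(test, control) {
  test <- as.character(test)
  control <- as.character(control)
  if (anyDuplicated(test) || anyDuplicated(control))
    stop("duplicated sample identifiers within a cohort", call. = FALSE)
  if (length(test) < 2L || length(control) < 2L)
    stop("each cohort needs at least 2 samples for pairwise error estimation",
         call. = FALSE)
  both <- intersect(test, control)
  if (length(both))
    stop("samples assigned to both cohorts: ",
         paste(utils::head(both, 5L), collapse = ", "), call. = FALSE)
  structure(list(test = test, control = control), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Two-cohort design:", length(x$test), "test vs",
      length(x$control), "control samples\n")
  cat("  test:   ", paste(x$test, collapse = ", "), "\n")
  cat("  control:", paste(x$control, collapse = ", "), "\n")
  invisible(x)
}

# Check that every sample of a design is a column of the matrix.
check_design <- function(design, x) {
  if (!inherits(design, "cohort_design"))
    stop("'design' must be a cohort_design object", call. = FALSE)
  missing <- setdiff(c(design$test, design$control), colnames(x))
  if (length(missing))
    stop("design samples absent from the matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  invisible(design)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors; each element is one
#'   function (gene set), its members drawn from `universe`.  Empty sets
#'   are not allowed.
#' @param universe character vector of all feature identifiers eligible
#'   for annotation.
#' @return an object of class `gene_set_collection` with elements `sets`
#'   and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a named list of member vectors", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicated set identifiers", call. = FALSE)
  sets <- lapply(sets, function(m) unique(as.character(m)))
  sizes <- lengths(sets)
  if (any(sizes == 0L))
    stop("empty gene sets: ",
         paste(utils::head(names(sets)[sizes == 0L], 5L), collapse = ", "),
         call. = FALSE)
  outside <- setdiff(unique(unlist(sets, use.names = FALSE)), universe)
  if (length(outside))
    stop("set members outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "sets over a universe of",
      length(x$universe), "features\n")
  invisible(x)
}

#' Read a log2 expression matrix from tab-delimited text
#'
#' Expected layout: a header row `feature<TAB>sample1<TAB>...`, then one
#' row per feature with the feature identifier in the first column and
#' numeric log2 intensities in the rest.  Any non-numeric cell (including
#' the literal string `NA`) is a parse error reported with its position;
#' missing values are rejected, not imputed.
#'
#' @param path path to the file.
#' @return a validated expression matrix; row and column order preserved.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path))
    stop("cannot read expression matrix, no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L)
    stop("expression matrix needs a header and at least 2 feature rows: ",
         path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 3L)
    stop("expression matrix needs at least 2 sample columns: ", path,
         call. = FALSE)
  samples <- header[-1L]
  nfield <- length(header)
  features <- character(length(fields) - 1L)
  vals <- matrix(NA_real_, length(fields) - 1L, length(samples))
  for (i in seq_along(features)) {
    row <- fields[[i + 1L]]
    if (length(row) != nfield)
      stop("line ", i + 1L, " has ", length(row), " fields, expected ",
           nfield, ": ", path, call. = FALSE)
    features[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v) || any(!is.finite(v))) {
      j <- which(is.na(v) | !is.finite(v))[1L]
      stop("non-numeric value '", row[j + 1L], "' at feature '", row[1L],
           "', sample '", samples[j], "' (line ", i + 1L, ")", call. = FALSE)
    }
    vals[i, ] <- v
  }
  dimnames(vals) <- list(features, samples)
  expression_matrix(vals)
}

#' Write a log2 expression matrix as tab-delimited text
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  x <- expression_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(v)
    paste(sprintf("%.15g", v), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a two-cohort design from tab-delimited text
#'
#' Expected layout: header `sample_id<TAB>cohort`, then one row per
#' sample with cohort either `test` or `control`.
#'
#' @param path path to the file.
#' @return a `cohort_design`.
#' @export
read_cohort_design <- function(path) {
  if (!file.exists(path))
    stop("cannot read design, no such file: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(d) < 2L)
    stop("design file needs columns sample_id and cohort: ", path,
         call. = FALSE)
  bad <- setdiff(unique(d[[2L]]), c("test", "control"))
  if (length(bad))
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "),
         " (expected 'test' or 'control')", call. = FALSE)
  cohort_design(d[[1L]][d[[2L]] == "test"], d[[1L]][d[[2L]] == "control"])
}

#' Write a two-cohort design as tab-delimited text
#' @param design a `cohort_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_design <- function(design, path) {
  if (!inherits(design, "cohort_design"))
    stop("'design' must be a cohort_design object", call. = FALSE)
  d <- data.frame(sample_id = c(design$test, design$control),
                  cohort = rep(c("test", "control"),
                               c(length(design$test), length(design$control))))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set identifier, description (ignored), then member
#' feature identifiers, all tab-separated.  Members outside `universe`
#' are dropped with a warning; sets emptied by the intersection are
#' dropped with a warning.
#'
#' @param path path to the GMT file.
#' @param universe character vector of eligible feature identifiers.
#' @return a `gene_set_collection`.
#' @export
read_gene_sets <- function(path, universe) {
  if (!file.exists(path))
    stop("cannot read gene sets, no such file: ", path, call. = FALSE)
  universe <- unique(as.character(universe))
  lines <- readLines(path)
  keep <- nzchar(lines)
  sets <- list()
  n_dropped_members <- 0L
  dropped_sets <- character()
  for (i in which(keep)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("unreadable GMT line ", i, " (fewer than 2 fields): ", path,
           call. = FALSE)
    id <- parts[1L]
    if (id %in% names(sets))
      stop("duplicated set identifier '", id, "' at GMT line ", i,
           call. = FALSE)
    members <- unique(parts[-(1:2)])
    inside <- intersect(members, universe)
    n_dropped_members <- n_dropped_members + length(members) - length(inside)
    if (length(inside) == 0L) {
      dropped_sets <- c(dropped_sets, id)
    } else {
      sets[[id]] <- inside
    }
  }
  if (n_dropped_members > 0L)
    warning(n_dropped_members,
            " set member(s) outside the universe were dropped",
            call. = FALSE)
  if (length(dropped_sets))
    warning("set(s) emptied by universe intersection were dropped: ",
            paste(utils::head(dropped_sets, 5L), collapse = ", "),
            call. = FALSE)
  if (length(sets) == 0L)
    stop("no gene set survived the universe intersection: ", path,
         call. = FALSE)
  gene_set_collection(sets, universe)
}

#' Write a gene-set collection in GMT format
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path) {
  if (!inherits(collection, "gene_set_collection"))
    stop("'collection' must be a gene_set_collection", call. = FALSE)
  lines <- vapply(names(collection$sets), function(id)
    paste(c(id, "na", collection$sets[[id]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a differential-expression result table
#'
#' Columns: feature, fc_hat (log2 fold-change estimate), var_fc, z, p, q.
#' Numbers are printed with 15 significant digits so a read-back
#' reproduces the table to floating-point print precision.
#'
#' @param results data.frame as returned by [hta_test()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(results, path) {
  cols <- c("feature", "fc_hat", "var_fc", "z", "p", "q")
  if (!all(cols %in% names(results)))
    stop("results must contain columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  out <- results[cols]
  for (nm in cols[-1L]) out[[nm]] <- sprintf("%.15g", out[[nm]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write results to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#' @param path path written by [write_de_results()].
#' @return data.frame with columns feature, fc_hat, var_fc, z, p, q.
#' @export
read_de_results <- function(path) {
  if (!file.exists(path))
    stop("cannot read results, no such file: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = TRUE,
                         colClasses = c("character", rep("numeric", 5L)))
  names(d)[1L] <- "feature"
  d
}
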