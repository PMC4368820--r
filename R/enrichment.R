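#' Fisher exact overrepresentation of gene sets in a selection
#'
#' For each set, with N the universe size, K the set size, n the
#' selection size and k the overlap, the one-sided overrepresentation
#' p-value is the hypergeometric upper tail P(X >= k).  A set is
#' "detected" when p falls strictly below `threshold` (default 0.001,
#' no multiplicity correction -- a fixed raw significance level).
#'
#' @param selected character vector of selected features, a subset of
#'   the collection's universe.
#' @param collection a `gene_set_collection`.
#' @param threshold detection significance level.
#' @return data.frame with columns `function_id`, `k`, `K`, `n`, `N`,
#'   `p`, `detected`, one row per set, in the collection's set order.
#' @export
fisher_overrepresentation <- function(selected, collection,
                                      threshold = 0.001) {
  if (!inherits(collection, "gene_set_collection"))
    stop("'collection' must be a gene_set_collection", call. = FALSE)
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, collection$universe)
  if (length(outside))
    stop("selected features outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  N <- length(collection$universe)
  n <- length(selected)
  K <- lengths(collection$sets)
  k <- vapply(collection$sets, function(m)
    length(intersect(m, selected)), integer(1L))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(function_id = names(collection$sets), k = k, K = K,
             n = n, N = N, p = p, detected = p < threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bias of a selection towards a union of specific functions
#'
#' Measures how strongly a method's selection is drawn towards a
#' designated group of functions (e.g. disease-specific ones) as the
#' one-sided hypergeometric tail of the overlap between the selection
#' and the union of the functions' member features.
#'
#' @param selected character vector of selected features.
#' @param specific character vector, the union gene set of the specific
#'   functions; subset of `universe`.
#' @param universe character vector of all eligible features.
#' @return the one-sided overrepresentation p-value.
#' @export
bias_toward_functions <- function(selected, specific, universe) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  specific <- unique(as.character(specific))
  out_sel <- setdiff(selected, universe)
  if (length(out_sel))
    stop("selected features outside the universe: ",
         paste(utils::head(out_sel, 5L), collapse = ", "), call. = FALSE)
  out_spec <- setdiff(specific, universe)
  if (length(out_spec))
    stop("specific-function features outside the universe: ",
         paste(utils::head(out_spec, 5L), collapse = ", "), call. = FALSE)
  N <- length(universe)
  K <- length(specific)
  n <- length(selected)
  k <- length(intersect(selected, specific))
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Disorder feature-function links (chance benchmark)
#'
#' Replaces every set's members with a uniform sample (without
#' replacement, per set) from the universe, preserving set sizes.
#' Running an analysis against the disordered collection yields the
#' detection level expected by chance, the benchmark against which
#' genuine functional bias is judged.
#'
#' @param collection a `gene_set_collection`.
#' @param seed integer seed; the same seed reproduces the same
#'   disordered collection.
#' @return a `gene_set_collection` with resampled memberships.
#' @export
disorder_links <- function(collection, seed) {
  if (!inherits(collection, "gene_set_collection"))
    stop("'collection' must be a gene_set_collection", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  set.seed(as.integer(seed))
  sets <- lapply(collection$sets, function(m)
    sample(collection$universe, length(m)))
  gene_set_collection(sets, collection$universe)
}
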