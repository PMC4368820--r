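#' Package a method's output on one data set for reliability scoring
#'
#' The benchmarking platform scores methods through what they select and
#' the functions those selections imply.  `method_output()` derives,
#' from a per-feature result table:
#' \itemize{
#'   \item the selection at `p < p_cut` (specificity role),
#'   \item the selection at `q < q_cut` (FDR role, sensitivity),
#'   \item the functions detected by Fisher overrepresentation (at
#'     `enrich_cut`) on the p-selection, and the full ranked function
#'     list with its enrichment p-values.
#' }
#' `method_output_from_selection()` does the same for methods exposing a
#' single joint selection with no p/FDR distinction (the hybrid method):
#' the one selection fills both roles.
#'
#' @param de data.frame with columns `feature`, `p`, `q` (e.g. from
#'   [hta_test()] or [pooled_t_test()]).
#' @param collection a `gene_set_collection`; selections are intersected
#'   with its universe before enrichment so all methods are scored on
#'   the annotatable features.
#' @param method,dataset identifiers recorded in the output.
#' @param p_cut,q_cut,enrich_cut thresholds (defaults 0.05, 0.05, 0.001).
#' @return an object of class `method_output`: list with `method`,
#'   `dataset`, `selected_p`, `selected_q`, `n_selected_fdr`,
#'   `functions_detected`, and `function_p` (named enrichment p-values
#'   over all sets of the collection).
#' @export
method_output <- function(de, collection, method, dataset,
                          p_cut = 0.05, q_cut = 0.05, enrich_cut = 0.001) {
  if (!is.data.frame(de) || !all(c("feature", "p", "q") %in% names(de)))
    stop("'de' must be a result table with feature, p and q columns",
         call. = FALSE)
  build_method_output(selected_p = de$feature[de$p < p_cut],
                      selected_q = de$feature[de$q < q_cut],
                      collection = collection, method = method,
                      dataset = dataset, enrich_cut = enrich_cut)
}

#' @rdname method_output
#' @param selected character vector, the method's single joint selection.
#' @export
method_output_from_selection <- function(selected, collection, method,
                                         dataset, enrich_cut = 0.001) {
  selected <- unique(as.character(selected))
  build_method_output(selected_p = selected, selected_q = selected,
                      collection = collection, method = method,
                      dataset = dataset, enrich_cut = enrich_cut)
}

build_method_output <- function(selected_p, selected_q, collection,
                                method, dataset, enrich_cut) {
  if (!inherits(collection, "gene_set_collection"))
    stop("'collection' must be a gene_set_collection", call. = FALSE)
  selected_p <- intersect(unique(selected_p), collection$universe)
  selected_q <- intersect(unique(selected_q), collection$universe)
  enr <- fisher_overrepresentation(selected_p, collection,
                                   threshold = enrich_cut)
  structure(list(method = as.character(method),
                 dataset = as.character(dataset),
                 selected_p = selected_p,
                 selected_q = selected_q,
                 n_selected_fdr = length(selected_q),
                 functions_detected = enr$function_id[enr$detected],
                 function_p = stats::setNames(enr$p, enr$function_id)),
            class = "method_output")
}

#' @export
print.method_output <- function(x, ...) {
  cat("Method output [", x$method, " on ", x$dataset, "]: ",
      length(x$selected_p), " features at p, ", x$n_selected_fdr,
      " at FDR, ", length(x$functions_detected),
      " functions detected\n", sep = "")
  invisible(x)
}

undefined_ratio <- function() {
  structure(NA_real_, undefined = TRUE)
}

check_comparable <- function(method, reference) {
  if (!inherits(method, "method_output") ||
      !inherits(reference, "method_output"))
    stop("both arguments must be method_output objects", call. = FALSE)
  if (!identical(method$dataset, reference$dataset))
    stop("method and reference outputs come from different data sets: '",
         method$dataset, "' vs '", reference$dataset, "'", call. = FALSE)
  invisible(NULL)
}

#' Relative specificity of a method against a reference
#'
#' Coexpressed genes tend to be functionally coherent while randomly
#' selected genes do not, so the number of functions overrepresented in
#' a method's p < 0.05 selection proxies its specificity.  The measure
#' is that count divided by the reference method's count on the same
#' data set.  A reference count of zero yields a flagged undefined value
#' (`NA` with attribute `undefined`), never an exception.
#'
#' @param method,reference `method_output` objects on the same data set.
#' @return the ratio F_method / F_reference.
#' @export
relative_specificity <- function(method, reference) {
  check_comparable(method, reference)
  f_ref <- length(reference$functions_detected)
  if (f_ref == 0L) return(undefined_ratio())
  length(method$functions_detected) / f_ref
}

#' Relative sensitivity of a method against a reference
#'
#' Under the assumption that relative specificity is proportional to
#' absolute specificity, the product of relative specificity and the
#' number of features selected at the rigorous FDR < 0.05 cutoff is
#' proportional to the number of true positives.  The measure is that
#' product normalized by the reference's product (whose own relative
#' specificity is 1).
#'
#' @inheritParams relative_specificity
#' @return (RSP_method * Gq_method) / Gq_reference; flagged undefined if
#'   the reference detected no functions or selected no features at FDR.
#' @export
relative_sensitivity <- function(method, reference) {
  check_comparable(method, reference)
  rsp <- relative_specificity(method, reference)
  if (is.na(rsp)) return(undefined_ratio())
  if (reference$n_selected_fdr == 0L) return(undefined_ratio())
  rsp * method$n_selected_fdr / reference$n_selected_fdr
}

# Mean, over detected function instances (function-dataset pairs), of
# that function's occurrence count across the data sets.
occurrence_statistic <- function(outputs, per = c("instance", "function")) {
  per <- match.arg(per)
  instances <- unlist(lapply(outputs, `[[`, "functions_detected"),
                      use.names = FALSE)
  if (length(instances) == 0L) return(NA_real_)
  occ <- table(instances)
  if (per == "instance") mean(occ[instances]) else mean(occ)
}

#' Relative reproducibility of a method across data sets
#'
#' For multiple data sets of similar studies, a reproducible method
#' re-detects the same functions.  The raw statistic is the average,
#' over detected function instances (a function counted once per data
#' set detecting it), of that function's occurrence count across the
#' data sets; it is then divided by the reference method's statistic.
#' Averaging over unique functions instead is available via `per`.
#'
#' @param outputs list of `method_output`s for one method, one per data
#'   set (>= 2).
#' @param reference_outputs matching list for the reference method on
#'   the same data sets.
#' @param per average over detected `"instance"`s (default) or unique
#'   `"function"`s.
#' @return the ratio of occurrence statistics; flagged undefined (`NA`
#'   with attribute `undefined`) when either method detected nothing.
#' @export
relative_reproducibility <- function(outputs, reference_outputs,
                                     per = c("instance", "function")) {
  per <- match.arg(per)
  if (length(outputs) < 2L || length(reference_outputs) < 2L)
    stop("reproducibility needs outputs on at least 2 data sets",
         call. = FALSE)
  ds_m <- sort(vapply(outputs, `[[`, character(1L), "dataset"))
  ds_r <- sort(vapply(reference_outputs, `[[`, character(1L), "dataset"))
  if (!identical(ds_m, ds_r))
    stop("method and reference cover different data sets", call. = FALSE)
  raw_m <- occurrence_statistic(outputs, per)
  raw_r <- occurrence_statistic(reference_outputs, per)
  if (is.na(raw_m) || is.na(raw_r) || raw_r == 0) return(undefined_ratio())
  raw_m / raw_r
}

#' Detection rate of designated disease-specific functions
#'
#' The fraction of the listed functions present in a method's detected
#' function set, averaged over data sets (`per_dataset = TRUE`, the
#' default) or computed once over the union of detections.
#'
#' @param outputs list of `method_output`s for one method.
#' @param disease_functions character vector of function identifiers;
#'   must all be sets of `collection`.
#' @param collection the `gene_set_collection` the outputs were scored
#'   against.
#' @param per_dataset average per-data-set rates (default) or score
#'   detection in >= 1 data set.
#' @return a fraction in `[0, 1]`.
#' @export
detection_rate <- function(outputs, disease_functions, collection,
                           per_dataset = TRUE) {
  if (!inherits(collection, "gene_set_collection"))
    stop("'collection' must be a gene_set_collection", call. = FALSE)
  disease_functions <- unique(as.character(disease_functions))
  unknown <- setdiff(disease_functions, names(collection$sets))
  if (length(unknown))
    stop("unknown disease function(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  if (length(disease_functions) == 0L)
    stop("'disease_functions' must be non-empty", call. = FALSE)
  if (per_dataset) {
    rates <- vapply(outputs, function(o)
      mean(disease_functions %in% o$functions_detected), numeric(1L))
    mean(rates)
  } else {
    all_detected <- unique(unlist(lapply(outputs, `[[`,
                                         "functions_detected")))
    mean(disease_functions %in% all_detected)
  }
}

#' AUC of a method's function ranking against a reference function set
#'
#' Content agreement between a method's derived functions and a
#' reference set, as the Mann-Whitney area under the ROC curve of the
#' method's function ranking (ascending enrichment p-value; functions
#' without a score rank last; ties midranked) taking the reference
#' functions as positives.  A contrast is considered misanalyzed by the
#' method when AUC < 0.5 -- the ranking disagrees with the reference
#' more than a random ordering would.
#'
#' @param scores named numeric vector of enrichment p-values on the
#'   method's selection (smaller = stronger); names are function ids.
#'   Functions in `all_functions` missing from `scores` rank last.
#' @param reference character vector of reference function ids;
#'   non-empty and a strict subset of `all_functions`.
#' @param all_functions character vector of all function ids under
#'   consideration.
#' @return the AUC in `[0, 1]`, with attribute `misanalyzed`
#'   (`TRUE` iff AUC < 0.5).
#' @export
auc_vs_reference <- function(scores, reference, all_functions) {
  all_functions <- unique(as.character(all_functions))
  reference <- unique(as.character(reference))
  if (length(reference) == 0L)
    stop("reference function set must be non-empty", call. = FALSE)
  bad <- setdiff(reference, all_functions)
  if (length(bad))
    stop("reference functions outside the function universe: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (setequal(reference, all_functions))
    stop("reference must not equal the full function universe",
         call. = FALSE)
  full <- rep(Inf, length(all_functions))
  names(full) <- all_functions
  known <- intersect(names(scores), all_functions)
  full[known] <- scores[known]
  ranked <- rank(-full, ties.method = "average")  # high rank = small p
  pos <- all_functions %in% reference
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  auc <- (sum(ranked[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(auc, misanalyzed = auc < 0.5)
}

#' Progressive permutation degradation of a paired contrast
#'
#' Builds a series of replicates with step-wise destroyed signal:
#' replicate 0 is the original matrix; replicate i additionally has the
#' feature intensities of each array in its first i test-control pairs
#' independently permuted across features.  The replicates' selections
#' therefore carry monotonically degrading specificity, which a valid
#' specificity proxy must track.
#'
#' @param x expression matrix.
#' @param design a `cohort_design` whose cohorts are paired: test sample
#'   i is the partner of control sample i (equal cohort sizes required).
#' @param seed integer seed; the full replicate series is reproducible.
#' @return named list of P + 1 expression matrices (`rep0` ... `repP`,
#'   P = number of pairs).
#' @export
progressive_degradation <- function(x, design, seed) {
  x <- expression_matrix(x)
  check_design(design, x)
  if (length(design$test) != length(design$control))
    stop("degradation requires a paired design (equal cohort sizes)",
         call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  set.seed(as.integer(seed))
  n_pairs <- length(design$test)
  reps <- vector("list", n_pairs + 1L)
  names(reps) <- paste0("rep", 0:n_pairs)
  reps[[1L]] <- x
  cur <- x
  for (i in seq_len(n_pairs)) {
    for (s in c(design$test[i], design$control[i]))
      cur[, s] <- cur[sample(nrow(cur)), s]
    reps[[i + 1L]] <- cur
  }
  reps
}

#' Detected-function counts along a degradation series
#'
#' Runs a method on every replicate of [progressive_degradation()] and
#' counts the functions detected from the p < `p_cut` selection and
#' from fixed top-fraction selections of the method's ranking (p
#' ascending, ties broken by feature identifier).  On data bearing real
#' functional signal the counts decline with the replicate index.
#'
#' @param replicates list of matrices from [progressive_degradation()].
#' @param design the paired `cohort_design`.
#' @param collection a `gene_set_collection`.
#' @param method `"ttest"` (default, the classical validation) or
#'   `"hta"`.
#' @param p_cut selection p-value cutoff.
#' @param enrich_cut detection significance level.
#' @param top_fractions fractions of the ranking to use as fixed-size
#'   selections.
#' @return data.frame with columns `replicate`, `selection`,
#'   `n_functions`, long format.
#' @export
degradation_curve <- function(replicates, design, collection,
                              method = c("ttest", "hta"), p_cut = 0.05,
                              enrich_cut = 0.001,
                              top_fractions = c(0.05, 0.10, 0.15)) {
  method <- match.arg(method)
  rows <- list()
  for (i in seq_along(replicates)) {
    xi <- replicates[[i]]
    de <- if (method == "hta") hta_test(xi, design)
          else pooled_t_test(xi, design)
    ord <- order(de$p, de$feature)
    count <- function(sel) {
      enr <- fisher_overrepresentation(intersect(sel, collection$universe),
                                       collection, threshold = enrich_cut)
      sum(enr$detected)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = i - 1L, selection = sprintf("p<%g", p_cut),
      n_functions = count(de$feature[de$p < p_cut]),
      stringsAsFactors = FALSE)
    for (f in top_fractions) {
      top <- de$feature[ord][seq_len(ceiling(f * nrow(de)))]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = i - 1L, selection = sprintf("top%g%%", 100 * f),
        n_functions = count(top), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Full reliability report for a set of methods on a data-set collection
#'
#' Runs each method on each data set (the z-test on the matrix as given;
#' t-test and the hybrid method on the scaling-normalized matrix so all
#' methods see identical input), scores every method against the
#' reference, and assembles per-data-set and per-method measures.
#'
#' @param datasets named list; each element a list with components
#'   `matrix` (expression matrix) and `design` (`cohort_design`).
#' @param collection a `gene_set_collection`.
#' @param methods subset of `c("hta", "ttest", "hm")`.
#' @param reference the normalizing reference method (default `"hta"`).
#' @param disease_functions optional character vector of function ids
#'   for the detection-rate measure.
#' @param p_cut,q_cut,fc_cut,enrich_cut thresholds: selection p, FDR,
#'   hybrid |log2 FC| and enrichment detection (defaults 0.05, 0.05, 1,
#'   0.001).
#' @return an object of class `bmorr_report`: list with data.frames
#'   `per_dataset` (columns dataset, method, n_functions,
#'   n_selected_fdr, rsp, rse, auc, misanalyzed) and `per_method`
#'   (method, rr, detection_rate), plus the raw `outputs`.
#' @export
bmorr_report <- function(datasets, collection,
                         methods = c("hta", "ttest", "hm"),
                         reference = "hta", disease_functions = NULL,
                         p_cut = 0.05, q_cut = 0.05, fc_cut = 1,
                         enrich_cut = 0.001) {
  methods <- match.arg(methods, c("hta", "ttest", "hm"),
                       several.ok = TRUE)
  if (!reference %in% methods)
    methods <- c(reference, methods)
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    stop("'datasets' must be a named list", call. = FALSE)
  outputs <- list()
  for (ds in names(datasets)) {
    x <- expression_matrix(datasets[[ds]]$matrix)
    design <- datasets[[ds]]$design
    check_design(design, x)
    xn <- scaling_normalize(x)$matrix
    for (m in methods) {
      out <- switch(m,
        hta = method_output(hta_test(x, design), collection, "hta", ds,
                            p_cut, q_cut, enrich_cut),
        ttest = method_output(pooled_t_test(xn, design), collection,
                              "ttest", ds, p_cut, q_cut, enrich_cut),
        hm = {
          tt <- pooled_t_test(xn, design)
          method_output_from_selection(
            hybrid_select(tt, p_cut = p_cut, fc_cut = fc_cut),
            collection, "hm", ds, enrich_cut)
        })
      outputs[[paste(m, ds, sep = ".")]] <- out
    }
  }
  get_out <- function(m, ds) outputs[[paste(m, ds, sep = ".")]]
  per_ds <- list()
  for (ds in names(datasets)) {
    ref_out <- get_out(reference, ds)
    for (m in methods) {
      out <- get_out(m, ds)
      auc <- if (length(ref_out$functions_detected) == 0L ||
                 setequal(ref_out$functions_detected,
                          names(collection$sets)))
        undefined_ratio()
      else auc_vs_reference(out$function_p, ref_out$functions_detected,
                            names(collection$sets))
      per_ds[[length(per_ds) + 1L]] <- data.frame(
        dataset = ds, method = m,
        n_functions = length(out$functions_detected),
        n_selected_fdr = out$n_selected_fdr,
        rsp = as.numeric(relative_specificity(out, ref_out)),
        rse = as.numeric(relative_sensitivity(out, ref_out)),
        auc = as.numeric(auc),
        misanalyzed = isTRUE(attr(auc, "misanalyzed")),
        stringsAsFactors = FALSE)
    }
  }
  per_ds <- do.call(rbind, per_ds)
  per_m <- list()
  for (m in methods) {
    outs <- lapply(names(datasets), function(ds) get_out(m, ds))
    ref_outs <- lapply(names(datasets), function(ds)
      get_out(reference, ds))
    rr <- if (length(datasets) >= 2L)
      as.numeric(relative_reproducibility(outs, ref_outs))
    else NA_real_
    drf <- if (!is.null(disease_functions))
      detection_rate(outs, disease_functions, collection)
    else NA_real_
    per_m[[length(per_m) + 1L]] <- data.frame(
      method = m, rr = rr, detection_rate = drf,
      stringsAsFactors = FALSE)
  }
  structure(list(per_dataset = per_ds,
                 per_method = do.call(rbind, per_m),
                 reference = reference, outputs = outputs),
            class = "bmorr_report")
}

#' @export
print.bmorr_report <- function(x, ...) {
  cat("Reliability report (reference:", x$reference, ")\n\n")
  cat("Per data set:\n")
  print(x$per_dataset, row.names = FALSE)
  cat("\nPer method:\n")
  print(x$per_method, row.names = FALSE)
  invisible(x)
}
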