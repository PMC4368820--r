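#' Configuration for the synthetic cohort generator
#'
#' Describes a two-cohort expression experiment: a common template array
#' of baseline log2 levels, per-array additive Gaussian technical error,
#' optional true differential expression, optional latent sample
#' subtypes (molecular heterogeneity), and an optional gene-set layer
#' with signal sets aligned to the planted differential features.
#'
#' Type I data (genetically identical samples) use `n_subtypes = 0`:
#' every array is template + cohort effect + error, so per-feature
#' sample variance is independent of fold-change.  Type II data add
#' subtype-specific shifts within a cohort, producing the hallmark of
#' molecular heterogeneity: non-error variance that expands with
#' absolute fold-change.
#'
#' @param n_features number of features.
#' @param n_test,n_control cohort sizes (>= 2 each).
#' @param error_sd per-array technical error SD on the log2 scale; a
#'   scalar or a vector of length `n_test + n_control` (uneven sample
#'   quality).  Default 0.2, a typical single-array log2 error level.
#' @param template_mean,template_sd,template_clip baseline log2 level
#'   distribution: Normal(`template_mean`, `template_sd`) clipped to
#'   `template_clip`; defaults Normal(7, 2) on `[2, 15]`, spanning a
#'   realistic array intensity range.
#' @param deg_fraction fraction of features with a true cohort-level
#'   log2 shift.
#' @param effect_range range of absolute log2 shifts for those
#'   features; signs random.  Default `c(0.3, 2)` deliberately includes
#'   effects below the conventional |log2 FC| > 1 cutoff.
#' @param n_subtypes latent subtypes within the test cohort (0 = type I).
#' @param subtype_block_size features per subtype-specific block.
#' @param subtype_shift maximal absolute log2 shift of a subtype block;
#'   magnitudes drawn from Uniform(`subtype_shift`/2, `subtype_shift`),
#'   signs random per feature.  Setting it to 0 reduces type II to
#'   type I exactly.
#' @param shift_both_cohorts also plant subtypes (with their own blocks)
#'   in the control cohort.
#' @param n_sets number of gene sets to emit (0 = no annotation layer).
#' @param set_size members per set.
#' @param signal_fraction fraction of sets that are signal sets
#'   (enriched in planted differential features).
#' @param signal_purity fraction of a signal set's members drawn from
#'   the planted differential features.
#' @param seed integer seed; generation is a deterministic function of
#'   (config, seed).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_features = 5000, n_test = 3,
                             n_control = 3, error_sd = 0.2,
                             template_mean = 7, template_sd = 2,
                             template_clip = c(2, 15),
                             deg_fraction = 0, effect_range = c(0.3, 2),
                             n_subtypes = 0, subtype_block_size = 150,
                             subtype_shift = 1.5,
                             shift_both_cohorts = FALSE,
                             n_sets = 0, set_size = 40,
                             signal_fraction = 0.25,
                             signal_purity = 0.8, seed = 1) {
  n_samples <- n_test + n_control
  if (n_features < 2L) stop("need at least 2 features", call. = FALSE)
  if (n_test < 2L || n_control < 2L)
    stop("each cohort needs at least 2 samples", call. = FALSE)
  if (!length(error_sd) %in% c(1L, n_samples))
    stop("'error_sd' must be a scalar or one value per sample",
         call. = FALSE)
  if (any(error_sd <= 0)) stop("error SDs must be > 0", call. = FALSE)
  if (deg_fraction < 0 || deg_fraction > 1)
    stop("'deg_fraction' must lie in [0, 1]", call. = FALSE)
  if (signal_fraction < 0 || signal_fraction > 1 ||
      signal_purity < 0 || signal_purity > 1)
    stop("set fractions must lie in [0, 1]", call. = FALSE)
  if (n_subtypes < 0 || subtype_shift < 0)
    stop("'n_subtypes' and 'subtype_shift' must be >= 0", call. = FALSE)
  if (n_subtypes > 0 && n_subtypes > n_test)
    stop("more subtypes than test samples", call. = FALSE)
  structure(list(n_features = as.integer(n_features),
                 n_test = as.integer(n_test),
                 n_control = as.integer(n_control),
                 error_sd = rep_len(error_sd, n_samples),
                 template_mean = template_mean,
                 template_sd = template_sd,
                 template_clip = template_clip,
                 deg_fraction = deg_fraction,
                 effect_range = effect_range,
                 n_subtypes = as.integer(n_subtypes),
                 subtype_block_size = as.integer(subtype_block_size),
                 subtype_shift = subtype_shift,
                 shift_both_cohorts = isTRUE(shift_both_cohorts),
                 n_sets = as.integer(n_sets),
                 set_size = as.integer(set_size),
                 signal_fraction = signal_fraction,
                 signal_purity = signal_purity,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Template + cohort effect + per-array Gaussian error; the common core
# of both generators.  Consumes RNG in a fixed order so that the type II
# generator with zero subtype shift reproduces type I bit for bit.
simulate_base <- function(cfg) {
  nf <- cfg$n_features
  features <- sprintf("f%05d", seq_len(nf))
  samples <- c(sprintf("t%d", seq_len(cfg$n_test)),
               sprintf("c%d", seq_len(cfg$n_control)))
  template <- pmin(pmax(stats::rnorm(nf, cfg$template_mean,
                                     cfg$template_sd),
                        cfg$template_clip[1L]), cfg$template_clip[2L])
  true_fc <- numeric(nf)
  n_deg <- round(cfg$deg_fraction * nf)
  if (n_deg > 0L) {
    deg_idx <- sample.int(nf, n_deg)
    true_fc[deg_idx] <- sample(c(-1, 1), n_deg, replace = TRUE) *
      stats::runif(n_deg, cfg$effect_range[1L], cfg$effect_range[2L])
  }
  noise <- matrix(stats::rnorm(nf * length(samples)), nf,
                  length(samples))
  noise <- sweep(noise, 2L, cfg$error_sd, "*")
  x <- template + noise
  x[, seq_len(cfg$n_test)] <- x[, seq_len(cfg$n_test)] + true_fc
  dimnames(x) <- list(features, samples)
  dimnames(noise) <- dimnames(x)
  list(matrix = x, noise = noise,
       design = cohort_design(samples[seq_len(cfg$n_test)],
                              samples[cfg$n_test + seq_len(cfg$n_control)]),
       template = template, true_fc = true_fc)
}

# Divide features as evenly as possible: rep(1:k, length.out) sorted.
even_split <- function(ids, k) {
  split(ids, sort(rep_len(seq_len(k), length(ids))))
}

finish_dataset <- function(cfg, base, subtypes) {
  features <- rownames(base$matrix)
  truth_features <- data.frame(feature = features,
                               is_deg = base$true_fc != 0,
                               true_fc = base$true_fc,
                               stringsAsFactors = FALSE)
  collection <- NULL
  truth_functions <- NULL
  if (cfg$n_sets > 0L) {
    gs <- make_gene_sets(features, truth_features$is_deg, cfg)
    collection <- gs$collection
    truth_functions <- gs$truth
  }
  structure(list(matrix = base$matrix,
                 signal = base$matrix - base$noise,
                 design = base$design,
                 truth = list(features = truth_features,
                              subtypes = subtypes,
                              functions = truth_functions),
                 collection = collection, config = cfg),
            class = "synthetic_dataset")
}

# Signal sets draw signal_purity of their members from planted
# differential features, decoys draw uniformly from the universe.
make_gene_sets <- function(features, is_deg, cfg) {
  n_signal <- round(cfg$signal_fraction * cfg$n_sets)
  deg_pool <- features[is_deg]
  sets <- vector("list", cfg$n_sets)
  names(sets) <- sprintf("FN%04d", seq_len(cfg$n_sets))
  is_signal <- seq_len(cfg$n_sets) <= n_signal & length(deg_pool) > 0L
  for (i in seq_len(cfg$n_sets)) {
    if (is_signal[i]) {
      n_from_deg <- min(round(cfg$signal_purity * cfg$set_size),
                        length(deg_pool))
      members <- c(sample(deg_pool, n_from_deg),
                   sample(setdiff(features, deg_pool),
                          cfg$set_size - n_from_deg))
    } else {
      members <- sample(features, cfg$set_size)
    }
    sets[[i]] <- members
  }
  list(collection = gene_set_collection(sets, features),
       truth = data.frame(function_id = names(sets),
                          is_signal_set = is_signal,
                          stringsAsFactors = FALSE))
}

#' Simulate a type I (genetically identical) two-cohort data set
#'
#' Every array is the common template plus an optional cohort-level
#' shift on the planted differential features plus iid per-array
#' Gaussian error.  Per-feature sample variance carries no information
#' about fold-change, the defining property of genetically identical
#' replicates.
#'
#' @param config a `synthetic_config` with `n_subtypes = 0`.
#' @return an object of class `synthetic_dataset`: list with `matrix`,
#'   `design`, `truth` (feature/subtype/function ground truth),
#'   `collection` (or `NULL`), and the `config`.
#' @export
simulate_type1 <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("'config' must be a synthetic_config", call. = FALSE)
  if (config$n_subtypes != 0L)
    stop("type I data have no latent subtypes; set n_subtypes = 0",
         call. = FALSE)
  set.seed(config$seed)
  base <- simulate_base(config)
  subtypes <- data.frame(sample = colnames(base$matrix),
                         subtype = 1L, stringsAsFactors = FALSE)
  finish_dataset(config, base, subtypes)
}

#' Simulate a type II (molecularly heterogeneous) two-cohort data set
#'
#' Starts from the type I construction (identical random draws under
#' the same seed) and overlays latent subtypes: the test cohort is
#' partitioned as evenly as possible into `n_subtypes` groups, each
#' assigned a disjoint block of features that receives a
#' subtype-specific signed log2 shift.  Within-cohort spread on block
#' features then grows with the block's fold-change -- the variance
#' expansion with |FC| that corrupts per-feature variance estimators.
#' With `shift_both_cohorts = TRUE` the control cohort receives its own
#' subtype layer.
#'
#' @param config a `synthetic_config` with `n_subtypes >= 1`.
#' @return a `synthetic_dataset`; block features carry `is_deg = TRUE`
#'   with `true_fc` equal to the cohort-mean shift they induce.
#' @export
simulate_type2 <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("'config' must be a synthetic_config", call. = FALSE)
  if (config$n_subtypes < 1L)
    stop("type II data need at least one latent subtype", call. = FALSE)
  set.seed(config$seed)
  base <- simulate_base(config)
  k <- config$n_subtypes
  bs <- config$subtype_block_size
  free <- which(base$true_fc == 0)
  need <- k * bs * (1L + config$shift_both_cohorts)
  if (length(free) < need)
    stop("not enough non-differential features for the subtype blocks",
         call. = FALSE)
  block_pool <- sample(free, need)
  test_ids <- base$design$test
  control_ids <- base$design$control
  groups_t <- even_split(test_ids, k)
  subtypes <- data.frame(sample = colnames(base$matrix), subtype = 1L,
                         stringsAsFactors = FALSE)
  apply_layer <- function(groups, offset, cohort_ids) {
    for (s in seq_along(groups)) {
      block <- block_pool[(offset + s - 1L) * bs + seq_len(bs)]
      shift <- sample(c(-1, 1), bs, replace = TRUE) *
        stats::runif(bs, config$subtype_shift / 2, config$subtype_shift)
      base$matrix[block, groups[[s]]] <<-
        base$matrix[block, groups[[s]]] + shift
      # cohort-mean effect of the subtype shift
      frac <- length(groups[[s]]) / length(cohort_ids)
      sign_flip <- if (offset == 0L) 1 else -1
      base$true_fc[block] <<- base$true_fc[block] + sign_flip * shift * frac
      subtypes$subtype[subtypes$sample %in% groups[[s]]] <<- s
    }
  }
  apply_layer(groups_t, 0L, test_ids)
  if (config$shift_both_cohorts)
    apply_layer(even_split(control_ids, k), k, control_ids)
  finish_dataset(config, base, subtypes)
}

#' Simulate a collection of data sets for similar studies
#'
#' Repeated studies of one condition share the underlying biology --
#' the same functions are impaired -- while each study measures its own
#' cohorts with its own technical error.  This generator draws the
#' template, planted effects, subtype structure and annotation layer
#' once (from `config`), then produces `n_datasets` data sets that
#' share that signal and differ only in fresh per-array Gaussian error
#' (seeds derived from `config$seed`).  The result is the natural
#' substrate for cross-data-set reproducibility scoring.
#'
#' @param config a `synthetic_config`; `n_subtypes` decides whether the
#'   shared biology is type I or type II.
#' @param n_datasets number of data sets (>= 2).
#' @return list with `datasets` (named list of `synthetic_dataset`s,
#'   `d1` ... `dD`), the shared `collection`, and the shared `truth`.
#' @export
simulate_study_collection <- function(config, n_datasets = 2) {
  if (!inherits(config, "synthetic_config"))
    stop("'config' must be a synthetic_config", call. = FALSE)
  if (n_datasets < 2L)
    stop("a study collection needs at least 2 data sets", call. = FALSE)
  first <- if (config$n_subtypes > 0L) simulate_type2(config)
           else simulate_type1(config)
  datasets <- stats::setNames(vector("list", n_datasets),
                              paste0("d", seq_len(n_datasets)))
  datasets[[1L]] <- first
  sds <- config$error_sd
  for (d in 2:n_datasets) {
    set.seed(config$seed + (d - 1L))
    noise <- matrix(stats::rnorm(length(first$signal)),
                    nrow(first$signal), ncol(first$signal))
    noise <- sweep(noise, 2L, sds, "*")
    ds <- first
    ds$matrix <- first$signal + noise
    datasets[[d]] <- ds
  }
  list(datasets = datasets, collection = first$collection,
       truth = first$truth)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic data set:", nrow(x$matrix), "features x",
      ncol(x$matrix), "samples;", sum(x$truth$features$is_deg),
      "true differential features\n")
  if (!is.null(x$collection))
    cat("Annotation layer:", length(x$collection$sets), "sets (",
        sum(x$truth$functions$is_signal_set), "signal )\n")
  invisible(x)
}

#' Write a standard battery of small synthetic data sets
#'
#' Generates and writes, under `dir`: a type I null contrast (no true
#' differential features), a type I contrast with planted effects, a
#' type II contrast with two latent subtypes, and a paired 10 vs 10
#' type II contrast for degradation runs -- each with its design, ground
#' truth, and (where configured) a GMT annotation file with signal and
#' decoy sets -- plus a `manifest.tsv` indexing them.  All data sets are
#' at most 5000 features by 20 samples.
#'
#' @param dir output directory (created if absent).
#' @param seed integer master seed; the suite regenerates identically
#'   from the same seed.
#' @param n_features features per data set (default 2000).
#' @return the manifest path, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1, n_features = 2000) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir))
      stop("cannot create fixture directory: ", dir, call. = FALSE)
  }
  seed <- as.integer(seed)
  specs <- list(
    null_type1 = synthetic_config(n_features = n_features,
                                  deg_fraction = 0, n_sets = 20,
                                  seed = seed),
    deg_type1 = synthetic_config(n_features = n_features,
                                 deg_fraction = 0.05, n_sets = 20,
                                 seed = seed + 1L),
    type2 = synthetic_config(n_features = n_features,
                             deg_fraction = 0.03, n_subtypes = 2,
                             subtype_block_size = 100, n_sets = 20,
                             seed = seed + 2L),
    paired_type2 = synthetic_config(n_features = n_features,
                                    n_test = 10, n_control = 10,
                                    deg_fraction = 0.05, n_subtypes = 2,
                                    subtype_block_size = 100,
                                    n_sets = 20, seed = seed + 3L))
  rows <- list()
  for (nm in names(specs)) {
    ds <- if (specs[[nm]]$n_subtypes > 0L) simulate_type2(specs[[nm]])
          else simulate_type1(specs[[nm]])
    paths <- list(matrix = file.path(dir, paste0(nm, "_matrix.tsv")),
                  design = file.path(dir, paste0(nm, "_design.tsv")),
                  truth = file.path(dir, paste0(nm, "_truth.tsv")),
                  gmt = file.path(dir, paste0(nm, ".gmt")))
    write_expression_matrix(ds$matrix, paths$matrix)
    write_cohort_design(ds$design, paths$design)
    tr <- ds$truth$features
    tr$true_fc <- sprintf("%.15g", tr$true_fc)
    utils::write.table(tr, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    gmt_path <- ""
    if (!is.null(ds$collection)) {
      write_gene_sets(ds$collection, paths$gmt)
      gmt_path <- basename(paths$gmt)
    }
    rows[[nm]] <- data.frame(dataset = nm,
                             matrix = basename(paths$matrix),
                             design = basename(paths$design),
                             truth = basename(paths$truth),
                             gmt = gmt_path, seed = specs[[nm]]$seed,
                             stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
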