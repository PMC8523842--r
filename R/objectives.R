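#' Channel-parsimony objective
#'
#' `NC = K - C`: total channels minus selected channels, maximized so that
#' sparser masks score higher.
#'
#' @param mask 0/1 integer vector over the montage.
#' @return Integer in `[0, K]`.
#' @export
nc_objective <- function(mask) {
  length(mask) - sum(mask == 1L)
}

#' Create an evaluation ledger
#'
#' Counts distinct objective evaluations against a budget and caches results
#' keyed by (task, mask). Cache hits are free: the budget counts distinct
#' (mask, task) computations, and the same mask evaluated for MI and for
#' SSVEP counts twice.
#'
#' @param budget Maximum number of distinct evaluations (`Inf` to disable).
#' @return An environment of class `eval_ledger` with fields `count`,
#'   `hits`, `budget`, and the cache.
#' @export
eval_ledger <- function(budget = 10000L) {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  env$hits <- 0L
  env$budget <- budget
  env$cache <- new.env(parent = emptyenv())
  class(env) <- "eval_ledger"
  env
}

#' @export
print.eval_ledger <- function(x, ...) {
  cat("eval_ledger: ", x$count, " distinct evaluations (budget ", x$budget,
      "), ", x$hits, " cache hits\n", sep = "")
  invisible(x)
}

#' Summarize a ledger for a run manifest
#'
#' @param ledger An [eval_ledger()].
#' @return Named list (count, hits, cache size, budget).
#' @export
ledger_summary <- function(ledger) {
  list(evaluations = ledger$count, cache_hits = ledger$hits,
       cache_size = length(ls(ledger$cache)),
       budget = if (is.finite(ledger$budget)) ledger$budget else -1L)
}

ledger_key <- function(task, mask) paste0(task, ":", paste(mask, collapse = ""))

# Runs compute() under budget accounting. Returns the cached or fresh value,
# or NA_real_ when the cache misses and no budget (<= limit) remains.
ledger_eval <- function(ledger, task, mask, limit, compute) {
  key <- ledger_key(task, mask)
  if (!is.null(ledger$cache[[key]])) {
    ledger$hits <- ledger$hits + 1L
    return(ledger$cache[[key]])
  }
  if (ledger$count >= min(limit, ledger$budget)) return(NA_real_)
  val <- compute()
  ledger$count <- ledger$count + 1L
  ledger$cache[[key]] <- val
  val
}

# deterministic stratified fold assignment (round-robin within class)
stratified_folds <- function(labels, k, cv_seed = 1L) {
  n <- length(labels)
  min_per_class <- min(table(labels))
  if (min_per_class < k) {
    warning("reducing CV folds from ", k, " to ", min_per_class,
            " (fewest trials in a class)")
    k <- min_per_class
  }
  folds <- integer(n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cv_seed)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# median-heuristic RBF kernel width: gamma = 1 / median squared distance
median_gamma <- function(features) {
  d2 <- as.numeric(stats::dist(features))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) return(1)
  1 / med
}

mar_compute <- function(epochs, folds) {
  n <- dim(epochs$data)[1L]
  correct <- 0L
  for (f in sort(unique(folds))) {
    test <- which(folds == f)
    train <- setdiff(seq_len(n), test)
    train_ep <- epoch_set(epochs$data[train, , , drop = FALSE],
                          epochs$labels[train], epochs$fs,
                          epochs$channel_names)
    bank <- csp_fit(train_ep)
    len <- if (bank$single_channel) 1L else 2L * bank$m
    feats <- function(idx) {
      v <- vapply(idx, function(tr) csp_features(trial_matrix(epochs, tr), bank),
                  numeric(len))
      if (len == 1L) matrix(v, ncol = 1L) else t(v)
    }
    xtr <- feats(train); xte <- feats(test)
    model <- e1071::svm(xtr, factor(epochs$labels[train]), kernel = "radial",
                        cost = 1, gamma = median_gamma(xtr), scale = FALSE)
    pred <- stats::predict(model, xte)
    correct <- correct + sum(as.character(pred) ==
                               as.character(epochs$labels[test]))
  }
  correct / n
}

sar_compute <- function(epochs, stim, ref_bases) {
  n <- dim(epochs$data)[1L]
  correct <- 0L
  for (tr in seq_len(n)) {
    x <- trial_matrix(epochs, tr)
    qx <- orthobasis(x)
    scores <- vapply(ref_bases, function(qy) max_cancor(qx, qy), numeric(1))
    pred <- which(scores >= max(scores) - 1e-12)[1L]
    if (pred == epochs$labels[tr]) correct <- correct + 1L
  }
  correct / n
}

#' Build the objective backend for a pair of task datasets
#'
#' Pre-filters the MI epochs (5-30 Hz, zero-phase), precomputes the
#' orthonormal sinusoidal reference bases for every SSVEP stimulus, fixes
#' a deterministic stratified fold assignment, and attaches an evaluation
#' ledger. The returned object maps channel masks to MAR (mean held-out CSP +
#' RBF-SVM accuracy) and SAR (fraction of trials whose argmax canonical
#' correlation matches the stimulus), with caching and budget accounting.
#'
#' SSVEP labels must be integer indices into `stim$frequencies`.
#'
#' @param mi_epochs Two-class MI [epoch_set()] (raw; filtered here).
#' @param ssvep_epochs SSVEP [epoch_set()] labelled by stimulus index.
#' @param stim A [stimulus_spec()].
#' @param budget Evaluation budget (distinct computations).
#' @param cv_folds Stratified folds for MAR.
#' @param cv_seed Seed fixing the fold assignment.
#' @return List of class `emmoa_backend` with functions `mar(mask, limit)`
#'   and `sar(mask, limit)` plus the `ledger`.
#' @export
objective_backend <- function(mi_epochs, ssvep_epochs, stim,
                              budget = 10000L, cv_folds = 5L, cv_seed = 1L) {
  stopifnot(inherits(stim, "stimulus_spec"))
  mi_filt <- bandpass_mi(mi_epochs)
  folds <- stratified_folds(mi_filt$labels, cv_folds, cv_seed)
  n_samples <- dim(ssvep_epochs$data)[3L]
  ref_bases <- lapply(stim$frequencies, function(f) {
    orthobasis(cca_reference(f, n_samples, ssvep_epochs$fs, stim$n_harmonics))
  })
  ledger <- eval_ledger(budget)
  k_mi <- length(mi_epochs$channel_names)
  k_ss <- length(ssvep_epochs$channel_names)

  mar <- function(mask, limit = Inf) {
    stopifnot(length(mask) == k_mi)
    if (sum(mask) == 0L) return(0)   # invalid solution: no budget consumed
    ledger_eval(ledger, "MI", mask, limit, function() {
      mar_compute(select_channels(mi_filt, which(mask == 1L)), folds)
    })
  }
  sar <- function(mask, limit = Inf) {
    stopifnot(length(mask) == k_ss)
    if (sum(mask) == 0L) return(0)
    ledger_eval(ledger, "SSVEP", mask, limit, function() {
      sar_compute(select_channels(ssvep_epochs, which(mask == 1L)),
                  stim, ref_bases)
    })
  }
  structure(list(mar = mar, sar = sar, ledger = ledger, stim = stim,
                 n_channels = k_mi),
            class = "emmoa_backend")
}

#' MI accuracy objective for a channel mask
#'
#' Convenience wrapper: restricts to the selected channels and returns the
#' stratified cross-validated CSP + RBF-SVM accuracy through the backend's
#' ledger. The empty mask scores 0 without consuming budget.
#'
#' @param mask 0/1 mask over the montage.
#' @param backend An [objective_backend()].
#' @param limit Optional evaluation-count ceiling for stage budgeting.
#' @return Accuracy in `[0, 1]`, or `NA` when the budget is exhausted.
#' @export
mar_objective <- function(mask, backend, limit = Inf) backend$mar(mask, limit)

#' SSVEP accuracy objective for a channel mask
#'
#' @inheritParams mar_objective
#' @return Accuracy in `[0, 1]`, or `NA` when the budget is exhausted.
#' @export
sar_objective <- function(mask, backend, limit = Inf) backend$sar(mask, limit)
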