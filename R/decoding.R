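# Stimulation-site decoding from per-trial evoked responses with a linear
# maximum-margin classifier over enumerated or sampled site subsets.

#' Exact binomial coefficient
#'
#' @param n,k non-negative integers, `k <= n`.
#' @return `choose(n, k)` as a numeric scalar (exact for the sizes used
#'   here, e.g. `n_combinations(22, 5)` is 26334).
#' @export
n_combinations <- function(n, k) {
  if (k > n || k < 0 || n < 0) stop("need 0 <= k <= n")
  round(choose(n, k))
}

#' Chance decoding level for k equiprobable classes
#'
#' @param k number of stimulation sites among which the decoder chooses.
#' @return `1 / k`.
#' @export
chance_level <- function(k) {
  if (k < 1) stop("k must be >= 1")
  1 / k
}

#' Enumerate or sample site subsets
#'
#' Returns all `C(n_items, k)` subsets when that count does not exceed
#' `max_subsets`; otherwise samples `max_subsets` distinct subsets
#' uniformly without replacement, deterministically given `seed`.
#'
#' @param n_items pool size (e.g. 22 stimulation sites).
#' @param k subset size.
#' @param max_subsets cap on the number of subsets (default 26334, the full
#'   count at k = 5 from a pool of 22).
#' @param seed RNG seed used only when sampling.
#' @return Integer matrix, one subset per row, elements in `1..n_items`.
#' @export
enumerate_subsets <- function(n_items, k, max_subsets = 26334, seed = 1L) {
  stopifnot(k >= 1, k <= n_items, max_subsets >= 1)
  total <- n_combinations(n_items, k)
  if (total <= max_subsets)
    return(t(combn(n_items, k)))
  with_local_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, max_subsets, k)
    got <- 0L
    while (got < max_subsets) {
      s <- sort(sample.int(n_items, k))
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[got, ] <- s
      }
    }
    out
  })
}

# trials x electrodes feature matrix + site labels for a subset of sites
subset_features <- function(tensor, subset) {
  d <- dim(tensor)
  X <- NULL; y <- integer(0)
  for (j in subset) {
    M <- matrix(unclass(tensor)[j, , ], d[2], d[3])
    X <- rbind(X, M)
    y <- c(y, rep.int(j, d[2]))
  }
  X[is.na(X)] <- 0      # saturated stimulated channel contributes nothing
  list(X = X, y = factor(y))
}

#' Decode stimulation-site identity for one site subset
#'
#' Features are the per-trial evoked spike-count vectors over the target
#' electrodes; labels are the stimulation sites of the subset.  Trials are
#' split stratified per site -- `floor(train_fraction * n_trials)` train
#' (20 of 25 at the defaults), the rest test -- a linear-kernel support
#' vector machine (libsvm via e1071, default regularisation C = 1, no
#' feature scaling) is fit on the training trials, and the test accuracy is
#' returned.
#'
#' @param tensor a [trial_count_tensor()] restricted (in its electrode
#'   dimension) to the target region, e.g. via
#'   `tensor[, , target_electrode_names]` kept as a 3-d array.
#' @param subset integer site indices (rows of the tensor), length >= 2.
#' @param train_fraction fraction of trials per site used for training
#'   (default 0.8).
#' @param seed seed for the stratified split (and label permutation).
#' @param permute_labels permute site labels across trials before the
#'   split -- the chance-level null.
#' @return Test-set accuracy in `[0, 1]`.
#' @export
evaluate_decoder <- function(tensor, subset, train_fraction = 0.8,
                             seed = 1L, permute_labels = FALSE) {
  stopifnot(length(subset) >= 2)
  nt <- dim(tensor)[2]
  n_train <- floor(train_fraction * nt)
  if (n_train < 1 || n_train >= nt)
    stop("train_fraction leaves an empty train or test set")
  f <- subset_features(tensor, subset)
  with_local_seed(seed, {
    if (permute_labels) f$y <- f$y[sample.int(length(f$y))]
    train <- logical(length(f$y))
    for (lev in levels(f$y)) {
      idx <- which(f$y == lev)
      if (length(idx) < 2) stop("a class has fewer than 2 trials")
      train[idx[sample.int(length(idx), n_train)]] <- TRUE
    }
    fit <- e1071::svm(f$X[train, , drop = FALSE], f$y[train],
                      kernel = "linear", scale = FALSE)
    pred <- predict(fit, f$X[!train, , drop = FALSE])
    mean(pred == f$y[!train])
  })
}

#' Decode a whole experiment over site subsets
#'
#' Runs [evaluate_decoder()] over every subset from [enumerate_subsets()]
#' (full enumeration up to `max_subsets`, uniform sampling beyond) and
#' summarises the per-subset accuracies against the `1/k` chance level.
#' Each subset's stratified split uses a subset-derived seed, so results
#' are reproducible subset by subset.
#'
#' @param tensor a [trial_count_tensor()] restricted to the target-region
#'   electrodes.
#' @param k subset (group) size, number of candidate sites per decoding
#'   problem (2, 5, 10 or 15 in the standard protocol).
#' @param max_subsets cap on evaluated subsets (default 26334).
#' @param seed master seed for subset sampling and splits.
#' @param train_fraction per-site training fraction (default 0.8).
#' @param permute_labels chance-level null: permute labels within each
#'   subset before splitting.
#' @return List of class `decoding_result`: `k`, `subsets`, `accuracies`,
#'   `mean_accuracy`, `chance`, `mean_above_chance`, `n_subsets_evaluated`,
#'   `sampling_seed`.
#' @export
decode_experiment <- function(tensor, k = 5, max_subsets = 26334, seed = 1L,
                              train_fraction = 0.8, permute_labels = FALSE) {
  stopifnot(k >= 2)
  ns <- dim(tensor)[1]
  subsets <- enumerate_subsets(ns, k, max_subsets, seed)
  acc <- vapply(seq_len(nrow(subsets)), function(r) {
    s <- subsets[r, ]
    evaluate_decoder(tensor, s, train_fraction,
                     seed = derive_seed(seed, s),
                     permute_labels = permute_labels)
  }, numeric(1))
  structure(list(k = k, subsets = subsets, accuracies = acc,
                 mean_accuracy = mean(acc), chance = chance_level(k),
                 mean_above_chance = mean(acc) - chance_level(k),
                 n_subsets_evaluated = nrow(subsets), sampling_seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(paste0("<decoding_result> k = %d: mean accuracy %.1f%% over %d ",
                     "subsets (chance %.1f%%, +%.1f points)\n"),
              x$k, 100 * x$mean_accuracy, x$n_subsets_evaluated,
              100 * x$chance, 100 * x$mean_above_chance))
  invisible(x)
}
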