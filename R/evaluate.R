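#' Summed cross-entropy loss
#'
#' Negative log-likelihood of the true class summed over a batch of
#' two-class probability vectors, with an epsilon clamp (1e-12) guarding
#' `log(0)`.
#'
#' @param probabilities `B x 2` matrix (rows sum to 1) or length-2 vector.
#' @param labels 0/1 vector (0 = not associated, 1 = associated).
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(probabilities, labels) {
  if (!is.matrix(probabilities)) probabilities <- matrix(probabilities, 1L)
  if (nrow(probabilities) != length(labels))
    stopf("got %d probability rows for %d labels",
          nrow(probabilities), length(labels))
  p_true <- probabilities[cbind(seq_along(labels), labels + 1L)]
  -sum(log(pmax(p_true, 1e-12)))
}

#' Fuse the two module scores
#'
#' Convex combination `y = gamma * y_encoder + (1 - gamma) * y_capsule` of
#' the association probabilities from the context encoder and the capsule
#' scorer.
#'
#' @param y_encoder,y_capsule Association-probability vectors.
#' @param gamma Fusion weight in \[0,1\].
#' @return Fused score vector.
#' @export
fuse_scores <- function(y_encoder, y_capsule, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
    stopf("gamma must lie in [0,1]")
  gamma * y_encoder + (1 - gamma) * y_capsule
}

#' Dataset geometry of the bipartite prediction problem
#'
#' Pair-counting arithmetic underlying fold construction and the class
#' imbalance: total drug--side-effect pairs, unobserved (candidate
#' negative) pairs, and the negative:positive ratio.
#'
#' @param nr,ns Numbers of drugs and side-effects.
#' @param n_positive Number of known associations.
#' @return List with `n_pairs`, `n_unobserved`, `imbalance_ratio`.
#' @export
dataset_geometry <- function(nr, ns, n_positive) {
  n_pairs <- nr * ns
  if (n_positive > n_pairs) stopf("more positives than pairs")
  list(n_pairs = n_pairs,
       n_unobserved = n_pairs - n_positive,
       imbalance_ratio = (n_pairs - n_positive) / n_positive)
}

#' Balanced-negative-sampling cross-validation folds
#'
#' Randomly partitions the known associations into `k` near-equal parts.
#' For each fold, the held-out part forms the test positives; the remaining
#' positives train the model; training negatives are drawn uniformly
#' without replacement from the unobserved pairs, matching the training
#' positives in number. At evaluation time each drug's candidate set is
#' every side-effect outside its training positives (its test positives
#' plus all unobserved pairs).
#'
#' @param A Binary association matrix.
#' @param k Number of folds.
#' @param seed Optional seed (fold assignment and negative sampling).
#' @return List of `k` folds, each with `train_pairs` / `train_labels`
#'   (balanced), `test_positives` (2-column matrix), and `A_train` (the
#'   association matrix with test positives zeroed).
#' @export
make_folds <- function(A, k = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- association_matrix(A)
  pos <- which(A == 1)
  if (length(pos) < k)
    stopf("only %d positives for %d folds", length(pos), k)
  neg <- which(A == 0)
  part <- split(sample(pos), rep_len(seq_len(k), length(pos)))
  lapply(seq_len(k), function(f) {
    test_idx <- part[[f]]
    train_pos <- setdiff(pos, test_idx)
    train_neg <- sample(neg, length(train_pos))
    A_train <- A
    A_train[test_idx] <- 0
    idx2pair <- function(idx) cbind(drug = (idx - 1L) %% nrow(A) + 1L,
                                    side_effect = (idx - 1L) %/% nrow(A) + 1L)
    list(fold = f,
         train_pairs = idx2pair(c(train_pos, train_neg)),
         train_labels = rep(c(1, 0), c(length(train_pos), length(train_neg))),
         test_positives = idx2pair(test_idx),
         A_train = A_train)
  })
}

#' Ranking metrics for one candidate list
#'
#' `auc_score()` is the exact Mann-Whitney statistic (ties count 1/2),
#' identical to the trapezoidal area under the ROC curve over rank
#' thresholds. `aupr_score()` integrates the precision-recall curve by
#' steps (the average of precision at each positive's rank, descending
#' scores, ties broken by ascending index). `recall_at_k()` is the fraction
#' of positives ranked within the top `k`.
#'
#' @param scores Numeric score vector over candidates.
#' @param labels 0/1 vector of the same length.
#' @return Scalar in \[0,1\]; `NA` if either class is empty (`auc`), or if
#'   there are no positives (`aupr`, `recall`).
#' @export
auc_score <- function(scores, labels) {
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' @rdname auc_score
#' @export
aupr_score <- function(scores, labels) {
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  precision_at <- cumsum(lab) / seq_along(lab)
  sum(precision_at[lab == 1]) / npos
}

#' @rdname auc_score
#' @param k Top-k cutoff.
#' @export
recall_at_k <- function(scores, labels, k) {
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  ord <- order(-scores, seq_along(scores))
  sum(labels[ord][seq_len(min(k, length(ord)))]) / npos
}

#' Per-drug evaluation of one fold's scores
#'
#' For each drug with at least one test positive, computes AUC, AUPR, and
#' recall at every requested `k` over that drug's candidate set, then
#' averages across drugs (drugs without test positives are excluded, their
#' metrics being undefined).
#'
#' @param score_fn Function `(pairs) -> scores` for a 2-column (drug,
#'   side-effect) index matrix (ignored when `scores` is given).
#' @param fold One fold from [make_folds()].
#' @param recall_ks Top-k cutoffs.
#' @param scores Optional precomputed score vector in the canonical
#'   candidate order (drugs ascending, side-effects ascending within drug),
#'   as returned in the `scores` element.
#' @param shuffle Permute each drug's candidate scores (uses the current
#'   RNG state) -- the label-permutation null used as a calibration
#'   reference.
#' @return List with the per-drug data frame (`per_drug`), averaged `auc`,
#'   `aupr`, `recall` (named by k), and the `scores` used.
#' @export
evaluate_fold <- function(score_fn, fold, recall_ks = seq(30, 240, by = 30),
                          scores = NULL, shuffle = FALSE) {
  A_train <- fold$A_train
  test_pos <- fold$test_positives
  drugs <- sort(unique(test_pos[, 1L]))
  ## score all candidates of all test drugs in one call
  cand_list <- lapply(drugs, function(i) {
    js <- which(A_train[i, ] == 0)          # everything outside training positives
    cbind(i, js)
  })
  all_pairs <- do.call(rbind, cand_list)
  all_scores <- scores %||% score_fn(all_pairs)
  offsets <- c(0L, cumsum(vapply(cand_list, nrow, integer(1))))
  if (shuffle)
    for (d in seq_along(drugs)) {
      idx <- (offsets[d] + 1L):offsets[d + 1L]
      all_scores[idx] <- sample(all_scores[idx])
    }
  rows <- lapply(seq_along(drugs), function(d) {
    i <- drugs[d]
    idx <- (offsets[d] + 1L):offsets[d + 1L]
    js <- cand_list[[d]][, 2L]
    sc <- all_scores[idx]
    lab <- as.integer(js %in% test_pos[test_pos[, 1L] == i, 2L])
    rec <- vapply(recall_ks, function(k) recall_at_k(sc, lab, k), numeric(1))
    c(drug = i, n_test_pos = sum(lab), n_candidates = length(js),
      auc = auc_score(sc, lab), aupr = aupr_score(sc, lab),
      stats::setNames(rec, paste0("recall_at_", recall_ks)))
  })
  per_drug <- as.data.frame(do.call(rbind, rows))
  list(per_drug = per_drug,
       auc = mean(per_drug$auc, na.rm = TRUE),
       aupr = mean(per_drug$aupr, na.rm = TRUE),
       recall = colMeans(per_drug[grep("^recall_at_", names(per_drug))],
                         na.rm = TRUE),
       scores = all_scores)
}
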