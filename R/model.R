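#' Fit the full association model
#'
#' Builds the two heterogeneous graphs from the (training) association
#' matrix and the three similarity matrices, then trains the context
#' encoder and the capsule scorer independently on their own cross-entropy
#' losses over balanced positive/negative pairs (negatives sampled
#' uniformly from the unobserved pairs, one per positive, unless training
#' pairs are supplied). The two scores are fused only at prediction time.
#'
#' @param A Binary association matrix (drugs x side-effects).
#' @param D_che,D_dis Drug similarity matrices (chemical-substructure and
#'   disease-based modalities).
#' @param S Side-effect similarity matrix.
#' @param config An [adverank_config()].
#' @param train_pairs,train_labels Optional explicit training set (2-column
#'   index matrix + 0/1 labels), e.g. from [make_folds()].
#' @param seed Seed for negative sampling, initialization, and batching
#'   (default `config$seed`).
#' @param verbose Print per-epoch losses.
#' @return An `adverank_model`: graphs, trained encoder and capsule
#'   parameters, cached node encodings, loss traces, and the config.
#' @export
adverank_fit <- function(A, D_che, D_dis, S, config = adverank_config(),
                         train_pairs = NULL, train_labels = NULL,
                         seed = config$seed, verbose = FALSE) {
  A <- association_matrix(A)
  graphs <- list(che = build_adjacency(D_che, A, S, modality = "che"),
                 dis = build_adjacency(D_dis, A, S, modality = "dis"))
  set.seed(seed)
  if (is.null(train_pairs)) {
    pos <- which(A == 1)
    neg_pool <- which(A == 0)
    neg <- sample(neg_pool, min(length(pos), length(neg_pool)))
    idx <- c(pos, neg)
    train_pairs <- cbind((idx - 1L) %% nrow(A) + 1L,
                         (idx - 1L) %/% nrow(A) + 1L)
    train_labels <- rep(c(1, 0), c(length(pos), length(neg)))
  }
  enc <- train_context_encoder(graphs, train_pairs, train_labels, config,
                               verbose = verbose)
  cap <- train_capsule_net(graphs, train_pairs, train_labels, config,
                           verbose = verbose)
  fwd <- context_encoder_forward(enc$params, graphs, enc$nbrs, config)
  structure(list(graphs = graphs, config = config,
                 encoder = enc$params, encoder_nbrs = enc$nbrs,
                 encoder_fwd = fwd,
                 capsule = cap$params,
                 traces = list(encoder = enc$trace, capsule = cap$trace),
                 A = A, seed = seed),
            class = "adverank_model")
}

#' @export
print.adverank_model <- function(x, ...) {
  cat(sprintf(paste0("adverank model: %d drugs x %d side-effects ",
                     "(%d known associations)\n"),
              nrow(x$A), ncol(x$A), sum(x$A)))
  cat(sprintf("  encoder final loss %.4f | capsule final loss %.4f | gamma %.2f\n",
              utils::tail(x$traces$encoder, 1), utils::tail(x$traces$capsule, 1),
              x$config$gamma))
  invisible(x)
}

#' Fused association scores for drug--side-effect pairs
#'
#' @param model An `adverank_model`.
#' @param pairs Two-column (drug index, side-effect index) matrix.
#' @param components Also return the two module scores.
#' @return Vector of fused association probabilities (or a data frame when
#'   `components = TRUE`).
#' @export
predict_pairs <- function(model, pairs, components = FALSE) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  y_enc <- encoder_pair_scores(model$encoder, model$encoder_fwd,
                               model$graphs$che$nr, pairs)[, 2L]
  y_cap <- capsule_pair_scores(model$capsule, model$graphs, pairs,
                               model$config)
  y <- fuse_scores(y_enc, y_cap, model$config$gamma)
  if (components)
    data.frame(drug = pairs[, 1L], side_effect = pairs[, 2L],
               encoder = y_enc, capsule = y_cap, fused = y)
  else y
}

#' Rank candidate side-effects for one drug
#'
#' Scores every side-effect not already associated with the drug in the
#' model's training matrix and returns them sorted by descending fused
#' score, ties broken by ascending side-effect index.
#'
#' @param model An `adverank_model`.
#' @param drug Drug identifier (name) or index.
#' @param top Optional cutoff (e.g. 15 for a case-study table).
#' @return Data frame with `drug_id`, `side_effect_id`, `score`, `rank`.
#' @export
rank_candidates <- function(model, drug, top = NULL) {
  A <- model$A
  if (is.character(drug)) {
    i <- match(drug, rownames(A))
    if (is.na(i)) stopf("unknown drug id: %s", drug)
  } else {
    i <- as.integer(drug)
    if (is.na(i) || i < 1L || i > nrow(A)) stopf("drug index out of range")
  }
  js <- which(A[i, ] == 0)
  if (length(js) == 0L)
    return(data.frame(drug_id = character(), side_effect_id = character(),
                      score = numeric(), rank = integer()))
  sc <- predict_pairs(model, cbind(i, js))
  ord <- order(-sc, js)
  out <- data.frame(drug_id = rownames(A)[i],
                    side_effect_id = colnames(A)[js[ord]],
                    score = sc[ord], rank = seq_along(ord))
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Nearest-neighbor baseline scores
#'
#' Reference predictor used to certify that a benchmark carries learnable
#' signal: the score of pair (i, j) is the mean association with j among
#' the `nt` drugs most similar to drug i (self included).
#'
#' @param A Binary (training) association matrix.
#' @param D Drug similarity matrix.
#' @param nt Neighborhood size.
#' @return `nr x ns` score matrix.
#' @export
nn_baseline <- function(A, D, nt = 10) {
  t(vapply(seq_len(nrow(A)), function(i) {
    nb <- same_type_neighbors(D, i, nt)
    colMeans(A[nb, , drop = FALSE])
  }, numeric(ncol(A))))
}

#' Five-fold cross-validation of the full model
#'
#' Runs the balanced-negative-sampling protocol: for every fold the model
#' is retrained from scratch on the training associations (test positives
#' zeroed out of the graphs and attribute vectors), every drug's candidate
#' side-effects are scored with the fused model, and per-drug AUC / AUPR /
#' recall at k are averaged per fold and then across folds. A
#' score-permutation null (each drug's candidate scores shuffled) is
#' evaluated alongside as a calibration reference.
#'
#' @param A,D_che,D_dis,S Input matrices as in [adverank_fit()].
#' @param config An [adverank_config()].
#' @param seed Base seed; fold f trains with seed `seed + f`.
#' @param verbose Print per-fold progress.
#' @return An `adverank_cv` object: per-fold metrics, overall `auc`,
#'   `aupr`, `recall`, and the permuted-null `null_auc`.
#' @export
cross_validate <- function(A, D_che, D_dis, S, config = adverank_config(),
                           seed = config$seed, verbose = FALSE) {
  A <- association_matrix(A)
  folds <- make_folds(A, config$folds, seed = seed)
  fold_res <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    if (verbose) message(sprintf("fold %d/%d: training", f, length(folds)))
    model <- adverank_fit(fold$A_train, D_che, D_dis, S, config,
                          train_pairs = fold$train_pairs,
                          train_labels = fold$train_labels,
                          seed = seed + f, verbose = FALSE)
    ev <- evaluate_fold(function(p) predict_pairs(model, p), fold,
                        recall_ks = config$recall_ks)
    null_ev <- evaluate_fold(NULL, fold, recall_ks = config$recall_ks,
                             scores = ev$scores, shuffle = TRUE)
    fold_res[[f]] <- list(fold = f, eval = ev, null_auc = null_ev$auc,
                          traces = model$traces)
    if (verbose)
      message(sprintf("fold %d: AUC %.4f AUPR %.4f (null AUC %.4f)",
                      f, ev$auc, ev$aupr, null_ev$auc))
  }
  aucs <- vapply(fold_res, function(r) r$eval$auc, numeric(1))
  auprs <- vapply(fold_res, function(r) r$eval$aupr, numeric(1))
  recalls <- do.call(rbind, lapply(fold_res, function(r) r$eval$recall))
  structure(list(folds = fold_res,
                 auc = mean(aucs), aupr = mean(auprs),
                 recall = colMeans(recalls),
                 null_auc = mean(vapply(fold_res, function(r) r$null_auc,
                                        numeric(1))),
                 fold_auc = aucs, fold_aupr = auprs,
                 config = config, seed = seed),
            class = "adverank_cv")
}

#' @export
print.adverank_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (per-drug averaged metrics)\n",
              length(x$folds)))
  cat(sprintf("  mean AUC  %.4f   (fold range %.4f-%.4f, permuted null %.4f)\n",
              x$auc, min(x$fold_auc), max(x$fold_auc), x$null_auc))
  cat(sprintf("  mean AUPR %.4f\n", x$aupr))
  cat("  recall:", paste(sprintf("%s=%.3f", names(x$recall), x$recall),
                         collapse = " "), "\n")
  invisible(x)
}
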