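#' Model and training configuration
#'
#' Collects every tunable of the pipeline in one validated list. Defaults
#' follow the reference setting of the method: neighborhood sizes
#' `nt = nk = 10`, two encoder layers with 8 attention heads and output
#' dimensionalities 2400 and 2000, 64 first-stage convolution filters,
#' `w = 8` convolution groups (views) with 2x2 kernels, digit-capsule
#' dimension 32 with 3 routing iterations, fusion weight `gamma = 0.3`,
#' Adam with learning rate 1e-3, batch size 128, 50 epochs, five folds.
#'
#' The context encoder is transductive -- every parameter update requires
#' re-encoding the whole graph -- so it trains full-batch by default
#' (`encoder_batch_size = Inf`); the capsule scorer keeps per-pair
#' mini-batches.
#'
#' @param nt,nk Same-type / cross-type neighborhood sizes.
#' @param layers Number of encoder layers.
#' @param heads Attention heads per layer.
#' @param dims Integer vector of per-layer output dimensionalities
#'   (length `layers`, each divisible by `heads`).
#' @param att_dim Width of the category-attention tanh bottleneck.
#' @param scaled_attention If `TRUE`, scale attention scores by
#'   `1/sqrt(head_dim)` (the conventional transformer variant; the method
#'   itself defines unscaled scores, the default).
#' @param nf First convolution stage filter count.
#' @param w Number of convolution groups = views = primary-capsule dimension.
#' @param filters_per_group Optional inner channel expansion per view group;
#'   values > 1 apply that many 2x2 filters per group and reduce them to one
#'   view map by channel mean.
#' @param capsule_dim Digit-capsule dimensionality.
#' @param routing_iters Dynamic-routing iterations.
#' @param gamma Score-fusion weight on the encoder probability,
#'   `y = gamma * y_encoder + (1 - gamma) * y_capsule`.
#' @param lr,epochs,batch_size Shared Adam defaults.
#' @param encoder_lr,encoder_epochs,encoder_batch_size Encoder overrides.
#' @param capsule_lr,capsule_epochs,capsule_batch_size Capsule overrides.
#' @param folds Cross-validation fold count.
#' @param recall_ks Top-k cutoffs for recall reporting.
#' @param seed Base random seed (folds, negative sampling, initialization).
#' @return A classed list (`adverank_config`).
#' @export
adverank_config <- function(nt = 10, nk = 10,
                            layers = 2, heads = 8, dims = c(2400, 2000),
                            att_dim = 64, scaled_attention = FALSE,
                            nf = 64, w = 8, filters_per_group = 1,
                            capsule_dim = 32, routing_iters = 3,
                            gamma = 0.3,
                            lr = 1e-3, epochs = 50, batch_size = 128,
                            encoder_lr = NULL, encoder_epochs = NULL,
                            encoder_batch_size = Inf,
                            capsule_lr = NULL, capsule_epochs = NULL,
                            capsule_batch_size = NULL,
                            folds = 5, recall_ks = seq(30, 240, by = 30),
                            seed = 1L) {
  cfg <- list(nt = nt, nk = nk, layers = layers, heads = heads, dims = dims,
              att_dim = att_dim, scaled_attention = isTRUE(scaled_attention),
              nf = nf, w = w, filters_per_group = filters_per_group,
              capsule_dim = capsule_dim, routing_iters = routing_iters,
              gamma = gamma, lr = lr, epochs = epochs, batch_size = batch_size,
              encoder_lr = encoder_lr %||% lr,
              encoder_epochs = encoder_epochs %||% epochs,
              encoder_batch_size = encoder_batch_size,
              capsule_lr = capsule_lr %||% lr,
              capsule_epochs = capsule_epochs %||% epochs,
              capsule_batch_size = capsule_batch_size %||% batch_size,
              folds = folds, recall_ks = recall_ks, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "adverank_config")
}

validate_config <- function(cfg) {
  if (!is_count(cfg$nt)) stopf("nt must be a positive integer")
  if (!is_count(cfg$nk, min = 0L)) stopf("nk must be a non-negative integer")
  if (!is_count(cfg$layers)) stopf("layers must be >= 1")
  if (length(cfg$dims) != cfg$layers)
    stopf("dims must have one entry per layer (%d)", cfg$layers)
  if (any(cfg$dims %% cfg$heads != 0))
    stopf("every layer dimensionality must be divisible by heads = %d", cfg$heads)
  if (!is_count(cfg$routing_iters)) stopf("routing_iters must be >= 1")
  if (cfg$gamma < 0 || cfg$gamma > 1) stopf("gamma must lie in [0,1]")
  if (!is_count(cfg$epochs, min = 0L) || !is_count(cfg$encoder_epochs, min = 0L) ||
      !is_count(cfg$capsule_epochs, min = 0L))
    stopf("epoch counts must be non-negative integers")
  if (!is_count(cfg$folds, min = 2L)) stopf("folds must be >= 2")
  invisible(cfg)
}

## Merge user overrides (e.g. from YAML or CLI flags) into a full config.
config_with_overrides <- function(overrides = list()) {
  known <- names(formals(adverank_config))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) > 0)
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  do.call(adverank_config, overrides)
}

#' Reduced configuration for the planted synthetic benchmark
#'
#' The reference hyper-parameters are sized for the full 708 x 4192 data;
#' on the 60 x 120 planted benchmark the same architecture is used at a
#' width that matches the much smaller attribute dimension (180 instead of
#' 4900): 4 heads, two 32-dimensional encoder layers, 8 first-stage filters,
#' 4 views, 8-dimensional digit capsules. Training lengths are chosen for a
#' single-CPU run.
#'
#' @param seed Base seed.
#' @return An `adverank_config`.
#' @export
benchmark_config <- function(seed = 20260923L) {
  adverank_config(
    nt = 10, nk = 10,
    layers = 2, heads = 4, dims = c(32, 32), att_dim = 16,
    nf = 8, w = 4, capsule_dim = 8, routing_iters = 3,
    gamma = 0.3,
    encoder_lr = 5e-3, encoder_epochs = 40, encoder_batch_size = Inf,
    capsule_lr = 1e-2, capsule_epochs = 10, capsule_batch_size = 128,
    folds = 5, seed = seed)
}
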