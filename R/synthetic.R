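#' Specification of a synthetic drug--side-effect dataset
#'
#' The generator plants block structure: drugs and side-effects are
#' assigned to `n_blocks` co-association groups; pairs whose drug and
#' side-effect share a block associate at a high within-block rate, others
#' at a low background rate, and the resulting matrix is perturbed by
#' independent flips. Drug similarities come from noisy binary fingerprints
#' built around per-block prototypes -- two independently re-noised copies
#' give the two correlated-but-distinct similarity modalities -- and the
#' side-effect similarity is the cosine similarity of the association
#' columns.
#'
#' The within-block rate is derived so that the expected overall positive
#' rate equals `density`: with equal blocks a fraction `1/n_blocks` of the
#' pairs is within-block, the background rate is `background * density`,
#' and the within-block rate absorbs the rest.
#'
#' @param nr,ns Numbers of drugs and side-effects.
#' @param n_blocks Number of planted co-association groups.
#' @param density Overall expected positive rate, in (0,1).
#' @param noise Independent flip probability applied to every entry of the
#'   planted matrix, in \[0, 0.5).
#' @param profile_dim Latent fingerprint length.
#' @param background Fraction of the density assigned to out-of-block
#'   pairs (0 gives a strictly block-diagonal pattern before noise).
#' @param seed Seed used by [generate_synthetic()].
#' @return A classed list (`synthetic_spec`).
#' @export
synthetic_spec <- function(nr = 60, ns = 120, n_blocks = 4, density = 0.15,
                           noise = 0.02, profile_dim = 64,
                           background = 0.15, seed = 1L) {
  if (!is_count(nr) || !is_count(ns) || !is_count(n_blocks))
    stopf("nr, ns, n_blocks must be positive integers")
  if (density <= 0 || density >= 1) stopf("density must lie in (0,1)")
  if (noise < 0 || noise >= 0.5) stopf("noise must lie in [0, 0.5)")
  if (background < 0 || background > 1) stopf("background must lie in [0,1]")
  p_out <- background * density
  p_in <- n_blocks * (density - (1 - 1 / n_blocks) * p_out)
  if (p_in > 1)
    stopf("density %.3f is not reachable with %d blocks (within-block rate %.3f > 1)",
          density, n_blocks, p_in)
  structure(list(nr = nr, ns = ns, n_blocks = n_blocks, density = density,
                 noise = noise, profile_dim = profile_dim,
                 background = background, p_in = p_in, p_out = p_out,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Block assignment with a bounded number of re-draws when a block comes
## out empty.
draw_blocks <- function(n, n_blocks) {
  for (attempt in 1:10) {
    b <- sample.int(n_blocks, n, replace = TRUE)
    if (length(unique(b)) == n_blocks) return(b)
  }
  stopf("could not populate all %d blocks with %d members after 10 draws",
        n_blocks, n)
}

flip_bits <- function(m, p) {
  if (p <= 0) return(m)
  f <- matrix(stats::runif(length(m)) < p, nrow(m))
  m[f] <- 1 - m[f]
  m
}

## Binary profile rows must not be all-zero (cosine undefined); force one
## random bit on in such rows.
fix_zero_rows <- function(m) {
  z <- which(rowSums(m) == 0)
  for (i in z) m[i, sample.int(ncol(m), 1L)] <- 1
  m
}

#' Generate a synthetic dataset with planted block structure
#'
#' @param spec A [synthetic_spec()].
#' @return List with `A` (binary association matrix), `D_che`, `D_dis`
#'   (drug similarities from the two fingerprint modalities), `S`
#'   (side-effect similarity, cosine over association columns), the
#'   ground-truth `blocks` (`$drug`, `$side_effect`), and the `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  drug_block <- draw_blocks(spec$nr, spec$n_blocks)
  se_block <- draw_blocks(spec$ns, spec$n_blocks)
  p <- ifelse(outer(drug_block, se_block, "=="), spec$p_in, spec$p_out)
  A <- matrix(as.numeric(stats::runif(spec$nr * spec$ns) < p), spec$nr)
  A <- flip_bits(A, spec$noise)
  A <- association_matrix(A)
  ## per-block fingerprint prototypes; each drug flips 10% of its
  ## prototype, and the second modality re-flips independently
  proto <- matrix(as.numeric(stats::runif(spec$n_blocks * spec$profile_dim)
                             < 0.4),
                  spec$n_blocks)
  prof <- fix_zero_rows(flip_bits(proto[drug_block, , drop = FALSE], 0.1))
  prof2 <- fix_zero_rows(flip_bits(prof, 0.1))
  D_che <- cosine_profile_similarity(prof, ids = rownames(A), modality = "che")
  D_dis <- cosine_profile_similarity(prof2, ids = rownames(A), modality = "dis")
  S <- suppressWarnings(
    cosine_profile_similarity(t(A), ids = colnames(A)))
  list(A = A, D_che = D_che, D_dis = D_dis, S = S,
       blocks = list(drug = drug_block, side_effect = se_block),
       spec = spec)
}

#' Hand-checkable worked fixture (6 drugs x 8 side-effects)
#'
#' A fixed literal dataset small enough to verify every operation by hand:
#' two planted co-association groups (drugs 1-3 with side-effects 1-4,
#' drugs 4-6 with 5-8, plus a few cross links), literal binary fingerprints
#' for the chemical modality, a second modality obtained by flipping a few
#' fingerprint bits, and the cosine side-effect similarity. No randomness
#' is involved.
#'
#' @return Same structure as [generate_synthetic()] (without `blocks`).
#' @export
worked_fixture <- function() {
  A <- matrix(c(
    1, 1, 0, 1, 0, 0, 0, 0,
    1, 0, 1, 1, 0, 0, 0, 1,
    0, 1, 1, 1, 1, 0, 0, 0,
    0, 0, 0, 0, 1, 1, 0, 1,
    1, 0, 0, 0, 1, 0, 1, 1,
    0, 0, 0, 0, 0, 1, 1, 1), nrow = 6, byrow = TRUE)
  A <- association_matrix(A, sprintf("drug_%d", 1:6), sprintf("se_%d", 1:8))
  prof <- matrix(c(
    1, 1, 1, 0, 0, 1, 0, 0, 1, 0,
    1, 1, 0, 1, 0, 1, 0, 0, 1, 0,
    1, 0, 1, 1, 0, 1, 1, 0, 0, 0,
    0, 0, 0, 1, 1, 0, 1, 1, 0, 1,
    0, 1, 0, 0, 1, 0, 1, 1, 0, 1,
    0, 0, 0, 0, 1, 1, 1, 1, 0, 1), nrow = 6, byrow = TRUE)
  prof2 <- prof
  prof2[1, 4] <- 1; prof2[2, 3] <- 1; prof2[3, 2] <- 1
  prof2[4, 1] <- 1; prof2[5, 10] <- 0; prof2[6, 5] <- 0
  list(A = A,
       D_che = cosine_profile_similarity(prof, rownames(A), "che"),
       D_dis = cosine_profile_similarity(prof2, rownames(A), "dis"),
       S = cosine_profile_similarity(t(A), colnames(A)),
       profiles = prof)
}
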