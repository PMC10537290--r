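# Shared small fixtures built in code.

tiny_config <- function(...) {
  adverank_config(nt = 4, nk = 3, layers = 2, heads = 2, dims = c(6, 4),
                  att_dim = 5, nf = 3, w = 2, capsule_dim = 4,
                  routing_iters = 3, ...)
}

fixture_graphs <- function() {
  fx <- worked_fixture()
  list(che = build_adjacency(fx$D_che, fx$A, fx$S, modality = "che"),
       dis = build_adjacency(fx$D_dis, fx$A, fx$S, modality = "dis"))
}

## the 2-drug / 1-side-effect worked example used across graph tests
two_drug_example <- function() {
  list(D = similarity_matrix(matrix(c(1, .5, .5, 1), 2)),
       A = association_matrix(matrix(c(1, 0), 2, 1)),
       S = similarity_matrix(matrix(1, 1, 1)))
}

random_similarity <- function(n) {
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  similarity_matrix(m)
}

random_association <- function(nr, ns, p = 0.3) {
  association_matrix(matrix(as.numeric(stats::runif(nr * ns) < p), nr))
}
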