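# Binarize a probability matrix into a contact_graph (off-diagonal,
# symmetric). With top_k set, the k strongest off-diagonal pairs are kept
# instead of thresholding.
.binarize_graph <- function(P, Fm, threshold = 0.5, top_k = NULL,
                            id = "generated") {
  n <- nrow(P)
  E <- matrix(0, n, n)
  if (is.null(top_k)) {
    E[P >= threshold] <- 1
  } else {
    ut <- which(upper.tri(P))
    keep <- ut[order(P[ut], decreasing = TRUE)[seq_len(min(top_k,
                                                           length(ut)))]]
    E[keep] <- 1
    E <- E + t(E)
  }
  E <- ((E + t(E)) > 0) * 1
  diag(E) <- 0
  contact_graph(E, Fm, has_self_loops = FALSE, id = id)
}

#' Sample contact graphs from the prior
#'
#' Draws latent codes from the isotropic Gaussian prior `N(0, I)`, decodes
#' each into edge probabilities and binarizes: `E[i, j] = 1` iff
#' `P[i, j] >= threshold` (off-diagonal; the result is symmetric, binary,
#' zero-diagonal).
#'
#' @param state A trained [init_model_state()].
#' @param F N x 20 one-hot node attribute matrix (the protein's sequence).
#' @param n Number of graphs to generate.
#' @param threshold Binarization cutoff in (0, 1]; default 0.5.
#' @param top_k Optional: keep the `top_k` strongest contacts instead of
#'   thresholding (reconstruction tools often want fixed contact counts).
#' @param seed Integer seed; the generated set is reproducible given it.
#' @return A [graph_dataset()] with `n` graphs.
#' @export
sample_graphs <- function(state, F, n, threshold = 0.5, top_k = NULL,
                          seed = NULL) {
  stopifnot(inherits(state, "model_state"), n >= 1)
  F <- as.matrix(F)
  if (nrow(F) != state$params$n_residues ||
      ncol(F) != state$params$node_attr_dim)
    stop("node attribute matrix does not match the model's shape")
  H <- state$params$latent_dim
  Z <- local_seed(seed, matrix(stats::rnorm(n * H), n, H))
  graphs <- vector("list", n)
  for (i in seq_len(n)) {
    P <- .decoder_forward(Z[i, ], F, state)$P
    graphs[[i]] <- .binarize_graph(P, F, threshold = threshold,
                                   top_k = top_k,
                                   id = sprintf("gen_%04d", i))
  }
  graph_dataset(graphs)
}

#' Reconstruct a graph through the model
#'
#' Encode, take the posterior mean (or a reparameterized sample), decode.
#'
#' @param graph A [contact_graph()].
#' @param state A trained [init_model_state()].
#' @param use_mean Use `z = mu` (deterministic); otherwise sample via
#'   [reparameterize()].
#' @param seed Seed for the sampled case.
#' @return N x N edge probability matrix.
#' @export
reconstruct <- function(graph, state, use_mean = TRUE, seed = NULL) {
  stopifnot(inherits(graph, "contact_graph"), inherits(state, "model_state"))
  post <- encode(graph, state)
  z <- if (use_mean) post$mu else reparameterize(post, seed = seed)
  decode(z, graph$F, state)
}
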