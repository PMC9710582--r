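#' Traverse one latent coordinate
#'
#' Disentanglement inspection: decode a series of latent codes that differ
#' only in coordinate `dim`, which sweeps over `values` while every other
#' coordinate stays at `base_z`. The decoder is deterministic, so the
#' series isolates what that latent factor controls. The default grid
#' spans 1 to 10,000 in five log-spaced points — far outside the N(0, 1)
#' prior, which makes the factor's effect easy to see but the graphs
#' correspondingly extreme.
#'
#' @param state A trained [init_model_state()].
#' @param F N x 20 one-hot node attribute matrix.
#' @param dim Latent coordinate index (1-based, <= H).
#' @param values Numeric grid for the traversed coordinate
#'   (default `10^(0:4)`).
#' @param base_z Baseline latent code; default the prior mean (zeros).
#' @param threshold Binarization cutoff.
#' @return List of [contact_graph()]s, one per grid value.
#' @export
traverse_latent <- function(state, F, dim, values = 10^(0:4),
                            base_z = NULL, threshold = 0.5) {
  stopifnot(inherits(state, "model_state"), length(values) >= 1)
  H <- state$params$latent_dim
  if (dim < 1L || dim > H) stop("dim out of range (H = ", H, ")")
  if (is.null(base_z)) base_z <- numeric(H)
  if (length(base_z) != H) stop("base_z must have length H")
  F <- as.matrix(F)
  lapply(seq_along(values), function(i) {
    z <- base_z
    z[dim] <- values[i]
    P <- decode(z, F, state)
    .binarize_graph(P, F, threshold = threshold,
                    id = sprintf("z%d=%g", dim, values[i]))
  })
}

#' Signed difference maps along a traversal series
#'
#' For consecutive graphs in a series, `E[k+1] - E[k]`: +1 marks a contact
#' appearing, -1 a contact disappearing. The number of flipped cells per
#' step is attached as the `"flips"` attribute (always even, by symmetry).
#'
#' @param series List of >= 2 [contact_graph()]s with equal N (e.g. from
#'   [traverse_latent()]).
#' @return List of N x N matrices with entries in \{-1, 0, 1\}, of length
#'   `length(series) - 1`, with attribute `flips` (integer vector).
#' @export
diff_maps <- function(series) {
  if (length(series) < 2L) stop("need at least 2 graphs")
  n <- series[[1]]$n_residues
  for (g in series)
    if (!inherits(g, "contact_graph") || g$n_residues != n)
      stop("series must be contact graphs of equal N")
  out <- vector("list", length(series) - 1L)
  flips <- integer(length(out))
  for (k in seq_along(out)) {
    d <- series[[k + 1L]]$E - series[[k]]$E
    out[[k]] <- d
    flips[k] <- sum(d != 0)
  }
  attr(out, "flips") <- flips
  out
}
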