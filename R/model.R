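# log-sigma is clamped to this range before exponentiation; gradients are
# masked to zero on the clamp boundary
.LOGSIG_MIN <- -15
.LOGSIG_MAX <- 15

#' Architecture hyperparameters of the contact-graph VAE
#'
#' @param n_residues N, the (fixed) number of residues the model is built
#'   for.
#' @param latent_dim H, the latent dimensionality. Default 10.
#' @param encoder_widths Channel counts of the two graph-convolution
#'   (edge-convolution) layers preceding the mean/standard-deviation paths.
#' @param decoder_widths Two widths: the fully-connected/node-deconvolution
#'   width and the pairwise edge-deconvolution channel count.
#' @param beta Nonnegative KL weight; `beta = 1` is the plain VAE objective,
#'   `beta > 1` pushes the posterior toward the isotropic Gaussian prior and
#'   so encourages disentangled latent factors.
#' @param node_attr_dim Width of the one-hot node attributes (20 amino-acid
#'   types).
#' @return Object of class `vae_params`.
#' @export
vae_params <- function(n_residues, latent_dim = 10L,
                       encoder_widths = c(32L, 32L),
                       decoder_widths = c(32L, 32L),
                       beta = 1, node_attr_dim = 20L) {
  stopifnot(latent_dim >= 1L, beta >= 0,
            length(encoder_widths) == 2L, all(encoder_widths >= 1L),
            length(decoder_widths) == 2L, all(decoder_widths >= 1L),
            n_residues >= 2L)
  structure(list(n_residues = as.integer(n_residues),
                 latent_dim = as.integer(latent_dim),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 beta = as.numeric(beta),
                 node_attr_dim = as.integer(node_attr_dim)),
            class = "vae_params")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model weights
#'
#' Glorot-uniform initialization of every trainable tensor, seeded. The
#' encoder holds two GCN layers plus one GCN path each for the posterior
#' mean and log standard deviation; the decoder holds a fully connected
#' layer on the latent code, a node-deconvolution layer on the concatenated
#' `[z' || f_i]` features (shared weights plus a trainable per-node bias,
#' the positional filters of a transposed convolution in collapsed form)
#' and a two-stage symmetric pairwise edge-deconvolution scorer.
#'
#' @param params A [vae_params()].
#' @param seed Integer seed for the initialization draw.
#' @return Object of class `model_state`: a named list of weight arrays
#'   with the generating `params` and `seed` attached.
#' @export
init_model_state <- function(params, seed = 1L) {
  stopifnot(inherits(params, "vae_params"))
  L2 <- params$node_attr_dim
  c1 <- params$encoder_widths[1]; c2 <- params$encoder_widths[2]
  H <- params$latent_dim
  d <- params$decoder_widths[1]; k <- params$decoder_widths[2]
  w <- local_seed(seed, list(
    W_enc1 = glorot(L2, c1),
    W_enc2 = glorot(c1, c2),
    W_mu   = glorot(c2, H),  b_mu = numeric(H),
    # log-sigma readout starts at -1 so the posterior is narrow at
    # initialization and the reconstruction signal reaches the encoder
    # before reparameterization noise drowns it
    W_sig  = glorot(c2, H),  b_sig = rep(-1, H),
    W_fc   = glorot(H, d),  b_fc = numeric(d),
    W_nd   = glorot(d + L2, d), b_nd = numeric(d),
    B_nd   = glorot(params$n_residues, d),
    W_e1   = glorot(d, k),  b_e1 = numeric(k),
    w_e2   = as.vector(glorot(k, 1L)), b_e2 = 0
  ))
  structure(c(w, list(params = params, seed = as.integer(seed))),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  p <- x$params
  cat("contact-graph VAE weights: N =", p$n_residues,
      " H =", p$latent_dim,
      " encoder", paste(p$encoder_widths, collapse = "/"),
      " decoder", paste(p$decoder_widths, collapse = "/"), "\n")
  invisible(x)
}

.weight_names <- c("W_enc1", "W_enc2", "W_mu", "b_mu", "W_sig", "b_sig",
                   "W_fc", "b_fc", "W_nd", "b_nd", "B_nd", "W_e1", "b_e1",
                   "w_e2", "b_e2")

#' One graph-convolution layer
#'
#' The propagation rule `activation(E_norm %*% H_in %*% W)` over a
#' symmetrically normalized adjacency.
#'
#' @param E_norm N x N normalized adjacency (see [normalized_adjacency()]).
#' @param H_in N x C input node features.
#' @param W C x C' weight matrix.
#' @param activation Elementwise activation function (default identity).
#' @return N x C' matrix.
#' @export
gcn_layer <- function(E_norm, H_in, W, activation = identity) {
  E_norm <- as.matrix(E_norm); H_in <- as.matrix(H_in); W <- as.matrix(W)
  if (ncol(E_norm) != nrow(H_in) || ncol(H_in) != nrow(W))
    stop("shape mismatch in gcn_layer")
  activation(E_norm %*% H_in %*% W)
}

# encoder forward pass; returns mu, logsig (clamped), sigma and, when
# cache = TRUE, all intermediates needed for backprop
.encoder_forward <- function(A, Fm, state, cache = FALSE) {
  P1 <- A %*% Fm %*% state$W_enc1; H1 <- relu(P1)
  P2 <- A %*% H1 %*% state$W_enc2; H2 <- relu(P2)
  AH2 <- A %*% H2
  Mu_nodes <- AH2 %*% state$W_mu
  Ls_nodes <- AH2 %*% state$W_sig
  mu <- colMeans(Mu_nodes) + state$b_mu
  ls_raw <- colMeans(Ls_nodes) + state$b_sig
  logsig <- pmin(pmax(ls_raw, .LOGSIG_MIN), .LOGSIG_MAX)
  out <- list(mu = mu, logsig = logsig, sigma = exp(logsig),
              ls_mask = (ls_raw > .LOGSIG_MIN & ls_raw < .LOGSIG_MAX) * 1)
  if (cache) out <- c(out, list(P1 = P1, H1 = H1, P2 = P2, H2 = H2,
                                AH2 = AH2))
  out
}

# decoder forward pass from latent z; returns logits L, probabilities P
# and intermediates when cache = TRUE
.decoder_forward <- function(z, Fm, state, cache = FALSE) {
  n <- nrow(Fm)
  d <- length(state$b_fc); k <- length(state$b_e1)
  pfc <- as.vector(z %*% state$W_fc) + state$b_fc
  zp <- relu(pfc)
  Fp <- cbind(matrix(zp, n, d, byrow = TRUE), Fm)
  # node deconvolution: shared weights plus node-specific bias B_nd (the
  # positional filters of a transposed convolution, collapsed); without the
  # positional term, residues of the same amino-acid type would be
  # indistinguishable to the decoder
  Pnd <- Fp %*% state$W_nd + state$B_nd
  Pnd <- sweep(Pnd, 2, state$b_nd, "+")
  Hd <- relu(Pnd)
  Ae <- Hd %*% state$W_e1                       # n x k
  ii <- rep(seq_len(n), times = n)              # row index, column-major
  jj <- rep(seq_len(n), each = n)
  PreM <- Ae[ii, , drop = FALSE] + Ae[jj, , drop = FALSE]
  PreM <- sweep(PreM, 2, state$b_e1, "+")       # n^2 x k, symmetric pairs
  U <- relu(PreM)
  Lvec <- as.vector(U %*% state$w_e2) + state$b_e2
  L <- matrix(Lvec, n, n)
  P <- sigmoid(L)
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  out <- list(L = L, P = P)
  if (cache) out <- c(out, list(pfc = pfc, zp = zp, Fp = Fp, Pnd = Pnd,
                                Hd = Hd, Ae = Ae, PreM = PreM, U = U,
                                ii = ii, jj = jj))
  out
}

#' Encode a contact graph to its posterior Gaussian
#'
#' Runs the graph-convolutional encoder and mean-pools the per-node outputs
#' of the mean and standard-deviation paths into one graph-level posterior
#' `N(mu, diag(sigma^2))`. Self-loops are added internally if absent, so the
#' result is invariant to the graph's self-loop flag.
#'
#' @param graph A [contact_graph()].
#' @param state A [init_model_state()] (possibly trained).
#' @return Object of class `posterior_gaussian` with fields `mu` and
#'   `sigma`, both length-H vectors, `sigma > 0`.
#' @export
encode <- function(graph, state) {
  stopifnot(inherits(graph, "contact_graph"), inherits(state, "model_state"))
  g <- with_self_loops(graph)
  A <- normalized_adjacency(g)
  enc <- .encoder_forward(A, g$F, state)
  stopifnot_finite(c(enc$mu, enc$sigma), "encoder output")
  structure(list(mu = enc$mu, sigma = enc$sigma),
            class = "posterior_gaussian")
}

#' @export
print.posterior_gaussian <- function(x, ...) {
  cat("posterior Gaussian, H =", length(x$mu), "\n")
  cat("  mu:    ", paste(signif(x$mu, 3), collapse = " "), "\n")
  cat("  sigma: ", paste(signif(x$sigma, 3), collapse = " "), "\n")
  invisible(x)
}

#' Reparameterized sample from a posterior Gaussian
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, I)`; the draw is reproducible
#' given `seed`.
#'
#' @param post A `posterior_gaussian` from [encode()].
#' @param seed Optional integer seed.
#' @return Length-H latent code.
#' @export
reparameterize <- function(post, seed = NULL) {
  stopifnot(inherits(post, "posterior_gaussian"))
  eps <- local_seed(seed, stats::rnorm(length(post$mu)))
  post$mu + post$sigma * eps
}

#' Decode a latent code into edge probabilities
#'
#' The latent code passes through a fully connected layer, is concatenated
#' with every node's one-hot attribute vector, transformed per node
#' (node deconvolution), and scored for every residue pair by a symmetric
#' pairwise operator (edge deconvolution) with a logistic link. Node
#' attributes are not generated: the model copies `F` from its input.
#'
#' @param z Length-H latent code.
#' @param F N x 20 one-hot node attribute matrix.
#' @param state A [init_model_state()].
#' @return N x N symmetric matrix of probabilities strictly inside (0, 1).
#' @export
decode <- function(z, F, state) {
  stopifnot(inherits(state, "model_state"))
  F <- as.matrix(F)
  if (length(z) != state$params$latent_dim)
    stop("latent code has length ", length(z), ", expected ",
         state$params$latent_dim)
  if (ncol(F) != state$params$node_attr_dim)
    stop("node attribute matrix has wrong width")
  .decoder_forward(as.numeric(z), F, state)$P
}

#' Evidence-lower-bound loss of one graph
#'
#' The minimization form of the negative ELBO: mean binary cross-entropy
#' between the decoded edge probabilities and the observed adjacency
#' (diagonal cells excluded by default, since `F` is copied and self-loops
#' are a representation device), plus `beta` times the closed-form Gaussian
#' KL divergence from the `N(0, I)` prior,
#' `kl = -0.5 * sum(1 + log sigma^2 - mu^2 - sigma^2)`.
#'
#' @param graph A [contact_graph()] holding the target adjacency.
#' @param post A `posterior_gaussian`.
#' @param P N x N edge probability matrix from [decode()].
#' @param beta Nonnegative KL weight; `beta = 1` gives the plain VAE loss
#'   and `beta = 0` leaves only the reconstruction term.
#' @param include_diagonal Count diagonal cells in the reconstruction mean.
#' @return List with components `total`, `recon`, `kl`
#'   (`total = recon + beta * kl`).
#' @export
elbo_loss <- function(graph, post, P, beta = 1, include_diagonal = FALSE) {
  stopifnot(inherits(graph, "contact_graph"),
            inherits(post, "posterior_gaussian"), beta >= 0)
  n <- graph$n_residues
  if (!identical(dim(P), c(n, n))) stop("P has wrong shape")
  M <- matrix(1, n, n)
  if (!include_diagonal) diag(M) <- 0
  Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  E <- graph$E
  bce <- -(E * log(Pc) + (1 - E) * log(1 - Pc))
  recon <- sum(M * bce) / sum(M)
  mu <- post$mu; sig <- post$sigma
  kl <- -0.5 * sum(1 + 2 * log(sig) - mu^2 - sig^2)
  total <- recon + beta * kl
  stopifnot_finite(c(total, recon, kl), "elbo loss")
  list(total = total, recon = recon, kl = kl)
}

# Full forward + backward pass for one graph. Returns loss components and
# the gradient of `total` w.r.t. every weight. `eps` is the N(0,I) draw of
# the reparameterization (length H); pass zeros for a deterministic pass.
# `kl_weight` rescales the KL term in the optimized objective so that the
# reconstruction (reported as a per-cell mean) and the KL stay on the
# footing of the underlying ELBO; `kl` is always returned unscaled.
.vae_grad <- function(graph, state, eps, beta = 1, kl_weight = 1,
                      include_diagonal = FALSE) {
  g <- with_self_loops(graph)
  A <- normalized_adjacency(g)
  Fm <- g$F
  n <- nrow(Fm)
  enc <- .encoder_forward(A, Fm, state, cache = TRUE)
  z <- enc$mu + enc$sigma * eps
  dec <- .decoder_forward(z, Fm, state, cache = TRUE)

  M <- matrix(1, n, n)
  if (!include_diagonal) diag(M) <- 0
  ncell <- sum(M)
  Etgt <- graph$E
  recon <- sum(M * (softplus(dec$L) - Etgt * dec$L)) / ncell
  kl <- -0.5 * sum(1 + 2 * enc$logsig - enc$mu^2 - enc$sigma^2)
  bkl <- beta * kl_weight
  total <- recon + bkl * kl

  ## ---- backward ----
  G <- M * (dec$P - Etgt) / ncell               # d total / d logits
  Gvec <- as.vector(G)
  dw_e2 <- as.vector(crossprod(dec$U, Gvec))
  db_e2 <- sum(Gvec)
  dU <- outer(Gvec, state$w_e2)
  dPreM <- dU * (dec$PreM > 0)
  dAe <- rowsum(dPreM, dec$ii, reorder = TRUE) +
         rowsum(dPreM, dec$jj, reorder = TRUE)
  db_e1 <- colSums(dPreM)
  dW_e1 <- crossprod(dec$Hd, dAe)
  dHd <- dAe %*% t(state$W_e1)
  dPnd <- dHd * (dec$Pnd > 0)
  dW_nd <- crossprod(dec$Fp, dPnd)
  db_nd <- colSums(dPnd)
  dB_nd <- dPnd
  dFp <- dPnd %*% t(state$W_nd)
  d <- length(state$b_fc)
  dzp <- colSums(dFp[, seq_len(d), drop = FALSE])
  dpfc <- dzp * (dec$pfc > 0)
  dW_fc <- outer(as.numeric(z), dpfc)
  db_fc <- dpfc
  dz <- as.vector(state$W_fc %*% dpfc)

  dmu <- dz + bkl * enc$mu
  dlogsig <- (dz * eps * enc$sigma + bkl * (enc$sigma^2 - 1)) * enc$ls_mask

  H <- length(dmu)
  dMu_nodes <- matrix(dmu / n, n, H, byrow = TRUE)
  dLs_nodes <- matrix(dlogsig / n, n, H, byrow = TRUE)
  dW_mu <- crossprod(enc$AH2, dMu_nodes)
  dW_sig <- crossprod(enc$AH2, dLs_nodes)
  db_mu <- dmu
  db_sig <- dlogsig
  dAH2 <- dMu_nodes %*% t(state$W_mu) + dLs_nodes %*% t(state$W_sig)
  dH2 <- A %*% dAH2                             # A symmetric
  dP2 <- dH2 * (enc$P2 > 0)
  dW_enc2 <- crossprod(A %*% enc$H1, dP2)
  dH1 <- A %*% (dP2 %*% t(state$W_enc2))
  dP1 <- dH1 * (enc$P1 > 0)
  dW_enc1 <- crossprod(A %*% Fm, dP1)

  list(total = total, recon = recon, kl = kl, P = dec$P, z = z,
       mu = enc$mu, sigma = enc$sigma,
       grads = list(W_enc1 = dW_enc1, W_enc2 = dW_enc2, W_mu = dW_mu,
                    b_mu = db_mu, W_sig = dW_sig, b_sig = db_sig,
                    W_fc = dW_fc, b_fc = db_fc,
                    W_nd = dW_nd, b_nd = db_nd, B_nd = dB_nd, W_e1 = dW_e1,
                    b_e1 = db_e1, w_e2 = dw_e2, b_e2 = db_e2))
}
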