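#' Fit a contact-graph variational autoencoder
#'
#' The central fitting function. Given an ensemble of conformations of one
#' protein, represented as a [graph_dataset()] of binary CA contact graphs,
#' it learns a generative model of the ensemble: a graph-convolutional
#' encoder maps a graph to a Gaussian posterior over a graph-level latent
#' code, and a symmetric deconvolution decoder maps a latent code back to
#' edge probabilities. The objective is the negative evidence lower bound
#' with the KL term weighted by `beta`; `beta = 1` is the plain contact
#' graph VAE, `beta > 1` its disentangled variant.
#'
#' @param data A [graph_dataset()]. If it carries no train/test split, a
#'   seeded random split with train fraction `split_ratio` is drawn first.
#' @param latent_dim Latent dimensionality H (default 10).
#' @param beta Nonnegative KL weight (default 1).
#' @param encoder_widths,decoder_widths Layer widths, see [vae_params()].
#' @param learning_rate,batch_size,epochs,optimizer Training
#'   hyperparameters, see [train_config()]. Defaults: 5e-4, 100, 200, Adam.
#' @param split_ratio Train fraction for the automatic split (default 0.8,
#'   a 4:1 split).
#' @param seed Master seed governing split, initialization and training.
#' @param checkpoint_dir,checkpoint_every Optional periodic checkpointing,
#'   see [train_config()].
#' @return An object of class `cgvae`: a list with components `state`
#'   (trained [init_model_state()]), `params`, `config`, `history`
#'   (per-epoch loss data frame), `data` (the split dataset) and `call`.
#'   Methods: [print.cgvae()], [summary.cgvae()], [coef.cgvae()],
#'   [predict.cgvae()], [simulate.cgvae()], [residuals.cgvae()],
#'   [plot.cgvae()].
#'
#' @examples
#' base <- sample_base_fold(sim_config(n_residues = 20, seed = 7))
#' ds <- make_decoy_dataset(base, sim_config(n_residues = 20, n_decoys = 30,
#'                                           noise_sd = 1, seed = 7))
#' fit <- cgvae(ds, latent_dim = 4, epochs = 3, batch_size = 10, seed = 1)
#' fit
#' gen <- simulate(fit, nsim = 5, seed = 2)
#' @export
cgvae <- function(data, latent_dim = 10L, beta = 1,
                  encoder_widths = c(32L, 32L), decoder_widths = c(32L, 32L),
                  learning_rate = 5e-4, batch_size = 100L, epochs = 200L,
                  optimizer = c("adam", "sgd"), split_ratio = 0.8,
                  seed = 1L, checkpoint_dir = NULL, checkpoint_every = 50L) {
  stopifnot(inherits(data, "graph_dataset"))
  optimizer <- match.arg(optimizer)
  if (all(is.na(data$split)) && length(data$graphs) >= 5L)
    data <- split_dataset(data, ratio = split_ratio, seed = seed)
  params <- vae_params(n_residues = data$n_residues,
                       latent_dim = latent_dim,
                       encoder_widths = encoder_widths,
                       decoder_widths = decoder_widths, beta = beta,
                       node_attr_dim = ncol(data$F))
  cfg <- train_config(learning_rate = learning_rate,
                      batch_size = batch_size, epochs = epochs,
                      split_ratio = split_ratio, seed = seed,
                      optimizer = optimizer, checkpoint_dir = checkpoint_dir,
                      checkpoint_every = checkpoint_every)
  fit <- train_cgvae(data, params, cfg)
  structure(list(state = fit$state, params = params, config = cfg,
                 history = fit$history, data = data,
                 call = match.call()),
            class = "cgvae")
}

#' @export
print.cgvae <- function(x, ...) {
  p <- x$params
  cat("Contact-graph VAE", if (p$beta != 1)
    paste0(" (disentangled, beta = ", p$beta, ")"), "\n", sep = "")
  cat("  protein length N = ", p$n_residues,
      ", latent dim H = ", p$latent_dim, "\n", sep = "")
  n_tr <- sum(x$data$split == "train", na.rm = TRUE)
  cat("  trained on ", max(n_tr, length(x$data$graphs) * (n_tr == 0)),
      " graphs for ", nrow(x$history), " epochs\n", sep = "")
  if (nrow(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss: total %.4f (recon %.4f, kl %.4f)\n",
                h$total, h$recon, h$kl))
  }
  invisible(x)
}

#' Summarize a fitted contact-graph VAE
#'
#' Reports architecture, training setup, final losses and (when a native
#' graph is attached) a train-split reconstruction summary.
#'
#' @param object A [cgvae()] fit.
#' @param ... Unused.
#' @export
summary.cgvae <- function(object, ...) {
  h <- object$history
  res <- list(params = object$params, config = object$config,
              n_train = sum(object$data$split == "train", na.rm = TRUE),
              n_test = sum(object$data$split == "test", na.rm = TRUE),
              epochs_run = nrow(h),
              final = if (nrow(h)) h[nrow(h), ] else NULL,
              n_weights = sum(vapply(object$state[.weight_names], length,
                                     integer(1))))
  class(res) <- "summary.cgvae"
  res
}

#' @export
print.summary.cgvae <- function(x, ...) {
  p <- x$params
  cat("Contact-graph VAE summary\n")
  cat("  N = ", p$n_residues, ", H = ", p$latent_dim, ", beta = ", p$beta,
      "\n", sep = "")
  cat("  encoder widths: ", paste(p$encoder_widths, collapse = ", "),
      "; decoder widths: ", paste(p$decoder_widths, collapse = ", "),
      "; ", x$n_weights, " weights\n", sep = "")
  cat("  split: ", x$n_train, " train / ", x$n_test, " test; ",
      x$epochs_run, " epochs (", x$config$optimizer, ", lr ",
      x$config$learning_rate, ", batch ", x$config$batch_size, ")\n",
      sep = "")
  if (!is.null(x$final))
    cat(sprintf("  final loss: total %.4f = recon %.4f + beta * kl %.4f\n",
                x$final$total, x$final$recon, x$final$kl))
  invisible(x)
}

#' @export
coef.cgvae <- function(object, ...) object$state[.weight_names]

#' Reconstruct graphs through the fitted model
#'
#' Encodes each graph, takes the posterior mean (or a reparameterized
#' sample), decodes, and returns either edge probability matrices or
#' binarized contact graphs.
#'
#' @param object A [cgvae()] fit.
#' @param newdata A [graph_dataset()], a list of [contact_graph()]s or a
#'   single graph; default: the fit's training data.
#' @param type `"prob"` for probability matrices, `"graph"` for binarized
#'   [contact_graph()]s.
#' @param use_mean Use the posterior mean (deterministic) instead of a
#'   sampled latent code.
#' @param threshold Binarization cutoff for `type = "graph"`.
#' @param seed Seed for the sampled-latent case.
#' @param ... Unused.
#' @return A list (one element per input graph) of matrices or graphs.
#' @export
predict.cgvae <- function(object, newdata = NULL,
                          type = c("prob", "graph"), use_mean = TRUE,
                          threshold = 0.5, seed = NULL, ...) {
  type <- match.arg(type)
  graphs <- .as_graph_list(if (is.null(newdata)) object$data else newdata)
  out <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    P <- reconstruct(graphs[[i]], object$state, use_mean = use_mean,
                     seed = if (is.null(seed)) NULL else seed + i - 1L)
    out[[i]] <- if (type == "prob") P
      else .binarize_graph(P, object$data$F, threshold,
                           id = paste0("recon_", i))
  }
  out
}

#' Sample new contact graphs from the fitted prior
#'
#' Draws `nsim` latent codes from the `N(0, I)` prior, decodes each and
#' binarizes the edge probabilities.
#'
#' @param object A [cgvae()] fit.
#' @param nsim Number of graphs.
#' @param seed Integer seed (reproducible draws).
#' @param threshold Binarization cutoff (default 0.5).
#' @param top_k Optional integer: instead of thresholding, keep the `top_k`
#'   strongest contacts.
#' @param ... Unused.
#' @return A [graph_dataset()] of generated graphs (native carried over
#'   from the training data when present).
#' @export
simulate.cgvae <- function(object, nsim = 1, seed = NULL, threshold = 0.5,
                           top_k = NULL, ...) {
  gen <- sample_graphs(object$state, object$data$F, n = nsim,
                       threshold = threshold, top_k = top_k, seed = seed)
  gen$native <- object$data$native
  gen
}

#' Per-graph reconstruction error
#'
#' Mean binary cross-entropy between each training (or supplied) graph and
#' its posterior-mean reconstruction; a residual scale for the fit.
#'
#' @param object A [cgvae()] fit.
#' @param newdata Optional graphs as in [predict.cgvae()].
#' @param ... Unused.
#' @return Numeric vector of per-graph mean BCE values.
#' @export
residuals.cgvae <- function(object, newdata = NULL, ...) {
  graphs <- .as_graph_list(if (is.null(newdata)) object$data else newdata)
  vapply(graphs, function(g) {
    P <- reconstruct(g, object$state, use_mean = TRUE)
    post <- encode(g, object$state)
    elbo_loss(g, post, P, beta = 0)$recon
  }, numeric(1))
}

#' Plot training history of a contact-graph VAE
#'
#' Total, reconstruction and KL loss per epoch on a common axis.
#'
#' @param x A [cgvae()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cgvae <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot")
  graphics::matplot(h$epoch, cbind(h$total, h$recon, h$kl), type = "l",
                    lty = 1, col = c("black", "steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "recon", "kl"), lty = 1,
                   col = c("black", "steelblue", "firebrick"), bty = "n")
  invisible(x)
}

# normalize the various graph-collection inputs to a plain list
.as_graph_list <- function(x) {
  if (inherits(x, "graph_dataset")) x$graphs
  else if (inherits(x, "contact_graph")) list(x)
  else if (is.list(x)) x
  else stop("cannot interpret input as contact graphs")
}
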