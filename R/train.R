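#' Training configuration
#'
#' Defaults are sized for full-scale decoy ensembles (tens of thousands of
#' structures): Adam at learning rate 5e-4, mini-batches of 100 graphs,
#' 200 epochs, a 4:1 train/test split. Desk-scale ensembles want a larger
#' rate and smaller batches (see the package vignette).
#'
#' @param learning_rate Positive step size.
#' @param batch_size Mini-batch size (>= 1); the last partial batch is kept.
#' @param epochs Number of passes over the training split (>= 0; 0 returns
#'   the initialized state untouched).
#' @param split_ratio Train fraction used when the dataset carries no split.
#' @param seed Master seed; every random draw in training (initialization,
#'   shuffling, reparameterization noise) flows from it.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param checkpoint_dir Optional directory; when set, the model state is
#'   saved there every `checkpoint_every` epochs.
#' @param checkpoint_every Epoch interval between checkpoints.
#' @param include_diagonal Count diagonal cells in the reconstruction loss.
#' @param kl_norm Normalization of the KL term in the optimized objective,
#'   needed because the reconstruction is reported as a per-cell mean:
#'   `"cells"` (default) divides the KL by the number of reconstructed
#'   cells, so the objective is exactly the negative ELBO rescaled by a
#'   constant; `"nodes"` divides by N (a convention common in graph VAEs);
#'   `"none"` applies the raw KL sum, which overweights the prior by
#'   roughly N^2 and invites posterior collapse.
#' @param kl_anneal_epochs KL warm-up: the KL weight ramps linearly from 0
#'   to its full value over this many initial epochs (0 disables). Warm-up
#'   lets the decoder learn to use the latent code before the prior pulls
#'   the posterior in, a standard guard against posterior collapse.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 100L,
                         epochs = 200L, split_ratio = 0.8, seed = 1L,
                         optimizer = c("adam", "sgd"),
                         checkpoint_dir = NULL, checkpoint_every = 50L,
                         include_diagonal = FALSE,
                         kl_norm = c("cells", "nodes", "none"),
                         kl_anneal_epochs = 0L) {
  optimizer <- match.arg(optimizer)
  kl_norm <- match.arg(kl_norm)
  stopifnot(kl_anneal_epochs >= 0L)
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 0L,
            split_ratio > 0, split_ratio < 1, checkpoint_every >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 split_ratio = split_ratio, seed = as.integer(seed),
                 optimizer = optimizer, checkpoint_dir = checkpoint_dir,
                 checkpoint_every = as.integer(checkpoint_every),
                 include_diagonal = isTRUE(include_diagonal),
                 kl_norm = kl_norm,
                 kl_anneal_epochs = as.integer(kl_anneal_epochs)),
            class = "train_config")
}

#' Train a contact-graph VAE
#'
#' Mini-batch stochastic optimization of the beta-weighted negative ELBO.
#' The training split of `ds` is used when a split is present; otherwise
#' every graph is used. Fully reproducible given `cfg$seed`.
#'
#' @param ds A [graph_dataset()] (all graphs share N and sequence).
#' @param params A [vae_params()] (carries `beta`).
#' @param cfg A [train_config()].
#' @param state Optional starting [init_model_state()]; by default a fresh
#'   state is initialized from `cfg$seed`.
#' @return List with `state` (the trained `model_state`) and `history`
#'   (data frame with columns epoch, total, recon, kl — per-epoch means
#'   over training graphs; `total` is the optimized objective, i.e. recon
#'   plus the beta-weighted, `kl_norm`-scaled KL; `kl` is the raw KL sum).
#' @export
train_cgvae <- function(ds, params, cfg = train_config(), state = NULL) {
  stopifnot(inherits(ds, "graph_dataset"), inherits(params, "vae_params"),
            inherits(cfg, "train_config"))
  if (params$n_residues != ds$n_residues)
    stop("params built for N = ", params$n_residues,
         " but dataset has N = ", ds$n_residues)
  graphs <- if (any(!is.na(ds$split)))
    ds$graphs[!is.na(ds$split) & ds$split == "train"] else ds$graphs
  if (!length(graphs)) stop("no training graphs")
  if (is.null(state)) state <- init_model_state(params, seed = cfg$seed)
  H <- params$latent_dim
  beta <- params$beta
  n <- ds$n_residues
  kl_weight <- switch(cfg$kl_norm,
                      nodes = 1 / n,
                      cells = 1 / (n * n - if (cfg$include_diagonal) 0 else n),
                      none = 1)

  history <- data.frame(epoch = integer(0), total = numeric(0),
                        recon = numeric(0), kl = numeric(0))
  if (cfg$epochs == 0L) return(list(state = state, history = history))

  # Adam moments
  mom1 <- lapply(state[.weight_names], function(w) w * 0)
  mom2 <- mom1
  t_step <- 0L
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  m <- length(graphs)

  run <- function() {
    for (ep in seq_len(cfg$epochs)) {
      anneal <- if (cfg$kl_anneal_epochs > 0L)
        min(1, ep / cfg$kl_anneal_epochs) else 1
      ord <- sample.int(m)
      starts <- seq(1L, m, by = cfg$batch_size)
      ep_tot <- ep_rec <- ep_kl <- 0
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, m)]
        acc <- NULL
        btot <- brec <- bkl <- 0
        for (gi in idx) {
          eps <- stats::rnorm(H)
          r <- .vae_grad(graphs[[gi]], state, eps, beta = beta,
                         kl_weight = kl_weight * anneal,
                         include_diagonal = cfg$include_diagonal)
          if (!is.finite(r$total))
            stop("non-finite loss at epoch ", ep, ", batch ", bi)
          btot <- btot + r$total; brec <- brec + r$recon; bkl <- bkl + r$kl
          acc <- if (is.null(acc)) r$grads
                 else mapply(`+`, acc, r$grads, SIMPLIFY = FALSE)
        }
        nb <- length(idx)
        acc <- lapply(acc, `/`, nb)
        t_step <<- t_step + 1L
        for (wn in .weight_names) {
          g <- acc[[wn]]
          if (cfg$optimizer == "adam") {
            mom1[[wn]] <<- b1 * mom1[[wn]] + (1 - b1) * g
            mom2[[wn]] <<- b2 * mom2[[wn]] + (1 - b2) * g^2
            mhat <- mom1[[wn]] / (1 - b1^t_step)
            vhat <- mom2[[wn]] / (1 - b2^t_step)
            state[[wn]] <<- state[[wn]] -
              cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
          } else {
            state[[wn]] <<- state[[wn]] - cfg$learning_rate * g
          }
        }
        ep_tot <- ep_tot + btot; ep_rec <- ep_rec + brec; ep_kl <- ep_kl + bkl
      }
      history[nrow(history) + 1L, ] <<- list(ep, ep_tot / m, ep_rec / m,
                                             ep_kl / m)
      if (!is.null(cfg$checkpoint_dir) &&
          (ep %% cfg$checkpoint_every == 0L || ep == cfg$epochs)) {
        if (!dir.exists(cfg$checkpoint_dir))
          dir.create(cfg$checkpoint_dir, recursive = TRUE)
        saveRDS(state, file.path(cfg$checkpoint_dir,
                                 sprintf("state_epoch%04d.rds", ep)))
      }
    }
  }
  local_seed(cfg$seed + 1L, run())
  list(state = state, history = history)
}
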