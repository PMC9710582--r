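# cgvae — variational autoencoders for protein contact graphs

Proteins are dynamic: one sequence populates an ensemble of tertiary
structures, and capturing that ensemble — not just a single fold — is the
point of generative structure modelling. `cgvae` implements a graph
variational autoencoder over **CA contact graphs** for exactly this
setting: each conformation of an N-residue protein is reduced to a binary
symmetric adjacency `E` (contact whenever the alpha-carbon distance is
≤ 8 Å) plus a fixed one-hot residue-identity matrix `F`, the model learns
the ensemble distribution over `E`, and new conformations are sampled as
new contact graphs.

The model: a graph-convolutional encoder (propagation rule
`H = D^(-1/2) E D^(-1/2) · H_in · W` on the self-looped adjacency) is
mean-pooled into a graph-level Gaussian posterior `q(z | F, E) =
N(mu, diag(sigma^2))`; a deconvolution decoder maps `z` back to symmetric
edge probabilities `P`; training maximizes the evidence lower bound

    ELBO = E_q[log p(E | z)] − beta · KL(q(z | F, E) || N(0, I)),

with `beta = 1` the plain contact-graph VAE and `beta > 1` a
disentanglement-enhanced variant whose individual latent coordinates can
be interpreted by traversal. Evaluation covers graph-intrinsic property
distributions (density, edge count, degree assortativity, transitivity,
compared by Pearson correlation, Bhattacharyya distance and earth mover's
distance) and native-contact metrics (NAT-C, NONNAT-C, precision, recall,
coverage, F1). A synthetic decoy-ensemble generator makes the whole
pipeline testable at desk scale, and a CASP-RR writer connects generated
graphs to external contact-map-to-3D reconstruction tools.

See the methods vignette (`vignettes/contact-graph-vae.Rmd`) for the full
model description and design rationale.

## Worked example

```r
library(cgvae)

# a synthetic ensemble: compact 30-residue fold + 200 noisy decoys
cfg  <- sim_config(n_residues = 30, n_decoys = 200, noise_sd = 1, seed = 1)
base <- sample_base_fold(cfg)
ds   <- make_decoy_dataset(base, cfg)      # native graph attached

# fit the VAE (4:1 split drawn internally; desk-scale training settings)
fit <- cgvae(ds, latent_dim = 10, beta = 1,
             learning_rate = 5e-3, batch_size = 5, epochs = 30, seed = 1)
print(fit)
#> Contact-graph VAE
#>   protein length N = 30, latent dim H = 10
#>   trained on 160 graphs for 30 epochs
#>   final loss: total 0.2439 (recon 0.2391, kl 4.1767)

# sample 200 new contact graphs from the prior and score them
gen <- simulate(fit, nsim = 200, seed = 501)
report <- evaluate_datasets(gen, dataset_subset(fit$data, "train"),
                            native = ds$native)
print(report)
#> metric report: 200 generated vs 160 reference graphs
#>
#> property-distribution distances:
#>            property    pcc     bd    emd
#>             density 0.8208 0.0372 0.0082
#>             n_edges 0.8208 0.0372 3.5839
#>  degree_coefficient 0.8926 0.0474 0.0324
#>        transitivity 0.8368 0.1400 0.0251
#>
#> native-contact metrics (dataset means over generated):
#>   <NAT-C> 80.31%  <NONNAT-C> 0.8445  P 0.8298  R 0.8031  cov 0.8031  F1 0.8098
#>   delta vs reference: |d NAT-C| 3.376  |d NONNAT-C| 0.0186
```

Reading the numbers: the Bhattacharyya distances near zero say the
generated ensemble's property distributions sit almost on top of the
training ensemble's; a NAT-C of ~80% with ~0.84 non-native contacts per
residue says generated graphs recover most of the reference structure's
contacts while adding few spurious ones, and the small deltas say the
generated set resembles the training set in both respects. A latent
factor can then be inspected with

```r
series <- traverse_latent(fit$state, fit$data$F, dim = 3)  # grid 1..10000
flips  <- attr(diff_maps(series), "flips")                 # cells changed per step
```

A command-line front end over the same functions lives at
`inst/cli/cgvae.R` (subcommands `extract`, `simulate`, `train`,
`generate`, `evaluate`, `traverse`; run it with `--help`).

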