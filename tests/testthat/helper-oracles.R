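# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, direct definitions) so they are a second
# route, not a copy of the package implementation.

# random symmetric binary adjacency, zero diagonal
random_adjacency <- function(n, p = 0.4) {
  E <- matrix(0, n, n)
  ut <- which(upper.tri(E))
  E[ut] <- (runif(length(ut)) < p) * 1
  E + t(E)
}

random_onehot <- function(n, l2 = 20) {
  Fm <- matrix(0, n, l2)
  Fm[cbind(seq_len(n), sample.int(l2, n, replace = TRUE))] <- 1
  Fm
}

random_graph <- function(n, p = 0.4) {
  contact_graph(random_adjacency(n, p), random_onehot(n))
}

# brute-force D^{-1/2} E D^{-1/2} via explicit dense matrices
oracle_normalized_adjacency <- function(E) {
  D <- diag(rowSums(E))
  Dinv <- diag(1 / sqrt(diag(D)))
  Dinv %*% E %*% Dinv
}

# density / edges / assortativity / transitivity from first principles
oracle_properties <- function(E) {
  diag(E) <- 0
  n <- nrow(E)
  m <- sum(E) / 2
  deg <- rowSums(E)
  # transitivity: 3 * triangles / connected triples
  tri <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k && E[i, j] && E[j, k] && E[i, k]) tri <- tri + 1
  }
  triples <- sum(deg * (deg - 1) / 2)
  trans <- if (triples == 0) NA_real_ else 3 * tri / triples
  # assortativity: Pearson correlation over directed edge stubs
  xs <- ys <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && E[i, j] == 1) { xs <- c(xs, deg[i]); ys <- c(ys, deg[j]) }
  }
  dc <- if (length(xs) < 2 || sd(xs) == 0 || sd(ys) == 0) NA_real_
        else cor(xs, ys)
  list(density = m / (n * (n - 1) / 2), n_edges = m,
       degree_coefficient = dc, transitivity = trans)
}

# edge-set metrics by direct set operations on "i:j" labels
oracle_native_metrics <- function(Eg, En) {
  pairs <- function(E) {
    out <- character(0)
    n <- nrow(E)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (E[i, j] == 1) out <- c(out, paste(i, j, sep = ":"))
    out
  }
  g <- pairs(Eg); nat <- pairs(En)
  tp <- sum(g %in% nat); fp <- sum(!(g %in% nat)); fn <- sum(!(nat %in% g))
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- tp / (tp + fn)
  list(nat_c = 100 * tp / length(nat), nonnat_c = fp / nrow(Eg),
       precision = p, recall = r,
       f1 = if (p + r == 0) 0 else 2 * p * r / (p + r),
       coverage = tp / length(nat), tp = tp, fp = fp, fn = fn)
}

# histogram distances recomputed directly
oracle_distance <- function(a, b, metric, bins = 20) {
  rng <- range(c(a, b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  count <- function(x) {
    cnt <- numeric(bins)
    for (v in x) {
      k <- findInterval(v, br, rightmost.closed = TRUE)
      k <- min(max(k, 1), bins)
      cnt[k] <- cnt[k] + 1
    }
    cnt / length(x)
  }
  p <- count(a); q <- count(b)
  if (metric == "pcc") return(cor(p, q))
  if (metric == "bd") {
    ps <- p + 1e-10; ps <- ps / sum(ps)
    qs <- q + 1e-10; qs <- qs / sum(qs)
    return(-log(sum(sqrt(ps * qs))))
  }
  sum(abs(cumsum(p) - cumsum(q))) * (br[2] - br[1])
}

# tiny deterministic CA-trace PDB written to a temp file
write_fixture_pdb <- function(coords, resnames, path,
                              chain = rep("A", nrow(coords))) {
  n <- nrow(coords)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), resnames, chain, seq_len(n),
    coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "END"), path)
  path
}

# small trained-ish state for decoder-level tests (no training needed)
tiny_state <- function(n = 8, H = 3, seed = 42) {
  init_model_state(vae_params(n, latent_dim = H,
                              encoder_widths = c(6, 6),
                              decoder_widths = c(6, 6)), seed = seed)
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
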