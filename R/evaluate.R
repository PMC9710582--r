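#' Graph-intrinsic properties of a contact graph
#'
#' Density, edge count, degree assortativity ("average degree coefficient")
#' and transitivity, all computed on the simple graph: self-loops are
#' always excluded.
#'
#' @param graph A [contact_graph()].
#' @return List of class `property_vector` with `density`, `n_edges`,
#'   `degree_coefficient` and `transitivity`. Degenerate cases (e.g. zero
#'   degree variance for the assortativity, no connected triples for the
#'   transitivity) are flagged as `NA` rather than erroring.
#' @export
graph_properties <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  n <- graph$n_residues
  if (n < 2L) stop("need at least 2 residues")
  E <- graph$E
  diag(E) <- 0
  g <- igraph::graph_from_adjacency_matrix(E, mode = "undirected")
  m <- igraph::ecount(g)
  tr <- igraph::transitivity(g, type = "global")
  dc <- suppressWarnings(igraph::assortativity_degree(g))
  structure(list(density = m / (n * (n - 1) / 2),
                 n_edges = m,
                 degree_coefficient = if (is.finite(dc)) dc else NA_real_,
                 transitivity = if (is.finite(tr)) tr else NA_real_),
            class = "property_vector")
}

#' @export
print.property_vector <- function(x, ...) {
  cat(sprintf(
    "density %.4f | edges %d | degree coeff %s | transitivity %s\n",
    x$density, x$n_edges,
    ifelse(is.na(x$degree_coefficient), "NA",
           sprintf("%.4f", x$degree_coefficient)),
    ifelse(is.na(x$transitivity), "NA", sprintf("%.4f", x$transitivity))))
  invisible(x)
}

#' Distance between two empirical distributions
#'
#' Both samples are histogrammed on `bins` shared equal-width bins spanning
#' the pooled range, masses normalized to 1. Then:
#' * `"pcc"` — Pearson correlation of the two bin-mass vectors (`NA` when a
#'   mass vector has zero variance);
#' * `"bd"` — Bhattacharyya distance `-log(sum(sqrt(p * q)))`, with a small
#'   mass (`1e-10` per bin) added before normalization so disjoint supports
#'   give a large finite value;
#' * `"emd"` — earth mover's distance via the 1-D closed form
#'   `sum(|cdf_a - cdf_b|) * binwidth`.
#'
#' @param a,b Nonempty finite numeric vectors.
#' @param metric One of `"pcc"`, `"bd"`, `"emd"`.
#' @param bins Number of histogram bins (default 20).
#' @return A single number.
#' @export
distribution_distance <- function(a, b, metric = c("pcc", "bd", "emd"),
                                  bins = 20L) {
  metric <- match.arg(metric)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample")
  if (!all(is.finite(c(a, b)))) stop("non-finite values in sample")
  rng <- range(c(a, b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  width <- breaks[2] - breaks[1]
  ha <- .bin_masses(a, breaks)
  hb <- .bin_masses(b, breaks)
  switch(metric,
    pcc = {
      if (stats::sd(ha) == 0 || stats::sd(hb) == 0) NA_real_
      else stats::cor(ha, hb)
    },
    bd = {
      p <- ha + 1e-10; p <- p / sum(p)
      q <- hb + 1e-10; q <- q / sum(q)
      -log(sum(sqrt(p * q)))
    },
    emd = sum(abs(cumsum(ha) - cumsum(hb))) * width)
}

.bin_masses <- function(x, breaks) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  h$counts / length(x)
}

# undirected off-diagonal edge set as sorted "i-j" keys
.edge_keys <- function(E) {
  idx <- which(upper.tri(E) & E == 1, arr.ind = TRUE)
  if (!nrow(idx)) return(character(0))
  paste(idx[, 1], idx[, 2], sep = "-")
}

#' Native-contact metrics of one generated graph
#'
#' Compares the off-diagonal edge set of a generated graph against the
#' native (reference structure) graph. With `TP = |gen & native|`,
#' `FP = |gen \ native|`, `FN = |native \ gen|`:
#' * `nat_c` — percentage of native contacts recovered,
#'   `100 * TP / |native|`;
#' * `nonnat_c` — non-native contacts per residue, `FP / N`;
#' * `precision` `TP/(TP+FP)` (0 for an empty generated graph), `recall`
#'   `TP/(TP+FN)`, `f1 = 2PR/(P+R)` (0 when `P + R = 0`);
#' * `coverage` — `TP / |native|` by default (a 0-1 scale); the raw TP
#'   count is returned alongside as `coverage_raw`.
#'
#' @param gen,native [contact_graph()]s with the same N; `native` must have
#'   at least one contact.
#' @return Named list of the metrics above plus `tp`, `fp`, `fn`.
#' @export
native_contact_metrics <- function(gen, native) {
  stopifnot(inherits(gen, "contact_graph"), inherits(native, "contact_graph"))
  n <- gen$n_residues
  if (native$n_residues != n) stop("graphs differ in N")
  eg <- .edge_keys(gen$E)
  en <- .edge_keys(native$E)
  if (!length(en)) stop("native graph has no contacts")
  tp <- length(intersect(eg, en))
  fp <- length(setdiff(eg, en))
  fn <- length(setdiff(en, eg))
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * recall * precision / (recall + precision)
  list(nat_c = 100 * tp / length(en),
       nonnat_c = fp / n,
       precision = precision, recall = recall, f1 = f1,
       coverage = tp / length(en), coverage_raw = tp,
       tp = tp, fp = fp, fn = fn)
}

.property_matrix <- function(ds) {
  vals <- t(vapply(ds$graphs, function(g) {
    p <- graph_properties(g)
    c(density = p$density, n_edges = as.numeric(p$n_edges),
      degree_coefficient = p$degree_coefficient,
      transitivity = p$transitivity)
  }, numeric(4)))
  vals
}

.native_metric_frame <- function(ds, native) {
  do.call(rbind, lapply(ds$graphs, function(g) {
    m <- native_contact_metrics(g, native)
    as.data.frame(m[c("nat_c", "nonnat_c", "precision", "recall",
                      "coverage", "coverage_raw", "f1")])
  }))
}

#' Evaluate a generated dataset against a reference dataset
#'
#' Computes, for each of the four graph-intrinsic properties, the PCC, BD
#' and EMD between the generated and reference distributions; and, when a
#' native graph is available, the per-graph native-contact metrics on both
#' datasets, their means, and the absolute differences (delta) of the mean
#' NAT-C / NONNAT-C between generated and reference.
#'
#' @param gen Generated [graph_dataset()].
#' @param reference Reference (typically training) [graph_dataset()].
#' @param native Optional [contact_graph()]; defaults to
#'   `reference$native` then `gen$native`.
#' @param bins Histogram bins for the distribution distances.
#' @return Object of class `metric_report`: list with `distances` (data
#'   frame property x pcc/bd/emd), `per_graph` (native metrics on `gen`),
#'   `means`, `reference_means`, `delta`.
#' @export
evaluate_datasets <- function(gen, reference, native = NULL, bins = 20L) {
  stopifnot(inherits(gen, "graph_dataset"),
            inherits(reference, "graph_dataset"))
  if (gen$n_residues != reference$n_residues)
    stop("datasets differ in N")
  if (is.null(native)) native <- reference$native
  if (is.null(native)) native <- gen$native

  pg <- .property_matrix(gen)
  pr <- .property_matrix(reference)
  props <- colnames(pg)
  distances <- data.frame(property = props, pcc = NA_real_, bd = NA_real_,
                          emd = NA_real_)
  for (i in seq_along(props)) {
    x <- pg[, i]; y <- pr[, i]
    ok <- is.finite(x); oy <- is.finite(y)
    if (!any(ok) || !any(oy)) next
    distances$pcc[i] <- distribution_distance(x[ok], y[oy], "pcc", bins)
    distances$bd[i] <- distribution_distance(x[ok], y[oy], "bd", bins)
    distances$emd[i] <- distribution_distance(x[ok], y[oy], "emd", bins)
  }

  per_graph <- means <- ref_means <- delta <- NULL
  if (!is.null(native)) {
    per_graph <- .native_metric_frame(gen, native)
    ref_frame <- .native_metric_frame(reference, native)
    means <- colMeans(per_graph)
    ref_means <- colMeans(ref_frame)
    delta <- abs(means[c("nat_c", "nonnat_c")] -
                 ref_means[c("nat_c", "nonnat_c")])
  }
  structure(list(distances = distances, per_graph = per_graph,
                 means = means, reference_means = ref_means, delta = delta,
                 n_gen = length(gen$graphs),
                 n_reference = length(reference$graphs)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("metric report:", x$n_gen, "generated vs", x$n_reference,
      "reference graphs\n")
  cat("\nproperty-distribution distances:\n")
  print(cbind(property = x$distances$property,
              round(x$distances[, -1], digits)), row.names = FALSE)
  if (!is.null(x$means)) {
    cat("\nnative-contact metrics (dataset means over generated):\n")
    cat(sprintf("  <NAT-C> %.2f%%  <NONNAT-C> %.4f  P %.4f  R %.4f  cov %.4f  F1 %.4f\n",
                x$means["nat_c"], x$means["nonnat_c"], x$means["precision"],
                x$means["recall"], x$means["coverage"], x$means["f1"]))
    cat(sprintf("  delta vs reference: |d NAT-C| %.3f  |d NONNAT-C| %.4f\n",
                x$delta["nat_c"], x$delta["nonnat_c"]))
  }
  invisible(x)
}
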