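#' Construct a graph dataset
#'
#' An ordered collection of contact graphs sharing one sequence (hence one
#' `F` and one N), with optional train/test split bookkeeping and an
#' optional native reference graph.
#'
#' @param graphs List of [contact_graph()] objects with identical `F`.
#' @param split Optional character vector (`"train"`/`"test"`), one entry
#'   per graph. `NA` entries mean unassigned.
#' @param native Optional [contact_graph()]: the reference (e.g.
#'   experimental) structure's graph.
#' @return Object of class `graph_dataset`.
#' @export
graph_dataset <- function(graphs, split = NULL, native = NULL) {
  if (!length(graphs)) stop("empty graph list")
  if (!all(vapply(graphs, inherits, logical(1), "contact_graph")))
    stop("all elements must be contact_graph objects")
  n <- graphs[[1]]$n_residues
  F0 <- graphs[[1]]$F
  for (g in graphs) {
    if (g$n_residues != n) stop("graphs differ in number of residues")
    if (!identical(dim(g$F), dim(F0)) || any(g$F != F0))
      stop("graphs differ in node attributes (sequence)")
  }
  if (is.null(split)) split <- rep(NA_character_, length(graphs))
  split <- as.character(split)
  if (length(split) != length(graphs))
    stop("split must have one entry per graph")
  if (!all(split %in% c("train", "test", NA_character_)))
    stop("split entries must be 'train', 'test' or NA")
  if (!is.null(native)) {
    stopifnot(inherits(native, "contact_graph"))
    if (native$n_residues != n) stop("native graph has wrong N")
  }
  structure(list(graphs = graphs, split = split, native = native,
                 n_residues = n, F = F0),
            class = "graph_dataset")
}

#' @export
print.graph_dataset <- function(x, ...) {
  cat("graph dataset: ", length(x$graphs), " graphs, N = ", x$n_residues,
      "; split: ", sum(x$split == "train", na.rm = TRUE), " train / ",
      sum(x$split == "test", na.rm = TRUE), " test",
      if (!is.null(x$native)) "; native attached", "\n", sep = "")
  invisible(x)
}

#' @export
length.graph_dataset <- function(x) length(x$graphs)

#' Subset of a dataset by split label
#'
#' @param ds A [graph_dataset()].
#' @param which `"train"` or `"test"`.
#' @return A [graph_dataset()] holding only the requested subset (split
#'   labels preserved; native carried over).
#' @export
dataset_subset <- function(ds, which = c("train", "test")) {
  which <- match.arg(which)
  keep <- !is.na(ds$split) & ds$split == which
  if (!any(keep)) stop("no graphs in split '", which, "'")
  graph_dataset(ds$graphs[keep], split = ds$split[keep], native = ds$native)
}

#' Assign a train/test split
#'
#' Random, seeded assignment; the train fraction is matched to within one
#' graph by rounding.
#'
#' @param ds A [graph_dataset()].
#' @param ratio Train fraction in (0, 1); default 0.8 (a 4:1 split).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return The dataset with its `split` field filled.
#' @export
split_dataset <- function(ds, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "graph_dataset"))
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  m <- length(ds$graphs)
  if (m < 5L) stop("dataset too small to split (need >= 5 graphs)")
  n_train <- round(ratio * m)
  n_train <- min(max(n_train, 1L), m - 1L)
  idx <- local_seed(seed, sample.int(m, n_train))
  split <- rep("test", m)
  split[idx] <- "train"
  ds$split <- split
  ds
}

# dataset container format version (bump on incompatible layout change)
.cgvae_dataset_version <- 1L

#' Save / load a graph dataset
#'
#' Lossless round-trip through a versioned RDS container: graphs, split
#' membership and the native reference are all preserved. `load_dataset`
#' rejects files that are not such containers or have a different version.
#'
#' @param ds A [graph_dataset()].
#' @param path File path.
#' @return `load_dataset` returns the [graph_dataset()].
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "graph_dataset"))
  saveRDS(list(magic = "cgvae_dataset", version = .cgvae_dataset_version,
               dataset = ds), path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable dataset file: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$magic, "cgvae_dataset"))
    stop("not a cgvae dataset file")
  if (!identical(obj$version, .cgvae_dataset_version))
    stop("dataset container version mismatch (file: ", obj$version,
         ", supported: ", .cgvae_dataset_version, ")")
  ds <- obj$dataset
  if (!inherits(ds, "graph_dataset")) stop("corrupt dataset container")
  ds
}
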