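#' The 20-letter canonical amino-acid alphabet
#'
#' One-letter codes in the fixed column order used by the one-hot node
#' attribute matrix `F`.
#'
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a CA chain
#'
#' A CA chain is the point representation of one protein conformation: one
#' alpha-carbon coordinate per residue, ordered from the N- to the
#' C-terminus, plus the one-letter sequence.
#'
#' @param sequence One-letter amino-acid string (or character vector of
#'   single letters), length N.
#' @param coords Numeric N x 3 matrix of Cartesian CA coordinates in
#'   Angstrom.
#' @param id Free-text label.
#' @return An object of class `ca_chain` with elements `sequence` (character
#'   vector of length N), `coords` and `id`.
#' @export
ca_chain <- function(sequence, coords, id = "chain") {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(as.character(sequence))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z)")
  if (length(sequence) != nrow(coords))
    stop("sequence length (", length(sequence),
         ") does not match number of coordinate rows (", nrow(coords), ")")
  bad <- setdiff(unique(sequence), aa_alphabet())
  if (length(bad))
    stop("non-canonical residue letter(s): ", paste(bad, collapse = ", "))
  if (nrow(coords) >= 2L) {
    d <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                         coords[-nrow(coords), , drop = FALSE])^2))
    if (any(d == 0))
      stop("identical consecutive CA coordinates at position(s): ",
           paste(which(d == 0), collapse = ", "))
  }
  structure(list(sequence = sequence, coords = coords, id = as.character(id)),
            class = "ca_chain")
}

#' @export
print.ca_chain <- function(x, ...) {
  cat("CA chain '", x$id, "': ", length(x$sequence), " residues\n", sep = "")
  invisible(x)
}

#' Read a CA trace from a PDB file
#'
#' Parses ATOM records and keeps one CA atom per residue in chain order.
#' Alternate locations are resolved by highest occupancy, ties by altloc
#' "A"; any other altloc ambiguity is an error. Residues without a CA atom
#' are rejected.
#'
#' @param path Path to a PDB file.
#' @param chain_selector Optional single chain identifier (e.g. `"A"`). By
#'   default all chains are read in file order.
#' @return A [ca_chain()].
#' @export
read_ca_chain <- function(path, chain_selector = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (!is.null(chain_selector)) {
    atoms <- atoms[!is.na(atoms$chain) & atoms$chain == chain_selector, ,
                   drop = FALSE]
    if (nrow(atoms) == 0L)
      stop("no CA atoms in chain '", chain_selector, "'")
  }
  if (nrow(atoms) == 0L) stop("no CA atoms found in ", path)
  # residue key: chain + residue number + insertion code
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste(atoms$chain, atoms$resno, ins, sep = "|")
  keep <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 1L) {
      # altloc: keep highest occupancy, tie -> altloc "A"
      occ <- atoms$o[idx]
      occ[is.na(occ)] <- 0
      best <- idx[occ == max(occ)]
      if (length(best) > 1L) {
        a <- best[atoms$alt[best] %in% "A"]
        if (length(a) == 1L) best <- a
        else stop("unresolvable alternate locations for residue ", k)
      }
      keep <- c(keep, best)
    } else keep <- c(keep, idx)
  }
  keep <- sort(keep)
  atoms <- atoms[keep, , drop = FALSE]
  seq1 <- bio3d::aa321(atoms$resid)
  if (any(seq1 == "X"))
    stop("non-standard residue(s): ",
         paste(unique(atoms$resid[seq1 == "X"]), collapse = ", "))
  ca_chain(seq1, as.matrix(atoms[, c("x", "y", "z")]),
           id = sub("\\.pdb$", "", basename(path)))
}

#' Write a CA trace as a minimal PDB file
#'
#' Emits one ATOM record per residue (CA only), chain A, 1-based numbering.
#' Companion of [read_ca_chain()]; used to export simulated folds.
#'
#' @param chain A [ca_chain()].
#' @param path Output file path.
#' @export
write_ca_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "ca_chain"))
  res3 <- bio3d::aa123(chain$sequence)
  n <- length(chain$sequence)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), res3, seq_len(n),
    chain$coords[, 1], chain$coords[, 2], chain$coords[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' One-hot encode an amino-acid sequence
#'
#' @param sequence Character vector of one-letter codes (or a single string).
#' @return N x 20 binary matrix with columns ordered as [aa_alphabet()].
#' @export
one_hot_sequence <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  alpha <- aa_alphabet()
  idx <- match(toupper(sequence), alpha)
  if (anyNA(idx))
    stop("non-canonical residue letter(s): ",
         paste(unique(sequence[is.na(idx)]), collapse = ", "))
  Fm <- matrix(0, length(idx), length(alpha),
               dimnames = list(NULL, alpha))
  Fm[cbind(seq_along(idx), idx)] <- 1
  Fm
}

#' Construct a contact graph
#'
#' A contact graph represents one conformation as a binary symmetric
#' adjacency matrix `E` over residues plus a one-hot node attribute matrix
#' `F` holding residue identities. The diagonal of `E` is all ones when
#' `has_self_loops` and all zeros otherwise.
#'
#' @param E N x N binary symmetric matrix.
#' @param F N x 20 one-hot node attribute matrix (rows sum to 1).
#' @param has_self_loops Logical; whether `diag(E)` is 1.
#' @param id Free-text label.
#' @return Object of class `contact_graph` with fields `E`, `F`,
#'   `n_residues`, `has_self_loops`, `id`.
#' @export
contact_graph <- function(E, F, has_self_loops = FALSE, id = "graph") {
  E <- as.matrix(E); storage.mode(E) <- "double"; dimnames(E) <- NULL
  F <- as.matrix(F); storage.mode(F) <- "double"
  n <- nrow(E)
  if (ncol(E) != n) stop("E must be square")
  if (nrow(F) != n) stop("F must have one row per residue")
  if (!all(E %in% c(0, 1))) stop("E entries must be binary")
  if (!isTRUE(all.equal(E, t(E)))) stop("E must be symmetric")
  if (!all(F %in% c(0, 1)) || !all(rowSums(F) == 1))
    stop("F rows must be one-hot")
  d <- diag(E)
  if (has_self_loops && !all(d == 1))
    stop("has_self_loops = TRUE but diagonal is not all 1")
  if (!has_self_loops && !all(d == 0))
    stop("has_self_loops = FALSE but diagonal is not all 0")
  structure(list(E = E, F = F, n_residues = n,
                 has_self_loops = isTRUE(has_self_loops),
                 id = as.character(id)),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  m <- sum(x$E[upper.tri(x$E)])
  cat("contact graph '", x$id, "': ", x$n_residues, " residues, ",
      m, " contacts", if (x$has_self_loops) " (+self-loops)", "\n", sep = "")
  invisible(x)
}

#' Extract a contact graph from a CA chain
#'
#' Places an edge between residues i and j (i != j) whenever the Euclidean
#' CA-CA distance is no higher than `threshold` (inclusive at the boundary).
#' No minimum sequence separation is applied, so the near-diagonal virtual
#' bond contacts are kept.
#'
#' @param chain A [ca_chain()].
#' @param threshold Contact distance cutoff in Angstrom (default 8).
#' @param add_self_loops Logical; set the diagonal to 1 (required before
#'   feeding the graph to the model's normalized adjacency).
#' @return A [contact_graph()].
#' @export
extract_contact_graph <- function(chain, threshold = 8.0,
                                  add_self_loops = FALSE) {
  stopifnot(inherits(chain, "ca_chain"))
  n <- nrow(chain$coords)
  if (n < 2L) stop("need at least 2 residues")
  D <- as.matrix(stats::dist(chain$coords))
  E <- (D <= threshold) * 1
  diag(E) <- if (add_self_loops) 1 else 0
  contact_graph(E, one_hot_sequence(chain$sequence),
                has_self_loops = add_self_loops, id = chain$id)
}

#' Toggle self-loops on a contact graph
#'
#' @param graph A [contact_graph()].
#' @return The same graph with diagonal all 1 (`with_self_loops`) or all 0
#'   (`without_self_loops`).
#' @export
with_self_loops <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  if (graph$has_self_loops) return(graph)
  E <- graph$E; diag(E) <- 1
  contact_graph(E, graph$F, has_self_loops = TRUE, id = graph$id)
}

#' @rdname with_self_loops
#' @export
without_self_loops <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  if (!graph$has_self_loops) return(graph)
  E <- graph$E; diag(E) <- 0
  contact_graph(E, graph$F, has_self_loops = FALSE, id = graph$id)
}

#' Symmetrically normalized adjacency
#'
#' Computes `D^(-1/2) E D^(-1/2)` with `D = diag(rowSums(E))`, the
#' propagation operator of the graph-convolutional layers. The graph must
#' carry self-loops so no degree is zero.
#'
#' @param graph A [contact_graph()] with `has_self_loops = TRUE`.
#' @return Symmetric N x N numeric matrix.
#' @export
normalized_adjacency <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  if (!graph$has_self_loops)
    stop("normalized adjacency requires self-loops (degrees must be > 0)")
  deg <- rowSums(graph$E)
  if (any(deg == 0)) stop("zero-degree node")  # unreachable with self-loops
  s <- 1 / sqrt(deg)
  graph$E * outer(s, s)
}

#' Write a contact graph as a CASP-RR contact file
#'
#' First line is the one-letter sequence; each subsequent line is one
#' contact `"i j 0 8 1.0"` with 1-based residue indices, `i < j`, sorted by
#' i then j. Contacts with sequence separation below `min_separation` are
#' omitted. Self-loops are never written.
#'
#' @param graph A [contact_graph()].
#' @param path Output file path.
#' @param min_separation Minimum |i - j| for a contact to be written
#'   (default 1, i.e. all off-diagonal contacts).
#' @export
write_rr_contacts <- function(graph, path, min_separation = 1L) {
  stopifnot(inherits(graph, "contact_graph"))
  seq1 <- paste(aa_alphabet()[apply(graph$F, 1, which.max)], collapse = "")
  idx <- which(upper.tri(graph$E) & graph$E == 1, arr.ind = TRUE)
  if (nrow(idx)) {
    keep <- (idx[, 2] - idx[, 1]) >= min_separation
    idx <- idx[keep, , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  }
  lines <- c(seq1,
             if (nrow(idx)) sprintf("%d %d 0 8 1.0", idx[, 1], idx[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a CASP-RR contact file written by [write_rr_contacts()]
#'
#' @param path Path to an RR file (sequence line then contact lines).
#' @return A [contact_graph()] without self-loops.
#' @export
read_rr_contacts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty RR file")
  seq1 <- trimws(lines[[1]])
  n <- nchar(seq1)
  E <- matrix(0, n, n)
  if (length(lines) > 1L) {
    for (ln in lines[-1L]) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      i <- as.integer(f[[1]]); j <- as.integer(f[[2]])
      if (is.na(i) || is.na(j) || i < 1L || j > n || i >= j)
        stop("malformed RR contact line: ", ln)
      E[i, j] <- 1; E[j, i] <- 1
    }
  }
  contact_graph(E, one_hot_sequence(seq1), has_self_loops = FALSE,
                id = sub("\\.rr$", "", basename(path)))
}
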