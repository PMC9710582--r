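test_that("PDB CA traces are read with sequence order, chain selection and CA checks", {
  tmp <- tempfile(fileext = ".pdb")
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  write_fixture_pdb(coords, c("ALA", "GLY", "LYS"), tmp)
  ch <- read_ca_chain(tmp)
  expect_s3_class(ch, "ca_chain")
  expect_equal(length(ch$sequence), 3L)
  expect_equal(ch$sequence, c("A", "G", "K"))
  expect_equal(unname(ch$coords), coords, tolerance = 1e-6)

  # two chains, selector picks one
  tmp2 <- tempfile(fileext = ".pdb")
  write_fixture_pdb(rbind(coords, coords + 100), rep(c("ALA", "GLY", "LYS"), 2),
                    tmp2, chain = rep(c("A", "B"), each = 3))
  chA <- read_ca_chain(tmp2, chain_selector = "A")
  expect_equal(nrow(chA$coords), 3L)
  expect_error(read_ca_chain(tmp2, chain_selector = "Z"), "no CA atoms")

  # residue without CA -> that residue is not represented
  tmp3 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), tmp3)
  ch3 <- read_ca_chain(tmp3)
  expect_equal(length(ch3$sequence), 1L)
  expect_error(read_ca_chain(tempfile()), "no such file")
})

test_that("chain constructor enforces its invariants", {
  expect_error(ca_chain("AG", rbind(c(0, 0, 0))), "does not match")
  expect_error(ca_chain("AB", rbind(c(0, 0, 0), c(1, 0, 0))),
               "non-canonical")
  expect_error(ca_chain("AA", rbind(c(0, 0, 0), c(0, 0, 0))),
               "identical consecutive")
})

test_that("contact extraction uses an inclusive 8 A threshold", {
  mk <- function(d) ca_chain("AG", rbind(c(0, 0, 0), c(d, 0, 0)))
  g <- extract_contact_graph(mk(3.8))
  expect_equal(g$E[1, 2], 1)
  expect_equal(extract_contact_graph(mk(8.0))$E[1, 2], 1)  # boundary in
  expect_equal(extract_contact_graph(mk(9.0))$E[1, 2], 0)
  # collinear 3-chain spaced 5 A: (1,2), (2,3) in contact, (1,3) at 10 A out
  ch <- ca_chain("AGK", rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  E <- extract_contact_graph(ch)$E
  expect_equal(E, rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_error(extract_contact_graph(ca_chain("A", rbind(c(0, 0, 0)))),
               "at least 2")
})

test_that("extraction matches a pairwise-distance oracle and is binary symmetric", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    coords <- matrix(rnorm(n * 3, sd = 5), n, 3)
    ch <- ca_chain(sample(aa_alphabet(), n, replace = TRUE), coords)
    E <- extract_contact_graph(ch)$E
    expect_true(all(E %in% c(0, 1)))
    expect_identical(E, t(E))
    expect_true(all(diag(E) == 0))
    cnt <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= 8) cnt <- cnt + 1
    expect_equal(sum(E) / 2, cnt)
  }
})

test_that("extraction is invariant under rigid-body transforms", {
  set.seed(5)
  coords <- sample_base_fold(sim_config(n_residues = 15, seed = 3))$coords
  seqs <- sample(aa_alphabet(), 15, replace = TRUE)
  E0 <- extract_contact_graph(ca_chain(seqs, coords))$E
  for (rep in 1:20) {
    R <- rotation_matrix(runif(3, 0, 2 * pi))
    shift <- rnorm(3, sd = 50)
    moved <- sweep(coords %*% t(R), 2, shift, "+")
    expect_identical(extract_contact_graph(ca_chain(seqs, moved))$E, E0)
  }
})

test_that("extraction is permutation-equivariant", {
  set.seed(9)
  n <- 12
  coords <- matrix(rnorm(n * 3, sd = 4), n, 3)
  seqs <- sample(aa_alphabet(), n, replace = TRUE)
  E0 <- extract_contact_graph(ca_chain(seqs, coords))$E
  # reverse the residue order (a permutation that keeps consecutive
  # coordinates distinct)
  perm <- n:1
  Ep <- extract_contact_graph(ca_chain(seqs[perm], coords[perm, ]))$E
  expect_equal(Ep, E0[perm, perm])
})

test_that("normalized adjacency matches hand and dense-oracle computations", {
  g2 <- contact_graph(matrix(1, 2, 2), random_onehot(2),
                      has_self_loops = TRUE)
  expect_equal(normalized_adjacency(g2), matrix(0.5, 2, 2))
  g1 <- contact_graph(matrix(1, 1, 1), random_onehot(1),
                      has_self_loops = TRUE)
  expect_equal(normalized_adjacency(g1), matrix(1, 1, 1))
  # 3-node path with self-loops
  E <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  g3 <- contact_graph(E, random_onehot(3), has_self_loops = TRUE)
  expect_equal(normalized_adjacency(g3), oracle_normalized_adjacency(E),
               tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    E <- random_adjacency(n); diag(E) <- 1
    g <- contact_graph(E, random_onehot(n), has_self_loops = TRUE)
    A <- normalized_adjacency(g)
    expect_equal(A, oracle_normalized_adjacency(E), tolerance = 1e-10)
    expect_equal(A, t(A))
  }
  expect_error(normalized_adjacency(without_self_loops(g3)), "self-loops")
})

test_that("self-loop flag round-trips and is reflected in the diagonal", {
  g <- random_graph(6)
  g2 <- without_self_loops(with_self_loops(g))
  expect_equal(g2$E, g$E)
  expect_true(all(diag(with_self_loops(g)$E) == 1))
})

test_that("CASP-RR writer emits the documented dialect and round-trips", {
  E <- matrix(0, 3, 3); E[1, 3] <- E[3, 1] <- 1
  Fm <- one_hot_sequence("AGK")
  g <- contact_graph(E, Fm)
  tmp <- tempfile(fileext = ".rr")
  write_rr_contacts(g, tmp)
  expect_identical(readLines(tmp), c("AGK", "1 3 0 8 1.0"))
  expect_equal(read_rr_contacts(tmp)$E, E)

  # empty off-diagonal -> sequence line only
  g0 <- contact_graph(matrix(0, 3, 3), Fm)
  write_rr_contacts(g0, tmp)
  expect_identical(readLines(tmp), "AGK")

  # round-trip on a random graph; deterministic sorted output
  set.seed(3)
  g <- random_graph(10, p = 0.3)
  write_rr_contacts(g, tmp)
  expect_equal(read_rr_contacts(tmp)$E, g$E)
  ln <- readLines(tmp)[-1]
  ij <- do.call(rbind, lapply(strsplit(ln, " "), function(x)
    as.integer(x[1:2])))
  expect_true(all(ij[, 1] < ij[, 2]))
  expect_true(all(diff(ij[, 1] * 1000 + ij[, 2]) > 0))  # sorted by i then j

  # min_separation filters near-diagonal contacts
  write_rr_contacts(g, tmp, min_separation = 3)
  g3 <- read_rr_contacts(tmp)
  idx <- which(g3$E == 1, arr.ind = TRUE)
  expect_true(all(abs(idx[, 1] - idx[, 2]) >= 3))
})

test_that("dataset save/load is a lossless, versioned round-trip", {
  set.seed(2)
  cfg <- sim_config(n_residues = 12, n_decoys = 10, seed = 4)
  ds <- make_decoy_dataset(sample_base_fold(cfg), cfg)
  ds <- split_dataset(ds, 0.8, seed = 1)
  tmp <- tempfile(fileext = ".rds")
  save_dataset(ds, tmp)
  ds2 <- load_dataset(tmp)
  expect_equal(ds2$split, ds$split)
  expect_equal(length(ds2$graphs), length(ds$graphs))
  for (i in seq_along(ds$graphs))
    expect_equal(ds2$graphs[[i]]$E, ds$graphs[[i]]$E)
  expect_equal(ds2$native$E, ds$native$E)
  # wrong content rejected
  tmp2 <- tempfile()
  saveRDS(list(a = 1), tmp2)
  expect_error(load_dataset(tmp2), "not a cgvae dataset")
  writeLines("garbage", tmp2)
  expect_error(load_dataset(tmp2), "unreadable|not a")
})
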