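# Molecular graph construction, SMILES parsing, conformers, intrinsic states.

test_that("SMILES parsing handles simple molecules and aromatic perception", {
  g <- parse_smiles("CC")
  expect_equal(nrow(g$atoms), 2)
  expect_equal(nrow(g$bonds), 1)
  expect_equal(g$dist[1, 2], 1)
  expect_equal(g$atoms$nH, c(3L, 3L))

  benz <- parse_smiles("c1ccccc1")
  expect_equal(sum(benz$atoms$aromatic), 6)
  expect_equal(sum(benz$bonds$aromatic), 6)
  expect_equal(max(benz$dist), 3)

  # Kekule input is aromatized to the same perception
  kek <- parse_smiles("C1=CC=CC=C1")
  expect_equal(sum(kek$atoms$aromatic), 6)
  expect_equal(sum(kek$bonds$aromatic), 6)

  # fused bicyclic: both rings perceived
  naph <- parse_smiles("C1=CC=C2C=CC=CC2=C1")
  expect_equal(sum(naph$atoms$aromatic), 10)

  # pyridine nitrogen carries no hydrogen
  pyr <- parse_smiles("c1ccncc1")
  expect_equal(pyr$atoms$nH[pyr$atoms$element == "N"], 0L)

  # bracket atoms: charge and explicit hydrogens
  am <- parse_smiles("[NH4+]")
  expect_equal(am$atoms$charge, 1L)
  expect_equal(am$atoms$nH, 4L)
})

test_that("malformed and multi-fragment SMILES produce instructive errors", {
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("CC)C"), "position 3")
  expect_error(parse_smiles("C(C"), "unclosed branch")
  expect_error(parse_smiles("C$"), "position 2")
  expect_error(parse_smiles("CCCC.Cl"), "desalt")
  frag <- parse_smiles("CCCC.Cl", keep_largest = TRUE)
  expect_equal(nrow(frag$atoms), 4)
})

test_that("graph invariants are enforced by the constructor", {
  atoms <- data.frame(element = c("C", "C"), charge = 0L, nH = 3L,
                      aromatic = FALSE)
  expect_error(molecular_graph(atoms, data.frame(i = 1, j = 1, order = 1,
                                                 aromatic = FALSE)),
               "self-bond")
  expect_error(molecular_graph(atoms, data.frame(i = c(1, 2), j = c(2, 1),
                                                 order = 1,
                                                 aromatic = FALSE)),
               "duplicate bond")
  expect_error(molecular_graph(atoms, data.frame(i = 1, j = 3, order = 1,
                                                 aromatic = FALSE)),
               "outside")
  expect_error(molecular_graph(atoms, data.frame(i = 1, j = 2, order = 1,
                                                 aromatic = TRUE)),
               "aromatic bond")
})

test_that("topological distances equal breadth-first search on small molecules", {
  withr::with_seed(421, {
    for (k in 1:20) {
      g <- random_small_molecule(sample(3:12, 1), with_conformer = FALSE)
      expect_equal(g$dist, oracle_bfs_distances(g))
    }
  })
  smiles_set <- c("CCO", "c1ccccc1", "CC(C)CC", "C1CCCCC1", "N#CCC=O")
  for (s in smiles_set) {
    g <- parse_smiles(s)
    expect_equal(g$dist, oracle_bfs_distances(g))
  }
})

test_that("ring perception agrees with an independent parser (OpenBabel)", {
  for (s in c("c1ccccc1", "c1ccncc1", "C1CCCCC1")) {
    ours <- parse_smiles(s)
    sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", s)
    tf <- withr::local_tempfile(fileext = ".sdf")
    writeLines(sdf_txt, tf)
    theirs <- suppressWarnings(ChemmineR::read.SDFset(tf))[[1]]
    expect_equal(nrow(ours$atoms), nrow(ChemmineR::atomblock(theirs)))
    expect_equal(nrow(ours$bonds), nrow(ChemmineR::bondblock(theirs)))
    # independent connectivity -> identical distance matrix
    bb <- ChemmineR::bondblock(theirs)
    g2 <- molecular_graph(
      data.frame(element = sub("_.*", "", rownames(ChemmineR::atomblock(theirs))),
                 charge = 0L, nH = 0L, aromatic = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = 1L, aromatic = FALSE))
    expect_equal(ours$dist, g2$dist)
  }
})

test_that("canonical SMILES round-trips to an isomorphic graph", {
  smiles_set <- c("CC", "c1ccccc1", "CC(=O)NC", "Cc1ccccc1",
                  "c1ccc2ncccc2c1", "CC(C)(C)O", "N#Cc1ccc(Cl)cc1",
                  "CC(=O)Nc1ccc(S(N)(=O)=O)cc1")
  color_of <- function(g) {
    as.integer(factor(paste(g$atoms$element, g$atoms$nH, g$atoms$aromatic)))
  }
  for (s in smiles_set) {
    g1 <- parse_smiles(s)
    cs <- write_smiles(g1)
    g2 <- parse_smiles(cs)
    expect_identical(write_smiles(g2), cs)  # idempotent canonical form
    ig1 <- igraph::graph_from_edgelist(cbind(g1$bonds$i, g1$bonds$j), FALSE)
    ig2 <- igraph::graph_from_edgelist(cbind(g2$bonds$i, g2$bonds$j), FALSE)
    expect_true(igraph::isomorphic(
      ig1, ig2, method = "vf2",
      vertex.color1 = color_of(g1), vertex.color2 = color_of(g2)))
  }
  # canonical form is independent of input atom ordering
  a <- write_smiles(parse_smiles("CCO"))
  b <- write_smiles(parse_smiles("OCC"))
  expect_identical(a, b)
})

test_that("conformer leverages satisfy the influence-matrix identities", {
  withr::with_seed(77, {
    xyz <- matrix(rnorm(30, sd = 2), 10, 3)
    cf <- conformer(xyz, rep(12.011, 10))
    expect_true(all(cf$h >= 0 & cf$h <= 1))
    expect_equal(sum(cf$h), 3, tolerance = 1e-12)
    # rigid rotation/translation leave h_ii unchanged
    R <- random_rotation()
    cf2 <- conformer(sweep(xyz %*% t(R), 2, c(5, -2, 1), "+"),
                     rep(12.011, 10))
    expect_equal(cf2$h, cf$h, tolerance = 1e-9)
    # planar molecule: rank 2
    flat <- conformer(cbind(rnorm(6), rnorm(6), 0), rep(1, 6))
    expect_equal(sum(flat$h), 2, tolerance = 1e-9)
    # linear molecule: rank 1
    line <- conformer(cbind(1:5, 0, 0), rep(1, 5))
    expect_equal(sum(line$h), 1, tolerance = 1e-9)
  })
})

test_that("intrinsic states match hand-evaluated Kier-Hall values", {
  eth <- intrinsic_states(parse_smiles("CC"))
  expect_equal(eth$I, c(2, 2))
  prop <- intrinsic_states(parse_smiles("CCC"))
  expect_equal(prop$I[2], 1.5)
  expect_equal(prop$delta, c(1L, 2L, 1L))
  expect_equal(prop$delta_v, c(1L, 2L, 1L))
  # oxygen is more electronegative: higher I than carbon at equal degree
  etoh <- intrinsic_states(parse_smiles("CCO"))
  expect_gt(etoh$I[3], etoh$I[1])
  # doubling delta with delta_v fixed strictly decreases I
  I_of <- function(L, dv, d) ((2 / L)^2 * dv + 1) / d
  expect_lt(I_of(2, 3, 4), I_of(2, 3, 2))
  expect_error(intrinsic_states(parse_smiles("C")), "at least 2")
})

test_that("SDF reading attaches conformers and collapses explicit hydrogens", {
  # build a tiny V2000 SDF by hand: ethanol with explicit hydrogens absent
  sdf <- c("ethanol", "  test", "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.5200    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    2.0800    1.3200    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0  0  0  0",
           "  2  3  1  0  0  0  0",
           "M  END", "$$$$")
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, tf)
  mols <- read_sdf_molecules(tf)
  g <- mols[[1]]
  expect_equal(nrow(g$atoms), 3)
  expect_equal(g$atoms$nH, c(3L, 2L, 1L))
  expect_false(is.null(g$conformer))
  expect_equal(g$conformer$r[1, 2], 1.52, tolerance = 1e-12)
})
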