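# Trajectory post-statistics: superposition, RMSD/RMSF/Rg, DCCM, PCA, FEL,
# and the trajectory file readers.

test_that("Kabsch superposition recovers rigid motions", {
  withr::with_seed(1, {
    ref <- matrix(rnorm(30, sd = 3), 10, 3)
    expect_lt(superpose(ref, ref)$rmsd, 1e-12)
    # pure translation
    expect_lt(superpose(sweep(ref, 2, c(3, 4, 0), "+"), ref)$rmsd, 1e-9)
    # random rotation + translation
    R <- random_rotation()
    moved <- sweep(ref %*% t(R), 2, c(1, -2, 5), "+")
    expect_lt(superpose(moved, ref)$rmsd, 1e-9)
    # collinear subset is degenerate
    line <- cbind(1:5, 0, 0)
    expect_error(superpose(line, line), "collinear")
    expect_error(superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  })
})

test_that("RMSD series closed forms", {
  withr::with_seed(2, {
    ref <- matrix(rnorm(24, sd = 2), 8, 3)
    tr <- trajectory(list(ref, ref, ref))
    expect_true(all(rmsd_series(tr) < 1e-12))
    # frame translated by (3,4,0): unfitted RMSD 5, fitted ~0
    shifted <- sweep(ref, 2, c(3, 4, 0), "+")
    tr2 <- trajectory(list(ref, shifted))
    expect_equal(rmsd_series(tr2, fit = FALSE)[2], 5, tolerance = 1e-12)
    expect_lt(rmsd_series(tr2, fit = TRUE)[2], 1e-9)
    # single-atom displacement d on n atoms: RMSD = d / sqrt(n)
    one <- ref; one[3, 1] <- one[3, 1] + 2
    tr3 <- trajectory(list(ref, one))
    expect_equal(rmsd_series(tr3, fit = FALSE)[2], 2 / sqrt(8),
                 tolerance = 1e-12)
    expect_error(rmsd_series(tr, subset = integer(0)), "empty")
  })
})

test_that("radius of gyration matches direct summation", {
  two <- trajectory(array(c(0, 2, 0, 0, 0, 0), dim = c(1, 2, 3)),
                    masses = c(1, 1))
  expect_equal(rg_series(two), 1, tolerance = 1e-12)
  single <- trajectory(array(rnorm(3), dim = c(1, 1, 3)), masses = 7)
  expect_equal(rg_series(single), 0)
  withr::with_seed(3, {
    xyz <- matrix(rnorm(36, sd = 4), 12, 3)
    mass <- runif(12, 1, 16)
    tr <- trajectory(array(xyz, dim = c(1, 12, 3)), masses = mass)
    com <- colSums(xyz * mass) / sum(mass)
    direct <- sqrt(sum(mass * rowSums(sweep(xyz, 2, com)^2)) / sum(mass))
    expect_equal(rg_series(tr), direct, tolerance = 1e-12)
  })
})

test_that("RMSF closed forms and isotropic expectation", {
  # static trajectory: all zero
  ref <- matrix(rnorm(15), 5, 3)
  expect_true(all(rmsf(trajectory(list(ref, ref, ref))) < 1e-12))
  # one atom oscillating +-a along x
  arr <- array(0, dim = c(4, 3, 3))
  arr[, 2, 1] <- c(1, -1, 1, -1) * 0.8
  rf <- rmsf(trajectory(arr))
  expect_equal(rf[2], 0.8, tolerance = 1e-12)
  expect_lt(max(rf[-2]), 1e-12)
  expect_error(rmsf(trajectory(array(0, dim = c(1, 3, 3)))), "2 frames")
  # isotropic Gaussian noise sigma: RMSF ~ sigma * sqrt(3)
  withr::with_seed(4, {
    sig <- 0.5
    arr2 <- array(rnorm(3000 * 4 * 3, sd = sig), dim = c(3000, 4, 3))
    rf2 <- rmsf(trajectory(arr2))
    expect_equal(mean(rf2), sig * sqrt(3), tolerance = 0.05)
  })
})

test_that("DCCM closed forms and bio3d cross-check", {
  # rigid collective translation on a static structure: all entries 1
  withr::with_seed(5, {
    base <- matrix(rnorm(12, sd = 3), 4, 3)
    arr <- array(0, dim = c(6, 4, 3))
    for (f in 1:6) arr[f, , ] <- base + f * 0.7
    C <- gaqsar::dccm(trajectory(arr))
    expect_equal(max(abs(unclass(C) - 1)), 0, tolerance = 1e-12)
  })
  # exact anti-phase pair
  tt <- traj_truth(n_atoms = 5, n_frames = 100, anti_pairs = cbind(1, 2),
                   noise_sigma = 0, seed = 4)
  Ca <- suppressWarnings(gaqsar::dccm(gen_trajectory(tt)))
  expect_equal(Ca[1, 2], -1, tolerance = 1e-12)
  # matrix invariants
  tt2 <- traj_truth(n_atoms = 6, n_frames = 120, anti_pairs = cbind(1, 4),
                    noise_sigma = 0.3, seed = 8)
  trj <- superpose_trajectory(gen_trajectory(tt2))
  C2 <- gaqsar::dccm(trj)
  expect_equal(unclass(C2), t(unclass(C2)), tolerance = 1e-12)
  expect_equal(diag(C2), rep(1, 6))
  expect_true(all(C2 >= -1 & C2 <= 1))
  # independent implementation: bio3d
  nf <- trj$n_frames; na <- trj$n_atoms
  xyz <- matrix(0, nf, 3 * na)
  for (a in seq_len(na)) for (k in 1:3) {
    xyz[, 3 * (a - 1) + k] <- trj$coords[, a, k]
  }
  Cb <- bio3d::dccm.xyz(xyz)
  expect_equal(unclass(C2), unclass(Cb), tolerance = 1e-10,
               ignore_attr = TRUE)
  # global rotation applied to every frame leaves the DCCM unchanged
  withr::with_seed(10, {
    R <- random_rotation()
    rot <- trj$coords
    for (f in seq_len(nf)) rot[f, , ] <- trj$coords[f, , ] %*% t(R)
    C3 <- gaqsar::dccm(trajectory(rot, trj$masses))
    expect_equal(unclass(C3), unclass(C2), tolerance = 1e-9)
  })
})

test_that("PCA recovers a planted collective mode and conserves variance", {
  withr::with_seed(6, {
    n_at <- 10; nf <- 400
    ref <- matrix(rnorm(n_at * 3, sd = 5), n_at, 3)
    mode <- rnorm(n_at * 3); mode <- mode / sqrt(sum(mode^2))
    amp <- rnorm(nf, sd = 2)
    arr <- array(0, dim = c(nf, n_at, 3))
    for (f in seq_len(nf)) {
      disp <- matrix(0.03 * rnorm(n_at * 3), n_at, 3)  # small noise
      flat_mode <- cbind(mode[1:n_at], mode[n_at + 1:n_at],
                         mode[2 * n_at + 1:n_at])
      arr[f, , ] <- ref + amp[f] * flat_mode + disp
    }
    pc <- pca_modes(trajectory(arr))
    # first eigenvector aligns with the planted mode
    v1 <- pc$vectors[, 1]
    expect_gt(abs(sum(v1 * mode)), 0.99)
    # eigenvalues: non-negative, descending, summing to total variance
    expect_true(all(pc$values >= 0))
    expect_true(all(diff(pc$values) <= 1e-12))
    flat <- cbind(arr[, , 1], arr[, , 2], arr[, , 3])
    expect_equal(sum(pc$values), sum(apply(flat, 2, var)),
                 tolerance = 1e-8)
    # full back-composition reproduces the centered coordinates
    recon <- pc$projections %*% t(pc$vectors)
    expect_lt(max(abs(recon - sweep(flat, 2, colMeans(flat)))), 1e-8)
  })
})

test_that("free-energy landscape follows Boltzmann inversion closed forms", {
  # uniform occupancy: all populated bins at exactly 0
  fu <- fel(rep(1:4, 25), rep(1:4, 25), bins = 4)
  expect_true(all(abs(fu$G[fu$counts > 0]) < 1e-12))
  # 90/10 two-state occupancy: minor state at kB * 300 * ln 9
  tt <- traj_truth(n_atoms = 4, n_frames = 2000, noise_sigma = 0,
                   jump_frac = 0.1, jump_offset = 6, seed = 6)
  trj <- gen_trajectory(tt)
  fg <- fel(rmsd_series(trj, fit = FALSE), rg_series(trj), bins = 8)
  expect_equal(max(fg$G, na.rm = TRUE), 0.0083145 * 300 * log(9),
               tolerance = 1e-9)
  expect_equal(min(fg$G, na.rm = TRUE), 0)
  # duplicating every frame leaves G unchanged
  xs <- c(rep(0, 90), rep(1, 10)); ys <- rep(0, 100)
  f1 <- fel(xs, ys, bins = 4)
  f2 <- fel(rep(xs, 3), rep(ys, 3), bins = 4)
  expect_identical(f1$G, f2$G)
  # temperature scaling is linear
  f300 <- fel(xs, ys, bins = 4, temperature = 300)
  f600 <- fel(xs, ys, bins = 4, temperature = 600)
  pop <- f300$counts > 0
  expect_equal(f600$G[pop], 2 * f300$G[pop], tolerance = 1e-12)
  expect_error(fel(numeric(0), numeric(0)), "empty")
})

test_that("XYZ and PDB trajectory readers round-trip coordinates", {
  tt <- traj_truth(n_atoms = 5, n_frames = 3, noise_sigma = 0.2, seed = 12)
  trj <- gen_trajectory(tt)
  # write multi-frame XYZ
  tf <- withr::local_tempfile(fileext = ".xyz")
  con <- file(tf, "w")
  for (f in 1:3) {
    writeLines(c("5", paste("frame", f)), con)
    for (a in 1:5) {
      writeLines(sprintf("C %.6f %.6f %.6f", trj$coords[f, a, 1],
                         trj$coords[f, a, 2], trj$coords[f, a, 3]), con)
    }
  }
  close(con)
  back <- read_xyz_trajectory(tf)
  expect_equal(back$n_frames, 3)
  expect_equal(back$coords, trj$coords, tolerance = 1e-6)
  expect_equal(back$masses, rep(12.011, 5))

  # write multi-MODEL PDB with CA atoms
  tp <- withr::local_tempfile(fileext = ".pdb")
  con <- file(tp, "w")
  for (f in 1:3) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (a in 1:5) {
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        a, a, trj$coords[f, a, 1], trj$coords[f, a, 2],
        trj$coords[f, a, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  backp <- read_pdb_trajectory(tp)
  expect_equal(backp$n_frames, 3)
  expect_equal(backp$n_atoms, 5)
  expect_equal(backp$coords, trj$coords, tolerance = 1e-3)

  # grid writer emits CSV plus JSON sidecar
  C <- gaqsar::dccm(trj)
  tg <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(C, tg)
  expect_true(file.exists(paste0(tg, ".json")))
  grid <- as.matrix(utils::read.csv(tg, header = FALSE))
  expect_equal(unname(grid), unclass(C), tolerance = 1e-10,
               ignore_attr = TRUE)
})
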