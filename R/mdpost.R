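# Formula-level post-processing of MD trajectories: Kabsch superposition,
# RMSD / RMSF / radius of gyration, dynamic cross-correlation, PCA modes,
# and Boltzmann-inversion free-energy landscapes.

#' Boltzmann constant in kJ/(mol K)
#' @export
KB_KJ_MOL_K <- 0.0083145

#' Construct a trajectory object
#'
#' @param coords numeric array \code{frames x atoms x 3} (Angstrom), or a
#'   list of \code{atoms x 3} frame matrices.
#' @param masses per-atom masses in amu (default 12.011 for all atoms).
#' @param times optional per-frame timestamps (ns).
#' @param subset optional integer vector naming an atom subset of interest
#'   (e.g. the C-alpha atoms), carried as an attribute default for the
#'   statistics functions.
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(coords, masses = NULL, times = NULL, subset = NULL) {
  if (is.list(coords)) {
    nat <- unique(vapply(coords, nrow, 0L))
    if (length(nat) != 1L) stop("atom count varies across frames")
    arr <- array(0, dim = c(length(coords), nat, 3L))
    for (f in seq_along(coords)) arr[f, , ] <- as.matrix(coords[[f]])
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n_atoms <- dim(coords)[2]
  if (is.null(masses)) masses <- rep(12.011, n_atoms)
  stopifnot(length(masses) == n_atoms, all(masses > 0))
  structure(list(coords = coords, masses = as.numeric(masses),
                 times = times, subset = subset,
                 n_frames = dim(coords)[1], n_atoms = n_atoms),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms\n")
  invisible(x)
}

.frame <- function(traj, f) traj$coords[f, , , drop = TRUE]

.resolve_subset <- function(traj, subset) {
  if (is.null(subset)) subset <- traj$subset
  if (is.null(subset)) subset <- seq_len(traj$n_atoms)
  subset
}

#' Kabsch superposition of one frame onto a reference
#'
#' Finds the rigid rotation + translation minimizing the (mass-unweighted)
#' squared deviation over the chosen atom subset, applies it to the whole
#' frame, and reports the post-fit RMSD over the subset.
#'
#' @param frame numeric \code{atoms x 3} matrix.
#' @param reference numeric \code{atoms x 3} matrix with matching atom count.
#' @param subset atom indices used for the fit (default: all atoms).
#' @return list with \code{coords} (the rotated/translated frame) and
#'   \code{rmsd} (over the subset, after fitting).
#' @export
superpose <- function(frame, reference, subset = NULL) {
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  stopifnot(nrow(frame) == nrow(reference), ncol(frame) == 3L)
  if (is.null(subset)) subset <- seq_len(nrow(frame))
  if (length(subset) < 3L) stop("superposition needs at least 3 atoms")
  A <- frame[subset, , drop = FALSE]
  B <- reference[subset, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (qr(Ac)$rank < 2L) stop("degenerate fit: subset atoms are collinear")
  sv <- svd(crossprod(Ac, Bc))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(sweep(frame, 2, ca) %*% t(R), 2, cb, "+")
  dev <- moved[subset, , drop = FALSE] - B
  list(coords = moved, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @param traj a [trajectory()].
#' @param reference reference coordinates: a frame index into \code{traj}
#'   (default 1, the first frame), the string \code{"mean"}, or an
#'   \code{atoms x 3} matrix.
#' @param subset atom indices used for the fit.
#' @return the superposed [trajectory()].
#' @export
superpose_trajectory <- function(traj, reference = 1L, subset = NULL) {
  subset <- .resolve_subset(traj, subset)
  ref <- if (is.matrix(reference)) reference
  else if (identical(reference, "mean")) apply(traj$coords, c(2, 3), mean)
  else .frame(traj, reference)
  out <- traj$coords
  for (f in seq_len(traj$n_frames)) {
    out[f, , ] <- superpose(.frame(traj, f), ref, subset)$coords
  }
  trajectory(out, traj$masses, traj$times, traj$subset)
}

#' Per-frame RMSD against a reference structure
#'
#' @param traj a [trajectory()].
#' @param reference reference as in [superpose_trajectory()].
#' @param subset atom indices entering the deviation (and the fit).
#' @param fit superpose each frame before measuring (default TRUE).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, subset = NULL, fit = TRUE) {
  subset <- .resolve_subset(traj, subset)
  if (length(subset) == 0L) stop("empty atom subset")
  ref <- if (is.matrix(reference)) reference
  else if (identical(reference, "mean")) apply(traj$coords, c(2, 3), mean)
  else .frame(traj, reference)
  vapply(seq_len(traj$n_frames), function(f) {
    fr <- .frame(traj, f)
    if (fit) {
      superpose(fr, ref, subset)$rmsd
    } else {
      dev <- fr[subset, , drop = FALSE] - ref[subset, , drop = FALSE]
      sqrt(mean(rowSums(dev^2)))
    }
  }, 0)
}

#' Per-frame radius of gyration
#'
#' \deqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}}
#'
#' @param traj a [trajectory()].
#' @param masses per-atom masses (default: the trajectory's).
#' @return numeric vector, one Rg (Angstrom) per frame.
#' @export
rg_series <- function(traj, masses = traj$masses) {
  stopifnot(length(masses) == traj$n_atoms)
  mtot <- sum(masses)
  vapply(seq_len(traj$n_frames), function(f) {
    fr <- .frame(traj, f)
    if (traj$n_atoms == 1L) return(0)
    com <- colSums(fr * masses) / mtot
    sqrt(sum(masses * rowSums(sweep(fr, 2, com)^2)) / mtot)
  }, 0)
}

#' Per-atom root mean square fluctuation
#'
#' \eqn{RMSF_i = \sqrt{\langle |r_i(t) - \langle r_i \rangle|^2 \rangle}}
#' over frames. Frames are assumed already superposed (see
#' [superpose_trajectory()]).
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param subset atom indices to report (default: all).
#' @return numeric vector of per-atom RMSF (Angstrom).
#' @export
rmsf <- function(traj, subset = NULL) {
  if (traj$n_frames < 2L) stop("RMSF needs at least 2 frames")
  subset <- .resolve_subset(traj, subset)
  xyz <- traj$coords[, subset, , drop = FALSE]
  mean_pos <- apply(xyz, c(2, 3), mean)
  dev2 <- sweep(xyz, c(2, 3), mean_pos)^2
  sqrt(apply(dev2, 2, mean) * 3)  # mean over frames AND axes, times 3 axes
}

#' Dynamic cross-correlation matrix
#'
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}},}
#' with \eqn{\Delta r} the deviation from the time-mean position. +1 denotes
#' synchronized motion, -1 anti-correlated motion. Atoms with zero
#' fluctuation get zero off-diagonal entries (diagonal 1) with a warning.
#' Frames are assumed superposed.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param subset atom indices (default: the trajectory's subset tag, e.g.
#'   C-alpha atoms, else all).
#' @return symmetric \code{correlation_matrix} with unit diagonal.
#' @export
dccm <- function(traj, subset = NULL) {
  if (traj$n_frames < 2L) stop("DCCM needs at least 2 frames")
  subset <- .resolve_subset(traj, subset)
  xyz <- traj$coords[, subset, , drop = FALSE]
  nf <- dim(xyz)[1]; na <- dim(xyz)[2]
  mean_pos <- apply(xyz, c(2, 3), mean)
  dev <- sweep(xyz, c(2, 3), mean_pos)
  # <dri . drj> = (1/F) sum_f sum_axis dev_fi_a dev_fj_a
  flat <- matrix(0, nf, na * 3L)
  for (a in 1:3) flat[, (a - 1L) * na + seq_len(na)] <- dev[, , a]
  cross <- matrix(0, na, na)
  for (a in 1:3) {
    block <- flat[, (a - 1L) * na + seq_len(na), drop = FALSE]
    cross <- cross + crossprod(block) / nf
  }
  msf <- diag(cross)
  zero <- msf <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-fluctuation atom(s): rows/columns set to 0")
    msf[zero] <- 1
  }
  C <- cross / sqrt(outer(msf, msf))
  if (any(zero)) {
    C[zero, ] <- 0; C[, zero] <- 0
  }
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  structure(C, class = c("correlation_matrix", "matrix"))
}

#' Principal component modes of atomic fluctuations
#'
#' Eigendecomposition of the \eqn{3N \times 3N} covariance matrix of the
#' flattened (superposed) coordinates, with per-frame projections on the
#' modes.
#'
#' @param traj a [trajectory()] with at least 2 frames (superposed).
#' @param subset atom indices (default: all).
#' @return list with \code{values} (eigenvalues, descending),
#'   \code{vectors} (columns are modes in the 3N flattened space, ordering
#'   \code{x1..xN,y1..yN,z1..zN}), \code{projections} (frames x modes), and
#'   \code{center} (the flattened mean structure).
#' @export
pca_modes <- function(traj, subset = NULL) {
  if (traj$n_frames < 2L) stop("PCA needs at least 2 frames")
  subset <- .resolve_subset(traj, subset)
  xyz <- traj$coords[, subset, , drop = FALSE]
  nf <- dim(xyz)[1]; na <- dim(xyz)[2]
  flat <- matrix(0, nf, na * 3L)
  for (a in 1:3) flat[, (a - 1L) * na + seq_len(na)] <- xyz[, , a]
  center <- colMeans(flat)
  centered <- sweep(flat, 2, center)
  covm <- crossprod(centered) / (nf - 1L)
  eig <- eigen(covm, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  list(values = values, vectors = eig$vectors,
       projections = centered %*% eig$vectors, center = center)
}

#' Free-energy landscape by Boltzmann inversion
#'
#' Bins two collective-coordinate series (PC1/PC2 projections, or RMSD and
#' Rg) into a 2D histogram and converts occupancies to relative Gibbs free
#' energies \eqn{G = -k_B T \ln(P/P_{max})} (kJ/mol). Populated bins have
#' \eqn{G \ge 0} with the global minimum at exactly 0; empty bins are
#' \code{NA}.
#'
#' @param xs,ys equal-length numeric coordinate series.
#' @param bins number of bins per axis (>= 2), or a length-2 vector.
#' @param temperature temperature in K (default 300, matching typical
#'   production conditions).
#' @return object of class \code{fel_grid}: \code{G} (matrix, x bins by
#'   y bins), \code{x_edges}, \code{y_edges}, \code{temperature}, \code{kB},
#'   \code{counts}.
#' @export
fel <- function(xs, ys, bins = 32L, temperature = 300) {
  stopifnot(length(xs) == length(ys))
  if (length(xs) == 0L) stop("empty coordinate series")
  bins <- rep(as.integer(bins), length.out = 2L)
  if (any(bins < 2L)) stop("need at least 2 bins per axis")
  pad <- function(r) if (r[1] == r[2]) r + c(-0.5, 0.5) else r
  xr <- pad(range(xs)); yr <- pad(range(ys))
  x_edges <- seq(xr[1], xr[2], length.out = bins[1] + 1L)
  y_edges <- seq(yr[1], yr[2], length.out = bins[2] + 1L)
  xi <- pmin(findInterval(xs, x_edges, rightmost.closed = TRUE), bins[1])
  yi <- pmin(findInterval(ys, y_edges, rightmost.closed = TRUE), bins[2])
  counts <- matrix(0L, bins[1], bins[2])
  for (k in seq_along(xi)) {
    counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1L
  }
  P <- counts / length(xs)
  G <- matrix(NA_real_, bins[1], bins[2])
  pop <- counts > 0L
  G[pop] <- -KB_KJ_MOL_K * temperature * log(P[pop] / max(P))
  structure(list(G = G, x_edges = x_edges, y_edges = y_edges,
                 temperature = temperature, kB = KB_KJ_MOL_K,
                 counts = counts),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("free-energy landscape: %d x %d bins, T = %g K, max G = %.3f kJ/mol\n",
              nrow(x$G), ncol(x$G), x$temperature, max(x$G, na.rm = TRUE)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Trajectory readers and grid writers

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ: per frame, an atom-count line, a comment line, then one
#' \code{element x y z} line per atom.
#'
#' @param path XYZ file path.
#' @return a [trajectory()] with masses looked up from the element symbols.
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  elements <- NULL
  k <- 1L
  while (k <= length(lines)) {
    if (!nzchar(trimws(lines[k]))) { k <- k + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[k])))
    if (is.na(nat)) stop("XYZ format error at line ", k,
                         ": expected atom count")
    block <- lines[(k + 2L):(k + 1L + nat)]
    parts <- strsplit(trimws(block), "[ \t]+")
    el <- vapply(parts, `[[`, "", 1L)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- co
    k <- k + 2L + nat
  }
  if (length(frames) == 0L) stop("no frames in ", path)
  trajectory(frames, masses = atomic_mass(elements))
}

#' Read a multi-MODEL PDB trajectory
#'
#' Uses \pkg{bio3d} to parse the PDB; by default restricts to C-alpha atoms
#' (atom name \code{CA}), the subset used for DCCM and PCA.
#'
#' @param path PDB file path.
#' @param calpha_only keep only C-alpha atoms (default TRUE).
#' @return a [trajectory()].
#' @export
read_pdb_trajectory <- function(path, calpha_only = TRUE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                       # frames x 3N matrix
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  keep <- if (calpha_only) which(pdb$atom$elety == "CA") else
    seq_len(nrow(pdb$atom))
  if (length(keep) == 0L) stop("no C-alpha atoms found in ", path)
  nf <- nrow(xyz)
  arr <- array(0, dim = c(nf, length(keep), 3L))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    arr[f, , ] <- m[keep, , drop = FALSE]
  }
  elem <- toupper(substr(trimws(pdb$atom$elesy[keep]), 1L, 2L))
  elem[!elem %in% .ELEMENT_DATA$symbol] <- "C"
  first <- paste0(substr(elem, 1, 1),
                  tolower(substr(elem, 2, 2)))
  trajectory(arr, masses = atomic_mass(first))
}

#' Write a correlation matrix (or FEL grid) as CSV with a JSON sidecar
#'
#' @param x a \code{correlation_matrix} from [dccm()] or a \code{fel_grid}
#'   from [fel()].
#' @param path output CSV path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return the CSV path, invisibly.
#' @export
write_grid_csv <- function(x, path) {
  if (inherits(x, "fel_grid")) {
    utils::write.table(x$G, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, na = "")
    meta <- list(kind = "fel_grid", x_edges = x$x_edges,
                 y_edges = x$y_edges, temperature = x$temperature,
                 kB = x$kB, units = "kJ/mol")
  } else {
    utils::write.table(unclass(x), path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    meta <- list(kind = "correlation_matrix", n_atoms = nrow(x))
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}
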