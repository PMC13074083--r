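# Seeded generators that emulate the statistical structure of the study's
# inputs (descriptor pools with a planted five-term linear signal; harmonic
# trajectories with planted correlated/anti-correlated modes), plus the
# bundled published-model fixture tables.

#' Ground truth for a synthetic QSAR descriptor pool
#'
#' The defaults mirror the published study conditions: the five model
#' descriptors planted with the published coefficients and intercept, and
#' marginals scaled so that each planted term contributes roughly 0.6
#' activity-SD, giving a realized training R-squared near 0.76 at the
#' default noise (sigma = 0.75 log units).
#'
#' @param coefficients named planted coefficients.
#' @param intercept planted intercept.
#' @param sigma Gaussian response noise SD (pIC50 log units).
#' @param n_near_constant number of planted near-constant decoy columns.
#' @param n_duplicate number of planted exact-duplicate columns.
#' @param n_correlated number of decoys correlated with planted columns.
#' @param decoy_cor correlation of those decoys with their planted partner.
#' @param lognormal_decoys fraction of plain decoys drawn lognormal rather
#'   than normal (descriptor pools are heavy-tailed).
#' @param seed integer RNG seed.
#' @return a \code{qsar_truth} list.
#' @export
qsar_truth <- function(coefficients = c(max_conj_path = 0.0554,
                                        MATS3s = 5.3355, R8m = 2.0399,
                                        CNCO = 1.186, MNA = 1.5020),
                       intercept = 4.9509, sigma = 0.75,
                       n_near_constant = 0L, n_duplicate = 0L,
                       n_correlated = 0L, decoy_cor = 0.6,
                       lognormal_decoys = 0, seed = 1L) {
  stopifnot(sigma >= 0, !is.null(names(coefficients)),
            decoy_cor >= -1, decoy_cor <= 1,
            lognormal_decoys >= 0, lognormal_decoys <= 1)
  structure(list(coefficients = coefficients, intercept = intercept,
                 sigma = sigma, n_near_constant = as.integer(n_near_constant),
                 n_duplicate = as.integer(n_duplicate),
                 n_correlated = as.integer(n_correlated),
                 decoy_cor = decoy_cor, lognormal_decoys = lognormal_decoys,
                 seed = as.integer(seed)),
            class = "qsar_truth")
}

# realistic marginals for the five planted descriptor families
.planted_column <- function(name, n) {
  switch(name,
    max_conj_path = pmax(pmin(round(stats::rnorm(n, 14, 10.8)), 40L), 0L),
    MATS3s = stats::rnorm(n, 0.05, 0.112),
    R8m = pmax(stats::rnorm(n, 0.9, 0.294), 0),
    CNCO = stats::rbinom(n, 1L, 0.5),
    MNA = stats::rbinom(n, 1L, 0.25),
    stats::rnorm(n)  # unknown planted names: standard normal
  )
}

#' Generate a synthetic QSAR dataset with a planted linear signal
#'
#' Descriptor columns: the planted columns named in \code{truth}, then plain
#' decoys (standard normal, optionally lognormal), then optional
#' correlated-decoy, near-constant, and duplicate columns. The response is
#' \code{intercept + X beta + N(0, sigma)}. Pure function of
#' \code{(parameters, seed)}.
#'
#' @param n_compounds number of compounds (study scale: 115).
#' @param n_descriptors total number of descriptor columns (at least the
#'   planted count plus the requested junk columns).
#' @param truth a [qsar_truth()].
#' @return list with \code{X} (matrix, ids \code{c001...} as row names),
#'   \code{y} (named activities), and \code{truth} (with
#'   \code{$planted}, \code{$junk_columns} filled in).
#' @export
gen_qsar_dataset <- function(n_compounds = 115L, n_descriptors = 60L,
                             truth = qsar_truth()) {
  stopifnot(inherits(truth, "qsar_truth"))
  planted <- names(truth$coefficients)
  n_junk <- truth$n_near_constant + truth$n_duplicate + truth$n_correlated
  if (n_descriptors < length(planted) + n_junk) {
    stop("n_descriptors too small for planted + junk columns")
  }
  n <- as.integer(n_compounds)
  .with_seed(truth$seed, {
    cols <- list()
    for (nm in planted) cols[[nm]] <- .planted_column(nm, n)
    n_plain <- n_descriptors - length(planted) - n_junk
    if (n_plain > 0L) {
      n_logn <- round(truth$lognormal_decoys * n_plain)
      for (k in seq_len(n_plain)) {
        cols[[sprintf("D%03d", k)]] <- if (k <= n_logn) {
          stats::rlnorm(n, 0, 0.8)
        } else stats::rnorm(n)
      }
    }
    if (truth$n_correlated > 0L) {
      for (k in seq_len(truth$n_correlated)) {
        partner <- planted[1L + (k - 1L) %% length(planted)]
        z <- as.numeric(scale(cols[[partner]]))
        rho <- truth$decoy_cor
        cols[[sprintf("CORR%02d_%s", k, partner)]] <-
          rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      }
    }
    if (truth$n_near_constant > 0L) {
      for (k in seq_len(truth$n_near_constant)) {
        v <- rep(1, n)
        n_var <- max(1L, floor(0.1 * n))   # 90% constant
        v[sample.int(n, n_var)] <- stats::rnorm(n_var, 1, 1)
        cols[[sprintf("NC%02d", k)]] <- v
      }
    }
    if (truth$n_duplicate > 0L) {
      base_pool <- setdiff(names(cols), planted)
      if (length(base_pool) == 0L) base_pool <- planted
      src <- sample(base_pool, truth$n_duplicate, replace = TRUE)
      for (k in seq_len(truth$n_duplicate)) {
        cols[[sprintf("DUP%02d_%s", k, src[k])]] <- cols[[src[k]]]
      }
    }
    X <- do.call(cbind, cols)
    rownames(X) <- sprintf("c%03d", seq_len(n))
    y <- truth$intercept +
      drop(X[, planted, drop = FALSE] %*% truth$coefficients) +
      stats::rnorm(n, 0, truth$sigma)
    names(y) <- rownames(X)
    truth$planted <- planted
    truth$junk_columns <- grep("^(NC|DUP)", colnames(X), value = TRUE)
    list(X = X, y = y, truth = truth)
  })
}

#' Ground truth for a synthetic harmonic trajectory
#'
#' @param n_atoms number of atoms.
#' @param n_frames number of frames (>= 2).
#' @param reference optional \code{atoms x 3} reference coordinates; the
#'   default is a loose 3D grid with ~4 Angstrom spacing.
#' @param anti_pairs optional 2-column matrix of atom index pairs displaced
#'   in exact opposition (before noise).
#' @param pair_amplitude displacement amplitude (Angstrom) of those pairs.
#' @param noise_sigma isotropic Gaussian positional noise SD (Angstrom).
#' @param jump_frac occupancy of a minor displaced state (0 disables the
#'   two-state jump).
#' @param jump_offset rigid displacement (Angstrom, applied along x to every
#'   atom) of minor-state frames.
#' @param seed integer RNG seed.
#' @return a \code{traj_truth} list.
#' @export
traj_truth <- function(n_atoms = 20L, n_frames = 200L, reference = NULL,
                       anti_pairs = NULL, pair_amplitude = 1.0,
                       noise_sigma = 0.1, jump_frac = 0, jump_offset = 5,
                       seed = 1L) {
  stopifnot(n_frames >= 2L, pair_amplitude >= 0, noise_sigma >= 0,
            jump_frac >= 0, jump_frac <= 1)
  if (!is.null(anti_pairs)) {
    anti_pairs <- matrix(as.integer(anti_pairs), ncol = 2L)
    if (any(anti_pairs < 1L | anti_pairs > n_atoms)) {
      stop("anti_pairs index outside 1..n_atoms")
    }
  }
  structure(list(n_atoms = as.integer(n_atoms),
                 n_frames = as.integer(n_frames), reference = reference,
                 anti_pairs = anti_pairs, pair_amplitude = pair_amplitude,
                 noise_sigma = noise_sigma, jump_frac = jump_frac,
                 jump_offset = jump_offset, seed = as.integer(seed)),
            class = "traj_truth")
}

#' Generate a synthetic trajectory with planted motion structure
#'
#' Frames are \code{reference + planted pair modes + isotropic noise};
#' declared anti-correlated pairs move in exact opposition before noise, and
#' an optional two-state jump displaces a seeded fraction of frames rigidly
#' (for free-energy-landscape closed forms). Pure function of
#' \code{(truth, seed)}.
#'
#' @param truth a [traj_truth()].
#' @return a [trajectory()].
#' @export
gen_trajectory <- function(truth) {
  stopifnot(inherits(truth, "traj_truth"))
  n <- truth$n_atoms; nf <- truth$n_frames
  ref <- truth$reference
  if (is.null(ref)) {
    side <- ceiling(n^(1 / 3))
    idx <- seq_len(n) - 1L
    ref <- 4 * cbind(idx %% side, (idx %/% side) %% side,
                     idx %/% (side * side))
  }
  stopifnot(nrow(ref) == n, ncol(ref) == 3L)
  .with_seed(truth$seed, {
    arr <- array(0, dim = c(nf, n, 3L))
    for (f in seq_len(nf)) arr[f, , ] <- ref
    if (!is.null(truth$anti_pairs) && nrow(truth$anti_pairs) > 0L) {
      for (p in seq_len(nrow(truth$anti_pairs))) {
        i <- truth$anti_pairs[p, 1]; j <- truth$anti_pairs[p, 2]
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        u <- truth$pair_amplitude * stats::rnorm(nf)
        for (a in 1:3) {
          arr[, i, a] <- arr[, i, a] + u * dir[a]
          arr[, j, a] <- arr[, j, a] - u * dir[a]
        }
      }
    }
    if (truth$jump_frac > 0) {
      n_minor <- round(truth$jump_frac * nf)
      minor <- sample.int(nf, n_minor)
      arr[minor, , 1] <- arr[minor, , 1] + truth$jump_offset
    }
    if (truth$noise_sigma > 0) {
      arr <- arr + array(stats::rnorm(length(arr), 0, truth$noise_sigma),
                         dim = dim(arr))
    }
    trajectory(arr, masses = rep(12.011, n))
  })
}

# ---------------------------------------------------------------------------
# Bundled published fixture tables

#' External validation pairs (8 compounds)
#'
#' The printed calculated/experimental pIC50 pairs of the published external
#' validation set.
#'
#' @return data frame with columns \code{compound}, \code{calculated},
#'   \code{experimental}.
#' @export
external_validation_pairs <- function() {
  data.frame(
    compound = 1:8,
    calculated   = c(4.782, 5.288, 8.429, 7.620, 6.272, 6.024, 6.306, 7.314),
    experimental = c(4.849, 5.070, 10.700, 7.469, 6.066, 6.143, 6.857, 7.221)
  )
}

#' Predicted activities of the designed compound series (18 analogs)
#'
#' Display/regression-test fixture only: the descriptor values of the
#' designed series are unpublished, so these predictions cannot be
#' recomputed here.
#'
#' @return data frame with columns \code{compound}, \code{pIC50}.
#' @export
design_series_predictions <- function() {
  data.frame(
    compound = c(2L, 4L, 9:24),
    pIC50 = c(4.3725, 8.0588, 6.1265, 5.9286, 6.3097, 7.4803, 7.5403,
              7.5616, 5.6982, 5.3384, 5.3398, 5.1299, 5.8935, 5.9529,
              7.1775, 7.7726, 7.1909, 7.0912)
  )
}

#' All bundled published fixtures
#'
#' @return list with \code{external_pairs} ([external_validation_pairs()]),
#'   \code{model} (the [published_model()]), and \code{design_predictions}
#'   ([design_series_predictions()]).
#' @export
fixtures <- function() {
  list(external_pairs = external_validation_pairs(),
       model = published_model(),
       design_predictions = design_series_predictions())
}
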