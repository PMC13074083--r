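# The five descriptor families of the published five-term activity model:
# longest pi-conjugation path, Moran autocorrelation (lag 3, intrinsic-state
# weighted), GETAWAY R autocorrelation (lag 8, mass weighted), carbamoyl/urea
# fragment count, and one multilevel-neighborhood-of-atoms substructure count.

#' Longest continuous pi-conjugation path
#'
#' A bond is conjugated when it is aromatic, has order two or more, or is a
#' single bond both of whose endpoints carry another incident multiple or
#' aromatic bond. The descriptor is the number of bonds in the longest simple
#' path (no repeated atoms) within the conjugated-bond subgraph; a molecule
#' with no conjugated bonds scores 0. Ring closure under the no-revisit
#' convention yields ring size minus one (benzene scores 5).
#'
#' @param graph a [molecular_graph()].
#' @return integer bond count.
#' @export
max_conj_path <- function(graph) {
  bonds <- graph$bonds
  if (nrow(bonds) == 0L) return(0L)
  n <- nrow(graph$atoms)
  multiple <- bonds$order >= 2L | bonds$aromatic
  has_multiple <- rep(FALSE, n)
  has_multiple[unique(c(bonds$i[multiple], bonds$j[multiple]))] <- TRUE
  conj <- multiple | (bonds$order == 1L & has_multiple[bonds$i] &
                        has_multiple[bonds$j])
  if (!any(conj)) return(0L)
  cb <- bonds[conj, , drop = FALSE]
  adj <- vector("list", n)
  for (b in seq_len(nrow(cb))) {
    adj[[cb$i[b]]] <- c(adj[[cb$i[b]]], cb$j[b])
    adj[[cb$j[b]]] <- c(adj[[cb$j[b]]], cb$i[b])
  }
  best <- 0L
  visited <- rep(FALSE, n)
  dfs <- function(v, len) {
    visited[v] <<- TRUE
    if (len > best) best <<- len
    for (w in adj[[v]]) if (!visited[w]) dfs(w, len + 1L)
    visited[v] <<- FALSE
  }
  for (v in unique(c(cb$i, cb$j))) dfs(v, 0L)
  best
}

#' Moran autocorrelation at a topological lag
#'
#' The centered Moran form used by the Dragon MATS descriptors:
#' \deqn{MATS_k = \frac{\sum_{i<j:\,d_{ij}=k} (w_i-\bar w)(w_j-\bar w) / \Delta_k}
#'                    {\sum_i (w_i-\bar w)^2 / N},}
#' where \eqn{\Delta_k} is the number of atom pairs at topological distance
#' \eqn{k}. Returns 0 when no pair sits at the lag or the weights have zero
#' variance.
#'
#' @param graph a [molecular_graph()].
#' @param weights per-atom numeric weights (length = atom count).
#' @param lag topological distance \eqn{k \ge 1}.
#' @return the Moran coefficient.
#' @export
moran_autocorrelation <- function(graph, weights, lag) {
  n <- nrow(graph$atoms)
  stopifnot(length(weights) == n)
  if (!is.numeric(lag) || length(lag) != 1L || lag < 1) {
    stop("lag must be a single integer >= 1")
  }
  wbar <- mean(weights)
  denom <- sum((weights - wbar)^2) / n
  if (denom == 0) return(0)
  d <- graph$dist
  pair <- which(upper.tri(d) & d == lag, arr.ind = TRUE)
  if (nrow(pair) == 0L) return(0)
  num <- sum((weights[pair[, 1]] - wbar) * (weights[pair[, 2]] - wbar)) /
    nrow(pair)
  num / denom
}

#' MATS3s: Moran autocorrelation of lag 3 weighted by intrinsic states
#'
#' Convenience wrapper: [moran_autocorrelation()] at lag 3 with the Kier-Hall
#' intrinsic states of [intrinsic_states()] as weights.
#'
#' @param graph a [molecular_graph()] with at least two connected heavy atoms.
#' @return the MATS3s value.
#' @export
mats3s <- function(graph) {
  moran_autocorrelation(graph, intrinsic_states(graph)$I, lag = 3L)
}

#' GETAWAY R autocorrelation at a topological lag
#'
#' \deqn{R_k = \sum_{i<j:\,d_{ij}=k} \frac{\sqrt{h_{ii} h_{jj}}}{r_{ij}}\, w_i w_j,}
#' with \eqn{h_{ii}} the molecular-influence-matrix leverages and
#' \eqn{r_{ij}} interatomic distances of the conformer. Returns 0 when no
#' atom pair sits at the lag.
#'
#' @param graph a [molecular_graph()].
#' @param conf a [conformer()] aligned with the graph (defaults to the one
#'   attached to the graph).
#' @param lag topological distance \eqn{k \ge 1}.
#' @param weights per-atom weights; the default is atomic mass scaled by the
#'   carbon mass (the Dragon \code{m} weighting), giving R8m at
#'   \code{lag = 8}.
#' @return the \eqn{R_k} value.
#' @export
getaway_r_autocorr <- function(graph, conf = graph$conformer, lag,
                               weights = NULL) {
  if (is.null(conf)) {
    stop("no 3D conformer available: GETAWAY descriptors need coordinates; ",
         "supply an SDF with 3D structures (read_sdf_molecules)")
  }
  n <- nrow(graph$atoms)
  stopifnot(nrow(conf$coords) == n)
  if (!is.numeric(lag) || length(lag) != 1L || lag < 1) {
    stop("lag must be a single integer >= 1")
  }
  if (is.null(weights)) weights <- conf$masses / 12.011
  stopifnot(length(weights) == n)
  d <- graph$dist
  pair <- which(upper.tri(d) & d == lag, arr.ind = TRUE)
  if (nrow(pair) == 0L) return(0)
  i <- pair[, 1]; j <- pair[, 2]
  sum(sqrt(conf$h[i] * conf$h[j]) / conf$r[cbind(i, j)] *
        weights[i] * weights[j])
}

#' R8m: GETAWAY R autocorrelation of lag 8 weighted by mass
#'
#' @param graph a [molecular_graph()] with a conformer attached (or supplied).
#' @param conf optional [conformer()] overriding the attached one.
#' @return the R8m value.
#' @export
r8m <- function(graph, conf = graph$conformer) {
  getaway_r_autocorr(graph, conf, lag = 8L)
}

# Refinement-only ranks: atoms sharing a rank are (at least) candidates for
# the same automorphism orbit; used to collapse symmetric fragment matches.
.refined_orbits <- function(graph) {
  n <- nrow(graph$atoms)
  a <- graph$atoms
  deg <- tabulate(c(graph$bonds$i, graph$bonds$j), nbins = n)
  inv <- paste(a$element, a$charge, a$nH, a$aromatic, deg)
  ranks <- as.integer(factor(inv, levels = sort(unique(inv))))
  adj <- vector("list", n)
  for (b in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[b]; j <- graph$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  repeat {
    sig <- vapply(seq_len(n), function(v) {
      paste(sprintf("%08d", ranks[v]),
            paste(sprintf("%08d", sort(ranks[adj[[v]]])), collapse = ","))
    }, "")
    new <- as.integer(factor(sig, levels = sort(unique(sig))))
    if (identical(new, ranks)) return(ranks)
    ranks <- new
  }
}

#' Count C-N-C=O (carbamoyl / urea-like) fragments
#'
#' Enumerates atom quadruples (C, N, C, O) bonded as C-N, N-C, C=O. Matches
#' that differ only by symmetry-equivalent first carbons on the same nitrogen
#' (for example the two methyls of a N,N-dimethyl amide) are counted once, so
#' tetramethylurea scores 2.
#'
#' @param graph a [molecular_graph()].
#' @return non-negative integer count.
#' @export
count_cnc_o <- function(graph) {
  atoms <- graph$atoms; bonds <- graph$bonds
  if (nrow(bonds) == 0L) return(0L)
  n <- nrow(atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  is_double <- function(i, j) {
    any(bonds$order == 2L & !bonds$aromatic &
          ((bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i)))
  }
  orbits <- NULL
  matches <- character(0)
  for (c2 in which(atoms$element == "C")) {
    oxy <- adj[[c2]][atoms$element[adj[[c2]]] == "O"]
    oxy <- oxy[vapply(oxy, function(o) is_double(c2, o), FALSE)]
    if (length(oxy) == 0L) next
    nitro <- adj[[c2]][atoms$element[adj[[c2]]] == "N"]
    for (nn in nitro) {
      c1s <- adj[[nn]][atoms$element[adj[[nn]]] == "C"]
      c1s <- setdiff(c1s, c2)
      if (length(c1s) == 0L) next
      if (is.null(orbits)) orbits <- .refined_orbits(graph)
      for (o in oxy) {
        matches <- c(matches,
                     unique(paste(orbits[c1s], nn, c2, o)))
      }
    }
  }
  length(unique(matches))
}

# Parse an MNA level-2 pattern like "-H(-C(C-H-H-C))": a hydrogen bonded to
# an atom of element E whose full neighbor multiset is the listed elements.
.parse_mna_pattern <- function(target) {
  cleaned <- gsub("[* ]", "", target)
  m <- regmatches(cleaned, regexec(
    "^-?H\\(-?([A-Z][a-z]?)\\(([A-Za-z-]+)\\)\\)$", cleaned))[[1]]
  if (length(m) == 0L) {
    stop("malformed MNA pattern '", target,
         "': expected the form -H(-C(C-H-H-C))")
  }
  neigh <- strsplit(m[3], "-", fixed = TRUE)[[1]]
  neigh <- neigh[nzchar(neigh)]
  if (length(neigh) == 0L) stop("malformed MNA pattern: empty neighbor list")
  list(parent = m[2], neighbors = sort(neigh))
}

#' Count hydrogens matching a level-2 MNA substructure
#'
#' Multilevel neighborhoods of atoms (MNA) describe an atom by its element
#' and the canonically sorted elements of its neighbors, recursively. The
#' model uses one such pattern, \code{-H(-C(C-H-H-C))}: a hydrogen attached
#' to a carbon whose complete neighbor multiset (hydrogens expanded
#' virtually, the queried hydrogen included) is \{C, H, H, C\}. Propane
#' scores 2 (the central methylene hydrogens), cyclohexane 12.
#'
#' @param graph a [molecular_graph()].
#' @param target MNA pattern string; default is the model's pattern.
#' @return non-negative integer count of matching hydrogen atoms.
#' @export
count_mna <- function(graph, target = "-H(-C(C-H-H-C))") {
  pat <- .parse_mna_pattern(target)
  atoms <- graph$atoms
  n <- nrow(atoms)
  heavy_neigh <- vector("list", n)
  for (b in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[b]; j <- graph$bonds$j[b]
    heavy_neigh[[i]] <- c(heavy_neigh[[i]], j)
    heavy_neigh[[j]] <- c(heavy_neigh[[j]], i)
  }
  total <- 0L
  for (v in which(atoms$element == pat$parent)) {
    if (atoms$nH[v] == 0L) next  # need at least one H to anchor the pattern
    multiset <- sort(c(atoms$element[heavy_neigh[[v]]],
                       rep("H", atoms$nH[v])))
    if (identical(multiset, pat$neighbors)) total <- total + atoms$nH[v]
  }
  total
}

#' Compute the five model descriptors for one molecule
#'
#' @param graph a [molecular_graph()].
#' @param conf optional [conformer()]; when neither this nor
#'   \code{graph$conformer} is available, \code{R8m} is reported as \code{NA}
#'   (absent, not zero).
#' @return a one-row data frame with columns \code{max_conj_path},
#'   \code{MATS3s}, \code{R8m}, \code{CNCO} (the C-N-C=O fragment count) and
#'   \code{MNA}.
#' @export
descriptor_vector <- function(graph, conf = graph$conformer) {
  r8 <- if (is.null(conf)) NA_real_ else getaway_r_autocorr(graph, conf, 8L)
  data.frame(
    max_conj_path = max_conj_path(graph),
    MATS3s = mats3s(graph),
    R8m = r8,
    CNCO = count_cnc_o(graph),
    MNA = count_mna(graph)
  )
}

#' Descriptor table for a set of molecules
#'
#' @param mols named list of [molecular_graph()] objects (e.g. from
#'   [read_smiles()] or [read_sdf_molecules()]).
#' @return data frame with an \code{id} column followed by the five
#'   descriptor columns.
#' @export
descriptor_table <- function(mols) {
  stopifnot(is.list(mols), length(mols) > 0L)
  ids <- names(mols)
  if (is.null(ids)) ids <- paste0("mol", seq_along(mols))
  rows <- lapply(mols, descriptor_vector)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), out)
}
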