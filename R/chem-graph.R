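# Molecular graphs: the substrate for all 2D descriptors.
#
# A molecular_graph stores heavy atoms only; hydrogens are implicit counts on
# each atom (the MNA matcher expands them virtually). Topological distances
# are shortest-path bond counts, computed once at construction.

.ELEMENT_DATA <- local({
  sym <- c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S", "Cl",
           "K", "Ca", "Br", "I")
  data.frame(
    symbol  = sym,
    mass    = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 22.990,
                24.305, 28.086, 30.974, 32.06, 35.45, 39.098, 40.078,
                79.904, 126.904),
    # principal quantum number of the valence shell (periodic row)
    L       = c(1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L, 3L, 4L, 4L,
                4L, 5L),
    # valence electron count
    zv      = c(1L, 3L, 4L, 5L, 6L, 7L, 1L, 2L, 4L, 5L, 6L, 7L, 1L, 2L,
                7L, 7L),
    stringsAsFactors = FALSE
  )
})

# normal valences used for implicit-hydrogen filling (organic subset)
.DEFAULT_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

.element_field <- function(symbol, field) {
  idx <- match(symbol, .ELEMENT_DATA$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  .ELEMENT_DATA[[field]][idx]
}

#' Atomic masses for element symbols
#'
#' @param symbols character vector of element symbols (e.g. \code{"C"}).
#' @return numeric vector of atomic masses in amu.
#' @export
atomic_mass <- function(symbols) .element_field(symbols, "mass")

#' Construct a molecular graph
#'
#' Low-level constructor. Most users obtain graphs from [parse_smiles()] or
#' [read_sdf_molecules()].
#'
#' @param atoms data frame with columns \code{element}, \code{charge},
#'   \code{nH} (attached hydrogen count), \code{aromatic} (logical), and
#'   optionally \code{L} (valence-shell principal quantum number; filled from
#'   the element when absent).
#' @param bonds data frame with columns \code{i}, \code{j} (atom indices),
#'   \code{order} (1, 2 or 3) and \code{aromatic} (logical).
#' @param conformer optional [conformer()] carrying 3D coordinates.
#' @return an object of class \code{molecular_graph} with components
#'   \code{atoms}, \code{bonds}, \code{dist} (topological distance matrix)
#'   and \code{conformer}.
#' @export
molecular_graph <- function(atoms, bonds, conformer = NULL) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  n <- nrow(atoms)
  if (is.null(atoms$L)) atoms$L <- .element_field(atoms$element, "L")
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
      stop("bond endpoint indexes an atom outside 1..", n)
    }
    if (any(bonds$i == bonds$j)) stop("self-bond is not allowed")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
    bad <- bonds$aromatic & !(atoms$aromatic[bonds$i] & atoms$aromatic[bonds$j])
    if (any(bad)) stop("aromatic bond with a non-aromatic endpoint")
    if (any(!bonds$order %in% 1:3)) stop("bond order must be 1, 2 or 3")
  }
  g <- structure(
    list(atoms = atoms, bonds = bonds, dist = NULL, conformer = conformer),
    class = "molecular_graph"
  )
  g$dist <- .topological_distances(g)
  g
}

.as_igraph <- function(graph) {
  n <- nrow(graph$atoms)
  if (nrow(graph$bonds) == 0) {
    return(igraph::make_empty_graph(n, directed = FALSE))
  }
  ig <- igraph::graph_from_edgelist(
    cbind(graph$bonds$i, graph$bonds$j), directed = FALSE
  )
  if (igraph::vcount(ig) < n) {
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  }
  ig
}

.topological_distances <- function(graph) {
  n <- nrow(graph$atoms)
  d <- igraph::distances(.as_igraph(graph))
  dimnames(d) <- NULL
  d[!is.finite(d)] <- Inf
  d
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("molecular_graph:", nrow(x$atoms), "heavy atoms,",
      nrow(x$bonds), "bonds")
  if (!is.null(x$conformer)) cat(", 3D conformer attached")
  cat("\n  formula atoms:",
      paste(sprintf("%s(%d)", names(table(x$atoms$element)),
                    table(x$atoms$element)), collapse = " "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# SMILES parsing

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (\code{B C N O P S F Cl Br I}), aromatic
#' lowercase atoms, bracket atoms with explicit hydrogen counts and charges,
#' branches, ring-closure digits (including \code{\%nn}), and the bond
#' symbols \code{- = # : / \\}. Directional bonds are read as single bonds
#' (stereochemistry is out of scope). Aromaticity written in lowercase is
#' taken as given; Kekule input is aromatized by a Hueckel-style perception
#' over 5- and 6-membered rings.
#'
#' @param smiles a single SMILES string.
#' @param keep_largest if \code{TRUE}, a multi-fragment (salt) input is
#'   reduced to its largest connected fragment; the default is to refuse such
#'   input so that desalting stays an explicit decision.
#' @return a [molecular_graph()].
#' @export
parse_smiles <- function(smiles, keep_largest = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  nch <- nchar(smiles)
  if (nch == 0L) stop("empty SMILES string")

  atoms <- list()   # each: list(element, aromatic, charge, nH_explicit)
  bonds <- list()   # each: list(i, j, order, arom_explicit, default)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NULL        # explicit bond symbol waiting for next atom
  ring <- list()         # open ring closures: number -> list(atom, pending)
  fragment_break <- FALSE

  fail <- function(pos, msg) {
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 pos, substr(smiles, pos, pos), msg), call. = FALSE)
  }

  add_atom <- function(element, aromatic, charge = 0L, nH = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = charge, nH = nH
    )
    idx <- length(atoms)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- NULL
    prev <<- idx
    idx
  }

  add_bond <- function(i, j, pend) {
    if (is.null(pend)) {
      bonds[[length(bonds) + 1L]] <<- list(i = i, j = j, order = 1L,
                                           arom_explicit = FALSE,
                                           default = TRUE)
    } else {
      bonds[[length(bonds) + 1L]] <<- list(i = i, j = j, order = pend$order,
                                           arom_explicit = pend$aromatic,
                                           default = FALSE)
    }
  }

  close_ring <- function(num, pos) {
    key <- as.character(num)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, pending = pending)
    } else {
      open <- ring[[key]]
      ring[[key]] <<- NULL
      pend <- if (!is.null(pending)) pending else open$pending
      if (open$atom == prev) fail(pos, "ring bond closes on the same atom")
      add_bond(open$atom, prev, pend)
    }
    pending <<- NULL
  }

  i <- 1L
  while (i <= nch) {
    ch <- substr(smiles, i, i)
    two <- substr(smiles, i, i + 1L)
    if (ch %in% c("-", "/", "\\")) {
      pending <- list(order = 1L, aromatic = FALSE); i <- i + 1L
    } else if (ch == "=") {
      pending <- list(order = 2L, aromatic = FALSE); i <- i + 1L
    } else if (ch == "#") {
      pending <- list(order = 3L, aromatic = FALSE); i <- i + 1L
    } else if (ch == ":") {
      pending <- list(order = 1L, aromatic = TRUE); i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) fail(i, "branch opened before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail(i, "unmatched closing parenthesis")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      fragment_break <- TRUE
      prev <- NA_integer_; pending <- NULL; i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      if (is.na(prev)) fail(i, "ring closure before any atom")
      close_ring(as.integer(ch), i); i <- i + 1L
    } else if (ch == "%") {
      num <- substr(smiles, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", num)) fail(i, "'%' must be followed by two digits")
      close_ring(as.integer(num), i); i <- i + 3L
    } else if (ch == "[") {
      close_pos <- regexpr("]", substr(smiles, i, nch), fixed = TRUE)
      if (close_pos < 0) fail(i, "unclosed bracket atom")
      body <- substr(smiles, i + 1L, i + close_pos - 2L)
      spec <- .parse_bracket_atom(body, i, fail)
      add_atom(spec$element, spec$aromatic, spec$charge, spec$nH)
      i <- i + close_pos
    } else if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE); i <- i + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      add_atom(ch, FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE); i <- i + 1L
    } else {
      fail(i, "unrecognized token")
    }
  }
  if (length(stack) > 0L) stop("SMILES parse error: unclosed branch '('")
  if (length(ring) > 0L) {
    stop(sprintf("SMILES parse error: unclosed ring bond(s) %s",
                 paste(names(ring), collapse = ", ")))
  }
  if (length(atoms) == 0L) stop("SMILES contains no atoms")

  g <- .assemble_graph(atoms, bonds)
  comps <- igraph::components(.as_igraph(g))
  if (comps$no > 1L || fragment_break) {
    if (!keep_largest) {
      stop("SMILES describes ", comps$no, " disconnected fragments ",
           "(salt/solvate?); desalt the input or call with ",
           "keep_largest = TRUE to retain the largest fragment")
    }
    keep <- which(comps$membership == which.max(comps$csize))
    g <- .subset_graph(g, keep)
  }
  g
}

.parse_bracket_atom <- function(body, pos, fail) {
  # [isotope? symbol chirality? Hcount? charge?]  (isotope/chirality ignored)
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H([0-9]*))?([+-][0-9+-]*)?$", body))[[1]]
  if (length(m) == 0L) fail(pos, paste0("cannot parse bracket atom [", body, "]"))
  sym <- m[3]
  aromatic <- sym == tolower(sym) && nchar(sym) <= 2L &&
    sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
  } else sym
  nH <- if (m[5] == "") 0L else if (m[6] == "") 1L else as.integer(m[6])
  charge_str <- m[7]
  charge <- 0L
  if (nchar(charge_str) > 0) {
    if (grepl("^[+-][0-9]+$", charge_str)) {
      charge <- as.integer(charge_str)
    } else {
      charge <- sum(ifelse(strsplit(charge_str, "")[[1]] == "+", 1L, -1L))
    }
  }
  list(element = element, aromatic = aromatic, charge = charge, nH = nH)
}

.assemble_graph <- function(atoms, bonds) {
  atom_df <- data.frame(
    element  = vapply(atoms, `[[`, "", "element"),
    charge   = vapply(atoms, `[[`, 0L, "charge"),
    nH       = vapply(atoms, `[[`, 0L, "nH"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    stringsAsFactors = FALSE
  )
  nH_explicit <- !vapply(atoms, function(a) is.na(a$nH), FALSE)
  atom_df$nH[!nH_explicit] <- 0L

  if (length(bonds) > 0L) {
    bond_df <- data.frame(
      i = vapply(bonds, `[[`, 0L, "i"),
      j = vapply(bonds, `[[`, 0L, "j"),
      order = vapply(bonds, `[[`, 0L, "order"),
      aromatic = FALSE
    )
    arom_explicit <- vapply(bonds, `[[`, FALSE, "arom_explicit")
    is_default <- vapply(bonds, `[[`, FALSE, "default")
    # a default bond between two aromatic atoms is aromatic when it lies in a
    # ring; acyclic biaryl linkers stay single
    candidate <- is_default &
      atom_df$aromatic[bond_df$i] & atom_df$aromatic[bond_df$j]
    if (any(candidate) || any(arom_explicit)) {
      ig <- igraph::graph_from_edgelist(cbind(bond_df$i, bond_df$j),
                                        directed = FALSE)
      br <- igraph::bridges(ig)
      in_ring <- !(seq_len(nrow(bond_df)) %in% as.integer(br))
      bond_df$aromatic <- arom_explicit | (candidate & in_ring)
    }
  } else {
    bond_df <- data.frame(i = integer(0), j = integer(0),
                          order = integer(0), aromatic = logical(0))
  }

  # Kekule input: perceive aromatic rings before hydrogen filling
  perceived <- .perceive_aromaticity(atom_df, bond_df)
  atom_df <- perceived$atoms
  bond_df <- perceived$bonds

  atom_df$nH[!nH_explicit] <-
    .implicit_hydrogens(atom_df, bond_df)[!nH_explicit]
  molecular_graph(atom_df, bond_df)
}

.implicit_hydrogens <- function(atoms, bonds) {
  n <- nrow(atoms)
  order_sum <- numeric(n)
  arom_count <- integer(n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    if (bonds$aromatic[b]) {
      arom_count[i] <- arom_count[i] + 1L
      arom_count[j] <- arom_count[j] + 1L
    } else {
      order_sum[i] <- order_sum[i] + bonds$order[b]
      order_sum[j] <- order_sum[j] + bonds$order[b]
    }
  }
  total <- order_sum + ceiling(1.5 * arom_count)
  vapply(seq_len(n), function(k) {
    val <- .DEFAULT_VALENCES[[atoms$element[k]]]
    if (is.null(val) || atoms$charge[k] != 0L) return(0L)
    fits <- val[val >= total[k]]
    if (length(fits) == 0L) return(0L)
    as.integer(fits[1] - total[k])
  }, 0L)
}

# Hueckel-style perception over 5/6-membered fundamental cycles of Kekule
# input. Lowercase-aromatic input bypasses this (flags already set).
.perceive_aromaticity <- function(atoms, bonds) {
  if (nrow(bonds) == 0L) return(list(atoms = atoms, bonds = bonds))
  ig <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  rings <- .small_rings(ig, max_size = 6L)
  rings <- rings[vapply(rings, length, 0L) %in% c(5L, 6L)]
  if (length(rings) == 0L) return(list(atoms = atoms, bonds = bonds))

  bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  keys <- bond_key(bonds$i, bonds$j)
  double_partner <- rep(NA_integer_, nrow(atoms))
  dbl <- which(bonds$order == 2L & !bonds$aromatic)
  for (b in dbl) {
    double_partner[bonds$i[b]] <- bonds$j[b]
    double_partner[bonds$j[b]] <- bonds$i[b]
  }

  for (pass in 1:4) {
    changed <- FALSE
    for (ring in rings) {
      if (all(atoms$aromatic[ring])) next
      pi_e <- 0L; ok <- TRUE
      for (a in ring) {
        dp <- double_partner[a]
        if (!is.na(dp) && (dp %in% ring || atoms$aromatic[dp])) {
          pi_e <- pi_e + 1L
        } else if (is.na(dp) && atoms$aromatic[a]) {
          pi_e <- pi_e + 1L          # already part of a fused aromatic system
        } else if (is.na(dp) && atoms$element[a] %in% c("N", "O", "S")) {
          pi_e <- pi_e + 2L          # lone-pair donor (pyrrole-type)
        } else if (!is.na(dp)) {
          ok <- FALSE; break        # exocyclic double bond (quinoid)
        } else {
          ok <- FALSE; break        # sp3 center
        }
      }
      if (ok && pi_e == 6L) {
        atoms$aromatic[ring] <- TRUE
        m <- length(ring)
        rkeys <- bond_key(ring, ring[c(2:m, 1L)])
        hit <- keys %in% rkeys
        bonds$aromatic[hit] <- TRUE
        bonds$order[hit] <- 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(atoms = atoms, bonds = bonds)
}

# Smallest ring through each edge: delete the edge, take the shortest
# remaining path between its endpoints. Covers the SSSR of fused bi/tricyclic
# systems common in this chemistry.
.small_rings <- function(ig, max_size = 6L) {
  el <- igraph::as_edgelist(ig)
  rings <- list()
  seen <- character(0)
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    g2 <- igraph::delete_edges(ig, e)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = a, to = b)$vpath[[1]]
    )
    if (length(sp) == 0L || length(sp) > max_size) next
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- ring
  }
  rings
}

.subset_graph <- function(graph, keep) {
  remap <- match(seq_len(nrow(graph$atoms)), keep)
  bonds <- graph$bonds[graph$bonds$i %in% keep & graph$bonds$j %in% keep, ,
                       drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  conf <- graph$conformer
  if (!is.null(conf)) {
    conf <- conformer(conf$coords[keep, , drop = FALSE], conf$masses[keep])
  }
  molecular_graph(graph$atoms[keep, , drop = FALSE], bonds, conf)
}

# ---------------------------------------------------------------------------
# Canonical SMILES writer (provenance logs; round-trip tested)

#' Write a canonical SMILES string
#'
#' Produces a deterministic SMILES independent of input atom order, using
#' Morgan-style iterative rank refinement. All atoms are written in bracket
#' form with explicit hydrogen counts and aromatic bonds with explicit
#' \code{:} so that re-parsing reproduces the graph exactly.
#'
#' @param graph a [molecular_graph()].
#' @return a single SMILES string.
#' @export
write_smiles <- function(graph) {
  n <- nrow(graph$atoms)
  if (n == 0L) stop("empty graph")
  ranks <- .canonical_ranks(graph)
  adj <- vector("list", n)
  bond_of <- new.env()
  for (b in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[b]; j <- graph$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    assign(paste(min(i, j), max(i, j)), b, envir = bond_of)
  }
  bond_sym <- function(i, j) {
    b <- get(paste(min(i, j), max(i, j)), envir = bond_of)
    if (graph$bonds$aromatic[b]) ":"
    else switch(graph$bonds$order[b], "", "=", "#")
  }
  atom_token <- function(i) {
    a <- graph$atoms[i, ]
    sym <- if (a$aromatic) tolower(a$element) else a$element
    h <- if (a$nH == 0L) "" else if (a$nH == 1L) "H" else paste0("H", a$nH)
    q <- if (a$charge == 0L) ""
         else if (a$charge > 0L) paste0("+", if (a$charge > 1L) a$charge else "")
         else paste0("-", if (a$charge < -1L) -a$charge else "")
    paste0("[", sym, h, q, "]")
  }

  # two-pass scheme: plan the canonical DFS (ring bonds = non-tree edges),
  # then render, so both endpoints of a ring bond carry the same digit
  pre <- .smiles_dfs_plan(graph, ranks, adj, bond_of)
  paste0(.render_smiles_plan(graph, pre, bond_sym, atom_token), collapse = "")
}

# Plan the DFS once: records visit order, parent, and ring-closure bonds.
.smiles_dfs_plan <- function(graph, ranks, adj, bond_of) {
  n <- nrow(graph$atoms)
  visited <- rep(FALSE, n)
  plan <- list()
  ring_bonds <- integer(0)
  dfs <- function(v, from) {
    visited[v] <<- TRUE
    nb <- adj[[v]][order(ranks[adj[[v]]], adj[[v]])]
    closes <- integer(0)
    for (w in nb) {
      if (!is.na(from) && w == from) next
      if (visited[w]) {
        b <- get(paste(min(v, w), max(v, w)), envir = bond_of)
        if (!(b %in% ring_bonds)) {
          ring_bonds <<- c(ring_bonds, b)
          closes <- c(closes, b)
        }
      }
    }
    plan[[length(plan) + 1L]] <<- list(atom = v, parent = from,
                                       closes = closes)
    for (w in nb) if (!visited[w]) dfs(w, v)
  }
  roots <- order(ranks, seq_len(n))
  for (r in roots) if (!visited[r]) dfs(r, NA_integer_)
  list(plan = plan, ring_bonds = ring_bonds)
}

.render_smiles_plan <- function(graph, pre, bond_sym, atom_token) {
  ring_digit <- rep(NA_integer_, nrow(graph$bonds))
  for (k in seq_along(pre$ring_bonds)) ring_digit[pre$ring_bonds[k]] <- k
  fmt_digit <- function(d) if (d > 9L) paste0("%", sprintf("%02d", d)) else d
  n <- nrow(graph$atoms)
  # children per plan order
  order_of <- vapply(pre$plan, `[[`, 0L, "atom")
  parent_of <- rep(NA_integer_, n)
  for (p in pre$plan) parent_of[p$atom] <- p$parent
  children <- vector("list", n)
  for (p in pre$plan) {
    if (!is.na(p$parent)) {
      children[[p$parent]] <- c(children[[p$parent]], p$atom)
    }
  }
  closes_of <- vector("list", n)
  for (p in pre$plan) closes_of[[p$atom]] <- p$closes

  render <- function(v) {
    s <- atom_token(v)
    # ring-closure digits on this atom (both endpoints of each ring bond),
    # emitted in digit order so the form is reproducible
    mine <- which(!is.na(ring_digit) &
                    (graph$bonds$i == v | graph$bonds$j == v))
    for (b in mine[order(ring_digit[mine])]) {
      other <- if (graph$bonds$i[b] == v) graph$bonds$j[b] else graph$bonds$i[b]
      s <- paste0(s, bond_sym(v, other), fmt_digit(ring_digit[b]))
    }
    ch <- children[[v]]
    if (length(ch) > 0L) {
      for (k in seq_along(ch)) {
        inner <- paste0(bond_sym(v, ch[k]), render(ch[k]))
        if (k < length(ch)) inner <- paste0("(", inner, ")")
        s <- paste0(s, inner)
      }
    }
    s
  }
  roots <- order_of[is.na(parent_of[order_of])]
  vapply(roots, render, "")
}

.canonical_ranks <- function(graph) {
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
  refine <- function(ranks) {
    # fixed-width keys keep lexicographic order = numeric order, so each
    # iteration only splits rank classes and the loop must converge
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
  ranks <- refine(ranks)
  # break remaining ties deterministically
  while (length(unique(ranks)) < n) {
    tied <- which(ranks == min(ranks[duplicated(ranks) |
                                       duplicated(ranks, fromLast = TRUE)]))
    ranks[tied[1]] <- ranks[tied[1]] - 0.5
    ranks <- as.integer(factor(rank(ranks, ties.method = "min")))
    ranks <- refine(ranks)
  }
  ranks
}

# ---------------------------------------------------------------------------
# Conformers and the molecular influence matrix

#' Construct a conformer (3D coordinates) for a molecular graph
#'
#' Computes the diagonal of the molecular influence matrix
#' \eqn{H = M (M'M)^{-} M'} on centroid-centered coordinates (the GETAWAY
#' leverages) and the interatomic distance matrix. The pseudo-inverse is used
#' so that exactly planar or linear geometries yield leverages summing to the
#' coordinate rank rather than failing.
#'
#' @param coords numeric matrix, atoms x 3, in Angstrom.
#' @param masses per-atom masses in amu.
#' @return an object of class \code{conformer} with components \code{coords},
#'   \code{masses}, \code{h} (influence leverages) and \code{r} (interatomic
#'   distances).
#' @export
conformer <- function(coords, masses) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) == length(masses),
            all(masses > 0))
  M <- sweep(coords, 2, colMeans(coords))
  sv <- svd(M)
  tol <- max(dim(M)) * max(sv$d, 0) * .Machine$double.eps
  keep <- sv$d > tol
  h <- if (any(keep)) rowSums(sv$u[, keep, drop = FALSE]^2) else
    rep(0, nrow(M))
  r <- as.matrix(stats::dist(coords))
  dimnames(r) <- NULL
  structure(list(coords = coords, masses = as.numeric(masses),
                 h = h, r = r),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("conformer:", nrow(x$coords), "atoms; leverage sum",
      format(sum(x$h), digits = 4), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Electronic states

#' Kier-Hall intrinsic states
#'
#' Computes, per heavy atom, the simple vertex degree \eqn{\delta} (number of
#' heavy-atom connections), the valence degree \eqn{\delta^v} (valence
#' electrons minus attached hydrogens), and the intrinsic state
#' \deqn{I = ((2/L)^2 \delta^v + 1) / \delta,}
#' where \eqn{L} is the principal quantum number of the atom's valence shell.
#' These are the atomic weights behind the Moran autocorrelation descriptor
#' MATS3s.
#'
#' @param graph a [molecular_graph()] with at least two connected heavy atoms.
#' @return data frame with columns \code{delta}, \code{delta_v}, \code{I}.
#' @export
intrinsic_states <- function(graph) {
  n <- nrow(graph$atoms)
  if (n < 2L) stop("intrinsic states need at least 2 heavy atoms")
  delta <- tabulate(c(graph$bonds$i, graph$bonds$j), nbins = n)
  if (any(delta == 0L)) {
    stop("isolated heavy atom (delta = 0): intrinsic state undefined")
  }
  zv <- .element_field(graph$atoms$element, "zv")
  delta_v <- zv - graph$atoms$nH
  L <- graph$atoms$L
  I <- ((2 / L)^2 * delta_v + 1) / delta
  data.frame(delta = delta, delta_v = delta_v, I = I)
}

# ---------------------------------------------------------------------------
# File readers

#' Read SMILES from a file
#'
#' One molecule per line, optionally followed by whitespace and an identifier.
#'
#' @param path file path.
#' @param keep_largest passed to [parse_smiles()].
#' @return named list of [molecular_graph()] objects (names are the ids, or
#'   \code{mol1..molN} when absent).
#' @export
read_smiles <- function(path, keep_largest = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  ids <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) > 1L) parts[[k]][2] else paste0("mol", k)
  }, "")
  out <- lapply(parts, function(p) parse_smiles(p[1], keep_largest))
  names(out) <- ids
  out
}

#' Read molecules (with 3D conformers) from an SDF V2000 file
#'
#' Coordinates and elements come from the atom block; bond orders from the
#' bond block (order 4 is read as aromatic). Kekule structures are aromatized
#' by the same perception as [parse_smiles()]. Hydrogens are collapsed to
#' implicit counts on their heavy neighbor so the graph matches SMILES input.
#'
#' @param path SDF file path.
#' @return named list of [molecular_graph()] objects with conformers attached.
#' @export
read_sdf_molecules <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  out <- vector("list", length(sdfs))
  ids <- ChemmineR::sdfid(sdfs)
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    element <- sub("_.*$", "", rownames(ab))
    coords <- ab[, 1:3, drop = FALSE]
    bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2])
    border <- as.integer(bb[, 3])
    heavy <- which(element != "H")
    # implicit-H bookkeeping
    nH <- integer(length(heavy))
    remap <- match(seq_along(element), heavy)
    keep_bond <- element[bi] != "H" & element[bj] != "H"
    for (b in which(!keep_bond)) {
      hv <- if (element[bi[b]] == "H") bj[b] else bi[b]
      if (element[hv] != "H") nH[remap[hv]] <- nH[remap[hv]] + 1L
    }
    bonds <- data.frame(
      i = remap[bi[keep_bond]], j = remap[bj[keep_bond]],
      order = pmin(border[keep_bond], 3L),
      aromatic = border[keep_bond] == 4L
    )
    atoms <- data.frame(
      element = element[heavy], charge = 0L, nH = nH,
      aromatic = FALSE, stringsAsFactors = FALSE
    )
    atoms$aromatic[unique(c(bonds$i[bonds$aromatic], bonds$j[bonds$aromatic]))] <- TRUE
    perceived <- .perceive_aromaticity(atoms, bonds)
    atoms <- perceived$atoms; bonds <- perceived$bonds
    # fill hydrogens not present explicitly in the SDF
    filled <- .implicit_hydrogens(atoms, bonds)
    atoms$nH <- pmax(atoms$nH, filled)
    conf <- conformer(coords[heavy, , drop = FALSE],
                      atomic_mass(atoms$element))
    out[[k]] <- molecular_graph(atoms, bonds, conf)
  }
  names(out) <- ids
  out
}
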