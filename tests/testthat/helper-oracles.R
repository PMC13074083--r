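# Independent oracles and fixture builders shared by the test files.
# All oracles are deliberately naive (double loops, explicit refits,
# breadth-first search) and independent of the package's code paths.

# breadth-first shortest-path bond counts
oracle_bfs_distances <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[b]; j <- graph$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# naive double-loop Moran autocorrelation over ordered pairs
oracle_moran <- function(graph, w, lag) {
  n <- length(w)
  wbar <- mean(w)
  den <- sum((w - wbar)^2) / n
  if (den == 0) return(0)
  num <- 0; npairs <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && graph$dist[i, j] == lag) {
      num <- num + (w[i] - wbar) * (w[j] - wbar)
      npairs <- npairs + 1
    }
  }
  if (npairs == 0) return(0)
  (num / npairs) / den
}

# naive double-loop GETAWAY R autocorrelation (pairs counted once)
oracle_getaway <- function(graph, conf, lag, w) {
  n <- length(w)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (graph$dist[i, j] == lag) {
      total <- total + sqrt(conf$h[i] * conf$h[j]) / conf$r[i, j] * w[i] * w[j]
    }
  }
  total
}

# explicit leave-one-out refit
oracle_q2_loo <- function(X, y) {
  n <- nrow(X)
  press <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_mlr(X[-i, , drop = FALSE], y[-i])
    press[i] <- y[i] - predict(fit, X[i, , drop = FALSE])
  }
  1 - sum(press^2) / sum((y - mean(y))^2)
}

# random connected heavy-atom graph (tree plus optional chord), single bonds
random_small_molecule <- function(n_atoms, with_conformer = TRUE) {
  elements <- sample(c("C", "N", "O"), n_atoms, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15))
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                      aromatic = logical(0))
  for (v in seq_len(n_atoms)[-1]) {
    bonds[nrow(bonds) + 1L, ] <- list(sample.int(v - 1L, 1L), v, 1L, FALSE)
  }
  if (n_atoms >= 4 && stats::runif(1) < 0.5) {
    repeat {
      pair <- sort(sample.int(n_atoms, 2))
      key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
      if (!paste(pair[1], pair[2]) %in% key) {
        bonds[nrow(bonds) + 1L, ] <- list(pair[1], pair[2], 1L, FALSE)
        break
      }
    }
  }
  atoms <- data.frame(element = elements, charge = 0L, nH = 0L,
                      aromatic = FALSE, stringsAsFactors = FALSE)
  conf <- if (with_conformer) {
    conformer(matrix(stats::rnorm(n_atoms * 3, sd = 2), ncol = 3),
              atomic_mass(elements))
  } else NULL
  molecular_graph(atoms, bonds, conf)
}

# reorder a molecular graph's atoms by a permutation (perm[old] = new index)
permute_graph <- function(graph, perm) {
  atoms <- graph$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- graph$bonds
  bonds$i <- perm[bonds$i]; bonds$j <- perm[bonds$j]
  conf <- graph$conformer
  if (!is.null(conf)) {
    conf <- conformer(conf$coords[order(perm), , drop = FALSE],
                      conf$masses[order(perm)])
  }
  molecular_graph(atoms, bonds, conf)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# small seeded regression problem
random_regression <- function(seed, n = 30, p = 3, sigma = 0.5) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("d", seq_len(p))))
    beta <- stats::rnorm(p, sd = 1.5)
    y <- 1 + drop(X %*% beta) + stats::rnorm(n, sd = sigma)
    list(X = X, y = y, beta = beta)
  })
}
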