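# Multiple linear regression, genetic-algorithm descriptor selection, and the
# frozen published five-descriptor equation.

#' Fit a multiple linear regression model
#'
#' Ordinary least squares with an intercept. Columns are scaled to unit
#' variance internally for numerical conditioning and the coefficients are
#' back-transformed, so the reported equation is in raw descriptor units.
#'
#' @param X numeric matrix of selected descriptors (n x p', named columns).
#' @param y numeric response (pIC50), length n.
#' @param ids optional compound identifiers stored with the model.
#' @return an object of class \code{mlr_model}: intercept, named
#'   coefficients, residuals, fitted values, hat diagonal, residual standard
#'   deviation \code{sigma} (denominator n - p' - 1), \code{n}, \code{p}.
#' @export
fit_mlr <- function(X, y, ids = rownames(X)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("descriptor matrix must have column names")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 1L) {
    stop("need more observations (", n, ") than parameters (", p + 1L, ")")
  }
  scales <- apply(X, 2, stats::sd)
  scales[scales == 0] <- 1
  Xs <- sweep(X, 2, scales, "/")
  design <- cbind(`(Intercept)` = 1, Xs)
  fit <- stats::lm.fit(design, y)
  if (fit$rank < p + 1L) {
    bad <- colnames(design)[is.na(fit$coefficients)]
    stop("rank-deficient design: column(s) ",
         paste(setdiff(bad, "(Intercept)"), collapse = ", "),
         " are linearly dependent on the others")
  }
  Q <- qr.Q(fit$qr)
  hat <- rowSums(Q[, seq_len(fit$rank), drop = FALSE]^2)
  coefs <- fit$coefficients[-1] / scales
  intercept <- unname(fit$coefficients[1])
  # stored through the same expression predict() uses, so predict on the
  # training rows reproduces these values bit-identically
  fitted <- drop(intercept + X %*% coefs)
  structure(list(
    intercept = intercept,
    coefficients = coefs,
    training_ids = ids,
    residuals = unname(y - fitted),
    fitted = unname(fitted),
    hat = unname(hat),
    sigma = sqrt(sum((y - fitted)^2) / (n - p - 1L)),
    n = n, p = p
  ), class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, digits = 4, ...) {
  terms <- paste(sprintf("%+.*f*%s", digits, x$coefficients,
                         names(x$coefficients)), collapse = " ")
  cat("mlr_model: pIC50 =", format(x$intercept, digits = digits + 1), terms, "\n")
  if (!is.null(x$n)) cat("  fitted on n =", x$n, "compounds, p' =", x$p, "\n")
  invisible(x)
}

#' Predict activities from an MLR model
#'
#' @param object an \code{mlr_model}.
#' @param newdata data frame or matrix containing every descriptor column
#'   named in the model's coefficients.
#' @param ... unused.
#' @return numeric vector of predicted pIC50, one per row.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  nms <- names(object$coefficients)
  missing <- setdiff(nms, colnames(newdata))
  if (length(missing) > 0) {
    stop("newdata lacks model descriptor column(s): ",
         paste(missing, collapse = ", "))
  }
  M <- as.matrix(as.data.frame(newdata)[, nms, drop = FALSE])
  storage.mode(M) <- "double"
  drop(object$intercept + M %*% object$coefficients)
}

#' The published five-descriptor GA-MLR model
#'
#' The frozen equation
#' \deqn{pIC_{50} = 4.9509 + 0.0554\,max\_conj\_path + 5.3355\,MATS3s
#'   + 2.0399\,R8m + 1.186\,(C\mbox{-}N\mbox{-}C\mbox{=}O) + 1.5020\,MNA,}
#' trained on 81 quinoline-family acetylcholinesterase inhibitors. Descriptor
#' column names follow this package's conventions (\code{CNCO} is the
#' C-N-C=O fragment count, \code{MNA} the \code{-H(-C(C-H-H-C))} count).
#'
#' @param name model identifier; only \code{"paper2026_ache_gamlr"} is
#'   currently bundled.
#' @return an \code{mlr_model} (without fitted diagnostics: the training
#'   descriptor table is not published).
#' @export
published_model <- function(name = "paper2026_ache_gamlr") {
  if (!identical(name, "paper2026_ache_gamlr")) {
    stop("unknown built-in model '", name, "'")
  }
  structure(list(
    intercept = 4.9509,
    coefficients = c(max_conj_path = 0.0554, MATS3s = 5.3355, R8m = 2.0399,
                     CNCO = 1.186, MNA = 1.5020),
    training_ids = NULL, residuals = NULL, fitted = NULL, hat = NULL,
    sigma = NULL, n = 81L, p = 5L
  ), class = "mlr_model")
}

#' Serialize / restore an MLR model as JSON
#'
#' @param model an \code{mlr_model}.
#' @param path optional output file.
#' @return \code{model_to_json}: the JSON string (invisibly when written);
#'   \code{model_from_json}: the restored \code{mlr_model}.
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    training_ids = model$training_ids,
    n = model$n, p = model$p
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname model_to_json
#' @param json JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(list(
    intercept = obj$intercept,
    coefficients = unlist(obj$coefficients),
    training_ids = obj$training_ids,
    residuals = NULL, fitted = NULL, hat = NULL, sigma = NULL,
    n = obj$n, p = obj$p
  ), class = "mlr_model")
}

# ---------------------------------------------------------------------------
# Genetic-algorithm descriptor selection

#' Configuration for GA descriptor selection
#'
#' All hyperparameters are overridable; the seed is mandatory so that every
#' selection run is reproducible. Fitness is leave-one-out cross-validated
#' \eqn{Q^2} (not training \eqn{R^2}), which keeps the search from rewarding
#' overfit subsets.
#'
#' @param k model size (number of descriptors selected).
#' @param pop_size population size.
#' @param generations number of generations (0 returns the best member of
#'   the seeded initial population).
#' @param tournament tournament size for parent selection.
#' @param p_crossover per-mating crossover probability.
#' @param p_mutation per-gene mutation probability.
#' @param elitism number of best chromosomes copied unchanged.
#' @param seed integer RNG seed (required).
#' @return a \code{ga_config} list.
#' @export
ga_config <- function(k = 5L, pop_size = 100L, generations = 200L,
                      tournament = 2L, p_crossover = 0.9, p_mutation = 0.1,
                      elitism = 1L, seed) {
  if (missing(seed)) stop("ga_config requires an explicit seed")
  stopifnot(k >= 1L, pop_size >= 2L, generations >= 0L, tournament >= 1L,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1, elitism >= 0L)
  structure(list(k = as.integer(k), pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

# Q2_LOO fitness of a column subset; -Inf when the fit is singular
.ga_fitness <- function(X, y, subset) {
  out <- tryCatch(q2_loo(X[, subset, drop = FALSE], y),
                  error = function(e) -Inf)
  if (!is.finite(out)) -Inf else out
}

# TRUE when chromosome a beats b: higher fitness, ties to the
# lexicographically smaller sorted index tuple
.ga_better <- function(fa, a, fb, b) {
  if (fa != fb) return(fa > fb)
  for (k in seq_along(a)) {
    if (a[k] != b[k]) return(a[k] < b[k])
  }
  FALSE
}

#' Genetic-algorithm descriptor subset selection
#'
#' Chromosomes are k-sets of descriptor column indices. Each generation
#' applies tournament selection, uniform set-crossover with duplicate repair,
#' per-gene mutation to a random non-member, and elitism. Fitness is
#' \eqn{Q^2_{LOO}} of the OLS fit on the candidate columns. Identical seeds
#' give identical results; the best fitness per generation is traced and is
#' non-decreasing under elitism.
#'
#' @param X filtered descriptor pool (n x m numeric matrix, named columns).
#' @param y numeric response.
#' @param config a [ga_config()].
#' @return list with \code{subset} (selected column names), \code{model}
#'   (the refitted \code{mlr_model}), \code{fitness} (its \eqn{Q^2_{LOO}}),
#'   \code{trace} (best fitness per generation, length generations + 1
#'   including the initial population), and \code{config}.
#' @export
ga_select <- function(X, y, config) {
  X <- as.matrix(X)
  stopifnot(inherits(config, "ga_config"))
  m <- ncol(X); k <- config$k
  if (m < k) stop("descriptor pool (", m, ") smaller than model size ", k)
  if (nrow(X) <= k + 1L) stop("need n > k + 1 observations")
  .with_seed(config$seed, {
    pop <- replicate(config$pop_size, sort(sample.int(m, k)),
                     simplify = FALSE)
    fit <- vapply(pop, function(s) .ga_fitness(X, y, s), 0)
    best_of <- function(pop, fit) {
      b <- 1L
      for (i in seq_along(pop)[-1]) {
        if (.ga_better(fit[i], pop[[i]], fit[b], pop[[b]])) b <- i
      }
      b
    }
    trace <- numeric(config$generations + 1L)
    b <- best_of(pop, fit)
    trace[1] <- fit[b]

    pick_parent <- function() {
      cand <- sample.int(config$pop_size, config$tournament, replace = TRUE)
      w <- cand[1]
      for (i in cand[-1]) {
        if (.ga_better(fit[i], pop[[i]], fit[w], pop[[w]])) w <- i
      }
      pop[[w]]
    }
    crossover <- function(pa, pb) {
      genes <- ifelse(stats::runif(k) < 0.5, pa, pb)
      genes <- unique(genes)
      pool <- setdiff(union(pa, pb), genes)
      while (length(genes) < k) {
        if (length(pool) > 0L) {
          g <- pool[sample.int(length(pool), 1L)]
          pool <- setdiff(pool, g)
        } else {
          g <- sample(setdiff(seq_len(m), genes), 1L)
        }
        genes <- c(genes, g)
      }
      sort(genes)
    }
    mutate <- function(s) {
      hit <- stats::runif(k) < config$p_mutation
      if (!any(hit)) return(s)
      for (idx in which(hit)) {
        nonmembers <- setdiff(seq_len(m), s)
        s[idx] <- nonmembers[sample.int(length(nonmembers), 1L)]
      }
      sort(s)
    }

    gen <- 0L
    while (gen < config$generations) {
      gen <- gen + 1L
      new_pop <- vector("list", config$pop_size)
      new_fit <- numeric(config$pop_size)
      n_elite <- min(config$elitism, config$pop_size)
      if (n_elite > 0L) {
        ord <- order(-fit)
        for (e in seq_len(n_elite)) {
          new_pop[[e]] <- pop[[ord[e]]]
          new_fit[e] <- fit[ord[e]]
        }
        # elite slot 1 must be the tie-broken best, not just order(-fit)[1]
        bi <- best_of(pop, fit)
        new_pop[[1]] <- pop[[bi]]; new_fit[1] <- fit[bi]
      }
      for (i in seq(n_elite + 1L, config$pop_size)) {
        pa <- pick_parent(); pb <- pick_parent()
        child <- if (stats::runif(1) < config$p_crossover) {
          crossover(pa, pb)
        } else pa
        child <- mutate(child)
        new_pop[[i]] <- child
        new_fit[i] <- .ga_fitness(X, y, child)
      }
      pop <- new_pop; fit <- new_fit
      b <- best_of(pop, fit)
      trace[gen + 1L] <- fit[b]
    }
    b <- best_of(pop, fit)
    subset <- colnames(X)[pop[[b]]]
    model <- fit_mlr(X[, subset, drop = FALSE], y)
    list(subset = subset, model = model, fitness = fit[b], trace = trace,
         config = config)
  })
}
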