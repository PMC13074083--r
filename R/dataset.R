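# Compound/descriptor table management: activity conversion, the three-stage
# descriptor pre-filter, and seeded training/test partitioning.

# run code with a local, seeded RNG without disturbing the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Convert IC50 in molar units to pIC50
#'
#' \eqn{pIC_{50} = -\log_{10}(IC_{50}\,[M])}. Values must be strictly
#' positive.
#'
#' @param ic50_molar numeric vector of IC50 values in molar units.
#' @return numeric vector of pIC50 values.
#' @export
to_pic50 <- function(ic50_molar) {
  if (any(!is.finite(ic50_molar)) || any(ic50_molar <= 0)) {
    stop("IC50 values must be finite and > 0 to take -log10")
  }
  -log10(ic50_molar)
}

#' Three-stage descriptor pre-filter
#'
#' Reduces a raw descriptor pool in a fixed stage order:
#' \enumerate{
#'   \item near-constant columns (modal-value frequency above
#'     \code{near_constant_frac}) are removed;
#'   \item pairwise-correlated columns: pairs are scanned in lexicographic
#'     name order and, for each pair with \eqn{|r|} above \code{corr_cutoff}
#'     in which both members are still retained, the member with the smaller
#'     absolute correlation to the response is dropped (falling back to the
#'     smaller variance, then to the later name, when no response is given
#'     or the criteria tie);
#'   \item low-variance columns (variance below \code{var_floor}) are
#'     removed.
#' }
#' The procedure is deterministic, never reorders retained columns, and is
#' idempotent.
#'
#' @param X numeric matrix or data frame of descriptors (named columns; rows
#'   are compounds).
#' @param y optional numeric response (activities) used by stage 2.
#' @param near_constant_frac stage-1 modal-frequency cutoff in (0, 1].
#' @param corr_cutoff stage-2 absolute-correlation cutoff in (0, 1].
#' @param var_floor stage-3 variance floor (the threshold is a configurable
#'   choice; 1e-4 by default).
#' @return list with \code{X} (the filtered matrix) and \code{report}, a
#'   \code{filter_report} recording each removed column with its stage,
#'   reason and (for stage 2) the retained partner.
#' @export
prefilter <- function(X, y = NULL, near_constant_frac = 0.80,
                      corr_cutoff = 0.95, var_floor = 1e-4) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("descriptor matrix must have column names")
  if (anyDuplicated(colnames(X))) stop("duplicate descriptor column names")
  stopifnot(nrow(X) > 0, ncol(X) > 0,
            near_constant_frac > 0, near_constant_frac <= 1,
            corr_cutoff > 0, corr_cutoff <= 1)
  if (!is.null(y)) stopifnot(length(y) == nrow(X))

  removed <- data.frame(column = character(0), stage = integer(0),
                        reason = character(0), partner = character(0),
                        stringsAsFactors = FALSE)
  drop_col <- function(name, stage, reason, partner = NA_character_) {
    removed[nrow(removed) + 1L, ] <<- list(name, stage, reason, partner)
  }
  alive <- colnames(X)

  # stage 1: near-constant
  for (nm in alive) {
    modal <- max(table(X[, nm])) / nrow(X)
    if (modal > near_constant_frac) drop_col(nm, 1L, "near_constant")
  }
  alive <- setdiff(alive, removed$column)

  # stage 2: pairwise correlation, lexicographic scan order
  if (length(alive) >= 2L) {
    nms <- sort(alive)
    vars <- apply(X[, alive, drop = FALSE], 2, stats::var)
    ycor <- if (is.null(y)) NULL else {
      sapply(alive, function(nm) {
        if (vars[nm] == 0) 0 else abs(stats::cor(X[, nm], y))
      })
    }
    dead <- character(0)
    for (a in seq_len(length(nms) - 1L)) {
      na <- nms[a]
      if (na %in% dead) next
      for (b in seq((a + 1L), length(nms))) {
        nb <- nms[b]
        if (na %in% dead) break
        if (nb %in% dead) next
        if (vars[na] == 0 || vars[nb] == 0) next
        r <- stats::cor(X[, na], X[, nb])
        if (!is.finite(r) || abs(r) <= corr_cutoff) next
        victim <- .stage2_victim(na, nb, ycor, vars)
        dead <- c(dead, victim$drop)
        drop_col(victim$drop, 2L, "correlated", victim$keep)
      }
    }
    alive <- setdiff(alive, dead)
  }

  # stage 3: low variance
  for (nm in alive) {
    if (stats::var(X[, nm]) < var_floor) drop_col(nm, 3L, "low_variance")
  }
  alive <- setdiff(alive, removed$column)

  if (length(alive) == 0L) {
    stop("prefilter removed every descriptor column: empty pool")
  }
  report <- structure(
    list(removed = removed,
         retained = colnames(X)[colnames(X) %in% alive],
         parameters = list(near_constant_frac = near_constant_frac,
                           corr_cutoff = corr_cutoff,
                           var_floor = var_floor,
                           used_response = !is.null(y))),
    class = "filter_report"
  )
  list(X = X[, report$retained, drop = FALSE], report = report)
}

.stage2_victim <- function(na, nb, ycor, vars) {
  if (!is.null(ycor) && ycor[[na]] != ycor[[nb]]) {
    if (ycor[[na]] < ycor[[nb]]) list(drop = na, keep = nb)
    else list(drop = nb, keep = na)
  } else if (vars[[na]] != vars[[nb]]) {
    if (vars[[na]] < vars[[nb]]) list(drop = na, keep = nb)
    else list(drop = nb, keep = na)
  } else {
    # tie: drop the later name
    if (na < nb) list(drop = nb, keep = na) else list(drop = na, keep = nb)
  }
}

#' @export
print.filter_report <- function(x, ...) {
  cat("descriptor pre-filter:", length(x$retained), "columns retained,",
      nrow(x$removed), "removed\n")
  if (nrow(x$removed) > 0) {
    print(table(stage = x$removed$stage, reason = x$removed$reason))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a \code{filter_report} from [prefilter()].
#' @param path optional file path; when omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
filter_report_json <- function(report, path = NULL) {
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Seeded partitioning of compounds into training / internal test sets
#'
#' Reproducibly assigns each compound a partition label. The published study
#' design splits 115 compounds into 81 training and 34 internal test
#' compounds; the original membership is unpublished, so the split here is a
#' seeded random draw with a fixed documented default seed.
#'
#' @param records data frame with a unique \code{id} column.
#' @param n_train number of training compounds.
#' @param n_test number of internal test compounds; the default uses all
#'   remaining compounds.
#' @param seed integer RNG seed.
#' @return the records with a \code{partition} factor column
#'   (\code{"training"} / \code{"internal_test"}).
#' @export
partition_compounds <- function(records, n_train, n_test = NULL, seed = 20260404) {
  stopifnot(is.data.frame(records), "id" %in% names(records))
  if (anyDuplicated(records$id)) stop("compound ids must be unique")
  n <- nrow(records)
  if (is.null(n_test)) n_test <- n - n_train
  if (n_train + n_test > n) {
    stop("requested partition sizes (", n_train, " + ", n_test,
         ") exceed available compounds (", n, ")")
  }
  idx <- .with_seed(seed, sample.int(n, n_train + n_test))
  label <- rep(NA_character_, n)
  label[idx[seq_len(n_train)]] <- "training"
  label[idx[n_train + seq_len(n_test)]] <- "internal_test"
  if (anyNA(label)) label[is.na(label)] <- "unassigned"
  records$partition <- factor(label,
                              levels = c("training", "internal_test",
                                         "external", "design", "unassigned"))
  records
}

#' Read a compound activity table from CSV
#'
#' The header row is mandatory and must contain an \code{id} column; a
#' \code{smiles} column and either \code{pIC50} or \code{IC50_M} (molar,
#' converted via [to_pic50()]) are recognized.
#'
#' @param path CSV file path.
#' @return data frame with at least \code{id} and, when available,
#'   \code{smiles} and \code{pIC50}.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("compound table needs an 'id' column")
  if (anyDuplicated(df$id)) stop("duplicate compound ids in ", path)
  if (!"pIC50" %in% names(df) && "IC50_M" %in% names(df)) {
    df$pIC50 <- to_pic50(df$IC50_M)
  }
  df$id <- as.character(df$id)
  df
}

#' Read a descriptor matrix from CSV
#'
#' @param path CSV file path with an \code{id} column and one column per
#'   descriptor.
#' @return numeric matrix with compound ids as row names.
#' @export
read_descriptor_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("descriptor matrix needs an 'id' column")
  ids <- as.character(df$id)
  if (anyDuplicated(ids)) stop("duplicate compound ids in ", path)
  X <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

#' Write a descriptor matrix to CSV
#'
#' @param X numeric matrix with row names (compound ids).
#' @param path output CSV path.
#' @export
write_descriptor_matrix <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
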