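# OECD-style validation statistics: internal cross-validation, external
# regression, rm2 metrics, Y-randomization, and the Williams-plot
# applicability domain.

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = \frac{2\,cov(x,y)}{var(x) + var(y) + (\bar x - \bar y)^2}}
#' with population (1/n) moments, penalizing both scatter and location/scale
#' shift.
#'
#' @param x,y numeric vectors of equal length (observed and predicted).
#' @return the concordance coefficient.
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Training-set goodness-of-fit statistics
#'
#' @param model a fitted \code{mlr_model} from [fit_mlr()].
#' @param X the training descriptor matrix used for the fit.
#' @param y the training response.
#' @return list with \code{r2}, \code{r2_adj}, \code{rmse} (denominator n),
#'   \code{mae} and \code{ccc} (observed vs fitted).
#' @export
training_stats <- function(model, X, y) {
  yhat <- predict(model, X)
  n <- length(y); p <- length(model$coefficients)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero-variance response: R2 undefined")
  rss <- sum((y - yhat)^2)
  r2 <- 1 - rss / tss
  list(
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    rmse = sqrt(rss / n),
    mae = mean(abs(y - yhat)),
    ccc = ccc(y, yhat)
  )
}

#' Leave-one-out cross-validated Q2
#'
#' \eqn{Q^2_{LOO} = 1 - PRESS/TSS}, computed through the hat-matrix shortcut
#' \eqn{e_i/(1-h_{ii})} for the deleted residuals. When a leverage reaches 1
#' the affected points are refit explicitly, with a warning.
#'
#' @param X numeric descriptor matrix (n x p', named columns).
#' @param y numeric response.
#' @return the \eqn{Q^2_{LOO}} value.
#' @export
q2_loo <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2L) stop("Q2(LOO) needs n > p' + 2")
  model <- fit_mlr(X, y)
  h <- model$hat
  e <- model$residuals
  press_res <- numeric(n)
  near_one <- h > 1 - 1e-10
  press_res[!near_one] <- e[!near_one] / (1 - h[!near_one])
  if (any(near_one)) {
    warning(sum(near_one), " point(s) with leverage ~1: explicit refit used")
    for (i in which(near_one)) {
      fi <- fit_mlr(X[-i, , drop = FALSE], y[-i])
      press_res[i] <- y[i] - predict(fi, X[i, , drop = FALSE])
    }
  }
  tss <- sum((y - mean(y))^2)
  1 - sum(press_res^2) / tss
}

#' Leave-many-out cross-validated Q2
#'
#' Per repeat, a seeded random group of \code{floor(n * leave_frac)}
#' compounds is held out, the model refit, and the held-out points
#' predicted. \eqn{Q^2_{LMO} = 1 - \sum e^2 / \sum (y - \bar y_{full})^2}
#' aggregated over all held-out predictions. With group size 1 and
#' \code{repeats = n} the folds are the n deterministic leave-one-out folds
#' and the value equals [q2_loo()].
#'
#' @param X numeric descriptor matrix.
#' @param y numeric response.
#' @param leave_frac fraction left out per repeat, in (0, 0.5] (or exactly
#'   1/n for the LOO limit).
#' @param repeats number of held-out groups.
#' @param seed integer RNG seed.
#' @return the \eqn{Q^2_{LMO}} value.
#' @export
q2_lmo <- function(X, y, leave_frac = 0.2, repeats = 1000, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  g <- max(1L, floor(n * leave_frac))
  if (leave_frac <= 0 || (leave_frac > 0.5 && g > 1L)) {
    stop("leave_frac must be in (0, 0.5]")
  }
  folds <- if (g == 1L && repeats == n) {
    lapply(seq_len(n), identity)          # deterministic LOO limit
  } else {
    .with_seed(seed, replicate(repeats, sample.int(n, g), simplify = FALSE))
  }
  ybar <- mean(y)
  press <- 0; denom <- 0; skipped <- 0L
  for (hold in folds) {
    fi <- tryCatch(fit_mlr(X[-hold, , drop = FALSE], y[-hold]),
                   error = function(e) NULL)
    if (is.null(fi)) { skipped <- skipped + 1L; next }
    pred <- predict(fi, X[hold, , drop = FALSE])
    press <- press + sum((y[hold] - pred)^2)
    denom <- denom + sum((y[hold] - ybar)^2)
  }
  if (skipped > 0L) {
    warning(skipped, " singular repeat(s) skipped in Q2(LMO)")
  }
  if (denom == 0) stop("no usable LMO repeats")
  1 - press / denom
}

#' Predictive R2 on an external/internal test set
#'
#' \deqn{R^2_{pred} = 1 - \frac{\sum (y_{test} - \hat y)^2}
#'                             {\sum (y_{test} - \bar y_{train})^2}}
#'
#' @param model a fitted \code{mlr_model}.
#' @param X_test test-set descriptor matrix (disjoint from training).
#' @param y_test test-set response.
#' @param ybar_train training-set response mean.
#' @return the \eqn{R^2_{pred}} value.
#' @export
r2_pred <- function(model, X_test, y_test, ybar_train) {
  if (length(y_test) == 0L) stop("empty test set")
  yhat <- predict(model, X_test)
  1 - sum((y_test - yhat)^2) / sum((y_test - ybar_train)^2)
}

#' rm2 metrics (scaled determination coefficients)
#'
#' For observed/predicted pairs, \eqn{r^2} is the ordinary squared
#' correlation and \eqn{r_0^2} the determination coefficient of the
#' through-origin regression. \eqn{r_m^2 = r^2 (1 - \sqrt{r^2 - r_0^2})} is
#' evaluated in both regression directions; the average and the absolute
#' difference diagnose prediction bias. Radicands pushed below zero by
#' rounding are clamped at zero with a warning.
#'
#' @param obs,pred numeric vectors (at least 3 pairs, both with positive
#'   variance).
#' @return list with \code{rm2_avg}, \code{delta_rm2}, and the two
#'   directional values \code{rm2_fwd} (pred on obs), \code{rm2_rev}.
#' @export
rm2_metrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 3)
  if (stats::var(obs) == 0 || stats::var(pred) == 0) {
    stop("rm2 metrics need positive variance in both vectors")
  }
  r2 <- stats::cor(obs, pred)^2
  one_dir <- function(x, yv) {
    k <- sum(x * yv) / sum(x^2)
    r02 <- 1 - sum((yv - k * x)^2) / sum((yv - mean(yv))^2)
    rad <- r2 - r02
    if (rad < 0) {
      if (rad < -1e-8) warning("r2 < r0^2; radicand clamped at 0")
      rad <- 0
    }
    r2 * (1 - sqrt(rad))
  }
  fwd <- one_dir(obs, pred)   # predicted regressed on observed
  rev <- one_dir(pred, obs)
  list(rm2_avg = (fwd + rev) / 2, delta_rm2 = abs(fwd - rev),
       rm2_fwd = fwd, rm2_rev = rev)
}

#' External-set regression of calculated on experimental activity
#'
#' Ordinary least squares of calculated pIC50 on experimental pIC50;
#' \eqn{R^2_{ext}} is the squared Pearson correlation.
#'
#' @param experimental numeric vector of experimental pIC50.
#' @param calculated numeric vector of calculated pIC50 (same length, >= 3).
#' @return object of class \code{external_regression}: \code{slope},
#'   \code{intercept}, \code{r2}, \code{n}, \code{residuals}.
#' @export
external_regression <- function(experimental, calculated) {
  stopifnot(length(experimental) == length(calculated),
            length(experimental) >= 3)
  if (stats::var(experimental) == 0) {
    stop("zero variance in experimental values")
  }
  fit <- stats::lm.fit(cbind(1, experimental), calculated)
  structure(list(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    r2 = stats::cor(experimental, calculated)^2,
    n = length(experimental),
    residuals = unname(fit$residuals)
  ), class = "external_regression")
}

#' @export
print.external_regression <- function(x, ...) {
  cat(sprintf("external regression (n = %d): calc = %.3f * exp + %.3f, R2ext = %.4f\n",
              x$n, x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Y-randomization (response scrambling)
#'
#' Permutes the response \code{iterations} times (seeded), refits the
#' coefficients on the fixed selected descriptors, and records the scrambled
#' \eqn{R^2} and \eqn{Q^2_{LOO}} per iteration. A structurally anchored
#' model shows its original \eqn{R^2} far above the whole scrambled
#' distribution; under independence the scrambled \eqn{R^2} mean is close to
#' \eqn{p'/(n-1)}.
#'
#' @param X numeric descriptor matrix (the fixed selected subset).
#' @param y numeric response.
#' @param iterations number of scrambles (the study design uses 2000).
#' @param seed integer RNG seed.
#' @return object of class \code{yrand_result}: vectors \code{r2_scr},
#'   \code{q2_scr}, their means and maxima, \code{iterations}, \code{seed},
#'   plus the original-model \code{r2_orig}, \code{q2_orig}.
#' @export
y_randomize <- function(X, y, iterations = 2000, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(iterations >= 1)
  n <- nrow(X); p <- ncol(X)
  base <- fit_mlr(X, y)
  h <- base$hat
  # fixed design: project each permuted response through the same QR
  scales <- apply(X, 2, stats::sd); scales[scales == 0] <- 1
  design <- cbind(1, sweep(X, 2, scales, "/"))
  qr_d <- qr(design)
  Q <- qr.Q(qr_d)[, seq_len(qr_d$rank), drop = FALSE]
  tss_fun <- function(v) sum((v - mean(v))^2)
  r2_scr <- numeric(iterations)
  q2_scr <- numeric(iterations)
  .with_seed(seed, {
    for (it in seq_len(iterations)) {
      yp <- y[sample.int(n)]
      e <- yp - Q %*% crossprod(Q, yp)
      rss <- sum(e^2)
      tss <- tss_fun(yp)
      r2_scr[it] <- 1 - rss / tss
      q2_scr[it] <- 1 - sum((e / (1 - h))^2) / tss
    }
  })
  orig_stats <- training_stats(base, X, y)
  structure(list(
    r2_scr = r2_scr, q2_scr = q2_scr,
    r2_scr_mean = mean(r2_scr), q2_scr_mean = mean(q2_scr),
    r2_scr_max = max(r2_scr), q2_scr_max = max(q2_scr),
    r2_orig = orig_stats$r2, q2_orig = q2_loo(X, y),
    iterations = iterations, seed = seed, n = n, p = p
  ), class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Y-randomization (%d iterations): mean R2scr = %.4f (max %.4f), ",
    "mean Q2scr = %.4f\n  original R2 = %.4f, Q2loo = %.4f\n"),
    x$iterations, x$r2_scr_mean, x$r2_scr_max, x$q2_scr_mean,
    x$r2_orig, x$q2_orig))
  invisible(x)
}

#' Warning-leverage threshold for the Williams plot
#'
#' \eqn{h^* = 3(p' + 1)/n} with \eqn{p'} model descriptors and \eqn{n}
#' training compounds.
#'
#' @param p_prime number of model descriptors.
#' @param n training-set size.
#' @return the threshold \eqn{h^*}.
#' @export
hstar <- function(p_prime, n) {
  stopifnot(p_prime >= 1, n > 0)
  3 * (p_prime + 1) / n
}

#' Williams-plot applicability domain analysis
#'
#' Leverages \eqn{h_i = x_i (X'X)^{-1} x_i'} (intercept column included)
#' against standardized residuals (training points; residual standard
#' deviation with \eqn{n - p' - 1} denominator). Points are flagged
#' \code{high_leverage} above \eqn{h^* = 3(p'+1)/n} and \code{outlier}
#' beyond \eqn{\pm 3\sigma}; \code{in_domain} requires neither flag.
#'
#' @param model a fitted \code{mlr_model} (for the descriptor names and
#'   training diagnostics).
#' @param X_train training descriptor matrix (the fit's design).
#' @param X_query optional matrix of query compounds to place in the domain;
#'   query points get leverages and flags but no residuals.
#' @return object of class \code{ad_result} with a \code{table} data frame
#'   (\code{id}, \code{set}, \code{leverage}, \code{std_residual},
#'   \code{high_leverage}, \code{outlier}, \code{in_domain}) and
#'   \code{h_star}.
#' @export
williams_ad <- function(model, X_train, X_query = NULL) {
  nms <- names(model$coefficients)
  X_train <- as.matrix(as.data.frame(X_train)[, nms, drop = FALSE])
  n <- nrow(X_train); p <- length(nms)
  D <- cbind(1, X_train)
  G <- crossprod(D)
  Ginv <- tryCatch(solve(G), error = function(e) {
    warning("singular Gram matrix: pseudo-inverse used")
    .pinv(G)
  })
  lev <- function(M) rowSums((M %*% Ginv) * M)
  h_train <- lev(D)
  resid <- model$residuals
  s <- model$sigma
  std_res <- if (!is.null(resid) && !is.null(s)) resid / s else
    rep(NA_real_, n)
  hs <- hstar(p, n)
  ids_train <- if (!is.null(model$training_ids)) model$training_ids else
    paste0("train", seq_len(n))
  tab <- data.frame(
    id = ids_train, set = "training", leverage = h_train,
    std_residual = std_res, stringsAsFactors = FALSE
  )
  if (!is.null(X_query)) {
    Xq <- as.matrix(as.data.frame(X_query)[, nms, drop = FALSE])
    ids_q <- rownames(Xq)
    if (is.null(ids_q)) ids_q <- paste0("query", seq_len(nrow(Xq)))
    tab <- rbind(tab, data.frame(
      id = ids_q, set = "query", leverage = lev(cbind(1, Xq)),
      std_residual = NA_real_, stringsAsFactors = FALSE
    ))
  }
  tab$high_leverage <- tab$leverage > hs
  tab$outlier <- !is.na(tab$std_residual) & abs(tab$std_residual) > 3
  tab$in_domain <- !tab$high_leverage & !tab$outlier
  structure(list(table = tab, h_star = hs, n = n, p = p),
            class = "ad_result")
}

.pinv <- function(M, tol = NULL) {
  sv <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > tol
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' @export
print.ad_result <- function(x, ...) {
  tr <- x$table[x$table$set == "training", ]
  cat(sprintf("applicability domain: h* = %.4f (p' = %d, n = %d)\n",
              x$h_star, x$p, x$n))
  cat(sprintf("  training: %d/%d in domain, %d high leverage, %d outliers\n",
              sum(tr$in_domain), nrow(tr), sum(tr$high_leverage),
              sum(tr$outlier)))
  invisible(x)
}

#' Full validation report for a fitted model
#'
#' Assembles the complete statistic bundle: training fit statistics,
#' \eqn{Q^2_{LOO}}, \eqn{Q^2_{LMO}}, predictive \eqn{R^2} with external CCC
#' and rm2 metrics on the test partition.
#'
#' @param model a fitted \code{mlr_model}.
#' @param X_train,y_train training partition.
#' @param X_test,y_test test partition (disjoint from training).
#' @param lmo_frac,lmo_repeats,seed leave-many-out settings.
#' @return object of class \code{validation_report} (a named list; see
#'   [report_to_json()]).
#' @export
validate_all <- function(model, X_train, y_train, X_test, y_test,
                         lmo_frac = 0.2, lmo_repeats = 1000, seed = 1L) {
  if (is.null(X_train) || is.null(y_train)) stop("missing training partition")
  if (is.null(X_test) || is.null(y_test)) stop("missing test partition")
  nms <- names(model$coefficients)
  Xtr <- as.matrix(as.data.frame(X_train)[, nms, drop = FALSE])
  Xte <- as.matrix(as.data.frame(X_test)[, nms, drop = FALSE])
  ts <- training_stats(model, Xtr, y_train)
  yhat_test <- predict(model, Xte)
  rm2 <- rm2_metrics(y_test, yhat_test)
  structure(list(
    r2 = ts$r2, r2_adj = ts$r2_adj, rmse = ts$rmse, mae = ts$mae,
    ccc_train = ts$ccc,
    q2_loo = q2_loo(Xtr, y_train),
    q2_lmo = q2_lmo(Xtr, y_train, leave_frac = lmo_frac,
                    repeats = lmo_repeats, seed = seed),
    r2_pred = r2_pred(model, Xte, y_test, mean(y_train)),
    ccc_external = ccc(y_test, yhat_test),
    rm2_avg = rm2$rm2_avg, delta_rm2 = rm2$delta_rm2,
    n_train = length(y_train), n_test = length(y_test),
    p = length(nms)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation report (n_train =", x$n_train, ", n_test =", x$n_test,
      ", p' =", x$p, ")\n")
  fields <- c("r2", "r2_adj", "rmse", "mae", "ccc_train", "q2_loo",
              "q2_lmo", "r2_pred", "ccc_external", "rm2_avg", "delta_rm2")
  for (f in fields) cat(sprintf("  %-12s %8.4f\n", f, x[[f]]))
  invisible(x)
}

#' Serialize / restore a validation report as JSON
#'
#' @param report a \code{validation_report}.
#' @param path optional output file.
#' @return JSON string, or the restored report for [report_from_json()].
#' @export
report_to_json <- function(report, path = NULL) {
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname report_to_json
#' @param json JSON string or file path from [report_to_json()].
#' @export
report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(obj, class = "validation_report")
}
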