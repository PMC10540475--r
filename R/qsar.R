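#' Canonical descriptor names of the pKa model
#'
#' The six regressors, in model order: deprotonation energy `delta_e`
#' (kcal/mol), HOMO--LUMO gap change `delta_hl_gap` (eV), Mulliken
#' electronegativity `chi_m` (eV), nonpolar surface area percentage
#' `npsa_percent` (\%), nitrogen ALIE change `delta_alie_n` (eV), and the
#' categorical amine-type indicator `base_t` (0 aromatic, 1 aliphatic or
#' non-aromatic).
#'
#' @export
pka_descriptor_names <- c("delta_e", "delta_hl_gap", "chi_m",
                          "npsa_percent", "delta_alie_n", "base_t")

#' The published basic-pKa regression model
#'
#' Returns the frozen six-descriptor multiple linear regression for basic
#' pKa of nitrogen compounds:
#' \deqn{pK_a = 0.1074\,\Delta E - 0.1422\,\Delta HL_{Gap}
#'   - 0.9132\,\chi_M + 0.0151\,\%NPSA - 1.4887\,\Delta ALIE_N
#'   + 3.0608\,BaseT - 30.7139}
#' trained on 130 nitrogenous compounds (reported training statistics:
#' R^2 0.9905, s 0.3066, F 2141.9289, RMSE 0.2982, MAE 0.2440).
#'
#' @return a `pka_qsar` model object usable with [predict()],
#'   [coef()] and [print()].
#' @examples
#' m <- published_model()
#' predict(m, data.frame(delta_e = 0, delta_hl_gap = 0, chi_m = 0,
#'                       npsa_percent = 0, delta_alie_n = 0, base_t = 0))
#' @export
published_model <- function() {
  coefs <- c("(Intercept)" = -30.7139,
             delta_e       =   0.1074,
             delta_hl_gap  =  -0.1422,
             chi_m         =  -0.9132,
             npsa_percent  =   0.0151,
             delta_alie_n  =  -1.4887,
             base_t        =   3.0608)
  structure(list(coefficients = coefs,
                 provenance = paste("published model, trained on 130",
                                    "nitrogenous compounds")),
            class = "pka_qsar")
}

#' Fit a pKa QSAR model by ordinary least squares
#'
#' Fits a multiple linear regression of experimental pKa on molecular
#' descriptors and attaches the validation statistics used in QSAR work:
#' R^2, standard error of estimate s, Fisher F, RMSE, MAE, leave-one-out
#' Q^2 and the stability R^2 - Q^2.
#'
#' @param formula model formula, e.g. `pka_exp ~ .`; when omitted, supply
#'   `x` (descriptor data frame) and `y` (pKa vector) instead.
#' @param data data frame holding the response and descriptors.
#' @param x,y alternative matrix-style interface: descriptors and
#'   response.
#' @return an object of class `pka_qsar` with elements `coefficients`,
#'   `fitted.values`, `residuals`, `statistics` (class `fit_statistics`),
#'   `model_frame` and `provenance`.
#' @details Statistic conventions: R^2 = 1 - SSE/SST; s uses the
#'   n - k - 1 denominator; F = (R^2/k) / ((1-R^2)/(n-k-1)); RMSE uses n;
#'   Q^2 = 1 - PRESS/SST with PRESS from the leave-one-out hat-matrix
#'   identity. The design must have more observations than k + 1 and full
#'   column rank; collinear columns are reported by name.
#' @examples
#' d <- linear_dataset(n = 40, noise_sd = 0, seed = 1)
#' fit <- qsar_fit(pka_exp ~ ., data = d)
#' summary(fit)
#' @export
qsar_fit <- function(formula, data, x, y) {
  if (missing(formula)) {
    if (missing(x) || missing(y))
      stop("supply either a formula with data, or x and y")
    data <- as.data.frame(x)
    data$.response <- y
    formula <- stats::as.formula(".response ~ .")
  }
  mf <- stats::model.frame(formula, data)
  yv <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X)
  k <- ncol(X) - 1L
  if (n <= k + 1L)
    stop("need more than k + 1 = ", k + 1L,
         " observations to fit ", k, " descriptors (got ", n, ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }

  fit <- stats::lm.fit(X, yv)
  beta <- fit$coefficients
  fitted <- as.vector(X %*% beta)
  res <- yv - fitted

  stats <- .fit_statistics(yv, fitted, k, hat = .hat_diag(qrX))

  structure(list(coefficients = beta,
                 fitted.values = fitted,
                 residuals = res,
                 statistics = stats,
                 model_frame = mf,
                 provenance = paste0("fitted by OLS on ", n,
                                     " observations, ", k, " descriptors")),
            class = "pka_qsar")
}

.hat_diag <- function(qrX) {
  Q <- qr.Q(qrX)
  rowSums(Q^2)
}

.fit_statistics <- function(y, fitted, k, hat = NULL) {
  n <- length(y)
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  s <- sqrt(sse / (n - k - 1))
  f <- if (k > 0) (r2 / k) / ((1 - r2) / (n - k - 1)) else NA_real_
  rmse <- sqrt(sse / n)
  mae <- mean(abs(res))
  q2 <- if (!is.null(hat)) {
    press <- sum((res / (1 - hat))^2)
    1 - press / sst
  } else NA_real_
  structure(list(n = n, k = k, r2 = r2, s = s, f_statistic = f,
                 rmse = rmse, mae = mae, q2_loo = q2,
                 stability = r2 - q2),
            class = "fit_statistics")
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf("n = %d; k = %d\n", x$n, x$k))
  cat(sprintf("R2 = %.4f; s = %.4f; F = %.4f\n",
              x$r2, x$s, x$f_statistic))
  cat(sprintf("RMSE = %.4f; MAE = %.4f\n", x$rmse, x$mae))
  if (is.finite(x$q2_loo))
    cat(sprintf("Q2(LOO) = %.4f; stability (R2 - Q2) = %.4f\n",
                x$q2_loo, x$stability))
  invisible(x)
}

#' @export
print.pka_qsar <- function(x, ...) {
  cat("<pka_qsar> ", x$provenance, "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.pka_qsar <- function(object, ...) {
  structure(list(model = object), class = "summary.pka_qsar")
}

#' @export
print.summary.pka_qsar <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$statistics)) {
    cat("\nValidation statistics:\n")
    print(x$model$statistics)
  }
  invisible(x)
}

#' @export
coef.pka_qsar <- function(object, ...) object$coefficients

#' @export
residuals.pka_qsar <- function(object, ...) object$residuals

#' @export
fitted.pka_qsar <- function(object, ...) object$fitted.values

#' Predict pKa from descriptors
#'
#' Evaluates the affine model \eqn{a_0 + \sum_i a_i X_i} on new descriptor
#' values. Full precision is retained; round to 2 decimals for reporting,
#' matching the convention of the validation tables.
#'
#' @param object a `pka_qsar` model ([published_model()] or [qsar_fit()]).
#' @param newdata data frame (or single named numeric vector) containing
#'   every descriptor the model uses; a missing descriptor is a contract
#'   violation.
#' @param ... unused.
#' @return numeric vector of predicted pKa values.
#' @export
predict.pka_qsar <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  beta <- object$coefficients
  terms <- setdiff(names(beta), "(Intercept)")
  missing_terms <- setdiff(terms, names(newdata))
  if (length(missing_terms))
    stop("missing descriptor(s) in newdata: ",
         paste(missing_terms, collapse = ", "))
  out <- rep.int(unname(beta["(Intercept)"]), nrow(newdata))
  for (tm in terms) {
    v <- newdata[[tm]]
    if (any(!is.finite(v))) stop("non-finite value for descriptor ", tm)
    out <- out + beta[[tm]] * v
  }
  out
}

#' @export
plot.pka_qsar <- function(x, y = NULL, ...) {
  if (is.null(x$fitted.values))
    stop("plot needs a fitted model (the published model carries no data)")
  obs <- x$fitted.values + x$residuals
  graphics::plot(obs, x$fitted.values,
                 xlab = "experimental pKa", ylab = "predicted pKa", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Leave-one-out cross-validated Q^2
#'
#' \eqn{Q^2 = 1 - PRESS/SST} where PRESS is the sum of squared
#' leave-one-out prediction errors. Uses the exact hat-matrix identity
#' \eqn{e_{(i)} = e_i / (1 - h_{ii})}, which reproduces naive n-refit
#' cross-validation to numerical precision.
#'
#' @param x descriptor data frame or matrix.
#' @param y response vector.
#' @return Q^2 (at most 1; can be negative for uninformative models).
#' @export
loo_q2 <- function(x, y) {
  X <- cbind(1, as.matrix(as.data.frame(x)))
  n <- nrow(X)
  if (n <= ncol(X)) stop("need n > k + 1 for every leave-one-out subset")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design in loo_q2")
  beta <- qr.coef(qrX, y)
  res <- y - as.vector(X %*% beta)
  h <- .hat_diag(qrX)
  press <- sum((res / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Pairwise descriptor correlation screen
#'
#' Pearson correlations between all descriptor pairs, flagging pairs whose
#' absolute correlation exceeds the cap (default |0.7744|, the largest
#' inter-descriptor correlation tolerated in the published model's
#' training pool). Zero-variance columns give undefined correlations,
#' reported as `NA` and never flagged.
#'
#' @param x descriptor data frame or matrix (n >= 3 rows).
#' @param cap flagging threshold on |r|.
#' @return list with `r` (correlation matrix), `flagged` (data frame of
#'   offending pairs) and `cap`.
#' @export
correlation_screen <- function(x, cap = 0.7744) {
  x <- as.data.frame(x)
  if (nrow(x) < 3L) stop("need at least 3 rows for a correlation screen")
  xm <- as.matrix(x)
  p <- ncol(xm)
  r <- suppressWarnings(stats::cor(xm))
  zero_var <- apply(xm, 2, stats::sd) == 0
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r) <- 1
  flagged <- NULL
  if (p >= 2L) {
    idx <- which(upper.tri(r) & !is.na(r) & abs(r) > cap, arr.ind = TRUE)
    if (nrow(idx))
      flagged <- data.frame(var1 = colnames(xm)[idx[, 1]],
                            var2 = colnames(xm)[idx[, 2]],
                            r = r[idx])
  }
  list(r = r,
       flagged = flagged %||% data.frame(var1 = character(0),
                                         var2 = character(0),
                                         r = numeric(0)),
       cap = cap)
}

#' All-subsets descriptor selection ranked by leave-one-out Q^2
#'
#' Exhaustively fits every descriptor subset of size up to `max_k` and
#' ranks them by Q^2(LOO), breaking ties by smaller subset size and then
#' larger F. A simplified stand-in for iterative add/remove descriptor
#' selection: with a moderate pool, exhaustive enumeration dominates any
#' stepwise scheme.
#'
#' @param x descriptor pool, data frame with at most 20 columns
#'   (exhaustive enumeration bound).
#' @param y response vector.
#' @param max_k largest subset size to consider.
#' @return data frame with columns `subset` (comma-joined names), `k`,
#'   `q2_loo`, `r2`, `f_statistic`, ordered best-first.
#' @export
select_descriptors <- function(x, y, max_k) {
  x <- as.data.frame(x)
  if (ncol(x) > 20L)
    stop("descriptor pool too large for exhaustive enumeration (",
         ncol(x), " > 20); pre-filter the pool first")
  max_k <- min(max_k, ncol(x))
  rows <- list()

  # intercept-only entry (k = 0)
  n <- length(y)
  fitted0 <- rep(mean(y), n)
  st0 <- .fit_statistics(y, fitted0, 0L, hat = rep(1 / n, n))
  rows[[1]] <- data.frame(subset = "(none)", k = 0L,
                          q2_loo = st0$q2_loo, r2 = st0$r2,
                          f_statistic = NA_real_)

  if (max_k >= 1L) {
    for (k in seq_len(max_k)) {
      combos <- utils::combn(sort(colnames(x)), k, simplify = FALSE)
      for (cols in combos) {
        X <- cbind(1, as.matrix(x[, cols, drop = FALSE]))
        qrX <- qr(X)
        if (qrX$rank < ncol(X)) next  # collinear subset: not rankable
        beta <- qr.coef(qrX, y)
        fitted <- as.vector(X %*% beta)
        st <- .fit_statistics(y, fitted, k, hat = .hat_diag(qrX))
        rows[[length(rows) + 1L]] <-
          data.frame(subset = paste(cols, collapse = ","), k = k,
                     q2_loo = st$q2_loo, r2 = st$r2,
                     f_statistic = st$f_statistic)
      }
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$q2_loo, out$k, -ifelse(is.na(out$f_statistic),
                                           -Inf, out$f_statistic))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a QSAR model to a JSON document
#'
#' @param model a `pka_qsar` object.
#' @param path output path.
#' @return `path` invisibly; `read_qsar_model()` returns the model.
#' @export
write_qsar_model <- function(model, path) {
  stopifnot(inherits(model, "pka_qsar"))
  doc <- list(coefficients = as.list(model$coefficients),
              provenance = model$provenance)
  if (!is.null(model$statistics))
    doc$statistics <- unclass(model$statistics)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_qsar_model
#' @export
read_qsar_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- list(coefficients = unlist(doc$coefficients),
            provenance = doc$provenance %||% "read from file")
  if (!is.null(doc$statistics)) {
    st <- doc$statistics
    class(st) <- "fit_statistics"
    m$statistics <- st
  }
  structure(m, class = "pka_qsar")
}
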