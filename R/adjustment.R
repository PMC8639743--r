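# Adjusted YPLLG: residuals of a median (least-absolute-deviations)
# regression of YPLLG on nationality and neighborhood covariates. Gender
# and age never enter the model because they already define the individual
# LEB. The LP solve is delegated to quantreg's Barrodale-Roberts simplex;
# on the (degenerate) optimal face the intercept is canonicalized so the
# residual median is zero.

#' Fit a median regression
#'
#' Minimizes the sum of absolute residuals (quantile tau = 0.5) of `y` on
#' the columns of `X` plus an intercept. When the least-absolute-deviations
#' optimum is a degenerate face (the sign counts allow shifting the
#' intercept at no cost), the reported solution is the point of that face
#' with zero median residual.
#'
#' @param y numeric response (e.g. YPLLG in years).
#' @param X data frame or matrix of numeric covariates (e.g. nationality
#'   indicator, income in 1000 CHF, neighborhood median age in years).
#' @return object of class `median_fit`: list with `coefficients`
#'   (intercept first), `residuals`, `fitted`, `objective`, `converged`.
#' @export
fit_median_regression <- function(y, X) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("y and X have different lengths")
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  A <- cbind(`(Intercept)` = 1, as.matrix(X))
  storage.mode(A) <- "double"
  p <- ncol(A)
  if (length(y) <= p) stop("need more observations than coefficients")
  qrA <- qr(A)
  if (qrA$rank < p) {
    drop <- colnames(A)[qrA$pivot[(qrA$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  fit <- if (length(y) <= 5000) {
    quantreg::rq.fit.br(A, y, tau = 0.5)
  } else {
    quantreg::rq.fit.fnb(A, y, tau = 0.5)
  }
  beta <- as.numeric(fit$coefficients)
  names(beta) <- colnames(A)
  resid <- as.numeric(y - A %*% beta)
  obj <- sum(abs(resid))

  # canonicalize on the optimal face: shifting the intercept by the median
  # residual must not change the objective (to rounding)
  shift <- median(resid)
  if (is.finite(shift) && shift != 0) {
    if (sum(abs(resid - shift)) <= obj * (1 + 1e-9) + 1e-9) {
      beta[1] <- beta[1] + shift
      resid <- resid - shift
      obj <- sum(abs(resid))
    }
  }

  structure(list(coefficients = beta, residuals = resid,
                 fitted = as.numeric(A %*% beta), objective = obj,
                 converged = TRUE),
            class = "median_fit")
}

#' Adjusted YPLLG values
#'
#' The adjusted variable fed back into the cluster analysis is the raw
#' residual of the median regression (not re-centred to the original
#' scale).
#'
#' @param fit a [fit_median_regression()] result.
#' @return signed numeric vector of residuals, in years.
#' @export
adjusted_yplg <- function(fit) {
  stopifnot(inherits(fit, "median_fit"))
  if (!isTRUE(fit$converged)) stop("median regression did not converge")
  fit$residuals
}

#' Sum of absolute residuals of a candidate coefficient vector
#'
#' @param y response; `X` covariates as in [fit_median_regression()];
#'   `beta` coefficients with the intercept first.
#' @param X,beta see above.
#' @return the least-absolute-deviations objective value.
#' @export
lad_objective <- function(y, X, beta) {
  A <- cbind(1, as.matrix(as.data.frame(X)))
  sum(abs(y - as.numeric(A %*% beta)))
}

#' Write a median-regression fit summary to CSV
#'
#' @param fit a [fit_median_regression()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  write.csv(data.frame(coefficient = names(fit$coefficients),
                       estimate = unname(fit$coefficients)),
            path, row.names = FALSE)
  invisible(path)
}
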