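#' Fit a ridge-regression BLUP (RR-BLUP) marker model
#'
#' Fits `y = mu + sum_i x_i g_i + e` where every marker effect `g_i` is a
#' random draw from a common normal distribution. Markers are column-centred
#' on the training means and `mu` is the training mean of `y`. The ridge
#' parameter `lambda = sigma2_e / sigma2_g` is estimated by REML on the
#' equivalent kernel model (`u ~ N(0, sigma2_g K)`, `K = Xc Xc'`), profiling
#' the restricted likelihood over `lambda` on the spectrum of the centred
#' kernel, so the fit costs one `n x n` eigendecomposition regardless of the
#' marker count. Effects are recovered through the identity
#' `g = Xc' (K + lambda I)^-1 (y - ybar)
#'    = (Xc' Xc + lambda I)^-1 Xc' (y - ybar)`.
#'
#' @param X entries x markers dosage matrix (real-valued dosages allowed;
#'   no missing values)
#' @param y named or aligned numeric response (typically per-entry BLUPs),
#'   no missing values
#' @param lambda optional fixed ridge parameter; `NULL` (default) estimates
#'   it by REML
#' @return an object of class `rrblup_model`: list with `mu`, `effects`
#'   (named per-marker), `lambda`, `sigma2_g`, `sigma2_e`, `centers`
#'   (training column means), `marker_ids`, `fitted`
#' @export
rrblup_fit <- function(X, y, lambda = NULL) {
  if (inherits(X, "geno_matrix")) X <- X$geno
  X <- as.matrix(X)
  if (!is.null(names(y)) && !is.null(rownames(X)))
    y <- y[rownames(X)]
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y))
    stop("X and y must be free of missing values (impute first)")
  n <- nrow(X)
  if (n < 2) stop("need at least 2 entries")
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(ncol(X)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  mu <- mean(y)
  yc <- y - mu

  if (stats::var(y) == 0) {
    warning("constant response: all marker effects set to 0")
    return(structure(list(
      mu = mu, effects = stats::setNames(numeric(ncol(X)), colnames(X)),
      lambda = Inf, sigma2_g = 0, sigma2_e = 0, centers = ctr,
      marker_ids = colnames(X),
      fitted = stats::setNames(rep(mu, n), rownames(X))),
      class = "rrblup_model"))
  }

  K <- tcrossprod(Xc)
  if (is.null(lambda)) {
    # restricted likelihood on the intercept-orthogonal subspace:
    # eigen of S (K + I) S separates the constant direction (eigenvalue 0)
    # from the n-1 informative directions (eigenvalues theta_i + 1)
    SKS <- K + diag(n)
    SKS <- SKS - rowMeans(SKS)
    SKS <- t(t(SKS) - colMeans(SKS))  # S A S for the centring projector S
    eg <- eigen(SKS, symmetric = TRUE)
    keep <- eg$values > 1e-8
    theta <- pmax(eg$values[keep] - 1, 0)
    eta <- crossprod(eg$vectors[, keep, drop = FALSE], y)[, 1]
    nq <- length(theta)
    negll <- function(loglam) {
      lam <- exp(loglam)
      0.5 * (nq * log(sum(eta^2 / (theta + lam))) + sum(log(theta + lam)))
    }
    opt <- stats::optimize(negll, interval = c(-25, 25), tol = 1e-8)
    lambda <- exp(opt$minimum)
    sigma2_g <- sum(eta^2 / (theta + lambda)) / nq
    sigma2_e <- lambda * sigma2_g
  } else {
    if (lambda <= 0) stop("lambda must be positive")
    sigma2_g <- NA_real_
    sigma2_e <- NA_real_
  }

  sol <- solve(K + lambda * diag(n), yc)
  effects <- drop(crossprod(Xc, sol))
  names(effects) <- colnames(X)
  fitted <- stats::setNames(mu + drop(Xc %*% effects), rownames(X))
  structure(list(mu = mu, effects = effects, lambda = lambda,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e, centers = ctr,
                 marker_ids = colnames(X), fitted = fitted),
            class = "rrblup_model")
}

#' @method print rrblup_model
#' @export
print.rrblup_model <- function(x, ...) {
  cat("rrblup_model: ", length(x$effects), " markers, lambda = ",
      format(x$lambda, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict genomic estimated breeding values from an RR-BLUP model
#'
#' Applies `mu + Xc_new %*% effects` with the new dosages centred on the
#' training column means. Fractional dosages (projected hybrids) are used
#' as-is.
#'
#' @param object an `rrblup_model`
#' @param X_new dosage matrix (or [geno_matrix()]) whose columns match the
#'   model's markers (matched by name when column names are present)
#' @param ... unused
#' @return numeric vector of predictions, named by the rows of `X_new`
#' @export
predict.rrblup_model <- function(object, X_new, ...) {
  if (inherits(X_new, "geno_matrix")) X_new <- X_new$geno
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new))) {
    j <- match(object$marker_ids, colnames(X_new))
    if (anyNA(j))
      stop("X_new is missing model marker(s): ",
           paste(utils::head(object$marker_ids[is.na(j)], 5), collapse = ", "))
    X_new <- X_new[, j, drop = FALSE]
  } else if (ncol(X_new) != length(object$marker_ids)) {
    stop("X_new has ", ncol(X_new), " columns; model expects ",
         length(object$marker_ids))
  }
  if (anyNA(X_new)) stop("X_new must be free of missing values")
  Xc <- sweep(X_new, 2, object$centers)
  stats::setNames(object$mu + drop(Xc %*% object$effects), rownames(X_new))
}
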