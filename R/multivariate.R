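## Spearman correlation, correlation-matrix PCA, varimax ---------------------

#' Spearman rank correlation matrix
#'
#' Pairwise rank correlation over the chosen parameters with average-rank
#' (midrank) tie handling. A constant parameter has no defined rank
#' correlation; its row and column are returned as `NA` and the parameter
#' is listed in the `constant` attribute instead of being silently zeroed.
#'
#' @param samples A [water_samples] object (or any data frame).
#' @param variables Parameters to correlate (default: the 12 index
#'   parameters present in `samples`).
#' @return Symmetric matrix of class `correlation_matrix` with unit
#'   diagonal; attribute `constant` names any flagged parameters.
#' @export
spearman_matrix <- function(samples,
                            variables = intersect(.wqi_parameters,
                                                  names(samples))) {
  X <- as.matrix(as.data.frame(samples)[variables])
  if (nrow(X) < 3) stop("need at least 3 samples", call. = FALSE)
  const <- variables[apply(X, 2, function(v) stats::sd(v) == 0)]
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  if (length(const)) {
    warning("constant variable(s), correlations undefined: ",
            paste(const, collapse = ", "))
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- 1
  structure(rho, constant = const,
            class = c("correlation_matrix", class(rho)))
}

#' @export
print.correlation_matrix <- function(x, digits = 3, strong = 0.7, ...) {
  m <- unclass(x)
  attr(m, "constant") <- NULL
  cat("Rank correlation matrix (", ncol(m), " parameters); |rho| >= ",
      strong, " marked *\n", sep = "")
  fm <- format(round(m, digits))
  fm[!is.na(m) & abs(m) >= strong & row(m) != col(m)] <-
    paste0(fm[!is.na(m) & abs(m) >= strong & row(m) != col(m)], "*")
  print(fm, quote = FALSE, ...)
  invisible(x)
}

#' Kaiser retention rule
#'
#' Number of principal components of a correlation-matrix PCA worth
#' retaining: those with eigenvalue strictly greater than 1 (a component
#' explaining less than one standardized variable's worth of variance adds
#' nothing).
#'
#' @param eigenvalues Numeric vector sorted in descending order.
#' @return Integer count of eigenvalues > 1.
#' @examples
#' kaiser_retain(c(2.5, 1.1, 0.7, 0.4))  # 2
#' @export
kaiser_retain <- function(eigenvalues) {
  if (!length(eigenvalues)) stop("empty eigenvalue list", call. = FALSE)
  if (is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be sorted in descending order", call. = FALSE)
  sum(eigenvalues > 1)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation of retained loading columns maximizing the varimax
#' criterion (sum over components of the variance of squared loadings),
#' via classical pairwise planar rotations. The criterion is checked to be
#' non-decreasing across sweeps; iteration stops when a full sweep improves
#' it by less than `tol`. With one column the input is returned unchanged.
#'
#' `normalize = TRUE` applies Kaiser row normalization (rows scaled to unit
#' communality before rotation and rescaled after), the SPSS default; raw
#' varimax is the package default.
#'
#' @param loadings Numeric matrix, variables x retained components.
#' @param tol Convergence tolerance on the criterion gain per sweep.
#' @param max_iter Maximum number of sweeps.
#' @param normalize Kaiser row normalization (default `FALSE`).
#' @return Rotated matrix with attributes `rotmat` (the orthogonal rotation),
#'   `criterion` (per-sweep path), `iterations`, `converged`.
#' @export
varimax_rotate <- function(loadings, tol = 1e-6, max_iter = 100,
                           normalize = FALSE) {
  L <- as.matrix(loadings)
  p <- nrow(L); k <- ncol(L)
  if (k < 1) stop("no components to rotate", call. = FALSE)
  if (k == 1)
    return(structure(.fix_signs(L), rotmat = diag(1),
                     criterion = .varimax_criterion(L),
                     iterations = 0L, converged = TRUE))
  h <- rep(1, p)
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  R <- diag(k)
  path <- .varimax_criterion(L)
  prev <- path
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      x <- L[, i]; y <- L[, j]
      u <- x^2 - y^2; v <- 2 * x * y
      A <- sum(u); B <- sum(v)
      C <- sum(u^2 - v^2); D <- sum(2 * u * v)
      num <- D - 2 * A * B / p
      den <- C - (A^2 - B^2) / p
      phi <- atan2(num, den) / 4
      if (abs(phi) > 1e-14) {
        G <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
        L[, c(i, j)] <- L[, c(i, j)] %*% G
        R[, c(i, j)] <- R[, c(i, j)] %*% G
      }
    }
    cur <- .varimax_criterion(L)
    if (cur < prev - 1e-12)
      stop("internal error: varimax criterion decreased", call. = FALSE)
    path <- c(path, cur)
    if (cur - prev < tol) { converged <- TRUE; break }
    prev <- cur
  }
  if (!converged)
    warning("varimax did not converge in ", max_iter,
            " sweeps; returning best iterate")
  L <- L * h
  # fold the deterministic sign convention into the rotation matrix too
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; R[, j] <- -R[, j] }
  }
  structure(L, rotmat = R, criterion = path, iterations = iter,
            converged = converged)
}

# raw varimax criterion: per-column variance of squared loadings
.varimax_criterion <- function(L) {
  s <- L^2
  sum(apply(s, 2, function(col) mean(col^2) - mean(col)^2))
}

# deterministic sign convention: largest-|loading| entry of each column
# made positive
.fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Label loading strength
#'
#' The conventional interpretation bands for absolute component loadings:
#' strong at 0.75 and above, moderate in [0.50, 0.75), weak in
#' [0.30, 0.50), and negligible below 0.30.
#'
#' @param value Numeric vector of loadings (|value| at most 1 within
#'   numerical tolerance).
#' @return Character vector of labels.
#' @examples
#' classify_loading(c(0.823, -0.435, 0.2))
#' @export
classify_loading <- function(value) {
  if (any(abs(value) > 1 + 1e-6))
    stop("|loading| exceeds 1", call. = FALSE)
  a <- abs(value)
  ifelse(a >= 0.75, "strong",
         ifelse(a >= 0.50, "moderate",
                ifelse(a >= 0.30, "weak", "negligible")))
}

#' Correlation-matrix PCA with Kaiser retention and varimax rotation
#'
#' Standardizes each parameter to zero mean and unit variance,
#' eigendecomposes the Pearson correlation matrix, and scales eigenvectors
#' to loadings (`eigenvector * sqrt(eigenvalue)`). Components are retained
#' by the Kaiser rule (eigenvalue > 1) applied to the unrotated spectrum,
#' and the retained loading columns are varimax-rotated. Correlation-matrix
#' (rather than covariance) PCA is the right choice here because major-ion
#' parameters span four orders of magnitude in concentration.
#'
#' A deterministic sign convention (largest-|loading| entry of each
#' component positive) keeps results reproducible across linear-algebra
#' backends. Tiny negative eigenvalues from rank-deficient input are
#' clipped to zero with a warning.
#'
#' @param samples A [water_samples] object (or data frame).
#' @param variables Parameters to analyze.
#' @param rotate Apply varimax to the retained components (default `TRUE`).
#' @param normalize Kaiser row normalization for the rotation.
#' @return A `gw_pca` object: list with `variables`, `eigenvalues`,
#'   `pct_variance`, `n_retained`, `loadings` (all components, unrotated),
#'   `rotated_loadings` (retained columns), `strength_labels` (on the
#'   rotated retained loadings), `scores` (standardized data projected on
#'   retained components), `correlation`.
#' @export
pca_correlation <- function(samples,
                            variables = intersect(.wqi_parameters,
                                                  names(samples)),
                            rotate = TRUE, normalize = FALSE) {
  X <- as.matrix(as.data.frame(samples)[variables])
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1)
    stop("need at least one more sample than variables (", p + 1, ")",
         call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  Z <- scale(X)
  C <- stats::cor(X)
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -1e-10))
    warning("negative eigenvalue(s) clipped at zero (rank-deficient input)")
  lam <- pmax(lam, 0)
  V <- e$vectors
  L <- V %*% diag(sqrt(lam), p, p)
  dimnames(L) <- list(variables, paste0("PC", seq_len(p)))
  L <- .fix_signs(L)
  n_ret <- kaiser_retain(lam)
  rot <- NULL
  if (n_ret >= 1) {
    ret <- L[, seq_len(n_ret), drop = FALSE]
    rot <- if (rotate && n_ret >= 2)
      varimax_rotate(ret, normalize = normalize)
    else .fix_signs(ret)
  }
  labels <- if (!is.null(rot)) {
    m <- matrix(classify_loading(as.vector(rot)), nrow(rot), ncol(rot),
                dimnames = dimnames(rot))
    m
  }
  scores <- if (n_ret >= 1) Z %*% V[, seq_len(n_ret), drop = FALSE]
  structure(list(variables = variables,
                 eigenvalues = lam,
                 pct_variance = 100 * lam / sum(lam),
                 n_retained = n_ret,
                 loadings = L,
                 rotated_loadings = rot,
                 strength_labels = labels,
                 scores = scores,
                 correlation = C,
                 rotate = rotate, normalize = normalize,
                 n = n),
            class = "gw_pca")
}

#' @export
print.gw_pca <- function(x, digits = 3, ...) {
  cat("Correlation-matrix PCA of", length(x$variables), "parameters,",
      x$n, "samples\n")
  ev <- rbind(eigenvalue = x$eigenvalues, `% variance` = x$pct_variance,
              `cum %` = cumsum(x$pct_variance))
  colnames(ev) <- paste0("PC", seq_along(x$eigenvalues))
  print(round(ev, digits))
  cat("Kaiser rule retains", x$n_retained, "component(s)\n")
  if (!is.null(x$rotated_loadings)) {
    cat(if (x$rotate && x$n_retained >= 2) "Varimax-rotated loadings"
        else "Retained loadings", "(strength in brackets):\n")
    m <- x$rotated_loadings
    disp <- matrix(paste0(format(round(unclass(m), digits)), " [",
                          x$strength_labels, "]"),
                   nrow(m), ncol(m), dimnames = dimnames(m))
    print(disp, quote = FALSE)
  }
  invisible(x)
}

#' @describeIn pca_correlation Scree plot of the eigenvalue spectrum with
#'   the Kaiser threshold marked.
#' @param x A `gw_pca` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gw_pca <- function(x, ...) {
  graphics::plot(seq_along(x$eigenvalues), x$eigenvalues, type = "b",
                 xlab = "component", ylab = "eigenvalue", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
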