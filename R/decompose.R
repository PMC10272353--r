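#' Build a response matrix from a PETH table
#'
#' Observations are channels (columns); features are the smoothed sqrt-rate
#' time samples of the analysis window (rows), by default the 50 five-ms bins
#' of the 250 ms immediately following solenoid onset. Channels excluded by
#' the baseline criterion are dropped.
#'
#' @param peth long PETH data.frame from [compute_peths()].
#' @param summary the matching summary data.frame (for inclusion flags and
#'   covariates).
#' @param trial_type trial type(s) to include; each included channel x type
#'   combination contributes one observation.
#' @param window_ms ms interval of bins to use (relative to trial zero).
#' @param value column of `peth` to use as the response.
#' @return object of class `response_matrix`: list with `X` (p x n matrix),
#'   `info` (n-row data.frame of observation covariates), `bin_starts_ms`.
#' @export
build_response_matrix <- function(peth, summary, trial_type,
                                  window_ms = c(50, 300),
                                  value = "smoothed") {
  keep <- summary[summary$included & summary$trial_type %in% trial_type, ,
                  drop = FALSE]
  if (nrow(keep) == 0) stop("no included observations for ", paste(trial_type, collapse = "/"))
  sel_bins <- NULL
  cols <- vector("list", nrow(keep))
  for (i in seq_len(nrow(keep))) {
    rows <- peth$animal == keep$animal[i] & peth$channel == keep$channel[i] &
      peth$trial_type == keep$trial_type[i] &
      peth$bin_start_ms >= window_ms[1] & peth$bin_start_ms < window_ms[2]
    sub <- peth[rows, , drop = FALSE]
    sub <- sub[order(sub$bin_start_ms), , drop = FALSE]
    if (is.null(sel_bins)) sel_bins <- sub$bin_start_ms
    cols[[i]] <- sub[[value]]
  }
  X <- do.call(cbind, cols)
  if (anyNA(X)) stop("response matrix contains missing values")
  structure(list(X = X, info = keep, bin_starts_ms = sel_bins),
            class = "response_matrix")
}

as_matrix_X <- function(X) if (inherits(X, "response_matrix")) X$X else X

#' Top-k principal components of the evoked responses
#'
#' Singular value decomposition of the column-centered response matrix
#' (each observation minus the mean observation profile).
#'
#' @param X a `response_matrix` or p x n numeric matrix (columns =
#'   observations).
#' @param k number of components.
#' @return list: `vectors` (p x k orthonormal, ordered by decreasing
#'   singular value), `explained` (variance fractions), `mu` (mean profile),
#'   `k_effective` (components actually returned; fewer than `k` when the
#'   matrix rank is deficient, with a warning).
#' @export
pca_topk <- function(X, k = 3) {
  X <- as_matrix_X(X)
  if (ncol(X) < k)
    stop("need at least k observations")
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  keff <- min(k, rank)
  if (keff < k) warning("matrix rank ", rank, " < k; returning ", keff,
                        " components")
  list(vectors = sv$u[, seq_len(keff), drop = FALSE],
       explained = if (tot > 0) sv$d[seq_len(keff)]^2 / tot else rep(0, keff),
       mu = mu, k_effective = keff)
}

#' Combined principal-component basis for two trial groupings
#'
#' PCA of the column-wise concatenation of the two response matrices, used
#' to seed the combined reconstruction-ICA so that Solenoid and
#' ICMS+Solenoid responses are expressed in one shared basis.
#'
#' @param X1,X2 response matrices (same number of rows).
#' @param k components.
#' @return as [pca_topk()].
#' @export
combined_basis <- function(X1, X2, k = 3) {
  X1 <- as_matrix_X(X1); X2 <- as_matrix_X(X2)
  if (nrow(X1) != nrow(X2)) stop("response matrices have mismatched p")
  pca_topk(cbind(X1, X2), k)
}

rica_objective <- function(Xc, lambda, n) {
  function(a) {
    A <- matrix(a, nrow(Xc))
    S <- crossprod(A, Xc)
    R <- A %*% S - Xc
    lambda * sum(R^2) / n + sum(log(cosh(S))) / n
  }
}

rica_gradient <- function(Xc, lambda, n) {
  function(a) {
    A <- matrix(a, nrow(Xc))
    S <- crossprod(A, Xc)
    R <- A %*% S - Xc
    as.numeric(2 * lambda / n * (R %*% t(S) + Xc %*% t(R) %*% A) +
                 (Xc %*% t(tanh(S))) / n)
  }
}

#' Fit the reconstruction-ICA model x = mu + A s
#'
#' Minimizes a reconstruction penalty plus a smooth independence contrast
#' (log-cosh of the source activations) with the L-BFGS quasi-Newton
#' optimizer, initialized at the seed eigenvectors. Sources are the
#' least-squares projections of the centered observations on the fitted
#' mixing matrix, standardized to zero mean and unit variance across
#' observations (the scaling is folded into `A` and `mu` so that
#' `mu + A %*% s` reproduces each observation). Components are reordered to
#' match the seed and oriented so each column's largest-magnitude
#' coefficient is positive.
#'
#' @param X a `response_matrix` or p x n matrix (columns = observations).
#' @param seed_basis p x q orthonormal seed (top principal eigenvectors).
#' @param lambda weight of the reconstruction penalty.
#' @param maxit iteration cap; 0 returns the seed basis unmodified (the
#'   initialization contract).
#' @param tol relative objective-change tolerance.
#' @return object of class `component_basis`: list with `mu`, `A` (p x q),
#'   `S` (q x n standardized sources), `seed_basis`, `info` (observation
#'   covariates when available), `converged`, `iterations`, `objective`.
#' @export
rica_fit <- function(X, seed_basis, lambda = 1, maxit = 1000, tol = 1e-6) {
  info <- if (inherits(X, "response_matrix")) X$info else NULL
  X <- as_matrix_X(X)
  p <- nrow(X); n <- ncol(X); q <- ncol(seed_basis)
  if (nrow(seed_basis) != p) stop("seed basis has wrong dimension")
  mu <- rowMeans(X)
  Xc <- X - mu
  if (maxit == 0) {
    A <- seed_basis
    conv <- TRUE; iters <- 0L
    value <- rica_objective(Xc, lambda, n)(as.numeric(A))
  } else {
    o <- stats::optim(as.numeric(seed_basis), rica_objective(Xc, lambda, n),
                      rica_gradient(Xc, lambda, n), method = "L-BFGS-B",
                      control = list(maxit = maxit,
                                     factr = tol / .Machine$double.eps))
    A <- matrix(o$par, p, q)
    conv <- o$convergence == 0
    if (!conv) warning("reconstruction-ICA did not converge within ", maxit,
                       " iterations; returning best iterate")
    iters <- o$counts[["function"]]
    value <- o$value
  }
  S <- solve(crossprod(A), crossprod(A, Xc))
  if (maxit > 0) {
    m <- rowMeans(S)
    sdv <- apply(S, 1, stats::sd)
    sdv[sdv == 0] <- 1
    mu <- mu + as.numeric(A %*% m)
    A <- A %*% diag(sdv, q)
    S <- (S - m) / sdv
  }
  basis <- structure(list(mu = mu, A = A, S = S, seed_basis = seed_basis,
                          info = info, converged = conv, iterations = iters,
                          objective = value, lambda = lambda),
                     class = "component_basis")
  if (maxit > 0) basis <- align_components(basis, seed_basis)
  basis
}

#' @export
print.component_basis <- function(x, ...) {
  cat(sprintf("component_basis: p = %d, q = %d, n = %d observations\n",
              nrow(x$A), ncol(x$A), ncol(x$S)))
  cat(sprintf("  objective %.6g after %d evaluations (%sconverged)\n",
              x$objective, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Project observations onto a fitted component basis
#'
#' Least-squares coefficients of `x - mu` on the columns of `A`, i.e. the
#' component weights on the basis's standardized source scale.
#'
#' @param basis a `component_basis`.
#' @param x length-p profile or p x m matrix of profiles.
#' @return numeric weight vector (length q) or q x m matrix.
#' @export
project_weights <- function(basis, x) {
  xc <- x - basis$mu
  qr.solve(basis$A, xc)
}

#' Reconstruct a rate profile from component weights
#'
#' @param basis a `component_basis`.
#' @param w weight vector of length q (e.g. a group-mean weight).
#' @return reconstructed profile `mu + A w`, length p.
#' @export
reconstruct_profile <- function(basis, w) {
  as.numeric(basis$mu + basis$A %*% w)
}

all_perms <- function(q) {
  if (q == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(q - 1L)
  unname(do.call(rbind, lapply(seq_len(q), function(i) {
    cbind(i, matrix(setdiff(seq_len(q), i)[sub], nrow(sub))) })))
}

#' Align components to a reference (sign and permutation)
#'
#' ICA components are determined only up to order and sign; this reorders
#' and sign-flips the basis to maximize the summed absolute correlation of
#' its columns with the reference columns, transforming sources consistently
#' so that reconstructions are unchanged.
#'
#' @param basis a `component_basis`.
#' @param reference p x q matrix (seed eigenvectors or ground-truth shapes)
#'   or another `component_basis`.
#' @return the aligned `component_basis`, with attribute `alignment` (the
#'   permutation and signs applied).
#' @export
align_components <- function(basis, reference) {
  if (inherits(reference, "component_basis")) reference <- reference$A
  q <- ncol(basis$A)
  if (ncol(reference) != q) stop("reference has a different number of components")
  cors <- suppressWarnings(stats::cor(basis$A, reference))
  cors[is.na(cors)] <- 0
  perms <- all_perms(q)
  score <- apply(perms, 1, function(pm) sum(abs(cors[cbind(pm, seq_len(q))])))
  pm <- as.integer(perms[which.max(score), ])
  sgn <- sign(cors[cbind(pm, seq_len(q))])
  sgn[sgn == 0] <- 1
  basis$A <- basis$A[, pm, drop = FALSE] %*% diag(sgn, q)
  basis$S <- diag(sgn, q) %*% basis$S[pm, , drop = FALSE]
  attr(basis, "alignment") <- list(perm = pm, sign = sgn)
  basis
}

#' Orient components so the largest-magnitude coefficient is positive
#'
#' @param basis a `component_basis`.
#' @return the basis with each column's dominant coefficient positive.
#' @export
orient_components <- function(basis) {
  q <- ncol(basis$A)
  sgn <- vapply(seq_len(q), function(j) {
    v <- basis$A[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  basis$A <- basis$A %*% diag(sgn, q)
  basis$S <- diag(sgn, q) %*% basis$S
  basis
}

#' Decompose evoked responses per trial type and for the combined grouping
#'
#' Runs the full component analysis: a PCA-seeded reconstruction-ICA per
#' trial type (each over the 250-ms post-solenoid window) and a combined
#' decomposition of the Solenoid and ICMS+Solenoid responses sharing one
#' basis (ICMS-only trials are excluded from the combined basis because they
#' lack the solenoid-evoked response). The combined basis yields the
#' per-channel weight table used for statistical modelling.
#'
#' @param peth,summary outputs of [compute_peths()].
#' @param trial_types the three trial-type labels, ordered (Solenoid, ICMS,
#'   ICMS+Solenoid).
#' @param window_ms analysis window, ms.
#' @param k components.
#' @param lambda,maxit reconstruction-ICA settings.
#' @return list: `per_type` (named list of `component_basis`), `combined`
#'   (`component_basis`), `weights` (data.frame: covariates plus `w1..wk`
#'   from the combined fit).
#' @export
decompose_responses <- function(peth, summary,
                                trial_types = c("Solenoid", "ICMS", "ICMS+Solenoid"),
                                window_ms = c(50, 300), k = 3,
                                lambda = 1, maxit = 1000) {
  per_type <- list()
  for (ty in trial_types) {
    Xt <- build_response_matrix(peth, summary, ty, window_ms)
    seed <- pca_topk(Xt, k)
    fit <- rica_fit(Xt, seed$vectors, lambda, maxit)
    per_type[[ty]] <- orient_components(fit)
  }
  X1 <- build_response_matrix(peth, summary, trial_types[1], window_ms)
  X2 <- build_response_matrix(peth, summary, trial_types[3], window_ms)
  seed <- combined_basis(X1, X2, k)
  Xall <- structure(list(X = cbind(X1$X, X2$X), info = rbind(X1$info, X2$info),
                         bin_starts_ms = X1$bin_starts_ms),
                    class = "response_matrix")
  comb <- orient_components(rica_fit(Xall, seed$vectors, lambda, maxit))
  W <- t(comb$S)
  colnames(W) <- paste0("w", seq_len(ncol(W)))
  weights <- cbind(Xall$info[, c("animal", "channel", "area", "trial_type",
                                 "lesion_volume")], as.data.frame(W))
  rownames(weights) <- NULL
  list(per_type = per_type, combined = comb, weights = weights)
}
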