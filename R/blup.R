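#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A from a pedigree.
#' Unknown parents are treated as unrelated non-inbred founders. The
#' pedigree is topologically sorted internally, so parents may appear
#' after offspring in the input; the returned matrix is in the input
#' animal order.
#'
#' @param ped Data frame with columns `animal`, `sire`, `dam` (ids;
#'   `0`, `""` or `NA` mark unknown parents). Animal ids must be unique.
#' @return Symmetric matrix A with `dimnames` set to the animal ids;
#'   diagonal `1 + F` with `F` the inbreeding coefficient.
#' @export
build_A <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$animal)
  if (anyDuplicated(id)) stop("duplicate animal ids in pedigree")
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | x == ""] <- NA_character_
    x
  }
  sire <- clean(ped$sire)
  dam <- clean(ped$dam)
  unknown_parent <- c(sire, dam)
  unknown_parent <- unknown_parent[!is.na(unknown_parent) &
                                     !(unknown_parent %in% id)]
  if (length(unknown_parent))
    stop("parents not in pedigree: ", paste(unique(unknown_parent), collapse = ", "))
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  ord <- pedigree_order(si, di)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (t in seq_along(ord)) {
    i <- ord[t]
    s <- si[i]; d <- di[i]
    prev <- ord[seq_len(t - 1L)]
    if (length(prev)) {
      as_ <- if (!is.na(s)) A[s, prev] else 0
      ad_ <- if (!is.na(d)) A[d, prev] else 0
      A[i, prev] <- A[prev, i] <- 0.5 * (as_ + ad_)
    }
    Fi <- if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    A[i, i] <- 1 + Fi
  }
  A
}

# topological order: parents before offspring (Kahn's algorithm)
pedigree_order <- function(si, di) {
  n <- length(si)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
                     (is.na(di) | placed[ifelse(is.na(di), 1L, di)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle (an animal is its own ancestor)")
  ord
}

#' Mixed-model specification
#'
#' Container for the variance components and structure of the animal
#' model `y = Xb + Za + e` with `var(a) = sigma2_a * A`,
#' `var(e) = sigma2_e * I`.
#'
#' @param sigma2_a Additive polygenic variance (> 0).
#' @param sigma2_e Residual variance (> 0).
#' @param A Numerator relationship matrix.
#' @param Z Animal-to-record incidence matrix (default identity: one
#'   record per animal in A's order).
#' @return An object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(sigma2_a, sigma2_e, A, Z = NULL) {
  stopifnot(sigma2_a > 0, sigma2_e > 0, is.matrix(A),
            nrow(A) == ncol(A))
  if (is.null(Z)) Z <- diag(nrow(A))
  stopifnot(ncol(Z) == nrow(A))
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e, A = A, Z = Z),
            class = "mixed_model_spec")
}

#' Henderson's mixed model equations
#'
#' Exact joint solution of the animal model at desk scale: returns the
#' BLUE of (estimable functions of) the fixed effects and the BLUP of
#' the polygenic values from
#' `[X'X, X'Z; Z'X, Z'Z + lambda A^-1] [b; a] = [X'y; Z'y]`,
#' `lambda = sigma2_e / sigma2_a`. A Moore-Penrose generalized inverse is
#' used, so rank-deficient fixed designs are allowed (only estimable
#' contrasts of `b_hat` are then meaningful).
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix.
#' @param Z Incidence matrix for the polygenic values (defaults to the
#'   spec's `Z`).
#' @param spec A `mixed_model_spec`.
#' @param max_n Guard on problem size (dense algebra only; default 2000).
#' @return List with `b_hat`, `a_hat`, and `lambda`.
#' @export
solve_mme <- function(y, X, spec, Z = spec$Z, max_n = 2000L) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  n <- length(y)
  if (n > max_n) stop("instance too large for the dense MME oracle")
  if (nrow(X) != n || nrow(Z) != n) stop("dimension mismatch")
  lambda <- spec$sigma2_e / spec$sigma2_a
  Ainv <- robust_inverse(spec$A)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ainv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(C, rhs),
                  error = function(e) MASS::ginv(C) %*% rhs)
  p <- ncol(X)
  list(b_hat = drop(sol[seq_len(p)]),
       a_hat = drop(sol[-seq_len(p)]),
       lambda = lambda)
}

#' Generalized least-squares estimator with explicit V
#'
#' The GLS solution `b_hat = (X' V^-1 X)^- X' V^-1 y` with
#' `V = sigma2_a Z A Z' + sigma2_e I`, formed explicitly. Desk-scale
#' only; serves as the independent oracle for the MME and AGLS paths
#' (all three agree on estimable contrasts).
#'
#' @inheritParams solve_mme
#' @return Vector `b_hat` (a generalized-inverse solution; estimable
#'   contrasts are unique).
#' @export
gls_estimate <- function(y, X, spec, Z = spec$Z, max_n = 2000L) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  n <- length(y)
  if (n > max_n) stop("instance too large for the dense GLS oracle")
  V <- spec$sigma2_a * Z %*% spec$A %*% t(Z) + spec$sigma2_e * diag(n)
  Vinv <- robust_inverse(V)
  XtVinv <- crossprod(X, Vinv)
  drop(MASS::ginv(XtVinv %*% X) %*% (XtVinv %*% y))
}

# symmetric-PD inverse via Cholesky, ridged on numerical singularity
robust_inverse <- function(M) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    warning("matrix numerically singular; adding 1e-8 ridge")
    R <- chol(M + 1e-8 * diag(nrow(M)))
  }
  chol2inv(R)
}

# exact intercept-only BLUP with Z = I, avoiding A^-1: uses
# (I + lambda A^-1)^-1 = (A + lambda I)^-1 A, one Cholesky of A + lambda I.
# Used by the simulator for populations too large for the dense MME.
blup_intercept <- function(y, A, sigma2_a, sigma2_e) {
  n <- length(y)
  lambda <- sigma2_e / sigma2_a
  R <- chol(A + lambda * diag(n))
  f <- function(r) backsolve(R, forwardsolve(t(R), A %*% r))
  f1 <- f(rep(1, n))
  fy <- f(y)
  mu <- (sum(y) - sum(fy)) / (n - sum(f1))
  a_hat <- drop(fy - mu * f1)
  list(mu = mu, a_hat = a_hat)
}
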