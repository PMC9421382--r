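#' Reference-based cell-type deconvolution
#'
#' Estimates per-sample cell-type proportions by constrained projection: each
#' sample's beta profile over the probes shared with the reference panel is
#' regressed on the reference cell-type profiles under the constraints that
#' proportions are nonnegative and sum to one. The quadratic program is solved
#' exactly by an active-set method on the KKT system (equality constraint kept
#' active throughout), so returned proportions lie on the probability simplex
#' to solver precision.
#'
#' @param beta Beta matrix (probes x samples).
#' @param reference Numeric matrix of mean beta profiles, probes x cell types
#'   (>= 2 cell types); its probes must be a subset of `beta`'s, with at least
#'   as many shared probes as cell types, and full column rank on the shared
#'   probes.
#' @param tol Convergence / feasibility tolerance. Default 1e-8.
#' @return Matrix of proportions, samples x cell types; rows sum to 1.
#' @export
estimate_cell_composition <- function(beta, reference, tol = 1e-8) {
  check_beta_matrix(beta, open_interval = FALSE)
  if (!is.matrix(reference) || ncol(reference) < 2L)
    stop("reference must be a matrix with >= 2 cell-type columns")
  shared <- intersect(rownames(reference), rownames(beta))
  if (length(shared) < ncol(reference))
    stop("need at least as many shared probes as cell types (have ",
         length(shared), ")")
  A <- reference[shared, , drop = FALSE]
  if (qr(A)$rank < ncol(A))
    stop("reference panel is rank-deficient on the shared probes")
  Y <- beta[shared, , drop = FALSE]
  k <- ncol(A)
  Q <- crossprod(A)
  C <- crossprod(A, Y)                 # k x samples
  out <- matrix(NA_real_, ncol(beta), k,
                dimnames = list(colnames(beta), colnames(A)))
  for (j in seq_len(ncol(Y)))
    out[j, ] <- simplex_lsq(Q, C[, j], tol = tol)
  out
}

## internal: minimize 1/2 p'Qp - c'p  s.t.  sum(p) = 1, p >= 0
## Active-set iteration on the KKT system; exact for positive-definite Q.
simplex_lsq <- function(Q, c_vec, tol = 1e-8, max_iter = 200L) {
  k <- length(c_vec)
  active <- rep(FALSE, k)              # variables pinned at zero
  for (iter in seq_len(max_iter)) {
    free <- which(!active)
    nf <- length(free)
    ## solve [Q_FF 1; 1' 0] [p_F; lambda] = [c_F; 1]
    K <- rbind(cbind(Q[free, free, drop = FALSE], 1),
               c(rep(1, nf), 0))
    sol <- solve(K, c(c_vec[free], 1))
    p <- numeric(k)
    p[free] <- sol[seq_len(nf)]
    lambda <- sol[nf + 1L]
    if (any(p[free] < -tol)) {
      active[free[which.min(p[free])]] <- TRUE
      next
    }
    p[p < 0] <- 0
    ## KKT multipliers of pinned variables: mu = (Qp - c) + lambda >= 0
    if (any(active)) {
      mu <- (Q %*% p - c_vec)[active] + lambda
      if (any(mu < -tol)) {
        rel <- which(active)[which.min(mu)]
        active[rel] <- FALSE
        next
      }
    }
    p <- p / sum(p)                    # exact simplex projection of rounding
    return(p)
  }
  stop("simplex least-squares failed to converge")
}

#' Principal components of estimated cellular composition
#'
#' Column-centred (unscaled) PCA of the proportions matrix; the top `k` score
#' columns are the cell-composition covariates ("Ecc PCs") used in the
#' association models. Because proportions sum to one, at most
#' `n_cell_types - 1` components carry variance. Signs are fixed so that each
#' loading vector's largest-magnitude entry is positive.
#'
#' @param composition Samples x cell-types proportions matrix.
#' @param k Number of components (<= cell types - 1). Default 5.
#' @return List with `scores` (samples x k), `loadings` (cell types x k) and
#'   `explained` (variance fractions, length k).
#' @export
composition_pcs <- function(composition, k = 5L) {
  composition <- as.matrix(composition)
  if (k > ncol(composition) - 1L)
    stop("k must be <= number of cell types - 1 (sum-to-one constraint)")
  if (all(apply(composition, 2L, stats::var) < 1e-24))
    stop("compositions have zero variance; PCA undefined")
  pc <- stats::prcomp(composition, center = TRUE, scale. = FALSE)
  k <- as.integer(k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {              # deterministic sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("EccPC", seq_len(k))
  var_all <- pc$sdev^2
  list(scores = scores, loadings = loadings,
       explained = var_all[seq_len(k)] / sum(var_all))
}
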