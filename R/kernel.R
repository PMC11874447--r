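#' Pairwise Euclidean distances between spots
#'
#' @param coords numeric matrix with one row per spot and columns (x, y).
#' @return A symmetric S x S matrix of Euclidean distances with zero
#'   diagonal.
#' @export
pairwise_distances <- function(coords) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords)))
    stop("'coords' contains non-finite entries", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  diag(d) <- 0
  d
}

#' Squared-exponential covariance
#'
#' Builds the squared-exponential (SE) spatial covariance
#' `exp(-d^2 * r / 2)` from a distance matrix and a decay rate `r`.  The
#' decay rate relates to the length scale `l` by \code{r = 1/l^2}: small `r`
#' (large `l`) gives slowly decaying, smooth covariance.
#'
#' @param dist S x S Euclidean distance matrix.
#' @param r positive decay rate.
#' @return S x S covariance matrix with unit diagonal.
#' @export
se_covariance <- function(dist, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("'r' must be a single positive decay rate", call. = FALSE)
  sig <- exp(-0.5 * dist^2 * r)
  diag(sig) <- 1
  sig
}

#' Periodic covariance
#'
#' Optional alternative kernel `exp(-2 * sin(pi * d / period)^2 * r)` for
#' tissues with repeating structure; the period is user-fixed.
#'
#' @inheritParams se_covariance
#' @param period positive repeat distance.
#' @return S x S covariance matrix with unit diagonal.
#' @export
periodic_covariance <- function(dist, r, period) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("'r' must be a single positive decay rate", call. = FALSE)
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("'period' must be a single positive number", call. = FALSE)
  sig <- exp(-2 * sin(pi * dist / period)^2 * r)
  diag(sig) <- 1
  sig
}

#' Cholesky factor of a (nearly) positive semi-definite matrix
#'
#' Returns a lower-triangular factor `F` with `F %*% t(F) = sigma +
#' used_jitter * I`.  If factorization fails at the requested jitter, the
#' jitter escalates geometrically (x10) up to `max_jitter`; the jitter
#' actually used is attached as attribute `"jitter"`.
#'
#' @param sigma symmetric matrix.
#' @param jitter initial diagonal regularizer (>= 0).
#' @param max_jitter escalation cap.
#' @return Lower-triangular matrix with attribute `"jitter"`.
#' @export
chol_psd <- function(sigma, jitter = 1e-6, max_jitter = 1e-2) {
  sigma <- as.matrix(sigma)
  if (!isSymmetric(sigma, tol = 1e-8))
    stop("'sigma' must be symmetric", call. = FALSE)
  j <- jitter
  repeat {
    res <- tryCatch(chol(sigma + diag(j, nrow(sigma))), error = function(e) NULL)
    if (!is.null(res)) {
      out <- t(res)
      attr(out, "jitter") <- j
      return(out)
    }
    j <- if (j == 0) 1e-10 else j * 10
    if (j > max_jitter) {
      ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
      stop(sprintf(paste0("matrix not positive definite within the jitter ",
                          "cap %g (smallest eigenvalue ~ %g)"),
                   max_jitter, ev_min), call. = FALSE)
    }
  }
}

#' Candidate length-scale grid
#'
#' Builds a geometric grid of candidate SE decay rates for the per-module
#' length-scale selection.  Length scales span the median nearest-neighbour
#' distance up to the maximum pairwise distance; rates are \code{r = 1/l^2}.
#' With `n_grid = 1` the single candidate sits at the geometric midpoint of
#' the span.
#'
#' @param coords spot coordinates (S x 2).
#' @param n_grid number of candidates.
#' @return A list with `r` (decay rates, increasing), `l` (matching length
#'   scales, decreasing) and `nn_dist` (the median nearest-neighbour
#'   distance, the natural coordinate unit).
#' @export
candidate_length_scales <- function(coords, n_grid = 10) {
  stopifnot(n_grid >= 1)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 spots", call. = FALSE)
  d <- pairwise_distances(coords)
  off <- d; diag(off) <- Inf
  nn <- apply(off, 1L, min)
  med_nn <- stats::median(nn)
  dmax <- max(d)
  if (med_nn == 0 || dmax == 0)
    stop("degenerate geometry: coordinates are not distinct", call. = FALSE)
  l <- if (n_grid == 1L) sqrt(med_nn * dmax)
       else exp(seq(log(med_nn), log(dmax), length.out = n_grid))
  r <- 1 / l^2
  ord <- order(r)
  list(r = r[ord], l = l[ord], nn_dist = med_nn)
}

#' Kernel settings
#'
#' @param kind `"squared_exponential"` (default) or `"periodic"`.
#' @param n_grid number of candidate length scales when `r_grid` is not
#'   given.
#' @param r_grid optional explicit increasing vector of decay rates (in
#'   rescaled units where the median nearest-neighbour distance is 1).
#' @param jitter diagonal regularizer added to every covariance.
#' @param period period of the periodic kernel (rescaled units).
#' @return A list of class `"kernel_control"`.
#' @export
kernel_control <- function(kind = c("squared_exponential", "periodic"),
                           n_grid = 10, r_grid = NULL, jitter = 1e-6,
                           period = 2) {
  kind <- match.arg(kind)
  stopifnot(n_grid >= 1, jitter >= 0, period > 0)
  if (!is.null(r_grid)) {
    r_grid <- as.numeric(unlist(r_grid))
    if (length(r_grid) == 0L) r_grid <- NULL
    else if (any(r_grid <= 0) || is.unsorted(r_grid, strictly = TRUE))
      stop("'r_grid' must be strictly increasing and positive", call. = FALSE)
  }
  structure(list(kind = kind, n_grid = n_grid, r_grid = r_grid,
                 jitter = jitter, period = period),
            class = "kernel_control")
}

# ---- internal kernel cache -------------------------------------------------
#
# Coordinates are rescaled so the median nearest-neighbour distance is 1
# (recorded in `scale` so selected length scales can be reported in original
# units).  For each grid candidate the cache lazily stores the symmetric
# eigendecomposition of the covariance; eigenvalues are clamped at zero and
# the jitter added analytically, which makes log-determinants, quadratic
# forms, solves and inverse diagonals cheap and exactly consistent with each
# other.

kernel_cache <- function(coords, kernel = kernel_control(),
                         keep_inverse = FALSE) {
  coords <- as.matrix(coords)
  d <- pairwise_distances(coords)
  off <- d; diag(off) <- Inf
  nn <- apply(off, 1L, min)
  scale <- stats::median(nn)
  if (scale == 0) {
    # duplicate coordinates: jitter them by a tiny fraction of the smallest
    # positive spacing so the geometry is non-degenerate
    pos <- nn[nn > 0]
    if (!length(pos))
      stop("degenerate geometry: all coordinates identical", call. = FALSE)
    eps <- 1e-9 * stats::median(pos)
    k <- seq_len(length(coords))
    coords <- coords + eps * matrix((k * 37 %% 101) / 101 - 0.5, nrow(coords))
    d <- pairwise_distances(coords)
    off <- d; diag(off) <- Inf
    nn <- apply(off, 1L, min)
    scale <- stats::median(nn)
  }
  ds <- d / scale
  if (is.null(kernel$r_grid)) {
    dmax <- max(ds)
    l <- if (kernel$n_grid == 1L) sqrt(dmax)
         else exp(seq(log(1), log(dmax), length.out = kernel$n_grid))
    r_grid <- sort(1 / l^2)
  } else r_grid <- kernel$r_grid
  env <- new.env(parent = emptyenv())
  env$d2h <- 0.5 * ds^2            # precomputed d^2/2 in rescaled units
  env$sinpd <- NULL
  if (kernel$kind == "periodic")
    env$sinpd <- 2 * sin(pi * ds / kernel$period)^2
  env$kind <- kernel$kind
  env$r_grid <- r_grid
  env$jitter <- kernel$jitter
  env$scale <- scale
  env$S <- nrow(ds)
  env$keep_inverse <- keep_inverse
  env$entries <- vector("list", length(r_grid))
  env
}

# Eigendecomposition entry for grid candidate i:
#   Q, ej (eigenvalues + jitter), logdet, dinv (diag of inverse),
#   optionally inv (full inverse, small-S exact path).
kernel_entry <- function(cache, i) {
  ent <- cache$entries[[i]]
  if (!is.null(ent)) return(ent)
  r <- cache$r_grid[i]
  sig <- if (cache$kind == "periodic") exp(-cache$sinpd * r)
         else exp(-cache$d2h * r)
  diag(sig) <- 1
  ee <- eigen(sig, symmetric = TRUE)
  ej <- pmax(ee$values, 0) + cache$jitter
  if (any(ej <= 0))
    stop("kernel covariance is singular and jitter is 0; increase 'jitter'",
         call. = FALSE)
  Q <- ee$vectors
  dinv <- as.vector(Q^2 %*% (1 / ej))
  ent <- list(Q = Q, ej = ej, logdet = sum(log(ej)), dinv = dinv, r = r)
  if (cache$keep_inverse)
    ent$inv <- Q %*% (t(Q) / ej)
  cache$entries[[i]] <- ent
  ent
}

# Sigma^{-1} %*% v for candidate i.
kernel_solve <- function(cache, i, v) {
  ent <- kernel_entry(cache, i)
  ent$Q %*% (crossprod(ent$Q, v) / ent$ej)
}

# t(mu) %*% Sigma^{-1} %*% mu.
kernel_quad <- function(cache, i, mu) {
  ent <- kernel_entry(cache, i)
  sum(crossprod(ent$Q, mu)^2 / ent$ej)
}
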