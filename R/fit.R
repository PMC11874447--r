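#' Prior hyperparameters
#'
#' Hyperparameters of the generative model.  All Gamma priors are given as
#' `c(shape, rate)`, Beta priors as `c(shape1, shape2)`.  Defaults are
#' weakly informative (`Gamma(1e-3, 1e-3)`) for the precisions/scales and
#' uniform (`Beta(1, 1)`) for the inclusion weights, keeping inference
#' data-driven.
#'
#' @param noise Gamma prior of the per-spot noise precision.
#' @param map_scale Gamma prior of the per-module spatial-map scale (the
#'   precision multiplier of the Gaussian-process prior).
#' @param decay Gamma prior of the per-module SE decay rate, applied as a
#'   log-prior penalty on the candidate grid (rescaled coordinate units).
#' @param loading_prec Gamma prior of the per-module slab precision of the
#'   gene loadings.
#' @param slab_weight Beta prior of the per-gene slab weight.
#' @param module_sparsity Beta prior of the per-module inclusion rate.
#' @return A list of class `"tismod_prior"`.
#' @export
tismod_prior <- function(noise = c(1e-3, 1e-3), map_scale = c(1e-3, 1e-3),
                         decay = c(1e-3, 1e-3), loading_prec = c(1e-3, 1e-3),
                         slab_weight = c(1, 1), module_sparsity = c(1, 1)) {
  pr <- list(noise = noise, map_scale = map_scale, decay = decay,
             loading_prec = loading_prec, slab_weight = slab_weight,
             module_sparsity = module_sparsity)
  for (nm in names(pr)) {
    p <- pr[[nm]]
    if (length(p) != 2L || any(!is.finite(p)) || any(p <= 0))
      stop("prior '", nm, "' must be two positive numbers", call. = FALSE)
  }
  structure(pr, class = "tismod_prior")
}

#' Fitting controls
#'
#' @param max_iter maximum number of coordinate-ascent rounds.
#' @param tol relative ELBO change below which the fit is declared
#'   converged.
#' @param diverge_slack relative slack for the ELBO monotonicity check; an
#'   ELBO drop beyond the slack for 3 consecutive rounds aborts the fit.
#' @param full_cov_threshold spot count up to which the exact per-module
#'   posterior covariance of the spatial maps is maintained; above it a
#'   diagonal variational covariance is used (the posterior mean still uses
#'   the full spatial prior).
#' @param cg_tol,cg_maxit tolerance and iteration cap of the conjugate
#'   gradient solver used for the map means in diagonal mode.
#' @param verbose print the ELBO each round.
#' @return A list of class `"tismod_control"`.
#' @export
tismod_control <- function(max_iter = 500, tol = 1e-5, diverge_slack = 1e-6,
                           full_cov_threshold = 1000, cg_tol = 1e-10,
                           cg_maxit = 500, verbose = FALSE) {
  stopifnot(max_iter >= 1, tol > 0, diverge_slack >= 0,
            full_cov_threshold >= 0, cg_tol > 0, cg_maxit >= 1)
  structure(list(max_iter = max_iter, tol = tol,
                 diverge_slack = diverge_slack,
                 full_cov_threshold = full_cov_threshold,
                 cg_tol = cg_tol, cg_maxit = cg_maxit, verbose = verbose),
            class = "tismod_control")
}

# ---- variational state -----------------------------------------------------
#
# All variational factors of the mean-field posterior
#   Q = q(P) * prod_cl q(omega, s, phi) * prod_cl q(psi) * prod_c q(rho)
#       * prod_s q(lambda) * prod_c q(sigma) * prod_c q(beta)
# with the per-module decay rate point-estimated on the candidate grid.
# (omega, s, phi) is one joint factor over the three reachable states
# (s=1,phi=1), (s=0,phi=1), (s=0,phi=0): this avoids the degenerate
# expectations of a fully factorized spike-and-slab and gives the PIP as the
# weight of the slab state.

state_expectations <- function(st) {
  list(
    Elam = st$lam_a / st$lam_b,
    Eloglam = digamma(st$lam_a) - log(st$lam_b),
    Esig = st$sig_a / st$sig_b,
    Elogsig = digamma(st$sig_a) - log(st$sig_b),
    Ebet = st$bet_a / st$bet_b,
    Elogbet = digamma(st$bet_a) - log(st$bet_b),
    Elogpsi = digamma(st$psi_a) - digamma(st$psi_a + st$psi_b),
    Elog1mpsi = digamma(st$psi_b) - digamma(st$psi_a + st$psi_b),
    Elogrho = digamma(st$rho_a) - digamma(st$rho_a + st$rho_b),
    Elog1mrho = digamma(st$rho_b) - digamma(st$rho_a + st$rho_b)
  )
}

# E[G], E[G^2], E[omega^2] given the joint (omega, s, phi) factor.
loading_moments <- function(st) {
  EG <- st$w11 * st$m_om
  EG2 <- st$w11 * (st$m_om^2 + st$v_om)
  Eom2 <- EG2 + (1 - st$w11) * st$v0
  list(EG = EG, EG2 = EG2, Eom2 = Eom2)
}

init_state <- function(Yc, coords, C, prior, cache, control,
                       init = c("svd", "random"), seed = 1L) {
  init <- match.arg(init)
  S <- nrow(Yc); L <- ncol(Yc)
  if (C < 1L) stop("'C' must be at least 1", call. = FALSE)
  if (C > min(S, L))
    stop(sprintf("C = %d exceeds min(spots, genes) = %d", C, min(S, L)),
         call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (init == "svd") {
    sv <- svd(Yc, nu = C, nv = C)
    d <- sv$d[seq_len(C)]
    d[d < 1e-12] <- 1e-12
    U <- sv$u; V <- sv$v
    for (c in seq_len(C)) {           # fix the sign indeterminacy
      s <- sign(U[which.max(abs(U[, c])), c])
      if (s == 0) s <- 1
      U[, c] <- U[, c] * s; V[, c] <- V[, c] * s
    }
    mu_P <- U %*% diag(sqrt(d), C)
    m_om <- t(V %*% diag(sqrt(d), C))
  } else {
    mu_P <- matrix(stats::rnorm(S * C), S, C)
    m_om <- matrix(0, C, L)
  }
  pr <- prior
  st <- list(
    C = C, S = S, L = L,
    mu_P = mu_P, vdiag = matrix(1e-4, S, C), Vfull = NULL,
    m_om = m_om,
    v_om = matrix(pr$loading_prec[2] / pr$loading_prec[1], C, L),
    w11 = matrix(0.5, C, L), w01 = matrix(0.25, C, L),
    w00 = matrix(0.25, C, L),
    v0 = rep(pr$loading_prec[2] / pr$loading_prec[1], C),
    psi_a = matrix(pr$slab_weight[1], C, L),
    psi_b = matrix(pr$slab_weight[2], C, L),
    rho_a = rep(pr$module_sparsity[1], C),
    rho_b = rep(pr$module_sparsity[2], C),
    lam_a = rep(pr$noise[1], S), lam_b = rep(pr$noise[2], S),
    sig_a = rep(pr$map_scale[1], C), sig_b = rep(pr$map_scale[2], C),
    bet_a = rep(pr$loading_prec[1], C), bet_b = rep(pr$loading_prec[2], C),
    r_idx = rep(as.integer(ceiling(length(cache$r_grid) / 2)), C),
    full_cov = S <= control$full_cov_threshold
  )
  if (st$full_cov)
    st$Vfull <- replicate(C, NULL, simplify = FALSE)
  st
}

# Preconditioned conjugate gradient for (esig * Sigma^{-1} + diag(Dc)) x = h.
# Preconditioner: (esig * Sigma^{-1} + mean(Dc) I)^{-1}, exact in the
# eigenbasis of Sigma.
cg_solve <- function(cache, i, esig, Dc, h, x0, tol, maxit) {
  ent <- kernel_entry(cache, i)
  Q <- ent$Q; ej <- ent$ej
  dbar <- mean(Dc)
  pre <- 1 / (esig / ej + dbar)
  Amul <- function(x) esig * (Q %*% (crossprod(Q, x) / ej)) + Dc * x
  hn <- sqrt(sum(h^2))
  if (hn == 0) return(list(x = h * 0, iters = 0L))
  x <- x0
  rr <- h - Amul(x)
  z <- Q %*% (crossprod(Q, rr) * pre)
  p <- z
  rz <- sum(rr * z)
  for (it in seq_len(maxit)) {
    Ap <- Amul(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    rr <- rr - alpha * Ap
    if (sqrt(sum(rr^2)) <= tol * hn) return(list(x = x, iters = it))
    z <- Q %*% (crossprod(Q, rr) * pre)
    rz_new <- sum(rr * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iters = maxit)
}

# One full coordinate-ascent round.  Update order: loadings (joint
# omega/s/phi per module) -> sparsity hierarchy (psi, rho) -> maps ->
# noise/scale/precision (lambda, sigma, beta) -> decay rate.
# With fix_loadings = TRUE (transfer) only maps, lambda, sigma and the decay
# rate are updated and the loadings are the fixed point values in st$m_om
# with w11 = 1, v_om = 0.  With fix_sparsity = TRUE the slab means/variances
# are updated but the state weights (and psi, rho) are left untouched.
cavi_round <- function(st, Yc, cache, prior, control,
                       fix_loadings = FALSE, fix_sparsity = FALSE) {
  ex <- state_expectations(st)
  lm <- loading_moments(st)
  EG <- lm$EG; EG2 <- lm$EG2
  C <- st$C; S <- st$S; L <- st$L
  Yhat <- st$mu_P %*% EG

  if (!fix_loadings) {
    for (c in seq_len(C)) {
      Rc <- Yc - Yhat + tcrossprod(st$mu_P[, c], EG[c, ])
      EP2c <- st$mu_P[, c]^2 + st$vdiag[, c]
      tau <- ex$Ebet[c] + sum(ex$Elam * EP2c)
      b <- as.vector(crossprod(Rc, ex$Elam * st$mu_P[, c]))
      st$m_om[c, ] <- b / tau
      st$v_om[c, ] <- 1 / tau
      st$v0[c] <- 1 / ex$Ebet[c]
      if (!fix_sparsity) {
        e1 <- 0.5 * ex$Elogbet[c] - 0.5 * log(tau) + b^2 / (2 * tau)
        e0 <- 0.5 * ex$Elogbet[c] + 0.5 * log(st$v0[c])
        l11 <- ex$Elogpsi[c, ] + ex$Elogrho[c] + e1
        l01 <- ex$Elog1mpsi[c, ] + ex$Elogrho[c] + e0
        l00 <- ex$Elog1mrho[c] + e0
        mx <- pmax(l11, l01, l00)
        a11 <- exp(l11 - mx); a01 <- exp(l01 - mx); a00 <- exp(l00 - mx)
        tot <- a11 + a01 + a00
        st$w11[c, ] <- a11 / tot
        st$w01[c, ] <- a01 / tot
        st$w00[c, ] <- a00 / tot
      }
      EGc_new <- st$w11[c, ] * st$m_om[c, ]
      Yhat <- Yhat + tcrossprod(st$mu_P[, c], EGc_new - EG[c, ])
      EG[c, ] <- EGc_new
      EG2[c, ] <- st$w11[c, ] * (st$m_om[c, ]^2 + st$v_om[c, ])
    }
    if (!fix_sparsity) {
      st$psi_a <- prior$slab_weight[1] + st$w11
      st$psi_b <- prior$slab_weight[2] + st$w01
      eta <- st$w11 + st$w01
      st$rho_a <- prior$module_sparsity[1] + rowSums(eta)
      st$rho_b <- prior$module_sparsity[2] + rowSums(1 - eta)
    }
  }

  for (c in seq_len(C)) {
    Rc <- Yc - Yhat + tcrossprod(st$mu_P[, c], EG[c, ])
    g2 <- sum(EG2[c, ])
    Dc <- ex$Elam * g2
    hvec <- ex$Elam * as.vector(Rc %*% EG[c, ])
    esig <- ex$Esig[c]
    i <- st$r_idx[c]
    ent <- kernel_entry(cache, i)
    if (st$full_cov) {
      Lam <- esig * ent$inv
      diag(Lam) <- diag(Lam) + Dc
      V <- chol2inv(chol(Lam))
      mu_new <- as.vector(V %*% hvec)
      st$Vfull[[c]] <- V
      st$vdiag[, c] <- diag(V)
    } else {
      st$vdiag[, c] <- 1 / (esig * ent$dinv + Dc)
      mu_new <- as.vector(cg_solve(cache, i, esig, Dc, hvec,
                                   x0 = st$mu_P[, c], tol = control$cg_tol,
                                   maxit = control$cg_maxit)$x)
    }
    Yhat <- Yhat + tcrossprod(mu_new - st$mu_P[, c], EG[c, ])
    st$mu_P[, c] <- mu_new
  }

  # noise precision
  g2vec <- rowSums(EG2)
  qvec <- rowSums(EG2 - EG^2)
  sse <- rowSums((Yc - Yhat)^2) + as.vector(st$vdiag %*% g2vec) +
    as.vector(st$mu_P^2 %*% qvec)
  st$lam_a <- rep(prior$noise[1] + L / 2, S)
  st$lam_b <- prior$noise[2] + 0.5 * sse
  if (any(!is.finite(st$lam_b)))
    stop("non-finite value in the noise-precision update", call. = FALSE)

  # map scale and decay rate (grid neighbourhood ascent), then slab precision
  for (c in seq_len(C)) {
    i <- st$r_idx[c]
    tr_fun <- function(j) {
      entj <- kernel_entry(cache, j)
      if (st$full_cov && !is.null(st$Vfull[[c]]))
        sum(entj$inv * st$Vfull[[c]])
      else sum(entj$dinv * st$vdiag[, c])
    }
    quad_i <- kernel_quad(cache, i, st$mu_P[, c])
    st$sig_a[c] <- prior$map_scale[1] + st$S / 2
    st$sig_b[c] <- prior$map_scale[2] + 0.5 * (quad_i + tr_fun(i))
    esig <- st$sig_a[c] / st$sig_b[c]
    cand <- unique(pmin(pmax(c(i, i - 1L, i + 1L), 1L),
                        length(cache$r_grid)))
    obj <- vapply(cand, function(j) {
      entj <- kernel_entry(cache, j)
      r <- cache$r_grid[j]
      -0.5 * entj$logdet -
        0.5 * esig * (kernel_quad(cache, j, st$mu_P[, c]) + tr_fun(j)) +
        (prior$decay[1] - 1) * log(r) - prior$decay[2] * r
    }, numeric(1))
    best <- cand[which.max(obj)]
    st$r_idx[c] <- best
  }

  if (!fix_loadings) {
    Eom2 <- EG2 + (1 - st$w11) * st$v0
    st$bet_a <- rep(prior$loading_prec[1] + L / 2, C)
    st$bet_b <- prior$loading_prec[2] + 0.5 * rowSums(Eom2)
  }
  st
}

gamma_entropy <- function(shape, rate)
  shape - log(rate) + lgamma(shape) + (1 - shape) * digamma(shape)

beta_entropy <- function(a, b)
  lbeta(a, b) - (a - 1) * digamma(a) - (b - 1) * digamma(b) +
  (a + b - 2) * digamma(a + b)

xlogx <- function(w) ifelse(w > 0, w * log(w), 0)

# Evidence lower bound of the current state; returns the total with the
# per-term decomposition as an attribute.
elbo_state <- function(st, Yc, cache, prior, fix_loadings = FALSE) {
  ex <- state_expectations(st)
  lm <- loading_moments(st)
  EG <- lm$EG; EG2 <- lm$EG2
  C <- st$C; S <- st$S; L <- st$L
  l2p <- log(2 * pi)
  Yhat <- st$mu_P %*% EG
  g2vec <- rowSums(EG2)
  qvec <- rowSums(EG2 - EG^2)
  sse <- rowSums((Yc - Yhat)^2) + as.vector(st$vdiag %*% g2vec) +
    as.vector(st$mu_P^2 %*% qvec)

  terms <- c(likelihood = sum(L / 2 * (ex$Eloglam - l2p)) -
               0.5 * sum(ex$Elam * sse))

  lp_P <- 0; H_P <- 0; lp_r <- 0
  for (c in seq_len(C)) {
    ent <- kernel_entry(cache, st$r_idx[c])
    quad <- kernel_quad(cache, st$r_idx[c], st$mu_P[, c])
    tr <- if (st$full_cov && !is.null(st$Vfull[[c]]))
            sum(ent$inv * st$Vfull[[c]])
          else sum(ent$dinv * st$vdiag[, c])
    lp_P <- lp_P - S / 2 * l2p + S / 2 * ex$Elogsig[c] - 0.5 * ent$logdet -
      0.5 * ex$Esig[c] * (quad + tr)
    H_P <- H_P + S / 2 * (1 + l2p) +
      if (st$full_cov && !is.null(st$Vfull[[c]]))
        sum(log(diag(chol(st$Vfull[[c]]))))
      else 0.5 * sum(log(st$vdiag[, c]))
    r <- cache$r_grid[st$r_idx[c]]
    lp_r <- lp_r + prior$decay[1] * log(prior$decay[2]) -
      lgamma(prior$decay[1]) + (prior$decay[1] - 1) * log(r) -
      prior$decay[2] * r
  }
  terms["map_prior"] <- lp_P
  terms["map_entropy"] <- H_P
  terms["decay_prior"] <- lp_r

  if (!fix_loadings) {
    Eom2 <- lm$Eom2
    terms["loading_prior"] <-
      sum(0.5 * (ex$Elogbet - l2p) * L - 0.5 * ex$Ebet * rowSums(Eom2))
    terms["inclusion_prior"] <- sum(
      st$w11 * (ex$Elogpsi + ex$Elogrho) +
      st$w01 * (ex$Elog1mpsi + ex$Elogrho) +
      st$w00 * ex$Elog1mrho)
    terms["loading_entropy"] <- sum(
      -xlogx(st$w11) - xlogx(st$w01) - xlogx(st$w00) +
      st$w11 * 0.5 * log(2 * pi * exp(1) * st$v_om) +
      (1 - st$w11) * 0.5 * log(2 * pi * exp(1) * st$v0))
    g <- prior$slab_weight
    terms["slab_weight"] <- sum((g[1] - 1) * ex$Elogpsi +
                                (g[2] - 1) * ex$Elog1mpsi - lbeta(g[1], g[2])) +
      sum(beta_entropy(st$psi_a, st$psi_b))
    tz <- prior$module_sparsity
    terms["module_sparsity"] <- sum((tz[1] - 1) * ex$Elogrho +
                                    (tz[2] - 1) * ex$Elog1mrho -
                                    lbeta(tz[1], tz[2])) +
      sum(beta_entropy(st$rho_a, st$rho_b))
    e <- prior$loading_prec
    terms["loading_prec"] <- sum(e[1] * log(e[2]) - lgamma(e[1]) +
                                 (e[1] - 1) * ex$Elogbet - e[2] * ex$Ebet) +
      sum(gamma_entropy(st$bet_a, st$bet_b))
  }
  u <- prior$noise
  terms["noise"] <- sum(u[1] * log(u[2]) - lgamma(u[1]) +
                        (u[1] - 1) * ex$Eloglam - u[2] * ex$Elam) +
    sum(gamma_entropy(st$lam_a, st$lam_b))
  m <- prior$map_scale
  terms["map_scale"] <- sum(m[1] * log(m[2]) - lgamma(m[1]) +
                            (m[1] - 1) * ex$Elogsig - m[2] * ex$Esig) +
    sum(gamma_entropy(st$sig_a, st$sig_b))

  total <- sum(terms)
  if (!is.finite(total))
    stop("non-finite ELBO; offending term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "),
         call. = FALSE)
  attr(total, "terms") <- terms
  total
}

#' Fit tissue modules to a spatial expression profile
#'
#' Factorizes a normalized spots-by-genes expression matrix into `C` tissue
#' modules.  Each module consists of a spatial activity map over the spots,
#' drawn a priori from a zero-mean Gaussian process with squared-exponential
#' covariance (per-module scale and length scale), and a sparse vector of
#' gene loadings under a spike-and-slab prior.  The posterior is
#' approximated by mean-field coordinate-ascent variational inference; the
#' per-module decay rate is point-estimated by ascent on a geometric
#' candidate grid.  Genes are centred to mean zero before fitting (the
#' spatial maps carry zero-mean priors); the per-gene centres are stored in
#' the fit.
#'
#' Gene membership in a module is read off the posterior inclusion
#' probability (PIP): gene `l` belongs to module `c` when `pip[c, l] > 0.5`.
#' Modules whose loading vectors are numerically zero (no gene with
#' PIP > 0.5) are flagged inactive, so a generous `C` is safe: surplus
#' modules empty out.
#'
#' @param profile a normalized `stm_profile` (see [normalize_profile()]),
#'   usually restricted to highly variable genes.
#' @param C number of modules (default 10, enough to reveal the major
#'   expression components of a section).
#' @param prior a [tismod_prior()].
#' @param kernel a [kernel_control()].
#' @param control a [tismod_control()].
#' @param init `"svd"` (deterministic, default) or `"random"`.
#' @param seed integer seed (used by random initialization; recorded in the
#'   fit).
#' @param kernels optional precomputed kernel cache from
#'   [tismod_kernels()]; lets repeated fits on the same coordinates share
#'   the spectral decompositions of the candidate covariances.
#' @param keep_data keep the normalized expression matrix inside the fit
#'   (needed by `residuals()` and [simulate.tismod()]).
#' @return An object of class `"tismod"` with components `loadings` (C x L,
#'   posterior mean loadings), `pip` (C x L posterior inclusion
#'   probabilities), `maps` (S x C posterior mean spatial maps, unscaled),
#'   `map_var` (S x C posterior variances), `r_hat` (selected decay rates,
#'   rescaled units), `length_scales` (selected length scales in original
#'   coordinate units), `active` (logical per module), `elbo` (trace, first
#'   element at initialization), `converged`, `n_iter`, `centers`,
#'   `gene_names`, `spot_ids`, `coords`, and the settings used.
#' @examples
#' sim <- simulate_scenario(1, n_genes = 60, grid_size = 8, set_size = 15,
#'                          seed = 7)
#' fit <- tismod(sim$profile, C = 2, seed = 7)
#' fit
#' table(gene_membership(fit)[1, ])
#' @export
tismod <- function(profile, C = 10, prior = tismod_prior(),
                   kernel = kernel_control(), control = tismod_control(),
                   init = c("svd", "random"), seed = 1L, kernels = NULL,
                   keep_data = TRUE) {
  stopifnot(inherits(profile, "stm_profile"))
  if (!profile$is_normalized)
    stop("tismod() expects a normalized profile; see normalize_profile()",
         call. = FALSE)
  init <- match.arg(init)
  Y <- profile$values
  vars <- apply(Y, 2L, stats::var)
  if (any(vars == 0)) {
    warning("dropping ", sum(vars == 0),
            " gene(s) with zero variance before fitting", call. = FALSE)
    profile <- subset_profile(profile, genes = which(vars > 0))
    Y <- profile$values
  }
  centers <- colMeans(Y)
  Yc <- sweep(Y, 2L, centers, "-")
  S <- nrow(Yc); L <- ncol(Yc)
  cache <- if (is.null(kernels))
    kernel_cache(profile$coords, kernel,
                 keep_inverse = S <= control$full_cov_threshold)
  else kernels
  if (cache$S != S)
    stop("precomputed kernels were built for a different spot set",
         call. = FALSE)
  if ((S <= control$full_cov_threshold) && !cache$keep_inverse)
    stop("precomputed kernels lack full inverses needed below ",
         "'full_cov_threshold'; rebuild with tismod_kernels(..., ",
         "full_cov = TRUE)", call. = FALSE)

  st <- init_state(Yc, profile$coords, C, prior, cache, control, init, seed)
  trace <- elbo_state(st, Yc, cache, prior)
  el_prev <- trace[1L]
  drops <- 0L
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    st <- cavi_round(st, Yc, cache, prior, control)
    el <- as.numeric(elbo_state(st, Yc, cache, prior))
    trace <- c(trace, el)
    if (control$verbose)
      message(sprintf("round %3d  elbo %.6f", it, el))
    if (el < el_prev - control$diverge_slack * abs(el_prev)) {
      drops <- drops + 1L
      if (drops >= 3L) {
        err <- simpleError("ELBO decreased for 3 consecutive rounds")
        err$elbo_trace <- as.numeric(trace)
        stop(err)
      }
    } else drops <- 0L
    if (it > 1L && abs(el - el_prev) <= control$tol * abs(el_prev)) {
      converged <- TRUE
      el_prev <- el
      break
    }
    el_prev <- el
  }

  lmom <- loading_moments(st)
  pip <- st$w11
  active <- apply(pip > 0.5, 1L, any)
  mods <- paste0("module", seq_len(C))
  dimnames(lmom$EG) <- list(mods, profile$gene_names)
  dimnames(pip) <- list(mods, profile$gene_names)
  dimnames(st$mu_P) <- list(profile$spot_ids, mods)
  r_hat <- cache$r_grid[st$r_idx]
  structure(list(
    loadings = lmom$EG, pip = pip, maps = st$mu_P, map_var = st$vdiag,
    r_hat = r_hat, length_scales = cache$scale / sqrt(r_hat),
    active = active, elbo = as.numeric(trace), converged = converged,
    n_iter = length(trace) - 1L, centers = centers,
    gene_names = profile$gene_names, spot_ids = profile$spot_ids,
    coords = profile$coords, platform = profile$platform,
    C = C, prior = prior, kernel = kernel, control = control,
    init = init, seed = seed, scale = cache$scale, r_grid = cache$r_grid,
    y = if (keep_data) Y else NULL,
    state = st, call = match.call()), class = "tismod")
}

#' Precompute kernel decompositions
#'
#' Builds the candidate covariance decompositions for a fixed set of
#' coordinates once, so that several [tismod()] or [transfer()] calls on the
#' same geometry (e.g. simulation replicates) can share them.
#'
#' @param coords spot coordinates (S x 2).
#' @param kernel a [kernel_control()].
#' @param full_cov keep full inverses (needed when S is at or below
#'   `full_cov_threshold` of the fitting controls).
#' @return An opaque kernel cache object.
#' @export
tismod_kernels <- function(coords, kernel = kernel_control(),
                           full_cov = FALSE) {
  kernel_cache(as.matrix(coords), kernel, keep_inverse = full_cov)
}
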