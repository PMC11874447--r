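#' Transfer fitted tissue modules to another section
#'
#' Re-estimates spatial maps on a new tissue section while holding the gene
#' loadings fixed at their posterior means from a previous fit.  The new
#' profile is restricted to the genes of the source fit (genes absent from
#' the new section are dropped from both sides with a warning; the overlap
#' must reach at least `min_overlap` of the source genes).  The per-spot
#' noise, per-module map scale and decay rate are re-inferred for the new
#' section by the same coordinate-ascent updates.
#'
#' @param object a fitted [tismod()] model.
#' @param profile_b a normalized `stm_profile` for the new section.
#' @param control a [tismod_control()]; defaults to the controls of the
#'   source fit.
#' @param min_overlap minimum fraction of source genes that must be present
#'   in the new section.
#' @param kernels optional precomputed kernel cache for the new coordinates
#'   (see [tismod_kernels()]).
#' @return An object of class `"tismod_transfer"` with `maps` (S_B x C),
#'   `map_var`, `r_hat`, `length_scales`, `elbo`, `converged`,
#'   `overlap_fraction`, `genes` and the new section's `spot_ids`/`coords`.
#' @export
transfer <- function(object, profile_b, control = object$control,
                     min_overlap = 0.5, kernels = NULL) {
  stopifnot(inherits(object, "tismod"), inherits(profile_b, "stm_profile"))
  if (!profile_b$is_normalized)
    stop("transfer() expects a normalized profile", call. = FALSE)
  common <- intersect(object$gene_names, profile_b$gene_names)
  frac <- length(common) / length(object$gene_names)
  if (frac < min_overlap)
    stop(sprintf(paste0("gene overlap with the source fit is %.1f%%, below ",
                        "the %.0f%% required for transfer"),
         100 * frac, 100 * min_overlap), call. = FALSE)
  if (frac < 1)
    warning(sprintf("%d source gene(s) absent from the new section dropped",
                    length(object$gene_names) - length(common)),
            call. = FALSE)
  G <- object$loadings[, common, drop = FALSE]
  Yb <- profile_b$values[, match(common, profile_b$gene_names), drop = FALSE]
  centers <- colMeans(Yb)
  Yc <- sweep(Yb, 2L, centers, "-")
  S <- nrow(Yc); L <- ncol(Yc); C <- object$C
  cache <- if (is.null(kernels))
    kernel_cache(profile_b$coords, object$kernel,
                 keep_inverse = S <= control$full_cov_threshold)
  else kernels
  if (cache$S != S)
    stop("precomputed kernels were built for a different spot set",
         call. = FALSE)

  prior <- object$prior
  st <- list(
    C = C, S = S, L = L,
    mu_P = matrix(0, S, C), vdiag = matrix(1e-4, S, C), Vfull = NULL,
    m_om = unname(G), v_om = matrix(0, C, L),
    w11 = matrix(1, C, L), w01 = matrix(0, C, L), w00 = matrix(0, C, L),
    v0 = rep(0, C),
    psi_a = matrix(1, C, L), psi_b = matrix(1, C, L),
    rho_a = rep(1, C), rho_b = rep(1, C),
    lam_a = rep(prior$noise[1], S), lam_b = rep(prior$noise[2], S),
    sig_a = rep(prior$map_scale[1], C), sig_b = rep(prior$map_scale[2], C),
    bet_a = rep(prior$loading_prec[1], C),
    bet_b = rep(prior$loading_prec[2], C),
    r_idx = rep(as.integer(ceiling(length(cache$r_grid) / 2)), C),
    full_cov = S <= control$full_cov_threshold
  )
  if (st$full_cov) st$Vfull <- replicate(C, NULL, simplify = FALSE)

  trace <- as.numeric(elbo_state(st, Yc, cache, prior, fix_loadings = TRUE))
  el_prev <- trace[1L]
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    st <- cavi_round(st, Yc, cache, prior, control, fix_loadings = TRUE)
    el <- as.numeric(elbo_state(st, Yc, cache, prior, fix_loadings = TRUE))
    trace <- c(trace, el)
    if (it > 1L && abs(el - el_prev) <= control$tol * abs(el_prev)) {
      converged <- TRUE
      break
    }
    el_prev <- el
  }
  maps <- st$mu_P
  dimnames(maps) <- list(profile_b$spot_ids, rownames(object$loadings))
  r_hat <- cache$r_grid[st$r_idx]
  structure(list(maps = maps, map_var = st$vdiag, r_hat = r_hat,
                 length_scales = cache$scale / sqrt(r_hat),
                 elbo = trace, converged = converged, n_iter = it,
                 overlap_fraction = frac, genes = common,
                 spot_ids = profile_b$spot_ids, coords = profile_b$coords),
            class = "tismod_transfer")
}

#' @export
print.tismod_transfer <- function(x, ...) {
  cat(sprintf(paste0("Tissue-module transfer: %d spots x %d modules ",
                     "(gene overlap %.1f%%, %s)\n"),
              nrow(x$maps), ncol(x$maps), 100 * x$overlap_fraction,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
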