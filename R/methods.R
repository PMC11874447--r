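#' @export
print.tismod <- function(x, ...) {
  cat(sprintf("Tissue-module factorization: %d spots x %d genes, C = %d\n",
              nrow(x$maps), ncol(x$loadings), x$C))
  cat(sprintf("  active modules: %d of %d; %s after %d rounds (ELBO %.2f)\n",
              sum(x$active), x$C,
              if (x$converged) "converged" else "stopped", x$n_iter,
              x$elbo[length(x$elbo)]))
  invisible(x)
}

#' Summarize a tissue-module fit
#'
#' @param object a fitted [tismod()] model.
#' @param ... unused.
#' @return A `summary.tismod` object whose `modules` component tabulates,
#'   per module: activity flag, number of member genes (PIP > 0.5), selected
#'   length scale (original coordinate units) and the standard deviation of
#'   the spatial map.
#' @export
summary.tismod <- function(object, ...) {
  members <- rowSums(object$pip > 0.5)
  tab <- data.frame(
    module = rownames(object$loadings),
    active = object$active,
    n_genes = members,
    length_scale = object$length_scales,
    map_sd = apply(object$maps, 2L, stats::sd))
  structure(list(modules = tab, C = object$C, n_iter = object$n_iter,
                 converged = object$converged,
                 elbo = object$elbo[length(object$elbo)]),
            class = "summary.tismod")
}

#' @export
print.summary.tismod <- function(x, ...) {
  cat(sprintf("Tissue-module fit with C = %d (%s, %d rounds, ELBO %.2f)\n\n",
              x$C, if (x$converged) "converged" else "not converged",
              x$n_iter, x$elbo))
  print(x$modules, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.tismod <- function(object, ...) object$loadings

#' @export
fitted.tismod <- function(object, ...) {
  fit <- object$maps %*% object$loadings
  sweep(fit, 2L, object$centers, "+")
}

#' @export
residuals.tismod <- function(object, ...) {
  if (is.null(object$y))
    stop("fit was made with keep_data = FALSE; residuals unavailable",
         call. = FALSE)
  object$y - fitted(object)
}

#' Predict spatial maps, optionally on a new section
#'
#' Without `newdata`, returns the fitted spatial maps.  With a normalized
#' `stm_profile` as `newdata`, runs [transfer()] (fixed loadings) and
#' returns the inferred maps for the new section.
#'
#' @param object a fitted [tismod()] model.
#' @param newdata optional normalized `stm_profile` of another section.
#' @param ... passed on to [transfer()].
#' @return An S x C matrix of spatial-map posterior means.
#' @export
predict.tismod <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$maps)
  transfer(object, newdata, ...)$maps
}

#' Simulate expression from a fitted model
#'
#' Draws spots-by-genes matrices from the fitted generative model: posterior
#' mean reconstruction plus Gaussian noise at the posterior mean per-spot
#' precision.
#'
#' @param object a fitted [tismod()] model.
#' @param nsim number of matrices to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` matrices.
#' @export
simulate.tismod <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mean_fit <- fitted(object)
  sds <- sqrt(object$state$lam_b / object$state$lam_a)
  lapply(seq_len(nsim), function(i)
    mean_fit + matrix(stats::rnorm(length(mean_fit)), nrow(mean_fit)) * sds)
}

#' Plot spatial maps of a fit
#'
#' Draws the (scaled) spatial activity maps of the selected modules as
#' coloured spot scatters in array coordinates.
#'
#' @param x a fitted [tismod()] model.
#' @param modules which modules to draw (default: the active ones, or all
#'   if none is active).
#' @param mode scaling handed to [scale_map()].
#' @param cex point size.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tismod <- function(x, modules = NULL,
                        mode = c("zscore", "signed_log"), cex = 1, ...) {
  mode <- match.arg(mode)
  if (is.null(modules))
    modules <- if (any(x$active)) which(x$active) else seq_len(x$C)
  n <- length(modules)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  for (m in modules) {
    v <- tryCatch(scale_map(x$maps[, m], mode), error = function(e) NULL)
    if (is.null(v)) v <- x$maps[, m]
    idx <- pmin(64L, pmax(1L, as.integer(
      1 + 63 * (v - min(v)) / max(1e-12, diff(range(v))))))
    graphics::plot(x$coords[, 1L], x$coords[, 2L], col = pal[idx],
                   pch = 16, cex = cex, asp = 1, xlab = "", ylab = "",
                   main = colnames(x$maps)[m], ...)
  }
  invisible(x)
}
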