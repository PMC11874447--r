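#' Gene membership matrix
#'
#' A gene belongs to a module when its posterior inclusion probability
#' strictly exceeds the threshold (default 0.5); a PIP of exactly 0.5 is not
#' membership.
#'
#' @param modules a fitted [tismod()] model (or any object with a `pip`
#'   matrix).
#' @param threshold probability threshold in `[0, 1]`.
#' @return A C x L logical matrix.
#' @export
gene_membership <- function(modules, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("'threshold' must be a probability in [0, 1]", call. = FALSE)
  pip <- if (is.matrix(modules)) modules else modules$pip
  pip > threshold
}

#' Scale a spatial map for display
#'
#' `"zscore"` rescales to zero mean and unit variance (the convention for
#' spot-level arrays); `"signed_log"` applies
#' `sign(x) * log(1 + |x| / median(|x|))`, compressing the dynamic range of
#' bead-level maps while keeping the sign of each activity.
#'
#' @param map numeric vector of spatial activities (length >= 2).
#' @param mode `"zscore"` or `"signed_log"`.
#' @return The scaled vector.
#' @export
scale_map <- function(map, mode = c("zscore", "signed_log")) {
  mode <- match.arg(mode)
  if (length(map) < 2L) stop("'map' needs at least 2 values", call. = FALSE)
  if (mode == "zscore") {
    s <- stats::sd(map)
    if (s == 0)
      stop("constant map cannot be z-scored (module should be inactive)",
           call. = FALSE)
    (map - mean(map)) / s
  } else {
    sc <- stats::median(abs(map))
    if (sc == 0) sc <- 1
    sign(map) * log1p(abs(map) / sc)
  }
}

#' Top associated genes of a module
#'
#' Among the member genes of a module (PIP > 0.5) whose loading sign matches
#' the requested direction, returns the `k` genes with the largest absolute
#' loading, ordered by decreasing absolute loading with ties broken by gene
#' name.  The direction is taken relative to the annotated orientation of
#' the spatial map; both tails can be extracted separately.
#'
#' @param modules a fitted [tismod()] model.
#' @param module module index or name.
#' @param k number of genes (all matching members if fewer).
#' @param direction `"positive"` or `"negative"` loading sign.
#' @return Character vector of gene names (possibly empty, with a warning).
#' @export
top_genes <- function(modules, module, k = 50,
                      direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (is.character(module)) module <- match(module, rownames(modules$pip))
  load <- modules$loadings[module, ]
  member <- modules$pip[module, ] > 0.5
  keep <- member & if (direction == "positive") load > 0 else load < 0
  if (!any(keep)) {
    warning("no member genes with ", direction, " loading in module ",
            module, call. = FALSE)
    return(character(0))
  }
  g <- modules$gene_names[keep]
  a <- abs(load[keep])
  ord <- order(-a, g, method = "radix")
  g[ord][seq_len(min(k, length(g)))]
}

#' Hypergeometric comparison of two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between two gene sets drawn from a common background, the
#' standard test for similarity of module gene lists (e.g. top-50 lists
#' against a 2,000-gene highly-variable background).
#'
#' @param genes_a,genes_b character vectors of gene names; must be subsets
#'   of `background`.
#' @param background character vector, the common gene universe.
#' @return A list with `overlap`, `set_sizes`, `background_size` and
#'   `p_value` (exact upper tail, `P(X >= overlap)`).
#' @export
compare_modules <- function(genes_a, genes_b, background) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  background <- unique(background)
  if (!all(genes_a %in% background) || !all(genes_b %in% background))
    stop("gene sets must be contained in the background", call. = FALSE)
  N <- length(background)
  ov <- length(intersect(genes_a, genes_b))
  nA <- length(genes_a); nB <- length(genes_b)
  p <- stats::phyper(ov - 1L, nA, N - nA, nB, lower.tail = FALSE)
  list(overlap = ov, set_sizes = c(nA, nB), background_size = N,
       p_value = min(1, p))
}
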