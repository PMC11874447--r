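#' Preprocessing settings
#'
#' Bundles the filtering/normalization/HVG thresholds used by
#' [filter_profile()], [normalize_profile()] and [select_hvgs()].  The
#' defaults are the conventional ones for the two platform classes: on
#' spot-level arrays genes detected in fewer than 10% of spots are dropped;
#' on bead/cell-level platforms genes detected at fewer than 50 locations and
#' cells detecting fewer than 100 genes are dropped.
#'
#' @param min_spot_fraction minimum fraction of spots a gene must be detected
#'   in (low-resolution platforms); in `[0, 1]`.
#' @param min_locations minimum number of locations a gene must be detected
#'   at (high-resolution platforms).
#' @param min_genes_per_cell minimum number of detected genes per location
#'   (high-resolution platforms).
#' @param scale_factor scale of the relative-abundance normalization.
#' @param n_hvg number of highly variable genes to keep.
#' @param gene_allowlist optional gene names always kept alongside the HVGs.
#' @return A list of class `"preprocess_control"`.
#' @export
preprocess_control <- function(min_spot_fraction = 0.1, min_locations = 50,
                               min_genes_per_cell = 100, scale_factor = 1e4,
                               n_hvg = 2000, gene_allowlist = NULL) {
  stopifnot(min_spot_fraction >= 0, min_spot_fraction <= 1,
            min_locations >= 0, min_genes_per_cell >= 0, scale_factor > 0,
            n_hvg >= 1)
  structure(list(min_spot_fraction = min_spot_fraction,
                 min_locations = min_locations,
                 min_genes_per_cell = min_genes_per_cell,
                 scale_factor = scale_factor, n_hvg = n_hvg,
                 gene_allowlist = gene_allowlist),
            class = "preprocess_control")
}

#' Filter genes and spots of a raw count profile
#'
#' Applies detection filters to raw counts.  "Detected" means count > 0, and
#' all thresholds are strict: on a `low_res` profile a gene detected in fewer
#' than `min_spot_fraction` of spots is removed; on a `high_res` profile a
#' gene detected at fewer than `min_locations` locations is removed and,
#' afterwards, locations detecting fewer than `min_genes_per_cell` of the
#' surviving genes are removed.  Ordering of the survivors is preserved.
#'
#' @param profile an `stm_profile` holding raw counts.
#' @param cfg a [preprocess_control()].
#' @return The filtered `stm_profile`.
#' @export
filter_profile <- function(profile, cfg = preprocess_control()) {
  stopifnot(inherits(profile, "stm_profile"))
  if (profile$is_normalized)
    stop("filter_profile() expects raw counts, got a normalized profile",
         call. = FALSE)
  detected <- profile$values > 0
  S <- nrow(detected)
  if (profile$platform == "low_res") {
    keep_genes <- colSums(detected) / S >= cfg$min_spot_fraction
    keep_spots <- rep(TRUE, S)
  } else {
    keep_genes <- colSums(detected) >= cfg$min_locations
    keep_spots <- rowSums(detected[, keep_genes, drop = FALSE]) >=
      cfg$min_genes_per_cell
  }
  if (!any(keep_genes))
    stop("all genes removed by the detection filter", call. = FALSE)
  if (sum(keep_spots) < 2L)
    stop("fewer than 2 spots left after filtering", call. = FALSE)
  subset_profile(profile, spots = which(keep_spots),
                 genes = which(keep_genes))
}

#' Log relative-abundance normalization
#'
#' Converts counts to `log(1 + count / spot_total * scale_factor)`, the
#' relative-abundance normalization with a fixed scale.  Spot totals are
#' computed over the retained genes, so the transform is invariant to
#' rescaling all counts of one spot.  Spots with zero total are dropped with
#' a warning (they carry no expression information).
#'
#' @param profile an `stm_profile` holding raw counts.
#' @param scale_factor positive scaling factor (default `1e4`).
#' @return A normalized `stm_profile` (`is_normalized = TRUE`).
#' @export
normalize_profile <- function(profile, scale_factor = 1e4) {
  stopifnot(inherits(profile, "stm_profile"), scale_factor > 0)
  if (profile$is_normalized)
    stop("profile is already normalized", call. = FALSE)
  totals <- rowSums(profile$values)
  if (any(totals == 0)) {
    drop <- which(totals == 0)
    warning("dropping ", length(drop), " spot(s) with zero total count: ",
            paste(utils::head(profile$spot_ids[drop], 5L), collapse = ", "),
            call. = FALSE)
    profile <- subset_profile(profile, spots = which(totals > 0))
    totals <- totals[totals > 0]
  }
  vals <- log1p(profile$values / totals * scale_factor)
  out <- profile
  out$values <- vals
  out$is_normalized <- TRUE
  out
}

# Standardized variance of each gene after a loess mean-variance trend fit
# (vst-style): fit log10(variance) ~ loess(log10(mean), span 0.3), predict an
# expected standard deviation per gene, standardize counts with it, clip at
# sqrt(S), and report the variance of the clipped standardized values.
standardized_variance <- function(values, span = 0.3) {
  S <- nrow(values)
  mu <- colMeans(values)
  v <- apply(values, 2L, stats::var)
  sv <- numeric(ncol(values))
  pos <- v > 0 & mu > 0
  if (any(pos)) {
    lm10 <- log10(mu[pos]); lv10 <- log10(v[pos])
    if (sum(pos) >= 4L && length(unique(lm10)) >= 4L) {
      # fit on canonically ordered points so the result is invariant to
      # gene-column permutation of the input; widen the span on small gene
      # sets so each quadratic neighbourhood keeps enough points
      ord <- order(lm10, lv10)
      span_eff <- max(span, min(1, 8 / sum(pos)))
      fit <- stats::loess(lv10[ord] ~ lm10[ord], span = span_eff,
                          degree = 2L, family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      exp_sd <- sqrt(10^stats::predict(fit, lm10))
    } else {
      exp_sd <- sqrt(v[pos])   # too few genes for a trend: no smoothing
    }
    clip <- sqrt(S)
    z <- sweep(sweep(values[, pos, drop = FALSE], 2L, mu[pos], "-"),
               2L, exp_sd, "/")
    z <- pmin(pmax(z, -clip), clip)
    # variance of clipped standardized values, computed about the
    # pre-clipping mean of zero as in the vst convention
    sv[pos] <- colSums(z^2) / (S - 1L)
  }
  sv
}

#' Select highly variable genes
#'
#' Ranks genes by vst-style standardized variance (loess-smoothed
#' mean-variance trend on the log10 scale, variance of clipped standardized
#' values) and returns the union of the top `n_hvg` genes with the
#' `allowlist`.  The ranking is deterministic; ties are broken by gene-name
#' order.
#'
#' @param profile an `stm_profile` (counts or normalized values; the ranking
#'   uses the stored values as-is).
#' @param n_hvg number of top genes to keep.
#' @param allowlist optional gene names merged with the selection; names not
#'   present in the profile are dropped with a warning.
#' @return Character vector of selected gene names, in ranking order with
#'   allowlist-only genes appended.
#' @export
select_hvgs <- function(profile, n_hvg = 2000, allowlist = NULL) {
  stopifnot(inherits(profile, "stm_profile"))
  if (n_hvg < 1) stop("'n_hvg' must be at least 1", call. = FALSE)
  # rank on 10 significant digits so floating-point noise in the trend fit
  # cannot reorder effectively tied genes past the name tie-break
  sv <- signif(standardized_variance(profile$values), 10)
  ord <- order(-sv, profile$gene_names, method = "radix")
  top <- profile$gene_names[ord[seq_len(min(n_hvg, length(ord)))]]
  if (!is.null(allowlist)) {
    missing <- setdiff(allowlist, profile$gene_names)
    if (length(missing))
      warning("allowlist gene(s) not in profile dropped: ",
              paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    extra <- setdiff(intersect(allowlist, profile$gene_names), top)
    top <- c(top, extra)
  }
  top
}

#' One-call preprocessing
#'
#' Convenience wrapper chaining [filter_profile()], [normalize_profile()] and
#' [select_hvgs()], returning the normalized profile restricted to the
#' selected genes.  Filtering happens before HVG selection.
#'
#' @inheritParams filter_profile
#' @return A normalized `stm_profile` restricted to the HVG set.
#' @export
preprocess_profile <- function(profile, cfg = preprocess_control()) {
  prof <- filter_profile(profile, cfg)
  # HVGs are ranked on the filtered counts (the vst convention); spot totals
  # for normalization are taken over all filtered genes before subsetting.
  hvgs <- select_hvgs(prof, n_hvg = cfg$n_hvg, allowlist = cfg$gene_allowlist)
  prof <- normalize_profile(prof, cfg$scale_factor)
  subset_profile(prof, genes = match(hvgs, prof$gene_names))
}
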