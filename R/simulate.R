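# Base spatial patterns on a square grid: a disk of elevated activity and an
# axis-aligned half-plane through the grid midline.  All geometry is
# parameterized so other shapes can be swapped in.

disk_mask <- function(coords, center, radius)
  sqrt((coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2) <= radius

halfplane_mask <- function(coords, grid_size, orientation) {
  mid <- (grid_size + 1) / 2
  switch(orientation,
         right = coords[, 1] > mid, left = coords[, 1] < mid,
         top = coords[, 2] > mid, bottom = coords[, 2] < mid)
}

random_base_mask <- function(coords, grid_size) {
  if (stats::runif(1) < 0.5) {
    radius <- grid_size / 4
    center <- stats::runif(2, 1 + radius, grid_size - radius)
    disk_mask(coords, center, radius)
  } else {
    halfplane_mask(coords, grid_size,
                   sample(c("right", "left", "top", "bottom"), 1L))
  }
}

#' Simulate a grid scenario with known spatial gene sets
#'
#' Generates a spots-by-genes profile on a `grid_size` x `grid_size` square
#' array (defaults: 1,000 genes at 256 spots on a 16 x 16 grid) in one of
#' seven scenarios built from two base patterns, a disk ("spot") and a
#' half-plane ("linear"):
#'
#' 1. one gene set with one base pattern;
#' 2. one gene set with the union of two base patterns;
#' 3. one gene set with the union of three base patterns;
#' 4. two gene sets with disjoint patterns and disjoint genes;
#' 5. two gene sets with disjoint patterns sharing `overlap_frac` of their
#'    genes;
#' 6. two gene sets with nested patterns at different spatial scales;
#' 7. three gene sets with nested multi-scale patterns.
#'
#' Member genes have their mean shifted by `effect` inside their pattern;
#' all other genes are pure noise.  Values are Gaussian on the log scale
#' (matching the model's likelihood); with `counts = TRUE` they are
#' exponentiated and rounded to counts instead.
#'
#' @param scenario integer 1-7.
#' @param n_genes total number of genes.
#' @param grid_size side length of the square grid (>= 4).
#' @param set_size genes per spatial gene set.
#' @param effect mean shift inside the pattern (log scale).
#' @param noise_sd Gaussian noise standard deviation (log scale).
#' @param overlap_frac fraction of shared genes between the two sets of
#'   scenario 5.
#' @param counts return rounded count output instead of log-scale values.
#' @param seed integer seed; the same seed reproduces the profile and truth
#'   bit for bit.
#' @return A list with `profile` (an `stm_profile`) and `truth` (a list with
#'   `pattern_fields`: one logical mask per gene set; `memberships`: per
#'   gene, the integer ids of the sets it belongs to; `params`; `seed`).
#' @export
simulate_scenario <- function(scenario, n_genes = 1000, grid_size = 16,
                              set_size = 100, effect = 1, noise_sd = 0.5,
                              overlap_frac = 0.2, counts = FALSE, seed = 1L) {
  if (!scenario %in% 1:7) stop("'scenario' must be 1..7", call. = FALSE)
  if (grid_size < 4) stop("'grid_size' must be at least 4", call. = FALSE)
  if (overlap_frac < 0 || overlap_frac > 1)
    stop("'overlap_frac' must be in [0, 1]", call. = FALSE)
  stopifnot(n_genes >= 1, set_size >= 1, effect >= 0, noise_sd > 0)
  set.seed(as.integer(seed))
  g <- grid_size
  coords <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g)))
  S <- nrow(coords)

  masks <- list()
  if (scenario %in% 1:3) {
    n_base <- scenario
    repeat {
      m <- Reduce(`|`, lapply(seq_len(n_base),
                              function(i) random_base_mask(coords, g)))
      if (any(m) && !all(m)) break
    }
    masks <- list(m)
  } else if (scenario %in% 4:5) {
    mid <- (g + 1) / 2
    # disk confined to the right half, clear of the half-plane pattern;
    # shrink the radius on small grids so a valid placement always exists
    radius <- min(g / 5, 0.45 * (g - mid))
    lo <- mid + radius; hi <- g - radius
    center <- c(if (hi > lo) stats::runif(1, lo, hi) else (lo + hi) / 2,
                stats::runif(1, 1 + radius, g - radius))
    masks <- list(halfplane_mask(coords, g, "left"),
                  disk_mask(coords, center, radius))
  } else {
    n_sets <- scenario - 4L       # 2 for scenario 6, 3 for scenario 7
    center <- c((g + 1) / 2, (g + 1) / 2)
    radii <- g * 0.45 * (2 / 3)^(seq_len(n_sets) - 1L)
    masks <- lapply(radii, function(r) disk_mask(coords, center, r))
  }
  n_sets <- length(masks)

  memberships <- rep(list(integer(0)), n_genes)
  next_gene <- 1L
  for (k in seq_len(n_sets)) {
    if (scenario == 5 && k == 2L) {
      n_shared <- round(overlap_frac * set_size)
      shared <- seq_len(n_shared)           # first genes of set 1
      fresh <- seq(next_gene, length.out = set_size - n_shared)
      idx <- c(shared, fresh)
      next_gene <- next_gene + set_size - n_shared
    } else {
      idx <- seq(next_gene, length.out = set_size)
      next_gene <- next_gene + set_size
    }
    if (max(idx) > n_genes)
      stop("not enough genes for the requested gene sets", call. = FALSE)
    for (i in idx) memberships[[i]] <- c(memberships[[i]], k)
  }

  X <- matrix(stats::rnorm(S * n_genes, sd = noise_sd), S, n_genes)
  for (l in seq_len(n_genes))
    for (k in memberships[[l]])
      X[masks[[k]], l] <- X[masks[[k]], l] + effect
  gene_names <- sprintf("gene%04d", seq_len(n_genes))
  spot_ids <- paste0(coords[, 1], "x", coords[, 2])
  if (counts) X <- round(exp(X))
  profile <- expression_profile(X, coords, gene_names = gene_names,
                                spot_ids = spot_ids, platform = "low_res",
                                is_normalized = !counts)
  truth <- list(pattern_fields = masks, memberships = memberships,
                params = list(scenario = scenario, n_genes = n_genes,
                              grid_size = grid_size, set_size = set_size,
                              effect = effect, noise_sd = noise_sd,
                              overlap_frac = overlap_frac, counts = counts),
                seed = seed)
  list(profile = profile, truth = truth)
}

#' Layered lattice geometry
#'
#' Builds a cortical-style geometry: a near-square lattice of `n_spots`
#' locations partitioned into `n_layers` parallel, spatially contiguous
#' bands (layers).  Band boundaries are placed so that per-layer spot counts
#' follow the relative `widths` as closely as whole lattice rows allow.
#'
#' @param n_spots number of spots (default 3611, a typical section).
#' @param n_layers number of layers (>= 2; default 7).
#' @param lattice `"hex"` (offset rows, bead-array style) or `"square"`.
#' @param widths relative layer widths (recycled default: equal).
#' @param seed integer seed (recorded; the construction is deterministic).
#' @return A list of class `"stm_geometry"` with `coords` (S x 2) and
#'   `layers` (integer label per spot, 1-based, contiguous bands by y).
#' @export
make_layered_geometry <- function(n_spots = 3611, n_layers = 7,
                                  lattice = c("hex", "square"),
                                  widths = NULL, seed = 1L) {
  lattice <- match.arg(lattice)
  if (n_layers < 2) stop("'n_layers' must be at least 2", call. = FALSE)
  if (n_spots < n_layers)
    stop("'n_spots' must be at least 'n_layers'", call. = FALSE)
  if (is.null(widths)) widths <- rep(1, n_layers)
  stopifnot(length(widths) == n_layers, all(widths > 0))
  ncols <- ceiling(sqrt(n_spots))
  nrows <- ceiling(n_spots / ncols)
  if (nrows < n_layers)
    stop("lattice has fewer rows than layers; increase 'n_spots'",
         call. = FALSE)
  ys <- if (lattice == "hex") sqrt(3) / 2 else 1
  rows <- rep(seq_len(nrows), each = ncols)[seq_len(n_spots)]
  cols <- rep(seq_len(ncols), times = nrows)[seq_len(n_spots)]
  x <- cols + if (lattice == "hex") 0.5 * (rows %% 2) else 0
  coords <- cbind(x = x, y = rows * ys)

  # assign whole rows to layers, matching cumulative relative widths
  row_counts <- tabulate(rows, nrows)
  target <- cumsum(widths) / sum(widths) * n_spots
  layer_of_row <- integer(nrows)
  k <- 1L; acc <- 0
  for (rr in seq_len(nrows)) {
    layer_of_row[rr] <- k
    acc <- acc + row_counts[rr]
    rows_left <- nrows - rr
    layers_left <- n_layers - k
    if (k < n_layers && (acc >= target[k] || rows_left <= layers_left))
      k <- k + 1L
  }
  layers <- layer_of_row[rows]
  structure(list(coords = coords, layers = layers, n_layers = n_layers,
                 lattice = lattice, widths = widths, seed = seed),
            class = "stm_geometry")
}

#' @export
print.stm_geometry <- function(x, ...) {
  cat(sprintf("Layered %s lattice: %d spots, %d layers (sizes %s)\n",
              x$lattice, nrow(x$coords), x$n_layers,
              paste(tabulate(x$layers, x$n_layers), collapse = "/")))
  invisible(x)
}

#' Simulate a layer-enriched count profile
#'
#' Negative-binomial counts on a layered geometry: `n_spatial` layer-genes
#' are drawn with mean `mu_in` inside the target layer and `mu_out` outside,
#' while `n_noise` background genes have mean `mu_out` everywhere; all genes
#' share the NB `dispersion` (size) parameter.
#'
#' @param geometry an [make_layered_geometry()] object.
#' @param target_layer layer label (1-based) to enrich.
#' @param n_spatial number of layer-enriched genes (default 100).
#' @param n_noise number of background genes (default 900).
#' @param mu_in,mu_out NB means inside/outside the layer; both positive
#'   with `mu_in >= mu_out` (equality gives a null profile without layer
#'   signal).
#' @param dispersion NB size parameter (> 0; smaller is more overdispersed).
#' @param seed integer seed.
#' @return A list with `profile` (raw-count `stm_profile`) and `truth`
#'   (layer mask, spatial gene names, parameters, seed).
#' @export
simulate_layered <- function(geometry, target_layer, n_spatial = 100,
                             n_noise = 900, mu_in = 5, mu_out = 1,
                             dispersion = 0.5, seed = 1L) {
  stopifnot(inherits(geometry, "stm_geometry"))
  if (!target_layer %in% seq_len(geometry$n_layers))
    stop("'target_layer' is not a layer of the geometry", call. = FALSE)
  if (!(mu_in >= mu_out && mu_out > 0))
    stop("need mu_in >= mu_out > 0", call. = FALSE)
  if (dispersion <= 0) stop("'dispersion' must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  S <- nrow(geometry$coords)
  mask <- geometry$layers == target_layer
  L <- n_spatial + n_noise
  mu <- matrix(mu_out, S, L)
  mu[mask, seq_len(n_spatial)] <- mu_in
  counts <- matrix(stats::rnbinom(S * L, mu = mu, size = dispersion), S, L)
  gene_names <- c(sprintf("layergene%03d", seq_len(n_spatial)),
                  sprintf("noisegene%03d", seq_len(n_noise)))
  profile <- expression_profile(counts, geometry$coords,
                                gene_names = gene_names,
                                spot_ids = sprintf("spot%04d", seq_len(S)),
                                platform = "low_res", is_normalized = FALSE)
  truth <- list(mask = mask, spatial_genes = gene_names[seq_len(n_spatial)],
                params = list(target_layer = target_layer,
                              n_spatial = n_spatial, n_noise = n_noise,
                              mu_in = mu_in, mu_out = mu_out,
                              dispersion = dispersion),
                seed = seed)
  list(profile = profile, truth = truth)
}
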