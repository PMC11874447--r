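# Shared fixture builders. Everything is generated in code at test time.

# tiny raw-count profile with hand-set detection structure
tiny_count_profile <- function(S = 6, L = 5, platform = "low_res",
                               seed = 42) {
  set.seed(seed)
  counts <- matrix(rpois(S * L, lambda = 3) + 1, S, L)
  expression_profile(counts, cbind(seq_len(S), rep(1, S)),
                     gene_names = paste0("g", seq_len(L)),
                     spot_ids = paste0("s", seq_len(S)),
                     platform = platform)
}

# normalized low-rank profile: maps drawn from the SE prior, dense loadings
gp_profile <- function(grid = 8, L = 60, C = 2, noise_sd = 0.1, r = 0.2,
                       seed = 1) {
  set.seed(seed)
  coords <- as.matrix(expand.grid(x = seq_len(grid), y = seq_len(grid)))
  S <- nrow(coords)
  F <- chol_psd(se_covariance(pairwise_distances(coords), r), 1e-6)
  P <- F %*% matrix(rnorm(S * C), S, C)
  G <- matrix(rnorm(C * L), C, L)
  Y <- P %*% G + matrix(rnorm(S * L, sd = noise_sd), S, L)
  list(profile = expression_profile(Y, coords,
                                    gene_names = sprintf("g%03d", seq_len(L)),
                                    spot_ids = sprintf("s%03d", seq_len(S)),
                                    is_normalized = TRUE),
       P = P, G = G, coords = coords)
}

# independent pair-counting AUROC (probability a positive outranks a
# negative, ties counted half)
pair_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# independent adjusted Rand index by explicit pair counting
pair_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  expected <- (n11 + n10) * (n11 + n01) / choose(n, 2)
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(0)
  (n11 - expected) / (maxi - expected)
}

# identity-covariance kernel cache for closed-form oracle checks
identity_kernel_cache <- function(S, r = 1) {
  env <- new.env(parent = emptyenv())
  env$kind <- "squared_exponential"
  env$r_grid <- r
  env$jitter <- 0
  env$scale <- 1
  env$S <- S
  env$keep_inverse <- TRUE
  env$entries <- list(list(Q = diag(S), ej = rep(1, S), logdet = 0,
                           dinv = rep(1, S), inv = diag(S), r = r))
  env
}
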