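#' AUROC and AUPR of a continuous score against binary labels
#'
#' AUROC is computed as the Mann-Whitney statistic with midranks for ties;
#' AUPR by step interpolation of the precision-recall curve over the
#' distinct score thresholds.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector; both classes must be present.
#' @return A list with `auroc` and `aupr`.
#' @export
auroc_aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L)
    stop("both classes must be present to compute AUROC/AUPR", call. = FALSE)
  r <- rank(scores)                       # midranks
  auroc <- (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  last <- cumsum(tabulate(match(s, unique(s))))  # end index of each tie group
  tp <- cumsum(y)[last]
  n_at <- last
  recall <- tp / P
  precision <- tp / n_at
  aupr <- sum(diff(c(0, recall)) * precision)
  list(auroc = auroc, aupr = aupr)
}

#' Best adjusted Rand index over a threshold sweep
#'
#' Binarizes a continuous spatial map at `n_thresholds` equally spaced
#' quantiles and reports the highest adjusted Rand index against the given
#' labels, the standard way to score a continuous map against a discrete
#' domain partition.  Being quantile-based, the sweep is invariant to
#' strictly monotone transforms of the map.
#'
#' @param map numeric vector of spatial activities.
#' @param labels class labels (factor, integer or logical) per spot.
#' @param n_thresholds number of quantile thresholds.
#' @return A list with `ari` (the maximum) and `threshold` (a threshold
#'   achieving it).
#' @export
best_threshold_ari <- function(map, labels, n_thresholds = 100) {
  stopifnot(length(map) == length(labels), n_thresholds >= 1)
  qs <- unique(stats::quantile(map, probs = seq(0, 1,
                                                length.out = n_thresholds),
                               names = FALSE, type = 7))
  best <- -Inf; best_thr <- qs[1L]
  for (thr in qs) {
    ari <- mclust::adjustedRandIndex(map > thr, labels)
    if (ari > best) { best <- ari; best_thr <- thr }
  }
  list(ari = best, threshold = best_thr)
}

#' FDR-power curve of a ranked gene list
#'
#' Walks down the ranking (decreasing `scores`, optional `tie_break`,
#' remaining ties by index) and reports, at every prefix, the realized false
#' discovery rate `FP / (TP + FP)` and the power `TP / P` against the truth
#' labels.
#'
#' @param scores numeric vector, primary ranking score (e.g. PIP).
#' @param truth logical vector of true memberships (at least one `TRUE`).
#' @param tie_break optional secondary score (e.g. absolute loading).
#' @return A data frame with columns `rank`, `fdr`, `power`.
#' @export
fdr_power_curve <- function(scores, truth, tie_break = NULL) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  if (!any(truth))
    stop("'truth' must contain at least one true positive", call. = FALSE)
  ord <- if (is.null(tie_break)) order(-scores)
         else order(-scores, -tie_break)
  y <- truth[ord]
  tp <- cumsum(y)
  n <- seq_along(y)
  data.frame(rank = n, fdr = (n - tp) / n, power = tp / sum(truth))
}

# Orientation-aware AUROC: a factorization map is sign-symmetric, so a
# domain may be matched by either the map or its negation.
oriented_auroc <- function(map, mask) {
  a <- auroc_aupr(map, mask)$auroc
  if (a >= 1 - a) c(auroc = a, orientation = 1)
  else c(auroc = 1 - a, orientation = -1)
}

# O(n^3) shortest-augmenting-path assignment maximizing the total score.
# Arrays are 0..n with a virtual row/column 0, stored at R index k+1.
hungarian_max <- function(score) {
  n <- nrow(score)
  stopifnot(ncol(score) == n)
  cost <- max(score) - score              # minimize
  INF <- Inf
  u <- numeric(n + 1)                     # row potentials (rows 0..n)
  v <- numeric(n + 1)                     # column potentials (cols 0..n)
  p <- integer(n + 1)                     # p[j+1]: row assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1L] <- i                            # column 0 holds the new row
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)                    # assign[row] = column
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Align modules to annotated domains
#'
#' Matches module spatial maps to annotated spatial domains by AUROC, trying
#' both map orientations.  `"best_per_domain"` picks, independently for each
#' domain, the module with the highest AUROC (modules may repeat);
#' `"one_to_one"` picks the injective module-to-domain assignment with the
#' highest average AUROC (exhaustive search up to 8 modules, otherwise an
#' O(n^3) assignment solver).  When there are fewer modules than domains the
#' one-to-one mode assigns as many domains as possible and warns about the
#' rest.
#'
#' @param maps S x C matrix of spatial maps.
#' @param domains logical S x D matrix, or a list of logical masks, or a
#'   factor/labels vector (expanded to one mask per level).
#' @param mode `"best_per_domain"` or `"one_to_one"`.
#' @return A list with `mode`, `alignment` (data frame: domain, module,
#'   auroc, orientation) and `mean_auroc`.
#' @export
align_to_domains <- function(maps, domains,
                             mode = c("best_per_domain", "one_to_one")) {
  mode <- match.arg(mode)
  maps <- as.matrix(maps)
  if (is.list(domains)) domains <- do.call(cbind, domains)
  if (!is.matrix(domains)) {
    f <- factor(domains)
    domains <- vapply(levels(f), function(lv) f == lv,
                      logical(length(f)))
  }
  storage.mode(domains) <- "logical"
  C <- ncol(maps); D <- ncol(domains)
  if (D < 1L) stop("need at least one domain", call. = FALSE)
  if (is.null(colnames(domains)))
    colnames(domains) <- paste0("domain", seq_len(D))
  if (is.null(colnames(maps)))
    colnames(maps) <- paste0("module", seq_len(C))

  score <- matrix(NA_real_, C, D)
  orient <- matrix(1, C, D)
  for (c in seq_len(C)) for (d in seq_len(D)) {
    oa <- oriented_auroc(maps[, c], domains[, d])
    score[c, d] <- oa["auroc"]; orient[c, d] <- oa["orientation"]
  }

  if (mode == "best_per_domain") {
    mod <- apply(score, 2L, which.max)
    ali <- data.frame(domain = colnames(domains),
                      module = colnames(maps)[mod],
                      auroc = score[cbind(mod, seq_len(D))],
                      orientation = orient[cbind(mod, seq_len(D))])
  } else {
    if (C < D)
      warning(sprintf("only %d module(s) for %d domains; %d domain(s) left unmatched",
                      C, D, D - C), call. = FALSE)
    n <- max(C, D)
    sq <- matrix(0, n, n)
    sq[seq_len(C), seq_len(D)] <- score
    if (n <= 8L) {
      perms <- permutations_of(n)
      vals <- apply(perms, 1L, function(p) sum(sq[cbind(seq_len(n), p)]))
      p <- perms[which.max(vals), ]
      assign <- p
    } else assign <- hungarian_max(sq)
    dom_of_mod <- assign[seq_len(C)]
    keep <- which(dom_of_mod <= D)
    ali <- data.frame(domain = colnames(domains)[dom_of_mod[keep]],
                      module = colnames(maps)[keep],
                      auroc = score[cbind(keep, dom_of_mod[keep])],
                      orientation = orient[cbind(keep, dom_of_mod[keep])])
    ali <- ali[order(match(ali$domain, colnames(domains))), ]
    rownames(ali) <- NULL
  }
  list(mode = mode, alignment = ali, mean_auroc = mean(ali$auroc))
}

# all permutations of 1..n as rows (n <= 8)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
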