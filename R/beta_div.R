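# Hill-number node turnover between webs, principal coordinate analysis, and
# a permutation pseudo-F test on dissimilarity matrices.

#' Hill number of order q
#'
#' Effective number of types of a probability vector: `q = 0` gives the
#' richness of the support, `q = 1` the exponential Shannon entropy
#' (continuity limit), any other `q >= 0` gives `(sum p^q)^(1/(1-q))`.
#'
#' @param p non-negative vector summing to 1 (zeros allowed).
#' @param q Hill order, `q >= 0`.
#' @return real >= 1 for a non-degenerate p
#' @export
hill_number <- function(p, q) {
  if (q < 0) stop("q must be >= 0")
  if (any(p < 0)) stop("p must be non-negative")
  s <- sum(p)
  if (s <= 0) stop("p must have positive mass")
  if (abs(s - 1) > 1e-9) p <- p / s
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Node distribution of a web over a node universe
#'
#' `mode = "presence"`: uniform over present nodes; `mode = "reads"`:
#' read-count proportions. Nodes of the universe absent from the web get 0.
#'
#' @param web a [food_web()] (non-empty).
#' @param mode `"presence"` or `"reads"`.
#' @param universe node ids to index the vector by (default: the web's nodes).
#' @return named probability vector over `universe`
#' @export
node_distribution <- function(web, mode = c("presence", "reads"),
                              universe = web$nodes) {
  mode <- match.arg(mode)
  if (length(web$nodes) == 0) stop("empty web has no node distribution")
  p <- stats::setNames(numeric(length(universe)), universe)
  present <- intersect(web$nodes, universe)
  if (mode == "presence") {
    p[present] <- 1 / length(web$nodes)
  } else {
    rc <- web$read_counts[present]
    if (sum(rc) <= 0) stop("no reads in web; cannot use mode='reads'")
    p[present] <- rc / sum(web$read_counts)
  }
  p
}

#' Pairwise Hill-number node turnover between two webs
#'
#' Two-assemblage Hill decomposition with equal weights: gamma is the Hill
#' number of the mean of the two distributions; alpha is the power mean of
#' order `1 - q` of the two within-web Hill numbers (the geometric mean at
#' `q = 1`); `beta = gamma / alpha` lies in `[1, 2]` and the dissimilarity is
#' `beta - 1`, in `[0, 1]`. At `q = 0` with presence mode this is the
#' Sorensen-type turnover.
#'
#' @param web1,web2 [food_web()]s.
#' @param q Hill order.
#' @param mode `"presence"` or `"reads"` (see [node_distribution()]).
#' @return dissimilarity in `[0, 1]`
#' @export
pairwise_dissimilarity <- function(web1, web2, q = 0, mode = "presence") {
  if (length(web1$nodes) == 0 || length(web2$nodes) == 0)
    stop("cannot compare empty webs")
  universe <- union(web1$nodes, web2$nodes)
  p1 <- node_distribution(web1, mode, universe)
  p2 <- node_distribution(web2, mode, universe)
  gamma <- hill_number((p1 + p2) / 2, q)
  h1 <- hill_number(p1, q)
  h2 <- hill_number(p2, q)
  alpha <- if (abs(q - 1) < 1e-12) sqrt(h1 * h2)
  else ((h1^(1 - q) + h2^(1 - q)) / 2)^(1 / (1 - q))
  beta <- min(max(gamma / alpha, 1), 2)
  beta - 1
}

#' Dissimilarity matrix over a list of webs
#'
#' @param webs named list of [food_web()]s (>= 2).
#' @param q Hill order.
#' @param mode `"presence"` or `"reads"`.
#' @return object of class `dissimilarity_matrix`: list(D, labels, q, mode)
#'   with D symmetric, zero-diagonal, entries in `[0,1]`.
#' @export
dissimilarity_matrix <- function(webs, q = 0, mode = "presence") {
  n <- length(webs)
  if (n < 2) stop("need at least two webs")
  labels <- names(webs)
  if (is.null(labels)) labels <- sprintf("web%02d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- pairwise_dissimilarity(webs[[i]], webs[[j]], q, mode)
  }
  structure(list(D = D, labels = labels, q = q, mode = mode),
            class = "dissimilarity_matrix")
}

as_dist_matrix <- function(D) {
  if (inherits(D, "dissimilarity_matrix")) D <- D$D
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("D must be a symmetric square matrix")
  D
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centring of `-D^2 / 2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues. Negative eigenvalues (non-Euclidean D) are reported and their
#' axes dropped; `variance_explained` is relative to the positive part.
#'
#' @param D symmetric dissimilarity matrix (or a `dissimilarity_matrix`).
#' @return list of class `pcoa_result`: coordinates (centred columns,
#'   axes ordered by eigenvalue), eigenvalues (all), variance_explained.
#' @export
pcoa_ordination <- function(D) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- eig$values > max(eig$values, 0) * 1e-9 & eig$values > 1e-12
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- sprintf("PCoA%d", seq_len(ncol(coords)))
  ve <- if (any(pos)) eig$values[pos] / sum(eig$values[pos]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = eig$values,
                 variance_explained = ve),
            class = "pcoa_result")
}

#' Permutation F test (PERMANOVA) on a dissimilarity matrix
#'
#' One-factor pseudo-F from sums of squared dissimilarities:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` summed per group analogously,
#' `F = (SS_between / (k-1)) / (SS_within / (n-k))`. The p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` under random label permutations
#' (optionally restricted within strata).
#'
#' @param D symmetric dissimilarity matrix (or `dissimilarity_matrix`).
#' @param grouping factor-like vector of group labels, one per row of D.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @param strata optional vector; permutations shuffle labels only within
#'   each stratum.
#' @return list of class `permanova_result`: F, p, df_between, df_within,
#'   n_perm, seed.
#' @export
permutation_f <- function(D, grouping, n_perm = 999L, seed = 1L,
                          strata = NULL) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  grouping <- as.character(grouping)
  if (length(grouping) != n) stop("grouping must match dim(D)")
  sizes <- table(grouping)
  if (any(sizes < 1)) stop("every group needs at least one member")
  k <- length(sizes)
  if (k < 2) stop("need at least two groups")
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1)
        s <- s + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    s
  }
  f_stat <- function(g) {
    ssw <- ss_within(g)
    ((ss_total - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_stat(grouping)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (is.null(strata)) {
      g <- grouping[sample.int(n)]
    } else {
      g <- grouping
      for (s in unique(strata)) {
        idx <- which(strata == s)
        g[idx] <- g[idx][sample.int(length(idx))]
      }
    }
    if (f_stat(g) >= f_obs) exceed <- exceed + 1L
  }
  structure(list(F = f_obs, p = (1 + exceed) / (1 + n_perm),
                 df_between = k - 1L, df_within = n - k,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("Permutation F test: F = %.3f, df = (%d, %d), p = %.4g (%d permutations)\n",
              x$F, x$df_between, x$df_within, x$p, x$n_perm))
  invisible(x)
}
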