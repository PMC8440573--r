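# Independent oracles: every routine here recomputes a quantity by the most
# direct method available (enumeration, brute force, closed form), sharing no
# code with the implementation under test.

# all-pairs shortest paths by Floyd-Warshall on the directed adjacency
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  diag(D) <- Inf  # ordered pairs i != j only
  D
}

# trophic levels by fixed-point iteration TL <- 1 + W TL
oracle_trophic_levels <- function(web, iters = 500) {
  n <- length(web$nodes)
  W <- matrix(0, n, n, dimnames = list(web$nodes, web$nodes))
  e <- web$edges
  for (k in seq_len(nrow(e))) W[e$consumer[k], e$resource[k]] <- 1
  rs <- rowSums(W)
  W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  tl <- rep(1, n)
  for (i in seq_len(iters)) tl <- 1 + W %*% tl
  stats::setNames(as.numeric(tl), web$nodes)
}

# adjusted Rand index from the contingency table
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  d <- choose(sum(tab), 2)
  expected <- b * c / d
  (a - expected) / ((b + c) / 2 - expected)
}

# complete-data log-likelihood of a hard SBM assignment, written from scratch
# with explicit loops over group pairs
oracle_sbm_loglik <- function(A, z) {
  n <- nrow(A)
  Q <- max(z)
  ll <- 0
  for (q in seq_len(Q)) {
    nq <- sum(z == q)
    if (nq > 0) ll <- ll + nq * log(nq / n)
  }
  for (q in seq_len(Q)) for (r in seq_len(Q)) {
    iq <- which(z == q); jr <- which(z == r)
    m <- length(iq) * length(jr) - (q == r) * length(iq)
    if (m == 0) next
    e <- sum(A[iq, jr])
    p <- e / m
    if (e > 0) ll <- ll + e * log(p)
    if (m - e > 0) ll <- ll + (m - e) * log(1 - p)
  }
  ll
}

# exhaustive optimum of the complete-data log-likelihood over all
# 2-colourings (label symmetry fixed by pinning node 1 to group 1)
oracle_exhaustive_Q2 <- function(A) {
  n <- nrow(A)
  best <- -Inf
  for (code in 0:(2^(n - 1) - 1)) {
    z <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    ll <- oracle_sbm_loglik(A, z)
    if (ll > best) best <- ll
  }
  best
}

# Hill number evaluated directly from its definition
oracle_hill <- function(p, q) {
  p <- p[p > 0] / sum(p)
  if (q == 0) length(p)
  else if (q == 1) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

# random directed graph without self-loops
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(A) <- 0L
  A
}

# planted two-role SBM adjacency with diagonal-free block structure
planted_sbm <- function(n, Q, p_in, p_out, seed) {
  set.seed(seed)
  z <- rep(seq_len(Q), length.out = n)[sample.int(n)]
  P <- matrix(p_out, n, n)
  P[outer(z, z, "==")] <- p_in
  diag(P) <- 0
  A <- matrix(as.integer(runif(n * n) < P), n, n)
  diag(A) <- 0L
  list(A = A, z = z)
}

# food_web from an adjacency matrix, optional guilds/types/reads
web_from_adjacency <- function(A, guild = NULL, types = NULL, reads = NULL) {
  n <- nrow(A)
  ids <- sprintf("n%02d", seq_len(n))
  idx <- which(A == 1, arr.ind = TRUE)
  edges <- if (nrow(idx) > 0)
    data.frame(resource = ids[idx[, 1]], consumer = ids[idx[, 2]],
               type = if (is.null(types)) "predation" else types,
               weight = 1, stringsAsFactors = FALSE) else NULL
  food_web(ids, edges,
           read_counts = if (is.null(reads)) NULL else stats::setNames(reads, ids),
           guild = if (is.null(guild)) NULL else stats::setNames(guild, ids))
}

# random upper-triangular DAG (edges low -> high index)
random_dag_web <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  web_from_adjacency(A)
}
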