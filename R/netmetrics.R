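# Food-web topology metrics. All operate on a food_web (taxa- or group-level)
# whose edges point resource -> consumer. Undefined values are returned as NA
# rather than errors so metric tables stay rectangular.

#' Node richness (S)
#'
#' Number of nodes including isolates.
#' @param web a [food_web()]
#' @return integer count
#' @export
node_richness <- function(web) length(web$nodes)

#' Trophic-group richness (|G|)
#'
#' Number of distinct group labels among the nodes present in the web.
#' @param web a [food_web()]
#' @param membership named vector mapping node id -> group label
#' @return integer count
#' @export
trophic_group_richness <- function(web, membership) {
  if (length(web$nodes) == 0) return(0L)
  g <- membership[web$nodes]
  if (anyNA(g)) stop("nodes without a group label: ",
                     paste(utils::head(web$nodes[is.na(g)], 5), collapse = ", "))
  length(unique(g))
}

#' Trophic-group entropy (equitability of read counts among groups)
#'
#' Hill number of order `q` of the group-level read-count proportions; for
#' `q = 1` this is the exponential of the Shannon entropy, the effective
#' number of equally-abundant groups.
#'
#' @param read_counts named non-negative counts per node.
#' @param membership named group labels per node.
#' @param q Hill order (default 1).
#' @return a real >= 1 (effective group number)
#' @export
trophic_group_entropy <- function(read_counts, membership, q = 1) {
  g <- membership[names(read_counts)]
  if (anyNA(g)) stop("read-count nodes without a group label")
  tot <- tapply(read_counts, g, sum)
  if (all(tot == 0)) stop("all read counts are zero")
  hill_number(tot / sum(tot), q)
}

#' Average degree (2L/S)
#'
#' Mean over nodes of in-degree + out-degree; each link contributes to two
#' node degrees, so this equals 2L/S. Empty web: 0 by convention.
#' @param web a [food_web()]
#' @return real
#' @export
average_degree <- function(web) {
  S <- node_richness(web)
  if (S == 0) return(0)
  2 * n_links(web) / S
}

#' Link density (L/S)
#' @param web a [food_web()]
#' @return real, NA for an empty web
#' @export
link_density <- function(web) {
  S <- node_richness(web)
  if (S == 0) return(NA_real_)
  n_links(web) / S
}

#' Trophic levels
#'
#' Basal nodes (no resources, in-degree 0) have trophic level 1; every other
#' node has level 1 plus the weighted average of the levels of its resources:
#' `TL_i = 1 + sum_j w_ij TL_j`, with `w` the row-normalized diet matrix
#' (equal weight per resource by default; proportional to edge weights when
#' `weighted = TRUE`). The system `(I - W) TL = 1` is solved directly; if a
#' cycle unreachable from any basal node makes it singular, a ridge of 1e-6 is
#' added and the result flagged (`attr(., "damped")`).
#'
#' @param web a [food_web()]
#' @param weighted use edge weights in the diet matrix.
#' @return named numeric of trophic levels; attributes `damped` (logical) and
#'   `residual` (max defining-equation residual).
#' @export
trophic_levels <- function(web, weighted = FALSE) {
  S <- node_richness(web)
  if (S == 0) return(stats::setNames(numeric(0), character(0)))
  W <- matrix(0, S, S, dimnames = list(web$nodes, web$nodes))
  e <- web$edges
  if (nrow(e) > 0) {
    wt <- if (weighted) e$weight else rep(1, nrow(e))
    # consumer rows, resource columns
    for (k in seq_len(nrow(e)))
      W[e$consumer[k], e$resource[k]] <- W[e$consumer[k], e$resource[k]] + wt[k]
    rs <- rowSums(W)
    pos <- rs > 0
    W[pos, ] <- W[pos, , drop = FALSE] / rs[pos]
  }
  M <- diag(S) - W
  damped <- FALSE
  tl <- tryCatch(solve(M, rep(1, S)), error = function(e) NULL)
  if (is.null(tl)) {
    damped <- TRUE
    tl <- tryCatch(solve(M + diag(1e-6, S), rep(1, S)), error = function(e) NULL)
    if (is.null(tl)) {
      comp <- igraph::components(as_igraph(web), mode = "strong")
      cyc <- which(comp$csize[comp$membership] > 1)
      stop("trophic-level system singular even after damping; ",
           "offending component nodes: ",
           paste(utils::head(web$nodes[cyc], 10), collapse = ", "))
    }
  }
  tl <- stats::setNames(as.numeric(tl), web$nodes)
  attr(tl, "damped") <- damped
  # residual of the system actually solved: the exact defining equation when
  # it is regular, the ridge-damped one otherwise (flagged above)
  Msolved <- if (damped) M + diag(1e-6, S) else M
  attr(tl, "residual") <- max(abs(Msolved %*% tl - 1))
  tl
}

#' Mean trophic level
#' @param web a [food_web()]
#' @param weighted passed to [trophic_levels()]
#' @return real, NA for an empty web
#' @export
mean_trophic_level <- function(web, weighted = FALSE) {
  if (node_richness(web) == 0) return(NA_real_)
  mean(trophic_levels(web, weighted))
}

#' Omnivory level
#'
#' Per consumer (node with >= 1 resource): the population standard deviation
#' of its resources' trophic levels (single-resource consumers score 0).
#' Network value: mean over consumers; 0 when the web has no consumers.
#'
#' @param web a [food_web()]
#' @param weighted passed to [trophic_levels()]
#' @return real >= 0
#' @export
omnivory_level <- function(web, weighted = FALSE) {
  if (n_links(web) == 0) return(0)
  tl <- trophic_levels(web, weighted)
  by_cons <- split(web$edges$resource, web$edges$consumer)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mean(vapply(by_cons, function(r) pop_sd(tl[r]), 0))
}

#' Average and maximum directed path length
#'
#' All-pairs shortest directed path lengths. The average is taken over ordered
#' pairs `i != j` with a finite distance (the finite-pair count is reported in
#' `n_pairs`); the maximum is the largest finite shortest-path length (the
#' diameter over reachable pairs).
#'
#' @param web a [food_web()]
#' @return list(average, maximum, n_pairs); average NA and maximum 0 when no
#'   pair is reachable.
#' @export
path_lengths <- function(web) {
  S <- node_richness(web)
  if (S == 0 || n_links(web) == 0)
    return(list(average = NA_real_, maximum = 0L, n_pairs = 0L))
  D <- igraph::distances(as_igraph(web), mode = "out")
  diag(D) <- Inf
  fin <- is.finite(D)
  if (!any(fin)) return(list(average = NA_real_, maximum = 0L, n_pairs = 0L))
  list(average = mean(D[fin]), maximum = as.integer(max(D[fin])),
       n_pairs = sum(fin))
}

#' Percentage of parasitic links
#' @param web a [food_web()]
#' @return percentage in `[0, 100]`, NA when the web has no links
#' @export
pct_parasitic_links <- function(web) {
  L <- n_links(web)
  if (L == 0) return(NA_real_)
  100 * sum(web$edges$type == "parasitism") / L
}

#' Energy-channel total pathway length and channel ratios
#'
#' The total pathway length of a channel seeded in a guild set is the sum,
#' over all nodes reachable (directed) from any seed node, of the shortest
#' path length from the nearest seed. [channel_path_ratio()] divides the
#' numerator channel's total by the denominator channel's; the two standard
#' ratios are bacteria:fungi (`bacteria_decomposer` / `fungi_saprotroph`) and
#' detritivore:root-herbivore channels.
#'
#' @param web a [food_web()] with guild annotations.
#' @param seed_guilds guild labels whose members seed the channel.
#' @return total pathway length (0 if no seed or nothing reachable)
#' @export
channel_total_path <- function(web, seed_guilds) {
  seeds <- web$nodes[!is.na(web$guild) & web$guild %in% seed_guilds]
  if (length(seeds) == 0 || n_links(web) == 0) return(0)
  D <- igraph::distances(as_igraph(web), v = seeds, mode = "out")
  d <- apply(D, 2, min)
  sum(d[is.finite(d) & d > 0])
}

#' @rdname channel_total_path
#' @param seed_guilds_num,seed_guilds_den guild sets of the numerator and
#'   denominator channels.
#' @return ratio of channel totals; NA when the denominator channel is 0
#'   (excluded from downstream regressions)
#' @export
channel_path_ratio <- function(web, seed_guilds_num, seed_guilds_den) {
  num <- channel_total_path(web, seed_guilds_num)
  den <- channel_total_path(web, seed_guilds_den)
  if (den == 0) return(NA_real_)
  num / den
}

#' Compute the full metric record for one web
#'
#' One row with the twelve indices: node richness, trophic-group richness and
#' entropy, average degree, mean trophic level, omnivory, link density,
#' average and maximum path length, % parasitic links, and the bacteria:fungi
#' and detritivore:herbivore channel ratios. Undefined values are NA.
#'
#' @param web a [food_web()]
#' @param membership optional named group labels (group metrics NA if absent).
#' @param read_counts optional named counts (defaults to the web's own).
#' @param weighted_tl use edge weights for trophic levels.
#' @return one-row data.frame
#' @export
network_metrics <- function(web, membership = NULL, read_counts = NULL,
                            weighted_tl = FALSE) {
  if (is.null(read_counts)) read_counts <- web$read_counts
  S <- node_richness(web)
  pl <- path_lengths(web)
  has_groups <- !is.null(membership) && S > 0 &&
    !anyNA(membership[web$nodes])
  tg_rich <- if (has_groups) trophic_group_richness(web, membership) else NA_integer_
  tg_ent <- if (has_groups && sum(read_counts[web$nodes]) > 0)
    trophic_group_entropy(read_counts[web$nodes], membership) else NA_real_
  data.frame(
    node_richness = S,
    trophic_group_richness = tg_rich,
    trophic_group_entropy = tg_ent,
    average_degree = if (S > 0) average_degree(web) else NA_real_,
    mean_trophic_level = mean_trophic_level(web, weighted_tl),
    omnivory_level = if (S > 0) omnivory_level(web, weighted_tl) else NA_real_,
    link_density = link_density(web),
    average_path_length = pl$average,
    max_path_length = pl$maximum,
    pct_parasitic_links = pct_parasitic_links(web),
    bf_path_ratio = channel_path_ratio(web, "bacteria_decomposer",
                                       "fungi_saprotroph"),
    dh_path_ratio = channel_path_ratio(web, "detritivore", "root_herbivore"),
    stringsAsFactors = FALSE)
}
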