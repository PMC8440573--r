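#' Guild vocabulary used throughout the package
#'
#' Eight functional guilds cover the basal microbial pools (bacterial
#' decomposers, saprotrophic fungi), the main soil consumer channels
#' (detritivores, root herbivores), parasites, predators, and two catch-all
#' categories.
#'
#' @export
GUILDS <- c("bacteria_decomposer", "fungi_saprotroph", "detritivore",
            "root_herbivore", "parasite", "predator",
            "other_basal", "other_consumer")

#' Soil habitat layers
#' @export
HABITAT_LAYERS <- c("surface", "0-10cm", ">10cm")

#' Interaction types
#' @export
INTERACTION_TYPES <- c("predation", "parasitism", "symbiosis")

#' Evidence ranks, most specific first
#' @export
EVIDENCE_RANKS <- c("species", "genus", "family", "generalized")

#' Construct a food web
#'
#' A `food_web` is a directed graph of trophic interactions. Edges point from
#' resource to consumer (the direction of energy flow). Nodes are taxa (or
#' trophic groups); isolated nodes are legal and count towards richness.
#'
#' @param nodes character vector of node identifiers (unique, non-NA).
#' @param edges data.frame with columns `resource`, `consumer`, and optionally
#'   `type` (one of [INTERACTION_TYPES]) and `weight` (in `[0,1]`). All
#'   endpoints must be in `nodes`; self-loops are rejected.
#' @param read_counts optional named numeric vector of sequencing read counts
#'   per node; missing nodes default to 0.
#' @param guild optional named character vector of guild labels per node.
#' @param meta list of free-form metadata (plot/field/site ids, level, ...).
#' @return an object of class `food_web`.
#' @export
food_web <- function(nodes, edges = NULL, read_counts = NULL, guild = NULL,
                     meta = list()) {
  nodes <- as.character(nodes)
  if (anyNA(nodes) || anyDuplicated(nodes) > 0)
    stop("nodes must be unique and non-NA")
  if (is.null(edges)) {
    edges <- data.frame(resource = character(), consumer = character(),
                        type = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("resource", "consumer") %in% names(edges)))
      stop("edges needs 'resource' and 'consumer' columns")
    if (is.null(edges$type)) edges$type <- rep("predation", nrow(edges))
    if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
    bad <- setdiff(c(edges$resource, edges$consumer), nodes)
    if (length(bad) > 0)
      stop("edge endpoints not in node set: ", paste(utils::head(bad, 5), collapse = ", "))
    if (any(edges$resource == edges$consumer))
      stop("self-loops are not allowed")
    if (any(edges$weight < 0 | edges$weight > 1))
      stop("edge weights must be in [0,1]")
  }
  rc <- stats::setNames(numeric(length(nodes)), nodes)
  if (!is.null(read_counts)) {
    keep <- intersect(names(read_counts), nodes)
    rc[keep] <- read_counts[keep]
  }
  g <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  if (!is.null(guild)) {
    keep <- intersect(names(guild), nodes)
    g[keep] <- guild[keep]
  }
  structure(list(nodes = nodes, edges = edges, read_counts = rc,
                 guild = g, meta = meta),
            class = "food_web")
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf("<food_web> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  if (length(x$meta) > 0)
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of edges in a web
#' @param web a [food_web()]
#' @return integer edge count
#' @export
n_links <- function(web) nrow(web$edges)

#' Convert a food web to an igraph object
#'
#' @param web a [food_web()]
#' @return an igraph directed graph, vertices in `web$nodes` order
#' @export
as_igraph <- function(web) {
  igraph::graph_from_data_frame(
    web$edges[, c("resource", "consumer", "type", "weight")],
    directed = TRUE,
    vertices = data.frame(name = web$nodes, stringsAsFactors = FALSE))
}

#' Binary adjacency matrix of a web (resource rows, consumer columns)
#'
#' @param web a [food_web()]
#' @return a 0/1 matrix with dimnames = node ids
#' @export
adjacency <- function(web) {
  n <- length(web$nodes)
  A <- matrix(0L, n, n, dimnames = list(web$nodes, web$nodes))
  if (nrow(web$edges) > 0)
    A[cbind(web$edges$resource, web$edges$consumer)] <- 1L
  A
}

# shared input checkers ------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop(sprintf("%s must be an integer >= %d", name, min))
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a probability in [0,1]", name))
  as.numeric(x)
}

split_tags <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  names(out) <- names(x)
  out
}
join_tags <- function(x) vapply(x, paste, "", collapse = ";")
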