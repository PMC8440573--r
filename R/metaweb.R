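# Metaweb construction: compile the interaction knowledge base, generalize
# coarse-rank records across observed family/genus members, trim by habitat
# co-occurrence and geographic range, and extract plot-level local webs as
# induced subgraphs.

.rank_order <- stats::setNames(seq_along(EVIDENCE_RANKS), EVIDENCE_RANKS)

as_kb <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("resource", "consumer", "type", "evidence_rank")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("interaction records need columns: ", paste(miss, collapse = ", "))
  if (is.null(df$source_tag)) df$source_tag <- rep("", nrow(df))
  if (is.null(df$audit_only)) df$audit_only <- rep(FALSE, nrow(df))
  bad_type <- setdiff(unique(df$type), INTERACTION_TYPES)
  if (length(bad_type) > 0)
    stop("unknown interaction type(s): ", paste(bad_type, collapse = ", "))
  bad_rank <- setdiff(unique(df$evidence_rank), EVIDENCE_RANKS)
  if (length(bad_rank) > 0)
    stop("unknown evidence rank(s): ", paste(bad_rank, collapse = ", "))
  df
}

# a name is resolvable if it is a taxon id, or a genus or family present in
# the taxonomy (coarse-rank records are expanded later)
resolve_names <- function(x, taxonomy) {
  ifelse(x %in% taxonomy$taxon_id, "taxon",
         ifelse(x %in% taxonomy$genus, "genus",
                ifelse(x %in% taxonomy$family, "family", "unknown")))
}

#' Compile and deduplicate the interaction knowledge base
#'
#' Records whose resource or consumer cannot be resolved against the taxonomy
#' (as a taxon id, genus or family name) are diverted to a rejects report
#' rather than failing. Duplicate (resource, consumer) pairs are collapsed to
#' the record with the most specific evidence rank
#' (species > genus > family > generalized); among equal ranks the first
#' record wins.
#'
#' @param records data.frame of interaction records (resource, consumer, type,
#'   evidence_rank, optional source_tag).
#' @param taxonomy data.frame with taxon_id, family, genus columns.
#' @return the compiled KB data.frame, with attributes `report` (counts) and
#'   `rejects` (the unresolvable records).
#' @export
compile_kb <- function(records, taxonomy) {
  kb <- as_kb(records)
  res_r <- resolve_names(kb$resource, taxonomy)
  res_c <- resolve_names(kb$consumer, taxonomy)
  ok <- res_r != "unknown" & res_c != "unknown"
  rejects <- kb[!ok, , drop = FALSE]
  kb <- kb[ok, , drop = FALSE]
  # self-interactions at species level are biologically spurious here
  kb <- kb[!(kb$resource == kb$consumer & res_r[ok] == "taxon"), , drop = FALSE]
  if (nrow(kb) > 0) {
    ord <- order(.rank_order[kb$evidence_rank])
    kb <- kb[ord, , drop = FALSE]
    kb <- kb[!duplicated(kb[, c("resource", "consumer")]), , drop = FALSE]
    kb <- kb[order(kb$resource, kb$consumer), , drop = FALSE]
    row.names(kb) <- NULL
  }
  attr(kb, "report") <- list(n_in = nrow(records), n_kept = nrow(kb),
                             n_rejected = nrow(rejects))
  attr(kb, "rejects") <- rejects
  kb
}

#' Expand genus- and family-rank records to observed member taxa
#'
#' A record whose resource or consumer names a genus or family (rather than a
#' taxon id) is expanded to one record per observed member taxon of that rank
#' (the cross product when both sides are coarse). Expanded records are tagged
#' `evidence_rank = "generalized"`; the coarse original is retained with
#' `audit_only = TRUE` and is excluded from graph construction. Names absent
#' from the taxonomy pass through unexpanded with a warning.
#'
#' @param kb compiled KB data.frame.
#' @param taxonomy data.frame with taxon_id, family, genus.
#' @return expanded KB data.frame (deduplicated, taxon-level records keep
#'   their original rank where they already existed).
#' @export
generalize_within_families <- function(kb, taxonomy) {
  kb <- as_kb(kb)
  if (nrow(kb) == 0) return(kb)
  members <- function(name) {
    if (name %in% taxonomy$taxon_id) return(name)
    hits <- taxonomy$taxon_id[taxonomy$genus == name | taxonomy$family == name]
    hits
  }
  kind_r <- resolve_names(kb$resource, taxonomy)
  kind_c <- resolve_names(kb$consumer, taxonomy)
  unknown <- kind_r == "unknown" | kind_c == "unknown"
  if (any(unknown & !kb$audit_only))
    warning(sum(unknown), " record(s) reference names absent from the taxonomy;",
            " passed through unexpanded")
  coarse <- (kind_r %in% c("genus", "family") |
               kind_c %in% c("genus", "family")) & !kb$audit_only
  out <- list(kb[!coarse, , drop = FALSE])
  for (i in which(coarse)) {
    r <- members(kb$resource[i]); cns <- members(kb$consumer[i])
    audit <- kb[i, , drop = FALSE]
    audit$audit_only <- TRUE
    out[[length(out) + 1L]] <- audit
    if (length(r) == 0 || length(cns) == 0) next
    grid <- expand.grid(resource = r, consumer = cns,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$resource != grid$consumer, , drop = FALSE]
    if (nrow(grid) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      grid, type = kb$type[i], evidence_rank = "generalized",
      source_tag = kb$source_tag[i], audit_only = FALSE,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  live <- res[!res$audit_only, , drop = FALSE]
  if (nrow(live) > 0) {
    ord <- order(.rank_order[live$evidence_rank])
    live <- live[ord, , drop = FALSE]
    live <- live[!duplicated(live[, c("resource", "consumer")]), , drop = FALSE]
  }
  res <- rbind(live, res[res$audit_only, , drop = FALSE])
  res <- res[order(res$audit_only, res$resource, res$consumer), , drop = FALSE]
  row.names(res) <- NULL
  res
}

annotation_lookup <- function(annotations, col) {
  stats::setNames(annotations[[col]], annotations$taxon_id)
}

#' Trim the KB to pairs that can co-occur in a soil layer
#'
#' An interaction is kept iff the habitat-layer sets of resource and consumer
#' intersect. Taxa with missing habitat annotation are treated permissively
#' (edge kept, warning): trimming applies only where non-co-occurrence is
#' known. Audit-only rows are untouched.
#'
#' @param kb KB data.frame (taxon-level records).
#' @param annotations data.frame with taxon_id and `habitat_layers`
#'   (semicolon-separated subset of [HABITAT_LAYERS]).
#' @return filtered KB with attribute `n_removed`.
#' @export
filter_by_habitat <- function(kb, annotations) {
  kb <- as_kb(kb)
  if (nrow(kb) == 0) { attr(kb, "n_removed") <- 0L; return(kb) }
  layers <- split_tags(annotation_lookup(annotations, "habitat_layers"))
  get_layers <- function(x) layers[[x]]
  live <- !kb$audit_only
  known_r <- kb$resource %in% names(layers)
  known_c <- kb$consumer %in% names(layers)
  missing_ann <- live & !(known_r & known_c)
  if (any(missing_ann))
    warning(sum(missing_ann),
            " edge(s) kept despite missing habitat annotation")
  keep <- rep(TRUE, nrow(kb))
  idx <- which(live & known_r & known_c)
  keep[idx] <- vapply(idx, function(i)
    length(intersect(get_layers(kb$resource[i]), get_layers(kb$consumer[i]))) > 0,
    TRUE)
  out <- kb[keep, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trim taxa (and their interactions) by geographic range
#'
#' Non-microorganism taxa lacking the target region among their geographic
#' tags are dropped together with all incident edges; microorganisms are
#' always retained (broad-distribution assumption).
#'
#' @param kb KB data.frame.
#' @param annotations data.frame with taxon_id, `geographic_tags`
#'   (semicolon-separated), `is_microorganism`.
#' @param target_region region label required for macro-organisms.
#' @return filtered KB with attributes `dropped_taxa` and `n_removed`.
#' @export
filter_by_geography <- function(kb, annotations, target_region = "temperate_europe") {
  kb <- as_kb(kb)
  tags <- split_tags(annotation_lookup(annotations, "geographic_tags"))
  micro <- annotation_lookup(annotations, "is_microorganism")
  in_region <- vapply(annotations$taxon_id, function(t)
    isTRUE(micro[[t]]) || target_region %in% tags[[t]], TRUE)
  dropped <- annotations$taxon_id[!in_region]
  live <- !kb$audit_only
  keep <- !(live & (kb$resource %in% dropped | kb$consumer %in% dropped))
  out <- kb[keep, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "dropped_taxa") <- dropped
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Assemble the metaweb from observed taxa and the filtered KB
#'
#' Nodes are all observed taxa -- including taxa with no known interaction,
#' kept as isolated nodes so they still count towards richness. Edges are the
#' non-audit KB records whose endpoints are both observed. Cycles are allowed.
#'
#' @param annotations data.frame of observed taxa (taxon_id, guild, ...).
#' @param kb filtered, taxon-level KB.
#' @return a [food_web()] with `meta$level = "metaweb"`.
#' @export
build_metaweb <- function(annotations, kb) {
  ids <- annotations$taxon_id
  if (length(ids) == 0) stop("empty taxa list")
  kb <- as_kb(kb)
  kb <- kb[!kb$audit_only & kb$resource %in% ids & kb$consumer %in% ids, ,
           drop = FALSE]
  edges <- if (nrow(kb) > 0)
    data.frame(resource = kb$resource, consumer = kb$consumer,
               type = kb$type, weight = 1, stringsAsFactors = FALSE) else NULL
  food_web(nodes = ids,
           edges = edges,
           guild = annotation_lookup(annotations, "guild"),
           meta = list(level = "metaweb"))
}

#' Extract the local food web of one plot
#'
#' The node set is the union (default) or intersection of the four replicate
#' taxa lists; edges are induced from the metaweb (an edge is present iff both
#' endpoints were detected). Read counts are summed over replicates. Each edge
#' is weighted by the product of the two endpoints' replicate detection
#' fractions -- the probability of co-occurrence of the resource/consumer pair.
#'
#' @param metaweb a [food_web()] from [build_metaweb()].
#' @param plot_detections data.frame rows for one plot: taxon_id and read
#'   counts `rep1..rep4` (0 = not detected in that replicate).
#' @param aggregate `"union"` (default) or `"intersection"` of replicates.
#' @return a [food_web()] with plot/field/site ids in `meta`.
#' @export
extract_local_web <- function(metaweb, plot_detections,
                              aggregate = c("union", "intersection")) {
  aggregate <- match.arg(aggregate)
  pd <- as.data.frame(plot_detections, stringsAsFactors = FALSE)
  repcols <- c("rep1", "rep2", "rep3", "rep4")
  stopifnot(all(c("taxon_id", repcols) %in% names(pd)))
  det <- as.matrix(pd[, repcols]) > 0
  n_det <- rowSums(det)
  keep <- if (aggregate == "union") n_det > 0 else n_det == ncol(det)
  pd <- pd[keep, , drop = FALSE]
  if (nrow(pd) == 0) {
    warning("no detected taxa in plot; returning empty web")
    return(food_web(character(0),
                    meta = c(as.list(pd[0, intersect(c("plot_id", "field_id",
                                                       "site_id"), names(pd))]),
                             level = "local")))
  }
  detfrac <- stats::setNames(rowSums(det[keep, , drop = FALSE]) / ncol(det),
                             pd$taxon_id)
  reads <- stats::setNames(rowSums(pd[, repcols]), pd$taxon_id)
  e <- metaweb$edges
  e <- e[e$resource %in% pd$taxon_id & e$consumer %in% pd$taxon_id, ,
         drop = FALSE]
  if (nrow(e) > 0)
    e$weight <- detfrac[e$resource] * detfrac[e$consumer]
  meta <- list(level = "local")
  for (col in c("plot_id", "field_id", "site_id"))
    if (col %in% names(pd)) meta[[col]] <- pd[[col]][1]
  food_web(nodes = pd$taxon_id, edges = e, read_counts = reads,
           guild = metaweb$guild[intersect(pd$taxon_id, names(metaweb$guild))],
           meta = meta)
}

#' Extract local webs for all plots of a scenario
#'
#' @param metaweb a [food_web()].
#' @param observations detection table with plot_id and rep1..rep4 columns.
#' @param aggregate replicate aggregation mode, see [extract_local_web()].
#' @return named list of [food_web()]s, one per plot.
#' @export
extract_all_webs <- function(metaweb, observations, aggregate = "union") {
  webs <- lapply(split(observations, observations$plot_id),
                 extract_local_web, metaweb = metaweb, aggregate = aggregate)
  webs[order(names(webs))]
}
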