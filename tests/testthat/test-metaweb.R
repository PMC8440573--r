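kb_record <- function(resource, consumer, type = "predation",
                      rank = "species", tag = "") {
  n <- length(resource)
  data.frame(resource = resource, consumer = consumer,
             type = rep_len(type, n), evidence_rank = rep_len(rank, n),
             source_tag = rep_len(tag, n), stringsAsFactors = FALSE)
}

test_that("compile_kb deduplicates and applies rank precedence", {
  tax <- toy_taxonomy()
  # identical duplicates collapse
  kb <- compile_kb(rbind(kb_record("sp1", "sp5"), kb_record("sp1", "sp5")), tax)
  expect_equal(nrow(kb), 1)
  # most specific evidence wins regardless of type
  recs <- rbind(kb_record("sp2", "sp1", type = "parasitism", rank = "family"),
                kb_record("sp2", "sp1", type = "predation", rank = "species"))
  kb <- compile_kb(recs, tax)
  expect_equal(nrow(kb), 1)
  expect_equal(kb$evidence_rank, "species")
  expect_equal(kb$type, "predation")
  # unknown taxa go to the rejects report, not an error
  recs <- rbind(kb_record("sp1", "sp5"), kb_record("ghost", "sp5"))
  kb <- compile_kb(recs, tax)
  expect_equal(nrow(kb), 1)
  expect_equal(nrow(attr(kb, "rejects")), 1)
  expect_equal(attr(kb, "report")$n_rejected, 1)
})

test_that("compile_kb survivor count equals the set-union oracle", {
  set.seed(42)
  tax <- data.frame(taxon_id = sprintf("t%02d", 1:20),
                    phylum = "P", family = "F", genus = "G",
                    species = sprintf("s%02d", 1:20),
                    stringsAsFactors = FALSE)
  pairs <- expand.grid(resource = tax$taxon_id, consumer = tax$taxon_id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$resource != pairs$consumer, ]
  base <- pairs[sample.int(nrow(pairs), 40), ]
  dup <- base[sample.int(40, 10), ]
  recs <- kb_record(c(base$resource, dup$resource),
                    c(base$consumer, dup$consumer))
  kb <- compile_kb(recs, tax)
  oracle_n <- nrow(unique(base[, c("resource", "consumer")]))
  expect_equal(nrow(kb), oracle_n)
  expect_equal(nrow(kb), 40)
})

test_that("family/genus records expand to observed members", {
  tax <- toy_taxonomy()
  # genus-level resource with 2 members -> 2 edges; family (3 members) -> 3
  kb <- compile_kb(kb_record("FunG1", "sp1", rank = "genus"), tax)
  kb <- generalize_within_families(kb, tax)
  live <- kb[!kb$audit_only, ]
  expect_equal(nrow(live), 2)
  expect_setequal(live$resource, c("sp2", "sp3"))
  expect_true(all(live$evidence_rank == "generalized"))
  expect_equal(sum(kb$audit_only), 1)  # coarse original kept for audit
  kb2 <- generalize_within_families(
    compile_kb(kb_record("FunF", "sp1", rank = "family"), tax), tax)
  expect_equal(nrow(kb2[!kb2$audit_only, ]), 3)
  # species-rank record passes through unchanged
  kb3 <- generalize_within_families(
    compile_kb(kb_record("sp2", "sp1"), tax), tax)
  expect_equal(kb3$resource, "sp2")
  expect_equal(kb3$evidence_rank, "species")
  # name absent from the taxonomy: warning, no expansion, no graph edges
  raw <- kb_record("GhostFam", "sp1", rank = "family")
  raw$audit_only <- FALSE
  expect_warning(kb4 <- generalize_within_families(raw, tax), "absent")
  mw <- build_metaweb(toy_annotations(), kb4)
  expect_equal(n_links(mw), 0)
})

test_that("habitat filter keeps exactly the co-occurring pairs", {
  ann <- toy_annotations()
  # sp1 {0-10cm} vs sp4 {>10cm}: disjoint -> removed
  kb <- filter_by_habitat(kb_record("sp1", "sp4"), ann)
  expect_equal(nrow(kb), 0)
  expect_equal(attr(kb, "n_removed"), 1)
  # shared 0-10cm -> kept
  kb <- filter_by_habitat(kb_record("sp1", "sp3"), ann)
  expect_equal(nrow(kb), 1)
  # missing annotation -> kept with warning
  expect_warning(kb <- filter_by_habitat(kb_record("sp1", "spX"), ann),
                 "missing habitat")
  expect_equal(nrow(kb), 1)
})

test_that("habitat filter equals the pairwise-intersection oracle", {
  set.seed(7)
  n <- 40
  ids <- sprintf("t%02d", seq_len(n))
  layer_sets <- lapply(seq_len(n), function(i)
    sample(HABITAT_LAYERS, sample(1:3, 1)))
  ann <- data.frame(taxon_id = ids,
                    guild = "predator",
                    habitat_layers = vapply(layer_sets, paste, "",
                                            collapse = ";"),
                    geographic_tags = "temperate_europe",
                    is_microorganism = FALSE, stringsAsFactors = FALSE)
  pairs <- expand.grid(resource = ids, consumer = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$resource != pairs$consumer, ]
  recs <- kb_record(pairs$resource[1:100], pairs$consumer[1:100])
  out <- filter_by_habitat(recs, ann)
  keep_oracle <- vapply(seq_len(100), function(k) {
    i <- match(recs$resource[k], ids); j <- match(recs$consumer[k], ids)
    length(intersect(layer_sets[[i]], layer_sets[[j]])) > 0
  }, TRUE)
  expect_setequal(paste(out$resource, out$consumer),
                  paste(recs$resource[keep_oracle], recs$consumer[keep_oracle]))
})

test_that("geography filter drops out-of-region macro-organisms only", {
  ann <- toy_annotations()
  # sp5 is non-micro and tagged tropical -> dropped with incident edges
  kb <- filter_by_geography(rbind(kb_record("sp1", "sp5"),
                                  kb_record("sp2", "sp1")), ann)
  expect_equal(nrow(kb), 1)
  expect_true("sp5" %in% attr(kb, "dropped_taxa"))
  # microorganism with empty tags retained (sp2)
  expect_false("sp2" %in% attr(kb, "dropped_taxa"))
  # oracle check on a randomized table
  set.seed(8)
  n <- 30
  ids <- sprintf("g%02d", seq_len(n))
  micro <- runif(n) < 0.4
  tagged <- runif(n) < 0.5
  ann2 <- data.frame(taxon_id = ids, guild = "predator",
                     habitat_layers = "0-10cm",
                     geographic_tags = ifelse(tagged, "temperate_europe",
                                              "tropical"),
                     is_microorganism = micro, stringsAsFactors = FALSE)
  kb2 <- filter_by_geography(kb_record(ids[1:29], ids[2:30]), ann2)
  survivors_oracle <- ids[micro | tagged]
  expect_setequal(attr(kb2, "dropped_taxa"), setdiff(ids, survivors_oracle))
  expect_true(all(kb2$resource %in% survivors_oracle))
  expect_true(all(kb2$consumer %in% survivors_oracle))
})

test_that("filters are contractive, idempotent and order-invariant", {
  cfg <- small_config(seed = 20)
  scen <- simulate_scenario(cfg)
  # randomize habitats so the filters actually bite
  set.seed(21)
  ann <- scen$annotations
  ann$habitat_layers <- vapply(seq_len(nrow(ann)), function(i)
    paste(sample(HABITAT_LAYERS, sample(1:2, 1)), collapse = ";"), "")
  ann$geographic_tags <- ifelse(runif(nrow(ann)) < 0.7, "temperate_europe",
                                "tropical")
  kb0 <- compile_kb(scen$kb, scen$taxonomy)
  h1 <- filter_by_habitat(kb0, ann)
  expect_lte(nrow(h1), nrow(kb0))
  h2 <- filter_by_habitat(h1, ann)
  expect_equal(h1$resource, h2$resource)
  expect_equal(h1$consumer, h2$consumer)
  g1 <- filter_by_geography(kb0, ann)
  g2 <- filter_by_geography(g1, ann)
  expect_equal(nrow(g1), nrow(g2))
  # order invariance
  hg <- filter_by_geography(filter_by_habitat(kb0, ann), ann)
  gh <- filter_by_habitat(filter_by_geography(kb0, ann), ann)
  expect_setequal(paste(hg$resource, hg$consumer),
                  paste(gh$resource, gh$consumer))
})

test_that("build_metaweb keeps isolates and restricts edges to observed taxa", {
  ann <- toy_annotations()
  kb <- rbind(kb_record("sp1", "sp5"), kb_record("sp2", "sp1"),
              kb_record("sp3", "sp1"), kb_record("sp9", "sp1"))
  mw <- build_metaweb(ann, kb)
  expect_equal(node_richness(mw), 5)
  expect_equal(n_links(mw), 3)
  # empty KB: valid edgeless metaweb
  mw0 <- build_metaweb(ann, kb_record(character(0), character(0)))
  expect_equal(n_links(mw0), 0)
  expect_equal(node_richness(mw0), 5)
  expect_error(build_metaweb(ann[0, ], kb), "empty")
})

test_that("synthetic metaweb equals planted KB restricted to observed taxa", {
  cfg <- small_config(seed = 22)
  scen <- simulate_scenario(cfg)
  kb <- compile_kb(scen$kb, scen$taxonomy)
  kb <- generalize_within_families(kb, scen$taxonomy)
  kb <- filter_by_geography(filter_by_habitat(kb, scen$annotations),
                            scen$annotations)
  mw <- build_metaweb(scen$annotations, kb)
  # default annotations share a layer and the region, so nothing is trimmed:
  # metaweb edge set == planted KB edge set
  expect_setequal(paste(mw$edges$resource, mw$edges$consumer),
                  paste(scen$kb$resource, scen$kb$consumer))
})

test_that("local webs are induced subgraphs with co-detection weights", {
  ann <- toy_annotations()
  kb <- rbind(kb_record("sp1", "sp5"), kb_record("sp2", "sp5"),
              kb_record("sp3", "sp4"))
  mw <- build_metaweb(ann, kb)
  pd <- data.frame(plot_id = "p1", field_id = "f1", site_id = "s1",
                   taxon_id = c("sp1", "sp5", "sp3"),
                   rep1 = c(10, 5, 1), rep2 = c(3, 0, 1),
                   rep3 = c(2, 0, 1), rep4 = c(1, 5, 1),
                   stringsAsFactors = FALSE)
  lw <- extract_local_web(mw, pd)
  expect_setequal(lw$nodes, c("sp1", "sp5", "sp3"))
  expect_equal(n_links(lw), 1)  # only sp1 -> sp5 has both endpoints
  # sp1 in 4/4 replicates, sp5 in 2/4 -> weight 1 * 0.5
  expect_equal(lw$edges$weight, 0.5)
  expect_equal(unname(lw$read_counts["sp1"]), 16)
  # intersection mode keeps only taxa seen in all four replicates
  lw2 <- extract_local_web(mw, pd, aggregate = "intersection")
  expect_setequal(lw2$nodes, c("sp1", "sp3"))
  expect_warning(extract_local_web(mw, pd[0, ]), "no detected taxa")
})

test_that("every local web is an induced subgraph of the metaweb", {
  cfg <- small_config(seed = 23)
  scen <- simulate_scenario(cfg)
  kb <- compile_kb(scen$kb, scen$taxonomy)
  mw <- build_metaweb(scen$annotations, kb)
  webs <- extract_all_webs(mw, scen$observations)
  mw_edges <- paste(mw$edges$resource, mw$edges$consumer)
  for (w in webs[1:8]) {
    expect_true(all(w$nodes %in% mw$nodes))
    expect_true(all(paste(w$edges$resource, w$edges$consumer) %in% mw_edges))
    # induced: every metaweb edge between detected nodes is present
    sub <- mw$edges[mw$edges$resource %in% w$nodes &
                      mw$edges$consumer %in% w$nodes, ]
    expect_equal(n_links(w), nrow(sub))
    # node set equals the union of the four replicate lists (oracle)
    obs <- scen$observations[scen$observations$plot_id == w$meta$plot_id, ]
    expect_setequal(w$nodes, obs$taxon_id)
  }
})
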