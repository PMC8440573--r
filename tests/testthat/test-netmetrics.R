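test_that("richness, degree and link density on simple webs", {
  w3 <- food_web(c("a", "b", "c"))
  expect_equal(node_richness(w3), 3)
  expect_equal(node_richness(food_web(character(0))), 0)
  expect_equal(average_degree(w3), 0)
  expect_equal(link_density(w3), 0)
  one <- food_web(c("a", "b"), data.frame(resource = "a", consumer = "b"))
  expect_equal(average_degree(one), 1.0)
  # complete digraph n=4: L = 12, average degree 6, density 3
  A <- matrix(1L, 4, 4); diag(A) <- 0L
  k4 <- web_from_adjacency(A)
  expect_equal(average_degree(k4), 6.0)
  expect_equal(link_density(k4), 3.0)
})

test_that("group richness and entropy follow their definitions", {
  w <- food_web(c("a", "b", "c", "d"))
  memb <- c(a = 1, b = 2, c = 2, d = 5)
  expect_equal(trophic_group_richness(w, memb), 3)
  expect_equal(trophic_group_richness(w, c(a = 1, b = 1, c = 1, d = 1)), 1)
  expect_error(trophic_group_richness(w, c(a = 1)), "without a group")
  # uniform counts over 4 groups: Hill = 4; single group: 1
  rc <- c(a = 10, b = 10, c = 10, d = 10)
  expect_equal(trophic_group_entropy(rc, c(a = 1, b = 2, c = 3, d = 4)), 4.0)
  expect_equal(trophic_group_entropy(rc, c(a = 1, b = 1, c = 1, d = 1)), 1.0)
  # p = (0.5, 0.25, 0.25), q = 1 -> exp(1.5 ln 2) = 2.828427...
  rc2 <- c(a = 2, b = 1, c = 1)
  expect_equal(trophic_group_entropy(rc2, c(a = 1, b = 2, c = 3)),
               2^1.5, tolerance = 1e-12)
  expect_error(trophic_group_entropy(c(a = 0), c(a = 1)), "zero")
})

test_that("trophic levels solve the defining equation", {
  ch <- chain_web()
  tl <- trophic_levels(ch)
  expect_equal(as.numeric(tl), c(1, 2, 3, 4))
  expect_equal(mean_trophic_level(ch), 2.5)
  # consumer eating one TL-1 and one TL-2 resource: 1 + (1+2)/2 = 2.5
  w <- food_web(c("x", "y", "z"),
                data.frame(resource = c("x", "x", "y"),
                           consumer = c("y", "z", "z")))
  expect_equal(unname(trophic_levels(w)["z"]), 2.5)
  # random DAGs match the fixed-point oracle and have tiny residuals
  for (s in 1:5) {
    web <- random_dag_web(15, 0.3, seed = 600 + s)
    tl <- trophic_levels(web)
    expect_equal(as.numeric(tl),
                 unname(oracle_trophic_levels(web)[web$nodes]),
                 tolerance = 1e-8)
    expect_lt(attr(tl, "residual"), 1e-8)
    expect_false(attr(tl, "damped"))
  }
})

test_that("cycles unreachable from basal nodes are damped and flagged", {
  w <- food_web(c("a", "b"),
                data.frame(resource = c("a", "b"), consumer = c("b", "a")))
  tl <- trophic_levels(w)
  expect_true(attr(tl, "damped"))
  expect_true(all(is.finite(tl)))
})

test_that("omnivory is the mean population SD of resource levels", {
  # consumer of TLs {1, 3}: population SD = 1
  w <- food_web(c("a", "b", "c", "k"),
                data.frame(resource = c("a", "b", "a", "c"),
                           consumer = c("b", "c", "k", "k")))
  tl <- trophic_levels(w)
  expect_equal(as.numeric(tl), c(1, 2, 3, 3))  # k eats a (1) and c (3)
  expect_equal(omnivory_level(chain_web()), 0)  # single-resource consumers
  # direct-SD oracle on a random DAG
  for (s in 1:3) {
    web <- random_dag_web(12, 0.35, seed = 700 + s)
    tl <- trophic_levels(web)
    cons <- unique(web$edges$consumer)
    ov <- vapply(cons, function(cn) {
      r <- web$edges$resource[web$edges$consumer == cn]
      sqrt(mean((tl[r] - mean(tl[r]))^2))
    }, 0)
    expect_equal(omnivory_level(web),
                 if (length(ov)) mean(ov) else 0, tolerance = 1e-10)
  }
})

test_that("path lengths match Floyd-Warshall", {
  # chain of 4: finite distances {1,1,1,2,2,3} -> mean 10/6, max 3
  pl <- path_lengths(chain_web())
  expect_equal(pl$average, 10 / 6)
  expect_equal(pl$maximum, 3L)
  expect_equal(pl$n_pairs, 6L)
  # complete digraph: average 1, max 1
  A <- matrix(1L, 5, 5); diag(A) <- 0L
  pl <- path_lengths(web_from_adjacency(A))
  expect_equal(pl$average, 1)
  expect_equal(pl$maximum, 1L)
  # edgeless: undefined
  pl0 <- path_lengths(food_web(c("a", "b")))
  expect_true(is.na(pl0$average))
  expect_equal(pl0$maximum, 0L)
  # random graphs: exact equality with the brute-force oracle
  for (s in 1:5) {
    A <- random_digraph(25, 0.12, seed = 800 + s)
    D <- oracle_floyd_warshall(A)
    fin <- is.finite(D)
    pl <- path_lengths(web_from_adjacency(A))
    expect_equal(pl$average, mean(D[fin]))
    expect_equal(pl$maximum, as.integer(max(D[fin])))
    expect_equal(pl$n_pairs, sum(fin))
  }
})

test_that("parasitic link percentage counts typed edges", {
  expect_equal(pct_parasitic_links(chain_web()), 100 / 3)
  set.seed(9)
  A <- random_digraph(10, 0.3, seed = 9)
  L <- sum(A)
  types <- rep("predation", L); types[1:2] <- "parasitism"
  w <- web_from_adjacency(A, types = types)
  expect_equal(pct_parasitic_links(w), 100 * 2 / L)
  expect_true(is.na(pct_parasitic_links(food_web("a"))))
})

test_that("channel path totals follow the nearest-seed definition", {
  # bacteria seed with a 3-consumer chain: 1 + 2 + 3; fungal seed with one
  # consumer: 1; ratio 6
  w <- food_web(c("b", "c1", "c2", "c3", "f", "g"),
                data.frame(resource = c("b", "c1", "c2", "f"),
                           consumer = c("c1", "c2", "c3", "g")),
                guild = c(b = "bacteria_decomposer", c1 = "other_consumer",
                          c2 = "other_consumer", c3 = "other_consumer",
                          f = "fungi_saprotroph", g = "other_consumer"))
  expect_equal(channel_total_path(w, "bacteria_decomposer"), 6)
  expect_equal(channel_total_path(w, "fungi_saprotroph"), 1)
  expect_equal(channel_path_ratio(w, "bacteria_decomposer",
                                  "fungi_saprotroph"), 6.0)
  # symmetric channels give ratio 1
  expect_equal(channel_path_ratio(w, "fungi_saprotroph", "fungi_saprotroph"),
               1.0)
  # empty denominator channel -> undefined
  expect_true(is.na(channel_path_ratio(w, "bacteria_decomposer",
                                       "detritivore")))
})

test_that("network_metrics assembles the full record", {
  rec <- network_metrics(chain_web(),
                         membership = c(A = 1, B = 1, C = 2, D = 2))
  expect_equal(rec$node_richness, 4)
  expect_equal(rec$trophic_group_richness, 2)
  expect_equal(rec$average_degree, 1.5)
  expect_equal(rec$mean_trophic_level, 2.5)
  expect_equal(rec$omnivory_level, 0)
  expect_equal(rec$link_density, 0.75)
  expect_equal(rec$average_path_length, 10 / 6)
  expect_equal(rec$max_path_length, 3L)
  expect_equal(rec$pct_parasitic_links, 100 / 3)
  # read counts (40,30,20,10) over groups {A,B} vs {C,D}: p = (0.7, 0.3)
  expect_equal(rec$trophic_group_entropy, oracle_hill(c(0.7, 0.3), 1),
               tolerance = 1e-10)
  # empty web: S = 0 and undefined metrics are NA
  empty <- network_metrics(food_web(character(0)))
  expect_equal(empty$node_richness, 0)
  expect_true(is.na(empty$link_density))
  # idempotence
  expect_identical(rec, network_metrics(
    chain_web(), membership = c(A = 1, B = 1, C = 2, D = 2)))
})

test_that("metric identities and relabelling invariance hold", {
  for (s in 1:20) {
    A <- random_digraph(sample(5:25, 1), runif(1, 0.05, 0.4), seed = 900 + s)
    w <- web_from_adjacency(A)
    expect_equal(average_degree(w), 2 * link_density(w), tolerance = 1e-12)
    expect_equal(link_density(w), sum(A) / nrow(A), tolerance = 1e-12)
  }
  # relabelling: permute node ids, metrics unchanged
  A <- random_digraph(12, 0.25, seed = 950)
  w1 <- web_from_adjacency(A)
  perm <- sample(12)
  w2 <- web_from_adjacency(A[perm, perm])
  m1 <- network_metrics(w1); m2 <- network_metrics(w2)
  for (col in c("node_richness", "average_degree", "mean_trophic_level",
                "omnivory_level", "link_density", "average_path_length",
                "max_path_length"))
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-9)
})
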