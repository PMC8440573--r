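# Synthetic scenario generator: a 4-site x 4-field x 4-plot design with a
# planted block-structured interaction network and land-use-dependent taxon
# loss, so every downstream stage has a known ground truth.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe the stated world the package is tested against: sixteen
#' fields in four sites, four sampling plots per field, a regional pool of 120
#' taxa partitioned into 4 planted trophic blocks, and a land-use intensity
#' (LUI) gradient that preferentially removes taxa of sensitive guilds.
#'
#' @param n_sites,fields_per_site,plots_per_field study design counts.
#' @param n_taxa number of taxa in the regional pool.
#' @param n_groups planted number of trophic blocks (Q).
#' @param pi_within,pi_between probability of a directed interaction between
#'   two taxa of the same / of different planted blocks.
#' @param guild_proportions named simplex over [GUILDS] (sums to 1).
#' @param lui_slope_per_metric named numeric: planted per-unit-LUI slopes used
#'   by [simulate_metric_response()] for direct response simulations.
#' @param site_sd standard deviation of the random site offsets added to the
#'   evenly spaced LUI gradient (and of site intercepts in direct response
#'   simulations).
#' @param residual_sd residual standard deviation for direct response
#'   simulations.
#' @param detection_decay per-unit-LUI decline (on the logit scale) of the
#'   detection probability of sensitive-guild taxa; other guilds decline at
#'   half this rate. 0 disables the planted land-use effect.
#' @param base_detection plot-level detection probability at LUI = 0.
#' @param replicate_detection probability that a taxon present in a plot is
#'   detected in any one of the four PCR replicates.
#' @param parasitic_edge_prob probability that an edge whose consumer is a
#'   parasite-guild taxon is typed `parasitism` (otherwise `predation`).
#' @param sensitive_guilds guilds whose detection declines fastest with LUI.
#' @param criteria_noise_sd noise standard deviation of management criteria
#'   around their loading on the latent intensity axis.
#' @param seed integer master seed; all sub-generators derive fixed offsets
#'   from it so regenerating one table never reshuffles another.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 4, fields_per_site = 4, plots_per_field = 4,
                            n_taxa = 150, n_groups = 12,
                            pi_within = 0.8, pi_between = 0.05,
                            guild_proportions = c(
                              bacteria_decomposer = 0.25, fungi_saprotroph = 0.20,
                              detritivore = 0.10, root_herbivore = 0.10,
                              parasite = 0.10, predator = 0.15,
                              other_basal = 0.05, other_consumer = 0.05),
                            lui_slope_per_metric = c(link_density = -0.5,
                                                     trophic_group_richness = -0.5),
                            site_sd = 0.3, residual_sd = 0.2,
                            detection_decay = 0.8,
                            base_detection = 0.45, replicate_detection = 0.8,
                            parasitic_edge_prob = 0.9,
                            sensitive_guilds = c("parasite", "fungi_saprotroph"),
                            criteria_noise_sd = 0.3,
                            seed = 1L) {
  cfg <- list(
    n_sites = assert_count(n_sites, "n_sites"),
    fields_per_site = assert_count(fields_per_site, "fields_per_site"),
    plots_per_field = assert_count(plots_per_field, "plots_per_field"),
    n_taxa = assert_count(n_taxa, "n_taxa"),
    n_groups = assert_count(n_groups, "n_groups"),
    pi_within = assert_prob(pi_within, "pi_within"),
    pi_between = assert_prob(pi_between, "pi_between"),
    guild_proportions = guild_proportions,
    lui_slope_per_metric = lui_slope_per_metric,
    site_sd = site_sd, residual_sd = residual_sd,
    detection_decay = detection_decay,
    base_detection = assert_prob(base_detection, "base_detection"),
    replicate_detection = assert_prob(replicate_detection, "replicate_detection"),
    parasitic_edge_prob = assert_prob(parasitic_edge_prob, "parasitic_edge_prob"),
    sensitive_guilds = sensitive_guilds,
    criteria_noise_sd = criteria_noise_sd,
    seed = assert_count(seed, "seed", min = 0L))
  if (is.null(names(guild_proportions)) ||
      !all(names(guild_proportions) %in% GUILDS))
    stop("guild_proportions must be named with guilds from GUILDS")
  if (abs(sum(guild_proportions) - 1) > 1e-9)
    stop("guild_proportions must sum to 1")
  if (any(guild_proportions < 0)) stop("guild_proportions must be >= 0")
  if (cfg$n_groups > cfg$n_taxa) stop("n_groups cannot exceed n_taxa")
  if (site_sd < 0 || residual_sd < 0) stop("site_sd and residual_sd must be >= 0")
  class(cfg) <- "scenario_config"
  cfg
}

# fixed sub-stream offsets from the master seed
.seed_offsets <- c(taxa = 0L, kb = 1L, obs = 2L, criteria = 3L, response = 4L)

.with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

# guilds that are pure resources: they never consume other nodes
.BASAL_GUILDS <- c("bacteria_decomposer", "fungi_saprotroph", "other_basal")

# Partition the planted groups between the basal and consumer roles in
# proportion to the guild mix, and give every guild a "home" group inside its
# role (round-robin). Taxa join their guild's home group with probability
# `home_weight`, otherwise a uniform group of their role: planted groups are
# guild-coherent (as real trophic groups are) but not guild-pure.
planted_group_layout <- function(Q, guild_proportions) {
  if (Q == 1) {
    return(list(Q_basal = 0L,
                basal_groups = integer(0), consumer_groups = 1L))
  }
  p_basal <- sum(guild_proportions[names(guild_proportions) %in% .BASAL_GUILDS])
  Q_basal <- min(max(round(Q * p_basal), 1L), Q - 1L)
  list(Q_basal = as.integer(Q_basal),
       basal_groups = seq_len(Q_basal),
       consumer_groups = (Q_basal + 1L):Q)
}

# planted Q x Q connection-probability matrix. Each consumer group has one
# preferred diet group eaten with pi_within (everything else at pi_between):
# the first half of the consumer groups graze the basal groups (round-robin),
# the second half prey on first-half consumers, giving three-level energy
# channels (e.g. fungi -> fungivore -> predator). Columns of basal groups are
# structural zeros: basal resources never consume.
planted_pi_matrix <- function(Q, Q_basal, pi_within, pi_between) {
  pi <- matrix(pi_between, Q, Q)
  if (Q_basal > 0) pi[, seq_len(Q_basal)] <- 0
  consumers <- setdiff(seq_len(Q), seq_len(Q_basal))
  k <- length(consumers)
  h <- ceiling(k / 2)
  for (j in seq_len(k)) {
    r <- consumers[j]
    diet <- if (Q_basal == 0) r
    else if (j <= h) (j - 1L) %% Q_basal + 1L
    else consumers[j - h]
    pi[diet, r] <- pi_within
  }
  pi
}

.HOME_WEIGHT <- 0.75

#' Generate the regional taxa pool with taxonomy, guilds and planted blocks
#'
#' Taxa get a four-rank lineage (phylum, family, genus, species) consistent
#' with their guild, a single guild label, habitat layers (all taxa share the
#' 0-10 cm layer, so planted interactions survive habitat trimming), broad
#' temperate-Europe geography, and a planted trophic-block membership.
#' Planted blocks are guild-coherent: the blocks are split between a basal
#' role (bacteria, fungi, other basal resources) and a consumer role in
#' proportion to the guild mix, each guild has a home block within its role,
#' and a taxon joins its home block with probability 0.75 (else a uniform
#' block of its role). All blocks are guaranteed non-empty.
#'
#' @param config a [scenario_config()].
#' @return list with `taxonomy` (data.frame: taxon_id, phylum, family, genus,
#'   species), `annotations` (data.frame: taxon_id, guild, habitat_layers,
#'   geographic_tags, is_microorganism), and `truth` (list: membership, role,
#'   Q_basal, pi (planted group-pair probabilities), true_slopes; `true_lui`
#'   is filled in by [generate_field_observations()]).
#' @export
generate_taxa_pool <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  .with_seed(config$seed + .seed_offsets[["taxa"]], {
    n <- config$n_taxa
    ids <- sprintf("t%04d", seq_len(n))
    guild <- sample(names(config$guild_proportions), n, replace = TRUE,
                    prob = config$guild_proportions)
    phyla_by_guild <- list(
      bacteria_decomposer = c("Proteobacteria", "Actinobacteria", "Firmicutes"),
      fungi_saprotroph = c("Ascomycota", "Basidiomycota", "Mucoromycota"),
      detritivore = c("Annelida", "Arthropoda"),
      root_herbivore = c("Nematoda", "Arthropoda"),
      parasite = c("Nematoda", "Apicomplexa"),
      predator = c("Arthropoda", "Nematoda"),
      other_basal = c("Cercozoa", "Ciliophora"),
      other_consumer = c("Rotifera", "Tardigrada"))
    phylum <- vapply(guild, function(g) sample(phyla_by_guild[[g]], 1), "")
    n_fam <- max(2L, ceiling(n / 8))
    family <- sprintf("fam_%s_%02d", substr(guild, 1, 4),
                      sample.int(n_fam, n, replace = TRUE) %% 6 + 1)
    genus <- sprintf("gen_%s_%02d", substr(family, 5, 12),
                     sample.int(3L, n, replace = TRUE))
    species <- sprintf("%s_sp%04d", genus, seq_len(n))
    taxonomy <- data.frame(taxon_id = ids, phylum = phylum, family = family,
                           genus = genus, species = species,
                           stringsAsFactors = FALSE, row.names = NULL)

    # planted blocks: guild-coherent home-group assignment within roles
    Q <- config$n_groups
    layout <- planted_group_layout(Q, config$guild_proportions)
    role <- ifelse(guild %in% .BASAL_GUILDS, "basal", "consumer")
    draw_membership <- function() {
      z <- integer(n)
      for (r in c("basal", "consumer")) {
        grp <- if (Q == 1) 1L
        else if (r == "basal") layout$basal_groups else layout$consumer_groups
        if (length(grp) == 0) grp <- seq_len(Q)
        guilds_r <- intersect(names(config$guild_proportions),
                              unique(guild[role == r]))
        home <- stats::setNames(
          grp[(seq_along(guilds_r) - 1L) %% length(grp) + 1L], guilds_r)
        idx <- which(role == r)
        for (i in idx) {
          z[i] <- if (stats::runif(1) < .HOME_WEIGHT) home[[guild[i]]]
          else grp[sample.int(length(grp), 1)]
        }
      }
      z
    }
    membership <- draw_membership()
    tries <- 0L
    while (length(unique(membership)) < Q && tries < 100L) {
      membership <- draw_membership()
      tries <- tries + 1L
    }
    if (length(unique(membership)) < Q) {
      # tiny pools: force coverage while respecting roles where possible
      missing <- setdiff(seq_len(Q), unique(membership))
      membership[sample.int(n, length(missing))] <- missing
    }
    names(membership) <- ids

    micro <- guild %in% c("bacteria_decomposer", "fungi_saprotroph",
                          "other_basal")
    layers <- lapply(seq_len(n), function(i) {
      if (micro[i]) return(HABITAT_LAYERS)
      extra <- HABITAT_LAYERS[c(1, 3)][stats::runif(2) < 0.5]
      unique(c("0-10cm", extra))
    })
    annotations <- data.frame(
      taxon_id = ids, guild = unname(guild),
      habitat_layers = join_tags(layers),
      geographic_tags = "temperate_europe",
      is_microorganism = micro,
      stringsAsFactors = FALSE, row.names = NULL)

    truth <- list(membership = membership,
                  role = stats::setNames(role, ids),
                  Q_basal = layout$Q_basal,
                  pi = planted_pi_matrix(Q, layout$Q_basal,
                                         config$pi_within, config$pi_between),
                  true_lui = NULL,
                  true_slopes = config$lui_slope_per_metric)
    list(taxonomy = taxonomy, annotations = annotations, truth = truth)
  })
}

#' Planted taxon-pair interaction probabilities
#'
#' The matrix of independent edge probabilities implied by the planted SBM:
#' `P(i -> j) = pi[z_i, z_j]` when taxon j belongs to a consumer guild, 0 when
#' j is basal (basal resources never consume); no self-loops.
#'
#' @param taxa output of [generate_taxa_pool()].
#' @param truth ground truth with `membership`, `role`, `pi`.
#' @return n x n probability matrix (rows = resource, cols = consumer)
#' @export
planted_edge_probabilities <- function(taxa, truth) {
  ids <- taxa$taxonomy$taxon_id
  z <- truth$membership[ids]
  p <- truth$pi[z, z, drop = FALSE]
  p[, truth$role[ids] == "basal"] <- 0
  diag(p) <- 0
  dimnames(p) <- list(ids, ids)
  p
}

#' Generate the planted interaction knowledge base
#'
#' Directed edges are sampled independently with the planted block
#' probabilities of [planted_edge_probabilities()]: a consumer group feeds on
#' its diet group with `pi_within` and on any other group with `pi_between`;
#' basal-guild taxa never consume; no self-loops. Edges whose consumer
#' belongs to the parasite guild are typed `parasitism` with probability
#' `parasitic_edge_prob`, all other edges are `predation`. All records carry
#' species-level evidence.
#'
#' @param taxa output of [generate_taxa_pool()] (or a compatible list).
#' @param truth ground-truth list with planted `membership`, `role`, `pi`.
#' @param config a [scenario_config()].
#' @return data.frame interaction KB (resource, consumer, type, evidence_rank,
#'   source_tag).
#' @export
generate_interaction_kb <- function(taxa, truth, config) {
  stopifnot(inherits(config, "scenario_config"))
  ids <- taxa$taxonomy$taxon_id
  if (!all(ids %in% names(truth$membership)))
    stop("membership must cover all taxa")
  .with_seed(config$seed + .seed_offsets[["kb"]], {
    n <- length(ids)
    p <- planted_edge_probabilities(taxa, truth)
    draw <- matrix(stats::runif(n * n), n, n) < p
    idx <- which(draw, arr.ind = TRUE)
    guild <- stats::setNames(taxa$annotations$guild, taxa$annotations$taxon_id)
    consumer <- ids[idx[, 2]]
    is_par <- guild[consumer] == "parasite" &
      stats::runif(nrow(idx)) < config$parasitic_edge_prob
    data.frame(resource = ids[idx[, 1]],
               consumer = consumer,
               type = ifelse(is_par, "parasitism", "predation"),
               evidence_rank = "species",
               source_tag = "synthetic",
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

field_layout <- function(config) {
  sites <- sprintf("S%d", seq_len(config$n_sites))
  fields <- as.vector(t(outer(sites, seq_len(config$fields_per_site),
                              function(s, f) sprintf("%sF%d", s, f))))
  data.frame(field_id = fields,
             site_id = rep(sites, each = config$fields_per_site),
             stringsAsFactors = FALSE)
}

#' Generate plot-level detections and read counts along the LUI gradient
#'
#' Field LUI values sit on an evenly spaced gradient over `[-2, 2]` (assigned
#' in field order, so sites occupy contiguous intensity blocks as in a real
#' management trial) plus a Gaussian site offset (`site_sd`). A taxon is
#' present in a plot with probability `plogis(qlogis(base_detection) -
#' w * detection_decay * LUI)` where `w = 1` for sensitive-guild taxa and
#' `0.25` otherwise; each of the four PCR replicates then detects a present
#' taxon independently with probability `replicate_detection`. Read counts of
#' detected replicates are `ceiling(lognormal(meanlog 5, sdlog 1.5))`, the
#' right-skewed shape typical of metabarcoding counts; non-detections are 0.
#'
#' @param taxa output of [generate_taxa_pool()].
#' @param config a [scenario_config()].
#' @param truth ground-truth list; its `true_lui` field is filled and returned.
#' @return list with `observations` (one row per plot x detected taxon with
#'   per-replicate read counts `rep1..rep4` and `reads_total`), `design`
#'   (field_id, site_id, lui), and the updated `truth`.
#' @export
generate_field_observations <- function(taxa, config, truth) {
  stopifnot(inherits(config, "scenario_config"))
  .with_seed(config$seed + .seed_offsets[["obs"]], {
    lay <- field_layout(config)
    n_fields <- nrow(lay)
    grid <- if (n_fields == 1) 0 else seq(-2, 2, length.out = n_fields)
    site_offset <- stats::rnorm(config$n_sites, 0, config$site_sd)
    names(site_offset) <- unique(lay$site_id)
    lui <- grid + site_offset[lay$site_id]
    names(lui) <- lay$field_id
    truth$true_lui <- lui

    ids <- taxa$taxonomy$taxon_id
    guild <- stats::setNames(taxa$annotations$guild, ids)
    # non-sensitive guilds also decline, at half the rate (the land-use
    # effect is preferential, not exclusive)
    w <- ifelse(guild %in% config$sensitive_guilds, 1, 0.5)
    base_logit <- stats::qlogis(config$base_detection)

    rows <- vector("list", n_fields * config$plots_per_field)
    k <- 0L
    for (f in seq_len(n_fields)) {
      p_det <- stats::plogis(base_logit - w * config$detection_decay * lui[f])
      for (pl in seq_len(config$plots_per_field)) {
        k <- k + 1L
        present <- stats::runif(length(ids)) < p_det
        reps <- matrix(stats::runif(4 * length(ids)) <
                         config$replicate_detection,
                       ncol = 4) & present
        det <- rowSums(reps) > 0
        if (!any(det)) next
        counts <- matrix(0, sum(det), 4)
        hit <- reps[det, , drop = FALSE]
        counts[hit] <- ceiling(stats::rlnorm(sum(hit), meanlog = 5, sdlog = 1.5))
        rows[[k]] <- data.frame(
          plot_id = sprintf("%sP%d", lay$field_id[f], pl),
          field_id = lay$field_id[f], site_id = lay$site_id[f],
          taxon_id = ids[det],
          rep1 = counts[, 1], rep2 = counts[, 2],
          rep3 = counts[, 3], rep4 = counts[, 4],
          reads_total = rowSums(counts),
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
    observations <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    design <- data.frame(lay, lui = unname(lui), stringsAsFactors = FALSE)
    list(observations = observations, design = design, truth = truth)
  })
}

# loadings of the default management criteria on the latent intensity axis;
# negative loadings (N fixation, ground cover) exercise sign orientation
.criteria_loadings <- c(
  n_mineral = 1.0, tillage_depth = 0.9, tillage_freq = 0.8,
  pesticide_freq = 0.8, c_export = 0.7, residue_removal = 0.6,
  n_fixation = -0.4, ground_cover = -0.8)

#' Generate the field-by-criterion management table
#'
#' Each criterion is `loading * true_lui + Gaussian noise`
#' (`criteria_noise_sd`); two loadings are negative so the LUI index's sign
#' orientation is exercised.
#'
#' @param config a [scenario_config()].
#' @param truth ground truth with `true_lui` filled in.
#' @return data.frame: field_id, site_id, then one column per criterion.
#' @export
generate_management_criteria <- function(config, truth) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(truth$true_lui))
    stop("truth$true_lui missing: run generate_field_observations first")
  .with_seed(config$seed + .seed_offsets[["criteria"]], {
    lay <- field_layout(config)
    lui <- truth$true_lui[lay$field_id]
    crit <- vapply(.criteria_loadings, function(a)
      a * lui + stats::rnorm(length(lui), 0, config$criteria_noise_sd),
      numeric(length(lui)))
    data.frame(field_id = lay$field_id, site_id = lay$site_id, crit,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate a single scenario end to end
#'
#' Convenience wrapper chaining the four generators with their fixed seed
#' sub-streams.
#'
#' @param config a [scenario_config()].
#' @return list: taxonomy, annotations, truth, kb, observations, design,
#'   criteria, config.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  taxa <- generate_taxa_pool(config)
  kb <- generate_interaction_kb(taxa, taxa$truth, config)
  obs <- generate_field_observations(taxa, config, taxa$truth)
  criteria <- generate_management_criteria(config, obs$truth)
  list(taxonomy = taxa$taxonomy, annotations = taxa$annotations,
       truth = obs$truth, kb = kb, observations = obs$observations,
       design = obs$design, criteria = criteria, config = config)
}

#' Simulate a field-level metric response with a planted LUI slope
#'
#' Direct response simulation for calibrating the mixed-model stage:
#' `y = intercept + slope * lui + site intercept + residual` with
#' `site ~ N(0, site_sd)` and `residual ~ N(0, residual_sd)`.
#'
#' @param design data.frame with field_id, site_id, lui.
#' @param slope planted fixed-effect slope.
#' @param site_sd,residual_sd Gaussian standard deviations.
#' @param intercept fixed intercept.
#' @param seed integer seed.
#' @return numeric vector of field-level responses, named by field_id.
#' @export
simulate_metric_response <- function(design, slope, site_sd = 0.3,
                                     residual_sd = 0.2, intercept = 2,
                                     seed = 1L) {
  .with_seed(seed + .seed_offsets[["response"]], {
    sites <- unique(design$site_id)
    b <- stats::setNames(stats::rnorm(length(sites), 0, site_sd), sites)
    y <- intercept + slope * design$lui + b[design$site_id] +
      stats::rnorm(nrow(design), 0, residual_sd)
    stats::setNames(as.numeric(y), design$field_id)
  })
}
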