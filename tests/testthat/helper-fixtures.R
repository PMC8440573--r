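# Shared fixtures, all built in code.

small_config <- function(seed = 1L, ...) {
  scenario_config(n_taxa = 60, n_groups = 4, seed = seed, ...)
}

# linear chain A -> B -> C -> D with mixed edge types and guilds
chain_web <- function() {
  food_web(
    nodes = c("A", "B", "C", "D"),
    edges = data.frame(
      resource = c("A", "B", "C"), consumer = c("B", "C", "D"),
      type = c("predation", "parasitism", "predation"), weight = 1,
      stringsAsFactors = FALSE),
    read_counts = c(A = 40, B = 30, C = 20, D = 10),
    guild = c(A = "bacteria_decomposer", B = "detritivore",
              C = "predator", D = "predator"))
}

toy_taxonomy <- function() {
  data.frame(
    taxon_id = c("sp1", "sp2", "sp3", "sp4", "sp5"),
    phylum = c("Nematoda", "Ascomycota", "Ascomycota", "Ascomycota",
               "Arthropoda"),
    family = c("NemF", "FunF", "FunF", "FunF", "ArtF"),
    genus = c("NemG", "FunG1", "FunG1", "FunG2", "ArtG"),
    species = paste0("s", 1:5),
    stringsAsFactors = FALSE)
}

toy_annotations <- function() {
  data.frame(
    taxon_id = c("sp1", "sp2", "sp3", "sp4", "sp5"),
    guild = c("root_herbivore", "fungi_saprotroph", "fungi_saprotroph",
              "fungi_saprotroph", "predator"),
    habitat_layers = c("0-10cm", "0-10cm;surface", "0-10cm", ">10cm",
                       "surface;0-10cm;>10cm"),
    geographic_tags = c("temperate_europe", "", "temperate_europe",
                        "temperate_europe", "tropical"),
    is_microorganism = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}
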