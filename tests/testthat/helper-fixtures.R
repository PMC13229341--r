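# Fixtures and independent brute-force oracles shared across test files.

# --- hand-built taxonomies ----------------------------------------------

# root -> genus G -> species S (minimal chain)
chain_tax <- function() {
  build_taxonomy(data.frame(
    taxon_id = c("r", "G", "S"),
    parent_id = c(NA, "r", "G"),
    rank = c("superkingdom", "genus", "species"),
    name = c("root", "G", "S"),
    stringsAsFactors = FALSE), "gx")
}

# 7-node binary taxonomy: root, 2 genera, 4 species
binary_tax <- function(gene = "gx") {
  build_taxonomy(data.frame(
    taxon_id = c("r", "g1", "g2", "sA", "sB", "sC", "sD"),
    parent_id = c(NA, "r", "r", "g1", "g1", "g2", "g2"),
    rank = c("superkingdom", "genus", "genus", rep("species", 4)),
    name = c("root", "g1", "g2", "sA", "sB", "sC", "sD"),
    stringsAsFactors = FALSE), gene)
}

# root -> family F -> genus G -> {species A, B}; second genus H -> {C}
family_tax <- function(gene = "gx") {
  build_taxonomy(data.frame(
    taxon_id = c("r", "F", "G", "A", "B", "H", "C"),
    parent_id = c(NA, "r", "F", "G", "G", "F", "H"),
    rank = c("superkingdom", "family", "genus", "species", "species",
             "genus", "species"),
    name = c("root", "F", "G", "A", "B", "H", "C"),
    stringsAsFactors = FALSE), gene)
}

# random taxonomy: species grouped into genera grouped into families,
# structure independent of the package's simulator
rand_tax <- function(n_species, gene = "gx") {
  n_gen <- max(2L, rpois(1, n_species / 3) + 1L)
  n_fam <- max(1L, ceiling(n_gen / 3))
  gen_of <- sample.int(n_gen, n_species, replace = TRUE)
  fam_of <- sample.int(n_fam, n_gen, replace = TRUE)
  used_g <- sort(unique(gen_of))
  used_f <- sort(unique(fam_of[used_g]))
  tab <- rbind(
    data.frame(taxon_id = "r", parent_id = NA_character_,
               rank = "superkingdom", name = "r", stringsAsFactors = FALSE),
    data.frame(taxon_id = sprintf("F%02d", used_f), parent_id = "r",
               rank = "family", name = sprintf("F%02d", used_f),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = sprintf("g%02d", used_g),
               parent_id = sprintf("F%02d", fam_of[used_g]),
               rank = "genus", name = sprintf("g%02d", used_g),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = sprintf("s%03d", seq_len(n_species)),
               parent_id = sprintf("g%02d", gen_of),
               rank = "species", name = sprintf("s%03d", seq_len(n_species)),
               stringsAsFactors = FALSE))
  build_taxonomy(tab, gene)
}

# random placement record on a tree: 1-4 distinct edges, total mass in (0, 1]
rand_record <- function(tree, read_id = "q1") {
  k <- sample.int(min(4L, tree$n_edges), 1L)
  edges <- sample(0:(tree$n_edges - 1L), k)
  w <- runif(k)
  w <- w / sum(w) * runif(1, 0.5, 1)
  markerdetect:::new_placement_record(read_id, tree$gene_id, edges, w)
}

# --- independent oracles ------------------------------------------------

# clade support by exhaustive per-edge enumeration of clade node sets
oracle_clade_support <- function(record, tree) {
  n <- nrow(tree$nodes)
  # descendants-or-self of each node by repeated parent-walk
  in_clade <- function(anchor, node) {
    i <- node
    while (!is.na(i)) {
      if (i == anchor) return(TRUE)
      i <- tree$parent[i]
    }
    FALSE
  }
  cand_rows <- unname(tree$edge2node[as.character(record$edges)])
  out <- numeric(0)
  for (i in seq_len(n)) {
    if (is.na(tree$edge_id[i])) next
    s <- 0
    for (k in seq_along(cand_rows)) {
      if (in_clade(i, cand_rows[k])) s <- s + record$weights[k]
    }
    if (s > 0) out[as.character(tree$edge_id[i])] <- s
  }
  out[order(as.integer(names(out)))]
}

# marker vote + confidence by explicit (gene, read, species) triple loops
oracle_scores <- function(classifications, presence) {
  species <- presence$species
  vote <- setNames(integer(length(species)), species)
  conf <- setNames(numeric(length(species)), species)
  for (s in species) {
    voting_genes <- character(0)
    for (g in classifications) {
      sup <- numeric(0)
      for (r in g$reads) {
        if (!r$eligible || length(r$species_support) == 0) next
        # vote of this read
        ss <- r$species_support
        best <- sort(names(ss)[ss == max(ss)])[1]
        if (best == s) voting_genes <- union(voting_genes, g$gene_id)
        if (s %in% names(ss)) sup <- c(sup, unname(ss[[s]]))
      }
      if (g$gene_id %in% presence$G[[s]] && length(sup) > 0) {
        conf[s] <- conf[s] + mean(sup)
      }
    }
    vote[s] <- length(voting_genes)
    conf[s] <- conf[s] / presence$m[[s]]
  }
  list(vote_fraction = vote / presence$m[species], confidence = conf)
}

# PR curve by per-threshold recomputation from first principles
oracle_pr_point <- function(detected, present) {
  tp <- length(intersect(detected, present))
  fp <- length(detected) - tp
  fn <- length(present) - tp
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- tp / (tp + fn)
  c(precision = p, recall = r,
    f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
}

# small helper: classifications from a list of (gene, tree, records)
classify_genes <- function(psets, ...) lapply(psets, classify_set, ...)

make_pset <- function(tree, records) {
  structure(list(gene_id = tree$gene_id, records = records, tree = tree),
            class = "placement_set")
}

make_record <- function(read_id, gene, edges, weights) {
  markerdetect:::new_placement_record(read_id, gene, edges, weights)
}

# edge id of a taxon (the edge above its node)
edge_of <- function(tree, taxon_id) tree$edge_id[tree$index[[taxon_id]]]

# S in both genes; g1 has reads with supports 0.8 and 0.6 for S; g2 none
two_gene_fixture <- function() {
  # S in both genes; g1 has reads with supports 0.8 and 0.6 for S; g2 none
  t1 <- build_taxonomy(data.frame(
    taxon_id = c("r", "G", "S", "X"), parent_id = c(NA, "r", "G", "G"),
    rank = c("superkingdom", "genus", "species", "species"),
    name = c("r", "G", "S", "X"), stringsAsFactors = FALSE), "g1")
  t2 <- build_taxonomy(data.frame(
    taxon_id = c("r", "G", "S", "X"), parent_id = c(NA, "r", "G", "G"),
    rank = c("superkingdom", "genus", "species", "species"),
    name = c("r", "G", "S", "X"), stringsAsFactors = FALSE), "g2")
  p1 <- make_pset(t1, list(make_record("a", "g1", edge_of(t1, "S"), 0.8),
                           make_record("b", "g1", edge_of(t1, "S"), 0.6),
                           make_record("c", "g1", edge_of(t1, "X"), 1.0)))
  p2 <- make_pset(t2, list(make_record("d", "g2", edge_of(t2, "X"), 0.9)))
  list(psets = list(p1, p2),
       presence = build_presence_index(list(t1, t2)))
}
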