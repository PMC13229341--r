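# Placement-level community simulator.
#
# Read simulation and phylogenetic placement are external to this package,
# so sequencing noise is abstracted to what the detection stage actually
# sees: per-read placement supports. Three knobs control the corruption of
# a read from species s in gene g:
#   delta_max     - a fraction delta ~ U(0, delta_max) of the read's mass
#                   leaks onto a confusable neighbor (same genus, falling
#                   back to same family, then any species in the gene tree)
#   epsilon_mis   - probability the roles swap (the neighbor gets 1 - delta)
#   p_ineligible  - probability the read carries only genus-level mass and
#                   is therefore ineligible for species scoring

#' Simulation configuration
#'
#' Defaults describe a mock community in the style of equal-abundance
#' known-genome benchmarks: 200 reference species over 30 marker genes,
#' 50 present at equal abundance, moderate placement noise. The
#' variable-abundance regime (abundances spanning several orders of
#' magnitude, as in CAMI-style marine communities) is selected with
#' `abundance_model = "lognormal"`; [cami_config()] is a preset for it.
#'
#' @param n_species number of reference species (>= 2).
#' @param n_genes number of marker genes (>= 1).
#' @param p_presence probability a species appears in a given gene's tree
#'   (every species is guaranteed at least one gene).
#' @param n_present number of species truly present in the sample.
#' @param abundance_model `"uniform"` (equal abundances) or `"lognormal"`.
#' @param lognormal_sigma sigma of the log-normal abundance model; 2.5
#'   spreads abundances over 4+ orders of magnitude.
#' @param mean_reads mean reads per present species per marker gene at
#'   equal abundance (a coverage proxy); the Poisson rate for species s is
#'   `mean_reads * abundance_s * n_present`.
#' @param delta_max upper bound of the uniform leaked-mass fraction.
#' @param epsilon_mis probability of a swapped (misleading) placement.
#' @param p_ineligible probability of an above-species-only placement.
#' @param min_reads_per_gene floor on reads per (present species, gene)
#'   pair. The default 1 makes every marker of a present species observed,
#'   as expected at the benchmark coverage; set 0 for variable-abundance
#'   communities where rare species may contribute no reads at all.
#' @param seed integer seed fixing all randomness (keep below 2^31 - 2).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_species = 200L, n_genes = 30L, p_presence = 0.7,
                       n_present = 50L, abundance_model = c("uniform", "lognormal"),
                       lognormal_sigma = 2.5, mean_reads = 10,
                       delta_max = 0.3, epsilon_mis = 0.05,
                       p_ineligible = 0.1, min_reads_per_gene = 1L,
                       seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_species >= 2, n_genes >= 1, n_present >= 1,
            n_present <= n_species,
            p_presence > 0, p_presence <= 1,
            delta_max >= 0, delta_max < 1,
            epsilon_mis >= 0, p_ineligible >= 0,
            epsilon_mis + p_ineligible <= 1,
            mean_reads >= 0, min_reads_per_gene >= 0,
            lognormal_sigma > 0)
  structure(list(n_species = as.integer(n_species),
                 n_genes = as.integer(n_genes),
                 p_presence = p_presence,
                 n_present = as.integer(n_present),
                 abundance_model = abundance_model,
                 lognormal_sigma = lognormal_sigma,
                 mean_reads = mean_reads,
                 delta_max = delta_max,
                 epsilon_mis = epsilon_mis,
                 p_ineligible = p_ineligible,
                 min_reads_per_gene = as.integer(min_reads_per_gene),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param ... overrides passed on to [sim_config()].
#' @export
cami_config <- function(seed = 1L, ...) {
  args <- list(n_species = 300L, n_genes = 30L, n_present = 100L,
               abundance_model = "lognormal", lognormal_sigma = 2.5,
               min_reads_per_gene = 0L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

#' Simulate a marker-gene reference package
#'
#' Builds a shared rank-annotated taxonomy (species grouped randomly into
#' genera, genera into families, all under one root) and per-gene trees
#' obtained by Bernoulli(`p_presence`) pruning of the species set, with
#' the guarantees that every species keeps at least one gene and every
#' gene keeps at least one species. Fully deterministic under the seed.
#'
#' @param config a `sim_config`.
#' @return an object of class `sim_reference`: list with `trees` (named
#'   list of `taxonomy_tree`), `presence` (a `presence_index`),
#'   `taxonomy_table` (the shared node table), `membership` (0/1 species
#'   x gene matrix) and `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sp <- config$n_species
  n_ge <- config$n_genes
  species <- sprintf("s%04d", seq_len(n_sp))
  n_genera <- max(2L, ceiling(n_sp / 4))
  n_fam <- max(1L, ceiling(n_genera / 4))
  genus_of <- sample.int(n_genera, n_sp, replace = TRUE)
  family_of_genus <- sample.int(n_fam, n_genera, replace = TRUE)

  used_gen <- sort(unique(genus_of))
  used_fam <- sort(unique(family_of_genus[used_gen]))
  tab <- rbind(
    data.frame(taxon_id = "root", parent_id = NA_character_,
               rank = "superkingdom", name = "root",
               stringsAsFactors = FALSE),
    data.frame(taxon_id = sprintf("f%03d", used_fam), parent_id = "root",
               rank = "family", name = sprintf("family_%03d", used_fam),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = sprintf("G%03d", used_gen),
               parent_id = sprintf("f%03d", family_of_genus[used_gen]),
               rank = "genus", name = sprintf("genus_%03d", used_gen),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = species,
               parent_id = sprintf("G%03d", genus_of),
               rank = "species", name = paste0("species_", species),
               stringsAsFactors = FALSE)
  )

  genes <- sprintf("g%02d", seq_len(n_ge))
  M <- matrix(stats::rbinom(n_sp * n_ge, 1L, config$p_presence),
              nrow = n_sp, ncol = n_ge, dimnames = list(species, genes))
  for (i in which(rowSums(M) == 0)) M[i, sample.int(n_ge, 1L)] <- 1L
  for (j in which(colSums(M) == 0)) M[sample.int(n_sp, 1L), j] <- 1L

  trees <- lapply(genes, function(g) {
    keep <- species[M[, g] == 1L]
    build_taxonomy(prune_taxonomy_table(tab, keep), g)
  })
  names(trees) <- genes
  structure(list(trees = trees,
                 presence = build_presence_index(trees),
                 taxonomy_table = tab,
                 membership = M,
                 config = config),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference: ", x$config$n_species, " species x ",
      x$config$n_genes, " marker genes (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

# Same-genus neighbor lists (fallback same family, then any other species)
# for every species of one gene tree.
neighbor_pool <- function(tree) {
  sp <- tree$species_set
  rows <- tree$index[sp]
  genus <- tree$nodes$taxon_id[tree$parent[rows]]
  family <- tree$nodes$taxon_id[tree$parent[tree$parent[rows]]]
  lapply(seq_along(sp), function(i) {
    same_gen <- sp[genus == genus[i] & sp != sp[i]]
    if (length(same_gen) > 0) return(same_gen)
    same_fam <- sp[family == family[i] & sp != sp[i]]
    if (length(same_fam) > 0) return(same_fam)
    sp[sp != sp[i]]
  }) -> pools
  names(pools) <- sp
  pools
}

#' Simulate a community sample as per-gene placement sets
#'
#' Draws the present species and their abundances, then per present
#' species and per marker gene containing it draws a Poisson read count
#' and emits noisy placement records (see the noise model at the top of
#' this file's documentation). With `out_dir` set, writes one jplace v3
#' file per gene plus `taxonomy.tsv`, `gene_map.tsv`, `truth.tsv` and a
#' `manifest.json` recording the configuration; regenerating with the same
#' config reproduces the files byte for byte.
#'
#' @param reference a `sim_reference`.
#' @param config a `sim_config`; defaults to the reference's own.
#' @param out_dir optional output directory.
#' @return an object of class `synthetic_dataset`: list with `placements`
#'   (named list of `placement_set`), `truth` (a `ground_truth`),
#'   `reference`, `config` and `files` (named paths when written).
#' @export
simulate_sample <- function(reference, config = reference$config,
                            out_dir = NULL) {
  stopifnot(inherits(reference, "sim_reference"),
            inherits(config, "sim_config"))
  # distinct stream from simulate_reference, still fully seed-determined
  set.seed(config$seed + 1L)
  presence <- reference$presence
  present <- sort(sample(presence$species, config$n_present))
  ab <- switch(config$abundance_model,
               uniform = rep(1 / config$n_present, config$n_present),
               lognormal = {
                 x <- stats::rlnorm(config$n_present, 0, config$lognormal_sigma)
                 x / sum(x)
               })
  names(ab) <- present
  truth <- ground_truth(present, unname(ab))

  pools <- lapply(reference$trees, neighbor_pool)
  records <- stats::setNames(vector("list", length(reference$trees)),
                             names(reference$trees))
  for (s in present) {
    lam <- config$mean_reads * ab[[s]] * config$n_present
    for (g in presence$G[[s]]) {
      tree <- reference$trees[[g]]
      k <- max(stats::rpois(1, lam), config$min_reads_per_gene)
      if (k == 0) next
      row_s <- tree$index[[s]]
      edge_s <- tree$edge_id[row_s]
      edge_genus <- tree$edge_id[tree$parent[row_s]]
      nb <- pools[[g]][[s]]
      for (i in seq_len(k)) {
        u <- stats::runif(1)
        delta <- stats::runif(1, 0, config$delta_max)
        id <- sprintf("%s:%s:r%04d", g, s, i)
        rec <- if (u < config$p_ineligible) {
          new_placement_record(id, g, edge_genus, 1)
        } else {
          swap <- u < config$p_ineligible + config$epsilon_mis
          if (length(nb) == 0 || delta == 0) {
            target <- if (swap && length(nb) > 0) {
              tree$edge_id[tree$index[[nb[sample.int(length(nb), 1L)]]]]
            } else edge_s
            new_placement_record(id, g, target, 1)
          } else {
            nbr <- nb[sample.int(length(nb), 1L)]
            edge_n <- tree$edge_id[tree$index[[nbr]]]
            if (swap) {
              new_placement_record(id, g, c(edge_n, edge_s),
                                   c(1 - delta, delta))
            } else {
              new_placement_record(id, g, c(edge_s, edge_n),
                                   c(1 - delta, delta))
            }
          }
        }
        records[[g]][[length(records[[g]]) + 1L]] <- rec
      }
    }
  }

  placements <- lapply(names(reference$trees), function(g) {
    structure(list(gene_id = g,
                   records = records[[g]] %||% list(),
                   tree = reference$trees[[g]]),
              class = "placement_set")
  })
  names(placements) <- names(reference$trees)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(taxonomy = file.path(out_dir, "taxonomy.tsv"),
               gene_map = file.path(out_dir, "gene_map.tsv"),
               truth = file.path(out_dir, "truth.tsv"),
               manifest = file.path(out_dir, "manifest.json"))
    write_taxonomy_table(reference$taxonomy_table, files[["taxonomy"]])
    gm <- data.frame(
      gene_id = rep(colnames(reference$membership),
                    each = nrow(reference$membership)),
      taxon_id = rep(rownames(reference$membership),
                     times = ncol(reference$membership)),
      keep = as.vector(reference$membership) == 1L,
      stringsAsFactors = FALSE)
    gm <- gm[gm$keep, c("gene_id", "taxon_id")]
    utils::write.table(gm, files[["gene_map"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_truth(truth, files[["truth"]])
    for (g in names(placements)) {
      p <- file.path(out_dir, paste0(g, ".jplace"))
      files[[g]] <- p
      write_jplace(placements[[g]], p)
    }
    manifest <- c(unclass(config),
                  list(package = "markerdetect",
                       version = as.character(utils::packageVersion("markerdetect")),
                       n_reads = sum(vapply(placements, function(p)
                         length(p$records), 1L))))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
               files[["manifest"]], useBytes = TRUE)
  }

  structure(list(placements = placements, truth = truth,
                 reference = reference, config = config, files = files),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset: ", length(x$truth$present), " present species, ",
      sum(vapply(x$placements, function(p) length(p$records), 1L)),
      " reads over ", length(x$placements), " genes\n", sep = "")
  invisible(x)
}

#' Write a taxonomy node table (TSV, root parent as empty field)
#'
#' @param tab node table with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(tab, path) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  tab$parent_id[is.na(tab$parent_id)] <- ""
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth table (TSV)
#'
#' @param truth a `ground_truth`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(species_id = names(truth$abundance),
                   abundance = unname(truth$abundance),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
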