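# Canonical rank vocabulary, most inclusive first. "strain" is an optional
# leaf level below species (genome-level leaves in reference taxonomies).
RANKS <- c("superkingdom", "phylum", "class", "order", "family",
           "genus", "species", "strain")

rank_level <- function(rank) {
  lv <- match(rank, RANKS)
  if (anyNA(lv)) {
    stop("unknown rank(s): ", paste(unique(rank[is.na(lv)]), collapse = ", "),
         call. = FALSE)
  }
  lv
}

#' Load a rank-annotated reference taxonomy for one marker gene
#'
#' Reads a 4-column TSV (`taxon_id`, `parent_id`, `rank`, `name`; header
#' required; the root row has an empty `parent_id`) and builds an indexed,
#' validated taxonomy tree. Edge ids are assigned deterministically by a
#' depth-first preorder traversal from the root, visiting children in
#' lexicographic `taxon_id` order, numbering from 0 (the edge above each
#' non-root node). When the taxonomy serves several marker genes, an
#' optional gene map restricts the tree to the species present in one gene.
#'
#' @param taxonomy path to a taxonomy TSV, or a data.frame with columns
#'   `taxon_id`, `parent_id`, `rank`, `name`.
#' @param gene_id marker-gene identifier attached to the tree.
#' @param gene_map optional path to a 2-column TSV (`gene_id`, `taxon_id`)
#'   listing the species contained in each gene's reference tree, or a
#'   data.frame of the same shape. When given, the taxonomy is pruned to
#'   the species listed for `gene_id` (keeping their ancestors and any
#'   strain-level descendants).
#' @return an object of class `taxonomy_tree`.
#' @export
load_taxonomy <- function(taxonomy, gene_id, gene_map = NULL) {
  nodes <- if (is.character(taxonomy)) {
    utils::read.delim(taxonomy, header = TRUE, sep = "\t",
                      colClasses = "character", quote = "",
                      na.strings = NULL)
  } else {
    as.data.frame(taxonomy, stringsAsFactors = FALSE)
  }
  need <- c("taxon_id", "parent_id", "rank", "name")
  if (!all(need %in% names(nodes))) {
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  nodes <- nodes[need]
  for (j in need) nodes[[j]] <- as.character(nodes[[j]])
  nodes$parent_id[is.na(nodes$parent_id) | nodes$parent_id == ""] <- NA_character_

  if (!is.null(gene_map)) {
    gm <- if (is.character(gene_map)) {
      utils::read.delim(gene_map, header = TRUE, sep = "\t",
                        colClasses = "character", quote = "")
    } else {
      as.data.frame(gene_map, stringsAsFactors = FALSE)
    }
    if (!all(c("gene_id", "taxon_id") %in% names(gm))) {
      stop("gene map must have columns gene_id, taxon_id", call. = FALSE)
    }
    keep <- unique(gm$taxon_id[gm$gene_id == gene_id])
    if (length(keep) == 0) {
      stop("gene map lists no species for gene '", gene_id, "'", call. = FALSE)
    }
    nodes <- prune_taxonomy_table(nodes, keep)
  }
  build_taxonomy(nodes, gene_id)
}

# Restrict a taxonomy node table to the given species ids, their ancestors
# and their (strain-level) descendants.
prune_taxonomy_table <- function(nodes, species_ids) {
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$taxon_id)
  missing <- setdiff(species_ids, nodes$taxon_id)
  if (length(missing) > 0) {
    stop("gene map references unknown taxa: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  keep <- logical(nrow(nodes))
  # ancestors-or-self of each kept species
  for (s in species_ids) {
    i <- idx[[s]]
    while (!is.na(i) && !keep[i]) {
      keep[i] <- TRUE
      p <- nodes$parent_id[i]
      i <- if (is.na(p)) NA_integer_ else idx[[p]]
    }
  }
  # descendants of kept species (strain leaves)
  sp_keep <- nodes$taxon_id %in% species_ids
  repeat {
    add <- !keep & !is.na(nodes$parent_id) &
      nodes$parent_id %in% nodes$taxon_id[keep & (sp_keep | rank_level(nodes$rank) >= rank_level("species"))]
    if (!any(add)) break
    keep <- keep | add
  }
  nodes[keep, , drop = FALSE]
}

#' @rdname load_taxonomy
#' @param nodes a validated node table (`taxon_id`, `parent_id`, `rank`,
#'   `name`), one row per taxon.
#' @export
build_taxonomy <- function(nodes, gene_id) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  n <- nrow(nodes)
  if (n == 0) stop("empty taxonomy table", call. = FALSE)
  if (anyDuplicated(nodes$taxon_id)) {
    stop("duplicate taxon_id in taxonomy table", call. = FALSE)
  }
  levels <- rank_level(nodes$rank)
  idx <- stats::setNames(seq_len(n), nodes$taxon_id)
  root <- which(is.na(nodes$parent_id))
  if (length(root) != 1) {
    stop("taxonomy must have exactly one root (empty parent_id), found ",
         length(root), call. = FALSE)
  }
  parent <- rep(NA_integer_, n)
  nz <- which(!is.na(nodes$parent_id))
  parent[nz] <- idx[nodes$parent_id[nz]]
  if (anyNA(parent[nz])) {
    bad <- nodes$taxon_id[nz][is.na(parent[nz])]
    stop("parent_id not found for taxa: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  children <- vector("list", n)
  for (i in nz) children[[parent[i]]] <- c(children[[parent[i]]], i)
  # lexicographic taxon_id order makes edge numbering deterministic
  children <- lapply(children, function(ch) {
    if (is.null(ch)) integer(0) else ch[order(nodes$taxon_id[ch], method = "radix")]
  })

  # iterative preorder DFS: detects unreachable nodes (cycles) and assigns
  # 0-based edge ids in visit order
  edge_id <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  order_visit <- integer(n)
  stack <- root
  depth[root] <- 0L
  k <- 0L
  next_edge <- 0L
  while (length(stack) > 0) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order_visit[k] <- i
    if (i != root) {
      edge_id[i] <- next_edge
      next_edge <- next_edge + 1L
    }
    ch <- children[[i]]
    if (length(ch) > 0) {
      depth[ch] <- depth[i] + 1L
      stack <- c(stack, rev(ch))
    }
  }
  if (k < n) {
    stop("taxonomy contains a cycle or disconnected nodes (",
         n - k, " unreachable)", call. = FALSE)
  }
  # rank order checked after reachability so cycles report as structural
  if (any(levels[nz] <= levels[parent[nz]])) {
    bad <- nodes$taxon_id[nz][levels[nz] <= levels[parent[nz]]]
    stop("rank does not descend from parent's rank for: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  # edge ids were assigned in stack order; reassign strictly in preorder
  edge_id[] <- NA_integer_
  e <- 0L
  for (i in order_visit) {
    if (i != root) { edge_id[i] <- e; e <- e + 1L }
  }

  # species-ancestor-or-self for every node (NA above species level)
  sp_level <- rank_level("species")
  species_of <- rep(NA_integer_, n)
  for (i in order_visit) {
    if (levels[i] == sp_level) {
      species_of[i] <- i
    } else if (levels[i] > sp_level && !is.na(parent[i])) {
      species_of[i] <- species_of[parent[i]]
    }
  }
  is_leaf <- vapply(children, length, 1L) == 0
  no_sp <- is_leaf & is.na(species_of)
  if (any(no_sp)) {
    stop("leaf taxa with no species-rank ancestor-or-self: ",
         paste(utils::head(nodes$taxon_id[no_sp], 5), collapse = ", "),
         call. = FALSE)
  }

  species_rows <- which(levels == sp_level)
  tree <- list(
    gene_id = gene_id,
    nodes = nodes,
    index = idx,
    parent = parent,
    children = children,
    root = root,
    depth = depth,
    level = levels,
    edge_id = edge_id,
    species_of = species_of,
    species_set = sort(nodes$taxon_id[species_rows]),
    n_edges = n - 1L
  )
  # edge2node keyed by edge id as character
  e2n <- which(!is.na(edge_id))
  tree$edge2node <- stats::setNames(e2n, as.character(edge_id[e2n]))
  class(tree) <- "taxonomy_tree"
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree for gene '", x$gene_id, "': ",
      nrow(x$nodes), " taxa, ", x$n_edges, " edges, ",
      length(x$species_set), " species\n", sep = "")
  invisible(x)
}

#' Root-to-node lineage of a taxon
#'
#' @param tree a `taxonomy_tree`.
#' @param taxon_id taxon to look up.
#' @return named character vector of taxon ids keyed by rank, ordered from
#'   the root down; ranks absent from the path are absent from the result.
#' @export
lineage <- function(tree, taxon_id) {
  i <- unname(tree$index[taxon_id])
  if (length(i) != 1 || is.na(i)) {
    stop("unknown taxon_id '", taxon_id, "' in gene '", tree$gene_id, "'",
         call. = FALSE)
  }
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(i, path)
    i <- tree$parent[i]
  }
  stats::setNames(tree$nodes$taxon_id[path], tree$nodes$rank[path])
}

#' Species/marker-gene presence structure
#'
#' For a collection of per-gene taxonomy trees, records for every species s
#' the set G_s of marker genes whose reference tree contains s, and the
#' count m_s = |G_s|. Species detection scores divide by m_s because a
#' species missing from a gene's tree can never receive votes or placement
#' support from that gene.
#'
#' @param trees list of `taxonomy_tree` objects with distinct gene ids.
#' @return an object of class `presence_index`: list with `gene_ids`,
#'   `G` (named list species -> character vector of genes), `m` (named
#'   integer), `species` (sorted ids).
#' @export
build_presence_index <- function(trees) {
  if (length(trees) == 0) stop("need at least one taxonomy tree", call. = FALSE)
  gene_ids <- vapply(trees, function(t) t$gene_id, "")
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_id among taxonomy trees", call. = FALSE)
  }
  pairs_s <- unlist(lapply(trees, function(t) t$species_set), use.names = FALSE)
  pairs_g <- rep(gene_ids, vapply(trees, function(t) length(t$species_set), 1L))
  G <- split(pairs_g, pairs_s)
  G <- lapply(G, function(g) sort(unique(g)))
  G <- G[order(names(G), method = "radix")]
  idx <- list(
    gene_ids = sort(gene_ids),
    G = G,
    m = vapply(G, length, 1L),
    species = names(G)
  )
  class(idx) <- "presence_index"
  idx
}

#' @export
print.presence_index <- function(x, ...) {
  cat("presence_index: ", length(x$species), " species across ",
      length(x$gene_ids), " marker genes (mean m_s = ",
      round(mean(x$m), 2), ")\n", sep = "")
  invisible(x)
}
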