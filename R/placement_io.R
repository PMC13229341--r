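# jplace v3 input/output.
#
# A placement record holds one read's candidate edges with their
# like_weight_ratio supports. Supports are used exactly as produced by the
# placement tool (truncated top-k mass is informative); renormalization to
# sum 1 is available but off by default.

new_placement_record <- function(read_id, gene_id, edges, weights) {
  if (length(edges) == 0) {
    stop("placement record '", read_id, "' has no candidates", call. = FALSE)
  }
  if (any(weights <= 0)) {
    stop("placement record '", read_id, "' has non-positive weights",
         call. = FALSE)
  }
  if (anyDuplicated(edges)) {
    stop("placement record '", read_id, "' repeats an edge", call. = FALSE)
  }
  if (sum(weights) > 1 + 1e-6) {
    stop("placement record '", read_id, "' has weight sum ",
         format(sum(weights)), " > 1", call. = FALSE)
  }
  structure(list(read_id = read_id, gene_id = gene_id,
                 edges = as.integer(edges), weights = as.numeric(weights)),
            class = "placement_record")
}

#' @export
print.placement_record <- function(x, ...) {
  cat("placement_record ", x$read_id, " (gene ", x$gene_id, "): ",
      length(x$edges), " candidate edge(s), total mass ",
      format(sum(x$weights)), "\n", sep = "")
  invisible(x)
}

# Map node labels to the {edge_num} annotations of a jplace tree string.
# Topology is not needed: edge ids are reconciled against the taxonomy by
# the label of the child node under each edge.
jplace_edge_map <- function(tree_string) {
  m <- gregexpr("([^(),:{}\\s;]+)(:[-+0-9.eE]+)?\\{([0-9]+)\\}", tree_string,
                perl = TRUE)
  toks <- regmatches(tree_string, m)[[1]]
  if (length(toks) == 0) {
    stop("jplace tree string carries no {edge_num} annotations", call. = FALSE)
  }
  label <- sub("^([^(),:{}\\s;]+).*$", "\\1", toks, perl = TRUE)
  num <- as.integer(sub("^.*\\{([0-9]+)\\}$", "\\1", toks, perl = TRUE))
  if (anyDuplicated(num)) {
    stop("duplicate edge_num in jplace tree string", call. = FALSE)
  }
  stats::setNames(num, label)
}

#' Read a jplace v3 placement file against a reference taxonomy
#'
#' Parses the jplace JSON, reconciles the file's `{edge_num}` annotations
#' with the taxonomy's edge index through the node labels of the tree
#' string, and returns one placement record per named query read. Weights
#' are taken from the `like_weight_ratio` field in the order declared by
#' the file's `fields` array; zero-weight candidates are dropped. An `nm`
#' name entry with multiplicity k > 1 is expanded into k identical reads
#' (suffixed `/1` ... `/k`), matching jplace multiplicity semantics.
#'
#' @param path jplace v3 file.
#' @param tree the `taxonomy_tree` the placements refer to.
#' @return an object of class `placement_set`: list with `gene_id`,
#'   `records` (list of placement records) and `tree`.
#' @export
read_jplace <- function(path, tree) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$version) || as.integer(doc$version) != 3L) {
    stop("unsupported jplace version: ",
         if (is.null(doc$version)) "missing" else doc$version, call. = FALSE)
  }
  fields <- unlist(doc$fields)
  i_edge <- match("edge_num", fields)
  i_lwr <- match("like_weight_ratio", fields)
  if (is.na(i_edge) || is.na(i_lwr)) {
    stop("jplace 'fields' must include edge_num and like_weight_ratio",
         call. = FALSE)
  }
  emap <- jplace_edge_map(doc$tree)
  known <- names(emap) %in% names(tree$index)
  if (!all(known)) {
    stop("jplace tree labels not in taxonomy for gene '", tree$gene_id, "': ",
         paste(utils::head(names(emap)[!known], 5), collapse = ", "),
         call. = FALSE)
  }
  # file edge_num -> taxonomy edge id, via the child-node label
  file2tax <- stats::setNames(tree$edge_id[tree$index[names(emap)]],
                              as.character(emap))
  if (anyNA(file2tax)) {
    stop("jplace annotates the root label with an edge_num", call. = FALSE)
  }

  records <- list()
  for (pl in doc$placements) {
    rows <- pl$p
    edges_file <- vapply(rows, function(r) as.integer(r[[i_edge]]), 1L)
    lwr <- vapply(rows, function(r) as.numeric(r[[i_lwr]]), 1.0)
    if (any(lwr < 0)) stop("negative like_weight_ratio", call. = FALSE)
    keep <- lwr > 0
    edges_file <- edges_file[keep]
    lwr <- lwr[keep]
    miss <- !(as.character(edges_file) %in% names(file2tax))
    if (any(miss)) {
      stop("edge_num ", paste(edges_file[miss], collapse = ", "),
           " not present in the reference tree for gene '", tree$gene_id,
           "'", call. = FALSE)
    }
    edges <- unname(file2tax[as.character(edges_file)])

    if (!is.null(pl[["n"]])) {
      nm <- vapply(pl[["n"]], as.character, "")
      mult <- rep(1L, length(nm))
    } else if (!is.null(pl[["nm"]])) {
      nm <- vapply(pl[["nm"]], function(x) as.character(x[[1]]), "")
      mult <- vapply(pl[["nm"]], function(x) as.integer(x[[2]]), 1L)
    } else {
      stop("placement entry without 'n' or 'nm' names", call. = FALSE)
    }
    for (j in seq_along(nm)) {
      ids <- if (mult[j] == 1L) nm[j] else paste0(nm[j], "/", seq_len(mult[j]))
      for (id in ids) {
        if (length(edges) == 0) {
          stop("read '", id, "' has no candidate with positive support",
               call. = FALSE)
        }
        records[[length(records) + 1L]] <-
          new_placement_record(id, tree$gene_id, edges, lwr)
      }
    }
  }
  ids <- vapply(records, function(r) r$read_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate read name(s) in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "),
         call. = FALSE)
  }
  structure(list(gene_id = tree$gene_id, records = records, tree = tree),
            class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat("placement_set for gene '", x$gene_id, "': ",
      length(x$records), " read(s)\n", sep = "")
  invisible(x)
}

#' Rescale a placement record's weights to sum to one
#'
#' Placement tools report top-k edges only, so record mass can be below 1;
#' by default that truncated mass is used as-is. This optional step rescales
#' the weights so they sum exactly to 1, leaving edges and order unchanged.
#'
#' @param record a placement record.
#' @return the record with weights summing to 1.
#' @export
renormalize <- function(record) {
  s <- sum(record$weights)
  if (length(record$weights) == 0 || s <= 0) {
    stop("cannot renormalize a record with no positive mass", call. = FALSE)
  }
  record$weights <- record$weights / s
  record
}

# Newick string with node labels and {edge_num} annotations for a taxonomy
# tree; branch lengths fixed at 1 (lengths carry no meaning here).
taxonomy_newick <- function(tree) {
  build <- function(i) {
    ch <- tree$children[[i]]
    lab <- tree$nodes$taxon_id[i]
    inner <- if (length(ch) > 0) {
      paste0("(", paste(vapply(ch, build, ""), collapse = ","), ")")
    } else ""
    if (i == tree$root) {
      paste0(inner, lab)
    } else {
      paste0(inner, lab, ":1{", tree$edge_id[i], "}")
    }
  }
  paste0(build(tree$root), ";")
}

#' Write a placement set as a jplace v3 file
#'
#' Emits the tree string from the set's taxonomy (node labels with
#' `{edge_num}` annotations matching the taxonomy's edge ids) and one
#' placement entry per record with fields `edge_num, like_weight_ratio`.
#'
#' @param pset a `placement_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(pset, path) {
  placements <- lapply(pset$records, function(r) {
    list(p = lapply(seq_along(r$edges),
                    function(i) list(r$edges[i], r$weights[i])),
         n = list(r$read_id))
  })
  doc <- list(
    version = 3L,
    tree = taxonomy_newick(pset$tree),
    fields = list("edge_num", "like_weight_ratio"),
    placements = placements,
    metadata = list(invocation = "markerdetect::write_jplace")
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
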