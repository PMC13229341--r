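# Per-read classification: edge supports -> clade supports -> taxonomic
# assignment (clade-support threshold B) and species-support vector.

# Clade support over node rows: S_row[i] = mass of candidates lying in the
# clade below node i's edge (node-or-descendant), computed by pushing each
# candidate's weight up its ancestor chain. Returns full numeric vector
# indexed by node row; root entry holds the record's total mass.
clade_support_rows <- function(record, tree) {
  S <- numeric(nrow(tree$nodes))
  rows <- unname(tree$edge2node[as.character(record$edges)])
  if (anyNA(rows)) {
    stop("record '", record$read_id, "' references edges absent from gene '",
         tree$gene_id, "'", call. = FALSE)
  }
  for (k in seq_along(rows)) {
    i <- rows[k]
    w <- record$weights[k]
    while (!is.na(i)) {
      S[i] <- S[i] + w
      i <- tree$parent[i]
    }
  }
  S
}

#' Clade support of a read on every edge of the reference tree
#'
#' The support S(e) for the read belonging to the clade below edge e is the
#' sum of the candidate weights on edges within that clade (inclusive of e).
#' S is monotone non-decreasing from any edge toward the root.
#'
#' @param record a placement record.
#' @param tree the `taxonomy_tree` the record refers to.
#' @return named numeric vector, edge id -> S(e), positive entries only.
#' @export
clade_support <- function(record, tree) {
  S <- clade_support_rows(record, tree)
  pos <- which(S > 0 & !is.na(tree$edge_id))
  stats::setNames(S[pos], tree$edge_id[pos])[order(tree$edge_id[pos])]
}

#' Classify one read from its placement supports
#'
#' Implements the clade-support labeling rule: select the deepest edge e
#' whose clade support S(e) is at least B, and label the read with the
#' lineage of that edge's child node (it may stop at genus or higher when
#' no species-level clade is well supported). B must exceed 0.5 so that at
#' most one root-anchored path of edges can qualify. If no edge qualifies
#' the assignment is empty and the support reported is the record's total
#' mass at the root.
#'
#' The read's species-support vector maps each species s to the candidate
#' mass falling within s's clade (the species node and any strain leaves
#' below it). Eligibility for species-level scoring is either
#' `"any_species_mass"` (default: some positive mass lies in some species
#' clade) or `"b_threshold"` (the B-rule assignment reaches species rank).
#'
#' @param record a placement record.
#' @param tree the `taxonomy_tree` the record refers to.
#' @param B clade-support threshold in (0.5, 1]; 0.9 suits pplacer-style
#'   supports, 0.95 EPA-ng-style.
#' @param eligibility eligibility mode for species-level scoring.
#' @return an object of class `read_classification`: list with `read_id`,
#'   `gene_id`, `assignment` (named character, rank -> taxon id, root
#'   down), `assigned_rank`, `assignment_support`, `species_support`
#'   (named numeric) and `eligible`.
#' @export
classify_read <- function(record, tree, B = 0.9,
                          eligibility = c("any_species_mass", "b_threshold")) {
  eligibility <- match.arg(eligibility)
  if (!is.numeric(B) || length(B) != 1 || B <= 0.5 || B > 1) {
    stop("B must lie in (0.5, 1]; got ", B, call. = FALSE)
  }
  S <- clade_support_rows(record, tree)
  qual <- which(S >= B - 1e-12 & !is.na(tree$edge_id))
  if (length(qual) > 0) {
    sel <- qual[which.max(tree$depth[qual])]
    assignment <- lineage(tree, tree$nodes$taxon_id[sel])
    support <- S[sel]
  } else {
    assignment <- stats::setNames(character(0), character(0))
    support <- S[tree$root]
  }

  sp <- species_support_vector(record, tree)
  eligible <- if (eligibility == "any_species_mass") {
    length(sp) > 0
  } else {
    "species" %in% names(assignment)
  }
  structure(list(
    read_id = record$read_id,
    gene_id = record$gene_id,
    assignment = assignment,
    assigned_rank = if (length(assignment)) names(assignment)[length(assignment)] else NA_character_,
    assignment_support = unname(support),
    species_support = sp,
    eligible = eligible
  ), class = "read_classification")
}

#' Species-support vector of a read
#'
#' @rdname classify_read
#' @return for `species_support_vector`: named numeric vector, species id ->
#'   candidate mass within that species' clade; species with zero support
#'   are omitted (an empty vector means no species-level mass at all).
#' @export
species_support_vector <- function(record, tree) {
  rows <- unname(tree$edge2node[as.character(record$edges)])
  if (anyNA(rows)) {
    stop("record '", record$read_id, "' references edges absent from gene '",
         tree$gene_id, "'", call. = FALSE)
  }
  sp_rows <- tree$species_of[rows]
  keep <- !is.na(sp_rows)
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  agg <- rowsum(record$weights[keep], tree$nodes$taxon_id[sp_rows[keep]])
  stats::setNames(agg[, 1], rownames(agg))[order(rownames(agg))]
}

#' Classify every read of a placement set
#'
#' @param pset a `placement_set`.
#' @param B clade-support threshold, see [classify_read()].
#' @param eligibility eligibility mode, see [classify_read()].
#' @param renormalize_records rescale each record's weights to sum 1 before
#'   classification (off by default; truncated mass is informative).
#' @return an object of class `gene_classifications`: list with `gene_id`
#'   and `reads` (list of `read_classification`).
#' @export
classify_set <- function(pset, B = 0.9,
                         eligibility = c("any_species_mass", "b_threshold"),
                         renormalize_records = FALSE) {
  eligibility <- match.arg(eligibility)
  reads <- lapply(pset$records, function(r) {
    if (renormalize_records) r <- renormalize(r)
    classify_read(r, pset$tree, B = B, eligibility = eligibility)
  })
  structure(list(gene_id = pset$gene_id, reads = reads),
            class = "gene_classifications")
}

#' @export
print.gene_classifications <- function(x, ...) {
  n_el <- sum(vapply(x$reads, function(r) r$eligible, TRUE))
  cat("gene_classifications for '", x$gene_id, "': ", length(x$reads),
      " read(s), ", n_el, " species-eligible\n", sep = "")
  invisible(x)
}

#' Write per-read classifications as a TSV
#'
#' @param classifications list of `gene_classifications`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path) {
  rows <- do.call(rbind, lapply(classifications, function(g) {
    do.call(rbind, lapply(g$reads, function(r) {
      data.frame(read_id = r$read_id, gene_id = r$gene_id,
                 assigned_rank = ifelse(is.na(r$assigned_rank), "",
                                        r$assigned_rank),
                 assigned_taxon = if (length(r$assignment)) unname(r$assignment[length(r$assignment)]) else "",
                 assignment_support = r$assignment_support,
                 eligible = r$eligible,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
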