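# Species-level detection scores aggregated across marker genes.
#
# Marker vote: each species-eligible read votes for its highest-support
# species; a gene votes for s if at least one of its reads does;
# vote_fraction = vote(s) / m_s.
#
# Marker confidence: c(g, s) is the mean of the non-zero species supports
# for s over gene g's eligible reads (0 when no such read), and
# C_s = sum_{g in G_s} c(g, s) / |G_s|.

#' Per-species detection scores across marker genes
#'
#' Computes both detection scores for every species of the reference
#' package: the marker-vote fraction vote(s)/m_s and the marker confidence
#' C_s. Species never supported by any read keep a score of 0 (they are
#' still rows of the table, so threshold sweeps see the full reference).
#'
#' @param classifications list of `gene_classifications`, one per marker
#'   gene (see [classify_set()]).
#' @param presence a `presence_index` over the same genes.
#' @return a data.frame of class `species_score_table` with columns
#'   `species_id`, `m_s`, `vote_count`, `vote_fraction`, `confidence`,
#'   `n_supporting_reads` and a list column `supporting_genes`.
#' @export
species_scores <- function(classifications, presence) {
  genes <- vapply(classifications, function(g) g$gene_id, "")
  if (anyDuplicated(genes)) {
    stop("duplicate gene_id among classification sets", call. = FALSE)
  }
  unknown <- setdiff(genes, presence$gene_ids)
  if (length(unknown) > 0) {
    stop("classifications for gene(s) absent from the presence index: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  species <- presence$species
  n <- length(species)
  sidx <- stats::setNames(seq_len(n), species)

  vote_genes <- vector("list", n)    # genes voting for s
  conf_sum <- numeric(n)             # sum over genes of c(g, s)
  n_reads <- integer(n)              # reads with positive support for s

  for (g in classifications) {
    sup_sum <- numeric(n)
    sup_cnt <- integer(n)
    voted <- logical(n)
    for (r in g$reads) {
      if (!r$eligible) next
      ss <- r$species_support
      if (length(ss) == 0) next
      sp <- names(ss)
      i <- sidx[sp]
      if (anyNA(i)) {
        stop("gene '", g$gene_id, "' carries support for species absent ",
             "from the presence index: ",
             paste(sp[is.na(i)], collapse = ", "), call. = FALSE)
      }
      sup_sum[i] <- sup_sum[i] + unname(ss)
      sup_cnt[i] <- sup_cnt[i] + 1L
      # vote: argmax support, ties to the lexicographically smallest id
      best <- sp[order(-unname(ss), sp, method = "radix")][1]
      voted[sidx[[best]]] <- TRUE
    }
    touched <- which(sup_cnt > 0L)
    for (i in touched) {
      if (!(g$gene_id %in% presence$G[[i]])) {
        stop("gene '", g$gene_id, "' has placement mass on species '",
             species[i], "' which is absent from that gene's tree",
             call. = FALSE)
      }
    }
    conf_sum[touched] <- conf_sum[touched] +
      sup_sum[touched] / sup_cnt[touched]
    n_reads <- n_reads + sup_cnt
    for (i in which(voted)) {
      vote_genes[[i]] <- c(vote_genes[[i]], g$gene_id)
    }
  }

  vote_count <- vapply(vote_genes, length, 1L)
  m_s <- unname(presence$m[species])
  out <- data.frame(
    species_id = species,
    m_s = m_s,
    vote_count = vote_count,
    vote_fraction = vote_count / m_s,
    confidence = conf_sum / m_s,
    n_supporting_reads = n_reads,
    stringsAsFactors = FALSE
  )
  out$supporting_genes <- lapply(vote_genes, function(g) sort(unique(g %||% character(0))))
  class(out) <- c("species_score_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname species_scores
#' @export
marker_vote_scores <- function(classifications, presence) {
  species_scores(classifications, presence)
}

#' @rdname species_scores
#' @export
marker_confidence_scores <- function(classifications, presence) {
  species_scores(classifications, presence)
}

# Numeric score column for a detection method.
score_vector <- function(scores, method = c("confidence", "vote")) {
  method <- match.arg(method)
  col <- if (method == "confidence") "confidence" else "vote_fraction"
  stats::setNames(scores[[col]], scores$species_id)
}

#' Call species present at a score threshold
#'
#' A species is detected when its score (marker confidence C_s or
#' marker-vote fraction vote(s)/m_s) is at least T. Defaults used in
#' practice: a conservative T of about 0.2 (better precision) and a
#' sensitive T of about 0.12 (better recall).
#'
#' @param scores a `species_score_table`.
#' @param method `"confidence"` (default) or `"vote"`.
#' @param T detection threshold in (0, 1]. T = 0 is rejected: every
#'   reference species would be called present.
#' @return sorted character vector of detected species ids.
#' @export
detect_species <- function(scores, method = c("confidence", "vote"), T = 0.2) {
  if (!is.numeric(T) || length(T) != 1 || T <= 0 || T > 1) {
    stop("detection threshold T must lie in (0, 1]; got ", T, call. = FALSE)
  }
  v <- score_vector(scores, method)
  sort(names(v)[v >= T])
}

#' Relative abundance profile at a taxonomic rank
#'
#' Aggregates the per-read assignments into relative frequencies at the
#' requested rank. A read counts toward taxon t when its assignment
#' lineage carries t at that rank. The default denominator is the number
#' of reads assigned at (or below) that rank, so the profile sums to 1;
#' `denominator = "all_reads"` divides by every classified read instead.
#'
#' @param classifications list of `gene_classifications`.
#' @param rank rank name (one of the canonical rank vocabulary).
#' @param denominator `"assigned_at_rank"` (default) or `"all_reads"`.
#' @return named numeric vector of relative abundances (possibly empty),
#'   of class `abundance_profile`, with the rank and denominator stored as
#'   attributes.
#' @export
abundance_profile <- function(classifications, rank,
                              denominator = c("assigned_at_rank", "all_reads")) {
  denominator <- match.arg(denominator)
  rank_level(rank)  # validates
  taxa <- character(0)
  n_total <- 0L
  for (g in classifications) {
    for (r in g$reads) {
      n_total <- n_total + 1L
      t <- r$assignment[rank]
      if (!is.na(t)) taxa <- c(taxa, unname(t))
    }
  }
  denom <- if (denominator == "assigned_at_rank") length(taxa) else n_total
  ab <- if (denom == 0) {
    stats::setNames(numeric(0), character(0))
  } else {
    tab <- table(taxa)
    stats::setNames(as.numeric(tab) / denom, names(tab))
  }
  structure(ab, rank = rank, denominator = denominator,
            n_reads = n_total, class = "abundance_profile")
}

#' Abundance-threshold detection (profiling baseline)
#'
#' The profiling-based baseline calls a species "detected" when its
#' relative abundance strictly exceeds the threshold. Note the strict
#' comparison, unlike the score-based [detect_species()] which uses >= T.
#'
#' @param profile an `abundance_profile` at species rank.
#' @param threshold abundance threshold, >= 0.
#' @return sorted character vector of detected taxa.
#' @export
detect_by_abundance <- function(profile, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("abundance threshold must be a single value >= 0", call. = FALSE)
  }
  sort(names(profile)[unclass(profile) > threshold])
}

#' Write a species score table (TSV)
#'
#' @param scores a `species_score_table`.
#' @param path output TSV; `supporting_genes` is comma-collapsed.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- as.data.frame(scores)
  out$supporting_genes <- vapply(out$supporting_genes,
                                 function(g) paste(g, collapse = ","), "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
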