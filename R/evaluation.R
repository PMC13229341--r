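# Detection accuracy: precision/recall/F1, threshold-sweep PR curves with
# AUPR, threshold selection at a target recall, and precision for
# low-abundance species.

#' Ground truth for a community
#'
#' @param species character vector of species ids.
#' @param abundance true relative abundances (finite, >= 0), parallel to
#'   `species`. The "present set" is the species with abundance > 0.
#' @return an object of class `ground_truth`: list with `abundance` (named
#'   numeric) and `present` (sorted ids).
#' @export
ground_truth <- function(species, abundance) {
  species <- as.character(species)
  abundance <- as.numeric(abundance)
  if (length(species) != length(abundance)) {
    stop("species and abundance lengths differ", call. = FALSE)
  }
  if (anyDuplicated(species)) stop("duplicate species in truth", call. = FALSE)
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundances must be finite and >= 0", call. = FALSE)
  }
  o <- order(species, method = "radix")
  structure(list(abundance = stats::setNames(abundance[o], species[o]),
                 present = species[o][abundance[o] > 0]),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @param path TSV with columns `species_id`, `abundance`.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c("character", "numeric"))
  if (!all(c("species_id", "abundance") %in% names(df))) {
    stop("truth table must have columns species_id, abundance", call. = FALSE)
  }
  ground_truth(df$species_id, df$abundance)
}

#' Precision, recall and F1 of a detected species set
#'
#' TP are species correctly identified, FP species falsely detected, FN
#' present species missed. Precision is 1 by convention when nothing is
#' detected (it anchors the high-threshold end of PR curves); F1 is 0 when
#' precision and recall are both 0.
#'
#' @param detected character vector of detected species ids.
#' @param truth a `ground_truth` with a non-empty present set.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(detected, truth) {
  present <- truth$present
  if (length(present) == 0) {
    stop("ground truth has an empty present set", call. = FALSE)
  }
  detected <- unique(as.character(detected))
  tp <- sum(detected %in% present)
  fp <- length(detected) - tp
  fn <- length(present) - tp
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Precision-recall curve from a threshold sweep
#'
#' Sweeps the detection threshold over the descending unique positive
#' scores, plus a sentinel above the maximum (the empty-detection point
#' with precision 1, recall 0). AUPR is the right-continuous step
#' integral sum_i (R_i - R_{i-1}) * P_i over the points in sweep order
#' reversed (ascending recall, ties in sweep order), with R_0 = 0.
#'
#' @param scores a `species_score_table`.
#' @param method `"confidence"` (default) or `"vote"`.
#' @param truth a `ground_truth`.
#' @return data.frame of class `pr_curve` with columns `threshold`,
#'   `precision`, `recall`, `f1`, ordered by descending threshold;
#'   attributes `aupr` and `unscored_truth` (present species absent from
#'   the score table — permanently FN).
#' @export
pr_curve <- function(scores, method = c("confidence", "vote"), truth) {
  method <- match.arg(method)
  v <- score_vector(scores, method)
  thresholds <- sort(unique(v[v > 0]), decreasing = TRUE)
  pts <- lapply(thresholds, function(t) {
    m <- precision_recall_f1(names(v)[v >= t], truth)
    c(threshold = t, m)
  })
  pts <- c(list(c(threshold = Inf, precision = 1, recall = 0, f1 = 0)), pts)
  df <- as.data.frame(do.call(rbind, pts))
  # descending-threshold sweep order is already ascending in recall (ties
  # keep sweep order), as the step integral requires
  aupr <- sum(diff(c(0, df$recall)) * df$precision)
  structure(df,
            aupr = aupr,
            unscored_truth = setdiff(truth$present, names(v)),
            class = c("pr_curve", "data.frame"))
}

#' @rdname pr_curve
#' @param x a `pr_curve`.
#' @export
aupr <- function(x) attr(x, "aupr")

#' Largest threshold reaching a target recall
#'
#' Sweeps the detection threshold downward and returns the largest one
#' whose recall is at least `r`, together with the detected set and its
#' false positives. When even the most permissive threshold (every species
#' with a positive score detected) misses `r`, the target is flagged
#' unattainable.
#'
#' @param scores a `species_score_table`.
#' @param method `"confidence"` (default) or `"vote"`.
#' @param truth a `ground_truth`.
#' @param r target recall in (0, 1].
#' @return list with `attainable` (logical) and, when attainable,
#'   `threshold`, `detected`, `false_positives`, `precision`, `recall`,
#'   `f1`.
#' @export
threshold_at_recall <- function(scores, method = c("confidence", "vote"),
                                truth, r) {
  method <- match.arg(method)
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r > 1) {
    stop("target recall r must lie in (0, 1]; got ", r, call. = FALSE)
  }
  v <- score_vector(scores, method)
  thresholds <- sort(unique(v[v > 0]), decreasing = TRUE)
  for (t in thresholds) {
    detected <- sort(names(v)[v >= t])
    m <- precision_recall_f1(detected, truth)
    if (m[["recall"]] >= r) {
      return(list(attainable = TRUE, threshold = unname(t),
                  detected = detected,
                  false_positives = sort(setdiff(detected, truth$present)),
                  precision = m[["precision"]], recall = m[["recall"]],
                  f1 = m[["f1"]]))
    }
  }
  list(attainable = FALSE, threshold = NA_real_, detected = character(0),
       false_positives = character(0),
       precision = NA_real_, recall = NA_real_, f1 = NA_real_)
}

#' Precision when low-abundance species must be recovered
#'
#' Restricts the truth to present species whose true abundance does not
#' exceed `abundance_cap`, picks the largest threshold whose recall over
#' that restricted set is at least `r`, and reports the precision of the
#' full detected set at that threshold (against the full present set).
#' `precision_scope = "restricted"` instead reports the fraction of the
#' detected set that belongs to the restricted truth.
#'
#' @param scores a `species_score_table`.
#' @param method `"confidence"` (default) or `"vote"`.
#' @param truth a `ground_truth`.
#' @param r target recall over the restricted truth, in (0, 1].
#' @param abundance_cap maximum allowed true abundance (> 0).
#' @param precision_scope `"full"` (default) or `"restricted"`.
#' @return list with `status` (one of `"ok"`, `"unattainable"`,
#'   `"undefined"` when no present species falls under the cap) and, when
#'   ok, `threshold`, `precision`, `restricted_recall`, `n_restricted`.
#' @export
low_abundance_precision <- function(scores, method = c("confidence", "vote"),
                                    truth, r, abundance_cap,
                                    precision_scope = c("full", "restricted")) {
  method <- match.arg(method)
  precision_scope <- match.arg(precision_scope)
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r > 1) {
    stop("target recall r must lie in (0, 1]; got ", r, call. = FALSE)
  }
  if (!is.numeric(abundance_cap) || length(abundance_cap) != 1 ||
      abundance_cap <= 0) {
    stop("abundance_cap must be a single value > 0", call. = FALSE)
  }
  restricted <- truth$present[truth$abundance[truth$present] <= abundance_cap]
  if (length(restricted) == 0) {
    return(list(status = "undefined", threshold = NA_real_,
                precision = NA_real_, restricted_recall = NA_real_,
                n_restricted = 0L))
  }
  v <- score_vector(scores, method)
  thresholds <- sort(unique(v[v > 0]), decreasing = TRUE)
  for (t in thresholds) {
    detected <- names(v)[v >= t]
    rec <- sum(detected %in% restricted) / length(restricted)
    if (rec >= r) {
      precision <- if (precision_scope == "full") {
        precision_recall_f1(detected, truth)[["precision"]]
      } else {
        if (length(detected) == 0) 1 else
          sum(detected %in% restricted) / length(detected)
      }
      return(list(status = "ok", threshold = unname(t), precision = precision,
                  restricted_recall = rec,
                  n_restricted = length(restricted)))
    }
  }
  list(status = "unattainable", threshold = NA_real_, precision = NA_real_,
       restricted_recall = NA_real_, n_restricted = length(restricted))
}

#' Write a PR curve (TSV) with a trailing AUPR record
#'
#' @param curve a `pr_curve`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_pr_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("# AUPR\t%.17g\n", attr(curve, "aupr")), file = path,
      append = TRUE)
  invisible(path)
}
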