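# Scoring of a predicted complexome against a reference complex set:
# overlap score, recall, maximal matching ratio (MMR), geometric accuracy,
# composite score, f-score, novelty labelling and reference preprocessing.

#' Overlap score between two complexes
#'
#' The matching statistic `omega(A, B) = |A n B|^2 / (|A| * |B|)`, the
#' standard neighbourhood-affinity overlap used in complex-prediction
#' evaluation. It is symmetric, 1 exactly when the sets are equal and 0
#' exactly when they are disjoint.
#'
#' @param a,b Non-empty character vectors of member identifiers
#'   (duplicates are collapsed).
#' @return A value in \[0, 1\].
#' @examples
#' overlap_score(c("a", "b", "c"), c("a", "b", "d"))  # 4/9
#' @export
overlap_score <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (!length(a) || !length(b)) stop("overlap_score requires non-empty sets")
  i <- sum(a %in% b)
  i * i / (length(a) * length(b))
}

# coerce predictions/references to a plain list of unique member sets
.as_member_sets <- function(x) {
  if (inherits(x, "refined_complexes")) {
    lapply(x$rc, function(r) unique(r$members))
  } else if (inherits(x, "sc_sim")) {
    lapply(x$scs, function(s) unique(s$members))
  } else {
    lapply(x, unique)
  }
}

.omega_matrix <- function(ref, pred) {
  outer(seq_along(ref), seq_along(pred),
        Vectorize(function(i, j) overlap_score(ref[[i]], pred[[j]])))
}

#' Match predictions to a reference set and label novel complexes
#'
#' Each predicted complex is paired with its best-overlapping reference
#' complex; predictions whose best overlap score is at or below
#' `new_threshold` are labelled newly predicted complexes.
#'
#' @param pred Predicted complexes: a `refined_complexes`, `sc_sim`, or
#'   list of member sets.
#' @param ref Reference complexes (list of member sets).
#' @param new_threshold Novelty boundary (default 0.25; a best overlap
#'   exactly at the boundary counts as new).
#' @return Data frame with one row per prediction: `pred_index`,
#'   `best_ref`, `best_omega`, `label` (`"matched"` or `"new"`).
#' @export
match_and_label <- function(pred, ref, new_threshold = 0.25) {
  pred <- .as_member_sets(pred)
  ref <- .as_member_sets(ref)
  if (!length(ref)) {
    return(data.frame(pred_index = seq_along(pred), best_ref = NA_integer_,
                      best_omega = 0, label = rep("new", length(pred)),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(pred), function(j) {
    om <- vapply(ref, function(r) overlap_score(pred[[j]], r), numeric(1))
    b <- which.max(om)
    data.frame(pred_index = j, best_ref = b, best_omega = om[b],
               label = if (om[b] <= new_threshold) "new" else "matched",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recall of a predicted complexome
#'
#' Fraction of reference complexes for which at least one prediction
#' exceeds the overlap threshold.
#'
#' @inheritParams match_and_label
#' @param match_threshold Overlap threshold; a match requires
#'   `omega > match_threshold` (default 0.25).
#' @return Value in \[0, 1\]; `NA` for an empty reference.
#' @export
recall_score <- function(pred, ref, match_threshold = 0.25) {
  pred <- .as_member_sets(pred)
  ref <- .as_member_sets(ref)
  if (!length(ref)) return(NA_real_)
  if (!length(pred)) return(0)
  hit <- vapply(ref, function(r) {
    any(vapply(pred, function(p) overlap_score(p, r), numeric(1)) >
          match_threshold)
  }, logical(1))
  mean(hit)
}

#' Maximal matching ratio (MMR)
#'
#' Total weight of a maximum one-to-one matching in the bipartite graph of
#' reference versus predicted complexes weighted by overlap score, divided
#' by the number of reference complexes. Computed exactly by maximum-weight
#' bipartite matching.
#'
#' @inheritParams match_and_label
#' @return Value in \[0, 1\]; `NA` for an empty reference.
#' @export
mmr_score <- function(pred, ref) {
  pred <- .as_member_sets(pred)
  ref <- .as_member_sets(ref)
  if (!length(ref)) return(NA_real_)
  if (!length(pred)) return(0)
  W <- .omega_matrix(ref, pred)
  if (all(W == 0)) return(0)
  nr <- length(ref)
  np <- length(pred)
  idx <- which(W > 0, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nr), rep(TRUE, np)),
                                    rbind(idx[, 1], nr + idx[, 2]))
  m <- igraph::max_bipartite_match(g, weights = W[idx])
  mate <- m$matching[seq_len(nr)]
  matched <- which(!is.na(mate))
  sum(W[cbind(matched, mate[matched] - nr)]) / nr
}

#' Geometric accuracy
#'
#' With `t[i, j] = |ref_i n pred_j|`, the clustering-wise sensitivity is
#' `Sn = sum_i max_j t[i, j] / sum_i |ref_i|` and the positive predictive
#' value is `PPV = sum_j max_i t[i, j] / sum_ij t[i, j]`; the geometric
#' accuracy is `sqrt(Sn * PPV)`.
#'
#' @inheritParams match_and_label
#' @return Value in \[0, 1\] (0 when no protein is shared).
#' @export
accuracy_score <- function(pred, ref) {
  pred <- .as_member_sets(pred)
  ref <- .as_member_sets(ref)
  if (!length(ref)) return(NA_real_)
  if (!length(pred)) return(0)
  tmat <- outer(seq_along(ref), seq_along(pred),
                Vectorize(function(i, j) length(intersect(ref[[i]], pred[[j]]))))
  if (sum(tmat) == 0) return(0)
  sn <- sum(apply(tmat, 1, max)) / sum(lengths(ref))
  ppv <- sum(apply(tmat, 2, max)) / sum(tmat)
  sqrt(sn * ppv)
}

#' Composite score
#'
#' The sum recall + MMR + geometric accuracy, a global performance measure
#' in \[0, 3\].
#'
#' @inheritParams recall_score
#' @export
composite_score <- function(pred, ref, match_threshold = 0.25) {
  recall_score(pred, ref, match_threshold) + mmr_score(pred, ref) +
    accuracy_score(pred, ref)
}

#' F-score of a predicted complexome
#'
#' Complex-level harmonic mean of precision (fraction of predictions
#' matching at least one reference above the threshold) and recall.
#'
#' @inheritParams recall_score
#' @export
f_score <- function(pred, ref, match_threshold = 0.25) {
  p <- precision_score(pred, ref, match_threshold)
  r <- recall_score(pred, ref, match_threshold)
  if (is.na(p) || is.na(r)) return(NA_real_)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' @rdname f_score
#' @export
precision_score <- function(pred, ref, match_threshold = 0.25) {
  pred <- .as_member_sets(pred)
  ref <- .as_member_sets(ref)
  if (!length(ref)) return(NA_real_)
  if (!length(pred)) return(NA_real_)
  hit <- vapply(pred, function(p) {
    any(vapply(ref, function(r) overlap_score(p, r), numeric(1)) >
          match_threshold)
  }, logical(1))
  mean(hit)
}

#' Score a predicted complexome against a reference set
#'
#' @inheritParams recall_score
#' @param new_threshold Novelty boundary for [match_and_label()].
#' @return List with `recall`, `mmr`, `accuracy`, `composite`, `fscore`,
#'   `precision`, `n_matched`, `n_new`.
#' @export
score_complexome <- function(pred, ref, match_threshold = 0.25,
                             new_threshold = 0.25) {
  lab <- match_and_label(pred, ref, new_threshold)
  rec <- recall_score(pred, ref, match_threshold)
  mmr <- mmr_score(pred, ref)
  acc <- accuracy_score(pred, ref)
  list(recall = rec, mmr = mmr, accuracy = acc,
       composite = rec + mmr + acc,
       fscore = f_score(pred, ref, match_threshold),
       precision = precision_score(pred, ref, match_threshold),
       n_matched = sum(lab$label == "matched"),
       n_new = sum(lab$label == "new"))
}

#' Preprocess a raw reference complex set
#'
#' Removes complexes smaller than `min_size`, then scans the remainder in
#' descending size order (lexicographic tie-break), dropping any complex
#' whose overlap score against an already kept complex reaches
#' `redundancy_threshold`. The result is order-invariant with respect to
#' the input.
#'
#' @param complexes List of character member sets.
#' @param min_size Minimum complex size kept (default 3).
#' @param redundancy_threshold Overlap at or above which a complex is
#'   considered redundant (default 0.8).
#' @return The deduplicated list of member sets, with attribute `source`
#'   preserved when present.
#' @export
dedup_reference <- function(complexes, min_size = 3,
                            redundancy_threshold = 0.8) {
  src <- attr(complexes, "source")
  sets <- lapply(complexes, unique)
  sets <- sets[lengths(sets) >= min_size]
  if (!length(sets)) return(structure(list(), source = src))
  key <- vapply(sets, function(m) paste(sort(m), collapse = "\r"), character(1))
  ord <- order(-lengths(sets), key)
  sets <- sets[ord]
  kept <- list()
  for (s in sets) {
    redundant <- any(vapply(kept, function(k) {
      overlap_score(s, k) >= redundancy_threshold
    }, logical(1)))
    if (!redundant) kept[[length(kept) + 1]] <- s
  }
  structure(kept, source = src)
}

#' Subunit-average abundance baseline
#'
#' The trivial comparison baseline for quantitative complex abundance:
#' the arithmetic mean of the raw abundances of a complex's members.
#' Members missing from the abundance table are skipped with a warning.
#'
#' @param members Character vector of member identifiers.
#' @param abundance Data frame (`protein`, `copies_per_cell`) or named
#'   numeric vector of raw abundances.
#' @return The mean raw abundance of the members with data.
#' @export
baseline_subunit_average <- function(members, abundance) {
  if (is.data.frame(abundance)) {
    abundance <- setNames(as.numeric(abundance$copies_per_cell),
                          as.character(abundance$protein))
  }
  members <- unique(members)
  have <- members %in% names(abundance)
  if (any(!have)) {
    warning(sprintf("no abundance data for %d member(s): %s",
                    sum(!have), paste(members[!have], collapse = ", ")))
  }
  if (!any(have)) return(NA_real_)
  mean(abundance[members[have]])
}
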