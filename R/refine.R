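# Refinement of pooled simulated complexes (SCs) into refined complexes
# (RCs): co-occurrence frequency matrix, agglomerative clustering,
# quantitative abundance assignment, size/abundance filters, the RC
# overlap graph, and unbound-subunit accounting.

#' Build the pairwise co-occurrence frequency matrix
#'
#' Every simulated complex increments, for each unordered pair of distinct
#' proteins it contains, that pair's count by one; each protein's
#' occurrence count is incremented once per SC containing it.
#'
#' @param scs List of SC records (or an `sc_sim` object).
#' @return Object of class `freq_matrix`: list with `mat` (symmetric
#'   integer matrix of pair counts, proteins sorted lexicographically) and
#'   `occurrence` (named integer vector).
#' @export
build_frequency_matrix <- function(scs) {
  if (inherits(scs, "sc_sim")) scs <- scs$scs
  member_sets <- lapply(scs, function(sc) sort(unique(sc$members)))
  proteins <- sort(unique(unlist(member_sets, use.names = FALSE)))
  n <- length(proteins)
  mat <- matrix(0L, n, n, dimnames = list(proteins, proteins))
  occurrence <- setNames(integer(n), proteins)
  idx <- setNames(seq_len(n), proteins)
  for (m in member_sets) {
    i <- idx[m]
    occurrence[i] <- occurrence[i] + 1L
    if (length(i) >= 2) {
      pr <- combn(i, 2)
      for (k in seq_len(ncol(pr))) {
        a <- pr[1, k]; b <- pr[2, k]
        mat[a, b] <- mat[a, b] + 1L
        mat[b, a] <- mat[b, a] + 1L
      }
    }
  }
  structure(list(mat = mat, occurrence = occurrence), class = "freq_matrix")
}

#' Cluster the frequency matrix into refined complex member sets
#'
#' The pair count is normalized into an affinity
#' `entry(a, b) / max(occurrence(a), occurrence(b))` in \[0, 1\]; proteins
#' are then clustered by average-linkage agglomeration on the distance
#' `1 - affinity`, and the dendrogram is cut at distance `1 - tau`.
#' Clusters with at least two members become refined complex member sets.
#'
#' @param freq A `freq_matrix`.
#' @param tau Affinity threshold in \[0, 1\] at which the dendrogram is cut
#'   (default 0.5: two proteins end up together roughly when they co-occur
#'   in at least half of the SCs of the more frequent one).
#' @return List of character vectors (member sets), ordered by decreasing
#'   size then lexicographically.
#' @export
cluster_matrix <- function(freq, tau = 0.5) {
  stopifnot(inherits(freq, "freq_matrix"))
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0 || tau > 1) {
    stop("tau must be a single value in [0, 1]")
  }
  n <- nrow(freq$mat)
  if (n < 2) return(list())
  occ <- freq$occurrence
  denom <- outer(occ, occ, pmax)
  affinity <- freq$mat / denom
  diag(affinity) <- 1
  d <- as.dist(1 - affinity)
  hc <- hclust(d, method = "average")
  grp <- cutree(hc, h = 1 - tau)
  sets <- split(names(grp), grp)
  sets <- lapply(sets, sort)
  sets <- sets[lengths(sets) >= 2]
  ord <- order(-lengths(sets),
               vapply(sets, `[`, character(1), 1))
  unname(sets[ord])
}

#' Assign simulated complexes to refined complexes and quantify them
#'
#' Each SC is assigned to the refined complex whose member set it overlaps
#' best (by [overlap_score()]), provided the best score reaches
#' `assoc_threshold`; ties go to the larger RC, then to the
#' earlier-numbered one. The number of SCs assigned to an RC is its
#' simulated abundance; the reported abundance is that count squared,
#' restoring the scale compressed by the square-root abundance transform.
#'
#' @param rcs List of member sets (from [cluster_matrix()]).
#' @param scs List of SC records (or an `sc_sim`).
#' @param assoc_threshold Minimum overlap score for assignment (default
#'   0.25, the same convention used for benchmark matching).
#' @return Object of class `refined_complexes`: list with `rc` (one record
#'   per RC: `rc_id`, `members`, `size`, `sim_abundance`,
#'   `reported_abundance`, `per_run`, `per_snapshot`, `cv`,
#'   `fictitious_fraction`) and `unassigned` (number of SCs below
#'   threshold for every RC). The coefficient of variation `cv` is
#'   sd/mean of the per-run counts (`NA` when the mean is zero).
#' @export
assign_abundance <- function(rcs, scs, assoc_threshold = 0.25) {
  if (inherits(scs, "sc_sim")) scs <- scs$scs
  n_rc <- length(rcs)
  rc_sizes <- lengths(rcs)
  run_ids <- vapply(scs, function(s) as.character(s$run_id), character(1))
  snap_ids <- vapply(scs, function(s) {
    paste(s$run_id, s$sample_time, sep = "@")
  }, character(1))
  runs <- sort(unique(run_ids))
  snaps <- sort(unique(snap_ids))

  assigned <- rep(NA_integer_, length(scs))
  for (i in seq_along(scs)) {
    mem <- unique(scs[[i]]$members)
    if (!n_rc) break
    om <- vapply(rcs, function(rc) overlap_score(mem, rc), numeric(1))
    best <- max(om)
    if (best < assoc_threshold) next
    cand <- which(om == best)
    if (length(cand) > 1) {
      cand <- cand[order(-rc_sizes[cand], cand)]
    }
    assigned[i] <- cand[1]
  }

  fict <- vapply(scs, function(s) s$fictitious_fraction, numeric(1))
  rc <- lapply(seq_len(n_rc), function(j) {
    hit <- which(!is.na(assigned) & assigned == j)
    per_run <- setNames(numeric(length(runs)), runs)
    tab_r <- table(run_ids[hit])
    per_run[names(tab_r)] <- as.numeric(tab_r)
    per_snap <- setNames(numeric(length(snaps)), snaps)
    tab_s <- table(snap_ids[hit])
    per_snap[names(tab_s)] <- as.numeric(tab_s)
    sim_ab <- length(hit)
    cv <- if (length(per_run) && mean(per_run) > 0) {
      sd(per_run) / mean(per_run)
    } else NA_real_
    list(rc_id = sprintf("RC%03d", j),
         members = rcs[[j]],
         size = rc_sizes[j],
         sim_abundance = sim_ab,
         reported_abundance = sim_ab^2,
         per_run = per_run,
         per_snapshot = per_snap,
         cv = cv,
         fictitious_fraction = if (length(hit)) mean(fict[hit]) else NA_real_)
  })
  structure(list(rc = rc, unassigned = sum(is.na(assigned))),
            class = "refined_complexes")
}

#' Refine a pooled SC list into quantified refined complexes
#'
#' Convenience wrapper: frequency matrix, clustering, abundance
#' assignment, and optional filtering in one call.
#'
#' @inheritParams cluster_matrix
#' @inheritParams assign_abundance
#' @param scs SC list or `sc_sim`.
#' @param policy Optional [filter_policy()].
#' @return A `refined_complexes` object.
#' @export
refine_complexes <- function(scs, tau = 0.5, assoc_threshold = 0.25,
                             policy = NULL) {
  freq <- build_frequency_matrix(scs)
  sets <- cluster_matrix(freq, tau = tau)
  rcs <- assign_abundance(sets, scs, assoc_threshold = assoc_threshold)
  if (!is.null(policy)) rcs <- filter_complexes(rcs, policy)
  rcs
}

#' Abundance/size filter policy for refined complexes
#'
#' Mode `"LG"` drops low-abundance *large* complexes (more members than
#' `size_threshold` and simulated abundance below `abundance_threshold`);
#' mode `"SM"` drops low-abundance *small* complexes (at most
#' `size_threshold` members); `"none"` keeps everything. Filters operate
#' on the simulated (pre-squaring) abundance.
#'
#' @param mode One of `"none"`, `"LG"`, `"SM"`.
#' @param abundance_threshold Minimum simulated abundance (default 2).
#' @param size_threshold Member-count boundary between small and large
#'   (default 10).
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(mode = c("none", "LG", "SM"),
                          abundance_threshold = 2, size_threshold = 10) {
  mode <- match.arg(mode)
  stopifnot(abundance_threshold >= 0, size_threshold >= 0)
  structure(list(mode = mode, abundance_threshold = abundance_threshold,
                 size_threshold = size_threshold), class = "filter_policy")
}

#' Apply a filter policy to refined complexes
#'
#' @param rcs A `refined_complexes` object.
#' @param policy A [filter_policy()].
#' @return The filtered `refined_complexes`.
#' @export
filter_complexes <- function(rcs, policy) {
  stopifnot(inherits(rcs, "refined_complexes"),
            inherits(policy, "filter_policy"))
  if (policy$mode == "none") return(rcs)
  drop <- vapply(rcs$rc, function(r) {
    low <- r$sim_abundance < policy$abundance_threshold
    if (policy$mode == "LG") {
      r$size > policy$size_threshold && low
    } else {
      r$size <= policy$size_threshold && low
    }
  }, logical(1))
  rcs$rc <- rcs$rc[!drop]
  rcs
}

#' Overlap graph between refined complexes
#'
#' Undirected edges connect RC pairs whose member sets overlap at or above
#' `threshold` by [overlap_score()]; isolated RCs appear only in the node
#' table. Suitable for export to graph viewers.
#'
#' @param rcs A `refined_complexes` object or a list of member sets.
#' @param threshold Minimum overlap score for an edge (default 0.1).
#' @return List with `nodes` (data frame `rc_id`, `size`,
#'   `reported_abundance`) and `edges` (data frame `rc_i`, `rc_j`,
#'   `overlap`).
#' @export
rc_overlap_graph <- function(rcs, threshold = 0.1) {
  recs <- if (inherits(rcs, "refined_complexes")) rcs$rc else {
    lapply(seq_along(rcs), function(i) {
      list(rc_id = sprintf("RC%03d", i), members = rcs[[i]],
           size = length(rcs[[i]]), reported_abundance = NA_real_)
    })
  }
  if (!length(recs)) stop("at least one refined complex is required")
  nodes <- data.frame(rc_id = vapply(recs, `[[`, character(1), "rc_id"),
                      size = vapply(recs, `[[`, numeric(1), "size"),
                      reported_abundance = vapply(recs, function(r) {
                        as.numeric(r$reported_abundance)
                      }, numeric(1)),
                      stringsAsFactors = FALSE)
  edges <- list()
  n <- length(recs)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        om <- overlap_score(recs[[i]]$members, recs[[j]]$members)
        if (om >= threshold) {
          edges[[length(edges) + 1]] <- data.frame(
            rc_i = nodes$rc_id[i], rc_j = nodes$rc_id[j], overlap = om,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(rc_i = character(0), rc_j = character(0), overlap = numeric(0),
               stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}

#' Unbound-subunit accounting
#'
#' For every protein and every snapshot, the number of free instances is
#' the instance count minus the instances bound inside complexes of size
#' two or more; the reported fraction is the snapshot mean of free
#' instances divided by the instance count. Proteins with a fraction near
#' zero are fully consumed in complexes and can limit the formation of
#' their partners' complexes. The protein's degree in the input PPI
#' network is reported alongside.
#'
#' @param model The `complexome_model` that was simulated.
#' @param scs SC list or `sc_sim` from [run_simulation()] on that model.
#' @return Data frame with columns `protein`, `instance_count`,
#'   `mean_free`, `fraction_free`, `degree`.
#' @export
unbound_fractions <- function(model, scs) {
  if (inherits(scs, "sc_sim")) scs <- scs$scs
  inst <- setNames(model$proteins$instance_count, model$proteins$id)
  snap_ids <- vapply(scs, function(s) {
    paste(s$run_id, s$sample_time, sep = "@")
  }, character(1))
  snaps <- unique(snap_ids)
  if (!length(snaps)) snaps <- "none"
  bound <- matrix(0, nrow = length(inst), ncol = length(snaps),
                  dimnames = list(names(inst), snaps))
  for (i in seq_along(scs)) {
    tab <- table(scs[[i]]$members)
    bound[names(tab), snap_ids[i]] <- bound[names(tab), snap_ids[i]] +
      as.numeric(tab)
  }
  free <- pmax(inst - bound, 0)
  deg <- setNames(numeric(length(inst)), names(inst))
  if (nrow(model$ppi)) {
    dt <- table(c(model$ppi$protein_a, model$ppi$protein_b))
    common <- intersect(names(dt), names(deg))
    deg[common] <- as.numeric(dt[common])
  }
  data.frame(protein = names(inst),
             instance_count = unname(inst),
             mean_free = unname(rowMeans(free)),
             fraction_free = unname(ifelse(inst > 0, rowMeans(free) / inst, NA)),
             degree = unname(deg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
as.data.frame.refined_complexes <- function(x, ...) {
  if (!length(x$rc)) {
    return(data.frame(rc_id = character(0), members = character(0),
                      size = integer(0), sim_abundance = numeric(0),
                      reported_abundance = numeric(0), cv = numeric(0),
                      fictitious_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(rc_id = vapply(x$rc, `[[`, character(1), "rc_id"),
             members = vapply(x$rc, function(r) {
               paste(sort(r$members), collapse = ";")
             }, character(1)),
             size = vapply(x$rc, `[[`, numeric(1), "size"),
             sim_abundance = vapply(x$rc, `[[`, numeric(1), "sim_abundance"),
             reported_abundance = vapply(x$rc, `[[`, numeric(1),
                                         "reported_abundance"),
             cv = vapply(x$rc, `[[`, numeric(1), "cv"),
             fictitious_fraction = vapply(x$rc, `[[`, numeric(1),
                                          "fictitious_fraction"),
             stringsAsFactors = FALSE)
}

#' @export
print.refined_complexes <- function(x, ...) {
  cat(sprintf("%d refined complexes (%d unassigned SCs)\n",
              length(x$rc), x$unassigned))
  if (length(x$rc)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write refined complexes as TSV
#'
#' @param rcs A `refined_complexes` object.
#' @param path Output path.
#' @export
write_rcs <- function(rcs, path) {
  write.table(as.data.frame(rcs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
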