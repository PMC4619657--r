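# Independent oracles and small model constructors used across the suite.

# assemble a complexome_model from terse inputs
toy_model <- function(ppi, domains, ddi, abundance, annotations = NULL) {
  if (is.null(annotations)) {
    annotations <- data.frame(protein = character(0), term = character(0),
                              stringsAsFactors = FALSE)
  }
  build_model(ppi, ddi, domains, abundance, annotations)
}

edge_df <- function(...) {
  if (!length(list(...))) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(protein_a = m[, 1], protein_b = m[, 2], stringsAsFactors = FALSE)
}

dom_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(protein = m[, 1], domain = m[, 2], stringsAsFactors = FALSE)
}

ddi_df <- function(...) {
  if (!length(list(...))) {
    return(data.frame(domain_a = character(0), domain_b = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(domain_a = m[, 1], domain_b = m[, 2], stringsAsFactors = FALSE)
}

ab_df <- function(proteins, copies) {
  data.frame(protein = proteins, copies_per_cell = copies,
             stringsAsFactors = FALSE)
}

ann_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(protein = m[, 1], term = m[, 2], stringsAsFactors = FALSE)
}

# union-find connected components, the oracle for complex extraction
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1])
      rb <- find(edges[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# brute-force pair-count oracle for the frequency matrix
brute_freq <- function(member_sets) {
  proteins <- sort(unique(unlist(member_sets)))
  n <- length(proteins)
  mat <- matrix(0L, n, n, dimnames = list(proteins, proteins))
  occ <- stats::setNames(integer(n), proteins)
  for (m in member_sets) {
    u <- unique(m)
    for (p in u) occ[p] <- occ[p] + 1L
    if (length(u) >= 2) {
      for (i in seq_len(length(u) - 1)) {
        for (j in seq(i + 1, length(u))) {
          mat[u[i], u[j]] <- mat[u[i], u[j]] + 1L
          mat[u[j], u[i]] <- mat[u[j], u[i]] + 1L
        }
      }
    }
  }
  list(mat = mat, occurrence = occ)
}

# exhaustive maximum-weight one-to-one matching oracle for MMR
brute_matching <- function(W) {
  nr <- nrow(W)
  np <- ncol(W)
  best <- 0
  cols <- seq_len(np)
  rec <- function(i, used, acc) {
    if (i > nr) {
      best <<- max(best, acc)
      return()
    }
    rec(i + 1, used, acc)
    for (j in cols[!used]) {
      u <- used
      u[j] <- TRUE
      rec(i + 1, u, acc + W[i, j])
    }
  }
  rec(1, rep(FALSE, np), 0)
  best
}

omega_matrix <- function(ref, pred) {
  outer(seq_along(ref), seq_along(pred),
        Vectorize(function(i, j) overlap_score(ref[[i]], pred[[j]])))
}

# make an SC record directly
sc_rec <- function(members, run_id = 1, sample_time = 1, fict = 0) {
  list(members = members, bonds = NULL, run_id = run_id,
       sample_time = sample_time, fictitious_fraction = fict)
}

# reconstruct per-snapshot state facts from raw snapshots for invariant checks
snapshot_checks <- function(sim, model) {
  proteins <- model$proteins$id
  inst_protein <- rep(proteins, model$proteins$instance_count)
  res <- list()
  for (r in seq_along(sim$snapshots)) {
    for (snap in sim$snapshots[[r]]) {
      bm <- snap$bonds
      res[[length(res) + 1]] <- list(run = r, time = snap$time, bonds = bm,
                                     inst_sv = snap$inst_sv,
                                     inst_protein = inst_protein)
    }
  }
  res
}
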