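# Integration of PPI, domain, DDI, abundance and functional-annotation tables
# into the rule-based binding model that the lattice simulator executes.

#' Convert a raw protein copy number to a simulated instance count
#'
#' The simulator represents each protein by a number of discrete instances
#' equal to the square root of its measured copies per cell, which keeps
#' proteome-scale simulations tractable while preserving the rank order of
#' abundances. Values are rounded half-up, with a floor of one instance for
#' any protein actually present (abundance >= 1); an abundance of zero maps
#' to zero instances. Squaring a predicted complex count undoes this
#' compression on the reporting side (see [assign_abundance()]).
#'
#' @param abundance_raw Numeric vector of copies per cell (non-negative).
#' @return Integer vector of instance counts.
#' @examples
#' transform_abundance(c(10000, 0, 7491))
#' @export
transform_abundance <- function(abundance_raw) {
  if (!is.numeric(abundance_raw)) stop("abundance_raw must be numeric")
  if (any(is.na(abundance_raw))) stop("abundance_raw contains NA")
  if (any(abundance_raw < 0)) stop("abundance_raw must be non-negative")
  out <- as.integer(floor(sqrt(abundance_raw) + 0.5))
  out[abundance_raw >= 1 & out < 1L] <- 1L
  out[abundance_raw == 0] <- 0L
  out
}

.canon_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

.dedup_edges <- function(df, col_a, col_b) {
  p <- .canon_pairs(as.character(df[[col_a]]), as.character(df[[col_b]]))
  keep <- !duplicated(paste(p$a, p$b, sep = "\r"))
  out <- data.frame(a = p$a[keep], b = p$b[keep], stringsAsFactors = FALSE)
  names(out) <- c(col_a, col_b)
  out
}

.as_slot_list <- function(domains) {
  if (is.list(domains) && !is.data.frame(domains)) return(domains)
  split(as.character(domains$domain), as.character(domains$protein))
}

.as_term_list <- function(annotations) {
  if (is.list(annotations) && !is.data.frame(annotations)) return(annotations)
  lapply(split(as.character(annotations$term), as.character(annotations$protein)), unique)
}

#' Derive binding rules from known domain-domain interactions
#'
#' For every protein-protein interaction edge, emits one binding rule per
#' domain pair that (a) occurs with one domain on each partner and (b) is
#' listed in the DDI table. DDI evidence is only used where a PPI edge
#' exists. Edges for which no domain pair is supported (including edges
#' whose proteins have no domain annotation at all) are returned separately
#' as `uncovered`, the input to fictitious-domain rescue.
#'
#' @param ppi Data frame with columns `protein_a`, `protein_b` (undirected
#'   edges; duplicate orderings are collapsed).
#' @param domains Data frame with columns `protein`, `domain` (one row per
#'   slot occurrence), or an equivalent named list of domain vectors.
#' @param ddi Data frame with columns `domain_a`, `domain_b` (undirected).
#' @return List with elements `rules` (data frame `protein_a`, `domain_a`,
#'   `protein_b`, `domain_b`, `provenance = "known_ddi"`) and `uncovered`
#'   (the PPI edges with no supported domain pair).
#' @export
derive_known_rules <- function(ppi, domains, ddi) {
  edges <- .dedup_edges(ppi, "protein_a", "protein_b")
  slots <- .as_slot_list(domains)
  ddi_keys <- character(0)
  if (nrow(ddi) > 0) {
    p <- .canon_pairs(as.character(ddi$domain_a), as.character(ddi$domain_b))
    ddi_keys <- unique(paste(p$a, p$b, sep = "\r"))
  }
  rule_rows <- vector("list", nrow(edges))
  covered <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    pa <- edges$protein_a[i]
    pb <- edges$protein_b[i]
    da <- unique(slots[[pa]])
    db <- unique(slots[[pb]])
    if (is.null(da) || is.null(db) || !length(da) || !length(db)) next
    grid <- expand.grid(da = da, db = db, stringsAsFactors = FALSE)
    if (pa == pb) grid <- grid[grid$da <= grid$db, , drop = FALSE]
    key <- ifelse(grid$da <= grid$db,
                  paste(grid$da, grid$db, sep = "\r"),
                  paste(grid$db, grid$da, sep = "\r"))
    hit <- grid[key %in% ddi_keys, , drop = FALSE]
    if (nrow(hit)) {
      covered[i] <- TRUE
      rule_rows[[i]] <- data.frame(protein_a = pa, domain_a = hit$da,
                                   protein_b = pb, domain_b = hit$db,
                                   provenance = "known_ddi",
                                   stringsAsFactors = FALSE)
    }
  }
  rules <- do.call(rbind, c(rule_rows[covered], list(.empty_rules())))
  rules <- .canon_rules(rules)
  list(rules = rules, uncovered = edges[!covered, , drop = FALSE])
}

.empty_rules <- function() {
  data.frame(protein_a = character(0), domain_a = character(0),
             protein_b = character(0), domain_b = character(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

# canonical orientation (protein_a <= protein_b, domains following their
# protein; domain_a <= domain_b on self edges) and unordered dedup
.canon_rules <- function(rules) {
  if (!nrow(rules)) return(rules)
  swap <- rules$protein_a > rules$protein_b |
    (rules$protein_a == rules$protein_b & rules$domain_a > rules$domain_b)
  rules[swap, c("protein_a", "domain_a", "protein_b", "domain_b")] <-
    rules[swap, c("protein_b", "domain_b", "protein_a", "domain_a")]
  key <- paste(rules$protein_a, rules$domain_a, rules$protein_b, rules$domain_b,
               sep = "\r")
  rules <- rules[!duplicated(key), , drop = FALSE]
  rules[order(rules$protein_a, rules$protein_b, rules$domain_a, rules$domain_b), ,
        drop = FALSE]
}

#' Rescue uncovered PPI edges with fictitious domain pairs
#'
#' PPI edges without any supporting domain-domain interaction are kept in
#' the model only when the two proteins share at least one functional
#' annotation term, in which case a fresh pair of fictitious domains is
#' minted for that edge (one new slot appended to each partner) and a
#' binding rule with provenance `"fictitious"` is created. Each rescued
#' edge receives its own private domain pair so fictitious rules can never
#' license binding across edges the PPI network does not support. Edges
#' whose proteins share no term are dropped from the model.
#'
#' @param uncovered Data frame of PPI edges (`protein_a`, `protein_b`), as
#'   returned by [derive_known_rules()].
#' @param domains Domain table or slot list (unused members tolerated).
#' @param functions Data frame with columns `protein`, `term`, or a named
#'   list of term vectors.
#' @return List with `rules` (fictitious rules), `dropped` (edges excluded
#'   from the model) and `new_slots` (data frame `protein`, `domain` of the
#'   appended fictitious slots).
#' @export
add_fictitious_rules <- function(uncovered, domains, functions) {
  terms <- .as_term_list(functions)
  if (!nrow(uncovered)) {
    return(list(rules = .empty_rules(), dropped = uncovered,
                new_slots = data.frame(protein = character(0),
                                       domain = character(0),
                                       stringsAsFactors = FALSE)))
  }
  edges <- uncovered[order(uncovered$protein_a, uncovered$protein_b), ,
                     drop = FALSE]
  rescued <- logical(nrow(edges))
  rule_rows <- vector("list", nrow(edges))
  slot_rows <- vector("list", nrow(edges))
  k <- 0L
  for (i in seq_len(nrow(edges))) {
    pa <- edges$protein_a[i]
    pb <- edges$protein_b[i]
    if (length(intersect(terms[[pa]], terms[[pb]])) < 1) next
    k <- k + 1L
    base <- paste("FICT", pa, pb, k, sep = "_")
    da <- paste0(base, "_1")
    db <- paste0(base, "_2")
    rescued[i] <- TRUE
    rule_rows[[i]] <- data.frame(protein_a = pa, domain_a = da,
                                 protein_b = pb, domain_b = db,
                                 provenance = "fictitious",
                                 stringsAsFactors = FALSE)
    slot_rows[[i]] <- data.frame(protein = c(pa, pb), domain = c(da, db),
                                 stringsAsFactors = FALSE)
  }
  list(rules = do.call(rbind, c(rule_rows[rescued], list(.empty_rules()))),
       dropped = edges[!rescued, , drop = FALSE],
       new_slots = do.call(rbind, c(slot_rows[rescued],
                                    list(data.frame(protein = character(0),
                                                    domain = character(0),
                                                    stringsAsFactors = FALSE)))))
}

#' Build the integrated protein-domain binding model
#'
#' Combines the five input tables into the substrate of the lattice
#' simulator: a set of proteins with ordered domain slots and discrete
#' instance counts, and a set of pairwise binding rules, each licensed
#' either by a known domain-domain interaction or by a fictitious domain
#' pair added to a functionally related protein pair. A protein is retained
#' only if it takes part in at least one rule and has abundance data; rules
#' touching unretained proteins are dropped with them.
#'
#' Coverage statistics record the fraction of (deduplicated) PPI edges
#' supported by known DDIs alone (`ddi_coverage_before`) and after
#' fictitious rescue (`ddi_coverage_after`).
#'
#' @param ppi,ddi,domains,abundance,annotations Data frames (see the file
#'   readers [read_ppi()] and friends for the column contracts) or paths to
#'   the corresponding tab-separated files.
#' @return An object of class `complexome_model`: a list with elements
#'   `proteins` (data frame `id`, `abundance_raw`, `instance_count`),
#'   `slots` (named list of ordered domain-slot vectors), `rules`,
#'   `functions`, `ppi` (the deduplicated input edges) and `coverage`.
#' @export
build_model <- function(ppi, ddi, domains, abundance, annotations) {
  ppi <- .maybe_read(ppi, read_ppi)
  ddi <- .maybe_read(ddi, read_ddi)
  domains <- .maybe_read(domains, read_domains)
  abundance <- .maybe_read(abundance, read_abundance)
  annotations <- .maybe_read(annotations, read_annotations)

  edges <- .dedup_edges(ppi, "protein_a", "protein_b")
  known <- derive_known_rules(edges, domains, ddi)
  fict <- add_fictitious_rules(known$uncovered, domains, annotations)

  n_edges <- nrow(edges)
  n_covered <- n_edges - nrow(known$uncovered)
  n_rescued <- nrow(known$uncovered) - nrow(fict$dropped)
  coverage_before <- if (n_edges) n_covered / n_edges else NA_real_
  coverage_after <- if (n_edges) (n_covered + n_rescued) / n_edges else NA_real_

  rules <- rbind(known$rules, fict$rules)
  abun <- setNames(as.numeric(abundance$copies_per_cell),
                   as.character(abundance$protein))
  has_ab <- rules$protein_a %in% names(abun) & rules$protein_b %in% names(abun)
  rules <- rules[has_ab, , drop = FALSE]
  retained <- sort(unique(c(rules$protein_a, rules$protein_b)))
  if (!length(retained)) {
    stop("empty model: no PPI edge is supported by rules and abundance data")
  }
  rules <- .canon_rules(rules)

  slots <- .as_slot_list(domains)
  slots <- slots[intersect(retained, names(slots))]
  for (i in seq_len(nrow(fict$new_slots))) {
    p <- fict$new_slots$protein[i]
    if (!(p %in% retained)) next
    slots[[p]] <- c(slots[[p]], fict$new_slots$domain[i])
  }
  slots <- slots[retained]
  names(slots) <- retained

  terms <- .as_term_list(annotations)
  proteins <- data.frame(id = retained,
                         abundance_raw = unname(abun[retained]),
                         stringsAsFactors = FALSE)
  proteins$instance_count <- transform_abundance(proteins$abundance_raw)

  pair_key <- unique(paste(rules$protein_a, rules$protein_b, sep = "\r"))
  coverage <- list(
    n_ppi_input = n_edges,
    n_proteins_input = length(unique(c(edges$protein_a, edges$protein_b))),
    n_proteins_model = length(retained),
    n_interactions_model = length(pair_key),
    ddi_coverage_before = coverage_before,
    ddi_coverage_after = coverage_after)

  structure(list(proteins = proteins, slots = slots, rules = rules,
                 functions = terms[intersect(retained, names(terms))],
                 ppi = edges, coverage = coverage),
            class = "complexome_model")
}

.maybe_read <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' @export
print.complexome_model <- function(x, ...) {
  cov <- x$coverage
  cat("Integrated binding model\n")
  cat(sprintf("  proteins: %d (of %d in PPI input)\n",
              cov$n_proteins_model, cov$n_proteins_input))
  cat(sprintf("  rules: %d (%d known DDI, %d fictitious) over %d protein pairs\n",
              nrow(x$rules), sum(x$rules$provenance == "known_ddi"),
              sum(x$rules$provenance == "fictitious"), cov$n_interactions_model))
  cat(sprintf("  DDI coverage of PPI edges: %.3f before, %.3f after fictitious rescue\n",
              cov$ddi_coverage_before, cov$ddi_coverage_after))
  cat(sprintf("  total instances: %d\n", sum(x$proteins$instance_count)))
  invisible(x)
}

#' Serialize / restore an integrated model as JSON
#'
#' @param model A `complexome_model`.
#' @param path Output (input) file path.
#' @return `read_model` returns the restored `complexome_model`;
#'   `write_model` returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "complexome_model"))
  obj <- list(proteins = model$proteins,
              slots = model$slots,
              rules = model$rules,
              functions = model$functions,
              ppi = model$ppi,
              coverage = model$coverage)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  slots <- lapply(obj$slots, as.character)
  funs <- lapply(obj$functions, as.character)
  proteins <- as.data.frame(obj$proteins, stringsAsFactors = FALSE)
  proteins$instance_count <- as.integer(proteins$instance_count)
  structure(list(proteins = proteins,
                 slots = slots,
                 rules = as.data.frame(obj$rules, stringsAsFactors = FALSE),
                 functions = funs,
                 ppi = as.data.frame(obj$ppi, stringsAsFactors = FALSE),
                 coverage = as.list(obj$coverage)),
            class = "complexome_model")
}
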