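# Drug-perturbation analysis: inject a drug species that competes for
# protein binding domains, re-simulate, and call qualitative and
# quantitative complexome changes between control and treated conditions.

#' Specify a drug entity
#'
#' The drug is represented like a protein: its instance count is the
#' rounded square root of its raw molecule count, and its binding sites
#' compete for target domain slots under the same site-exclusivity rule as
#' protein-protein bonds.
#'
#' @param id Drug identifier (will appear as a model species).
#' @param targets Character vector of target protein identifiers.
#' @param abundance_raw Molecule count; a practical choice is the raw
#'   abundance of the most abundant protein in the model.
#' @param k_on,k_off Optional drug-specific binding rates; `NA` inherits
#'   the simulation defaults.
#' @return An object of class `drug_spec`.
#' @export
drug_spec <- function(id, targets, abundance_raw, k_on = NA_real_,
                      k_off = NA_real_) {
  stopifnot(length(id) == 1, length(targets) >= 1, abundance_raw >= 0)
  structure(list(id = as.character(id),
                 targets = unique(as.character(targets)),
                 abundance_raw = abundance_raw,
                 instance_count = transform_abundance(abundance_raw),
                 k_on = k_on, k_off = k_off),
            class = "drug_spec")
}

#' Infer the domains bound by a drug from its protein targets
#'
#' For every real (non-fictitious) domain type carried by at least one
#' target, a one-sided hypergeometric test asks whether proteins carrying
#' the domain are over-represented among the targets relative to all model
#' proteins; p-values are Benjamini-Hochberg adjusted. If no domain passes
#' `alpha`, the fallback returns the domains present in more than half of
#' the targets (with a message).
#'
#' @param targets Character vector of target proteins (must intersect the
#'   model).
#' @param model A `complexome_model`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Character vector of enriched domain identifiers, with
#'   attributes `p_adjusted` (named) and `method` (`"enrichment"` or
#'   `"majority_fallback"`).
#' @export
infer_drug_domains <- function(targets, model, alpha = 0.05) {
  targets <- intersect(unique(targets), model$proteins$id)
  if (!length(targets)) stop("no drug target is present in the model")
  prot_doms <- lapply(model$slots, unique)
  all_prot <- names(prot_doms)
  n_bg <- length(all_prot)
  n_tg <- length(targets)
  cand <- sort(unique(unlist(prot_doms[targets], use.names = FALSE)))
  cand <- cand[!startsWith(cand, "FICT_")]
  if (!length(cand)) stop("targets carry no real domain")
  pvals <- vapply(cand, function(d) {
    carriers <- vapply(prot_doms, function(s) d %in% s, logical(1))
    K <- sum(carriers)
    k <- sum(carriers[targets])
    phyper(k - 1, K, n_bg - K, n_tg, lower.tail = FALSE)
  }, numeric(1))
  padj <- p.adjust(pvals, method = "BH")
  hit <- cand[padj < alpha]
  method <- "enrichment"
  if (!length(hit)) {
    frac <- vapply(cand, function(d) {
      mean(vapply(prot_doms[targets], function(s) d %in% s, logical(1)))
    }, numeric(1))
    hit <- cand[frac > 0.5]
    method <- "majority_fallback"
    message("no domain passed enrichment; falling back to domains present in >50% of targets")
  }
  structure(hit, p_adjusted = padj, method = method)
}

#' Add a drug species to an integrated model
#'
#' The drug becomes a model species with one binding site per bound domain
#' type. For every bound domain, binding rules are created against each
#' model protein that carries the domain and is either a target itself or
#' shares a PPI edge with a target. Drug instances then compete for those
#' domain slots during simulation, occluding protein-protein bonds.
#'
#' @param model A `complexome_model`.
#' @param drug A [drug_spec()].
#' @param bound_domains Domains bound by the drug; default inferred with
#'   [infer_drug_domains()].
#' @return A new `complexome_model` with the drug appended as the last
#'   species (a zero-abundance drug leaves the simulated trajectory of the
#'   original model unchanged under the same seed).
#' @export
add_drug <- function(model, drug, bound_domains = NULL) {
  stopifnot(inherits(model, "complexome_model"), inherits(drug, "drug_spec"))
  if (is.null(bound_domains)) {
    bound_domains <- as.character(infer_drug_domains(drug$targets, model))
  }
  if (!length(bound_domains)) {
    warning("drug binds no domain; model returned unchanged")
    return(model)
  }
  near_target <- unique(c(
    drug$targets,
    model$ppi$protein_b[model$ppi$protein_a %in% drug$targets],
    model$ppi$protein_a[model$ppi$protein_b %in% drug$targets]))
  rules <- model$rules
  if (is.null(rules$k_on)) rules$k_on <- NA_real_
  if (is.null(rules$k_off)) rules$k_off <- NA_real_
  new_rules <- list()
  site_domains <- character(0)
  for (d in bound_domains) {
    site <- paste0("SITE_", d)
    carriers <- names(model$slots)[vapply(model$slots, function(s) d %in% s,
                                          logical(1))]
    carriers <- intersect(carriers, near_target)
    if (!length(carriers)) next
    site_domains <- c(site_domains, site)
    new_rules[[length(new_rules) + 1]] <- data.frame(
      protein_a = drug$id, domain_a = site,
      protein_b = carriers, domain_b = d,
      provenance = "drug", k_on = drug$k_on, k_off = drug$k_off,
      stringsAsFactors = FALSE)
  }
  if (!length(new_rules)) {
    warning("no model protein exposes the bound domains near the targets; model unchanged")
    return(model)
  }
  model$rules <- rbind(rules, do.call(rbind, new_rules))
  model$proteins <- rbind(model$proteins,
                          data.frame(id = drug$id,
                                     abundance_raw = drug$abundance_raw,
                                     instance_count = drug$instance_count,
                                     stringsAsFactors = FALSE))
  model$slots[[drug$id]] <- site_domains
  model
}

#' Match two complexomes one-to-one
#'
#' Greedy best-first assignment: control/treated RC pairs are matched in
#' order of decreasing overlap score, each RC used at most once, stopping
#' below `match_threshold`.
#'
#' @param control,treated `refined_complexes` objects or lists of member
#'   sets.
#' @param match_threshold Minimum overlap for a match (default 0.25).
#' @return Data frame with columns `control_rc`, `treated_rc`, `overlap`;
#'   unmatched complexes on either side appear with `NA` on the other.
#' @export
match_complexomes <- function(control, treated, match_threshold = 0.25) {
  cs <- .as_member_sets(control)
  ts <- .as_member_sets(treated)
  c_ids <- .rc_ids(control, length(cs))
  t_ids <- .rc_ids(treated, length(ts))
  pairs <- list()
  if (length(cs) && length(ts)) {
    W <- .omega_matrix(cs, ts)
    W[W < match_threshold] <- 0
    while (any(W > 0)) {
      best <- which(W == max(W), arr.ind = TRUE)[1, , drop = FALSE]
      i <- best[1, 1]; j <- best[1, 2]
      pairs[[length(pairs) + 1]] <- data.frame(
        control_rc = c_ids[i], treated_rc = t_ids[j],
        overlap = W[i, j], stringsAsFactors = FALSE)
      W[i, ] <- 0
      W[, j] <- 0
    }
  }
  matched <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(control_rc = character(0), treated_rc = character(0),
               overlap = numeric(0), stringsAsFactors = FALSE)
  }
  un_c <- setdiff(c_ids, matched$control_rc)
  un_t <- setdiff(t_ids, matched$treated_rc)
  rbind(matched,
        data.frame(control_rc = un_c,
                   treated_rc = rep(NA_character_, length(un_c)),
                   overlap = rep(NA_real_, length(un_c)),
                   stringsAsFactors = FALSE),
        data.frame(control_rc = rep(NA_character_, length(un_t)),
                   treated_rc = un_t,
                   overlap = rep(NA_real_, length(un_t)),
                   stringsAsFactors = FALSE))
}

.rc_ids <- function(x, n) {
  if (inherits(x, "refined_complexes")) {
    vapply(x$rc, `[[`, character(1), "rc_id")
  } else {
    sprintf("RC%03d", seq_len(n))
  }
}

#' Welch t-test on per-replicate complex abundances
#'
#' @param control_counts,treated_counts Numeric vectors of per-replicate
#'   (run x collection point) simulated abundances.
#' @param alpha Significance level (default 0.05).
#' @return List with `p_value` and `call` (one of
#'   `"quantitative_change"`, `"unchanged"`, `"untestable"`). Two
#'   identical constant vectors give p = 1.
#' @export
abundance_test <- function(control_counts, treated_counts, alpha = 0.05) {
  x <- as.numeric(control_counts)
  y <- as.numeric(treated_counts)
  if (length(x) < 2 || length(y) < 2) {
    return(list(p_value = NA_real_, call = "untestable"))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
  } else {
    p <- t.test(x, y, var.equal = FALSE)$p.value
  }
  list(p_value = p,
       call = if (p < alpha) "quantitative_change" else "unchanged")
}

#' Call qualitative and quantitative complexome changes
#'
#' Control and treated refined complexes are matched one-to-one with
#' [match_complexomes()]; matched pairs are tested for abundance change
#' with a Welch t-test on per-collection-point counts, and complexes
#' without a best match on the other side are called qualitatively
#' altered.
#'
#' @param control_rcs,treated_rcs `refined_complexes` objects carrying
#'   per-snapshot abundance vectors.
#' @param match_threshold Overlap threshold for matching (default 0.25).
#' @param alpha Significance level of the t-test (default 0.05).
#' @return Data frame with columns `control_rc`, `treated_rc`, `overlap`,
#'   `p_value`, `call`.
#' @export
call_perturbations <- function(control_rcs, treated_rcs,
                               match_threshold = 0.25, alpha = 0.05) {
  stopifnot(inherits(control_rcs, "refined_complexes"),
            inherits(treated_rcs, "refined_complexes"))
  m <- match_complexomes(control_rcs, treated_rcs, match_threshold)
  c_by_id <- setNames(control_rcs$rc, .rc_ids(control_rcs, NA))
  t_by_id <- setNames(treated_rcs$rc, .rc_ids(treated_rcs, NA))
  m$p_value <- NA_real_
  m$call <- NA_character_
  for (i in seq_len(nrow(m))) {
    if (is.na(m$control_rc[i]) || is.na(m$treated_rc[i])) {
      m$call[i] <- "qualitative_change"
      next
    }
    res <- abundance_test(c_by_id[[m$control_rc[i]]]$per_snapshot,
                          t_by_id[[m$treated_rc[i]]]$per_snapshot, alpha)
    m$p_value[i] <- res$p_value
    m$call[i] <- res$call
  }
  m
}

# split SCs at a removed species: drop the species' instances and bonds,
# then re-extract connected components of what remains
.strip_species <- function(scs, id) {
  out <- list()
  for (sc in scs) {
    if (!(id %in% sc$members)) {
      out[[length(out) + 1]] <- sc
      next
    }
    b <- sc$bonds
    b <- b[b$protein_a != id & b$protein_b != id, , drop = FALSE]
    if (is.null(b) || !nrow(b)) next
    insts <- sort(unique(c(b$inst_a, b$inst_b)))
    remap <- setNames(seq_along(insts), insts)
    prot <- character(length(insts))
    prot[remap[as.character(b$inst_a)]] <- b$protein_a
    prot[remap[as.character(b$inst_b)]] <- b$protein_b
    b2 <- b
    b2$inst_a <- unname(remap[as.character(b$inst_a)])
    b2$inst_b <- unname(remap[as.character(b$inst_b)])
    frags <- extract_complexes(prot, b2, run_id = sc$run_id,
                               sample_time = sc$sample_time)
    out <- c(out, frags)
  }
  out
}

#' Run a full drug-perturbation experiment
#'
#' Simulates the model with and without the drug under identical
#' configuration and seeds, refines both simulated complex pools (drug
#' instances are removed from treated complexes before refinement, and
#' complexes held together only by the drug are split accordingly), and
#' calls per-complex changes.
#'
#' @param model A `complexome_model`.
#' @param drug A [drug_spec()].
#' @param config A [lattice_config()].
#' @param bound_domains Optional explicit bound domain set (default:
#'   enrichment-based inference).
#' @param tau,assoc_threshold Refinement parameters (see
#'   [refine_complexes()]).
#' @param match_threshold,alpha Calling parameters (see
#'   [call_perturbations()]).
#' @return List with `control` and `treated` (`refined_complexes`),
#'   `calls` (data frame), `bound_domains` and the SC pools
#'   (`control_scs`, `treated_scs`).
#' @export
run_perturbation <- function(model, drug, config = lattice_config(),
                             bound_domains = NULL, tau = 0.5,
                             assoc_threshold = 0.25, match_threshold = 0.25,
                             alpha = 0.05) {
  if (is.null(bound_domains)) {
    bound_domains <- as.character(infer_drug_domains(drug$targets, model))
  }
  treated_model <- add_drug(model, drug, bound_domains)
  control_sim <- run_simulation(model, config)
  treated_sim <- run_simulation(treated_model, config)
  treated_scs <- .strip_species(treated_sim$scs, drug$id)
  control_rcs <- refine_complexes(control_sim$scs, tau = tau,
                                  assoc_threshold = assoc_threshold)
  treated_rcs <- refine_complexes(treated_scs, tau = tau,
                                  assoc_threshold = assoc_threshold)
  calls <- call_perturbations(control_rcs, treated_rcs,
                              match_threshold = match_threshold, alpha = alpha)
  list(control = control_rcs, treated = treated_rcs, calls = calls,
       bound_domains = bound_domains,
       control_scs = control_sim$scs, treated_scs = treated_scs)
}
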