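# Synthetic input bundles with planted ground-truth complexes, so the full
# pipeline (build -> simulate -> refine -> score -> perturb) is testable
# without any external dataset.

#' Configuration of a synthetic fixture
#'
#' @param n_planted Number of planted complexes (default 10).
#' @param size_range Two-element vector: min/max members per planted
#'   complex (default 3 to 8; the minimum of 3 keeps planted complexes
#'   above the reference-set size filter).
#' @param n_decoys Proteins outside planted complexes (default 100); they
#'   carry domains and abundances and are wired only by noise edges.
#' @param noise_ppi_rate Fraction of spurious edges in the PPI table
#'   (default 0.05).
#' @param ddi_coverage Probability that a planted or noise edge's domain
#'   pair is written to the DDI table (default 0.7); uncovered edges are
#'   left to fictitious-domain rescue via shared function terms.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters (natural
#'   log) of raw protein abundances, default `meanlog = 4`, `sdlog = 1`:
#'   copy numbers spanning roughly 10 to 1e5, emulating the spread of a
#'   proteome-wide abundance table. Draws are clamped to at least 1.
#' @param extra_edge_prob Probability of each non-spanning-tree member
#'   pair of a planted complex receiving an additional internal edge
#'   (default 0.3).
#' @param shared_function_rate Probability that a DDI-uncovered *noise*
#'   edge's endpoints are given a shared function term (and hence survive
#'   fictitious rescue); members of one planted complex always share that
#'   complex's term, keeping planted complexes connected.
#' @param seed RNG seed; identical configurations yield byte-identical
#'   bundles.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n_planted = 10, size_range = c(3, 8),
                           n_decoys = 100, noise_ppi_rate = 0.05,
                           ddi_coverage = 0.7, abundance_meanlog = 4,
                           abundance_sdlog = 1, extra_edge_prob = 0.3,
                           shared_function_rate = 0.8, seed = 1L) {
  stopifnot(n_planted >= 1, length(size_range) == 2,
            size_range[1] >= 3, size_range[2] >= size_range[1],
            n_decoys >= 0, noise_ppi_rate >= 0, noise_ppi_rate < 1,
            ddi_coverage >= 0, ddi_coverage <= 1,
            shared_function_rate >= 0, shared_function_rate <= 1)
  structure(list(n_planted = as.integer(n_planted),
                 size_range = as.integer(size_range),
                 n_decoys = as.integer(n_decoys),
                 noise_ppi_rate = noise_ppi_rate,
                 ddi_coverage = ddi_coverage,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 extra_edge_prob = extra_edge_prob,
                 shared_function_rate = shared_function_rate,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a complete synthetic input bundle
#'
#' Planted complexes are built as connected graphs over their members
#' (random spanning tree plus extra edges); every internal edge receives
#' its own exclusive domain pair, written to the DDI table with
#' probability `ddi_coverage`, and all members share a complex-specific
#' function term so uncovered internal edges are rescued by fictitious
#' domains. Decoy proteins carry private domains; noise edges between
#' random protein pairs get fresh domain pairs under the same coverage
#' rule. Abundances are log-normal. The planted member sets double as the
#' reference complex set.
#'
#' @param config A [fixture_config()].
#' @return An object of class `fixture_bundle`: list with the input tables
#'   (`ppi`, `ddi`, `domains`, `abundance`, `annotations`), the
#'   `reference` complex list, and `truth` (planted member sets,
#'   `edge_table` with per-edge domain pairs, and the expected
#'   co-membership pairs).
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  size_vals <- seq(config$size_range[1], config$size_range[2])
  sizes <- size_vals[sample.int(length(size_vals), config$n_planted,
                                replace = TRUE)]
  planted <- lapply(seq_len(config$n_planted), function(k) {
    sprintf("C%02dP%d", k, seq_len(sizes[k]))
  })
  decoys <- if (config$n_decoys) sprintf("DEC%03d", seq_len(config$n_decoys)) else character(0)
  all_prot <- c(unlist(planted), decoys)

  dom_counter <- 0L
  new_domain <- function() {
    dom_counter <<- dom_counter + 1L
    sprintf("D%05d", dom_counter)
  }

  ppi <- list(); ddi <- list(); domains <- list(); ann <- list()
  edge_rows <- list()

  for (k in seq_len(config$n_planted)) {
    mem <- planted[[k]]
    s <- length(mem)
    edges <- cbind(2:s, vapply(2:s, function(i) sample.int(i - 1, 1), integer(1)))
    others <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
    in_tree <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    others <- others[!(paste(others[, 1], others[, 2]) %in% in_tree), ,
                     drop = FALSE]
    if (nrow(others)) {
      take <- runif(nrow(others)) < config$extra_edge_prob
      edges <- rbind(edges, others[take, c(2, 1), drop = FALSE])
    }
    for (e in seq_len(nrow(edges))) {
      pa <- mem[min(edges[e, ])]; pb <- mem[max(edges[e, ])]
      da <- new_domain(); db <- new_domain()
      covered <- runif(1) < config$ddi_coverage
      ppi[[length(ppi) + 1]] <- c(pa, pb)
      domains[[length(domains) + 1]] <- c(pa, da)
      domains[[length(domains) + 1]] <- c(pb, db)
      if (covered) ddi[[length(ddi) + 1]] <- c(da, db)
      edge_rows[[length(edge_rows) + 1]] <- data.frame(
        complex = k, protein_a = pa, protein_b = pb,
        domain_a = da, domain_b = db, ddi_covered = covered,
        stringsAsFactors = FALSE)
    }
    for (p in mem) ann[[length(ann) + 1]] <- c(p, sprintf("FUNC%02d", k))
  }

  for (d in decoys) {
    domains[[length(domains) + 1]] <- c(d, new_domain())
  }

  n_planted_edges <- length(ppi)
  n_noise <- round(config$noise_ppi_rate * n_planted_edges /
                     (1 - config$noise_ppi_rate))
  existing <- vapply(ppi, function(e) paste(sort(e), collapse = "\r"),
                     character(1))
  noise_term <- 0L
  tries <- 0L
  while (n_noise > 0 && tries < 1000L) {
    tries <- tries + 1L
    pair <- sample(all_prot, 2)
    key <- paste(sort(pair), collapse = "\r")
    if (key %in% existing) next
    existing <- c(existing, key)
    da <- new_domain(); db <- new_domain()
    covered <- runif(1) < config$ddi_coverage
    ppi[[length(ppi) + 1]] <- pair
    domains[[length(domains) + 1]] <- c(pair[1], da)
    domains[[length(domains) + 1]] <- c(pair[2], db)
    if (covered) {
      ddi[[length(ddi) + 1]] <- c(da, db)
    } else if (runif(1) < config$shared_function_rate) {
      noise_term <- noise_term + 1L
      term <- sprintf("NOISEFUNC%02d", noise_term)
      ann[[length(ann) + 1]] <- c(pair[1], term)
      ann[[length(ann) + 1]] <- c(pair[2], term)
    }
    edge_rows[[length(edge_rows) + 1]] <- data.frame(
      complex = NA_integer_, protein_a = min(pair), protein_b = max(pair),
      domain_a = da, domain_b = db, ddi_covered = covered,
      stringsAsFactors = FALSE)
    n_noise <- n_noise - 1L
  }

  abundance <- data.frame(
    protein = all_prot,
    copies_per_cell = pmax(1, round(rlnorm(length(all_prot),
                                           config$abundance_meanlog,
                                           config$abundance_sdlog))),
    stringsAsFactors = FALSE)

  to_df <- function(lst, nms) {
    if (!length(lst)) {
      return(as.data.frame(setNames(rep(list(character(0)), length(nms)), nms),
                           stringsAsFactors = FALSE))
    }
    m <- do.call(rbind, lst)
    out <- data.frame(m[, 1], m[, 2], stringsAsFactors = FALSE)
    names(out) <- nms
    out
  }

  comember <- do.call(rbind, lapply(seq_along(planted), function(k) {
    mem <- sort(planted[[k]])
    if (length(mem) < 2) return(NULL)
    pr <- t(combn(mem, 2))
    data.frame(complex = k, protein_a = pr[, 1], protein_b = pr[, 2],
               stringsAsFactors = FALSE)
  }))

  structure(list(ppi = to_df(ppi, c("protein_a", "protein_b")),
                 ddi = to_df(ddi, c("domain_a", "domain_b")),
                 domains = to_df(domains, c("protein", "domain")),
                 abundance = abundance,
                 annotations = to_df(ann, c("protein", "term")),
                 reference = planted,
                 truth = list(complexes = planted,
                              edge_table = do.call(rbind, edge_rows),
                              comembership = comember),
                 drug = NULL,
                 config = config),
            class = "fixture_bundle")
}

#' Rewire a fixture into a drug-perturbation test bed
#'
#' One planted complex is designated the victim: its internal edges are
#' rewired through a single shared bridging domain (each member receives
#' `n_bridge_slots` slots of it, the old per-edge domains and DDIs are
#' removed), so the bridging domain is carried by every target and is rare
#' elsewhere - the enrichable signal for drug-domain inference. The drug's
#' target list is the victim's member set, and its default abundance is
#' the raw abundance of the most abundant fixture protein.
#'
#' @param bundle A `fixture_bundle` from [generate_fixture()].
#' @param victim Index of the planted complex to target (default 1).
#' @param drug_id Identifier of the drug species.
#' @param n_bridge_slots Bridging-domain slots per victim member (default
#'   2, enough for connected multimers to form through the shared domain).
#' @param drug_abundance Raw molecule count of the drug. The default doses
#'   the drug like a saturating inhibitor: its instance count is 50 times
#'   the mean protein instance count of the fixture, the same
#'   instance-scale excess that a drug dosed at the abundance of the most
#'   abundant protein has in a proteome-wide dataset, whose abundance
#'   spread is orders of magnitude wider than this compact fixture's.
#' @return The modified `fixture_bundle`, with elements `drug_targets`
#'   (data frame `drug_id`, `target_protein`) and `drug` (a [drug_spec()])
#'   added, and `truth$bridge_domain` recording the planted signal.
#' @export
generate_drug_fixture <- function(bundle, victim = 1, drug_id = "DRUG1",
                                  n_bridge_slots = 2, drug_abundance = NULL) {
  stopifnot(inherits(bundle, "fixture_bundle"),
            victim >= 1, victim <= length(bundle$truth$complexes))
  mem <- bundle$truth$complexes[[victim]]
  et <- bundle$truth$edge_table
  vic_rows <- which(!is.na(et$complex) & et$complex == victim)
  old_domains <- unique(c(et$domain_a[vic_rows], et$domain_b[vic_rows]))
  bundle$domains <- bundle$domains[!(bundle$domains$domain %in% old_domains), ,
                                   drop = FALSE]
  bundle$ddi <- bundle$ddi[!(bundle$ddi$domain_a %in% old_domains |
                               bundle$ddi$domain_b %in% old_domains), ,
                           drop = FALSE]
  bridge <- sprintf("BRIDGE%02d", victim)
  add <- data.frame(protein = rep(mem, each = n_bridge_slots),
                    domain = bridge, stringsAsFactors = FALSE)
  bundle$domains <- rbind(bundle$domains, add)
  bundle$ddi <- rbind(bundle$ddi,
                      data.frame(domain_a = bridge, domain_b = bridge,
                                 stringsAsFactors = FALSE))
  et$domain_a[vic_rows] <- bridge
  et$domain_b[vic_rows] <- bridge
  et$ddi_covered[vic_rows] <- TRUE
  bundle$truth$edge_table <- et
  bundle$truth$bridge_domain <- bridge
  bundle$truth$victim <- victim
  if (is.null(drug_abundance)) {
    mean_inst <- mean(transform_abundance(bundle$abundance$copies_per_cell))
    drug_abundance <- (50 * mean_inst)^2
  }
  bundle$drug_targets <- data.frame(drug_id = drug_id, target_protein = mem,
                                    stringsAsFactors = FALSE)
  bundle$drug <- drug_spec(drug_id, mem, drug_abundance)
  bundle
}

#' Write a fixture bundle to a directory of flat files
#'
#' Writes `ppi.tsv`, `ddi.tsv`, `domains.tsv`, `abundance.tsv`,
#' `annotations.tsv`, `reference_complexes.txt` and, when present,
#' `drug_targets.tsv`, in the tab-separated formats read by the package's
#' input readers. Output is byte-reproducible for a given configuration.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  w(bundle$ppi, "ppi.tsv")
  w(bundle$ddi, "ddi.tsv")
  w(bundle$domains, "domains.tsv")
  w(bundle$abundance, "abundance.tsv")
  w(bundle$annotations, "annotations.tsv")
  write_reference_complexes(bundle$reference,
                            file.path(dir, "reference_complexes.txt"))
  if (!is.null(bundle$drug_targets)) w(bundle$drug_targets, "drug_targets.tsv")
  invisible(dir)
}

#' Build the integrated model directly from a fixture bundle
#'
#' @param bundle A `fixture_bundle`.
#' @return A `complexome_model` (see [build_model()]).
#' @export
build_fixture_model <- function(bundle) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  build_model(bundle$ppi, bundle$ddi, bundle$domains, bundle$abundance,
              bundle$annotations)
}
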