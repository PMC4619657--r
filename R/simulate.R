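# Reaction-diffusion simulation of domain-mediated binding on the 2D
# sub-volume lattice, and extraction of simulated complexes (SCs) from
# snapshot bond graphs.

#' Configuration of the lattice simulation
#'
#' @param grid_side Sub-volumes per lattice axis. Default `NULL` sizes the
#'   grid at run time to target roughly 50 protein instances per sub-volume
#'   (`ceiling(sqrt(total_instances / 50))`), keeping the space fine enough
#'   that distant instances rarely meet while every instance can still
#'   traverse it within the simulated span.
#' @param diffusion_interval Time between diffusion sweeps; each sweep is
#'   followed by an exact stochastic simulation of binding within every
#'   sub-volume for this duration (operator splitting).
#' @param k_on Association propensity per complementary free slot pair
#'   co-located in one sub-volume (1/time).
#' @param k_off Dissociation propensity per bond (1/time). The default
#'   `k_on = 1`, `k_off = 0.1` is a binding-favoured regime in arbitrary
#'   time units, so complexes accumulate over the simulated span.
#' @param t_end Simulation length; default 200 diffusion intervals.
#' @param sample_times Times at which complexes are collected; default the
#'   midpoint and the end of the run, so that the default two runs yield
#'   four collection points in total.
#' @param n_runs Number of independent runs with different random initial
#'   placements; default 2.
#' @param seed Base RNG seed; run `r` uses `seed + r - 1`.
#' @param periodic Use periodic instead of reflecting lattice boundaries.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(grid_side = NULL, diffusion_interval = 1,
                           k_on = 1, k_off = 0.1, t_end = 200,
                           sample_times = NULL, n_runs = 2, seed = 1L,
                           periodic = FALSE) {
  if (is.null(sample_times)) sample_times <- c(t_end / 2, t_end)
  stopifnot(k_on > 0, k_off >= 0, t_end > 0, diffusion_interval > 0,
            n_runs >= 1)
  if (any(sample_times <= 0) || any(sample_times > t_end)) {
    stop("sample_times must lie in (0, t_end]")
  }
  if (!is.null(grid_side) && grid_side < 1) stop("grid_side must be >= 1")
  structure(list(grid_side = grid_side,
                 diffusion_interval = diffusion_interval,
                 k_on = k_on, k_off = k_off, t_end = t_end,
                 sample_times = sort(unique(sample_times)),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 periodic = isTRUE(periodic)),
            class = "lattice_config")
}

.default_grid_side <- function(total_instances) {
  max(1L, as.integer(ceiling(sqrt(total_instances / 50))))
}

# encode model into 0-based arrays for the C++ core
.encode_model <- function(model, config) {
  proteins <- model$proteins$id
  slots <- model$slots[proteins]
  domain_ids <- sort(unique(c(unlist(slots, use.names = FALSE),
                              model$rules$domain_a, model$rules$domain_b)))
  dmap <- setNames(seq_along(domain_ids) - 1L, domain_ids)
  pmap <- setNames(seq_along(proteins) - 1L, proteins)
  prot_slots <- lapply(slots, function(s) unname(dmap[s]))
  rules <- model$rules
  rmat <- cbind(pmap[rules$protein_a], dmap[rules$domain_a],
                pmap[rules$protein_b], dmap[rules$domain_b])
  storage.mode(rmat) <- "integer"
  kon <- rep(config$k_on, nrow(rules))
  koff <- rep(config$k_off, nrow(rules))
  if (!is.null(rules$k_on)) {
    kon <- ifelse(is.na(rules$k_on), kon, rules$k_on)
  }
  if (!is.null(rules$k_off)) {
    koff <- ifelse(is.na(rules$k_off), koff, rules$k_off)
  }
  inst_count <- model$proteins$instance_count
  list(proteins = proteins, prot_slots = prot_slots, rmat = rmat,
       kon = as.numeric(kon), koff = as.numeric(koff),
       n_prot = length(proteins), n_dom = length(domain_ids),
       inst_protein0 = rep(seq_along(proteins) - 1L, inst_count),
       inst_protein = rep(proteins, inst_count),
       provenance = rules$provenance)
}

#' Run the lattice simulation and collect simulated complexes
#'
#' Each run places `instance_count` copies of every protein uniformly at
#' random over the sub-volumes, then alternates a diffusion sweep (every
#' connected bound group moves as a rigid unit to a uniformly chosen option
#' among staying or entering a valid 4-neighbour sub-volume) with an exact
#' Gillespie simulation of association/dissociation inside each sub-volume.
#' A bond may form only between two free slots, co-located in one
#' sub-volume, whose (protein, domain) pair matches a model rule; a slot
#' holds at most one bond, so proteins compete for binding sites. At every
#' sampling time, each connected bound group with at least two members is
#' recorded as one simulated complex (SC).
#'
#' @param model A `complexome_model` from [build_model()].
#' @param config A [lattice_config()].
#' @param extract Extract SCs from the snapshots (set `FALSE` to keep only
#'   raw snapshots, e.g. for densely sampled kinetic runs).
#' @return An object of class `sc_sim`: list with `scs` (pooled SC list;
#'   each SC has `members`, `bonds`, `run_id`, `sample_time`,
#'   `fictitious_fraction`), `runs` (per-run event log with association /
#'   dissociation counts and the time integral of the bond count),
#'   `snapshots` (raw per-run snapshot data), `instance_counts`,
#'   `grid_side` and `config`.
#' @export
run_simulation <- function(model, config = lattice_config(), extract = TRUE) {
  stopifnot(inherits(model, "complexome_model"),
            inherits(config, "lattice_config"))
  enc <- .encode_model(model, config)
  total <- length(enc$inst_protein0)
  if (total < 1) stop("model has no protein instances")
  grid_side <- if (is.null(config$grid_side)) {
    .default_grid_side(total)
  } else as.integer(config$grid_side)

  n_steps <- as.integer(round(config$t_end / config$diffusion_interval))
  sample_steps <- as.integer(round(config$sample_times / config$diffusion_interval))
  sample_steps <- pmin(pmax(sample_steps, 1L), n_steps)

  scs <- list()
  raw <- vector("list", config$n_runs)
  logs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    set.seed(config$seed + r - 1L)
    res <- .sim_run_cpp(enc$inst_protein0, enc$prot_slots, enc$rmat,
                        enc$kon, enc$koff, enc$n_prot, enc$n_dom,
                        grid_side, n_steps, config$diffusion_interval,
                        sample_steps, config$periodic)
    raw[[r]] <- res$snapshots
    logs[[r]] <- data.frame(run_id = r, n_assoc = res$n_assoc,
                            n_dissoc = res$n_dissoc,
                            bond_time = res$bond_time)
    if (extract) {
      for (snap in res$snapshots) {
        scs <- c(scs, .snapshot_to_scs(snap, enc, model, r))
      }
    }
  }
  structure(list(scs = scs,
                 runs = do.call(rbind, logs),
                 snapshots = raw,
                 instance_counts = setNames(model$proteins$instance_count,
                                            model$proteins$id),
                 grid_side = grid_side,
                 config = config),
            class = "sc_sim")
}

.snapshot_to_scs <- function(snap, enc, model, run_id) {
  bm <- snap$bonds
  if (!nrow(bm)) return(list())
  bonds <- data.frame(inst_a = bm[, 1] + 1L, inst_b = bm[, 3] + 1L,
                      stringsAsFactors = FALSE)
  rule_idx <- bm[, 5] + 1L
  bonds$protein_a <- enc$inst_protein[bonds$inst_a]
  bonds$protein_b <- enc$inst_protein[bonds$inst_b]
  slot_a <- bm[, 2] + 1L
  slot_b <- bm[, 4] + 1L
  bonds$domain_a <- mapply(function(p, s) model$slots[[p]][s],
                           bonds$protein_a, slot_a)
  bonds$domain_b <- mapply(function(p, s) model$slots[[p]][s],
                           bonds$protein_b, slot_b)
  bonds$fictitious <- enc$provenance[rule_idx] == "fictitious"
  extract_complexes(enc$inst_protein, bonds,
                    run_id = run_id, sample_time = snap$time)
}

#' Extract simulated complexes from an instance-level bond graph
#'
#' Connected components with at least two member instances of the bond
#' graph become simulated-complex records. This realizes the definition of
#' a simulated complex as one connected bound group observed at a sampling
#' point.
#'
#' @param instance_proteins Character vector: protein identity of every
#'   instance (vertex) in the state.
#' @param bonds Data frame with integer columns `inst_a`, `inst_b`
#'   (1-based instance indices) and optionally `protein_a`, `domain_a`,
#'   `protein_b`, `domain_b`, `fictitious`.
#' @param run_id,sample_time Tags copied onto each record.
#' @return List of SC records: `members` (protein multiset as character
#'   vector), `bonds` (rows of `bonds` within the component), `run_id`,
#'   `sample_time`, `fictitious_fraction`.
#' @export
extract_complexes <- function(instance_proteins, bonds, run_id = NA,
                              sample_time = NA) {
  n <- length(instance_proteins)
  if (is.null(bonds) || !nrow(bonds)) return(list())
  g <- igraph::make_graph(rbind(bonds$inst_a, bonds$inst_b), n = n,
                          directed = FALSE)
  comp <- igraph::components(g)
  sizes <- tabulate(comp$membership, comp$no)
  keep <- which(sizes >= 2)
  comp_of_bond <- comp$membership[bonds$inst_a]
  has_fict <- !is.null(bonds$fictitious)
  lapply(keep, function(ci) {
    insts <- which(comp$membership == ci)
    brows <- bonds[comp_of_bond == ci, , drop = FALSE]
    ff <- if (has_fict) mean(as.logical(brows$fictitious)) else NA_real_
    list(members = instance_proteins[insts],
         bonds = brows,
         run_id = run_id,
         sample_time = sample_time,
         fictitious_fraction = ff)
  })
}

#' @export
print.sc_sim <- function(x, ...) {
  cat(sprintf("Lattice simulation: %d run(s), grid %dx%d, %d SCs collected\n",
              x$config$n_runs, x$grid_side, x$grid_side, length(x$scs)))
  tags <- table(vapply(x$scs, function(s) {
    paste0("run ", s$run_id, " @ t=", s$sample_time)
  }, character(1)))
  for (nm in names(tags)) cat(sprintf("  %s: %d complexes\n", nm, tags[[nm]]))
  invisible(x)
}
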