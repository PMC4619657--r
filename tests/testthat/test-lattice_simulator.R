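# Unit and property tests of the reaction-diffusion simulator: determinism,
# conservation, site exclusivity, co-location, licensed binding, kinetic
# limits and component extraction.

dimer_model <- function(ab_a = 100, ab_b = 100) {
  toy_model(edge_df("A", "B"), dom_df("A", "d1", "B", "d2"),
            ddi_df("d1", "d2"), ab_df(c("A", "B"), c(ab_a, ab_b)))
}

test_that("identical model, config and seed give identical SC lists", {
  m <- dimer_model()
  cfg <- lattice_config(t_end = 40, sample_times = c(20, 40), n_runs = 2,
                        seed = 11)
  s1 <- run_simulation(m, cfg)
  s2 <- run_simulation(m, cfg)
  expect_identical(s1$scs, s2$scs)
  expect_identical(s1$runs, s2$runs)
  s3 <- run_simulation(m, lattice_config(t_end = 40, sample_times = c(20, 40),
                                         n_runs = 2, seed = 12))
  expect_false(identical(s1$scs, s3$scs))
})

test_that("default sampling produces four distinct collection points", {
  m <- dimer_model()
  sim <- run_simulation(m, lattice_config(t_end = 40, seed = 1))
  tags <- unique(vapply(sim$scs, function(s) {
    paste(s$run_id, s$sample_time)
  }, character(1)))
  expect_setequal(tags, c("1 20", "1 40", "2 20", "2 40"))
})

test_that("a model without rules yields no complexes", {
  m <- dimer_model()
  m$rules <- m$rules[0, ]
  sim <- run_simulation(m, lattice_config(t_end = 20, seed = 1))
  expect_length(sim$scs, 0)
})

test_that("snapshot invariants hold: conservation, exclusivity, co-location, licensing", {
  set.seed(1)
  bundle <- generate_fixture(fixture_config(seed = 3))
  model <- build_fixture_model(bundle)
  sim <- run_simulation(model, lattice_config(t_end = 60,
                                              sample_times = c(30, 60),
                                              seed = 3))
  rule_keys <- with(model$rules, {
    k1 <- paste(protein_a, domain_a, protein_b, domain_b)
    k2 <- paste(protein_b, domain_b, protein_a, domain_a)
    unique(c(k1, k2))
  })
  snaps <- snapshot_checks(sim, model)
  expect_gt(length(snaps), 0)
  for (sn in snaps) {
    bm <- sn$bonds
    # site exclusivity: no (instance, slot) appears in two bonds
    ends <- c(paste(bm[, 1], bm[, 2]), paste(bm[, 3], bm[, 4]))
    expect_false(any(duplicated(ends)))
    # co-location: bonded instances share a sub-volume
    expect_true(all(sn$inst_sv[bm[, 1] + 1] == sn$inst_sv[bm[, 3] + 1]))
    # licensing: every bond's (protein, domain) endpoints match a rule
    pa <- sn$inst_protein[bm[, 1] + 1]
    pb <- sn$inst_protein[bm[, 3] + 1]
    da <- mapply(function(p, s) model$slots[[p]][s + 1], pa, bm[, 2])
    db <- mapply(function(p, s) model$slots[[p]][s + 1], pb, bm[, 4])
    expect_true(all(paste(pa, da, pb, db) %in% rule_keys))
  }
  # conservation: per snapshot, bound + free = instance_count for every protein
  inst <- sim$instance_counts
  snap_ids <- vapply(sim$scs, function(s) paste(s$run_id, s$sample_time),
                     character(1))
  for (sid in unique(snap_ids)) {
    bound <- table(unlist(lapply(sim$scs[snap_ids == sid], `[[`, "members")))
    expect_true(all(bound <= inst[names(bound)]))
  }
  ub <- unbound_fractions(model, sim)
  expect_true(all(ub$mean_free >= 0))
  expect_true(all(ub$mean_free <= ub$instance_count))
})

test_that("a 1x1 grid is the well-mixed limit and bound groups stay together", {
  m <- toy_model(edge_df("A", "B", "B", "C"),
                 dom_df("A", "d1", "B", "d2", "B", "d3", "C", "d4"),
                 ddi_df("d1", "d2", "d3", "d4"),
                 ab_df(c("A", "B", "C"), c(9, 9, 9)))
  sim <- run_simulation(m, lattice_config(grid_side = 3, t_end = 100,
                                          sample_times = seq(10, 100, 10),
                                          n_runs = 1, seed = 5, k_off = 0.05))
  # trimers observed; all members of any SC share one SV at sampling
  snaps <- snapshot_checks(sim, m)
  for (sn in snaps) {
    bm <- sn$bonds
    if (nrow(bm)) expect_true(all(sn$inst_sv[bm[, 1] + 1] == sn$inst_sv[bm[, 3] + 1]))
  }
  sizes <- vapply(sim$scs, function(s) length(s$members), numeric(1))
  expect_gte(max(sizes), 3)
})

test_that("with irreversible binding a co-located pair always ends bound", {
  m <- dimer_model(ab_a = 1, ab_b = 1)
  sim <- run_simulation(m, lattice_config(grid_side = 1, t_end = 50,
                                          sample_times = 50, n_runs = 1,
                                          seed = 2, k_on = 5, k_off = 0))
  expect_length(sim$scs, 1)
  expect_setequal(sim$scs[[1]]$members, c("A", "B"))
})

test_that("dimer counts never exceed the limiting instance count", {
  m <- dimer_model(10000, 10000)  # 100 instances each
  sim <- run_simulation(m, lattice_config(t_end = 60, sample_times = c(30, 60),
                                          n_runs = 1, seed = 4, k_off = 0))
  snap_ids <- vapply(sim$scs, function(s) paste(s$run_id, s$sample_time),
                     character(1))
  for (sid in unique(snap_ids)) {
    expect_lte(sum(snap_ids == sid), 100)
  }
})

test_that("a single pair with equal rates is bound half the time", {
  # two-state CTMC: stationary bound fraction k_on / (k_on + k_off) = 1/2;
  # the time integral of the bond count over one A-B pair in one SV
  # estimates it; tolerance is 3 standard errors from renewal theory
  m <- dimer_model(1, 1)
  t_end <- 20000
  sim <- run_simulation(m, lattice_config(grid_side = 1, t_end = t_end,
                                          sample_times = t_end, n_runs = 1,
                                          seed = 9, k_on = 1, k_off = 1),
                        extract = FALSE)
  n_events <- sim$runs$n_assoc + sim$runs$n_dissoc
  expect_gte(n_events, 1e4)
  p_hat <- sim$runs$bond_time / t_end
  se <- sqrt(2 * p_hat^2 * (1 - p_hat)^2 * (1 + 1) / t_end)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("complex extraction agrees with a union-find oracle on random bond graphs", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    prot <- paste0("p", sample(10, n, replace = TRUE))
    m <- sample(0:60, 1)
    bonds <- data.frame(inst_a = sample(n, m, replace = TRUE),
                        inst_b = sample(n, m, replace = TRUE))
    scs <- extract_complexes(prot, bonds, run_id = 1, sample_time = 1)
    comp <- uf_components(n, as.matrix(bonds))
    sizes <- table(comp)
    want <- sort(as.integer(sizes[sizes >= 2]))
    got <- sort(vapply(scs, function(s) length(s$members), integer(1)))
    expect_identical(got, want)
    # membership multisets agree component by component
    want_members <- sort(unname(vapply(
      names(sizes)[sizes >= 2],
      function(ci) paste(sort(prot[comp == as.integer(ci)]), collapse = ";"),
      character(1))))
    got_members <- sort(vapply(scs, function(s) {
      paste(sort(s$members), collapse = ";")
    }, character(1)))
    expect_identical(got_members, want_members)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(lattice_config(t_end = 100, sample_times = c(50, 150)),
               "sample_times")
  expect_error(lattice_config(k_on = 0), "k_on")
  expect_error(lattice_config(grid_side = 0), "grid_side")
})
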