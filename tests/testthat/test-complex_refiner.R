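# Frequency matrix, clustering, abundance assignment, filters, overlap
# graph and unbound-subunit accounting.

test_that("frequency matrix counts pairwise co-occurrence per SC", {
  scs <- list(sc_rec(c("A", "B", "C")), sc_rec(c("A", "B")))
  fm <- build_frequency_matrix(scs)
  expect_equal(fm$mat["A", "B"], 2)
  expect_equal(fm$mat["A", "C"], 1)
  expect_equal(fm$mat["B", "C"], 1)
  expect_equal(unname(fm$occurrence[c("A", "B", "C")]), c(2, 2, 1))
  empty <- build_frequency_matrix(list())
  expect_equal(nrow(empty$mat), 0)
})

test_that("frequency matrix equals the brute-force double-loop oracle", {
  set.seed(21)
  pool <- paste0("p", 1:30)
  scs <- lapply(1:1000, function(i) {
    sc_rec(sample(pool, sample(2:6, 1)))
  })
  fm <- build_frequency_matrix(scs)
  oracle <- brute_freq(lapply(scs, `[[`, "members"))
  expect_identical(fm$mat, oracle$mat)
  expect_identical(fm$occurrence, oracle$occurrence)
  # multiplicities in one SC do not inflate counts
  fm2 <- build_frequency_matrix(list(sc_rec(c("A", "A", "B"))))
  expect_equal(fm2$mat["A", "B"], 1)
  expect_equal(unname(fm2$occurrence["A"]), 1)
})

test_that("clustering separates disjoint co-occurring blocks at any tau", {
  scs <- c(replicate(10, sc_rec(c("A", "B", "C")), simplify = FALSE),
           replicate(10, sc_rec(c("X", "Y", "Z")), simplify = FALSE))
  fm <- build_frequency_matrix(scs)
  for (tau in c(0.1, 0.5, 1)) {
    cl <- cluster_matrix(fm, tau = tau)
    expect_setequal(vapply(cl, paste, character(1), collapse = ";"),
                    c("A;B;C", "X;Y;Z"))
  }
  # all-ones affinity collapses to a single cluster
  scs_one <- replicate(5, sc_rec(c("A", "B", "C", "D")), simplify = FALSE)
  cl_one <- cluster_matrix(build_frequency_matrix(scs_one), tau = 0.5)
  expect_length(cl_one, 1)
  expect_setequal(cl_one[[1]], c("A", "B", "C", "D"))
  expect_error(cluster_matrix(fm, tau = 1.5), "tau")
})

test_that("planted co-occurrence blocks are recovered under pair noise", {
  set.seed(31)
  planted <- lapply(1:10, function(k) sprintf("K%02dM%d", k, 1:4))
  scs <- list()
  for (k in 1:10) {
    for (r in 1:20) scs[[length(scs) + 1]] <- sc_rec(planted[[k]])
  }
  # 5% noise pairs across blocks
  n_noise <- round(0.05 * length(scs))
  all_p <- unlist(planted)
  for (i in seq_len(n_noise)) {
    scs[[length(scs) + 1]] <- sc_rec(sample(all_p, 2))
  }
  cl <- cluster_matrix(build_frequency_matrix(scs), tau = 0.5)
  keys <- vapply(cl, paste, character(1), collapse = ";")
  hits <- sum(vapply(planted, function(p) {
    paste(sort(p), collapse = ";") %in% keys
  }, logical(1)))
  expect_gte(hits, 9)
})

test_that("abundance assignment counts SCs and squares the report", {
  rc_sets <- list(c("A", "B", "C"))
  scs <- replicate(221, sc_rec(c("A", "B", "C")), simplify = FALSE)
  rcs <- assign_abundance(rc_sets, scs)
  expect_equal(rcs$rc[[1]]$sim_abundance, 221)
  expect_equal(rcs$rc[[1]]$reported_abundance, 48841)
  expect_equal(rcs$unassigned, 0)
})

test_that("each SC goes to its best-overlapping RC above the threshold", {
  rc_sets <- list(c("A", "B", "C", "D"), c("C", "D", "E"))
  # {A,B,C,D} scores 1 vs RC1 and 4/12 vs RC2
  scs <- list(sc_rec(c("A", "B", "C", "D")), sc_rec(c("C", "D", "E")),
              sc_rec(c("Q", "R")))
  rcs <- assign_abundance(rc_sets, scs)
  expect_equal(rcs$rc[[1]]$sim_abundance, 1)
  expect_equal(rcs$rc[[2]]$sim_abundance, 1)
  expect_equal(rcs$unassigned, 1)  # {Q,R} matches nothing
  # an RC no SC reaches gets zero abundance
  rcs2 <- assign_abundance(list(c("Z1", "Z2")), scs)
  expect_equal(rcs2$rc[[1]]$sim_abundance, 0)
  expect_equal(rcs2$unassigned, 3)
  # partition: assigned + unassigned = |SC list|
  tot <- sum(vapply(rcs$rc, `[[`, numeric(1), "sim_abundance")) + rcs$unassigned
  expect_equal(tot, length(scs))
})

test_that("per-run counts, CV and the squared report are consistent", {
  rc_sets <- list(c("A", "B"))
  scs <- c(lapply(1:3, function(i) sc_rec(c("A", "B"), run_id = 1)),
           lapply(1:5, function(i) sc_rec(c("A", "B"), run_id = 2)))
  rcs <- assign_abundance(rc_sets, scs)
  r <- rcs$rc[[1]]
  expect_equal(unname(r$per_run), c(3, 5))
  expect_equal(r$cv, sd(c(3, 5)) / mean(c(3, 5)))
  expect_equal(r$reported_abundance, r$sim_abundance^2)
})

test_that("LG and SM filters drop exactly the prescribed complexes", {
  mk <- function(id, size, ab) {
    list(rc_id = id, members = paste0("m", seq_len(size)), size = size,
         sim_abundance = ab, reported_abundance = ab^2, per_run = c(`1` = ab),
         per_snapshot = c(`1@1` = ab), cv = 0, fictitious_fraction = 0)
  }
  rcs <- structure(list(rc = list(mk("RC001", 12, 2), mk("RC002", 12, 5),
                                  mk("RC003", 3, 1)),
                        unassigned = 0), class = "refined_complexes")
  none <- filter_complexes(rcs, filter_policy("none"))
  expect_identical(none, rcs)
  lg <- filter_complexes(rcs, filter_policy("LG", abundance_threshold = 3,
                                            size_threshold = 10))
  expect_setequal(vapply(lg$rc, `[[`, character(1), "rc_id"),
                  c("RC002", "RC003"))
  sm <- filter_complexes(rcs, filter_policy("SM", abundance_threshold = 3,
                                            size_threshold = 10))
  expect_setequal(vapply(sm$rc, `[[`, character(1), "rc_id"),
                  c("RC001", "RC002"))
})

test_that("the RC overlap graph connects complexes sharing members", {
  sets <- list(c("a", "b", "c", "d"), c("c", "d", "e"), c("x", "y", "z"))
  g <- rc_overlap_graph(sets, threshold = 0.1)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$overlap, 4 / 12)
  g2 <- rc_overlap_graph(list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(g2$edges$overlap, 1)
})

test_that("unbound fractions respect conservation and edge cases", {
  m <- toy_model(edge_df("A", "B", "A", "C"),
                 dom_df("A", "d1", "B", "d2", "C", "d3"),
                 ddi_df("d1", "d2", "d1", "d3"),
                 ab_df(c("A", "B", "C"), c(16, 16, 16)))
  # C never bound; A and B bound pairwise in two snapshots
  scs <- list(sc_rec(c("A", "B"), run_id = 1, sample_time = 1),
              sc_rec(c("A", "A", "B", "B"), run_id = 1, sample_time = 2))
  ub <- unbound_fractions(m, scs)
  rownames(ub) <- ub$protein
  expect_equal(ub["C", "fraction_free"], 1)
  expect_equal(ub["A", "mean_free"], mean(c(4 - 1, 4 - 2)))
  expect_true(all(ub$mean_free + c(1.5, 1.5, 0)[match(ub$protein, c("A", "B", "C"))] ==
                    ub$instance_count))
  expect_equal(ub["A", "degree"], 2)
  # a fully consumed high-copy protein has fraction zero
  m2 <- toy_model(edge_df("T", "U"), dom_df("T", "d1", "U", "d2"),
                  ddi_df("d1", "d2"), ab_df(c("T", "U"), c(102000, 102000)))
  nT <- unname(m2$proteins$instance_count[m2$proteins$id == "T"])
  one <- list(sc_rec(rep(c("T", "U"), nT)))
  ub2 <- unbound_fractions(m2, one)
  expect_equal(ub2$fraction_free[ub2$protein == "T"], 0)
})

test_that("refined complexes survive the TSV writer", {
  rc_sets <- list(c("A", "B", "C"))
  scs <- replicate(4, sc_rec(c("A", "B", "C")), simplify = FALSE)
  rcs <- assign_abundance(rc_sets, scs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rcs(rcs, path)
  df <- read.delim(path)
  expect_equal(df$sim_abundance, 4)
  expect_equal(df$reported_abundance, 16)
})
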