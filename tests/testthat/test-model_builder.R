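test_that("abundance transform takes the rounded square root with a floor of one", {
  expect_identical(transform_abundance(10000), 100L)
  expect_identical(transform_abundance(0), 0L)
  # sqrt(7491) = 86.55, rounds half-up to 87
  expect_identical(transform_abundance(7491), 87L)
  expect_identical(transform_abundance(c(1, 2, 3)), c(1L, 1L, 2L))
  expect_error(transform_abundance(-5), "non-negative")
})

test_that("known-DDI rule derivation enumerates matching domain pairs per edge", {
  ppi <- edge_df("A", "B")
  # single match
  r1 <- derive_known_rules(ppi, dom_df("A", "d1", "B", "d2"), ddi_df("d1", "d2"))
  expect_equal(nrow(r1$rules), 1)
  expect_equal(r1$rules$domain_a, "d1")
  expect_equal(r1$rules$domain_b, "d2")
  expect_equal(r1$rules$provenance, "known_ddi")
  expect_equal(nrow(r1$uncovered), 0)
  # empty DDI: everything uncovered
  r2 <- derive_known_rules(ppi, dom_df("A", "d1", "B", "d2"), ddi_df())
  expect_equal(nrow(r2$rules), 0)
  expect_equal(nrow(r2$uncovered), 1)
  # all compatible pairs found (brute-force enumerable: d1-d2 and d3-d2)
  r3 <- derive_known_rules(ppi, dom_df("A", "d1", "A", "d3", "B", "d2"),
                           ddi_df("d1", "d2", "d3", "d2"))
  expect_equal(nrow(r3$rules), 2)
  expect_setequal(paste(r3$rules$domain_a, r3$rules$domain_b),
                  c("d1 d2", "d3 d2"))
})

test_that("proteins missing from the domain table go to uncovered, not error", {
  r <- derive_known_rules(edge_df("A", "X"), dom_df("A", "d1"), ddi_df("d1", "d1"))
  expect_equal(nrow(r$rules), 0)
  expect_equal(r$uncovered$protein_b, "X")
})

test_that("fictitious rescue requires a shared function term", {
  unc <- edge_df("A", "B", "C", "D")
  fun <- ann_df("A", "transcription", "B", "transcription", "C", "transport")
  res <- add_fictitious_rules(unc, dom_df("A", "d1"), fun)
  expect_equal(nrow(res$rules), 1)
  expect_equal(res$rules$provenance, "fictitious")
  expect_equal(res$rules$protein_a, "A")
  # both partners gain exactly one new slot with deterministic names
  expect_equal(res$new_slots$protein, c("A", "B"))
  expect_match(res$new_slots$domain, "^FICT_A_B_1_")
  expect_equal(res$dropped$protein_a, "C")
  # empty input is the identity
  empty <- add_fictitious_rules(edge_df()[0, ], dom_df("A", "d1"), fun)
  expect_equal(nrow(empty$rules), 0)
  expect_equal(nrow(empty$new_slots), 0)
})

# five proteins, four edges: two DDI-covered, one fictitious-rescued, one dropped
five_protein_inputs <- function() {
  list(ppi = edge_df("P1", "P2", "P2", "P3", "P3", "P4", "P4", "P5"),
       domains = dom_df("P1", "dA", "P2", "dB", "P2", "dC", "P3", "dD",
                        "P3", "dE", "P4", "dF", "P5", "dG"),
       ddi = ddi_df("dA", "dB", "dC", "dD"),
       abundance = ab_df(paste0("P", 1:5), c(100, 400, 900, 1600, 2500)),
       annotations = ann_df("P3", "metabolism", "P4", "metabolism",
                            "P5", "signalling"))
}

test_that("model building computes coverage and retains only ruled proteins", {
  inp <- five_protein_inputs()
  m <- build_model(inp$ppi, inp$ddi, inp$domains, inp$abundance, inp$annotations)
  expect_s3_class(m, "complexome_model")
  # 2 of 4 edges DDI-covered, 1 rescued, 1 dropped
  expect_equal(m$coverage$ddi_coverage_before, 0.5)
  expect_equal(m$coverage$ddi_coverage_after, 0.75)
  expect_setequal(m$proteins$id, c("P1", "P2", "P3", "P4"))  # P5 dropped
  expect_equal(m$coverage$n_interactions_model, 3)
  expect_identical(m$proteins$instance_count,
                   transform_abundance(m$proteins$abundance_raw))
  # every rule references retained proteins and existing slots
  for (i in seq_len(nrow(m$rules))) {
    expect_true(m$rules$protein_a[i] %in% m$proteins$id)
    expect_true(m$rules$domain_a[i] %in% m$slots[[m$rules$protein_a[i]]])
    expect_true(m$rules$domain_b[i] %in% m$slots[[m$rules$protein_b[i]]])
  }
})

test_that("full DDI coverage yields identical before/after fractions", {
  m <- build_model(edge_df("A", "B"), ddi_df("d1", "d2"),
                   dom_df("A", "d1", "B", "d2"), ab_df(c("A", "B"), c(4, 9)),
                   ann_df("A", "x"))
  expect_equal(m$coverage$ddi_coverage_before, 1)
  expect_equal(m$coverage$ddi_coverage_after, 1)
})

test_that("a protein with abundance but no rule is excluded from the model", {
  m <- build_model(edge_df("A", "B", "A", "C"), ddi_df("d1", "d2"),
                   dom_df("A", "d1", "B", "d2", "C", "d9"),
                   ab_df(c("A", "B", "C"), c(4, 9, 16)),
                   ann_df("A", "x"))
  expect_setequal(m$proteins$id, c("A", "B"))
})

test_that("an unsupported input combination raises an empty-model error", {
  expect_error(
    build_model(edge_df("A", "B"), ddi_df(), dom_df("A", "d1", "B", "d2"),
                ab_df(c("A", "B"), c(4, 9)),
                ann_df("A", "x", "B", "y")),
    "empty model")
})

test_that("model building is deterministic and locally sensitive to abundance removal", {
  inp <- five_protein_inputs()
  m1 <- build_model(inp$ppi, inp$ddi, inp$domains, inp$abundance, inp$annotations)
  m2 <- build_model(inp$ppi, inp$ddi, inp$domains, inp$abundance, inp$annotations)
  expect_identical(m1, m2)
  # coverage gain equals rescued edges / total edges, exactly
  n_fict_edges <- length(unique(paste(
    m1$rules$protein_a[m1$rules$provenance == "fictitious"],
    m1$rules$protein_b[m1$rules$provenance == "fictitious"])))
  expect_equal(m1$coverage$ddi_coverage_after - m1$coverage$ddi_coverage_before,
               n_fict_edges / m1$coverage$n_ppi_input)
  # dropping one protein's abundance removes it and its rules, nothing else
  ab2 <- inp$abundance[inp$abundance$protein != "P2", ]
  m3 <- build_model(inp$ppi, inp$ddi, inp$domains, ab2, inp$annotations)
  expect_false("P2" %in% m3$proteins$id)
  expect_false(any(m3$rules$protein_a == "P2" | m3$rules$protein_b == "P2"))
  kept <- m1$rules[m1$rules$protein_a != "P2" & m1$rules$protein_b != "P2", ]
  expect_equal(m3$rules[, c("protein_a", "domain_a", "protein_b", "domain_b")],
               kept[, c("protein_a", "domain_a", "protein_b", "domain_b")],
               ignore_attr = TRUE)
})

test_that("self-interactions produce rules on one protein", {
  m <- build_model(edge_df("A", "A"), ddi_df("d1", "d2"),
                   dom_df("A", "d1", "A", "d2"), ab_df("A", 100),
                   ann_df("A", "x"))
  expect_equal(nrow(m$rules), 1)
  expect_equal(m$rules$protein_a, "A")
  expect_equal(m$rules$protein_b, "A")
})

test_that("models survive a JSON round trip", {
  inp <- five_protein_inputs()
  m <- build_model(inp$ppi, inp$ddi, inp$domains, inp$abundance, inp$annotations)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$proteins, m$proteins, ignore_attr = TRUE)
  expect_equal(m2$rules, m$rules, ignore_attr = TRUE)
  expect_equal(m2$slots[order(names(m2$slots))], m$slots[order(names(m$slots))])
  expect_equal(m2$coverage, m$coverage)
})

test_that("malformed input lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tB", "brokenline"), path)
  expect_error(read_ppi(path), "line 3")
  writeLines(c("A\t12", "B\tnot_a_number"), path)
  expect_error(read_abundance(path), "line 2")
  writeLines(c("# only comments"), path)
  expect_equal(nrow(read_ppi(path)), 0)
})
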