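mkInv <- function(a = FALSE, f = FALSE, b = FALSE, id = "g") {
  cand <- function(role) structure(list(role = role, gene_id = "x",
                                        genome_id = id, evidence = list(),
                                        flags = character()),
                                   class = "Spo0Candidate")
  structure(list(genome_id = id,
                 spo0a = if (a) list(cand("SPO0A")) else list(),
                 spo0f = if (f) cand("SPO0F") else NULL,
                 spo0b = if (b) cand("SPO0B") else NULL,
                 kinases = data.frame(gene_id = character(),
                                      is_orphan = logical(),
                                      is_hybrid = logical(),
                                      has_nterm_pas = logical()),
                 phenotype = "unknown"),
            class = "Spo0Inventory")
}

test_that("architecture labels follow the component-presence rule", {
  expect_equal(callArchitecture(mkInv(a = TRUE, f = TRUE, b = TRUE))$label,
               "PHOSPHORELAY")
  expect_equal(callArchitecture(mkInv(a = TRUE))$label, "DIRECT")
  expect_equal(callArchitecture(mkInv(a = TRUE, b = TRUE))$label,
               "PARTIAL_RELAY")
  expect_equal(callArchitecture(mkInv(a = TRUE, f = TRUE))$label,
               "PARTIAL_RELAY")
  expect_equal(callArchitecture(mkInv())$label, "NO_SPO0")
  # intermediates without Spo0A still count as no pathway
  expect_equal(callArchitecture(mkInv(f = TRUE, b = TRUE))$label, "NO_SPO0")
  # pure function: same inventory, same call
  inv <- mkInv(a = TRUE, f = TRUE, b = TRUE)
  expect_identical(callArchitecture(inv), callArchitecture(inv))
})

test_that("Fitch transition counts match hand-worked trees", {
  t4 <- ape::read.tree(text = "((A,B),(C,D));")
  all_relay <- setNames(rep("PHOSPHORELAY", 4), c("A", "B", "C", "D"))
  expect_equal(fitchTransitionCount(t4, all_relay), 0L)
  alt <- setNames(c("PHOSPHORELAY", "DIRECT", "PHOSPHORELAY", "DIRECT"),
                  c("A", "B", "C", "D"))
  expect_equal(fitchTransitionCount(t4, alt), 2L)
  cherry <- ape::read.tree(text = "(A,B);")
  expect_equal(fitchTransitionCount(
    cherry, setNames(c("PHOSPHORELAY", "DIRECT"), c("A", "B"))), 1L)
})

test_that("NO_SPO0 leaves are pruned and unlabeled leaves are an error", {
  t4 <- ape::read.tree(text = "((A,B),(C,D));")
  lab <- setNames(c("PHOSPHORELAY", "NO_SPO0", "PHOSPHORELAY",
                    "PHOSPHORELAY"), c("A", "B", "C", "D"))
  expect_equal(fitchTransitionCount(t4, lab), 0L)
  expect_error(fitchTransitionCount(t4, lab[c("A", "B", "C")]), "unlabeled")
  # two-state mode collapses PARTIAL_RELAY into PHOSPHORELAY
  lab2 <- setNames(c("PHOSPHORELAY", "PARTIAL_RELAY", "DIRECT", "DIRECT"),
                   c("A", "B", "C", "D"))
  expect_equal(fitchTransitionCount(t4, lab2, twoState = TRUE), 1L)
  expect_equal(fitchTransitionCount(t4, lab2), 2L)
})

test_that("Fitch equals brute-force enumeration on random trees", {
  set.seed(77)
  states <- c("PHOSPHORELAY", "DIRECT", "PARTIAL_RELAY")
  for (i in 1:40) {
    n <- sample(3:8, 1)
    tr <- ape::rtree(n)
    lab <- setNames(sample(states, n, replace = TRUE), tr$tip.label)
    expect_equal(fitchTransitionCount(tr, lab),
                 bruteForceTransitions(tr, lab, states))
  }
})

test_that("transition count bounds hold", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    tr <- ape::rtree(n)
    lab <- setNames(sample(c("PHOSPHORELAY", "DIRECT"), n, replace = TRUE),
                    tr$tip.label)
    k <- fitchTransitionCount(tr, lab)
    expect_lte(k, n - 1L)
    expect_equal(k == 0L, length(unique(lab)) == 1L)
  }
})

test_that("presence/absence report follows tree order and flags strays", {
  cfg <- smallSimConfig(seed = 21,
                        architectures = c("PHOSPHORELAY", "DIRECT"))
  g1 <- generateGenome(cfg, 1, genomeId = "A")
  g2 <- generateGenome(cfg, 2, genomeId = "B")
  inv1 <- buildSpo0Inventory(g1$annotation)
  inv2 <- buildSpo0Inventory(g2$annotation)
  rep0 <- presenceAbsenceReport(list(inv1, inv2))
  expect_equal(nrow(rep0), 2L)
  expect_true(rep0$spo0f[rep0$genome_id == "A"])
  expect_false(rep0$spo0f[rep0$genome_id == "B"])
  expect_equal(rep0$architecture, c("PHOSPHORELAY", "DIRECT"))

  tree <- ape::read.tree(text = "((B,A),C);")
  repT <- presenceAbsenceReport(list(inv1, inv2), tree)
  expect_equal(repT$genome_id, c("B", "A", "C"))
  expect_true(is.na(repT$architecture[repT$genome_id == "C"]))
  expect_true(all(repT$in_tree[repT$genome_id %in% c("A", "B")]))

  tree2 <- ape::read.tree(text = "(A,C);")
  rep2 <- presenceAbsenceReport(list(inv1, inv2), tree2)
  expect_equal(rep2$genome_id, c("A", "C", "B"))
  expect_false(rep2$in_tree[rep2$genome_id == "B"])

  expect_equal(nrow(presenceAbsenceReport(list())), 0L)
})
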