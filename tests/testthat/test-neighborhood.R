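test_that("marker genes are found once each, by any marker domain", {
  ann <- toyAnn(n = 20,
                hits = rbind(h(5, "F_bp_aldolase"),
                             h(9, "Transaldolase"),
                             h(9, "CTP_Synth_N"),
                             h(12, "PAS")))
  mk <- findMarkerGenes(ann, markerSpec("SPO0F"))
  expect_setequal(S4Vectors::mcols(mk)$gene_id, c("g005", "g009"))
  expect_length(findMarkerGenes(ann, markerSpec("SPO0B")), 0L)
})

test_that("windows clip on linear replicons and wrap on circular ones", {
  lin <- toyAnn(n = 100)
  expect_equal(nbhdMembers(neighborhoodWindow(lin, "g011", 4)), 6:14)
  expect_equal(nbhdMembers(neighborhoodWindow(lin, "g002", 4)), 0:5)
  circ <- toyAnn(n = 10, circular = TRUE)
  expect_equal(nbhdMembers(neighborhoodWindow(circ, "g001", 4)),
               sort(c(6L, 7L, 8L, 9L, 0L, 1L, 2L, 3L, 4L)))
  # window covering the whole replicon
  expect_equal(nbhdMembers(neighborhoodWindow(circ, "g001", 6)), 0:9)
})

test_that("merge rule: markers within the gap merge, beyond it do not", {
  mkAnn <- function(orfs) toyAnn(n = 40, hits = do.call(rbind,
    lapply(orfs, function(i) h(i + 1L, "F_bp_aldolase"))))
  wins <- function(ann, orfs, radius) lapply(sprintf("g%03d", orfs + 1L),
    neighborhoodWindow, ann = ann, radius = radius)

  # 3 intervening ORFs (10 vs 14): one neighborhood
  ann <- mkAnn(c(10, 14))
  m <- mergeNeighborhoods(ann, wins(ann, c(10, 14), 4))
  expect_length(m, 1L)
  expect_equal(nbhdMembers(m[[1]]), 6:18)

  # 5 intervening ORFs and disjoint radius-2 windows: two neighborhoods
  ann <- mkAnn(c(10, 16))
  m <- mergeNeighborhoods(ann, wins(ann, c(10, 16), 2))
  expect_length(m, 2L)

  # 6 intervening ORFs but radius-4 windows share ORFs 13-14: merged
  ann <- mkAnn(c(10, 17))
  m <- mergeNeighborhoods(ann, wins(ann, c(10, 17), 4))
  expect_length(m, 1L)

  # boundary: 4 intervening ORFs (10 vs 15) merge, even with tiny windows
  ann <- mkAnn(c(10, 15))
  m <- mergeNeighborhoods(ann, wins(ann, c(10, 15), 1))
  expect_length(m, 1L)
  # 5 intervening ORFs with tiny windows do not
  ann <- mkAnn(c(10, 16))
  expect_length(mergeNeighborhoods(ann, wins(ann, c(10, 16), 1)), 2L)
})

test_that("merging rejects neighborhoods from different genomes", {
  a1 <- toyAnn(n = 10, genomeId = "a", hits = h(3, "F_bp_aldolase"))
  a2 <- toyAnn(n = 10, genomeId = "b", hits = h(3, "F_bp_aldolase"))
  w1 <- neighborhoodWindow(a1, "g003", 2)
  w2 <- neighborhoodWindow(a2, "g003", 2)
  expect_error(mergeNeighborhoods(a1, list(w1, w2)), "different genomes")
})

test_that("merge is idempotent, order-invariant, and covers each marker once", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(30:80, 1)
    circ <- sample(c(TRUE, FALSE), 1)
    k <- sample(2:6, 1)
    orfs <- sort(sample(0:(n - 1), k))
    ann <- toyAnn(n = n, circular = circ, hits = do.call(rbind,
      lapply(orfs, function(i) h(i + 1L, "F_bp_aldolase"))))
    wins <- lapply(sprintf("g%03d", orfs + 1L), neighborhoodWindow,
                   ann = ann, radius = 4)
    m1 <- mergeNeighborhoods(ann, wins)
    m2 <- mergeNeighborhoods(ann, wins[sample(length(wins))])
    m3 <- mergeNeighborhoods(ann, m1)
    sig <- function(m) lapply(m, function(nb)
      list(nbhdMembers(nb), sort(nbhdMarkers(nb))))
    expect_identical(sig(m1), sig(m2))
    expect_identical(sig(m1), sig(m3))
    allMarkers <- unlist(lapply(m1, nbhdMarkers))
    expect_identical(sort(allMarkers), sprintf("g%03d", sort(orfs) + 1L))
  }
})

test_that("marker-domain ranking follows the smoothed log-odds formula", {
  # 125-gene genome; 5 guide windows (radius 2) -> 25 inside, 100 outside.
  # Domain A hits a gene in all 5 windows, B in 3 of 5; none outside.
  anchors <- c(10, 35, 60, 85, 110)
  hits <- do.call(rbind, c(
    lapply(anchors, function(i) h(i + 1L, "Anchor_dom")),
    lapply(anchors, function(i) h(i + 2L, "DomA")),
    lapply(anchors[1:3], function(i) h(i, "DomB"))))
  ann <- toyAnn(n = 125, hits = hits)
  guides <- lapply(sprintf("g%03d", anchors + 1L), neighborhoodWindow,
                   ann = ann, radius = 2)
  rk <- selectMarkerDomains(guides, list(ann), topK = 10)
  expect_equal(rk$domain_name[1:2], c("Anchor_dom", "DomA"))
  scoreA <- log((5 + 1) / (5 + 2)) - log((0 + 1) / (100 + 2))
  scoreB <- log((3 + 1) / (5 + 2)) - log((0 + 1) / (100 + 2))
  expect_equal(rk$score[rk$domain_name == "DomA"], scoreA)
  expect_equal(rk$score[rk$domain_name == "DomB"], scoreB)
  expect_gt(scoreA, scoreB)
  # Anchor_dom and DomA tie on counts; the anchor-distance tie-break wins
  expect_equal(rk$score[1], rk$score[2])
  expect_error(selectMarkerDomains(list(), list(ann)), "empty")
})

test_that("a domain found only outside neighborhoods scores negatively", {
  hits <- rbind(h(11, "Anchor_dom"), do.call(rbind,
    lapply(20:49, function(i) h(i, "OutsideDom"))))
  ann <- toyAnn(n = 60, hits = hits)
  guides <- list(neighborhoodWindow(ann, "g011", 2))
  rk <- selectMarkerDomains(guides, list(ann), topK = 10)
  expect_lt(rk$score[rk$domain_name == "OutsideDom"], 0)
  expect_gt(rk$score[rk$domain_name == "Anchor_dom"],
            rk$score[rk$domain_name == "OutsideDom"])
})

test_that("neighborhood choice prefers candidates, then marker count, then position", {
  ann <- toyAnn(n = 60, lens = rep(120L, 60),
                hits = rbind(h(10, "F_bp_aldolase", 10, 100),
                             h(40, "F_bp_aldolase", 10, 100),
                             h(42, "Transaldolase", 10, 100),
                             h(12, "Response_reg", 5, 115)))
  nb <- discoverNeighborhoods(ann, markerSpec("SPO0F"))
  expect_length(nb, 2L)
  # rule 1: only the first set holds a stand-alone-REC candidate
  pick <- chooseMarkerNeighborhood(ann, nb, isSpo0fLike)
  expect_true("g010" %in% nbhdMarkers(pick))
  # rule 2 without a candidate predicate: most markers
  pick2 <- chooseMarkerNeighborhood(ann, nb, NULL)
  expect_true("g040" %in% nbhdMarkers(pick2))
  # rule 3: equal markers, no candidates -> lowest member index
  ann3 <- toyAnn(n = 60, hits = rbind(h(10, "F_bp_aldolase"),
                                      h(40, "F_bp_aldolase")))
  nb3 <- discoverNeighborhoods(ann3, markerSpec("SPO0F"))
  pick3 <- chooseMarkerNeighborhood(ann3, nb3, NULL)
  expect_true("g010" %in% nbhdMarkers(pick3))
  expect_error(chooseMarkerNeighborhood(ann, list(), NULL), "empty")
})
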