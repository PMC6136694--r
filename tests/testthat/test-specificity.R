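test_that("profiles carry the declared anchor residues and offset counts", {
  hk <- specificityProfile("HISKA_LIKE")
  rec <- specificityProfile("REC")
  expect_length(hk@offsets, 6L)
  expect_length(rec@offsets, 7L)
  for (i in seq_along(hk@references))
    expect_equal(substr(as.character(hk@references[[i]]), hk@anchors[i],
                        hk@anchors[i]), "H")
  for (i in seq_along(rec@references))
    expect_equal(substr(as.character(rec@references[[i]]), rec@anchors[i],
                        rec@anchors[i]), "D")
})

test_that("planted residues around a planted anchor are recovered exactly", {
  set.seed(31)
  for (role in c("HISKA_LIKE", "REC")) {
    p <- specificityProfile(role)
    ref <- as.character(p@references[[1]])
    a <- p@anchors[1]
    for (rep in 1:5) {
      sig <- randomSignature(length(p@offsets))
      ch <- strsplit(ref, "")[[1]]
      mut <- which(runif(length(ch)) < 0.2)
      mut <- setdiff(mut, c(a, a + p@offsets))
      for (i in mut) ch[i] <- sample(setdiff(strsplit(
        "ACDEFGHIKLMNPQRSTVWY", "")[[1]], ch[i]), 1)
      ch[a + p@offsets] <- strsplit(sig, "")[[1]]
      target <- paste0(randomSignature(25), paste(ch, collapse = ""),
                       randomSignature(15))
      s <- extractSignature(target, p)
      expect_identical(s$residues, sig)
      expect_equal(s$anchor_position, 25 + a)
      expect_length(s$flags, 0L)
    }
  }
})

test_that("a reference sequence extracts against itself at its own anchor", {
  hk <- specificityProfile("HISKA_LIKE")
  ref1 <- as.character(hk@references[[1]])
  s <- extractSignature(ref1, hk)
  expect_equal(s$anchor_position, hk@anchors[1])
  expect_equal(s$reference, names(hk@references)[1])
  expected <- paste(strsplit(ref1, "")[[1]][hk@anchors[1] + hk@offsets],
                    collapse = "")
  expect_identical(s$residues, expected)
})

test_that("unalignable sequences yield an all-gap signature with no_anchor", {
  hk <- specificityProfile("HISKA_LIKE")
  s <- extractSignature(strrep("A", 120), hk)
  expect_identical(s$residues, "------")
  expect_true("no_anchor" %in% s$flags)
  expect_error(extractSignature("", hk), "empty")
})

test_that("hamming distance counts mismatches, with gap semantics", {
  expect_equal(hammingDistance("TAGFQL", "TTGFQL"), 1L)
  expect_equal(hammingDistance("QGILEVD", "QGILEVD"), 0L)
  expect_equal(hammingDistance("NELLEYD", "NEFIDYD"), 3L)
  # '-' mismatches residues but matches another '-'
  expect_equal(hammingDistance("-AGFQL", "TAGFQL"), 1L)
  expect_equal(hammingDistance("-AGFQL", "-AGFQL"), 0L)
  expect_error(hammingDistance("TAGFQL", "QGILEVD"), "lengths")
})

test_that("hamming is a metric on gap-free signatures", {
  set.seed(8)
  for (i in 1:200) {
    len <- sample(c(6, 7), 1)
    a <- randomSignature(len); b <- randomSignature(len)
    c <- randomSignature(len)
    expect_equal(hammingDistance(a, a), 0L)
    expect_equal(hammingDistance(a, b), hammingDistance(b, a))
    expect_lte(hammingDistance(a, c),
               hammingDistance(a, b) + hammingDistance(b, c))
  }
})

test_that("position frequency matrix counts residues and excludes gaps", {
  m <- positionFrequencyMatrix(list("TAGFQL", "TAGFQL", "TAGFQL"))
  expect_equal(sum(m), 18L)
  expect_equal(unname(m[2, "A"]), 3L)
  m2 <- positionFrequencyMatrix(list("TAGFQL", "TTGFQL"))
  expect_equal(unname(m2[2, "A"]), 1L)
  expect_equal(unname(m2[2, "T"]), 1L)
  expect_equal(unname(rowSums(m2)), rep(2L, 6))
  # gaps reduce the column sum
  m3 <- positionFrequencyMatrix(list("TAGFQL", "-AGFQL"))
  expect_equal(unname(rowSums(m3)), c(1L, rep(2L, 5)))
  expect_warning(m0 <- positionFrequencyMatrix(list()), "no signatures")
  expect_equal(nrow(m0), 0L)
})

test_that("column sums equal the number of non-gap contributors", {
  set.seed(13)
  for (i in 1:25) {
    k <- sample(2:10, 1)
    sigs <- replicate(k, randomSignature(6))
    gapped <- vapply(sigs, function(s) {
      if (runif(1) < 0.3) substr(s, 1, 1) <- "-"
      s
    }, character(1))
    m <- positionFrequencyMatrix(as.list(gapped))
    expect_equal(unname(rowSums(m)),
                 vapply(1:6, function(p)
                   sum(substr(gapped, p, p) != "-"), integer(1)))
  }
})

test_that("group distance summary averages pairwise distances", {
  g <- groupDistanceSummary(list(X = list("AAAAAA", "AAAAAT"),
                                 Y = list("TTTTTT")))
  expect_equal(g["X", "X"], 1)
  expect_true(is.na(g["Y", "Y"]))
  expect_equal(g["X", "Y"], 5.5)   # mean of distances 6 and 5
  expect_equal(g["Y", "X"], g["X", "Y"])
  g2 <- groupDistanceSummary(list(A = list("QGILEVD"),
                                  B = list("QGIAEVA")))
  expect_equal(g2["A", "B"], 2)
  g3 <- groupDistanceSummary(list(Z = list("TAGFQL", "TAGFQL")))
  expect_equal(g3["Z", "Z"], 0)
  expect_error(groupDistanceSummary(list(X = list("AAA", "AAAA"))), "length")
})

test_that("mixed-role inputs are rejected", {
  hk <- specificityProfile("HISKA_LIKE")
  rec <- specificityProfile("REC")
  a <- extractSignature(as.character(hk@references[[1]]), hk)
  b <- extractSignature(as.character(rec@references[[1]]), rec)
  expect_error(hammingDistance(a, b), "roles")
  expect_error(positionFrequencyMatrix(list(a, b)), "mixed")
})
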