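test_that("write/read round trip preserves gene order, coordinates and hits", {
  cfg <- smallSimConfig(seed = 11)
  g <- generateGenome(cfg, 1)
  dir <- withr::local_tempdir()
  writeAnnotation(g$annotation, dir)
  ann <- readAnnotation(file.path(dir, "sim_genome_1.gff3"),
                        file.path(dir, "sim_genome_1.faa"),
                        file.path(dir, "sim_genome_1.domains.tsv"),
                        phenotype = "spore_former")
  a <- g$annotation
  expect_identical(S4Vectors::mcols(annGenes(ann))$gene_id,
                   S4Vectors::mcols(annGenes(a))$gene_id)
  expect_identical(S4Vectors::mcols(annGenes(ann))$orf_index,
                   S4Vectors::mcols(annGenes(a))$orf_index)
  expect_identical(GenomicRanges::start(annGenes(ann)),
                   GenomicRanges::start(annGenes(a)))
  expect_identical(GenomicRanges::end(annGenes(ann)),
                   GenomicRanges::end(annGenes(a)))
  expect_identical(as.character(GenomicRanges::strand(annGenes(ann))),
                   as.character(GenomicRanges::strand(annGenes(a))))
  expect_identical(as.character(annProteins(ann)[names(annProteins(a))]),
                   as.character(annProteins(a)))
  dh1 <- domainHits(ann); dh2 <- domainHits(a)
  ord <- function(d) d[order(d$gene_id, d$domain_name, d$ali_from), ]
  expect_equal(ord(dh1)$domain_name, ord(dh2)$domain_name)
  expect_equal(ord(dh1)$ali_from, ord(dh2)$ali_from)
  expect_equal(replicons(ann)$length, replicons(a)$length)
})

test_that("orf_index is a bijection onto 0..n-1 per replicon", {
  cfg <- smallSimConfig(seed = 3)
  for (i in 1:3) {
    ann <- generateGenome(cfg, i)$annotation
    ix <- S4Vectors::mcols(annGenes(ann))$orf_index
    expect_identical(sort(ix), seq_along(ix) - 1L)
  }
})

test_that("load errors and exclusions are reported, not silent", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "t.gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chr 1 5000",
               "chr\tx\tCDS\t1\t300\t.\t+\t0\tID=gA",
               "chr\tx\tCDS\t400\t700\t.\t-\t0\tID=gB",
               "chr\tx\tCDS\t800\t1100\t.\t+\t0\tID=gC"), gff)
  faa <- file.path(dir, "t.faa")
  writeLines(c(">gA", strrep("M", 100), ">gB", strrep("K", 100),
               ">gC", strrep("L", 100)), faa)
  dom <- file.path(dir, "t.tsv")
  writeLines(c("gene_id\tdomain_name\tdb\tevalue\tali_from\tali_to",
               "gA\tPAS\tPFAM\t1e-5\t5\t90",
               "gB\tHisKA\tPFAM\t1e-5\t10\t60",
               "gX\tPAS\tPFAM\t1e-5\t1\t50",
               "gC\tPAS\tPFAM\t1e-5\t10\t150"), dom)
  expect_warning(expect_warning(
    ann <- readAnnotation(gff, faa, dom),
    "unknown genes"), "invalid coordinates")
  expect_equal(nrow(domainHits(ann)), 2L)
  rep <- attr(ann, "loadReport")
  expect_equal(unname(rep["unknown_gene"]), 1L)
  expect_equal(unname(rep["bad_coords"]), 1L)
  expect_identical(S4Vectors::mcols(annGenes(ann))$orf_index, 0:2)

  # duplicate IDs are a hard error
  writeLines(c("##gff-version 3",
               "chr\tx\tCDS\t1\t300\t.\t+\t0\tID=gA",
               "chr\tx\tCDS\t400\t700\t.\t+\t0\tID=gA"), gff)
  expect_error(readAnnotation(gff, faa, NULL), "duplicate")
})

test_that("empty domain table loads with zero hits", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "t.gff3")
  writeLines(c("##gff-version 3",
               "chr\tx\tCDS\t1\t300\t.\t+\t0\tID=gA"), gff)
  faa <- file.path(dir, "t.faa")
  writeLines(c(">gA", strrep("M", 100)), faa)
  dom <- file.path(dir, "t.tsv")
  writeLines("gene_id\tdomain_name\tdb\tevalue\tali_from\tali_to", dom)
  ann <- readAnnotation(gff, faa, dom)
  expect_equal(nrow(domainHits(ann)), 0L)
})

test_that("domainsOf sorts hits by ali_from and errors on unknown genes", {
  ann <- toyAnn(n = 3, lens = rep(500L, 3),
                hits = rbind(h(2, "HisKA", 300, 360),
                             h(2, "PAS", 10, 110),
                             h(1, "Response_reg", 5, 115)))
  d <- domainsOf(ann, "g002")
  expect_equal(d$domain_name, c("PAS", "HisKA"))
  expect_equal(nrow(domainsOf(ann, "g003")), 0L)
  expect_error(domainsOf(ann, "nope"), "unknown gene")
})

test_that("normalized position divides the low-coordinate end by replicon length", {
  ann <- toyAnn(n = 2, starts = c(500000L, 100L),
                strands = c("+", "-"), repliconLength = 5000000L)
  # minus-strand gene: the stop codon falls on the low coordinate
  expect_equal(normalizedPosition(ann, "g001"), 0.1)
  ann2 <- toyAnn(n = 1, starts = 100L, strands = "-",
                 repliconLength = 1000L)
  expect_equal(normalizedPosition(ann2, "g001"), 0.1)
  expect_error(normalizedPosition(ann, "zz"), "unknown gene")
})

test_that("domtblout conversion extracts query, domain, evalue and ali coords", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "d.domtblout")
  writeLines(c(
    "# comment line",
    paste("PAS PF00989.1 110 gA - 400 1e-20 60 0.1 1 2 1e-9 2e-8 55 0.1",
          "3 100 10 108 8 110 0.9 desc here"),
    paste("HisKA PF00512.1 66 gB - 350 1e-10 40 0.0 1 1 1e-7 1e-6 39 0.0",
          "1 66 301 360 300 362 0.95 -")), f)
  df <- convertDomtblout(f)
  expect_equal(df$gene_id, c("gA", "gB"))
  expect_equal(df$domain_name, c("PAS", "HisKA"))
  expect_equal(df$ali_from, c(10L, 301L))
  expect_equal(df$ali_to, c(108L, 360L))
  expect_equal(df$evalue, c(2e-8, 1e-6))
  expect_equal(unique(df$db), "PFAM")
})
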