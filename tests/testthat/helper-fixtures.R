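# toy annotation builder: n genes on one replicon, optional domain hits and
# protein sequences keyed by gene index
toyAnn <- function(n = 30, circular = FALSE, lens = rep(200L, n),
                   hits = NULL, seqs = NULL, genomeId = "toy",
                   repliconLength = NULL, starts = NULL,
                   strands = rep("+", n)) {
  ids <- sprintf("g%03d", seq_len(n))
  if (is.null(starts)) starts <- (seq_len(n) - 1L) * 700L + 1L
  ends <- starts + 600L
  if (is.null(repliconLength)) repliconLength <- max(ends) + 500L
  genes <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands)
  S4Vectors::mcols(genes)$gene_id <- ids
  S4Vectors::mcols(genes)$orf_index <- seq_len(n) - 1L
  S4Vectors::mcols(genes)$product_length <- as.integer(lens)
  dh <- if (is.null(hits)) {
    data.frame(gene_id = character(), domain_name = character(),
               db = character(), evalue = numeric(), ali_from = integer(),
               ali_to = integer(), stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = ids[hits$gene],
               domain_name = hits$domain_name,
               db = if (is.null(hits$db)) "PFAM" else hits$db,
               evalue = 1e-10,
               ali_from = as.integer(hits$ali_from),
               ali_to = as.integer(hits$ali_to),
               stringsAsFactors = FALSE)
  }
  prot <- if (is.null(seqs)) Biostrings::AAStringSet() else
    Biostrings::AAStringSet(stats::setNames(unname(unlist(seqs)),
                                            ids[as.integer(names(seqs))]))
  new("GenomeAnnotation", genomeId = genomeId,
      replicons = data.frame(replicon_id = "chr",
                             length = as.numeric(repliconLength),
                             circular = circular, stringsAsFactors = FALSE),
      genes = genes, proteins = prot, domainHits = dh,
      phenotype = "unknown")
}

# shorthand for a domain-hit spec row
h <- function(gene, domain, from = 10L, to = 150L, db = "PFAM") {
  data.frame(gene = gene, domain_name = domain, db = db,
             ali_from = from, ali_to = to, stringsAsFactors = FALSE)
}

# brute-force minimum parsimony changes over all internal labelings of a
# rooted binary ape tree (independent oracle for the Fitch implementation)
bruteForceTransitions <- function(tree, labels, states) {
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  edges <- tree$edge
  internal <- sort(unique(edges[, 1]))
  best <- Inf
  assign <- rep(NA_character_, nTip + nNode)
  assign[seq_len(nTip)] <- labels[tree$tip.label]
  grid <- expand.grid(rep(list(states), length(internal)),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    assign[internal] <- unlist(grid[r, ])
    cost <- sum(assign[edges[, 1]] != assign[edges[, 2]])
    if (cost < best) best <- cost
  }
  best
}

randomSignature <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# a small simulation config used where generator scale is not the point
smallSimConfig <- function(seed = 1, ...) {
  simulationConfig(seed = seed, genesPerGenome = c(250L, 300L),
                   nCheyDecoys = 2L, nTcsPairs = 1L, ...)
}
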