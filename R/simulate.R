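.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.randProteins <- function(lens) {
  if (!length(lens)) return(character())
  chars <- sample(.AA20, sum(lens), replace = TRUE)
  s <- paste(chars, collapse = "")
  ends <- cumsum(lens)
  substring(s, ends - lens + 1L, ends)
}

# mutate a sequence at `rate` per position, sparing `keep` positions
.mutateSeq <- function(seq, rate, keep = integer()) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- setdiff(hit, keep)
  for (i in hit) ch[i] <- sample(setdiff(.AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

.mutateSig <- function(sig, rate) {
  if (rate <= 0) return(sig)
  ch <- strsplit(sig, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(.AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

# domain copy of a profile reference with a planted signature at the offsets
.plantDomain <- function(profile, signature, divergence) {
  ref <- as.character(profile@references[[1]])
  a <- profile@anchors[1]
  spots <- a + profile@offsets
  out <- .mutateSeq(ref, divergence, keep = c(a, spots))
  ch <- strsplit(out, "")[[1]]
  ch[a] <- if (identical(profile@role, "REC")) "D" else "H"
  sig <- strsplit(signature, "")[[1]]
  ch[spots] <- sig
  paste(ch, collapse = "")
}

#' Configure the synthetic genome generator
#'
#' The generator emulates the statistical structure of an annotated Firmicute
#' genome cohort: a few thousand ordered ORFs on a circular replicon, planted
#' Spo0 components and their marker-gene neighborhoods, decoy stand-alone
#' receivers (CheY-like), paired (non-orphan) two-component operons, and a
#' majority of domain-free background proteins. Protein sequences are random
#' except where a downstream stage aligns them (Spo0B N-termini and
#' signature-bearing domains), which are mutated copies of the shipped
#' reference sequences. All randomness flows from \code{seed}; the genome
#' index perturbs the stream deterministically, so the same seed and
#' configuration give identical output.
#'
#' @param seed integer seed.
#' @param nGenomes number of genomes (used by convenience loops).
#' @param genesPerGenome length-2 range (or single value) of ORFs per genome;
#'   default 2000-4000.
#' @param circular logical; replicons are circular by default.
#' @param architectures architecture per genome
#'   (\code{PHOSPHORELAY}/\code{DIRECT}/\code{PARTIAL_RELAY}/\code{NO_SPO0}),
#'   recycled over genomes.
#' @param markerGap ORFs between successive planted marker genes (default 2).
#' @param nOrphanKinases,nPasKinases planted orphan kinases and how many of
#'   them carry an N-terminal PAS domain (defaults 5 and 4).
#' @param nCheyDecoys stand-alone-REC decoy proteins outside marker
#'   neighborhoods (default 5).
#' @param nTcsPairs paired kinase+regulator operons (non-orphan decoys,
#'   default 3).
#' @param markerDeletionProb probability that a planted marker gene loses its
#'   marker domain annotation (default 0).
#' @param domainDropoutProb independent per-hit domain-call dropout
#'   probability (default 0).
#' @param signatureMutationRate per-position mutation rate applied to the
#'   planted specificity signatures (default 0; the mutated signature is the
#'   recorded truth).
#' @param domainDivergence divergence of alignment-bearing planted domains
#'   from their references, sparing anchor and signature positions
#'   (default 0.2).
#' @param spo0bDivergence divergence of the planted Spo0B N-terminus from the
#'   reference (default 0.2).
#' @return list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L, nGenomes = 1L,
                             genesPerGenome = c(2000L, 4000L),
                             circular = TRUE,
                             architectures = "PHOSPHORELAY",
                             markerGap = 2L,
                             nOrphanKinases = 5L, nPasKinases = 4L,
                             nCheyDecoys = 5L, nTcsPairs = 3L,
                             markerDeletionProb = 0,
                             domainDropoutProb = 0,
                             signatureMutationRate = 0,
                             domainDivergence = 0.2,
                             spo0bDivergence = 0.2) {
  probs <- c(markerDeletionProb, domainDropoutProb, signatureMutationRate,
             domainDivergence, spo0bDivergence)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(architectures %in% .ARCHITECTURES))
    stop("unknown architecture label")
  if (nPasKinases > nOrphanKinases)
    stop("nPasKinases cannot exceed nOrphanKinases")
  structure(list(seed = as.integer(seed), nGenomes = as.integer(nGenomes),
                 genesPerGenome = as.integer(genesPerGenome),
                 circular = isTRUE(circular),
                 architectures = architectures,
                 markerGap = as.integer(markerGap),
                 nOrphanKinases = as.integer(nOrphanKinases),
                 nPasKinases = as.integer(nPasKinases),
                 nCheyDecoys = as.integer(nCheyDecoys),
                 nTcsPairs = as.integer(nTcsPairs),
                 markerDeletionProb = markerDeletionProb,
                 domainDropoutProb = domainDropoutProb,
                 signatureMutationRate = signatureMutationRate,
                 domainDivergence = domainDivergence,
                 spo0bDivergence = spo0bDivergence),
            class = "SimulationConfig")
}

# default planted signatures (kinase-side 6-mers, receiver 7-mers)
.plantedSignatures <- function() {
  list(kinase = "TAGFQL", spo0f = "QGILEVD", spo0b = "QLGNSL",
       spo0a = "NELLEYD")
}

#' Generate one synthetic annotated genome with planted ground truth
#'
#' Phosphorelay genomes contain a stand-alone-REC Spo0F planted immediately
#' upstream of a fructose-bisphosphate aldolase marker gene with
#' transaldolase and CTP synthase nearby; a domain-free Spo0B, its N-terminus
#' a mutated copy of the reference, planted between the L27 and ObgE marker
#' genes; a Spo0A with receiver + Spo0A_C domains; and planted orphan
#' kinases, most with N-terminal PAS domains. Direct-phosphorylation genomes
#' keep the (housekeeping) marker genes but omit Spo0F and Spo0B;
#' partial-relay genomes keep Spo0B only; NO_SPO0 genomes omit Spo0A too.
#' Decoy stand-alone receivers, paired two-component operons and domain-free
#' background proteins are planted per the configuration.
#'
#' @param cfg a \code{"SimulationConfig"}.
#' @param genomeIndex 1-based genome index (perturbs the random stream and
#'   picks the architecture label).
#' @param genomeId identifier; default \code{sim_genome_<index>}.
#' @return list with elements \code{annotation}
#'   (\linkS4class{GenomeAnnotation}) and \code{truth} (planted role ->
#'   gene id map, architecture, signatures).
#' @export
generateGenome <- function(cfg, genomeIndex = 1L, genomeId = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(as.integer((as.numeric(cfg$seed) * 1000003 +
                         genomeIndex * 7919) %% 2147483629))
  if (is.null(genomeId)) genomeId <- paste0("sim_genome_", genomeIndex)
  arch <- cfg$architectures[((genomeIndex - 1L) %%
                               length(cfg$architectures)) + 1L]
  lo <- cfg$genesPerGenome[1]
  hi <- cfg$genesPerGenome[min(2L, length(cfg$genesPerGenome))]
  n <- if (hi > lo) sample(lo:hi, 1L) else lo

  hasF <- arch == "PHOSPHORELAY"
  hasB <- arch %in% c("PHOSPHORELAY", "PARTIAL_RELAY")
  hasA <- arch != "NO_SPO0"

  hk <- specificityProfile("HISKA_LIKE")
  rec <- specificityProfile("REC")
  Lh <- Biostrings::width(hk@references)[1]
  Lr <- Biostrings::width(rec@references)[1]
  refB <- as.character(spo0bReference())
  sig0 <- .plantedSignatures()
  sigs <- lapply(sig0, .mutateSig, rate = cfg$signatureMutationRate)
  kinSigs <- vapply(seq_len(cfg$nOrphanKinases), function(i)
    .mutateSig(sig0$kinase, max(cfg$signatureMutationRate, 0)),
    character(1))

  # ---- feature blocks: (width, builder) ----
  # each builder returns a list of gene specs: list(tag, len, hits, seq)
  gap <- cfg$markerGap
  hit <- function(dom, from, to, db = "PFAM")
    data.frame(domain_name = dom, db = db, evalue = 1e-10,
               ali_from = as.integer(from), ali_to = as.integer(to),
               stringsAsFactors = FALSE)
  bgGene <- function() list(tag = "bg", len = sample(150:450, 1L),
                            hits = NULL, seq = NULL)
  markerGene <- function(dom, len = 300L) {
    list(tag = paste0("marker_", dom), len = len,
         hits = hit(dom, 10L, len - 10L), seq = NULL, marker = TRUE)
  }
  recProtein <- function(sig) {
    dom <- .plantDomain(rec, sig, cfg$domainDivergence)
    list(seq = paste0(.randProteins(3L), dom, .randProteins(4L)),
         from = 4L, to = 3L + nchar(dom))
  }

  spo0fBlock <- function() {
    # Spo0F immediately upstream of fbaA; transaldolase and CTP synthase near
    out <- list()
    if (hasF) {
      rp <- recProtein(sigs$spo0f)
      out <- c(out, list(list(tag = "spo0f", len = nchar(rp$seq),
                              hits = hit("Response_reg", rp$from, rp$to),
                              seq = rp$seq)))
    }
    out <- c(out, list(markerGene("F_bp_aldolase")))
    for (i in seq_len(gap - 1L)) out <- c(out, list(bgGene()))
    out <- c(out, list(markerGene("Transaldolase")))
    for (i in seq_len(gap - 1L)) out <- c(out, list(bgGene()))
    c(out, list(markerGene("CTP_Synth_N")))
  }
  spo0bBlock <- function() {
    out <- list(markerGene("GTP1_OBG"))
    if (hasB) {
      nterm <- .mutateSeq(refB, cfg$spo0bDivergence)
      dom <- .plantDomain(hk, sigs$spo0b, cfg$domainDivergence)
      seqB <- paste0(nterm, dom, .randProteins(10L))
      out <- c(out, list(list(tag = "spo0b", len = nchar(seqB), hits = NULL,
                              seq = seqB)))
    }
    c(out, list(markerGene("Ribosomal_L27", 90L),
                markerGene("Ribosomal_L21p", 100L)))
  }
  spo0aBlock <- function() {
    rp <- recProtein(sigs$spo0a)
    tail <- .randProteins(110L)
    seqA <- paste0(rp$seq, tail)
    L <- nchar(seqA)
    list(list(tag = "spo0a", len = L,
              hits = rbind(hit("Response_reg", rp$from, rp$to),
                           hit("Spo0A_C", rp$to + 20L, L - 5L)),
              seq = seqA))
  }
  kinaseGene <- function(tag, sig, pas) {
    dom <- .plantDomain(hk, sig, cfg$domainDivergence)
    seqK <- paste0(.randProteins(119L), dom, .randProteins(140L))
    L <- nchar(seqK)
    fam <- if (arch %in% c("PHOSPHORELAY", "PARTIAL_RELAY")) "HK_CA:3"
           else "HK_CA:2"
    h <- rbind(hit("HisKA", 120L, 119L + nchar(dom)),
               hit("HATPase_c", 119L + nchar(dom) + 21L, L - 5L),
               hit(fam, 119L + nchar(dom) + 21L, L - 5L, db = "AGFAM"))
    if (pas) h <- rbind(hit("PAS", 10L, 110L), h)
    list(tag = tag, len = L, hits = h, seq = seqK)
  }
  tcsPairBlock <- function(j) {
    k <- kinaseGene(paste0("tcs_kinase_", j), .randProteins(6L), pas = FALSE)
    rp <- recProtein(.randProteins(7L))
    seqR <- paste0(rp$seq, .randProteins(80L))
    L <- nchar(seqR)
    rr <- list(tag = paste0("tcs_rr_", j), len = L,
               hits = rbind(hit("Response_reg", rp$from, rp$to),
                            hit("Trans_reg_C", rp$to + 10L, L - 5L)),
               seq = seqR)
    list(k, rr)
  }
  cheyGene <- function(j) {
    L <- Lr + 7L
    list(tag = paste0("chey_", j), len = L,
         hits = hit("Response_reg", 4L, 3L + Lr), seq = NULL)
  }

  blocks <- list(spo0fBlock(), spo0bBlock())
  if (hasA) blocks <- c(blocks, list(spo0aBlock()))
  for (i in seq_len(cfg$nOrphanKinases))
    blocks <- c(blocks, list(list(kinaseGene(paste0("orphan_kinase_", i),
                                             kinSigs[i],
                                             pas = i <= cfg$nPasKinases))))
  for (j in seq_len(cfg$nTcsPairs)) blocks <- c(blocks, list(tcsPairBlock(j)))
  for (j in seq_len(cfg$nCheyDecoys)) blocks <- c(blocks,
                                                  list(list(cheyGene(j))))

  widths <- vapply(blocks, length, integer(1))
  spacing <- 10L
  need <- sum(widths) + spacing * (length(blocks) + 1L)
  if (n < need)
    stop("genome too small for the configured features: need >= ", need,
         " ORFs, have ", n)
  extra <- n - need
  pad <- if (extra > 0)
    as.integer(stats::rmultinom(1, extra,
                                rep(1, length(blocks) + 1L)))
  else rep(0L, length(blocks) + 1L)

  # assemble the gene list in ORF order
  specs <- vector("list", n)
  pos <- 0L
  fill <- function(k) for (i in seq_len(k)) {
    pos <<- pos + 1L; specs[[pos]] <<- bgGene()
  }
  ord <- sample(length(blocks))   # shuffle block order along the replicon
  fill(spacing + pad[1])
  for (bi in seq_along(ord)) {
    for (gspec in blocks[[ord[bi]]]) { pos <- pos + 1L; specs[[pos]] <- gspec }
    fill(spacing + pad[bi + 1L])
  }

  lens <- vapply(specs, `[[`, integer(1), "len")
  ids <- sprintf("%s_g%04d", genomeId, seq_len(n))
  tags <- vapply(specs, `[[`, character(1), "tag")

  # sequences: planted where given, random elsewhere
  seqs <- character(n)
  given <- !vapply(specs, function(s) is.null(s$seq), logical(1))
  seqs[given] <- vapply(specs[given], `[[`, character(1), "seq")
  seqs[!given] <- .randProteins(lens[!given])

  # coordinates
  gaps <- sample(20:200, n, replace = TRUE)
  glen <- lens * 3L + 3L
  starts <- cumsum(c(1L, (glen + gaps)[-n]))
  ends <- starts + glen - 1L
  repLen <- ends[n] + 500L
  strands <- sample(c("+", "-"), n, replace = TRUE)

  genes <- GenomicRanges::GRanges(
    seqnames = "chr", ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands)
  mcols(genes)$gene_id <- ids
  mcols(genes)$orf_index <- seq_len(n) - 1L
  mcols(genes)$product_length <- lens

  # domain hits, with noise applied
  hitRows <- lapply(seq_len(n), function(i) {
    h <- specs[[i]]$hits
    if (is.null(h)) return(NULL)
    isMarker <- isTRUE(specs[[i]]$marker)
    if (isMarker && cfg$markerDeletionProb > 0 &&
        stats::runif(1) < cfg$markerDeletionProb) return(NULL)
    cbind(data.frame(gene_id = ids[i], stringsAsFactors = FALSE), h)
  })
  hitRows <- hitRows[!vapply(hitRows, is.null, logical(1))]
  dh <- if (length(hitRows)) do.call(rbind, hitRows) else .emptyDomainHits()
  if (nrow(dh) && cfg$domainDropoutProb > 0)
    dh <- dh[stats::runif(nrow(dh)) >= cfg$domainDropoutProb, , drop = FALSE]
  rownames(dh) <- NULL

  prot <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  ann <- new("GenomeAnnotation", genomeId = genomeId,
             replicons = data.frame(replicon_id = "chr",
                                    length = as.numeric(repLen),
                                    circular = cfg$circular,
                                    stringsAsFactors = FALSE),
             genes = genes, proteins = prot, domainHits = dh,
             phenotype = if (arch == "NO_SPO0") "non_spore_former"
                         else "spore_former")

  roleOf <- function(tag) ids[tags == tag]
  orphanIds <- ids[grepl("^orphan_kinase_", tags)]
  pasIds <- ids[tags %in% paste0("orphan_kinase_",
                                 seq_len(cfg$nPasKinases))]
  truth <- list(
    genome_id = genomeId,
    architecture = arch,
    roles = list(
      SPO0A = if (hasA) roleOf("spo0a") else character(),
      SPO0F = if (hasF) roleOf("spo0f") else character(),
      SPO0B = if (hasB) roleOf("spo0b") else character(),
      ORPHAN_KINASES = orphanIds,
      PAS_KINASES = pasIds,
      TCS_KINASES = ids[grepl("^tcs_kinase_", tags)],
      CHEY_DECOYS = ids[grepl("^chey_", tags)]),
    signatures = list(
      spo0a = if (hasA) sigs$spo0a else NA_character_,
      spo0f = if (hasF) sigs$spo0f else NA_character_,
      spo0b = if (hasB) sigs$spo0b else NA_character_,
      kinases = stats::setNames(kinSigs[seq_along(orphanIds)], orphanIds)))
  list(annotation = ann, truth = truth)
}

#' Generate one genome per tree leaf with mapped architectures
#'
#' @param tree rooted \code{ape::phylo} with unique leaf names.
#' @param cfg a \code{"SimulationConfig"}.
#' @param architectureMap named character vector: leaf name -> architecture
#'   label. Every leaf must be mapped.
#' @return list with \code{genomes} (named list of annotations),
#'   \code{truth} (named list), and \code{plantedTransitions} (Fitch count of
#'   the planted labels).
#' @export
generateClade <- function(tree, cfg, architectureMap) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- tree$tip.label
  if (anyDuplicated(leaves)) stop("leaf names must be unique")
  missing <- setdiff(leaves, names(architectureMap))
  if (length(missing))
    stop("leaf missing from architecture map: ",
         paste(missing, collapse = ", "))
  genomes <- list(); truth <- list()
  for (i in seq_along(leaves)) {
    cfgI <- cfg
    cfgI$architectures <- architectureMap[[leaves[i]]]
    g <- generateGenome(cfgI, genomeIndex = i, genomeId = leaves[i])
    genomes[[leaves[i]]] <- g$annotation
    truth[[leaves[i]]] <- g$truth
  }
  planted <- fitchTransitionCount(tree, architectureMap[leaves])
  list(genomes = genomes, truth = truth, plantedTransitions = planted)
}
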