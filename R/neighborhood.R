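#' Construct a marker specification
#'
#' The default marker domains are those most frequently found in the gene
#' neighborhoods of annotated Spo0F/Spo0B genes and rarely elsewhere:
#' F_bp_aldolase, Transaldolase and CTP_Synth_N for the Spo0F neighborhood;
#' GTP1_OBG, Ribosomal_L21p and Ribosomal_L27 for the Spo0B neighborhood.
#'
#' @param target "SPO0F" or "SPO0B".
#' @param markerDomains override the default marker domain names.
#' @param radius window half-width in ORFs (default 4).
#' @param mergeGap maximum intervening ORFs between marker genes for their
#'   windows to be merged (default 4).
#' @return a \linkS4class{MarkerSpec}.
#' @export
markerSpec <- function(target = c("SPO0F", "SPO0B"), markerDomains = NULL,
                       radius = 4L, mergeGap = 4L) {
  target <- match.arg(target)
  if (is.null(markerDomains))
    markerDomains <- switch(target,
      SPO0F = c("F_bp_aldolase", "Transaldolase", "CTP_Synth_N"),
      SPO0B = c("GTP1_OBG", "Ribosomal_L21p", "Ribosomal_L27"))
  new("MarkerSpec", target = target, markerDomains = markerDomains,
      radius = as.integer(radius), mergeGap = as.integer(mergeGap))
}

#' Find marker genes in a genome
#'
#' Every gene with at least one domain hit to any of the spec's marker
#' domains, each gene reported once.
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param spec a \linkS4class{MarkerSpec}.
#' @return GRanges subset of the annotation's genes (possibly empty).
#' @export
findMarkerGenes <- function(ann, spec) {
  dh <- ann@domainHits
  hitGenes <- unique(dh$gene_id[dh$domain_name %in% spec@markerDomains])
  ann@genes[.geneIds(ann) %in% hitGenes]
}

#' Window of ORFs around a gene
#'
#' Member indices are \code{orf_index - radius .. orf_index + radius},
#' clipped to the replicon when linear and wrapped around the origin when
#' circular.
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param geneId the anchor gene.
#' @param radius window half-width in ORFs.
#' @param target label recorded on the neighborhood (optional).
#' @return a \linkS4class{Neighborhood} whose markers are the anchor gene.
#' @export
neighborhoodWindow <- function(ann, geneId, radius = 4L, target = "SPO0F") {
  i <- .orfIndexOf(ann, geneId)
  rep <- .repliconOf(ann, geneId)
  n <- .nOrfs(ann, rep)
  circ <- .isCircular(ann, rep)
  ix <- (i - radius):(i + radius)
  if (circ) ix <- unique(ix %% n) else ix <- ix[ix >= 0L & ix < n]
  new("Neighborhood", genomeId = genomeId(ann), repliconId = rep,
      target = target, members = sort(as.integer(ix)),
      markerGenes = geneId, candidateGenes = character())
}

# intervening ORF count between the closest marker pair of two neighborhoods
.markerGap <- function(ann, nb1, nb2) {
  n <- .nOrfs(ann, nb1@repliconId)
  circ <- .isCircular(ann, nb1@repliconId)
  i1 <- vapply(nb1@markerGenes, function(g) .orfIndexOf(ann, g), integer(1))
  i2 <- vapply(nb2@markerGenes, function(g) .orfIndexOf(ann, g), integer(1))
  min(outer(i1, i2, function(a, b)
    mapply(.orfDistance, a, b, MoreArgs = list(n = n, circular = circ)))) - 1L
}

#' Merge overlapping or adjacent marker neighborhoods
#'
#' Takes the transitive closure of two merge conditions: two neighborhoods
#' share at least one member ORF, or their marker genes are separated by at
#' most \code{mergeGap} intervening ORFs (regardless of intergenic distance in
#' bp). The merged member set is the union of the member windows. The result
#' is sorted by smallest member index and the operation is idempotent and
#' order-invariant.
#'
#' @param ann the \linkS4class{GenomeAnnotation} the neighborhoods came from.
#' @param nbhds list of \linkS4class{Neighborhood}s from this one genome.
#' @param mergeGap maximum intervening ORFs between marker genes (default 4).
#' @return list of merged \linkS4class{Neighborhood}s.
#' @export
mergeNeighborhoods <- function(ann, nbhds, mergeGap = 4L) {
  if (!length(nbhds)) return(list())
  gids <- vapply(nbhds, function(nb) nb@genomeId, character(1))
  if (length(unique(gids)) > 1L || any(gids != genomeId(ann)))
    stop("neighborhoods from different genomes cannot be merged")
  k <- length(nbhds)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    if (nbhds[[i]]@repliconId != nbhds[[j]]@repliconId) next
    share <- length(intersect(nbhds[[i]]@members, nbhds[[j]]@members)) > 0L
    close <- .markerGap(ann, nbhds[[i]], nbhds[[j]]) <= mergeGap
    if (share || close) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  merged <- lapply(unique(roots), function(r) {
    grp <- nbhds[roots == r]
    new("Neighborhood",
        genomeId = grp[[1]]@genomeId,
        repliconId = grp[[1]]@repliconId,
        target = grp[[1]]@target,
        members = sort(unique(unlist(lapply(grp, function(x) x@members)))),
        markerGenes = sort(unique(unlist(lapply(grp,
                                                function(x) x@markerGenes)))),
        candidateGenes = sort(unique(unlist(lapply(grp,
                                         function(x) x@candidateGenes)))))
  })
  merged[order(vapply(merged, function(nb) min(nb@members), integer(1)),
               vapply(merged, function(nb) nb@repliconId, character(1)))]
}

#' Discover merged marker neighborhoods in one genome
#'
#' Convenience wrapper: find marker genes, window each, merge.
#'
#' @inheritParams findMarkerGenes
#' @return list of merged \linkS4class{Neighborhood}s (possibly empty).
#' @export
discoverNeighborhoods <- function(ann, spec) {
  mk <- findMarkerGenes(ann, spec)
  if (!length(mk)) return(list())
  wins <- lapply(mcols(mk)$gene_id, function(g)
    neighborhoodWindow(ann, g, radius = spec@radius, target = spec@target))
  mergeNeighborhoods(ann, wins, mergeGap = spec@mergeGap)
}

#' Rank candidate marker domains by neighborhood enrichment
#'
#' For method development: scores each domain by how often it occurs inside a
#' set of guide neighborhoods versus outside them, with a smoothed
#' log-odds score
#' \deqn{s(d) = \log\frac{n_{in}(d)+1}{N_{in}+2} -
#'              \log\frac{n_{out}(d)+1}{N_{out}+2}}
#' where \eqn{n_{in}} is the number of guide neighborhoods containing a hit to
#' the domain, \eqn{N_{in}} the number of guide neighborhoods, \eqn{n_{out}}
#' the number of genes outside any guide neighborhood hitting it and
#' \eqn{N_{out}} the total number of such outside genes. Ties are broken by
#' smaller mean absolute ORF distance to the neighborhood anchor gene, then by
#' domain name; this prefers domains encoded close to the anchored homolog.
#'
#' @param guideNbhds list of \linkS4class{Neighborhood}s; each must carry its
#'   anchor gene as (one of) its \code{markerGenes}.
#' @param genomes list of \linkS4class{GenomeAnnotation}s the guide
#'   neighborhoods were drawn from, named or ordered arbitrarily.
#' @param topK how many domains to return.
#' @return data.frame (domain_name, score, n_in, n_out, mean_anchor_dist),
#'   best first, at most \code{topK} rows.
#' @export
selectMarkerDomains <- function(guideNbhds, genomes, topK = 3L) {
  if (!length(guideNbhds)) stop("empty guide neighborhood set")
  gmap <- stats::setNames(genomes,
                          vapply(genomes, genomeId, character(1)))
  nIn <- length(guideNbhds)

  insideKeys <- character()    # "genome|replicon|orf"
  domIn <- list()              # per neighborhood: domains present
  distRec <- list()            # per domain: |orf dist to anchor| samples
  for (nb in guideNbhds) {
    ann <- gmap[[nb@genomeId]]
    if (is.null(ann)) stop("guide neighborhood from unsupplied genome: ",
                           nb@genomeId)
    g <- ann@genes
    onRep <- as.character(seqnames(g)) == nb@repliconId
    memb <- onRep & mcols(g)$orf_index %in% nb@members
    ids <- mcols(g)$gene_id[memb]
    insideKeys <- c(insideKeys,
                    paste(nb@genomeId, nb@repliconId,
                          mcols(g)$orf_index[memb], sep = "|"))
    dh <- ann@domainHits
    dh <- dh[dh$gene_id %in% ids, , drop = FALSE]
    domIn[[length(domIn) + 1L]] <- unique(dh$domain_name)
    anchor <- .orfIndexOf(ann, nb@markerGenes[[1]])
    if (nrow(dh)) {
      d <- abs(vapply(dh$gene_id, function(x) .orfIndexOf(ann, x),
                      integer(1)) - anchor)
      for (r in seq_len(nrow(dh))) {
        dn <- dh$domain_name[r]
        distRec[[dn]] <- c(distRec[[dn]], d[r])
      }
    }
  }

  nInD <- table(unlist(domIn))
  # outside genes: all guide-genome genes not in any guide neighborhood
  outDom <- list(); nOut <- 0L
  for (ann in gmap) {
    g <- ann@genes
    key <- paste(genomeId(ann), as.character(seqnames(g)),
                 mcols(g)$orf_index, sep = "|")
    outIds <- mcols(g)$gene_id[!key %in% insideKeys]
    nOut <- nOut + length(outIds)
    dh <- ann@domainHits
    dh <- dh[dh$gene_id %in% outIds, , drop = FALSE]
    if (nrow(dh))
      outDom[[length(outDom) + 1L]] <-
        unique(dh[, c("gene_id", "domain_name")])
  }
  outTab <- if (length(outDom)) {
    od <- do.call(rbind, outDom)
    table(od$domain_name)
  } else table(character())

  doms <- sort(unique(c(names(nInD), names(outTab))))
  ni <- as.integer(nInD[doms]); ni[is.na(ni)] <- 0L
  no <- as.integer(outTab[doms]); no[is.na(no)] <- 0L
  score <- log((ni + 1) / (nIn + 2)) - log((no + 1) / (nOut + 2))
  mdist <- vapply(doms, function(d)
    if (is.null(distRec[[d]])) Inf else mean(distRec[[d]]), numeric(1))
  ord <- order(-score, mdist, doms)
  res <- data.frame(domain_name = doms, score = score, n_in = ni,
                    n_out = no, mean_anchor_dist = mdist,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, topK)
}

#' Choose the marker neighborhood among merged sets
#'
#' Priority: (1) a set containing a gene passing \code{candidatePredicate};
#' (2) the set with the most distinct marker genes; (3) deterministic
#' tie-break on the lowest member ORF index.
#'
#' @param ann the genome annotation.
#' @param merged non-empty list of merged \linkS4class{Neighborhood}s.
#' @param candidatePredicate \code{function(ann, geneId) -> logical}, e.g.
#'   a stand-alone-REC test for Spo0F; \code{NULL} to skip rule (1).
#' @return the chosen \linkS4class{Neighborhood}.
#' @export
chooseMarkerNeighborhood <- function(ann, merged, candidatePredicate = NULL) {
  if (!length(merged)) stop("empty neighborhood list")
  hasCand <- vapply(merged, function(nb) {
    if (is.null(candidatePredicate)) return(FALSE)
    g <- ann@genes
    memb <- as.character(seqnames(g)) == nb@repliconId &
      mcols(g)$orf_index %in% nb@members
    any(vapply(mcols(g)$gene_id[memb],
               function(id) isTRUE(candidatePredicate(ann, id)), logical(1)))
  }, logical(1))
  pool <- if (any(hasCand)) merged[hasCand] else merged
  nmark <- vapply(pool, function(nb) length(unique(nb@markerGenes)),
                  integer(1))
  pool <- pool[nmark == max(nmark)]
  lo <- vapply(pool, function(nb) min(nb@members), integer(1))
  pool[[which.min(lo)]]
}

#' Member gene ids of a neighborhood
#'
#' @param ann the genome annotation.
#' @param nb a \linkS4class{Neighborhood}.
#' @return character vector of gene ids in ORF-index order.
#' @export
neighborhoodGenes <- function(ann, nb) {
  g <- ann@genes
  memb <- as.character(seqnames(g)) == nb@repliconId &
    mcols(g)$orf_index %in% nb@members
  ids <- mcols(g)$gene_id[memb]
  ids[order(mcols(g)$orf_index[memb])]
}

#' Export neighborhoods as a BED-like table
#'
#' @param ann the genome annotation.
#' @param nbhds list of \linkS4class{Neighborhood}s.
#' @return data.frame with genome, replicon, coordinate span, member and
#'   marker gene ids.
#' @export
neighborhoodTable <- function(ann, nbhds) {
  rows <- lapply(nbhds, function(nb) {
    ids <- neighborhoodGenes(ann, nb)
    i <- match(ids, .geneIds(ann))
    data.frame(genome_id = nb@genomeId, replicon_id = nb@repliconId,
               target = nb@target,
               start = min(GenomicRanges::start(ann@genes)[i]),
               end = max(GenomicRanges::end(ann@genes)[i]),
               n_members = length(ids),
               members = paste(ids, collapse = ","),
               markers = paste(nb@markerGenes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(genome_id = character(), replicon_id = character(),
                      target = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      members = character(), markers = character()))
  do.call(rbind, rows)
}
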