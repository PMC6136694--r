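#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings AAStringSet
NULL

.ARCHITECTURES <- c("PHOSPHORELAY", "DIRECT", "PARTIAL_RELAY", "NO_SPO0")
.PHENOTYPES <- c("spore_former", "non_spore_former", "unknown")
.DOMAIN_DBS <- c("PFAM", "AGFAM", "OTHER")

#' GenomeAnnotation: one annotated genome
#'
#' The unit of analysis: the ordered protein-coding genes of one genome, their
#' protein sequences, and the protein-domain hits annotated to them. Genes are
#' held as a \link[GenomicRanges]{GRanges} (seqnames = replicon) carrying
#' \code{gene_id}, \code{orf_index} (0-based rank along each replicon in
#' coordinate order) and \code{product_length} metadata columns; proteins as a
#' named \link[Biostrings]{AAStringSet}; domain hits as a data.frame with
#' columns \code{gene_id}, \code{domain_name}, \code{db} (PFAM/AGFAM/OTHER),
#' \code{evalue}, \code{ali_from}, \code{ali_to} (1-based amino-acid
#' coordinates on the protein).
#'
#' @slot genomeId single genome identifier.
#' @slot replicons data.frame with columns \code{replicon_id}, \code{length}
#'   (bp) and \code{circular} (logical).
#' @slot genes GRanges of CDS features, sorted by replicon then start.
#' @slot proteins AAStringSet named by \code{gene_id}.
#' @slot domainHits data.frame of per-protein domain hits (see above).
#' @slot phenotype one of \code{"spore_former"}, \code{"non_spore_former"},
#'   \code{"unknown"}.
#'
#' @seealso [readAnnotation()], [generateGenome()]
#' @export
setClass("GenomeAnnotation",
  representation(
    genomeId = "character",
    replicons = "data.frame",
    genes = "GRanges",
    proteins = "AAStringSet",
    domainHits = "data.frame",
    phenotype = "character"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || is.na(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-NA string")
  req <- c("replicon_id", "length", "circular")
  if (!all(req %in% names(object@replicons)))
    msg <- c(msg, "replicons needs columns replicon_id, length, circular")
  g <- object@genes
  need <- c("gene_id", "orf_index", "product_length")
  if (!all(need %in% names(mcols(g)))) {
    msg <- c(msg, "genes needs mcols gene_id, orf_index, product_length")
    return(msg)
  }
  gid <- mcols(g)$gene_id
  if (anyDuplicated(gid)) msg <- c(msg, "duplicate gene_id in genes")
  if (length(g)) {
    if (any(mcols(g)$product_length <= 0))
      msg <- c(msg, "product_length must be positive")
    # orf_index must be a bijection onto 0..n-1 per replicon
    by_rep <- split(mcols(g)$orf_index, as.character(seqnames(g)))
    ok <- vapply(by_rep, function(ix) {
      identical(sort(as.integer(ix)), seq_len(length(ix)) - 1L)
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "orf_index must be consecutive 0..n-1 on each replicon")
    if (!all(as.character(seqnames(g)) %in% object@replicons$replicon_id))
      msg <- c(msg, "gene on unknown replicon")
  }
  if (!all(names(object@proteins) %in% gid))
    msg <- c(msg, "protein sequence for unknown gene")
  dh <- object@domainHits
  if (nrow(dh)) {
    if (!all(dh$gene_id %in% gid))
      msg <- c(msg, "domain hit references unknown gene")
    if (any(dh$ali_from < 1L | dh$ali_to < dh$ali_from))
      msg <- c(msg, "domain hit with invalid ali_from/ali_to")
    plen <- mcols(g)$product_length[match(dh$gene_id, gid)]
    if (any(dh$ali_to > plen))
      msg <- c(msg, "domain hit extends beyond protein length")
    if (!all(dh$db %in% .DOMAIN_DBS))
      msg <- c(msg, "domain hit db must be PFAM, AGFAM or OTHER")
  }
  if (length(object@phenotype) != 1L ||
      !object@phenotype %in% .PHENOTYPES)
    msg <- c(msg, "phenotype must be spore_former/non_spore_former/unknown")
  if (length(msg)) msg else TRUE
})

#' Neighborhood: a conserved gene-context window
#'
#' A set of ORF indices on one replicon, produced by taking a window of
#' \code{radius} ORFs around each marker gene and merging windows that share a
#' gene or whose marker genes lie close together.
#'
#' @slot genomeId,repliconId location of the neighborhood.
#' @slot target which marker scheme produced it ("SPO0F" or "SPO0B").
#' @slot members integer ORF indices (sorted, unique).
#' @slot markerGenes gene ids of the marker genes inside the neighborhood.
#' @slot candidateGenes gene ids of downstream-classified candidates.
#' @export
setClass("Neighborhood",
  representation(
    genomeId = "character",
    repliconId = "character",
    target = "character",
    members = "integer",
    markerGenes = "character",
    candidateGenes = "character"
  )
)

setValidity("Neighborhood", function(object) {
  if (anyDuplicated(object@members)) return("duplicate member orf indices")
  TRUE
})

#' MarkerSpec: marker domains defining a neighborhood search
#'
#' Defaults follow the neighborhood markers used for the two hard-to-detect
#' phosphorelay proteins: fructose-bisphosphate aldolase, transaldolase and
#' CTP synthase flag the Spo0F neighborhood; ObgE and ribosomal proteins
#' L21/L27 flag the Spo0B neighborhood.
#'
#' @slot target "SPO0F" or "SPO0B".
#' @slot markerDomains Pfam domain names treated as markers.
#' @slot radius window half-width in ORFs (default 4, i.e. four adjacent ORFs
#'   up- and downstream).
#' @slot mergeGap maximum number of intervening ORFs between two marker genes
#'   for their windows to be merged (default 4).
#' @export
setClass("MarkerSpec",
  representation(
    target = "character",
    markerDomains = "character",
    radius = "integer",
    mergeGap = "integer"
  )
)

setValidity("MarkerSpec", function(object) {
  msg <- character()
  if (!length(object@markerDomains)) msg <- c(msg, "markerDomains empty")
  if (object@radius < 1L) msg <- c(msg, "radius must be >= 1")
  if (object@mergeGap < 0L) msg <- c(msg, "mergeGap must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SpecificityProfile: anchored specificity-residue extraction scheme
#'
#' Reference domain sequences plus the position of the conserved
#' phospho-accepting residue (His for kinase-side/HisKA-like profiles, Asp for
#' receiver/REC profiles) in each reference, and the signed offsets, relative
#' to that anchor, at which the specificity residues are read. Kinase-side
#' profiles carry six offsets, receiver profiles seven.
#'
#' @slot profileId profile name.
#' @slot role "HISKA_LIKE" or "REC".
#' @slot references AAStringSet of reference domains.
#' @slot anchors integer anchor position (1-based) in each reference.
#' @slot offsets signed integer offsets relative to the anchor.
#' @export
setClass("SpecificityProfile",
  representation(
    profileId = "character",
    role = "character",
    references = "AAStringSet",
    anchors = "integer",
    offsets = "integer"
  )
)

setValidity("SpecificityProfile", function(object) {
  msg <- character()
  if (!object@role %in% c("HISKA_LIKE", "REC"))
    msg <- c(msg, "role must be HISKA_LIKE or REC")
  want <- if (identical(object@role, "REC")) 7L else 6L
  if (length(object@offsets) != want)
    msg <- c(msg, sprintf("%s profiles need %d offsets", object@role, want))
  if (length(object@anchors) != length(object@references))
    msg <- c(msg, "one anchor per reference required")
  aa <- if (identical(object@role, "REC")) "D" else "H"
  res <- vapply(seq_along(object@references), function(i)
    substr(as.character(object@references[[i]]), object@anchors[i],
           object@anchors[i]), character(1))
  if (length(res) && !all(res == aa))
    msg <- c(msg, sprintf("anchor residue must be %s in every reference", aa))
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", object@genomeId, "\n")
  cat("  replicons:", nrow(object@replicons),
      sprintf("(%s)", paste(object@replicons$replicon_id, collapse = ", ")),
      "\n")
  cat("  genes:", length(object@genes),
      " proteins:", length(object@proteins),
      " domain hits:", nrow(object@domainHits), "\n")
  cat("  phenotype:", object@phenotype, "\n")
})

setMethod("show", "Neighborhood", function(object) {
  cat(sprintf("Neighborhood<%s> %s/%s: %d ORFs [%s], %d marker(s)\n",
              object@target, object@genomeId, object@repliconId,
              length(object@members),
              paste(range(object@members), collapse = "-"),
              length(object@markerGenes)))
})

setMethod("show", "MarkerSpec", function(object) {
  cat(sprintf("MarkerSpec<%s> domains: %s; radius %d, mergeGap %d\n",
              object@target, paste(object@markerDomains, collapse = ", "),
              object@radius, object@mergeGap))
})

setMethod("show", "SpecificityProfile", function(object) {
  cat(sprintf("SpecificityProfile '%s' (%s): %d reference(s), offsets %s\n",
              object@profileId, object@role, length(object@references),
              paste(object@offsets, collapse = ",")))
})

# ---- accessors ----

#' Accessors for GenomeAnnotation
#'
#' @param object a \linkS4class{GenomeAnnotation}.
#' @return \code{genomeId}: the genome identifier; \code{annGenes}: the gene
#'   GRanges; \code{annProteins}: the protein AAStringSet; \code{domainHits}:
#'   the domain-hit data.frame; \code{replicons}: the replicon table;
#'   \code{phenotype}: the sporulation phenotype.
#' @aliases genomeId annGenes annProteins domainHits replicons phenotype
#' @name GenomeAnnotation-accessors
NULL

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("genomeId", "GenomeAnnotation", function(object) object@genomeId)

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("annGenes", function(object) standardGeneric("annGenes"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("annGenes", "GenomeAnnotation", function(object) object@genes)

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("annProteins", function(object) standardGeneric("annProteins"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("annProteins", "GenomeAnnotation", function(object) object@proteins)

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("domainHits", function(object) standardGeneric("domainHits"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("domainHits", "GenomeAnnotation", function(object) object@domainHits)

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("replicons", function(object) standardGeneric("replicons"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("replicons", "GenomeAnnotation", function(object) object@replicons)

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("phenotype", function(object) standardGeneric("phenotype"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("phenotype", "GenomeAnnotation", function(object) object@phenotype)

#' Accessors for Neighborhood
#'
#' @param object a \linkS4class{Neighborhood}.
#' @aliases nbhdMembers nbhdMarkers nbhdTarget
#' @name Neighborhood-accessors
NULL

#' @rdname Neighborhood-accessors
#' @export
setGeneric("nbhdMembers", function(object) standardGeneric("nbhdMembers"))
#' @rdname Neighborhood-accessors
#' @export
setMethod("nbhdMembers", "Neighborhood", function(object) object@members)

#' @rdname Neighborhood-accessors
#' @export
setGeneric("nbhdMarkers", function(object) standardGeneric("nbhdMarkers"))
#' @rdname Neighborhood-accessors
#' @export
setMethod("nbhdMarkers", "Neighborhood", function(object) object@markerGenes)

#' @rdname Neighborhood-accessors
#' @export
setGeneric("nbhdTarget", function(object) standardGeneric("nbhdTarget"))
#' @rdname Neighborhood-accessors
#' @export
setMethod("nbhdTarget", "Neighborhood", function(object) object@target)

# internal helpers shared across modules

.geneIds <- function(ann) mcols(ann@genes)$gene_id

.geneRow <- function(ann, geneId) {
  i <- match(geneId, .geneIds(ann))
  if (is.na(i)) stop("unknown gene: ", geneId)
  i
}

.hitsFor <- function(ann, geneId) {
  dh <- ann@domainHits
  dh[dh$gene_id == geneId, , drop = FALSE]
}

.orfIndexOf <- function(ann, geneId) {
  mcols(ann@genes)$orf_index[.geneRow(ann, geneId)]
}

.repliconOf <- function(ann, geneId) {
  as.character(seqnames(ann@genes))[.geneRow(ann, geneId)]
}

.nOrfs <- function(ann, repliconId) {
  sum(as.character(seqnames(ann@genes)) == repliconId)
}

.isCircular <- function(ann, repliconId) {
  i <- match(repliconId, ann@replicons$replicon_id)
  if (is.na(i)) stop("unknown replicon: ", repliconId)
  isTRUE(ann@replicons$circular[i])
}

# minimal ORF-rank distance between two indices on a replicon
.orfDistance <- function(i, j, n, circular) {
  d <- abs(i - j)
  if (circular) min(d, n - d) else d
}

.emptyDomainHits <- function() {
  data.frame(gene_id = character(), domain_name = character(),
             db = character(), evalue = numeric(),
             ali_from = integer(), ali_to = integer(),
             stringsAsFactors = FALSE)
}
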