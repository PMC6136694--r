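.spo0Candidate <- function(role, geneId, genomeId, evidence = list(),
                           flags = character()) {
  structure(list(role = role, gene_id = geneId, genome_id = genomeId,
                 evidence = evidence, flags = flags),
            class = "Spo0Candidate")
}

#' @export
print.Spo0Candidate <- function(x, ...) {
  cat(sprintf("Spo0Candidate<%s> %s (%s)%s\n", x$role, x$gene_id,
              x$genome_id,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ","), "]")
              else ""))
  invisible(x)
}

# REC domain aliases; PF00072 by default, extensible via options
.recDomains <- function() getOption("spo0scan.rec_domains", "Response_reg")

#' Classify Spo0A candidates
#'
#' Spo0A is the one response regulator whose DNA-binding output domain,
#' Spo0A_C, uniquely distinguishes it from all others, so the search is
#' genome-wide and independent of neighborhoods: every gene with a Spo0A_C
#' hit is a candidate. Candidates lacking a receiver (Response_reg) hit are
#' flagged \code{"no_REC"}.
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @return list of Spo0Candidate (possibly empty).
#' @export
classifySpo0A <- function(ann) {
  dh <- ann@domainHits
  hits <- unique(dh$gene_id[dh$domain_name == "Spo0A_C"])
  lapply(hits, function(g) {
    gh <- .hitsFor(ann, g)
    flags <- if (!any(gh$domain_name %in% .recDomains())) "no_REC"
             else character()
    .spo0Candidate("SPO0A", g, genomeId(ann),
                   evidence = list(domains = unique(gh$domain_name)),
                   flags = flags)
  })
}

#' Stand-alone REC test used for Spo0F
#'
#' TRUE when the gene's domain hits consist of exactly one receiver
#' (Response_reg) hit covering at least \code{minRecCoverage} of the protein.
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param geneId gene to test.
#' @param minRecCoverage amino-acid coverage threshold (default 0.90,
#'   inclusive).
#' @return logical.
#' @export
isSpo0fLike <- function(ann, geneId, minRecCoverage = 0.90) {
  h <- .hitsFor(ann, geneId)
  if (nrow(h) != 1L || !h$domain_name %in% .recDomains()) return(FALSE)
  plen <- mcols(ann@genes)$product_length[.geneRow(ann, geneId)]
  (h$ali_to - h$ali_from + 1L) / plen >= minRecCoverage
}

#' Classify the Spo0F candidate of a marker neighborhood
#'
#' Spo0F cannot be told apart from other single-domain receivers (e.g. CheY)
#' by sequence, so the candidate is sought only inside the chosen Spo0F marker
#' neighborhood: the member protein whose domain hits consist of exactly one
#' REC (Response_reg) hit covering 90\% or more of the protein (inclusive).
#' If more than one member qualifies the highest-coverage one is emitted with
#' flag \code{"multiple_candidates"}; proteins shorter than 100 aa are
#' flagged \code{"truncated"}.
#'
#' @param nbhd a merged \linkS4class{Neighborhood} with target "SPO0F".
#' @param ann the genome annotation.
#' @param minRecCoverage coverage threshold (default 0.90).
#' @return a Spo0Candidate or \code{NULL}.
#' @export
classifySpo0F <- function(nbhd, ann, minRecCoverage = 0.90) {
  if (!identical(nbhd@target, "SPO0F"))
    stop("neighborhood target is ", nbhd@target, ", expected SPO0F")
  ids <- neighborhoodGenes(ann, nbhd)
  ok <- vapply(ids, isSpo0fLike, logical(1), ann = ann,
               minRecCoverage = minRecCoverage)
  ids <- ids[ok]
  if (!length(ids)) return(NULL)
  cov <- vapply(ids, function(g) {
    h <- .hitsFor(ann, g)
    plen <- mcols(ann@genes)$product_length[.geneRow(ann, g)]
    (h$ali_to[1] - h$ali_from[1] + 1L) / plen
  }, numeric(1))
  best <- ids[which.max(cov)]
  flags <- character()
  if (length(ids) > 1L) flags <- c(flags, "multiple_candidates")
  plen <- mcols(ann@genes)$product_length[.geneRow(ann, best)]
  if (plen < 100L) flags <- c(flags, "truncated")
  .spo0Candidate("SPO0F", best, genomeId(ann),
                 evidence = list(rec_coverage = max(cov),
                                 neighborhood_markers = nbhd@markerGenes),
                 flags = flags)
}

#' Reference Spo0B N-terminal sequence
#'
#' The first 50 amino acids of the reference Spo0B used by
#' [classifySpo0B()]. The shipped default is a synthetic stand-in sequence
#' (see \code{inst/extdata/spo0b_nterm_synthetic.fasta}); supply a real
#' Spo0B N-terminus to reproduce a production analysis.
#'
#' @param path FASTA containing one sequence; default: the shipped fixture.
#' @return an AAString.
#' @export
spo0bReference <- function(path = system.file("extdata",
                                              "spo0b_nterm_synthetic.fasta",
                                              package = "spo0scan")) {
  if (!nzchar(path) || !file.exists(path))
    stop("missing reference Spo0B N-terminal sequence")
  Biostrings::readAAStringSet(path)[[1]]
}

.localAlign <- function(query, ref, gapOpening = 10, gapExtension = 0.5) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(ref), subject = Biostrings::AAString(query),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpening, gapExtension = gapExtension)
}

.alignStats <- function(al) {
  p <- as.character(Biostrings::alignedPattern(al))
  s <- as.character(Biostrings::alignedSubject(al))
  cols <- nchar(p)
  pm <- strsplit(p, "")[[1]]; sm <- strsplit(s, "")[[1]]
  matches <- sum(pm == sm & pm != "-")
  list(columns = cols,
       identity = if (cols) matches / cols else 0,
       score = Biostrings::score(al))
}

#' Classify the Spo0B candidate of a marker neighborhood
#'
#' Spo0B has no reliable Pfam signature; in many genomes it carries no
#' recognizable Pfam domain at all. The candidate is the member protein of
#' the chosen Spo0B marker neighborhood with zero PFAM-database domain hits
#' whose local alignment (BLOSUM62, affine gaps) to the reference Spo0B
#' N-terminal 50 aa reaches at least \code{minIdentity} identity over at
#' least \code{minAligned} aligned columns. The evidence records identity,
#' aligned length, alignment score and whether the gene lies between the
#' L27 and ObgE marker genes (flag \code{"between_L27_ObgE"}; informative,
#' not required).
#'
#' @param nbhd a merged \linkS4class{Neighborhood} with target "SPO0B" and at
#'   least one marker gene.
#' @param ann the genome annotation.
#' @param refNterm reference N-terminal sequence (default [spo0bReference()]).
#' @param minIdentity alignment identity threshold (default 0.25).
#' @param minAligned minimum aligned columns (default 40).
#' @param minScore minimum raw alignment score (default 90), a significance
#'   cutoff set above the null score distribution of unrelated proteins of
#'   comparable length against the 50-aa reference.
#' @param gapOpening,gapExtension affine gap penalties.
#' @return a Spo0Candidate or \code{NULL}.
#' @export
classifySpo0B <- function(nbhd, ann, refNterm = spo0bReference(),
                          minIdentity = 0.25, minAligned = 40L,
                          minScore = 90,
                          gapOpening = 10, gapExtension = 0.5) {
  if (!identical(nbhd@target, "SPO0B"))
    stop("neighborhood target is ", nbhd@target, ", expected SPO0B")
  if (is.null(refNterm)) stop("missing reference Spo0B N-terminal sequence")
  ids <- neighborhoodGenes(ann, nbhd)
  domFree <- vapply(ids, function(g) {
    h <- .hitsFor(ann, g)
    !any(h$db == "PFAM")
  }, logical(1))
  ids <- ids[domFree & ids %in% names(ann@proteins)]
  if (!length(ids)) return(NULL)
  stats <- lapply(ids, function(g) {
    al <- .localAlign(as.character(ann@proteins[[g]]),
                      as.character(refNterm), gapOpening, gapExtension)
    .alignStats(al)
  })
  pass <- vapply(stats, function(s)
    s$identity >= minIdentity && s$columns >= minAligned &&
      s$score >= minScore, logical(1))
  if (!any(pass)) return(NULL)
  ids <- ids[pass]; stats <- stats[pass]
  best <- which.max(vapply(stats, `[[`, numeric(1), "score"))
  g <- ids[best]
  flags <- if (length(ids) > 1L) "multiple_candidates" else character()

  # between-L27/ObgE placement: observed for all known Spo0B genes, recorded
  # as evidence only
  dh <- ann@domainHits
  l27 <- unique(dh$gene_id[dh$domain_name == "Ribosomal_L27"])
  obg <- unique(dh$gene_id[dh$domain_name == "GTP1_OBG"])
  l27 <- intersect(l27, neighborhoodGenes(ann, nbhd))
  obg <- intersect(obg, neighborhoodGenes(ann, nbhd))
  between <- FALSE
  if (length(l27) && length(obg)) {
    gi <- .orfIndexOf(ann, g)
    for (a in l27) for (b in obg) {
      ia <- .orfIndexOf(ann, a); ib <- .orfIndexOf(ann, b)
      if (gi > min(ia, ib) && gi < max(ia, ib)) between <- TRUE
    }
  }
  if (between) flags <- c(flags, "between_L27_ObgE")
  .spo0Candidate("SPO0B", g, genomeId(ann),
                 evidence = list(identity = stats[[best]]$identity,
                                 aligned_columns = stats[[best]]$columns,
                                 score = stats[[best]]$score,
                                 between_L27_ObgE = between,
                                 neighborhood_markers = nbhd@markerGenes),
                 flags = flags)
}

#' Tabulate a list of Spo0 candidates
#'
#' @param cands list of Spo0Candidate objects.
#' @return data.frame (genome_id, role, gene_id, flags, key evidence).
#' @export
candidateTable <- function(cands) {
  rows <- lapply(cands, function(x) {
    data.frame(genome_id = x$genome_id, role = x$role, gene_id = x$gene_id,
               flags = paste(x$flags, collapse = ","),
               rec_coverage = if (!is.null(x$evidence$rec_coverage))
                 x$evidence$rec_coverage else NA_real_,
               identity = if (!is.null(x$evidence$identity))
                 x$evidence$identity else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(genome_id = character(), role = character(),
                      gene_id = character(), flags = character(),
                      rec_coverage = numeric(), identity = numeric()))
  do.call(rbind, rows)
}
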