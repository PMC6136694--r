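#' Load a specificity profile
#'
#' A profile bundles reference domain sequences, the position of the conserved
#' phospho-accepting anchor residue in each (His in HisKA-like domains, Asp in
#' REC domains), and the signed offsets, relative to the anchor, at which the
#' specificity residues are read: six kinase-side positions for
#' \code{"HISKA_LIKE"} (also used for Spo0B, whose interaction surface is
#' equivalent to that of HisKA), seven receiver positions for \code{"REC"}.
#' Offsets and anchors are data, not code: they live in a sidecar TSV next to
#' the reference FASTA. The shipped default profiles use synthetic stand-in
#' reference sequences (files \code{*_synthetic.fasta} under
#' \code{inst/extdata}); the offsets shipped with them are calibrated so that
#' extraction from the shipped synthetic construct sequences reproduces the
#' published signature strings.
#'
#' @param role "HISKA_LIKE" or "REC".
#' @param fastaPath reference FASTA; default: shipped synthetic references.
#' @param sidecarPath TSV with columns \code{profile_id}, \code{role},
#'   \code{ref_name}, \code{anchor}, \code{offsets} (comma-separated).
#' @return a \linkS4class{SpecificityProfile}.
#' @export
specificityProfile <- function(role = c("HISKA_LIKE", "REC"),
                               fastaPath = NULL, sidecarPath = NULL) {
  role <- match.arg(role)
  if (is.null(sidecarPath))
    sidecarPath <- system.file("extdata", "specificity_profiles.tsv",
                               package = "spo0scan")
  side <- utils::read.table(sidecarPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  side <- side[side$role == role, , drop = FALSE]
  if (!nrow(side)) stop("no profile rows for role ", role)
  if (is.null(fastaPath))
    fastaPath <- system.file("extdata", side$fasta[1], package = "spo0scan")
  refs <- Biostrings::readAAStringSet(fastaPath)
  names(refs) <- sub("\\s.*$", "", names(refs))
  refs <- refs[side$ref_name]
  offs <- as.integer(strsplit(side$offsets[1], ",")[[1]])
  new("SpecificityProfile", profileId = side$profile_id[1], role = role,
      references = refs, anchors = as.integer(side$anchor),
      offsets = offs)
}

# map reference positions to subject positions through a local alignment
.refToSubjectMap <- function(al) {
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  pi <- Biostrings::start(al@pattern@range) - 1L
  si <- Biostrings::start(al@subject@range) - 1L
  map <- integer(0)
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-") map[pi] <- if (s[k] != "-") si else NA_integer_
  }
  map
}

#' Extract a specificity-residue signature
#'
#' Aligns the target protein locally (BLOSUM62, affine gaps) against each of
#' the profile's reference sequences; the best-scoring alignment (ties broken
#' by reference order) maps the reference anchor column onto the target,
#' defining \code{anchor_position}. The residues at anchor + offsets (offsets
#' taken in reference coordinates and mapped through the alignment) form the
#' signature; positions falling in alignment gaps or outside the aligned
#' region yield \code{"-"} and a flag. If no alignment reaches
#' \code{minScore}, or the anchor column is unaligned, an all-gap signature
#' with flag \code{"no_anchor"} is returned. A target anchor residue other
#' than the expected His/Asp is flagged \code{"low_confidence_anchor"}.
#'
#' @param seq amino-acid sequence (character or AAString).
#' @param profile a \linkS4class{SpecificityProfile}.
#' @param minScore minimum alignment score to accept an anchor (default 60).
#' @param gapOpening,gapExtension affine gap penalties.
#' @return list of class \code{"SpecificitySignature"} with elements
#'   \code{role}, \code{residues}, \code{anchor_position},
#'   \code{alignment_score}, \code{reference}, \code{flags}.
#' @export
extractSignature <- function(seq, profile, minScore = 60,
                             gapOpening = 10, gapExtension = 0.5) {
  seq <- as.character(seq)
  if (!nzchar(seq)) stop("empty sequence")
  als <- lapply(seq_along(profile@references), function(i)
    .localAlign(seq, as.character(profile@references[[i]]),
                gapOpening, gapExtension))
  scores <- vapply(als, Biostrings::score, numeric(1))
  best <- which.max(scores)   # first max: ties broken by reference order
  empty <- function(flags) {
    structure(list(role = profile@role,
                   residues = paste(rep("-", length(profile@offsets)),
                                    collapse = ""),
                   anchor_position = NA_integer_,
                   alignment_score = scores[best],
                   reference = names(profile@references)[best],
                   flags = flags),
              class = "SpecificitySignature")
  }
  if (scores[best] < minScore) return(empty("no_anchor"))
  map <- .refToSubjectMap(als[[best]])
  a <- profile@anchors[best]
  anchorPos <- if (a <= length(map)) map[a] else NA_integer_
  if (is.na(anchorPos)) return(empty("no_anchor"))
  flags <- character()
  expected <- if (identical(profile@role, "REC")) "D" else "H"
  if (substr(seq, anchorPos, anchorPos) != expected)
    flags <- c(flags, "low_confidence_anchor")
  res <- vapply(profile@offsets, function(off) {
    p <- a + off
    if (p < 1L || p > length(map)) { flags <<- union(flags,
                                       "offset_outside_alignment"); return("-") }
    t <- map[p]
    if (is.na(t)) { flags <<- union(flags, "gap_at_offset"); return("-") }
    substr(seq, t, t)
  }, character(1))
  structure(list(role = profile@role,
                 residues = paste(res, collapse = ""),
                 anchor_position = anchorPos,
                 alignment_score = scores[best],
                 reference = names(profile@references)[best],
                 flags = flags),
            class = "SpecificitySignature")
}

#' @export
print.SpecificitySignature <- function(x, ...) {
  cat(sprintf("SpecificitySignature<%s> %s (anchor %s, score %.1f vs %s)%s\n",
              x$role, x$residues,
              ifelse(is.na(x$anchor_position), "-", x$anchor_position),
              x$alignment_score, x$reference,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ","), "]")
              else ""))
  invisible(x)
}

.sigString <- function(x) {
  if (inherits(x, "SpecificitySignature")) x$residues
  else as.character(x)
}

#' Hamming distance between two signatures
#'
#' Counts mismatching positions; a gap character \code{"-"} mismatches every
#' residue but matches another gap.
#'
#' @param a,b signatures (SpecificitySignature objects or plain strings) of
#'   equal length; when both are signature objects their roles must agree.
#' @return integer mismatch count.
#' @export
hammingDistance <- function(a, b) {
  if (inherits(a, "SpecificitySignature") &&
      inherits(b, "SpecificitySignature") && !identical(a$role, b$role))
    stop("signatures of different roles")
  sa <- .sigString(a); sb <- .sigString(b)
  if (nchar(sa) != nchar(sb)) stop("signatures of different lengths")
  sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
}

#' Position frequency matrix of signatures
#'
#' Counts residues per signature position over the 20 standard amino acids;
#' gap characters are excluded per column, so each column sum equals the
#' number of contributing non-gap signatures. The output is suitable for
#' sequence-logo rendering.
#'
#' @param sigs list of SpecificitySignature objects (one role) or character
#'   vector of equal-length residue strings.
#' @return integer matrix, positions x 20 amino acids.
#' @export
positionFrequencyMatrix <- function(sigs) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.list(sigs) && length(sigs)) {
    objs <- Filter(function(s) inherits(s, "SpecificitySignature"), sigs)
    if (length(objs)) {
      roles <- unique(vapply(objs, function(s) s$role, character(1)))
      if (length(roles) > 1L) stop("mixed signature roles")
    }
  }
  strs <- vapply(sigs, .sigString, character(1))
  if (!length(strs)) {
    warning("no signatures; returning zero matrix")
    return(matrix(0L, nrow = 0, ncol = length(aa),
                  dimnames = list(NULL, aa)))
  }
  L <- unique(nchar(strs))
  if (length(L) > 1L) stop("signatures of different lengths")
  m <- matrix(0L, nrow = L, ncol = length(aa),
              dimnames = list(seq_len(L), aa))
  for (s in strs) {
    ch <- strsplit(s, "")[[1]]
    for (p in seq_len(L)) if (ch[p] %in% aa) m[p, ch[p]] <- m[p, ch[p]] + 1L
  }
  m
}

#' Within- and between-group mean pairwise signature distances
#'
#' A declared summary statistic for comparing signature groups (e.g. by
#' taxonomic class or by pathway architecture): the mean pairwise Hamming
#' distance within each group (over unordered distinct pairs; \code{NA} for
#' singleton groups) and between each pair of groups (over all cross pairs).
#'
#' @param groups named list: label -> list of signatures (one role, equal
#'   lengths).
#' @return symmetric numeric matrix, labels x labels.
#' @export
groupDistanceSummary <- function(groups) {
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a non-empty named list")
  strs <- lapply(groups, function(g) vapply(g, .sigString, character(1)))
  for (g in strs) {
    if (!length(g)) stop("group with no signatures")
    if (length(unique(nchar(g))) > 1L)
      stop("group with signatures of mixed length")
  }
  labs <- names(groups)
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j < i) next
    a <- strs[[i]]; b <- strs[[j]]
    if (i == j) {
      if (length(a) < 2L) { m[i, j] <- NA_real_; next }
      pairs <- utils::combn(length(a), 2)
      m[i, j] <- mean(apply(pairs, 2, function(p)
        hammingDistance(a[p[1]], a[p[2]])))
    } else {
      d <- outer(seq_along(a), seq_along(b), Vectorize(function(x, y)
        hammingDistance(a[x], b[y])))
      m[i, j] <- m[j, i] <- mean(d)
    }
  }
  m
}

#' Published specificity-residue table
#'
#' The printed table of predicted specificity residues for the Spo0 proteins
#' of three reference species (and the orphan-kinase PAS annotation), shipped
#' as a plain-text fixture. Used as a worked-example input and lookup table.
#'
#' @return data.frame with columns \code{species}, \code{locus}, \code{role}
#'   (kinase/spo0f/spo0b/spo0a), \code{pas} (Yes/No/NA) and
#'   \code{signature}.
#' @export
readSpecificityTable <- function() {
  path <- system.file("extdata", "table1_specificity.tsv",
                      package = "spo0scan")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Summarize a species' orphan-kinase rows of the published table
#'
#' @param species species name as printed in the table.
#' @return list with \code{n_orphan_kinases} and \code{n_pas_positive}.
#' @export
summarizeTableKinases <- function(species) {
  tab <- readSpecificityTable()
  k <- tab[tab$species == species & tab$role == "kinase", , drop = FALSE]
  list(n_orphan_kinases = nrow(k),
       n_pas_positive = sum(k$pas == "Yes", na.rm = TRUE))
}
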