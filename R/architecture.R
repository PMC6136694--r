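#' Assemble the Spo0 inventory of one genome
#'
#' Runs the whole single-genome detection cascade: genome-wide Spo0A search;
#' Spo0F and Spo0B marker-neighborhood discovery, neighborhood choice and
#' classification; kinase inventory with orphan and PAS flags.
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param spo0fSpec,spo0bSpec marker specifications (defaults:
#'   [markerSpec()] for each target).
#' @param minRecCoverage Spo0F REC-coverage threshold (default 0.90).
#' @param refNterm reference Spo0B N-terminus (default [spo0bReference()]).
#' @param minIdentity,minAligned,minScore Spo0B alignability thresholds.
#' @param orphanWindow kinase co-location window in ORFs (default 4).
#' @return list of class \code{"Spo0Inventory"}: \code{genome_id},
#'   \code{spo0a} (list), \code{spo0f}, \code{spo0b} (candidate or NULL),
#'   \code{kinases} (data.frame), \code{phenotype}.
#' @export
buildSpo0Inventory <- function(ann,
                               spo0fSpec = markerSpec("SPO0F"),
                               spo0bSpec = markerSpec("SPO0B"),
                               minRecCoverage = 0.90,
                               refNterm = spo0bReference(),
                               minIdentity = 0.25, minAligned = 40L,
                               minScore = 90,
                               orphanWindow = 4L) {
  spo0a <- classifySpo0A(ann)

  spo0f <- NULL
  nbF <- discoverNeighborhoods(ann, spo0fSpec)
  if (length(nbF)) {
    chosen <- chooseMarkerNeighborhood(ann, nbF, function(a, g)
      isSpo0fLike(a, g, minRecCoverage))
    spo0f <- classifySpo0F(chosen, ann, minRecCoverage)
  }

  spo0b <- NULL
  nbB <- discoverNeighborhoods(ann, spo0bSpec)
  if (length(nbB)) {
    chosenB <- chooseMarkerNeighborhood(ann, nbB, NULL)
    spo0b <- classifySpo0B(chosenB, ann, refNterm = refNterm,
                           minIdentity = minIdentity,
                           minAligned = minAligned, minScore = minScore)
  }

  kin <- kinaseInventory(ann, window = orphanWindow)
  structure(list(genome_id = genomeId(ann), spo0a = spo0a, spo0f = spo0f,
                 spo0b = spo0b, kinases = kin, phenotype = phenotype(ann)),
            class = "Spo0Inventory")
}

#' @export
print.Spo0Inventory <- function(x, ...) {
  cat(sprintf(
    "Spo0Inventory %s: Spo0A x%d, Spo0F %s, Spo0B %s, %d kinase(s) (%d orphan)\n",
    x$genome_id, length(x$spo0a),
    if (is.null(x$spo0f)) "-" else x$spo0f$gene_id,
    if (is.null(x$spo0b)) "-" else x$spo0b$gene_id,
    nrow(x$kinases), sum(x$kinases$is_orphan, na.rm = TRUE)))
  invisible(x)
}

#' Call the Spo0 pathway architecture of a genome
#'
#' Rule: Spo0A together with both Spo0F and Spo0B predicts a
#' \code{PHOSPHORELAY}; Spo0A with neither predicts \code{DIRECT}
#' phosphorylation; Spo0A with exactly one of the two intermediates is
#' \code{PARTIAL_RELAY} (such genomes exist, e.g. Spo0B-like proteins in
#' direct-phosphorylation clades); no Spo0A means \code{NO_SPO0}. The call is
#' a pure function of the inventory.
#'
#' @param inv a \code{"Spo0Inventory"}.
#' @return list of class \code{"ArchitectureCall"}: \code{genome_id},
#'   \code{label}, \code{rationale}.
#' @export
callArchitecture <- function(inv) {
  hasA <- length(inv$spo0a) > 0L
  hasF <- !is.null(inv$spo0f)
  hasB <- !is.null(inv$spo0b)
  label <- if (!hasA) "NO_SPO0"
    else if (hasF && hasB) "PHOSPHORELAY"
    else if (!hasF && !hasB) "DIRECT"
    else "PARTIAL_RELAY"
  rationale <- sprintf("Spo0A:%s Spo0F:%s Spo0B:%s",
                       if (hasA) "yes" else "no",
                       if (hasF) "yes" else "no",
                       if (hasB) "yes" else "no")
  structure(list(genome_id = inv$genome_id, label = label,
                 rationale = rationale),
            class = "ArchitectureCall")
}

#' @export
print.ArchitectureCall <- function(x, ...) {
  cat(sprintf("ArchitectureCall %s: %s (%s)\n", x$genome_id, x$label,
              x$rationale))
  invisible(x)
}

# deterministic binarization: children ordered by smallest descendant tip
# label, then folded into a left caterpillar
.treeToNested <- function(tree) {
  nTip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    if (node <= nTip)
      return(list(t = tree$tip.label[node], m = tree$tip.label[node]))
    ch <- lapply(kids[[as.character(node)]], build)
    ch <- ch[order(vapply(ch, `[[`, character(1), "m"))]
    acc <- ch[[1]]
    for (k in seq_along(ch)[-1])
      acc <- list(t = list(acc$t, ch[[k]]$t), m = min(acc$m, ch[[k]]$m))
    acc
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  build(root)$t
}

#' Fitch parsimony count of architecture transitions
#'
#' Minimum number of discrete state changes on a rooted tree needed to
#' explain the leaf labels, by the Fitch small-parsimony algorithm. Leaves
#' whose label is outside \code{states} (e.g. \code{NO_SPO0} genomes) are
#' pruned first. Non-binary nodes are resolved deterministically (children
#' sorted by smallest descendant label, folded left). With
#' \code{twoState = TRUE}, \code{PARTIAL_RELAY} is mapped to
#' \code{PHOSPHORELAY} so the count concerns relay/direct transitions only.
#'
#' @param tree a rooted \code{ape::phylo}; leaf names are genome ids.
#' @param labels named character vector: genome id -> architecture label.
#' @param states the label subset treated as character states (default the
#'   three architecture labels).
#' @param twoState collapse PARTIAL_RELAY into PHOSPHORELAY first.
#' @return integer minimum change count.
#' @export
fitchTransitionCount <- function(tree, labels,
                                 states = c("PHOSPHORELAY", "DIRECT",
                                            "PARTIAL_RELAY"),
                                 twoState = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (twoState) {
    labels[labels == "PARTIAL_RELAY"] <- "PHOSPHORELAY"
    states <- setdiff(states, "PARTIAL_RELAY")
  }
  keep <- tree$tip.label[tree$tip.label %in% names(labels) &
                           labels[tree$tip.label] %in% states]
  missing <- setdiff(tree$tip.label, names(labels))
  if (length(missing))
    stop("unlabeled leaf after pruning: ", paste(missing, collapse = ", "))
  if (!length(keep)) return(0L)
  if (length(keep) == 1L) return(0L)
  sub <- ape::keep.tip(tree, keep)
  nested <- .treeToNested(sub)
  count <- 0L
  fitch <- function(node) {
    if (is.character(node)) return(labels[[node]])
    l <- fitch(node[[1]]); r <- fitch(node[[2]])
    inter <- intersect(l, r)
    if (length(inter)) inter else { count <<- count + 1L; union(l, r) }
  }
  fitch(nested)
  count
}

#' Presence/absence report across genomes
#'
#' One row per genome with booleans for orphan kinases, PAS-bearing orphans,
#' Spo0F, Spo0B, Spo0A, plus the architecture label and phenotype. When a
#' tree is supplied, rows follow its leaf order; genomes absent from the tree
#' are appended afterwards and flagged (\code{in_tree = FALSE}); tree leaves
#' without an inventory get a row of missing-data markers.
#'
#' @param invs list of \code{"Spo0Inventory"} objects.
#' @param tree optional \code{ape::phylo} whose tip labels are genome ids.
#' @return data.frame.
#' @export
presenceAbsenceReport <- function(invs, tree = NULL) {
  mk <- function(inv) {
    call <- callArchitecture(inv)
    orph <- inv$kinases$is_orphan & !inv$kinases$is_hybrid
    data.frame(genome_id = inv$genome_id,
               orphan_kinase = any(orph, na.rm = TRUE),
               pas_orphan = any(orph & inv$kinases$has_nterm_pas,
                                na.rm = TRUE),
               spo0a = length(inv$spo0a) > 0L,
               spo0f = !is.null(inv$spo0f),
               spo0b = !is.null(inv$spo0b),
               architecture = call$label,
               phenotype = inv$phenotype,
               in_tree = NA,
               stringsAsFactors = FALSE)
  }
  naRow <- function(id) data.frame(
    genome_id = id, orphan_kinase = NA, pas_orphan = NA, spo0a = NA,
    spo0f = NA, spo0b = NA, architecture = NA_character_,
    phenotype = NA_character_, in_tree = TRUE, stringsAsFactors = FALSE)
  empty <- data.frame(genome_id = character(), orphan_kinase = logical(),
                      pas_orphan = logical(), spo0a = logical(),
                      spo0f = logical(), spo0b = logical(),
                      architecture = character(), phenotype = character(),
                      in_tree = logical(), stringsAsFactors = FALSE)
  if (!length(invs) && is.null(tree)) return(empty)
  byId <- stats::setNames(invs, vapply(invs, `[[`, character(1),
                                       "genome_id"))
  if (is.null(tree)) {
    out <- do.call(rbind, lapply(invs, mk))
    out$in_tree <- NA
    rownames(out) <- NULL
    return(out)
  }
  rows <- lapply(tree$tip.label, function(id) {
    if (!is.null(byId[[id]])) { r <- mk(byId[[id]]); r$in_tree <- TRUE; r }
    else naRow(id)
  })
  extra <- setdiff(names(byId), tree$tip.label)
  rows <- c(rows, lapply(extra, function(id) {
    r <- mk(byId[[id]]); r$in_tree <- FALSE; r
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an iTOL-style dot annotation of the report
#'
#' Mirrors the dot scheme used to annotate species trees with predicted Spo0
#' proteins: orphan kinase, Spo0F, Spo0B, Spo0A presence per genome.
#'
#' @param report output of [presenceAbsenceReport()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeItolAnnotation <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("DATASET_BINARY", "SEPARATOR TAB", "DATASET_LABEL\tspo0scan",
               "FIELD_SHAPES\t2\t2\t2\t2",
               "FIELD_LABELS\torphan_kinase\tspo0f\tspo0b\tspo0a",
               "FIELD_COLORS\t#00c0c0\t#2040c0\t#e08020\t#20a040",
               "DATA"), con)
  for (r in seq_len(nrow(report))) {
    v <- function(x) if (is.na(x)) "-1" else if (isTRUE(x)) "1" else "0"
    writeLines(paste(report$genome_id[r], v(report$orphan_kinase[r]),
                     v(report$spo0f[r]), v(report$spo0b[r]),
                     v(report$spo0a[r]), sep = "\t"), con)
  }
  invisible(path)
}
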