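#' Scan one genome for Spo0 pathway components
#'
#' Single-genome core of the pipeline: builds the inventory, calls the
#' architecture, and extracts specificity signatures for every detected
#' component (receiver profile for Spo0A and Spo0F; kinase-side profile for
#' Spo0B and the candidate sporulation kinases).
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param hiskaProfile,recProfile specificity profiles (defaults: shipped
#'   profiles).
#' @param ... passed to [buildSpo0Inventory()].
#' @return list with \code{inventory}, \code{call} and \code{signatures}
#'   (data.frame: genome, role, gene, residues, anchor, score, flags).
#' @export
scanGenome <- function(ann,
                       hiskaProfile = specificityProfile("HISKA_LIKE"),
                       recProfile = specificityProfile("REC"), ...) {
  inv <- buildSpo0Inventory(ann, ...)
  call <- callArchitecture(inv)
  prot <- ann@proteins
  sigRow <- function(role, gene, profile) {
    if (is.null(gene) || !gene %in% names(prot)) return(NULL)
    s <- extractSignature(as.character(prot[[gene]]), profile)
    data.frame(genome_id = genomeId(ann), role = role, gene_id = gene,
               residues = s$residues, anchor_position = s$anchor_position,
               alignment_score = s$alignment_score,
               flags = paste(s$flags, collapse = ","),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (cand in inv$spo0a)
    rows <- c(rows, list(sigRow("SPO0A", cand$gene_id, recProfile)))
  if (!is.null(inv$spo0f))
    rows <- c(rows, list(sigRow("SPO0F", inv$spo0f$gene_id, recProfile)))
  if (!is.null(inv$spo0b))
    rows <- c(rows, list(sigRow("SPO0B", inv$spo0b$gene_id, hiskaProfile)))
  tiers <- predictSporulationKinases(inv$kinases)
  for (g in tiers$primary)
    rows <- c(rows, list(sigRow("KINASE_PRIMARY", g, hiskaProfile)))
  for (g in tiers$secondary)
    rows <- c(rows, list(sigRow("KINASE_SECONDARY", g, hiskaProfile)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  sigs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), role = character(),
               gene_id = character(), residues = character(),
               anchor_position = integer(), alignment_score = numeric(),
               flags = character(), stringsAsFactors = FALSE)
  list(inventory = inv, call = call, signatures = sigs)
}

#' Run the full Spo0 scan over a genome cohort
#'
#' Orchestrates load -> neighborhoods -> classifiers -> kinases -> signatures
#' -> architecture -> report as one reproducible run. Writes the inventory,
#' signature and architecture tables, per-role position frequency matrices,
#' the tree annotation (when a tree is given) and a machine-readable run
#' manifest with per-stage counts. A genome whose scan fails is logged and
#' marked in the report rather than aborting the cohort (set
#' \code{strict = TRUE} to abort instead).
#'
#' @param genomes list of \linkS4class{GenomeAnnotation}s, or a directory
#'   containing \code{<id>.gff3/.faa/.domains.tsv} triplets.
#' @param outDir output directory.
#' @param tree optional \code{ape::phylo} (or path to a Newick file); leaf
#'   names are genome ids.
#' @param strict abort on the first per-genome failure (default FALSE).
#' @param ... passed to [scanGenome()].
#' @return invisibly, a list with \code{report}, \code{signatures},
#'   \code{calls}, \code{transitions} and \code{manifest}.
#' @export
runScan <- function(genomes, outDir, tree = NULL, strict = FALSE, ...) {
  if (is.character(genomes) && length(genomes) == 1L) {
    gffs <- list.files(genomes, pattern = "\\.gff3$", full.names = TRUE)
    genomes <- lapply(gffs, function(g) {
      base <- sub("\\.gff3$", "", g)
      readAnnotation(g, paste0(base, ".faa"),
                     paste0(base, ".domains.tsv"))
    })
  }
  if (is.character(tree)) tree <- ape::read.tree(tree)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  invs <- list(); sigTabs <- list(); failed <- character()
  for (ann in genomes) {
    res <- tryCatch(scanGenome(ann, ...), error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop("scan failed for ", genomeId(ann), ": ",
                       conditionMessage(res))
      warning("scan failed for ", genomeId(ann), ": ",
              conditionMessage(res))
      failed <- c(failed, genomeId(ann))
      next
    }
    invs[[genomeId(ann)]] <- res$inventory
    sigTabs[[genomeId(ann)]] <- res$signatures
  }
  report <- presenceAbsenceReport(unname(invs), tree)
  sigs <- if (length(sigTabs)) do.call(rbind, c(sigTabs,
                                                make.row.names = FALSE))
          else data.frame()
  calls <- lapply(unname(invs), callArchitecture)
  labels <- stats::setNames(vapply(calls, `[[`, character(1), "label"),
                            vapply(calls, `[[`, character(1), "genome_id"))

  transitions <- NULL
  if (!is.null(tree)) {
    transitions <- list(
      three_state = fitchTransitionCount(tree, labels),
      two_state = fitchTransitionCount(tree, labels, twoState = TRUE))
  } else {
    message("no tree supplied; tree-dependent outputs skipped")
  }

  utils::write.table(report, file.path(outDir, "presence_absence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sigs, file.path(outDir, "signatures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  archTab <- data.frame(genome_id = names(labels),
                        architecture = unname(labels),
                        stringsAsFactors = FALSE)
  utils::write.table(archTab, file.path(outDir, "architecture.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (role in unique(sigs$role)) {
    sub <- sigs$residues[sigs$role == role & !grepl("no_anchor", sigs$flags)]
    sub <- sub[!grepl("-", sub, fixed = TRUE)]
    if (!length(sub)) next
    pfm <- positionFrequencyMatrix(as.list(sub))
    utils::write.table(pfm, file.path(outDir, paste0("pfm_", role, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(tree))
    writeItolAnnotation(report, file.path(outDir, "itol_annotation.txt"))

  manifest <- list(
    tool = "spo0scan",
    version = as.character(utils::packageVersion("spo0scan")),
    n_genomes = length(genomes),
    n_scanned = length(invs),
    n_failed = length(failed),
    failed = failed,
    counts = list(
      spo0a = sum(report$spo0a, na.rm = TRUE),
      spo0f = sum(report$spo0f, na.rm = TRUE),
      spo0b = sum(report$spo0b, na.rm = TRUE),
      orphan_kinase = sum(report$orphan_kinase, na.rm = TRUE)),
    architectures = as.list(table(labels)),
    transitions = transitions)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(archTab, file.path(outDir, "architecture.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(report = report, signatures = sigs, calls = calls,
                 transitions = transitions, manifest = manifest))
}
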