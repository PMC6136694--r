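#' Read a genome annotation from GFF3 + protein FASTA + domain table
#'
#' Builds a validated \linkS4class{GenomeAnnotation} from the three standard
#' files. CDS features are read from the GFF3 (via
#' \link[rtracklayer]{import.gff3}); their \code{ID} attribute keys the protein
#' FASTA and the domain table. ORFs are ranked along each replicon in
#' coordinate order into a 0-based \code{orf_index}. Domain rows that do not
#' match a loaded gene, or whose alignment coordinates exceed the protein
#' length, are excluded with a warning and counted in the load report
#' (\code{attr(ann, "loadReport")}); they are never silently dropped. CDS
#' without a protein sequence (e.g. pseudogenes) are skipped with a warning.
#'
#' @param gffPath GFF3 file with CDS features carrying stable \code{ID}s.
#' @param fastaPath protein FASTA keyed by the same IDs.
#' @param domainsPath tab-separated domain-hit table with header columns
#'   \code{gene_id}, \code{domain_name}, \code{db}, \code{evalue},
#'   \code{ali_from}, \code{ali_to} (a strict subset of hmmscan domtblout
#'   content; see [convertDomtblout()]), or \code{NULL} for none.
#' @param phenotype optional sporulation phenotype
#'   (\code{"spore_former"}, \code{"non_spore_former"}, \code{"unknown"}).
#' @param genomeId genome identifier; defaults to the GFF basename.
#' @param circular named logical vector (by replicon) or single logical;
#'   default \code{TRUE} (bacterial chromosomes).
#' @return a \linkS4class{GenomeAnnotation} with attribute
#'   \code{"loadReport"} (counts of excluded rows).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' cfg <- simulationConfig(seed = 1, genesPerGenome = c(250, 250))
#' gt <- generateGenome(cfg, 1)
#' writeAnnotation(gt$annotation, dir)
#' ann <- readAnnotation(file.path(dir, "sim_genome_1.gff3"),
#'                       file.path(dir, "sim_genome_1.faa"),
#'                       file.path(dir, "sim_genome_1.domains.tsv"))
#' ann
#' @export
readAnnotation <- function(gffPath, fastaPath, domainsPath = NULL,
                           phenotype = "unknown", genomeId = NULL,
                           circular = TRUE) {
  gff <- rtracklayer::import.gff3(gffPath)
  cds <- gff[gff$type == "CDS"]
  if (!length(cds)) stop("no CDS features in ", gffPath)
  ids <- as.character(cds$ID)
  if (anyDuplicated(ids)) stop("duplicate gene IDs in ", gffPath)
  if (is.null(genomeId))
    genomeId <- sub("\\.gff3?$", "", basename(gffPath))

  prot <- Biostrings::readAAStringSet(fastaPath)
  names(prot) <- sub("\\s.*$", "", names(prot))

  skipped <- setdiff(ids, names(prot))
  if (length(skipped)) {
    warning(length(skipped), " CDS without protein sequence skipped ",
            "(pseudogenes?): ", paste(utils::head(skipped, 3), collapse = ", "))
    cds <- cds[!ids %in% skipped]
    ids <- as.character(cds$ID)
  }
  prot <- prot[intersect(names(prot), ids)]

  # replicon table; length from seqinfo or sequence-region pragmas when
  # present, else max coordinate
  reps <- unique(as.character(GenomicRanges::seqnames(cds)))
  slen <- GenomeInfoDb::seqlengths(cds)[reps]
  hdr <- grep("^##sequence-region", readLines(gffPath, n = 200L),
              value = TRUE)
  if (length(hdr)) {
    parts <- strsplit(trimws(hdr), "\\s+")
    pr <- vapply(parts, `[`, character(1), 2L)
    pl <- as.numeric(vapply(parts, `[`, character(1), 4L))
    hit <- match(reps, pr)
    slen <- ifelse(is.na(slen) & !is.na(hit), pl[hit], slen)
  }
  lens <- ifelse(is.na(slen),
                 vapply(reps, function(r)
                   max(GenomicRanges::end(cds)[
                     as.character(GenomicRanges::seqnames(cds)) == r]) + 100L,
                   numeric(1)),
                 slen)
  circ <- if (length(circular) == 1L) rep(circular, length(reps))
          else circular[reps]
  repTab <- data.frame(replicon_id = reps, length = as.numeric(lens),
                       circular = as.logical(circ), stringsAsFactors = FALSE)

  ord <- order(as.character(GenomicRanges::seqnames(cds)),
               GenomicRanges::start(cds))
  cds <- cds[ord]
  orf <- unlist(lapply(split(seq_along(cds),
                             as.character(GenomicRanges::seqnames(cds))),
                       function(ix) seq_along(ix) - 1L), use.names = FALSE)

  genes <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(cds),
    ranges = IRanges::ranges(cds),
    strand = GenomicRanges::strand(cds))
  mcols(genes)$gene_id <- as.character(cds$ID)
  mcols(genes)$orf_index <- orf
  plen <- Biostrings::width(prot)[match(mcols(genes)$gene_id, names(prot))]
  mcols(genes)$product_length <- as.integer(plen)

  report <- c(unknown_gene = 0L, bad_coords = 0L,
              skipped_cds = length(skipped))
  dh <- .emptyDomainHits()
  if (!is.null(domainsPath)) {
    raw <- utils::read.table(domainsPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    if (nrow(raw)) {
      bad <- !raw$gene_id %in% mcols(genes)$gene_id
      if (any(bad)) {
        warning(sum(bad), " domain hit(s) referencing unknown genes excluded")
        report["unknown_gene"] <- sum(bad)
        raw <- raw[!bad, , drop = FALSE]
      }
      pl <- mcols(genes)$product_length[
        match(raw$gene_id, mcols(genes)$gene_id)]
      bad2 <- raw$ali_from < 1L | raw$ali_to < raw$ali_from | raw$ali_to > pl
      if (any(bad2)) {
        warning(sum(bad2), " domain hit(s) with invalid coordinates excluded")
        report["bad_coords"] <- sum(bad2)
        raw <- raw[!bad2, , drop = FALSE]
      }
      dh <- data.frame(gene_id = raw$gene_id, domain_name = raw$domain_name,
                       db = raw$db, evalue = as.numeric(raw$evalue),
                       ali_from = as.integer(raw$ali_from),
                       ali_to = as.integer(raw$ali_to),
                       stringsAsFactors = FALSE)
    }
  }

  ann <- new("GenomeAnnotation", genomeId = genomeId, replicons = repTab,
             genes = genes, proteins = prot, domainHits = dh,
             phenotype = match.arg(phenotype, .PHENOTYPES))
  attr(ann, "loadReport") <- report
  ann
}

#' Write a genome annotation to GFF3 + protein FASTA + domain table
#'
#' Inverse of [readAnnotation()]: emits \code{<genomeId>.gff3},
#' \code{<genomeId>.faa} and \code{<genomeId>.domains.tsv} so that reading
#' them back reproduces gene order, coordinates and domain hits exactly.
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeAnnotation <- function(ann, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, genomeId(ann))
  g <- ann@genes
  out <- g
  mcols(out) <- NULL
  out$source <- "spo0scan"
  out$type <- "CDS"
  out$ID <- mcols(g)$gene_id
  out$phase <- 0L
  sl <- stats::setNames(ann@replicons$length, ann@replicons$replicon_id)
  GenomeInfoDb::seqlengths(out) <- sl[GenomeInfoDb::seqlevels(out)]
  gff <- paste0(base, ".gff3")
  rtracklayer::export.gff3(out, gff)
  # ensure replicon lengths survive the round trip as sequence-region pragmas
  lines <- readLines(gff)
  if (!any(startsWith(lines, "##sequence-region"))) {
    pragma <- sprintf("##sequence-region %s 1 %d",
                      ann@replicons$replicon_id,
                      as.integer(ann@replicons$length))
    writeLines(append(lines, pragma, after = 1L), gff)
  }
  faa <- paste0(base, ".faa")
  Biostrings::writeXStringSet(ann@proteins, faa)
  tsv <- paste0(base, ".domains.tsv")
  utils::write.table(ann@domainHits, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gff = gff, faa = faa, domains = tsv))
}

#' Convert hmmscan domtblout to the package's domain-hit table
#'
#' Extracts gene id (query), domain name (target), independent E-value and
#' alignment envelope coordinates from a standard \code{hmmscan --domtblout}
#' file into the six-column TSV that [readAnnotation()] consumes.
#'
#' @param domtbloutPath hmmscan per-domain table.
#' @param outPath output TSV path, or \code{NULL} to return the data.frame.
#' @param db database label to assign (default \code{"PFAM"}).
#' @return the converted data.frame (invisibly if written).
#' @export
convertDomtblout <- function(domtbloutPath, outPath = NULL, db = "PFAM") {
  lines <- readLines(domtbloutPath)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(fields, length, integer(1)) < 22L
  if (any(bad)) stop("malformed domtblout line(s): ", which(bad)[1])
  df <- data.frame(
    gene_id = vapply(fields, `[`, character(1), 4L),
    domain_name = vapply(fields, `[`, character(1), 1L),
    db = db,
    evalue = as.numeric(vapply(fields, `[`, character(1), 13L)),
    ali_from = as.integer(vapply(fields, `[`, character(1), 18L)),
    ali_to = as.integer(vapply(fields, `[`, character(1), 19L)),
    stringsAsFactors = FALSE)
  if (is.null(outPath)) return(df)
  utils::write.table(df, outPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Domain hits of one gene
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param geneId gene identifier (must exist).
#' @return data.frame of the gene's domain hits, sorted by \code{ali_from}.
#' @export
domainsOf <- function(ann, geneId) {
  .geneRow(ann, geneId)  # errors on unknown gene
  h <- .hitsFor(ann, geneId)
  h[order(h$ali_from), , drop = FALSE]
}

#' Normalized genomic position of a gene
#'
#' Position of the start codon (or of the stop codon for genes on the
#' complementary strand) divided by the replicon length in bp; both ends fall
#' on the lower genomic coordinate, so the value is \code{start / length} on
#' either strand. Used to describe where pathway genes sit along the
#' chromosome (e.g. Spo0F near the replication origin).
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param geneId gene identifier.
#' @return numeric in [0, 1).
#' @export
normalizedPosition <- function(ann, geneId) {
  i <- .geneRow(ann, geneId)
  rep <- as.character(seqnames(ann@genes))[i]
  j <- match(rep, ann@replicons$replicon_id)
  if (is.na(j)) stop("gene on unknown replicon: ", rep)
  GenomicRanges::start(ann@genes)[i] / ann@replicons$length[j]
}
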