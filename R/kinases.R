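# domain alias sets used by the kinase inventory; overridable via options so
# that alternative HMM libraries can be accommodated without code changes
.hiskaDomains <- function()
  getOption("spo0scan.hiska_domains",
            c("HisKA", "HisKA_2", "HisKA_3", "HWE_HK"))
.catalyticDomains <- function()
  getOption("spo0scan.catalytic_domains", c("HATPase_c", "HK_CA"))
.pasDomains <- function()
  getOption("spo0scan.pas_domains", c("PAS", "PAC"))
.tcsDomains <- function()
  getOption("spo0scan.tcs_domains",
            c(.recDomains(), .hiskaDomains(), "HPt",
              "Trans_reg_C", "GerE", "LytTR"))

.emptyKinaseRecords <- function() {
  data.frame(gene_id = character(), genome_id = character(),
             has_hiska = logical(), has_catalytic = logical(),
             catalytic_family = character(), is_hybrid = logical(),
             is_orphan = logical(), has_nterm_pas = logical(),
             nearest_tcs_distance = numeric(), stringsAsFactors = FALSE)
}

#' Inventory histidine kinases
#'
#' A gene enters the inventory when its protein carries both a HisKA-family
#' dimerization/phosphotransfer hit and a kinase catalytic hit (HATPase_c or
#' an Agfam HK_CA row). A co-occurring receiver (Response_reg) hit marks the
#' kinase as hybrid. The Agfam catalytic-family label (e.g. "HK_CA:2",
#' "HK_CA:3") is passed through from AGFAM rows of the domain table, never
#' computed. Orphan and PAS flags are left unset; see
#' [assignOrphanStatus()] and [flagNtermPas()].
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @return data.frame of kinase records (one row per kinase).
#' @export
findHistidineKinases <- function(ann) {
  dh <- ann@domainHits
  if (!nrow(dh)) return(.emptyKinaseRecords())
  byGene <- split(dh, dh$gene_id)
  rows <- lapply(byGene, function(h) {
    hasK <- any(h$domain_name %in% .hiskaDomains())
    hasC <- any(h$domain_name %in% .catalyticDomains()) ||
      any(h$db == "AGFAM" & grepl("^HK_CA", h$domain_name))
    if (!(hasK && hasC)) return(NULL)
    fam <- h$domain_name[h$db == "AGFAM" & grepl("^HK_CA", h$domain_name)]
    data.frame(gene_id = h$gene_id[1], genome_id = genomeId(ann),
               has_hiska = TRUE, has_catalytic = TRUE,
               catalytic_family = if (length(fam)) fam[1] else NA_character_,
               is_hybrid = any(h$domain_name %in% .recDomains()),
               is_orphan = NA, has_nterm_pas = NA,
               nearest_tcs_distance = NA_real_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptyKinaseRecords())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Decide orphan status for each kinase
#'
#' A kinase is an orphan when it is not co-located with genes encoding other
#' two-component signaling proteins: no other gene within \code{window} ORFs
#' (on the same replicon, wrapping on circular replicons) carries a
#' two-component domain (receiver, HisKA family, HPt, or a configured
#' output-domain alias). The ORF distance to the nearest such gene is
#' recorded (\code{Inf} when none exists).
#'
#' @param ann the genome annotation.
#' @param kinases data.frame from [findHistidineKinases()].
#' @param window co-location window in ORFs (default 4, mirroring the
#'   neighborhood radius).
#' @return the records with \code{is_orphan} and \code{nearest_tcs_distance}
#'   filled in.
#' @export
assignOrphanStatus <- function(ann, kinases, window = 4L) {
  if (!nrow(kinases)) return(kinases)
  dh <- ann@domainHits
  tcsGenes <- unique(dh$gene_id[dh$domain_name %in% .tcsDomains()])
  g <- ann@genes
  gid <- .geneIds(ann)
  for (r in seq_len(nrow(kinases))) {
    kg <- kinases$gene_id[r]
    rep <- .repliconOf(ann, kg)
    n <- .nOrfs(ann, rep)
    circ <- .isCircular(ann, rep)
    ki <- .orfIndexOf(ann, kg)
    others <- setdiff(tcsGenes, kg)
    others <- others[vapply(others, function(x) .repliconOf(ann, x),
                            character(1)) == rep]
    if (!length(others)) {
      kinases$is_orphan[r] <- TRUE
      kinases$nearest_tcs_distance[r] <- Inf
      next
    }
    d <- vapply(others, function(x)
      .orfDistance(ki, .orfIndexOf(ann, x), n, circ), integer(1))
    kinases$nearest_tcs_distance[r] <- min(d)
    kinases$is_orphan[r] <- min(d) > window
  }
  kinases
}

#' Flag N-terminal PAS sensor domains
#'
#' \code{has_nterm_pas} is TRUE iff a PAS or PAC hit starts before the
#' (first) HisKA-family hit on the same protein.
#'
#' @param ann the genome annotation.
#' @param kinases kinase records.
#' @return the records with \code{has_nterm_pas} filled in.
#' @export
flagNtermPas <- function(ann, kinases) {
  if (!nrow(kinases)) return(kinases)
  for (r in seq_len(nrow(kinases))) {
    h <- .hitsFor(ann, kinases$gene_id[r])
    hiska <- h[h$domain_name %in% .hiskaDomains(), , drop = FALSE]
    pas <- h[h$domain_name %in% .pasDomains(), , drop = FALSE]
    kinases$has_nterm_pas[r] <-
      nrow(pas) > 0L && nrow(hiska) > 0L &&
      any(pas$ali_from < min(hiska$ali_from))
  }
  kinases
}

#' Nominate candidate sporulation kinases
#'
#' Orphan status combined with an N-terminal PAS domain is the signature of a
#' candidate Spo0 kinase. Primary tier: orphan, N-terminal PAS, not hybrid
#' (a fused receiver insulates hybrid kinases from the pathway). Secondary
#' tier: the remaining non-hybrid orphans, since verified sporulation kinases
#' without a PAS domain exist.
#'
#' @param kinases records with orphan and PAS flags assigned.
#' @return list with character vectors \code{primary} and \code{secondary}.
#' @export
predictSporulationKinases <- function(kinases) {
  if (!nrow(kinases)) return(list(primary = character(),
                                  secondary = character()))
  orphan <- kinases$is_orphan & !kinases$is_hybrid
  primary <- kinases$gene_id[orphan & kinases$has_nterm_pas]
  secondary <- kinases$gene_id[orphan & !kinases$has_nterm_pas]
  list(primary = primary, secondary = secondary)
}

#' Full kinase inventory for one genome
#'
#' Runs detection, orphan assignment and PAS flagging in one call.
#'
#' @param ann the genome annotation.
#' @param window orphan co-location window in ORFs.
#' @return kinase record data.frame with all flags set.
#' @export
kinaseInventory <- function(ann, window = 4L) {
  k <- findHistidineKinases(ann)
  k <- assignOrphanStatus(ann, k, window = window)
  flagNtermPas(ann, k)
}
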