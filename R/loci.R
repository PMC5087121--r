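#' Match a peak against the known-insertion database
#'
#' Returns database records of the same family group whose position lies
#' within `[start - margin, end + margin)` of the peak. The margin absorbs
#' the offset between an amplicon footprint boundary and the catalogued
#' insertion coordinate (1-2 kb in practice).
#'
#' @param peak one-row peak/locus data.frame (chrom, start, end, family).
#' @param db known-insertion database (chrom, start, family, source, id).
#' @param margin_bp matching margin in bp (typical range 1000-2000).
#' @param collapse_alu match AluYa/AluYb records interchangeably.
#' @return the matching database rows.
#' @export
match_known <- function(peak, db, margin_bp = 1000, collapse_alu = TRUE) {
  stop_if_not(nrow(peak) == 1, "match_known takes a single peak")
  fam_ok <- if (collapse_alu) family_group(db$family) ==
               family_group(peak$family) else db$family == peak$family
  hit <- fam_ok & db$chrom == peak$chrom &
    db$start >= peak$start - margin_bp & db$start < peak$end + margin_bp
  db[hit, , drop = FALSE]
}

#' Merge retained peaks across the panel into insertion loci
#'
#' Same-family-group peaks whose margin-expanded intervals overlap are merged
#' transitively into one locus; each locus records which cell lines
#' contributed a peak (the presence vector) and spans the union of its
#' member peak intervals (unexpanded).
#'
#' @param peaks retained peaks across the panel (need cell_line and family).
#' @param merge_margin_bp expansion applied to each peak before overlap (bp).
#' @param cell_lines panel cell-line labels (columns of the presence
#'   matrix); defaults to the lines observed among the peaks.
#' @param collapse_alu merge AluYa/AluYb peaks into a common Alu locus space.
#' @return list with `loci` (data.frame: locus_id, chrom, start, end, family,
#'   n_lines) and `presence` (loci x lines 0/1 matrix).
#' @export
build_loci <- function(peaks, merge_margin_bp = 1000, cell_lines = NULL,
                       collapse_alu = TRUE) {
  stop_if_not(nrow(peaks) > 0, "no peaks to merge")
  if (is.null(cell_lines)) cell_lines <- sort(unique(peaks$cell_line))
  grp <- if (collapse_alu) family_group(peaks$family) else peaks$family
  out_loci <- list(); out_pres <- list()
  for (g in unique(grp)) {
    p <- peaks[grp == g, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = p$chrom,
      ranges = IRanges::IRanges(start = pmax(0L, p$start - merge_margin_bp) + 1L,
                                end = p$end + merge_margin_bp))
    red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
    groups <- S4Vectors::mcols(red)$revmap
    for (i in seq_along(red)) {
      m <- p[groups[[i]], , drop = FALSE]
      pres <- as.integer(cell_lines %in% m$cell_line)
      out_loci[[length(out_loci) + 1L]] <- data.frame(
        chrom = m$chrom[1], start = min(m$start), end = max(m$end),
        family = g, n_lines = sum(pres), n_peaks = nrow(m),
        stringsAsFactors = FALSE)
      out_pres[[length(out_pres) + 1L]] <- pres
    }
  }
  loci <- do.call(rbind, out_loci)
  ord <- order(loci$family, loci$chrom, loci$start)
  loci <- loci[ord, , drop = FALSE]
  presence <- do.call(rbind, out_pres)[ord, , drop = FALSE]
  loci$locus_id <- sprintf("LOC_%s_%04d", loci$family,
                           stats::ave(seq_len(nrow(loci)), loci$family,
                                      FUN = seq_along))
  rownames(loci) <- NULL
  dimnames(presence) <- list(loci$locus_id, cell_lines)
  loci <- loci[, c("locus_id", "chrom", "start", "end", "family",
                   "n_lines", "n_peaks")]
  list(loci = loci, presence = presence)
}

#' Classify loci into the three-category scheme
#'
#' reference: matched a reference-genome record; known_polymorphic: matched a
#' catalogued polymorphic record; novel_polymorphic: no database match but
#' present in two or more cell lines; singleton: no match, one line.
#' Database membership takes precedence over presence counts; a reference
#' locus that also matches the polymorphic catalogue additionally carries a
#' `ref_and_poly` flag (counted in both groups in panel reporting).
#'
#' @param loci,presence output of [build_loci()].
#' @param db known-insertion database.
#' @param margin_bp matching margin (bp).
#' @return `loci` with added columns category, ref_and_poly, matched_db_ids.
#' @export
classify_loci <- function(loci, presence, db, margin_bp = 1000) {
  n <- nrow(loci)
  category <- character(n); rap <- logical(n); ids <- character(n)
  for (i in seq_len(n)) {
    m <- match_known(loci[i, , drop = FALSE], db, margin_bp)
    has_ref <- any(m$source == "reference")
    has_poly <- any(m$source == "known_polymorphic")
    category[i] <- if (has_ref) "reference"
      else if (has_poly) "known_polymorphic"
      else if (sum(presence[loci$locus_id[i], ]) >= 2) "novel_polymorphic"
      else "singleton"
    rap[i] <- has_ref && has_poly
    ids[i] <- paste(m$id, collapse = ",")
  }
  loci$category <- category
  loci$ref_and_poly <- rap
  loci$matched_db_ids <- ids
  loci
}

#' Panel-level summaries of classified loci
#'
#' @param loci classified loci (with category column).
#' @param presence presence matrix from [build_loci()].
#' @return list: `per_line` stacked counts (cell_line, family, category, n),
#'   `frequency` per-family table of loci by carrier count, and
#'   `singleton_fraction` per family among non-reference loci.
#' @export
summarize_panel <- function(loci, presence) {
  lines <- colnames(presence)
  per_line <- expand.grid(cell_line = lines, family = unique(loci$family),
                          category = unique(loci$category),
                          stringsAsFactors = FALSE)
  per_line$n <- mapply(function(cl, fam, cat) {
    sel <- loci$family == fam & loci$category == cat
    sum(presence[sel, cl, drop = FALSE])
  }, per_line$cell_line, per_line$family, per_line$category)

  frequency <- do.call(rbind, lapply(unique(loci$family), function(fam) {
    k <- rowSums(presence[loci$family == fam, , drop = FALSE])
    data.frame(family = fam, n_lines = as.integer(names(table(k))),
               n_loci = as.integer(table(k)), stringsAsFactors = FALSE)
  }))

  singleton_fraction <- vapply(unique(loci$family), function(fam) {
    nonref <- loci$family == fam & loci$category != "reference"
    if (!any(nonref)) return(0)
    mean(loci$category[nonref] == "singleton")
  }, numeric(1))

  list(per_line = per_line, frequency = frequency,
       singleton_fraction = singleton_fraction)
}

#' Gene-context annotation of loci
#'
#' Labels each locus by the containment of its midpoint: 3'UTR exon, coding
#' exon, intron, or intergenic-within-flank; loci outside all tiled regions
#' are labelled "untiled". A partial-overlap flag marks loci whose interval
#' straddles an exon boundary (typical of insertions near, not in, exons).
#'
#' @param loci classified loci.
#' @param genome genome layout (genes, exons, utr3, tiled) as produced by
#'   [simulate_panel()], or any list with those data.frames.
#' @return `loci` with added columns gene_id, context, partial_exon_overlap.
#' @export
exon_overlap_report <- function(loci, genome) {
  mid <- (loci$start + loci$end) %/% 2L
  mid_gr <- GenomicRanges::GRanges(loci$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  in_set <- function(df) {
    h <- GenomicRanges::findOverlaps(mid_gr, df_to_granges(df))
    out <- rep(NA_integer_, nrow(loci))
    out[S4Vectors::queryHits(h)] <- S4Vectors::subjectHits(h)
    out
  }
  i_utr <- in_set(genome$utr3)
  i_ex <- in_set(genome$exons)
  i_gene <- in_set(genome$genes)
  i_tile <- in_set(genome$tiled)

  context <- ifelse(!is.na(i_utr), "exonic_3utr",
             ifelse(!is.na(i_ex), "exonic_cds",
             ifelse(!is.na(i_gene), "intronic",
             ifelse(!is.na(i_tile), "intergenic_flank", "untiled"))))
  gene_id <- ifelse(!is.na(i_gene), genome$genes$gene_id[i_gene],
                    ifelse(!is.na(i_tile), genome$tiled$gene_id[i_tile],
                           NA_character_))
  if (any(context == "untiled"))
    message(sum(context == "untiled"), " locus/loci outside tiled regions")

  # partial overlap: the locus interval intersects an exon without being
  # contained in it
  loc_gr <- df_to_granges(loci)
  ex_gr <- df_to_granges(genome$exons)
  h <- GenomicRanges::findOverlaps(loc_gr, ex_gr)
  partial <- logical(nrow(loci))
  if (length(h)) {
    q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
    contained <- loci$start[q] >= genome$exons$start[s] &
      loci$end[q] <= genome$exons$end[s]
    partial[unique(q[!contained])] <- TRUE
  }
  loci$gene_id <- gene_id
  loci$context <- context
  loci$partial_exon_overlap <- partial
  loci
}

#' Flag candidate genomic deletions
#'
#' A reference insertion absent from only a few lines of an otherwise fixed
#' locus is more parsimoniously a genomic deletion in those lines than a
#' missing insertion; this lists reference loci absent in 1..`max_absent`
#' lines together with the lines lacking them.
#'
#' @param loci classified loci.
#' @param presence presence matrix.
#' @param max_absent maximum number of absent lines to flag (default 1).
#' @return data.frame (locus_id, n_absent, absent_lines).
#' @export
deletion_flag <- function(loci, presence, max_absent = 1L) {
  ref <- loci$locus_id[loci$category == "reference"]
  rows <- lapply(ref, function(id) {
    absent <- colnames(presence)[presence[id, ] == 0]
    if (length(absent) >= 1 && length(absent) <= max_absent)
      data.frame(locus_id = id, n_absent = length(absent),
                 absent_lines = paste(absent, collapse = ","),
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_id = character(0), n_absent = integer(0),
                      absent_lines = character(0), stringsAsFactors = FALSE)
  out
}
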