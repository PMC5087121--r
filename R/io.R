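## Plain-text readers/writers. All coordinates are 0-based half-open (BED
## convention); tables are tab-separated with a header unless the BED
## convention forbids one.

#' Write / read a probe track as 5-column BED-like TSV
#'
#' Columns: chrom, start, end, intensity, masked (0/1). No header.
#' @param track a [probe_track()].
#' @param path file path.
#' @export
write_probe_track <- function(track, path) {
  df <- as.data.frame(track)
  df$masked <- as.integer(df$masked)
  write.table(df[, c("chrom", "start", "end", "intensity", "masked")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_track
#' @param cell_line,family track labels to attach on read.
#' @export
read_probe_track <- function(path, cell_line = NA_character_,
                             family = NA_character_) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "intensity",
                                 "masked"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric", "integer"))
  df$masked <- df$masked != 0
  probe_track(df, cell_line = cell_line, family = family)
}

#' Write peak calls as BED6+
#'
#' chrom, start, end, peak_id, rank_threshold, strand ("."), n_probes,
#' max_intensity, cell_line, family.
#' @param peaks peak calls.
#' @param path file path.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    peaks$rank_threshold, ".", peaks$n_probes,
                    peaks$max_intensity, peaks$cell_line, peaks$family)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "peak_id",
                                 "rank_threshold", "strand", "n_probes",
                                 "max_intensity", "cell_line", "family"))
  df$strand <- NULL
  df
}

#' Write / read a known-insertion database as BED with family and source
#'
#' chrom, start, end, id, family, source.
#' @param db database data.frame.
#' @param path file path.
#' @export
write_known_db <- function(db, path) {
  write.table(db[, c("chrom", "start", "end", "id", "family", "source")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_known_db
#' @export
read_known_db <- function(path) {
  read.delim(path, header = FALSE,
             col.names = c("chrom", "start", "end", "id", "family",
                           "source"),
             colClasses = c("character", "integer", "integer", "character",
                            "character", "character"))
}

#' Write classified loci as BED9+ and the presence matrix as TSV
#'
#' Loci: chrom, start, end, locus_id, n_lines, strand ("."), family,
#' category, ref_and_poly, presence vector (comma-separated 0/1).
#' Presence: loci x lines 0/1 matrix with header and rownames.
#' @param loci classified loci.
#' @param presence presence matrix.
#' @param path file path.
#' @export
write_loci_bed <- function(loci, presence, path) {
  pv <- apply(presence[loci$locus_id, , drop = FALSE], 1,
              paste, collapse = ",")
  out <- data.frame(loci$chrom, loci$start, loci$end, loci$locus_id,
                    loci$n_lines, ".", loci$family, loci$category,
                    as.integer(loci$ref_and_poly), unname(pv))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_loci_bed
#' @export
write_presence_matrix <- function(presence, path) {
  df <- data.frame(locus_id = rownames(presence), presence,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_loci_bed
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$locus_id
  storage.mode(m) <- "integer"
  m
}

#' Write / read a phenotype matrix (features x lines TSV with anchors)
#'
#' First columns: feature_id, anchor_chrom, anchor_pos (empty when
#' unanchored); remaining columns one per cell line.
#' @param phenotypes a `phenotype_matrix`.
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- data.frame(feature_id = rownames(phenotypes$values),
                   anchor_chrom = phenotypes$anchors$chrom,
                   anchor_pos = phenotypes$anchors$pos,
                   phenotypes$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  values <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(values) <- df$feature_id
  anchors <- data.frame(feature_id = df$feature_id,
                        chrom = as.character(df$anchor_chrom),
                        pos = df$anchor_pos, stringsAsFactors = FALSE)
  out <- list(values = values, anchors = anchors, effects = NULL)
  class(out) <- "phenotype_matrix"
  out
}

#' Write planted truth as BED plus a JSON sidecar
#'
#' BED: chrom, pos, pos+1, locus_id, family, strand, category. JSON sidecar:
#' presence matrix, footprints and cell-line labels.
#' @param truth planted truth from [simulate_panel()].
#' @param bed_path,json_path output paths.
#' @export
write_truth <- function(truth, bed_path, json_path) {
  ins <- truth$insertions
  out <- data.frame(ins$chrom, ins$pos, ins$pos + 1L, ins$locus_id,
                    ins$family, ins$strand, ins$category)
  write.table(out, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  side <- list(cell_lines = truth$cell_lines,
               presence = as.data.frame(truth$presence),
               footprints = truth$footprints)
  jsonlite::write_json(side, json_path, dataframe = "rows", digits = NA)
  invisible(bed_path)
}

#' Read gene sets
#'
#' Either a plain-text file with one gene per line (one set, named from the
#' file) or a two-column (set, gene) TSV.
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    df <- read.delim(path, header = FALSE,
                     col.names = c("set", "gene"),
                     colClasses = c("character", "character"))
    split(df$gene, df$set)
  } else {
    stats::setNames(list(readLines(path)),
                    sub("\\.[^.]*$", "", basename(path)))
  }
}
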