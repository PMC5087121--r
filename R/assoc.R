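#' Point-biserial correlation with t-distribution p-value
#'
#' Pearson correlation of a 0/1 carrier indicator with a continuous profile
#' (the pattern-matching statistic specialised to a binary seed), with the
#' usual two-sided p from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees
#' of freedom. Missing values are dropped pairwise.
#'
#' @param presence 0/1 (or logical) carrier vector.
#' @param values numeric profile, same length.
#' @return list(r, p_raw, n_used, reason): `reason` is NA for an estimable
#'   test, otherwise a code ("too_few_obs", "single_group",
#'   "constant_values") and r/p are NA.
#' @export
point_biserial <- function(presence, values) {
  stop_if_not(length(presence) == length(values),
              "presence and values must have equal length")
  ok <- !is.na(presence) & !is.na(values)
  x <- as.numeric(presence[ok]); y <- values[ok]
  n <- length(x)
  bad <- function(code) list(r = NA_real_, p_raw = NA_real_, n_used = n,
                             reason = code)
  if (n < 3) return(bad("too_few_obs"))
  if (length(unique(x)) < 2) return(bad("single_group"))
  if (length(unique(y)) < 2) return(bad("constant_values"))
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin  # perfect separation; p in (0, 1] by contract
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- min(1, max(p, .Machine$double.xmin))
  }
  list(r = r, p_raw = p, n_used = n, reason = NA_character_)
}

#' Bonferroni correction
#'
#' @param p_raw raw p-value(s).
#' @param m family size (number of tests performed).
#' @return min(1, p_raw * m).
#' @export
bonferroni <- function(p_raw, m) {
  stop_if_not(m >= 1, "Bonferroni family size must be >= 1")
  pmin(1, p_raw * m)
}

#' Cis/trans classification of a locus-feature pair
#'
#' A feature is in cis with a locus when its genomic anchor lies on the same
#' chromosome within `window_bp` of the locus interval; unanchored features
#' are always trans.
#'
#' @param locus one-row locus data.frame (chrom, start, end).
#' @param anchor_chrom,anchor_pos feature anchor (NA = unanchored).
#' @param window_bp cis window (default 30 kb).
#' @return list(cis, distance_bp); distance is NA when unanchored or on a
#'   different chromosome.
#' @export
classify_cis_trans <- function(locus, anchor_chrom, anchor_pos,
                               window_bp = 30000) {
  if (is.na(anchor_chrom) || is.na(anchor_pos) ||
      anchor_chrom != locus$chrom)
    return(list(cis = FALSE, distance_bp = NA_integer_))
  d <- point_interval_distance(anchor_pos, locus$start, locus$end)
  list(cis = d <= window_bp, distance_bp = as.integer(d))
}

#' Pattern-matching association of insertion loci with phenotype profiles
#'
#' Each locus's presence vector is correlated with each phenotype feature.
#' Singleton loci are tested only against features anchored in cis (their
#' trans associations are dominated by false positives); all other loci are
#' tested against every feature, subject to a minimum carrier count.
#' The Bonferroni family is the number of tests actually performed in the
#' run. Not-estimable pairs are excluded and tallied by reason code in the
#' `skipped` attribute.
#'
#' @param presence loci x lines 0/1 matrix ([build_loci()]).
#' @param phenotypes a `phenotype_matrix` (values, anchors) or a bare
#'   features x lines matrix.
#' @param loci classified loci (category and coordinates).
#' @param window_bp cis window (default 30 kb).
#' @param min_minor_count minimum carrier count for non-singleton loci
#'   (default 2; guards degenerate groups).
#' @return data.frame of association results (locus_id, feature_id, r,
#'   p_raw, p_bonf, n_lines_used, cis, distance_bp), sorted by locus
#'   genomic position.
#' @export
run_compare <- function(presence, phenotypes, loci, window_bp = 30000,
                        min_minor_count = 2L) {
  if (inherits(phenotypes, "phenotype_matrix")) {
    values <- phenotypes$values
    anchors <- phenotypes$anchors
  } else {
    values <- phenotypes
    anchors <- data.frame(feature_id = rownames(values),
                          chrom = NA_character_, pos = NA_integer_,
                          stringsAsFactors = FALSE)
  }
  miss <- setdiff(colnames(presence), colnames(values))
  extra <- setdiff(colnames(values), colnames(presence))
  stop_if_not(length(miss) == 0 && length(extra) == 0,
              "cell-line label mismatch: missing [%s], unexpected [%s]",
              paste(miss, collapse = ","), paste(extra, collapse = ","))
  values <- values[, colnames(presence), drop = FALSE]
  rownames(anchors) <- anchors$feature_id

  singleton <- setNames(loci$category == "singleton", loci$locus_id)
  rows <- list()
  skipped <- character(0)
  for (li in seq_len(nrow(loci))) {
    id <- loci$locus_id[li]
    pres <- presence[id, ]
    is_singleton <- singleton[[id]]
    if (!is_singleton && sum(pres) < min_minor_count) {
      skipped <- c(skipped, "below_min_minor_count")
      next
    }
    locus <- loci[li, , drop = FALSE]
    for (fi in seq_len(nrow(values))) {
      fid <- rownames(values)[fi]
      ct <- classify_cis_trans(locus, anchors[fid, "chrom"],
                               anchors[fid, "pos"], window_bp)
      if (is_singleton && !ct$cis) next
      pb <- point_biserial(pres, values[fi, ])
      if (!is.na(pb$reason)) {
        skipped <- c(skipped, pb$reason)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = id, feature_id = fid, r = pb$r, p_raw = pb$p_raw,
        n_lines_used = pb$n_used, cis = ct$cis,
        distance_bp = if (is.null(ct$distance_bp)) NA_integer_
                      else ct$distance_bp,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(locus_id = character(0), feature_id = character(0),
                    r = numeric(0), p_raw = numeric(0),
                    n_lines_used = integer(0), cis = logical(0),
                    distance_bp = integer(0), stringsAsFactors = FALSE)
  m <- nrow(out)
  out$p_bonf <- if (m) bonferroni(out$p_raw, m) else numeric(0)
  pos <- loci$start[match(out$locus_id, loci$locus_id)]
  chr <- loci$chrom[match(out$locus_id, loci$locus_id)]
  out <- out[order(chr, pos, out$feature_id),
             c("locus_id", "feature_id", "r", "p_raw", "p_bonf",
               "n_lines_used", "cis", "distance_bp"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "skipped") <- table(skipped)
  out
}

#' Export association results in Manhattan-plot form
#'
#' One row per association, placed at the start coordinate of its locus,
#' ordered by genome position (all features of one locus stack vertically
#' at one x position).
#'
#' @param results association results from [run_compare()].
#' @param loci classified loci with coordinates.
#' @return data.frame (chrom, start, neg_log10_p_bonf, locus_id, feature_id,
#'   cis).
#' @export
manhattan_export <- function(results, loci) {
  idx <- match(results$locus_id, loci$locus_id)
  out <- data.frame(chrom = loci$chrom[idx], start = loci$start[idx],
                    neg_log10_p_bonf = -log10(results$p_bonf),
                    locus_id = results$locus_id,
                    feature_id = results$feature_id,
                    cis = results$cis, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
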