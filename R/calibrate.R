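#' Reference-insertion recovery curve
#'
#' For a ranked peak list, point i is the number of distinct reference
#' insertions matched (same family group, within `margin_bp`) by peaks 1..i.
#' Recovery of reference-genome insertions is the per-array quality metric
#' used to place the peak cutoff.
#'
#' @param peaks ranked peak calls (one track), best rank first.
#' @param ref_db known-insertion database; only `source == "reference"`
#'   records are used.
#' @param margin_bp matching margin around the peak interval (bp).
#' @return a `recovery_curve`: data.frame (rank_index,
#'   cumulative_reference_hits) with family/cell_line attributes.
#' @export
recovery_curve <- function(peaks, ref_db, margin_bp = 1000) {
  ref <- ref_db[ref_db$source == "reference", , drop = FALSE]
  n <- nrow(peaks)
  cum <- integer(n)
  if (n > 0) {
    seen <- character(0)
    for (i in seq_len(n)) {
      m <- match_known(peaks[i, , drop = FALSE], ref, margin_bp)
      seen <- union(seen, m$id)
      cum[i] <- length(seen)
    }
  }
  structure(data.frame(rank_index = seq_len(n),
                       cumulative_reference_hits = cum),
            family = if (n) peaks$family[1] else NA_character_,
            cell_line = if (n) peaks$cell_line[1] else NA_character_,
            class = c("recovery_curve", "data.frame"))
}

#' Locate the inflection (knee) of a recovery curve
#'
#' Default method: the index maximizing the perpendicular distance *above*
#' the chord joining the first and last curve points (recovery curves are
#' concave: they rise while true peaks recover references, then flatten);
#' ties break to the smallest index. A discrete second-difference
#' alternative is available. A perfectly linear or constant curve — or one
#' lying entirely below its chord — has no knee and raises a
#' degenerate-curve error, on which callers fall back to the fixed
#' percentile cutoffs.
#'
#' @param curve a [recovery_curve()] (or data.frame with the same columns).
#' @param method "chord" (default) or "second_diff".
#' @return integer rank index of the knee.
#' @export
find_inflection <- function(curve, method = c("chord", "second_diff")) {
  method <- match.arg(method)
  x <- curve$rank_index
  y <- curve$cumulative_reference_hits
  stop_if_not(length(x) >= 3, "curve must have at least 3 points")
  if (method == "chord") {
    dx <- x[length(x)] - x[1]
    dy <- y[length(y)] - y[1]
    # signed elevation above the chord
    d <- ((y - y[1]) * dx - (x - x[1]) * dy) / sqrt(dx^2 + dy^2)
    scale <- max(1, abs(dy), dx)
    if (max(d) <= 1e-9 * scale)
      stop("degenerate recovery curve: no inflection point", call. = FALSE)
    which.max(d)
  } else {
    d2 <- diff(diff(y))
    if (all(abs(d2) <= 1e-12))
      stop("degenerate recovery curve: no inflection point", call. = FALSE)
    which.min(d2) + 1L
  }
}

#' Cutoff decision for a ranked peak list
#'
#' @param method "knee" (rank index from the recovery-curve inflection) or
#'   "fixed" (family default percentile threshold: peaks kept when their
#'   rank threshold is strictly above 70 for L1 and 60 for Alu).
#' @param rank_cutoff rank index (required for method = "knee").
#' @param threshold_cutoff percentile threshold recorded for reporting.
#' @param family family (sets the fixed default).
#' @return a `cutoff_decision` list.
#' @export
cutoff_decision <- function(method = c("knee", "fixed"), rank_cutoff = NA,
                            threshold_cutoff = NA, family = "L1") {
  method <- match.arg(method)
  if (method == "knee")
    stop_if_not(is.finite(rank_cutoff) && rank_cutoff >= 1,
                "knee cutoff needs a rank_cutoff >= 1")
  if (method == "fixed" && !is.finite(threshold_cutoff))
    threshold_cutoff <- if (family_group(family) == "L1") 70 else 60
  structure(list(method = method, rank_cutoff = rank_cutoff,
                 threshold_cutoff = threshold_cutoff, family = family),
            class = "cutoff_decision")
}

#' Apply a cutoff decision to a ranked peak list
#'
#' Knee cutoffs keep the leading ranks (a prefix of the ranked list); fixed
#' cutoffs keep peaks whose rank threshold is strictly above the family
#' default percentile.
#'
#' @param peaks ranked peak calls.
#' @param decision a [cutoff_decision()].
#' @return the retained peaks.
#' @export
apply_cutoff <- function(peaks, decision) {
  stopifnot(inherits(decision, "cutoff_decision"))
  if (decision$method == "knee") {
    head(peaks, min(nrow(peaks), decision$rank_cutoff))
  } else {
    peaks[peaks$rank_threshold > decision$threshold_cutoff, , drop = FALSE]
  }
}

#' Calibrate and filter one track's peaks against the reference set
#'
#' Builds the recovery curve, attempts knee detection, and falls back to the
#' fixed family cutoff when the curve is degenerate (e.g. when essentially
#' every called peak recovers reference insertions and the curve never
#' flattens).
#'
#' @param peaks ranked peak calls for one (cell line, family) track.
#' @param ref_db known-insertion database.
#' @param margin_bp matching margin (bp).
#' @param method "knee" with fixed fallback (default) or "fixed".
#' @return list: `retained` peaks, `decision`, `curve`, and a one-row
#'   `report` data.frame.
#' @export
calibrate_peaks <- function(peaks, ref_db, margin_bp = 1000,
                            method = c("knee", "fixed")) {
  method <- match.arg(method)
  fam <- if (nrow(peaks)) peaks$family[1] else "L1"
  curve <- recovery_curve(peaks, ref_db, margin_bp)
  decision <- NULL
  if (method == "knee" && nrow(curve) >= 3) {
    knee <- tryCatch(find_inflection(curve), error = function(e) NULL)
    # Accept the knee only where the curve genuinely flattens: reference
    # recovery after the knee at less than half the pre-knee rate, AND a
    # post-knee reference drought too long to arise from random
    # interleaving of reference hits among true peaks (hypergeometric tail
    # at 0.01). A still-rising or short-tailed curve means the ranked list
    # never ran into a noise floor and carries no usable inflection.
    if (!is.null(knee) && knee > 1 && knee < nrow(curve)) {
      y <- curve$cumulative_reference_hits
      n <- nrow(curve)
      slope_before <- (y[knee] - y[1]) / (knee - 1)
      slope_after <- (y[n] - y[knee]) / (n - knee)
      flattens <- slope_before > 0 && slope_after < 0.5 * slope_before
      # first-hit ranks of the y[n] recovered references, treated as draws
      # without replacement among the n ranks
      p_tail <- phyper(y[n] - y[knee], y[n], n - y[n], n - knee)
      if (!(flattens && p_tail < 0.01)) knee <- NULL
    }
    if (!is.null(knee))
      decision <- cutoff_decision("knee", rank_cutoff = knee,
                                  threshold_cutoff =
                                    peaks$rank_threshold[knee],
                                  family = fam)
  }
  if (is.null(decision)) decision <- cutoff_decision("fixed", family = fam)
  retained <- apply_cutoff(peaks, decision)
  report <- data.frame(
    cell_line = if (nrow(peaks)) peaks$cell_line[1] else NA_character_,
    family = fam, method = decision$method,
    rank_cutoff = if (decision$method == "knee") decision$rank_cutoff
                  else nrow(retained),
    threshold_cutoff = decision$threshold_cutoff,
    n_peaks = nrow(peaks), n_retained = nrow(retained),
    reference_recovered = if (nrow(curve)) max(curve$cumulative_reference_hits)
                          else 0L,
    stringsAsFactors = FALSE)
  list(retained = retained, decision = decision, curve = curve,
       report = report)
}
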