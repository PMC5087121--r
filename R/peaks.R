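#' Construct a probe track
#'
#' A probe track is the raw substrate of peak calling: ordered genomic probes
#' (0-based half-open intervals) with a log2 intensity ratio and a
#' repeat-mask flag, for one array channel of one cell line.
#'
#' @param df data.frame with columns chrom, start, end, intensity and
#'   (optionally) masked.
#' @param cell_line,family track labels; family one of L1, AluYa, AluYb.
#' @return a `probe_track` (data.frame with attributes).
#' @export
probe_track <- function(df, cell_line = NA_character_,
                        family = NA_character_) {
  need <- c("chrom", "start", "end", "intensity")
  stop_if_not(all(need %in% names(df)),
              "probe track needs columns %s", paste(need, collapse = ", "))
  if (is.null(df$masked)) df$masked <- FALSE
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  stop_if_not(all(df$start < df$end), "probe start must be < end")
  stop_if_not(!anyDuplicated(df[, c("chrom", "start")]),
              "duplicate (chrom, start) probes")
  structure(df, cell_line = cell_line, family = family,
            class = c("probe_track", "data.frame"))
}

#' Peak-calling parameters
#'
#' Defaults follow the descending-threshold sliding-window settings used for
#' TIP-chip arrays: thresholds at the 90th down to the 14th percentile in
#' steps of 1 (76 steps), a 1500 bp window constraining the gap between
#' consecutive supporting probes, at least 4 probes above the percentile
#' threshold, every probe in the run above an absolute log2-ratio floor of 2,
#' and the top 5000 peaks kept.
#'
#' @param p_start,p_step,n_steps percentile grid: p_start, p_start - p_step,
#'   ..., down to p_start - p_step * n_steps.
#' @param window_bp maximum start-to-start distance between consecutive
#'   supporting probes of one peak.
#' @param min_probes_above minimum number of probes exceeding the percentile
#'   threshold.
#' @param floor_value absolute log2-ratio floor every run probe must exceed.
#' @param max_peaks truncation of the ranked output.
#' @return a `peak_params` list.
#' @export
peak_params <- function(p_start = 90, p_step = 1, n_steps = 76,
                        window_bp = 1500, min_probes_above = 4,
                        floor_value = 2, max_peaks = 5000) {
  stop_if_not(p_start - p_step * n_steps >= 0,
              "percentile grid must stay non-negative")
  stop_if_not(window_bp > 0, "window_bp must be > 0")
  stop_if_not(min_probes_above >= 1, "min_probes_above must be >= 1")
  structure(list(p_start = p_start, p_step = p_step, n_steps = n_steps,
                 window_bp = window_bp, min_probes_above = min_probes_above,
                 floor_value = floor_value, max_peaks = max_peaks),
            class = "peak_params")
}

#' Flag probes overlapping repeat intervals as masked
#'
#' Masked probes are excluded from threshold statistics and from peak
#' support (repeat masking reduces cross-hybridization noise).
#'
#' @param track a [probe_track()].
#' @param repeat_intervals data.frame chrom/start/end (0-based half-open);
#'   an empty set is the identity transform.
#' @return the track with its `masked` flag updated.
#' @export
mask_probes <- function(track, repeat_intervals) {
  if (is.null(repeat_intervals) || nrow(repeat_intervals) == 0) return(track)
  hits <- GenomicRanges::findOverlaps(df_to_granges(track),
                                      df_to_granges(repeat_intervals))
  track$masked[unique(S4Vectors::queryHits(hits))] <- TRUE
  track
}

## maximal runs of unmasked, above-floor probes whose consecutive starts are
## within window_bp on the same chromosome; returns a list of integer index
## vectors into the track
floor_runs <- function(track, params) {
  ok <- which(!track$masked & track$intensity > params$floor_value)
  if (!length(ok)) return(list())
  brk <- c(TRUE, track$chrom[ok[-1]] != track$chrom[ok[-length(ok)]] |
             (track$start[ok[-1]] - track$start[ok[-length(ok)]]) >
             params$window_bp)
  unname(split(ok, cumsum(brk)))
}

#' Call ranked candidate-insertion peaks on one probe track
#'
#' Thresholds are taken at descending percentiles of the unmasked intensity
#' distribution of the track. A candidate peak at level p is a maximal run
#' of unmasked probes, each above `floor_value`, with consecutive probes
#' within `window_bp`, of which at least `min_probes_above` exceed the
#' percentile threshold T(p). Each genomic peak is reported once, ranked by
#' the highest percentile at which it was detected; detections at lower
#' levels that overlap an existing call are merged into it. Output is sorted
#' by descending rank threshold, then descending maximum intensity, then
#' genomic position, and truncated to `max_peaks`.
#'
#' @param track a [probe_track()].
#' @param params a [peak_params()].
#' @return data.frame of peak calls (chrom, start, end, peak_id,
#'   rank_threshold, n_probes, max_intensity, cell_line, family).
#' @export
call_peaks <- function(track, params = peak_params()) {
  stopifnot(inherits(track, "probe_track"))
  unmasked <- track$intensity[!track$masked]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_id = character(0),
                      rank_threshold = numeric(0), n_probes = integer(0),
                      max_intensity = numeric(0), cell_line = character(0),
                      family = character(0), stringsAsFactors = FALSE)
  if (length(unmasked) < params$min_probes_above) {
    warning("fewer than min_probes_above unmasked probes; no peaks called")
    return(empty)
  }
  p_levels <- params$p_start - params$p_step * (0:params$n_steps)
  thr <- quantile(unmasked, p_levels / 100, names = FALSE, type = 7)

  runs <- floor_runs(track, params)
  if (!length(runs)) return(empty)

  # a run qualifies at level p iff its min_probes_above-th largest intensity
  # exceeds T(p); T is non-increasing along the descending grid, so the rank
  # is the first (highest) level whose threshold it beats
  calls <- lapply(runs, function(idx) {
    if (length(idx) < params$min_probes_above) return(NULL)
    v <- sort(track$intensity[idx], decreasing = TRUE)[params$min_probes_above]
    hit <- which(thr < v)
    if (!length(hit)) return(NULL)
    data.frame(chrom = track$chrom[idx[1]],
               start = min(track$start[idx]),
               end = max(track$end[idx]),
               rank_threshold = p_levels[hit[1]],
               n_probes = length(idx),
               max_intensity = max(track$intensity[idx]),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  ord <- order(-calls$rank_threshold, -calls$max_intensity,
               calls$chrom, calls$start)
  calls <- calls[ord, , drop = FALSE]
  calls <- head(calls, params$max_peaks)
  calls$peak_id <- sprintf("peak_%04d", seq_len(nrow(calls)))
  calls$cell_line <- attr(track, "cell_line")
  calls$family <- attr(track, "family")
  rownames(calls) <- NULL
  calls[, c("chrom", "start", "end", "peak_id", "rank_threshold",
            "n_probes", "max_intensity", "cell_line", "family")]
}

#' Merge overlapping peak calls across threshold levels
#'
#' Deduplicates calls from one track: overlapping peaks collapse to one call
#' spanning their union, keeping the maximum rank threshold (the level of
#' first detection), the maximum probe support and the maximum intensity.
#'
#' @param calls data.frame of peak calls from a single track.
#' @return deduplicated, re-ranked data.frame; no two output peaks overlap.
#' @export
peak_overlap_merge <- function(calls) {
  if (nrow(calls) <= 1) return(calls)
  gr <- df_to_granges(calls)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  groups <- S4Vectors::mcols(red)$revmap
  out <- lapply(seq_along(red), function(i) {
    m <- calls[groups[[i]], , drop = FALSE]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               rank_threshold = max(m$rank_threshold),
               n_probes = max(m$n_probes),
               max_intensity = max(m$max_intensity),
               cell_line = m$cell_line[1], family = m$family[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  ord <- order(-out$rank_threshold, -out$max_intensity, out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  out$peak_id <- sprintf("peak_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "peak_id", "rank_threshold",
          "n_probes", "max_intensity", "cell_line", "family")]
}

#' Two-channel log2 ratio for a family channel
#'
#' Alu channels are labelled red and L1 green; calling Alu peaks uses
#' log2(red/green) and L1 the reciprocal.
#'
#' @param red,green channel intensities (linear scale, positive).
#' @param family family being called.
#' @return signed log2 ratio vector.
#' @export
channel_log2ratio <- function(red, green, family) {
  if (family_group(family[1]) == "Alu") log2(red / green)
  else log2(green / red)
}
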