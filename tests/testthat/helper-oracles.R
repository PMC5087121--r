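# Independent oracles and fixture builders. Oracles deliberately use naive
# enumeration / explicit loops so they share no code path with the package.

# Brute-force peak caller: iterates every threshold level explicitly,
# enumerates candidate probe runs at that level, and merges lower-level
# detections into overlapping existing calls (coordinates extended, rank of
# first detection kept).
oracle_call_peaks <- function(track, params) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), rank_threshold = numeric(0),
                      n_probes = integer(0), max_intensity = numeric(0),
                      stringsAsFactors = FALSE)
  unmasked_int <- track$intensity[!track$masked]
  if (length(unmasked_int) < params$min_probes_above) return(empty)
  p_levels <- params$p_start - params$p_step * (0:params$n_steps)
  calls <- list()
  for (p in p_levels) {
    thr <- unname(quantile(unmasked_int, p / 100, type = 7))
    idx <- which(!track$masked & track$intensity > params$floor_value)
    runs <- list()
    cur <- integer(0)
    for (i in idx) {
      if (length(cur)) {
        last <- cur[length(cur)]
        if (track$chrom[i] != track$chrom[last] ||
            track$start[i] - track$start[last] > params$window_bp) {
          runs[[length(runs) + 1L]] <- cur
          cur <- integer(0)
        }
      }
      cur <- c(cur, i)
    }
    if (length(cur)) runs[[length(runs) + 1L]] <- cur
    for (r in runs) {
      if (sum(track$intensity[r] > thr) < params$min_probes_above) next
      ch <- track$chrom[r[1]]
      s <- min(track$start[r]); e <- max(track$end[r])
      merged <- FALSE
      for (j in seq_along(calls)) {
        cl <- calls[[j]]
        if (cl$chrom == ch && s < cl$end && e > cl$start) {
          calls[[j]]$start <- min(cl$start, s)
          calls[[j]]$end <- max(cl$end, e)
          calls[[j]]$n_probes <- max(cl$n_probes, length(r))
          calls[[j]]$max_intensity <- max(cl$max_intensity,
                                          max(track$intensity[r]))
          merged <- TRUE
          break
        }
      }
      if (!merged)
        calls[[length(calls) + 1L]] <- list(
          chrom = ch, start = s, end = e, rank_threshold = p,
          n_probes = length(r), max_intensity = max(track$intensity[r]))
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, lapply(calls, as.data.frame))
  out <- out[order(-out$rank_threshold, -out$max_intensity,
                   out$chrom, out$start), , drop = FALSE]
  out <- head(out, params$max_peaks)
  rownames(out) <- NULL
  out
}

peak_core_cols <- c("chrom", "start", "end", "rank_threshold", "n_probes",
                    "max_intensity")

# Brute-force knee: maximum signed elevation above the first-last chord
# (recovery curves are concave), computed point by point against the
# straight-line interpolation.
oracle_chord_knee <- function(x, y) {
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- vapply(seq_along(x), function(i) {
    chord_y <- y1 + (y2 - y1) * (x[i] - x1) / (x2 - x1)
    (y[i] - chord_y) * (x2 - x1) / len
  }, numeric(1))
  which.max(d)
}

# Combinatorial upper tail: sum of hypergeometric point masses from k up.
oracle_hyper_tail <- function(k, K, n, N) {
  j <- max(0, k):min(K, n)
  j <- j[j >= k]
  if (!length(j)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Random small probe track with planted clusters, for oracle-equivalence
# checks. Returns the track plus the parameters used.
random_small_track <- function(seed) {
  set.seed(seed)
  n <- sample(8:50, 1)
  gaps <- sample(100:2000, n - 1, replace = TRUE)
  starts <- cumsum(c(1000L, gaps))
  intensity <- rnorm(n, 0, 1)
  n_clusters <- sample(0:2, 1)
  for (k in seq_len(n_clusters)) {
    w <- sample(3:8, 1)
    at <- sample(seq_len(max(1, n - w)), 1)
    intensity[at:(at + w - 1)] <- rnorm(w, sample(4:10, 1), 1)
  }
  masked <- runif(n) < 0.1
  track <- probe_track(data.frame(chrom = "chr1", start = starts,
                                  end = starts + 50L,
                                  intensity = intensity, masked = masked),
                       cell_line = "CL", family = "L1")
  params <- peak_params(p_start = 90, p_step = 1, n_steps = 76,
                        window_bp = sample(c(500, 1500, 3000), 1),
                        min_probes_above = sample(2:4, 1),
                        floor_value = sample(c(0, 1, 2), 1))
  list(track = track, params = params)
}

# Perfect-detection peaks: one peak per (present insertion, line) spanning
# its amplicon footprint; used to test panel logic independently of the
# caller.
truth_to_peaks <- function(truth) {
  ins <- truth$insertions
  fp <- truth$footprints
  rows <- list()
  for (i in seq_len(nrow(ins))) {
    lines <- truth$cell_lines[truth$presence[ins$locus_id[i], ] == 1]
    for (cl in lines) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fp$chrom[i], start = fp$start[i], end = fp$end[i],
        peak_id = paste0(ins$locus_id[i], ".", cl), rank_threshold = 90,
        n_probes = max(1L, (fp$end[i] - fp$start[i]) %/% 250L),
        max_intensity = 10, cell_line = cl, family = ins$family[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Transitive-closure oracle for locus merging: repeated-pass union of
# margin-expanded intervals (same family group, same chromosome).
oracle_merge_groups <- function(peaks, margin) {
  n <- nrow(peaks)
  group <- seq_len(n)
  grp <- family_group(peaks$family)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (grp[i] != grp[j] || peaks$chrom[i] != peaks$chrom[j]) next
        if (peaks$start[i] - margin < peaks$end[j] + margin &&
            peaks$end[i] + margin > peaks$start[j] - margin) {
          g <- min(group[i], group[j])
          if (group[i] != g || group[j] != g) {
            group[group == group[i] | group == group[j]] <- g
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  group
}

# One small simulated panel shared across test files (computed lazily once).
.fixture_env <- new.env(parent = emptyenv())
get_small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 11L, n_cell_lines = 8L, n_genes = 40L,
                      n_reference = 8L, n_known_poly = 5L,
                      n_novel_poly = 5L, n_singleton = 5L)
    .fixture_env$cfg <- cfg
    .fixture_env$sim <- simulate_panel(cfg)
  }
  list(cfg = .fixture_env$cfg, sim = .fixture_env$sim)
}
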