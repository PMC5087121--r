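#' @importFrom stats quantile rnorm runif rbinom rexp cor pt phyper setNames
#' @importFrom utils head read.delim write.table
NULL

TE_FAMILIES <- c("L1", "AluYa", "AluYb")

#' Collapse a probe/insertion family label to its reporting group
#'
#' The assay maps three subfamily channels (L1, AluYa, AluYb); panel-level
#' summaries and known-insertion matching collapse the two Alu channels to a
#' single "Alu" group, mirroring the two-family reporting convention.
#'
#' @param family character vector of family labels.
#' @return character vector of group labels ("L1" or "Alu").
#' @export
family_group <- function(family) {
  ifelse(family %in% c("AluYa", "AluYb", "Alu"), "Alu", "L1")
}

## distance (bp) from a point to a 0-based half-open interval [start, end);
## 0 when the point falls inside the interval.
point_interval_distance <- function(pos, start, end) {
  pmax(0L, start - pos, pos - (end - 1L))
}

## GRanges from a data.frame with chrom/start/end in 0-based half-open
## coordinates (converted to the 1-based closed convention GRanges uses).
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

stop_if_not <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}

## deterministic child seed derived from a base seed and a stream index;
## kept below 2^31 - 1
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483029)
}
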