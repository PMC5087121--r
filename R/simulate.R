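#' Simulation configuration for a synthetic TIP-chip panel
#'
#' Collects every tunable parameter of the synthetic-data generator in one
#' validated object. The generator emulates the statistical structure of a
#' transposon-insertion-profiling experiment: a panel of cell lines sharing
#' fixed (reference), inherited-polymorphic and private (singleton) TE
#' insertions; a tiling array covering gene bodies plus flanks; and per-array
#' probe intensity tracks in which each insertion present in a line produces
#' an amplicon footprint of elevated log2 ratio spanning consecutive probes,
#' bounded by the nearest restriction site.
#'
#' @param seed integer; master seed. Identical configurations (including the
#'   seed) produce byte-identical simulations.
#' @param n_cell_lines number of cell lines in the panel.
#' @param n_genes number of tiled gene loci.
#' @param gene_length_mean_bp,gene_length_sd_bp,gene_length_min_bp gene body
#'   length distribution (truncated normal, bp).
#' @param flank_bp tiled flank added on each side of a gene body (bp).
#' @param probe_spacing_bp centre-to-centre spacing of array probes (bp).
#' @param probe_length_bp probe length (bp).
#' @param enzyme_site_mean_spacing_bp mean spacing of restriction sites per
#'   enzyme (bp); sites are a Poisson process at rate 1/spacing.
#' @param n_enzymes number of parallel restriction digests.
#' @param n_reference,n_known_poly,n_novel_poly,n_singleton insertion counts
#'   per family; either a scalar (applied to each of L1, AluYa, AluYb) or a
#'   named vector over those families.
#' @param allele_freq_range range of allele frequencies for polymorphic
#'   insertions; both ends strictly inside (0, 1).
#' @param known_poly_db_fraction fraction of known-polymorphic insertions
#'   actually recorded in the known-insertion database; unrecorded ones are
#'   relabelled novel-polymorphic (or singleton if carried by one line).
#' @param signal_mean,signal_sd log2-ratio distribution of probes inside an
#'   amplicon footprint.
#' @param baseline_sd log2-ratio standard deviation of background probes
#'   (mean 0).
#' @param masked_probe_fraction fraction of probes flagged as repeat-masked
#'   (panel-wide, i.e. the same probes in every track).
#' @param min_separation_bp minimum clearance between the realized amplicon
#'   footprints of same-reporting-group insertions (L1 vs Alu); placement
#'   rejects candidates closer than this, so planted events are resolvable
#'   at array resolution by construction (keep it above twice the locus
#'   merge margin).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_cell_lines = 20L,
                       n_genes = 200L,
                       gene_length_mean_bp = 20000,
                       gene_length_sd_bp = 8000,
                       gene_length_min_bp = 2000,
                       flank_bp = 10000L,
                       probe_spacing_bp = 250L,
                       probe_length_bp = 50L,
                       enzyme_site_mean_spacing_bp = 2500,
                       n_enzymes = 4L,
                       n_reference = 35L,
                       n_known_poly = 20L,
                       n_novel_poly = 20L,
                       n_singleton = 25L,
                       allele_freq_range = c(0.1, 0.9),
                       known_poly_db_fraction = 1,
                       signal_mean = 8,
                       signal_sd = 1,
                       baseline_sd = 0.3,
                       masked_probe_fraction = 0.02,
                       min_separation_bp = 5000L) {
  expand_counts <- function(x, what) {
    if (length(x) == 1L) x <- setNames(rep(as.integer(x), 3L), TE_FAMILIES)
    stop_if_not(length(x) == 3L && all(TE_FAMILIES %in% names(x)),
                "%s must be a scalar or a named vector over %s",
                what, paste(TE_FAMILIES, collapse = ", "))
    x <- setNames(as.integer(x[TE_FAMILIES]), TE_FAMILIES)
    stop_if_not(all(x >= 0L), "%s must be non-negative", what)
    x
  }
  stop_if_not(probe_spacing_bp > 0, "probe_spacing_bp must be > 0")
  stop_if_not(n_cell_lines >= 1, "n_cell_lines must be >= 1")
  stop_if_not(n_genes >= 1, "n_genes must be >= 1")
  stop_if_not(enzyme_site_mean_spacing_bp > 0, "enzyme spacing must be > 0")
  stop_if_not(length(allele_freq_range) == 2 &&
                allele_freq_range[1] > 0 && allele_freq_range[2] < 1 &&
                allele_freq_range[1] <= allele_freq_range[2],
              "allele_freq_range must lie within (0, 1)")
  stop_if_not(masked_probe_fraction >= 0 && masked_probe_fraction < 1,
              "masked_probe_fraction must be in [0, 1)")
  stop_if_not(known_poly_db_fraction >= 0 && known_poly_db_fraction <= 1,
              "known_poly_db_fraction must be in [0, 1]")
  cfg <- list(
    seed = as.integer(seed),
    n_cell_lines = as.integer(n_cell_lines),
    n_genes = as.integer(n_genes),
    gene_length_mean_bp = gene_length_mean_bp,
    gene_length_sd_bp = gene_length_sd_bp,
    gene_length_min_bp = gene_length_min_bp,
    flank_bp = as.integer(flank_bp),
    probe_spacing_bp = as.integer(probe_spacing_bp),
    probe_length_bp = as.integer(probe_length_bp),
    enzyme_site_mean_spacing_bp = enzyme_site_mean_spacing_bp,
    n_enzymes = as.integer(n_enzymes),
    n_reference = expand_counts(n_reference, "n_reference"),
    n_known_poly = expand_counts(n_known_poly, "n_known_poly"),
    n_novel_poly = expand_counts(n_novel_poly, "n_novel_poly"),
    n_singleton = expand_counts(n_singleton, "n_singleton"),
    allele_freq_range = allele_freq_range,
    known_poly_db_fraction = known_poly_db_fraction,
    signal_mean = signal_mean,
    signal_sd = signal_sd,
    baseline_sd = baseline_sd,
    masked_probe_fraction = masked_probe_fraction,
    min_separation_bp = as.integer(min_separation_bp)
  )
  class(cfg) <- "sim_config"
  cfg
}

## ---- genome layout -------------------------------------------------------

simulate_gene_models <- function(config) {
  n <- config$n_genes
  n_chrom <- max(1L, min(4L, n %/% 10L + 1L))
  chrom_of <- sort(rep_len(seq_len(n_chrom), n))
  gap_bp <- 5000L

  len <- pmax(config$gene_length_min_bp,
              round(rnorm(n, config$gene_length_mean_bp,
                          config$gene_length_sd_bp)))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  genes <- vector("list", n)
  tiled <- vector("list", n)
  chrom_len <- integer(n_chrom)
  pos <- config$flank_bp
  cur_chrom <- 1L
  for (i in seq_len(n)) {
    if (chrom_of[i] != cur_chrom) {
      chrom_len[cur_chrom] <- pos - gap_bp - config$flank_bp
      cur_chrom <- chrom_of[i]
      pos <- config$flank_bp
    }
    g_start <- pos
    g_end <- g_start + len[i]
    genes[[i]] <- data.frame(
      gene_id = sprintf("G%04d", i), chrom = sprintf("chr%d", chrom_of[i]),
      start = g_start, end = g_end, strand = strand[i],
      stringsAsFactors = FALSE)
    tiled[[i]] <- data.frame(
      chrom = sprintf("chr%d", chrom_of[i]),
      start = g_start - config$flank_bp, end = g_end + config$flank_bp,
      gene_id = sprintf("G%04d", i), stringsAsFactors = FALSE)
    pos <- g_end + 2L * config$flank_bp + gap_bp
  }
  chrom_len[cur_chrom] <- pos - gap_bp - config$flank_bp
  genes <- do.call(rbind, genes)
  tiled <- do.call(rbind, tiled)
  chroms <- data.frame(chrom = sprintf("chr%d", seq_len(n_chrom)),
                       length = chrom_len, stringsAsFactors = FALSE)

  # exon structure: 1-8 exons, first/last exon flush with the gene ends,
  # 3'UTR at the transcription-terminal end of the last exon
  exons <- vector("list", n)
  utr3 <- vector("list", n)
  for (i in seq_len(n)) {
    L <- genes$end[i] - genes$start[i]
    n_ex <- sample.int(8L, 1L)
    repeat {
      el <- pmin(round(runif(n_ex, 150, 1500)),
                 max(150L, L %/% max(1L, 2L * n_ex)))
      if (sum(el) + (n_ex - 1L) * 200L <= L || n_ex == 1L) break
      n_ex <- n_ex - 1L
    }
    if (n_ex == 1L) el <- min(L, el[1])
    intron_total <- L - sum(el)
    if (n_ex > 1L) {
      w <- runif(n_ex - 1L, 0.5, 1.5)
      il <- floor(intron_total * w / sum(w))
    } else il <- integer(0)
    starts <- genes$start[i] + cumsum(c(0L, el[-n_ex] + il))
    ends <- starts + el
    ends[n_ex] <- min(ends[n_ex], genes$end[i])
    exons[[i]] <- data.frame(gene_id = genes$gene_id[i],
                             chrom = genes$chrom[i],
                             start = starts, end = ends,
                             exon_index = seq_len(n_ex),
                             stringsAsFactors = FALSE)
    term <- if (genes$strand[i] == "+") n_ex else 1L
    te <- exons[[i]][term, ]
    ulen <- min(500L, max(50L, (te$end - te$start) %/% 2L))
    u <- if (genes$strand[i] == "+") {
      data.frame(start = te$end - ulen, end = te$end)
    } else {
      data.frame(start = te$start, end = te$start + ulen)
    }
    utr3[[i]] <- data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                            start = u$start, end = u$end,
                            stringsAsFactors = FALSE)
  }
  list(chroms = chroms, genes = genes, tiled = tiled,
       exons = do.call(rbind, exons), utr3 = do.call(rbind, utr3))
}

simulate_probes <- function(config, tiled) {
  probes <- lapply(seq_len(nrow(tiled)), function(i) {
    starts <- seq.int(tiled$start[i], tiled$end[i] - config$probe_length_bp,
                      by = config$probe_spacing_bp)
    data.frame(chrom = tiled$chrom[i], start = starts,
               end = starts + config$probe_length_bp,
               stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, probes)
  probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
  rownames(probes) <- NULL
  probes$masked <- runif(nrow(probes)) < config$masked_probe_fraction
  probes
}

## Amplicon footprint of one insertion: the parallel digests are amplified
## separately and pooled, so the hybridization footprint spans from the
## insertion to the farthest of the per-enzyme nearest sites on the side
## dictated by strand (plus strand -> rightward); max of n_enzymes
## exponential gaps, mean ~5.2 kb at the 2500 bp / 4 enzyme defaults,
## matching the ~5 kb example peak. Minimum one probe spacing; clipped to
## the chromosome.
footprint_one <- function(config, sites_by_enzyme, ch, pos, strand,
                          chrom_len) {
  if (strand == "+") {
    bounds <- vapply(sites_by_enzyme, function(s) {
      nxt <- s[[ch]][s[[ch]] > pos]
      if (length(nxt)) nxt[1] else NA_real_
    }, numeric(1))
    clipped <- anyNA(bounds)
    far <- if (clipped) chrom_len else max(bounds)
    start <- pos
    end <- max(far, pos + config$probe_spacing_bp)
  } else {
    bounds <- vapply(sites_by_enzyme, function(s) {
      prv <- s[[ch]][s[[ch]] < pos]
      if (length(prv)) prv[length(prv)] else NA_real_
    }, numeric(1))
    clipped <- anyNA(bounds)
    far <- if (clipped) 0 else min(bounds)
    end <- pos + 1L
    start <- min(far, pos + 1L - config$probe_spacing_bp)
  }
  c(start = as.integer(max(start, 0)),
    end = as.integer(min(end, chrom_len)),
    clipped = as.integer(clipped))
}

## Uniform placement over the tiled space. Candidates are rejected unless
## (i) the realized amplicon footprint stays inside its tiled region — an
## amplicon running off the probed part of the array is not recoverable and
## would break parameter-recovery against planted truth — and (ii) the
## footprints of same-group insertions keep at least min_separation_bp of
## clearance, so planted events are resolvable at array resolution by
## construction.
place_insertions <- function(n, tiled, config, sites_by_enzyme, clen) {
  widths <- tiled$end - tiled$start
  total <- sum(widths)
  cum <- cumsum(widths)
  out <- data.frame(chrom = character(n), pos = integer(n),
                    strand = character(n), fp_start = integer(n),
                    fp_end = integer(n), fp_clipped = logical(n),
                    stringsAsFactors = FALSE)
  fp_by_chrom <- list()
  attempts <- 0L
  i <- 1L
  while (i <= n) {
    attempts <- attempts + 1L
    if (attempts > 1000L * max(n, 1L))
      stop("insertion counts exceed placeable region capacity", call. = FALSE)
    u <- floor(runif(1) * total)
    ri <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    pos <- as.integer(tiled$start[ri] + (u - c(0, cum)[ri]))
    ch <- tiled$chrom[ri]
    strand <- sample(c("+", "-"), 1L)
    fp <- footprint_one(config, sites_by_enzyme, ch, pos, strand, clen[[ch]])
    if (fp[["start"]] < tiled$start[ri] || fp[["end"]] > tiled$end[ri]) next
    prev <- fp_by_chrom[[ch]]
    if (!is.null(prev) &&
        any(fp[["start"]] - config$min_separation_bp < prev[, 2] &
              fp[["end"]] + config$min_separation_bp > prev[, 1])) next
    out$chrom[i] <- ch; out$pos[i] <- pos; out$strand[i] <- strand
    out$fp_start[i] <- fp[["start"]]; out$fp_end[i] <- fp[["end"]]
    out$fp_clipped[i] <- fp[["clipped"]] == 1L
    fp_by_chrom[[ch]] <- rbind(prev, c(fp[["start"]], fp[["end"]]))
    i <- i + 1L
  }
  out
}

draw_presence <- function(category, n_lines, freq_range) {
  if (category == "reference") return(rep(1L, n_lines))
  if (category == "singleton") {
    v <- integer(n_lines); v[sample.int(n_lines, 1L)] <- 1L
    return(v)
  }
  min_carriers <- if (category == "novel_polymorphic") 2L else 1L
  for (try in 1:200) {
    f <- runif(1, freq_range[1], freq_range[2])
    v <- rbinom(n_lines, 1L, f)
    if (sum(v) >= min_carriers) return(v)
  }
  v <- integer(n_lines); v[sample.int(n_lines, min_carriers)] <- 1L
  v
}

#' Simulate a cell-line panel with planted TE insertions
#'
#' Builds the genome layout (chromosomes, gene models with exons and 3'UTRs,
#' tiled regions, probes), plants insertions of the four categories with
#' per-line presence vectors, computes amplicon footprints against a
#' simulated restriction map, and writes reference plus (a fraction of)
#' known-polymorphic insertions into the known-insertion database.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (layout, probes, restriction map),
#'   `truth` (planted insertions, presence matrix, footprints) and
#'   `db` (known-insertion database data.frame).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 0L))
  layout <- simulate_gene_models(config)
  probes <- simulate_probes(config, layout$tiled)

  lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  cats <- c("reference", "known_polymorphic", "novel_polymorphic", "singleton")
  per_family <- lapply(TE_FAMILIES, function(fam) {
    counts <- c(config$n_reference[fam], config$n_known_poly[fam],
                config$n_novel_poly[fam], config$n_singleton[fam])
    data.frame(family = fam, category = rep(cats, counts),
               stringsAsFactors = FALSE)
  })
  ins <- do.call(rbind, per_family)

  # restriction map first: placement rejects candidates whose realized
  # amplicon footprints would crowd a same-group neighbour
  rmap <- simulate_restriction_map(config, layout$chroms)
  sites_by_enzyme <- lapply(rmap$per_enzyme,
                            function(m) split(m$pos, m$chrom))
  clen <- setNames(layout$chroms$length, layout$chroms$chrom)

  # L1 and Alu groups placed independently; AluYa/AluYb share the Alu space
  set.seed(child_seed(config$seed, 4L))
  ins$chrom <- NA_character_; ins$pos <- NA_integer_
  ins$strand <- NA_character_
  fp_start <- integer(nrow(ins)); fp_end <- integer(nrow(ins))
  fp_clipped <- logical(nrow(ins))
  for (grp in c("L1", "Alu")) {
    sel <- family_group(ins$family) == grp
    if (!any(sel)) next
    p <- place_insertions(sum(sel), layout$tiled, config,
                          sites_by_enzyme, clen)
    ins$chrom[sel] <- p$chrom
    ins$pos[sel] <- p$pos
    ins$strand[sel] <- p$strand
    fp_start[sel] <- p$fp_start
    fp_end[sel] <- p$fp_end
    fp_clipped[sel] <- p$fp_clipped
  }
  ins$locus_id <- sprintf("INS_%s_%04d", ins$family,
                          stats::ave(seq_len(nrow(ins)), ins$family,
                                     FUN = seq_along))

  presence <- t(vapply(seq_len(nrow(ins)), function(i) {
    draw_presence(ins$category[i], config$n_cell_lines,
                  config$allele_freq_range)
  }, integer(config$n_cell_lines)))
  dimnames(presence) <- list(ins$locus_id, lines)

  # known-insertion database: all reference records, plus a configurable
  # fraction of known-polymorphic ones; insertions omitted from the DB are
  # relabelled to the category the classifier could at best assign them
  db_rows <- ins$category == "reference"
  for (fam in TE_FAMILIES) {
    kp <- which(ins$family == fam & ins$category == "known_polymorphic")
    n_in_db <- round(config$known_poly_db_fraction * length(kp))
    if (n_in_db > 0) db_rows[kp[seq_len(n_in_db)]] <- TRUE
    dropped <- kp[setdiff(seq_along(kp), seq_len(n_in_db))]
    if (length(dropped)) {
      ins$category[dropped] <- ifelse(rowSums(presence[dropped, , drop = FALSE]) >= 2,
                                      "novel_polymorphic", "singleton")
    }
  }
  db <- data.frame(
    chrom = ins$chrom[db_rows], start = ins$pos[db_rows],
    end = ins$pos[db_rows] + 1L,
    id = sprintf("DB_%s", ins$locus_id[db_rows]),
    family = ins$family[db_rows],
    source = ifelse(ins$category[db_rows] == "reference",
                    "reference", "known_polymorphic"),
    stringsAsFactors = FALSE)
  rownames(db) <- NULL

  footprints <- data.frame(locus_id = ins$locus_id, chrom = ins$chrom,
                           start = fp_start, end = fp_end,
                           clipped = fp_clipped, stringsAsFactors = FALSE)
  if (any(fp_clipped))
    message(sum(fp_clipped), " amplicon footprint(s) clipped at contig ends")

  genome <- c(layout, list(probes = probes, restriction = rmap,
                           cell_lines = lines))
  truth <- list(insertions = ins, presence = presence,
                footprints = footprints, cell_lines = lines)
  class(truth) <- "planted_truth"
  list(genome = genome, truth = truth, db = db)
}

#' Simulate per-enzyme restriction maps
#'
#' Restriction sites for each enzyme are drawn as a homogeneous Poisson
#' process along each chromosome (exponential inter-site gaps with the
#' configured mean spacing); the union over enzymes is what bounds amplicon
#' footprints, mirroring parallel digests pooled before hybridization.
#'
#' @param config a [sim_config()].
#' @param chroms data.frame with columns `chrom`, `length`.
#' @return list with `per_enzyme` (list of data.frames chrom/pos) and
#'   `union` (merged, sorted sites).
#' @export
simulate_restriction_map <- function(config, chroms) {
  if (!is.null(chroms$chroms)) chroms <- chroms$chroms  # accept genome list
  set.seed(child_seed(config$seed, 1L))
  per_enzyme <- lapply(seq_len(config$n_enzymes), function(e) {
    sites <- lapply(seq_len(nrow(chroms)), function(ci) {
      len <- chroms$length[ci]
      if (len <= 0) return(data.frame(chrom = character(0), pos = integer(0)))
      n_exp <- ceiling(len / config$enzyme_site_mean_spacing_bp * 1.5) + 10L
      pos <- cumsum(rexp(n_exp, 1 / config$enzyme_site_mean_spacing_bp))
      while (length(pos) && pos[length(pos)] < len) {
        pos <- c(pos, pos[length(pos)] +
                   cumsum(rexp(n_exp, 1 / config$enzyme_site_mean_spacing_bp)))
      }
      pos <- floor(pos[pos < len])
      data.frame(chrom = chroms$chrom[ci], pos = as.integer(pos),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, sites)
  })
  names(per_enzyme) <- sprintf("enzyme%d", seq_len(config$n_enzymes))
  un <- do.call(rbind, per_enzyme)
  un <- unique(un[order(un$chrom, un$pos), , drop = FALSE])
  rownames(un) <- NULL
  list(per_enzyme = per_enzyme, union = un)
}


#' Simulate probe intensity tracks for every (cell line, family channel)
#'
#' Probes inside the amplicon footprint of an insertion present in a line get
#' log2 intensities from Normal(signal_mean, signal_sd); all other probes
#' from Normal(0, baseline_sd). The repeat-mask flag is shared panel-wide.
#'
#' @param config a [sim_config()].
#' @param truth planted truth from [simulate_panel()].
#' @param genome genome layout from [simulate_panel()].
#' @param cell_lines,families optional subsets to simulate.
#' @return named list of [probe_track()] objects, names `"<line>.<family>"`.
#' @export
simulate_intensities <- function(config, truth, genome,
                                 cell_lines = NULL, families = NULL) {
  set.seed(child_seed(config$seed, 2L))
  if (is.null(cell_lines)) cell_lines <- truth$cell_lines
  if (is.null(families)) families <- TE_FAMILIES
  probes <- genome$probes
  pr_gr <- df_to_granges(probes)
  fp <- truth$footprints
  fp_hits <- GenomicRanges::findOverlaps(df_to_granges(fp), pr_gr)
  fp_probes <- split(S4Vectors::subjectHits(fp_hits),
                     fp$locus_id[S4Vectors::queryHits(fp_hits)])

  ins <- truth$insertions
  tracks <- list()
  for (cl in cell_lines) {
    for (fam in families) {
      intensity <- rnorm(nrow(probes), 0, config$baseline_sd)
      present <- ins$locus_id[ins$family == fam &
                                truth$presence[ins$locus_id, cl] == 1L]
      for (id in present) {
        idx <- fp_probes[[id]]
        if (length(idx))
          intensity[idx] <- rnorm(length(idx), config$signal_mean,
                                  config$signal_sd)
      }
      tr <- probes
      tr$intensity <- intensity
      tracks[[paste(cl, fam, sep = ".")]] <-
        probe_track(tr[, c("chrom", "start", "end", "intensity", "masked")],
                    cell_line = cl, family = fam)
    }
  }
  tracks
}

#' Simulate phenotype profiles over the panel
#'
#' Null features are standard-normal per line; planted-effect features add
#' `effect_size` (in SD units) times the carrier indicator of a chosen locus.
#' Cis-designated effect features receive a genomic anchor within 30 kb of
#' their locus; a configurable fraction of null features get random anchors
#' so cis/trans labeling is exercised, and the rest stay unanchored.
#'
#' @param config a [sim_config()].
#' @param truth planted truth from [simulate_panel()].
#' @param n_null_features number of pure-noise features.
#' @param effects optional data.frame (locus_id, effect_size, cis); if NULL,
#'   `n_cis_effects` + `n_trans_effects` effects of size `effect_size` are
#'   planted on randomly chosen multi-carrier loci.
#' @param n_cis_effects,n_trans_effects,effect_size auto-registry parameters.
#' @param anchored_null_fraction fraction of null features given a random
#'   genomic anchor.
#' @param genome genome layout (needed for random anchors).
#' @return `phenotype_matrix`: list with `values` (features x lines matrix),
#'   `anchors` (feature_id, chrom, pos; NA = unanchored) and `effects`
#'   (planted-effect registry).
#' @export
simulate_phenotypes <- function(config, truth, genome,
                                n_null_features = 100L,
                                effects = NULL,
                                n_cis_effects = 3L, n_trans_effects = 3L,
                                effect_size = 3,
                                anchored_null_fraction = 0.5) {
  set.seed(child_seed(config$seed, 3L))
  ins <- truth$insertions
  n_lines <- length(truth$cell_lines)
  carriers <- rowSums(truth$presence)

  if (is.null(effects)) {
    multi <- ins$locus_id[carriers[ins$locus_id] >= 2 &
                            carriers[ins$locus_id] <= n_lines - 2]
    n_eff <- n_cis_effects + n_trans_effects
    chosen <- sample(multi, min(n_eff, length(multi)))
    effects <- data.frame(
      locus_id = chosen,
      effect_size = rep(effect_size, length(chosen)),
      cis = seq_along(chosen) <= n_cis_effects,
      stringsAsFactors = FALSE)
  }
  stop_if_not(all(effects$locus_id %in% ins$locus_id),
              "planted effects must reference existing loci")
  if (any(carriers[effects$locus_id] == 1))
    message("planted effect on a singleton locus (cis-only testable)")

  n_feat <- n_null_features + nrow(effects)
  feat_ids <- c(sprintf("PH%04d", seq_len(n_null_features)),
                if (nrow(effects)) sprintf("EFF%02d", seq_len(nrow(effects))))
  values <- matrix(rnorm(n_feat * n_lines), nrow = n_feat,
                   dimnames = list(feat_ids, truth$cell_lines))
  anchors <- data.frame(feature_id = feat_ids,
                        chrom = NA_character_, pos = NA_integer_,
                        stringsAsFactors = FALSE)

  # random anchors for a fraction of null features
  tiled <- genome$tiled
  anchored <- which(runif(n_null_features) < anchored_null_fraction)
  if (length(anchored)) {
    ri <- sample.int(nrow(tiled), length(anchored), replace = TRUE)
    anchors$chrom[anchored] <- tiled$chrom[ri]
    anchors$pos[anchored] <- as.integer(tiled$start[ri] +
      floor(runif(length(anchored)) * (tiled$end[ri] - tiled$start[ri])))
  }

  if (nrow(effects)) {
    effects$feature_id <- sprintf("EFF%02d", seq_len(nrow(effects)))
    for (j in seq_len(nrow(effects))) {
      fid <- effects$feature_id[j]
      lid <- effects$locus_id[j]
      values[fid, ] <- values[fid, ] +
        effects$effect_size[j] * truth$presence[lid, ]
      if (effects$cis[j]) {
        row <- ins[ins$locus_id == lid, ]
        anchors$chrom[anchors$feature_id == fid] <- row$chrom
        anchors$pos[anchors$feature_id == fid] <-
          max(0L, row$pos + sample(-25000:25000, 1L))
      }
    }
  }
  out <- list(values = values, anchors = anchors, effects = effects)
  class(out) <- "phenotype_matrix"
  out
}
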