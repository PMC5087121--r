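test_that("sim_config validates its inputs", {
  expect_error(sim_config(probe_spacing_bp = 0), "probe_spacing_bp")
  expect_error(sim_config(allele_freq_range = c(0, 0.5)), "allele_freq")
  expect_error(sim_config(n_reference = -1), "non-negative")
  cfg <- sim_config(n_reference = c(L1 = 10, AluYa = 2, AluYb = 3))
  expect_identical(unname(cfg$n_reference), c(10L, 2L, 3L))
})

test_that("simulate_panel is deterministic and conserves planted counts", {
  fx <- get_small_sim()
  again <- simulate_panel(fx$cfg)
  expect_identical(fx$sim$truth, again$truth)
  expect_identical(fx$sim$db, again$db)
  expect_identical(fx$sim$genome$probes, again$genome$probes)

  ins <- fx$sim$truth$insertions
  for (fam in c("L1", "AluYa", "AluYb")) {
    expect_equal(sum(ins$family == fam),
                 fx$cfg$n_reference[[fam]] + fx$cfg$n_known_poly[[fam]] +
                   fx$cfg$n_novel_poly[[fam]] + fx$cfg$n_singleton[[fam]])
  }
})

test_that("presence vectors honour category definitions", {
  fx <- get_small_sim()
  ins <- fx$sim$truth$insertions
  pres <- fx$sim$truth$presence
  k <- rowSums(pres)
  expect_true(all(k[ins$locus_id[ins$category == "reference"]] ==
                    fx$cfg$n_cell_lines))
  expect_true(all(k[ins$locus_id[ins$category == "singleton"]] == 1))
  expect_true(all(k[ins$locus_id[ins$category == "novel_polymorphic"]] >= 2))
  expect_true(all(k >= 1))
  # DB membership consistent with labels
  db_loci <- sub("^DB_", "", fx$sim$db$id)
  expect_setequal(db_loci,
                  ins$locus_id[ins$category %in%
                                 c("reference", "known_polymorphic")])
})

test_that("n_singleton = 0 plants no single-carrier non-DB locus", {
  cfg <- sim_config(seed = 3L, n_cell_lines = 6L, n_genes = 25L,
                    n_reference = 5L, n_known_poly = 4L, n_novel_poly = 4L,
                    n_singleton = 0L)
  sim <- simulate_panel(cfg)
  ins <- sim$truth$insertions
  non_db <- ins$locus_id[!ins$locus_id %in% sub("^DB_", "", sim$db$id)]
  expect_true(all(rowSums(sim$truth$presence[non_db, , drop = FALSE]) >= 2))
})

test_that("over-stuffed genomes raise a capacity error", {
  cfg <- sim_config(seed = 1L, n_genes = 2L, n_cell_lines = 3L,
                    n_reference = 40L, n_known_poly = 0L, n_novel_poly = 0L,
                    n_singleton = 0L, min_separation_bp = 20000L)
  expect_error(simulate_panel(cfg), "capacity")
})

test_that("restriction sites behave as a Poisson process", {
  cfg <- sim_config(enzyme_site_mean_spacing_bp = 2500, n_enzymes = 4L)
  chroms <- data.frame(chrom = "chr1", length = 1e6L)
  gaps <- unlist(lapply(1:10, function(s) {
    cfg2 <- cfg; cfg2$seed <- s
    m <- simulate_restriction_map(cfg2, chroms)
    unlist(lapply(m$per_enzyme, function(e) diff(e$pos)))
  }))
  se <- 2500 / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 2500), 3 * se)

  # zero-length contig and determinism
  m0 <- simulate_restriction_map(cfg, data.frame(chrom = "c", length = 0L))
  expect_equal(nrow(m0$union), 0)
  m1 <- simulate_restriction_map(cfg, chroms)
  m2 <- simulate_restriction_map(cfg, chroms)
  expect_identical(m1, m2)
})

test_that("amplicon footprints sit on the strand-dictated side and bracket 5 kb", {
  fx <- get_small_sim()
  ins <- fx$sim$truth$insertions
  fp <- fx$sim$truth$footprints
  expect_true(all(fp$start <= ins$pos & ins$pos < fp$end))
  plus <- ins$strand == "+" & !fp$clipped
  minus <- ins$strand == "-" & !fp$clipped
  w <- fp$end - fp$start
  expect_true(all(fp$start[plus] == ins$pos[plus] |
                    w[plus] == fx$cfg$probe_spacing_bp))
  expect_true(all(fp$end[minus] == ins$pos[minus] + 1L |
                    w[minus] == fx$cfg$probe_spacing_bp))
  expect_true(all(w >= fx$cfg$probe_spacing_bp))
  # order-of-magnitude property anchored to the assay's ~5 kb example peak
  expect_gt(median(w), 1000)
  expect_lt(median(w), 10000)
})

test_that("footprint probes form contiguous runs and signal separates", {
  fx <- get_small_sim()
  sim <- fx$sim
  tracks <- simulate_intensities(fx$cfg, sim$truth, sim$genome,
                                 cell_lines = "CL01")
  tr <- tracks[["CL01.L1"]]
  ins <- sim$truth$insertions
  fp <- sim$truth$footprints
  present <- ins$family == "L1" & sim$truth$presence[ins$locus_id, "CL01"] == 1
  in_fp <- rep(FALSE, nrow(tr))
  for (i in which(present)) {
    idx <- which(tr$chrom == fp$chrom[i] & tr$start < fp$end[i] &
                   tr$end > fp$start[i])
    if (length(idx)) expect_identical(idx, seq(min(idx), max(idx)))
    in_fp[idx] <- TRUE
  }
  expect_gt(mean(tr$intensity[in_fp]), mean(tr$intensity[!in_fp]) + 5)

  # absent insertions leave baseline signal
  absent <- ins$family == "L1" & sim$truth$presence[ins$locus_id, "CL01"] == 0
  for (i in which(absent)) {
    idx <- which(tr$chrom == fp$chrom[i] & tr$start < fp$end[i] &
                   tr$end > fp$start[i])
    other <- in_fp[idx]  # may be covered by a different present insertion
    if (length(idx) && !any(other))
      expect_lt(mean(tr$intensity[idx]), 2)
  }
})

test_that("intensity tracks are deterministic and share the mask panel-wide", {
  fx <- get_small_sim()
  t1 <- simulate_intensities(fx$cfg, fx$sim$truth, fx$sim$genome,
                             cell_lines = c("CL01", "CL02"),
                             families = "AluYa")
  t2 <- simulate_intensities(fx$cfg, fx$sim$truth, fx$sim$genome,
                             cell_lines = c("CL01", "CL02"),
                             families = "AluYa")
  expect_identical(t1, t2)
  expect_identical(t1[["CL01.AluYa"]]$masked, t1[["CL02.AluYa"]]$masked)
})

test_that("null phenotype features are independent of presence", {
  fx <- get_small_sim()
  cfg <- sim_config(seed = 5L, n_cell_lines = 20L, n_genes = 40L,
                    n_reference = 8L, n_known_poly = 5L, n_novel_poly = 5L,
                    n_singleton = 5L)
  sim <- simulate_panel(cfg)
  ph <- simulate_phenotypes(cfg, sim$truth, sim$genome,
                            n_null_features = 100L,
                            n_cis_effects = 0L, n_trans_effects = 0L)
  k <- rowSums(sim$truth$presence)
  locus <- names(k)[which(k >= 5 & k <= 15)[1]]
  pres <- sim$truth$presence[locus, ]
  r <- apply(ph$values, 1, function(v) abs(cor(pres, v)))
  expect_gte(mean(r < 0.8), 0.95)
})

test_that("planted phenotype effects behave as declared", {
  fx <- get_small_sim()
  sim <- fx$sim
  k <- rowSums(sim$truth$presence)
  locus <- names(k)[which(k >= 3 & k <= 5)[1]]
  eff <- data.frame(locus_id = locus, effect_size = 10, cis = TRUE)
  ph <- simulate_phenotypes(fx$cfg, sim$truth, sim$genome,
                            n_null_features = 5L, effects = eff)
  pres <- sim$truth$presence[locus, ] == 1
  v <- ph$values[ph$effects$feature_id[1], ]
  expect_gt(min(v[pres]), max(v[!pres]))  # effect 10 >> unit noise
  # cis anchor lands within the 30 kb window of its locus
  a <- ph$anchors[ph$anchors$feature_id == ph$effects$feature_id[1], ]
  row <- sim$truth$insertions[sim$truth$insertions$locus_id == locus, ]
  ct <- classify_cis_trans(
    data.frame(chrom = row$chrom, start = row$pos, end = row$pos + 1L),
    a$chrom, a$pos)
  expect_true(ct$cis)
  expect_error(
    simulate_phenotypes(fx$cfg, sim$truth, sim$genome,
                        effects = data.frame(locus_id = "nope",
                                             effect_size = 1, cis = FALSE)),
    "existing loci")
})
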