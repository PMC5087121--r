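pk_row <- function(start, end = start + 5000L, cl = "CL01", family = "L1",
                   chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end,
             peak_id = paste0("p", start, cl), rank_threshold = 90,
             n_probes = 5L, max_intensity = 9, cell_line = cl,
             family = family, stringsAsFactors = FALSE)
}

test_that("match_known respects margins and family", {
  peak <- pk_row(10000L, 15000L)
  db <- data.frame(chrom = "chr1", start = c(15500L, 16500L, 12000L),
                   end = c(15501L, 16501L, 12001L),
                   id = c("near", "far", "wrongfam"),
                   family = c("L1", "L1", "AluYa"),
                   source = "reference", stringsAsFactors = FALSE)
  m <- match_known(peak, db, margin_bp = 1000)
  expect_identical(m$id, "near")  # 15500 within margin; 16500 beyond;
                                  # different family never matches
  # margin 2000 brings the far record in
  expect_setequal(match_known(peak, db, margin_bp = 2000)$id,
                  c("near", "far"))
  # exact-family matching can be requested
  alu_rec <- data.frame(chrom = "chr1", start = 12000L, end = 12001L,
                        id = "ya", family = "AluYb", source = "reference")
  peak_ya <- pk_row(10000L, 15000L, family = "AluYa")
  expect_equal(nrow(match_known(peak_ya, alu_rec, 1000)), 1)
  expect_equal(nrow(match_known(peak_ya, alu_rec, 1000,
                                collapse_alu = FALSE)), 0)
})

test_that("build_loci merges transitively and fills the presence matrix", {
  lines <- sprintf("CL%02d", 1:4)
  # identical peak in 3 lines -> one locus with row sum 3
  shared <- do.call(rbind, lapply(lines[1:3], function(cl)
    pk_row(50000L, cl = cl)))
  b <- build_loci(shared, cell_lines = lines)
  expect_equal(nrow(b$loci), 1)
  expect_equal(sum(b$presence), 3)
  expect_equal(unname(b$presence[1, ]), c(1L, 1L, 1L, 0L))

  # two peaks 10 kb apart with 1 kb margins stay separate
  apart <- rbind(pk_row(0L, 2000L), pk_row(12000L, 14000L, cl = "CL02"))
  expect_equal(nrow(build_loci(apart, cell_lines = lines)$loci), 2)

  # chain A-B overlapping, B-C overlapping -> one locus spanning A..C
  chain <- rbind(pk_row(0L, 3000L), pk_row(2500L, 6000L, cl = "CL02"),
                 pk_row(5500L, 9000L, cl = "CL03"))
  bc <- build_loci(chain, cell_lines = lines)
  expect_equal(nrow(bc$loci), 1)
  expect_equal(bc$loci$start, 0L)
  expect_equal(bc$loci$end, 9000L)
})

test_that("locus membership is a partition matching the union-find oracle", {
  set.seed(7)
  starts <- sort(sample.int(200000L, 25))
  peaks <- do.call(rbind, lapply(seq_along(starts), function(i)
    pk_row(starts[i], starts[i] + sample(500:4000, 1),
           cl = sprintf("CL%02d", sample(4, 1)),
           family = sample(c("L1", "AluYa", "AluYb"), 1))))
  b <- build_loci(peaks, merge_margin_bp = 1000)
  expect_equal(sum(b$loci$n_peaks), nrow(peaks))   # every peak in one locus
  expect_lte(nrow(b$loci), nrow(peaks))
  oracle_groups <- oracle_merge_groups(peaks, margin = 1000)
  expect_equal(nrow(b$loci), length(unique(oracle_groups)))
  # row sums equal contributing-line counts
  expect_true(all(rowSums(b$presence) == b$loci$n_lines))
})

test_that("classify_loci applies the category scheme with DB precedence", {
  lines <- sprintf("CL%02d", 1:4)
  peaks <- rbind(
    do.call(rbind, lapply(lines, function(cl) pk_row(10000L, cl = cl))),
    pk_row(50000L, cl = "CL01"),
    do.call(rbind, lapply(lines[1:3], function(cl) pk_row(90000L, cl = cl))),
    do.call(rbind, lapply(lines[1:2], function(cl) pk_row(130000L, cl = cl))))
  db <- data.frame(
    chrom = "chr1", start = c(10100L, 10200L, 130100L),
    end = c(10101L, 10201L, 130101L),
    id = c("ref1", "poly1", "poly2"), family = "L1",
    source = c("reference", "known_polymorphic", "known_polymorphic"),
    stringsAsFactors = FALSE)
  b <- build_loci(peaks, cell_lines = lines)
  cl <- classify_loci(b$loci, b$presence, db)
  cat_of <- function(start) cl$category[cl$start == start]
  expect_equal(cat_of(10000L), "reference")
  expect_true(cl$ref_and_poly[cl$start == 10000L])  # counted in both groups
  expect_equal(cat_of(50000L), "singleton")
  expect_equal(cat_of(90000L), "novel_polymorphic")
  expect_equal(cat_of(130000L), "known_polymorphic")
  expect_false(any(cl$ref_and_poly[cl$start != 10000L]))
})

test_that("noise-free classification reproduces planted categories", {
  fx <- get_small_sim()
  peaks <- truth_to_peaks(fx$sim$truth)
  b <- build_loci(peaks, cell_lines = fx$sim$truth$cell_lines)
  cl <- classify_loci(b$loci, b$presence, fx$sim$db)
  ins <- fx$sim$truth$insertions
  # map each planted insertion to the locus containing its position
  for (i in seq_len(nrow(ins))) {
    hit <- cl$chrom == ins$chrom[i] & cl$start <= ins$pos[i] &
      ins$pos[i] < cl$end & cl$family == family_group(ins$family[i])
    expect_equal(sum(hit), 1)
    expect_equal(cl$category[hit], ins$category[i],
                 label = ins$locus_id[i])
  }
})

test_that("summarize_panel reports counts, frequencies and singleton fractions", {
  lines <- sprintf("CL%02d", 1:4)
  all_ref <- do.call(rbind, lapply(lines, function(cl)
    rbind(pk_row(10000L, cl = cl), pk_row(60000L, cl = cl))))
  db <- data.frame(chrom = "chr1", start = c(10100L, 60100L),
                   end = c(10101L, 60101L), id = c("r1", "r2"),
                   family = "L1", source = "reference",
                   stringsAsFactors = FALSE)
  b <- build_loci(all_ref, cell_lines = lines)
  cl <- classify_loci(b$loci, b$presence, db)
  s <- summarize_panel(cl, b$presence)
  expect_equal(unname(s$singleton_fraction["L1"]), 0)
  expect_true(all(s$per_line$n[s$per_line$category == "reference"] == 2))
  # frequency table: both loci carried by all 4 lines
  expect_equal(s$frequency$n_loci[s$frequency$n_lines == 4], 2)
})

test_that("a 68% singleton plant is recovered under perfect detection", {
  cfg <- sim_config(seed = 21L, n_cell_lines = 10L, n_genes = 120L,
                    n_reference = c(L1 = 15L, AluYa = 5L, AluYb = 5L),
                    n_known_poly = c(L1 = 12L, AluYa = 5L, AluYb = 5L),
                    n_novel_poly = c(L1 = 20L, AluYa = 5L, AluYb = 5L),
                    n_singleton = c(L1 = 68L, AluYa = 5L, AluYb = 5L))
  sim <- simulate_panel(cfg)
  b <- build_loci(truth_to_peaks(sim$truth),
                  cell_lines = sim$truth$cell_lines)
  cl <- classify_loci(b$loci, b$presence, sim$db)
  s <- summarize_panel(cl, b$presence)
  # 68 of 100 non-reference L1 loci are singletons; allow binomial noise
  expect_lt(abs(s$singleton_fraction[["L1"]] - 0.68),
            3 * sqrt(0.68 * 0.32 / 100))
})

test_that("exon_overlap_report labels gene context from locus midpoints", {
  genome <- list(
    genes = data.frame(gene_id = "G1", chrom = "chr1", start = 10000L,
                       end = 30000L, strand = "+"),
    exons = data.frame(gene_id = "G1", chrom = "chr1",
                       start = c(10000L, 25000L), end = c(11000L, 30000L),
                       exon_index = 1:2),
    utr3 = data.frame(gene_id = "G1", chrom = "chr1", start = 29500L,
                      end = 30000L),
    tiled = data.frame(chrom = "chr1", start = 0L, end = 40000L,
                       gene_id = "G1"))
  loci <- data.frame(
    locus_id = sprintf("L%d", 1:5), chrom = "chr1",
    start = c(29600L, 10200L, 15000L, 35000L, 10800L),
    end = c(29800L, 10400L, 16000L, 36000L, 11500L),
    family = "L1", n_lines = 1L, n_peaks = 1L, category = "singleton",
    stringsAsFactors = FALSE)
  rep <- exon_overlap_report(loci, genome)
  expect_equal(rep$context,
               c("exonic_3utr", "exonic_cds", "intronic",
                 "intergenic_flank", "intronic"))
  # locus 5 straddles the first exon boundary
  expect_equal(rep$partial_exon_overlap, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- loci; out$start <- 100000L; out$end <- 101000L
  expect_message(rep2 <- exon_overlap_report(out, genome), "outside tiled")
  expect_true(all(rep2$context == "untiled"))
})

test_that("deletion_flag lists lines lacking otherwise-fixed reference loci", {
  pres <- rbind(c(1L, 1L, 1L, 0L), c(1L, 1L, 1L, 1L), c(1L, 0L, 0L, 0L))
  dimnames(pres) <- list(c("A", "B", "C"), sprintf("CL%02d", 1:4))
  loci <- data.frame(locus_id = c("A", "B", "C"), chrom = "chr1",
                     start = c(0L, 100L, 200L), end = c(10L, 110L, 210L),
                     family = "L1", n_lines = c(3L, 4L, 1L), n_peaks = 1L,
                     category = c("reference", "reference", "reference"),
                     stringsAsFactors = FALSE)
  fl <- deletion_flag(loci, pres)
  expect_equal(fl$locus_id, "A")
  expect_equal(fl$absent_lines, "CL04")
  # present everywhere or absent too often -> not flagged at the default
  expect_false(any(c("B", "C") %in% fl$locus_id))
  expect_equal(nrow(deletion_flag(loci[2, ], pres[2, , drop = FALSE])), 0)
})
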