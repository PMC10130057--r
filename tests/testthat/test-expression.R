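test_that("alignment filtering honours both dialects at the boundaries", {
  rec <- data.frame(read_id = "r1", target_id = "c1",
                    read_length = 100, aligned_length = 90,
                    identity = 0.99)
  # metagenomic dialect removes on equality (<=)
  expect_equal(nrow(filter_alignments(rec, strict = TRUE)), 0)
  # metatranscriptomic dialect keeps equality (<)
  rec2 <- data.frame(read_id = "r1", target_id = "c1",
                     read_length = 100, aligned_length = 95,
                     identity = 0.97)
  expect_equal(nrow(filter_alignments(rec2, strict = FALSE)), 1)
  expect_equal(nrow(filter_alignments(rec2, strict = TRUE)), 0)
  # empty input passes through
  empty <- rec[0, ]
  expect_equal(nrow(filter_alignments(empty)), 0)
  expect_error(filter_alignments(rec, min_identity = 1.5), "thresholds")
})

test_that("alignment filtering sweeps thresholds consistently", {
  set.seed(3)
  rec <- data.frame(
    read_id = paste0("r", 1:40),
    target_id = "c1",
    read_length = 100,
    aligned_length = sample(80:100, 40, replace = TRUE),
    identity = round(runif(40, 0.9, 1), 3))
  frac <- rec$aligned_length / rec$read_length
  for (thr in c(0.9, 0.95)) {
    loose <- filter_alignments(rec, thr, 0.97, strict = FALSE)
    strict <- filter_alignments(rec, thr, 0.97, strict = TRUE)
    expect_equal(loose$read_id,
                 rec$read_id[frac >= thr & rec$identity >= 0.97])
    expect_equal(strict$read_id,
                 rec$read_id[frac > thr & rec$identity > 0.97])
    # strict removes a superset of what the loose dialect removes
    expect_true(all(strict$read_id %in% loose$read_id))
  }
})

test_that("count_reads picks best alignments and flags ties", {
  rec <- data.frame(
    read_id = c("r1", "r1", "r2", "r3", "r3"),
    target_id = c("c1", "c2", "c2", "c1", "c2"),
    read_length = 100,
    aligned_length = c(100, 98, 100, 100, 100),
    identity = c(0.99, 0.999, 1, 0.98, 0.98))
  counts <- count_reads(rec, c("c1", "c2", "c3"))
  expect_equal(unname(counts["c2"]), 2L)  # r1 best by identity, r2
  expect_equal(unname(counts["c1"]), 1L)  # r3 tie -> first listed
  expect_equal(unname(counts["c3"]), 0L)
  expect_equal(attr(counts, "ties"), 1L)
})

test_that("TPM matches the length-normalised closed form", {
  expect_equal(unname(compute_tpm(c(10, 10), c(100, 100))),
               c(5e5, 5e5))
  expect_equal(unname(compute_tpm(c(10, 20), c(100, 400))),
               c(2 / 3, 1 / 3) * 1e6)
  expect_equal(unname(compute_tpm(c(0, 0), c(100, 400))), c(0, 0))
  expect_error(compute_tpm(c(1, 1), c(100, 0)), "lengths must be > 0")
  expect_error(compute_tpm(c(-1, 1), c(100, 100)), "counts")
  # normalisation invariant under random inputs
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    tpm <- compute_tpm(rpois(n, 50), sample(200:2000, n))
    expect_equal(sum(tpm), 1e6, tolerance = 1e-9)
  }
})

test_that("complex expression averages subunits, summing gene copies", {
  cds <- toy_cds()
  fm <- toy_function_map()
  tpm <- c(c1 = 30, c2 = 60, c3 = 90, c4 = 10, c5 = 5, c6 = 100)
  cx <- complex_expression(tpm, cds, fm, "G1")
  expect_equal(cx$value[cx$complex_id == "pmoCAB"], 60)  # mean(30,60,90)
  expect_equal(cx$flag[cx$complex_id == "pmoCAB"], "")
  # complexes of another genome are "not encoded" here
  expect_true(is.na(cx$value[cx$complex_id == "nar"]))
  expect_equal(cx$flag[cx$complex_id == "nar"], "not encoded")
  # duplicated copies of one subunit are summed before averaging
  cds2 <- rbind(cds, data.frame(cds_id = "c7", genome_id = "G1",
                                gene_symbol = "pmoA", length = 150,
                                strand = "+"))
  tpm2 <- c(tpm, c7 = 40)
  cx2 <- complex_expression(tpm2, cds2, fm, "G1")
  expect_equal(cx2$value[cx2$complex_id == "pmoCAB"],
               mean(c(30, 60 + 40, 90)))
  # a missing subunit contributes zero and is flagged
  cds3 <- cds[cds$gene_symbol != "pmoB", ]
  cx3 <- complex_expression(tpm, cds3, fm, "G1")
  expect_equal(cx3$value[cx3$complex_id == "pmoCAB"], mean(c(30, 60, 0)))
  expect_equal(cx3$flag[cx3$complex_id == "pmoCAB"], "missing_members")
})

test_that("reaction expression sums alternates; pathways average reactions", {
  cds <- toy_cds()
  fm <- toy_function_map()
  tpm <- c(c1 = 30, c2 = 60, c3 = 90, c4 = 10, c5 = 5, c6 = 100)
  cx <- complex_expression(tpm, cds, fm, "G2")
  rx <- reaction_expression(cx, fm)
  # nitrate reduction = nar + nap
  expect_equal(rx$value[rx$reaction_id == "nitrate_reduction"], 15)
  expect_equal(rx$value[rx$reaction_id == "methane_oxidation"], 0)
  expect_equal(rx$flag[rx$reaction_id == "methane_oxidation"],
               "not encoded")
  pw <- pathway_expression(rx, fm)
  expect_equal(pw$value[pw$pathway_id == "denitrification"], 15)
  expect_equal(pw$value[pw$pathway_id == "aom"], 0)
  expect_equal(pw$flag[pw$pathway_id == "aom"], "not encoded")
  # two-reaction pathway: mean with the absent reaction counting as 0
  expect_equal(pw$value[pw$pathway_id == "n_cycle"], mean(c(0, 15)))
  expect_equal(pw$flag[pw$pathway_id == "n_cycle"], "missing_reactions")
})

test_that("aggregation is scale-equivariant and order-invariant", {
  cds <- toy_cds()
  tpm <- c(c1 = 30, c2 = 60, c3 = 90, c4 = 10, c5 = 5, c6 = 100)
  fm <- toy_function_map()
  fm_reordered <- function_map(
    complexes = list(pmoCAB = c("pmoB", "pmoC", "pmoA"),
                     nar = "narG", nap = "napA"),
    reactions = fm$reactions, pathways = fm$pathways)
  cx1 <- complex_expression(tpm, cds, fm, "G1")
  cx2 <- complex_expression(tpm, cds, fm_reordered, "G1")
  expect_equal(cx1$value, cx2$value)
  for (k in c(0.5, 3)) {
    cxk <- complex_expression(tpm * k, cds, fm, "G1")
    expect_equal(cxk$value, cx1$value * k)
  }
  # additivity of alternates
  cx <- complex_expression(tpm, cds, fm, "G2")
  rx <- reaction_expression(cx, fm)
  expect_equal(rx$value[rx$reaction_id == "nitrate_reduction"],
               sum(cx$value[cx$complex_id %in% c("nar", "nap")]))
})

test_that("genome expression fractions sum to 100 and match truth", {
  cds <- toy_cds()
  tpm <- compute_tpm(c(c1 = 10, c2 = 5, c3 = 0, c4 = 30, c5 = 5,
                       c6 = 10),
                     cds$length)
  fr <- mag_expression_fraction(tpm, cds)
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  expect_true("unbinned" %in% names(fr))
  # one genome owning everything
  cds1 <- cds
  cds1$genome_id <- "G1"
  expect_equal(unname(mag_expression_fraction(tpm, cds1)), 100,
               tolerance = 1e-9)
  # two genomes with equal summed TPM split 50/50
  cds2 <- data.frame(cds_id = c("a", "b"), genome_id = c("GA", "GB"),
                     length = c(100, 100))
  expect_equal(unname(mag_expression_fraction(c(a = 5e5, b = 5e5), cds2)),
               c(50, 50))
})

test_that("mag_relative_abundance reports the unassigned remainder", {
  expect_equal(unname(mag_relative_abundance(c(g = 50), 100)[1]), 50)
  expect_equal(unname(mag_relative_abundance(c(g = 0), 100)[1]), 0)
  ab <- mag_relative_abundance(c(g1 = 40, g2 = 36), 100)
  expect_equal(unname(ab[["unmapped_or_unbinned"]]), 24)
  expect_equal(sum(ab), 100)
  expect_error(mag_relative_abundance(c(g = 120), 100), "exceed")
})

test_that("median relativization: log2 default, ratio option, flags", {
  cds <- data.frame(cds_id = paste0("c", 1:5), genome_id = "G1")
  tpm <- c(c1 = 10, c2 = 20, c3 = 40, c4 = 10, c5 = 0)
  rel <- relativize_to_median(tpm, cds)
  med <- stats::median(tpm)  # includes the zero
  expect_equal(rel$value[rel$cds_id == "c1"], log2(10 / med))
  expect_equal(rel$value[rel$cds_id == "c3"], log2(40 / med))
  # TPM equal to the median -> 0; twice the median -> 1
  tpm2 <- c(c1 = 10, c2 = 10, c3 = 10, c4 = 20, c5 = 10)
  rel2 <- relativize_to_median(tpm2, cds)
  expect_equal(rel2$value[rel2$cds_id == "c1"], 0)
  expect_equal(rel2$value[rel2$cds_id == "c4"], 1)
  # zero TPM is flagged undetectable, not -Inf
  expect_true(is.na(rel$value[rel$cds_id == "c5"]))
  expect_equal(rel$flag[rel$cds_id == "c5"], "undetectable")
  # ratio mode
  relr <- relativize_to_median(tpm2, cds, mode = "ratio")
  expect_equal(relr$value[relr$cds_id == "c4"], 2)
  # all-zero genome: everything flagged
  rel0 <- relativize_to_median(c(c1 = 0, c2 = 0, c3 = 0, c4 = 0, c5 = 0),
                               cds)
  expect_true(all(rel0$flag == "undetectable"))
})

test_that("function_map validates its hierarchy", {
  expect_error(function_map(complexes = list(x = character(0))),
               "empty member set")
  expect_error(function_map(complexes = list(a = "g1"),
                            reactions = list(r = "b")),
               "undefined complex")
  expect_error(function_map(complexes = list(a = "g1"),
                            reactions = list(r = "a"),
                            pathways = list(p = "zzz")),
               "undefined reaction")
})
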