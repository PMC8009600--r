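cfg <- caller_config()

test_that("line consensus applies depth, fraction and strand gates", {
  expect_equal(line_consensus(c(A = 15), cfg), "A")
  # 8/15 = 0.533 < 0.8
  expect_true(is.na(line_consensus(c(A = 8, G = 7), cfg)))
  expect_true(is.na(line_consensus(c(A = 9), cfg)))
  expect_equal(line_consensus(c(A = 9, G = 1), cfg), "A")
  # strand filter: majority base needs min_reads_per_strand on each strand
  expect_equal(line_consensus(c(A = 20), cfg, fwd = c(A = 10)), "A")
  expect_true(is.na(line_consensus(c(A = 20), cfg, fwd = c(A = 1))))
  expect_true(is.na(line_consensus(c(A = 20), cfg, fwd = c(A = 19))))
})

test_that("ancestral consensus requires a strict majority of called lines", {
  expect_equal(ancestral_consensus(c(rep("A", 51), "G"), cfg), "A")
  expect_true(is.na(ancestral_consensus(c("A", "A"), cfg)))
  expect_true(is.na(ancestral_consensus(c(rep("A", 26), rep("G", 26)), cfg)))
  expect_true(is.na(ancestral_consensus(rep(NA_character_, 10), cfg)))
})

ref12 <- "ACGTACGTACGTACGTACGT"

test_that("a divergent unanimous site yields one annotated call", {
  lines <- sprintf("L%02d", 1:12)
  pu <- uniform_pileup(ref12, lines, depth = 30,
                       edits = list(L03 = list(list(pos = 5, base = "G"))))
  g <- annotated_genome(c(c1 = ref12),
                        data.frame(contig = "c1", start = 1, end = 9,
                                   strand = "+", phase = 0))
  res <- call_mutations(pu, g, config = cfg)
  expect_equal(nrow(res$calls), 1L)
  call <- res$calls[1, ]
  expect_equal(call$line, "L03")
  expect_equal(call$pos, 5L)
  expect_equal(call$ref, "A")
  expect_equal(call$alt, "G")
  expect_equal(call$bps_type, "A:T>G:C")
  expect_equal(call$kind, "transition")
  expect_equal(call$context, "AT")
  expect_equal(call$region, "coding")
  expect_equal(unname(res$n_analyzed), rep(nchar(ref12), 12L))
})

test_that("no-called sites are excluded from a line's denominator", {
  lines <- sprintf("L%02d", 1:6)
  pu <- uniform_pileup(ref12, lines, depth = 30)
  # site 7 in L01: depth below the gate -> no-call there
  i <- pu$line == "L01" & pu$pos == 7
  pu[i, c("nA", "nC", "nG", "nT")] <- c(0, 0, 5, 0)
  res <- call_mutations(pu, annotated_genome(c(c1 = ref12)), config = cfg)
  expect_equal(unname(res$n_analyzed["L01"]), nchar(ref12) - 1L)
  expect_equal(unname(res$n_analyzed["L02"]), nchar(ref12))
  expect_equal(nrow(res$calls), 0L)
})

test_that("caller is invariant to pileup row order", {
  lines <- sprintf("L%02d", 1:8)
  pu <- uniform_pileup(ref12, lines, depth = 25,
                       edits = list(L02 = list(list(pos = 3, base = "T")),
                                    L05 = list(list(pos = 11, base = "C"))))
  g <- annotated_genome(c(c1 = ref12))
  res1 <- call_mutations(pu, g, config = cfg)
  set.seed(42)
  res2 <- call_mutations(pu[sample.int(nrow(pu)), ], g, config = cfg)
  expect_identical(res1$calls, res2$calls)
  expect_identical(res1$n_analyzed, res2$n_analyzed)
})

test_that("two lines divergent at one site each get their own call", {
  lines <- sprintf("L%02d", 1:10)
  pu <- uniform_pileup(ref12, lines, depth = 30,
                       edits = list(L01 = list(list(pos = 2, base = "A")),
                                    L02 = list(list(pos = 2, base = "T"))))
  res <- call_mutations(pu, annotated_genome(c(c1 = ref12)), config = cfg)
  expect_equal(nrow(res$calls), 2L)
  expect_setequal(res$calls$alt, c("A", "T"))
  expect_true(all(res$calls$ref == "C"))
})

test_that("indel divergence is called from the count columns", {
  lines <- sprintf("L%02d", 1:8)
  pu <- uniform_pileup(ref12, lines, depth = 30)
  pu$nIns[pu$line == "L01" & pu$pos == 4] <- 28L
  i <- pu$line == "L02" & pu$pos == 9
  pu[i, c("nA", "nC", "nG", "nT")] <- 0L
  pu$nDel[i] <- 30L
  res <- call_mutations(pu, annotated_genome(c(c1 = ref12)), config = cfg)
  idl <- res$calls[res$calls$class != "BPS", ]
  expect_equal(nrow(idl), 2L)
  expect_equal(idl$class[idl$line == "L01"], "INS")
  expect_equal(idl$pos[idl$line == "L01"], 4L)
  expect_equal(idl$class[idl$line == "L02"], "DEL")
  expect_equal(idl$pos[idl$line == "L02"], 9L)
})

test_that("pileups naming unknown contigs are rejected", {
  pu <- pile_row("L1", "cX", 1, A = 20)
  expect_error(call_mutations(pu, annotated_genome(c(c1 = "ACGT"))),
               "unknown contig")
})

test_that("line QC drops low-median-depth lines and reports breadth", {
  seq20 <- paste(rep("ACGT", 5), collapse = "")
  g <- annotated_genome(c(c1 = seq20))
  pu <- rbind(uniform_pileup(seq20, "good", depth = 25),
              uniform_pileup(seq20, "bad", depth = 12))
  qc <- qc_lines(pu, g, cfg)
  expect_true(qc$kept[qc$line == "good"])
  expect_false(qc$kept[qc$line == "bad"])
  expect_match(qc$reason[qc$line == "bad"], "median depth 12 < 20")
  expect_equal(qc$breadth, c(1, 1))
  # partial coverage: missing sites count as zero depth
  pu2 <- uniform_pileup(seq20, "half", depth = 30)[1:10, ]
  qc2 <- qc_lines(pu2, g, cfg)
  expect_equal(qc2$breadth, 0.5)
  expect_equal(qc2$median_depth, 15)  # median of 10 zeros + 10 thirties
})

test_that("a 73-line screen with 21 low-coverage lines keeps 52", {
  seq <- paste(rep("ACGTGGCCAT", 40), collapse = "")
  g <- annotated_genome(c(c1 = seq))
  set.seed(7)
  depths <- c(rep(30, 52), rep(10, 21))
  lines <- sprintf("photo%02d", seq_along(depths))
  pu <- do.call(rbind, lapply(seq_along(lines), function(i)
    uniform_pileup(seq, lines[i], depth = depths[i])))
  qc <- qc_lines(pu, g, cfg)
  expect_equal(sum(qc$kept), 52L)
  expect_equal(sum(!qc$kept), 21L)
})

test_that("contamination flags pairs by call-set Jaccard overlap", {
  mk <- function(line, pos) data.frame(line = line, contig = "c1",
                                       pos = pos, ref = "A", alt = "G",
                                       class = "BPS",
                                       stringsAsFactors = FALSE)
  # identical 5-call sets -> Jaccard 1
  calls <- rbind(mk("L1", 1:5), mk("L2", 1:5))
  fl <- flag_contamination(calls, cfg)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$jaccard, 1)
  # disjoint calls -> nothing flagged
  expect_equal(nrow(flag_contamination(rbind(mk("L1", 1:5),
                                             mk("L2", 6:10)), cfg)), 0L)
  # L1 and L2 share 3 of 4 calls (Jaccard 3/5 = 0.6); L3 is disjoint
  calls3 <- rbind(mk("L1", c(1, 2, 3, 4)), mk("L2", c(1, 2, 3, 9)),
                  mk("L3", 20:23))
  fl3 <- flag_contamination(calls3, cfg)
  expect_equal(nrow(fl3), 1L)
  expect_equal(sort(c(fl3$line1, fl3$line2)), c("L1", "L2"))
  expect_equal(fl3$jaccard, 0.6)
})

test_that("error-prone reads at adequate depth produce no false calls", {
  # 12 lines x 1e5 sites at depth ~50 with 1% per-read error:
  # expected false positives per 1e6 site-lines well below 1
  cfg_sim <- sim_config(genome_length = 1e5, gc = 0.42,
                        coding_fraction = 0, n_lines = 12,
                        divisions = 100,
                        rates = setNames(rep(0, 8), names(table2_counts())),
                        depth_mean = 50, depth_dispersion = 10,
                        error_rate = 0.01, seed = 303)
  g <- generate_genome(cfg_sim)
  tr <- plant_mutations(g, cfg_sim)
  expect_equal(nrow(tr$truth), 0L)
  pu <- simulate_pileups(g, tr, cfg_sim)
  res <- call_mutations(pu, g, config = cfg)
  expect_lte(nrow(res$calls), 1L)
})
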