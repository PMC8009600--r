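small_cfg <- function(seed, ...) {
  sim_config_scaled(seed = seed, genome_length = 30000, n_lines = 6, ...)
}

test_that("all simulators are deterministic functions of the seed", {
  cfg <- small_cfg(21)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  t1 <- plant_mutations(g1, cfg)
  expect_identical(t1, plant_mutations(g1, cfg))
  p1 <- simulate_pileups(g1, t1, cfg)
  expect_identical(p1, simulate_pileups(g1, t1, cfg))
  expect_identical(simulate_cfu(19.5, 5, 0.5, seed = 4),
                   simulate_cfu(19.5, 5, 0.5, seed = 4))
  mask <- fourfold_sites(g1)
  expect_identical(simulate_strains(g1, mask, 0.05, 3, seed = 9),
                   simulate_strains(g1, mask, 0.05, 3, seed = 9))
  # a different seed changes the genome
  expect_false(identical(g1$contigs,
                         generate_genome(small_cfg(22))$contigs))
})

test_that("generated genomes respect composition and gene-model contracts", {
  cfg <- sim_config(genome_length = 3000, gc = 0.42,
                    coding_fraction = 0.5, n_lines = 2, divisions = 10,
                    seed = 1)
  g <- generate_genome(cfg)
  expect_equal(sum(nchar(g$contigs)), 3000)
  expect_lt(abs(g$gc_fraction - 0.42), 0.03)

  # no annotation when coding fraction is zero
  g0 <- generate_genome(sim_config(genome_length = 1000, gc = 0.5,
                                   coding_fraction = 0, n_lines = 2,
                                   divisions = 10, seed = 1))
  expect_equal(nrow(g0$genes), 0L)

  # CDS: in bounds, non-overlapping, length % 3 == 0, ATG start on its
  # strand, no internal stop codons
  cfg2 <- small_cfg(31)
  g2 <- generate_genome(cfg2)
  genes <- g2$genes
  expect_gt(nrow(genes), 10)
  expect_true(all(genes$end <= nchar(g2$contigs[genes$contig])))
  expect_true(all((genes$end - genes$start + 1) %% 3 == 0))
  o <- order(genes$start)
  expect_true(all(genes$start[o][-1] > genes$end[o][-nrow(genes)]))
  for (i in seq_len(nrow(genes))) {
    s <- substr(g2$contigs[[genes$contig[i]]], genes$start[i], genes$end[i])
    if (genes$strand[i] == "-")
      s <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "",
                              fixed = TRUE)[[1]]), collapse = "")
    expect_equal(substr(s, 1, 3), "ATG")
    ncod <- nchar(s) / 3
    cods <- substring(s, 3 * (1:ncod) - 2, 3 * (1:ncod))
    expect_false(any(cods[-c(1, ncod)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("planted mutation counts follow their Poisson expectations", {
  # many lines on a small genome: total count per class ~ Poisson with
  # mean rate x context sites x T x lines
  cfg <- sim_config(genome_length = 20000, gc = 0.4239,
                    coding_fraction = 0, n_lines = 300, divisions = 500,
                    rates = c("G:C>A:T" = 2e-8,
                                              "A:T>G:C" = 0,
                                               "A:T>T:A" = 0,
                                               "G:C>T:A" = 0,
                                               "A:T>C:G" = 0,
                                               "G:C>C:G" = 0,
                                               insertion = 0,
                                               deletion = 0),
                    depth_mean = 10, seed = 77)
  g <- generate_genome(cfg)
  tr <- plant_mutations(g, cfg)
  s_gc <- round(g$gc_fraction * 20000)
  lambda <- 2e-8 * s_gc * 500 * 300
  expect_lt(abs(nrow(tr$truth) - lambda), 3 * sqrt(lambda))
  expect_true(all(tr$truth$bps_type == "G:C>A:T"))
  # internal consistency: classes re-derived from (ref, alt) match
  rederived <- bps_class(tr$truth$ref, tr$truth$alt)
  expect_identical(rederived, tr$truth$bps_type)
  expect_equal(unname(tr$class_counts["G:C>A:T"]), nrow(tr$truth),
               ignore_attr = TRUE)
  # no site hit twice within a line
  expect_false(any(duplicated(tr$truth[c("line", "pos")])))

  # zero rates -> empty truth set
  cfg0 <- sim_config(genome_length = 5000, coding_fraction = 0,
                     n_lines = 5, divisions = 10,
                     rates = setNames(rep(0, 8), names(table2_counts())),
                     seed = 3)
  g0 <- generate_genome(cfg0)
  expect_equal(nrow(plant_mutations(g0, cfg0)$truth), 0L)
})

test_that("error-free pileups reproduce each line's genome exactly", {
  cfg <- small_cfg(41, error_rate = 0, genome_length = 5000,
                   n_lines = 3, rates = default_rates() * 2e5)
  g <- generate_genome(cfg)
  tr <- plant_mutations(g, cfg)
  expect_gt(nrow(tr$truth), 0)
  pu <- simulate_pileups(g, tr, cfg)
  chars <- strsplit(g$contigs[[1]], "", fixed = TRUE)[[1]]
  for (l in unique(pu$line)) {
    rows <- pu[pu$line == l, ]
    tl <- tr$truth[tr$truth$line == l & tr$truth$class == "BPS", ]
    want <- chars
    want[tl$pos] <- tl$alt
    cm <- as.matrix(rows[, c("nA", "nC", "nG", "nT")])
    maj <- c("A", "C", "G", "T")[max.col(cm, ties.method = "first")]
    covered <- rowSums(cm) > 0
    expect_identical(maj[covered], want[covered])
  }
})

test_that("negative binomial depth hits its configured mean", {
  cfg <- sim_config(genome_length = 1e5, coding_fraction = 0,
                    n_lines = 1, divisions = 10,
                    rates = setNames(rep(0, 8), names(table2_counts())),
                    depth_mean = 163, depth_dispersion = 10, seed = 5)
  g <- generate_genome(cfg)
  pu <- simulate_pileups(g, plant_mutations(g, cfg), cfg)
  d <- pu$nA + pu$nC + pu$nG + pu$nT
  expect_lt(abs(mean(d) - 163) / 163, 0.01)
})

test_that("indel pileup columns carry the planted indel support", {
  cfg <- small_cfg(51, genome_length = 5000, n_lines = 4,
                   rates = setNames(c(rep(0, 6), 2e-5, 2e-5),
                                    names(table2_counts())))
  g <- generate_genome(cfg)
  tr <- plant_mutations(g, cfg)
  ins <- tr$truth[tr$truth$class == "INS", ]
  del <- tr$truth[tr$truth$class == "DEL", ]
  expect_gt(nrow(ins) + nrow(del), 0)
  pu <- simulate_pileups(g, tr, cfg)
  for (i in seq_len(nrow(ins))) {
    row <- pu[pu$line == ins$line[i] & pu$pos == ins$pos[i], ]
    expect_gt(row$nIns, 0)
  }
  for (i in seq_len(nrow(del))) {
    row <- pu[pu$line == del$line[i] & pu$pos == del$pos[i], ]
    expect_gt(row$nDel, row$nA + row$nC + row$nG + row$nT)
  }
})

test_that("CFU simulation inverts through division estimation", {
  cfu <- simulate_cfu(19.5, n = 10, sd = 0, seed = 1)
  expect_true(all(cfu == 741455))
  d <- estimate_divisions(cfu, transfers = 232)
  expect_equal(d$mean_divisions, 19.5, tolerance = 1e-3)
  expect_equal(simulate_cfu(19.5, n = 0, sd = 0.5, seed = 1), numeric())
})

test_that("strain simulation matches the pairwise mismatch expectation", {
  cfg <- small_cfg(61)
  g <- generate_genome(cfg)
  mask <- fourfold_sites(g)
  d <- 0.1
  s <- simulate_strains(g, mask, d, 2, seed = 62)
  res <- theta_fourfold(s, mask)
  q <- 2 * d * (1 - d) + (2 / 3) * d^2
  se <- sqrt(q * (1 - q) / res$n_sites)
  expect_lt(abs(res$theta - q), 3 * se)
  # non-masked sites untouched
  chars <- strsplit(g$contigs[[1]], "", fixed = TRUE)[[1]]
  s1 <- strsplit(s[[1]], "", fixed = TRUE)[[1]]
  off_mask <- setdiff(seq_along(chars), mask$pos)
  expect_identical(s1[off_mask], chars[off_mask])
})
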