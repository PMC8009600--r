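# shared fixture builders; everything is generated in code

# 12 bp two-contig genome with one plus-strand CDS
tiny_genome <- function() {
  annotated_genome(
    c(c1 = "ACGTACGTACGT", c2 = "GGGCCCAAATTT"),
    data.frame(contig = "c1", start = 4, end = 9, strand = "+", phase = 0)
  )
}

# one pileup row; unspecified counts are zero
pile_row <- function(line, contig, pos, A = 0, C = 0, G = 0, T = 0,
                     Ins = 0, Del = 0) {
  data.frame(line = line, contig = contig, pos = pos,
             nA = A, nC = C, nG = G, nT = T, nIns = Ins, nDel = Del,
             stringsAsFactors = FALSE)
}

# uniform-depth pileup for a set of lines over positions 1..len of a
# single-contig genome given as a character string; every line matches
# `seq` except where `edits` (list of line -> list(pos = , base = ))
# says otherwise
uniform_pileup <- function(seq, lines, depth, edits = list()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  rows <- lapply(lines, function(l) {
    b <- chars
    for (e in edits[[l]]) b[e$pos] <- e$base
    data.frame(line = l, contig = "c1", pos = seq_along(b),
               nA = depth * (b == "A"), nC = depth * (b == "C"),
               nG = depth * (b == "G"), nT = depth * (b == "T"),
               nIns = 0L, nDel = 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# random valid pileup table for round-trip tests
random_pileup <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(line = sample(sprintf("L%d", 1:3), n, replace = TRUE),
             contig = "c1",
             pos = sample.int(10 * n, n),
             nA = rpois(n, 5), nC = rpois(n, 5), nG = rpois(n, 5),
             nT = rpois(n, 5), nIns = rpois(n, 0.2),
             nDel = rpois(n, 0.2), stringsAsFactors = FALSE)
}

# Table-2-style count vector used across spectrum tests
table2_counts <- function() {
  c("G:C>A:T" = 30, "A:T>G:C" = 7, "A:T>T:A" = 1,
    "G:C>T:A" = 23, "A:T>C:G" = 0, "G:C>C:G" = 11,
    insertion = 4, deletion = 6)
}

study_denominator <- function() site_divisions(5171217, 4517, n_lines = 52)
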