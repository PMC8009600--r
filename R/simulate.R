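# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# observed per-class conditional rates (per site per division)
DEFAULT_RATES <- c("G:C>A:T" = 5.84e-11, "A:T>G:C" = 1.00e-11,
                   "A:T>T:A" = 0.14e-11, "G:C>T:A" = 4.47e-11,
                   "A:T>C:G" = 0,        "G:C>C:G" = 2.14e-11,
                   insertion = 0.33e-11, deletion = 0.49e-11)

#' Default per-class mutation rates for simulation
#'
#' The per-class conditional rates (substitutions) and unconditioned
#' rates (indels), per site per cell division, used as [sim_config()]
#' defaults; they reflect the spectrum observed in a low-mutation-rate
#' bacterial MA experiment.
#'
#' @return named numeric vector over the eight mutation classes.
#' @export
default_rates <- function() DEFAULT_RATES

#' Simulation configuration for a synthetic MA experiment
#'
#' Defaults mirror the design of a bacterial MA study: 52 lines over
#' 4517 cell divisions on a 5.17 Mb genome at 42.39% GC sequenced to
#' ~163x, with per-class conditional mutation rates of order
#' 1e-12 to 1e-10 per site per division and a 13-strain diversity
#' panel. [sim_config_scaled()] gives a reduced configuration for fast
#' full-pipeline runs.
#'
#' @param genome_length genome size in bp (single contig).
#' @param gc target G+C fraction.
#' @param coding_fraction fraction of the genome covered by CDS.
#' @param n_lines number of MA lines.
#' @param divisions cell divisions per line (T).
#' @param rates named per-class true rates: conditional per-context
#'   rates for the six substitution classes, unconditioned rates for
#'   `insertion` and `deletion`.
#' @param depth_mean,depth_dispersion negative-binomial read-depth
#'   model (mean and size parameter).
#' @param error_rate per-read per-base sequencing error probability.
#' @param n_strains strains in the simulated diversity alignment.
#' @param strain_density per-strain substitution probability at each
#'   four-fold site (default 0.042, giving pairwise diversity near
#'   0.08).
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5171217, gc = 0.4239,
                       coding_fraction = 0.865, n_lines = 52,
                       divisions = 4517, rates = DEFAULT_RATES,
                       depth_mean = 163, depth_dispersion = 10,
                       error_rate = 0.003, n_strains = 13,
                       strain_density = 0.042, seed = NULL) {
  stopifnot(genome_length >= 300, gc >= 0, gc <= 1,
            coding_fraction >= 0, coding_fraction <= 1,
            n_lines >= 1, divisions > 0, all(rates >= 0),
            depth_mean >= 1, depth_dispersion > 0,
            error_rate >= 0, error_rate < 1,
            n_strains >= 2, strain_density >= 0, strain_density <= 0.75)
  miss <- setdiff(MUTATION_CLASSES, names(rates))
  if (length(miss))
    stop("rates must name every class; missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (coding_fraction > 0.95)
    stop("coding_fraction above 0.95 cannot be placed", call. = FALSE)
  if (is.null(seed)) stop("sim_config requires an explicit seed",
                          call. = FALSE)
  structure(list(genome_length = genome_length, gc = gc,
                 coding_fraction = coding_fraction, n_lines = n_lines,
                 divisions = divisions, rates = rates[MUTATION_CLASSES],
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate, n_strains = n_strains,
                 strain_density = strain_density,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Reduced-scale simulation configuration
#'
#' A 0.5 Mb genome, 20 lines, 500 divisions and per-class rates scaled
#' up 100-fold (so the expected mutation yield stays in the tens), with
#' 60x depth — a configuration sized for quick end-to-end recovery
#' runs.
#'
#' @param seed mandatory integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return list of class `sim_config`.
#' @export
sim_config_scaled <- function(seed = NULL, ...) {
  args <- list(genome_length = 5e5, n_lines = 20, divisions = 500,
               rates = DEFAULT_RATES * 100, depth_mean = 60,
               depth_dispersion = 10, error_rate = 0.003, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

#' Generate a random annotated genome
#'
#' Bases are drawn i.i.d. at the configured GC fraction; CDS of random
#' strand are placed without overlap to approximately the configured
#' coding fraction. Each CDS starts with ATG on its own strand, has
#' length divisible by three and contains no internal stop codon
#' (offending codons are resampled).
#'
#' @param config a [sim_config()].
#' @return an [annotated_genome] with a single contig `"sim1"`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$genome_length
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    chars <- sample(BASES, L, replace = TRUE, prob = p)
    genes <- NULL
    if (config$coding_fraction > 0) {
      target <- config$coding_fraction * L
      mean_len <- 854
      mean_gap <- max(1, mean_len * (1 - config$coding_fraction) /
                        config$coding_fraction)
      starts <- integer(); ends <- integer()
      cursor <- 1L; placed <- 0
      while (placed < target) {
        gap <- 1L + as.integer(round(stats::rexp(1, 1 / mean_gap)))
        len <- 3L * pmax(34L, as.integer(round(stats::rnorm(1, mean_len / 3,
                                                            60))))
        st <- cursor + gap
        en <- st + len - 1L
        if (en > L) break
        starts <- c(starts, st); ends <- c(ends, en)
        placed <- placed + len
        cursor <- en + 1L
      }
      if (!length(starts))
        stop("genome too short to place any CDS at this coding fraction",
             call. = FALSE)
      strand <- sample(c("+", "-"), length(starts), replace = TRUE)
      genes <- data.frame(contig = "sim1", start = starts, end = ends,
                          strand = strand, phase = 0L,
                          stringsAsFactors = FALSE)
      stops <- c("TAA", "TAG", "TGA")
      for (i in seq_along(starts)) {
        len <- ends[i] - starts[i] + 1L
        ncod <- len %/% 3L
        body <- sample(BASES, len, replace = TRUE, prob = p)
        body[1:3] <- c("A", "T", "G")
        cod_start <- 3L * (seq_len(ncod) - 1L) + 1L
        repeat {
          cods <- paste0(body[cod_start], body[cod_start + 1L],
                         body[cod_start + 2L])
          bad <- which(cods[-c(1L, ncod)] %in% stops) + 1L
          if (!length(bad)) break
          for (b in bad) {
            body[cod_start[b] + 0:2] <- sample(BASES, 3, replace = TRUE,
                                               prob = p)
          }
        }
        # last codon made a stop so translation-minded tools see a full ORF
        body[cod_start[ncod] + 0:2] <- strsplit(sample(stops, 1), "")[[1]]
        if (strand[i] == "-")
          body <- rev(chartr("ACGT", "TGCA", body))
        chars[starts[i]:ends[i]] <- body
      }
    }
    annotated_genome(setNames(paste(chars, collapse = ""), "sim1"), genes)
  })
}

ALT_MAP <- list("G:C>A:T" = c(G = "A", C = "T"),
                "G:C>T:A" = c(G = "T", C = "A"),
                "G:C>C:G" = c(G = "C", C = "G"),
                "A:T>G:C" = c(A = "G", T = "C"),
                "A:T>C:G" = c(A = "C", T = "G"),
                "A:T>T:A" = c(A = "T", T = "A"))

#' Plant mutations into MA lines
#'
#' Per line and class, the planted count is Poisson with mean
#' (conditional rate x context sites x divisions) for substitutions and
#' (rate x genome length x divisions) for 1 bp indels; positions are
#' uniform over the class's context sites and no site is hit twice in
#' one line.
#'
#' @param genome an [annotated_genome] (typically from
#'   [generate_genome()]).
#' @param config a [sim_config()].
#' @return list of class `truth_set`: `truth` (data frame `line`,
#'   `contig`, `pos`, `ref`, `alt`, `class`, `bps_type`),
#'   `class_counts`, and `true_rates` (the configured per-class rates).
#' @export
plant_mutations <- function(genome, config) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(config, "sim_config"))
  ct <- names(genome$contigs)[1]
  chars <- strsplit(genome$contigs[[ct]], "", fixed = TRUE)[[1]]
  gc_sites <- which(chars %in% c("G", "C"))
  at_sites <- which(chars %in% c("A", "T"))
  L <- length(chars)
  TT <- config$divisions
  with_seed(config$seed + 1L, {
    rows <- list()
    for (l in seq_len(config$n_lines)) {
      line <- sprintf("line%02d", l)
      taken <- integer()
      for (cl in MUTATION_CLASSES) {
        r <- config$rates[[cl]]
        if (r == 0) next
        sites <- if (cl %in% GC_CONTEXT_CLASSES) gc_sites
                 else if (cl %in% AT_CONTEXT_CLASSES) at_sites
                 else seq_len(L)
        k <- stats::rpois(1, r * length(sites) * TT)
        if (k == 0) next
        pos <- sample(sites, k)
        repeat {
          bad <- duplicated(pos) | pos %in% taken
          if (!any(bad)) break
          pos[bad] <- sample(sites, sum(bad))
        }
        taken <- c(taken, pos)
        ref <- chars[pos]
        if (cl %in% BPS_CLASSES) {
          alt <- unname(ALT_MAP[[cl]][ref])
          rows[[length(rows) + 1L]] <-
            data.frame(line = line, contig = ct, pos = pos, ref = ref,
                       alt = alt, class = "BPS", bps_type = cl,
                       stringsAsFactors = FALSE)
        } else if (cl == "insertion") {
          rows[[length(rows) + 1L]] <-
            data.frame(line = line, contig = ct, pos = pos, ref = ref,
                       alt = sample(BASES, k, replace = TRUE),
                       class = "INS", bps_type = NA_character_,
                       stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <-
            data.frame(line = line, contig = ct, pos = pos, ref = ref,
                       alt = NA_character_, class = "DEL",
                       bps_type = NA_character_,
                       stringsAsFactors = FALSE)
        }
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows)
             else data.frame(line = character(), contig = character(),
                             pos = integer(), ref = character(),
                             alt = character(), class = character(),
                             bps_type = character(),
                             stringsAsFactors = FALSE)
    truth <- truth[order(truth$line, truth$pos), ]
    rownames(truth) <- NULL
    cc <- table(factor(ifelse(truth$class == "BPS", truth$bps_type,
                              ifelse(truth$class == "INS", "insertion",
                                     "deletion")),
                       levels = MUTATION_CLASSES))
    structure(list(truth = truth, class_counts = cc,
                   true_rates = config$rates),
              class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Planted truth set:", nrow(x$truth), "mutation(s)\n")
  print(x$class_counts)
  invisible(x)
}

#' Apply a line's planted mutations to the reference
#'
#' Returns the line's true base at every position (substitutions
#' applied; indels tracked separately by the pileup simulator).
#'
#' @param chars reference sequence as a character vector.
#' @param truth_line truth rows for one line.
#' @return character vector of per-site true bases.
#' @keywords internal
apply_bps <- function(chars, truth_line) {
  b <- truth_line[truth_line$class == "BPS", , drop = FALSE]
  if (nrow(b)) chars[b$pos] <- b$alt
  chars
}

#' Simulate pileup tables with sequencing error
#'
#' Per line and site, depth is negative binomial; each read reports the
#' line's true base, flipped to one of the three other bases with the
#' configured error probability. At planted indel sites the
#' supporting-read counts land in `nIns`/`nDel`.
#'
#' @param genome an [annotated_genome].
#' @param truth a `truth_set` from [plant_mutations()].
#' @param config a [sim_config()].
#' @param lines optional subset of line ids to simulate.
#' @return a `pileup_table` data frame covering every site of every
#'   line.
#' @export
simulate_pileups <- function(genome, truth, config, lines = NULL) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(truth, "truth_set"),
            inherits(config, "sim_config"))
  ct <- names(genome$contigs)[1]
  ref_chars <- strsplit(genome$contigs[[ct]], "", fixed = TRUE)[[1]]
  L <- length(ref_chars)
  if (is.null(lines)) lines <- sprintf("line%02d", seq_len(config$n_lines))
  e <- config$error_rate
  nl <- length(lines)
  n <- nl * L
  tr <- truth$truth[truth$truth$line %in% lines, , drop = FALSE]
  li_of <- match(tr$line, lines)
  gp <- (li_of - 1L) * L + tr$pos  # global row index per truth entry
  with_seed(config$seed + 2L, {
    # true base per (line, site), substitutions applied in place
    bidx <- rep.int(match(ref_chars, BASES), nl)
    is_bps <- tr$class == "BPS"
    bidx[gp[is_bps]] <- match(tr$alt[is_bps], BASES)
    depth <- stats::rnbinom(n, size = config$depth_dispersion,
                            mu = config$depth_mean)
    cols <- lapply(1:4, function(b) depth * (bidx == b))
    if (e > 0) {
      nerr <- stats::rbinom(n, depth, e)
      # rows carrying at least one error are a small minority; only
      # they need their counts redistributed
      i <- which(nerr > 0L)
      if (length(i)) {
        ne <- nerr[i]; bi <- bidx[i]
        # errors split uniformly over the three non-true bases
        e1 <- stats::rbinom(length(i), ne, 1 / 3)
        e2 <- stats::rbinom(length(i), ne - e1, 1 / 2)
        e3 <- ne - e1 - e2
        w1 <- bi %% 4L + 1L
        w2 <- (bi + 1L) %% 4L + 1L
        w3 <- (bi + 2L) %% 4L + 1L
        for (b in 1:4) {
          adj <- -ne * (bi == b) + e1 * (w1 == b) + e2 * (w2 == b) +
            e3 * (w3 == b)
          cols[[b]][i] <- cols[[b]][i] + adj
        }
      }
    }
    nIns <- integer(n); nDel <- integer(n)
    ins <- which(tr$class == "INS")
    if (length(ins))
      nIns[gp[ins]] <- stats::rbinom(length(ins), depth[gp[ins]], 1 - e)
    del <- which(tr$class == "DEL")
    if (length(del)) {
      i <- gp[del]
      nd <- stats::rbinom(length(del), depth[i], 1 - e)
      nDel[i] <- nd
      # non-deletion reads at a deleted site still show the old base
      refb <- match(tr$ref[del], BASES)
      for (b in 1:4) cols[[b]][i] <- ifelse(refb == b, depth[i] - nd, 0L)
    }
    as_pileup(data.frame(line = rep(lines, each = L), contig = ct,
                         pos = rep.int(seq_len(L), nl),
                         nA = cols[[1]], nC = cols[[2]],
                         nG = cols[[3]], nT = cols[[4]],
                         nIns = nIns, nDel = nDel,
                         stringsAsFactors = FALSE))
  })
}

#' Simulate colony-forming-unit counts
#'
#' CFU = round(2^N(mean, sd)) per sampled colony, the forward model
#' inverted by [estimate_divisions()].
#'
#' @param mean_divisions true mean divisions per transfer.
#' @param n number of sampled colonies.
#' @param sd standard deviation of the per-colony division estimate.
#' @param seed integer seed.
#' @return numeric vector of CFU counts.
#' @export
simulate_cfu <- function(mean_divisions = 19.5, n = 10, sd = 0.5,
                         seed = NULL) {
  stopifnot(sd >= 0, n >= 0)
  if (n == 0) return(numeric())
  with_seed(seed, round(2^stats::rnorm(n, mean_divisions, sd)))
}

#' Simulate a diverged strain alignment
#'
#' Each strain independently substitutes each masked (four-fold) site
#' with probability `density` to a uniformly chosen different base;
#' all other sites are untouched. The output is a gapless alignment in
#' reference coordinates.
#'
#' @param genome an [annotated_genome].
#' @param mask a [fourfold_sites()] mask.
#' @param density per-site substitution probability.
#' @param n_strains number of strains.
#' @param seed integer seed.
#' @return named character vector of aligned sequences
#'   (`strain01`, ...).
#' @export
simulate_strains <- function(genome, mask, density, n_strains,
                             seed = NULL) {
  stopifnot(density >= 0, density <= 0.75, n_strains >= 2)
  ct <- names(genome$contigs)[1]
  ref_chars <- strsplit(genome$contigs[[ct]], "", fixed = TRUE)[[1]]
  pos <- if (is.data.frame(mask)) mask$pos[mask$contig == ct]
         else as.integer(mask)
  with_seed(seed, {
    out <- vapply(seq_len(n_strains), function(s) {
      chars <- ref_chars
      hit <- pos[stats::runif(length(pos)) < density]
      if (length(hit)) {
        old <- match(chars[hit], BASES)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        chars[hit] <- BASES[(old - 1L + shift) %% 4L + 1L]
      }
      paste(chars, collapse = "")
    }, character(1))
    setNames(out, sprintf("strain%02d", seq_len(n_strains)))
  })
}
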