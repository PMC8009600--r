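BASES <- c("A", "C", "G", "T")

#' Caller configuration
#'
#' Thresholds for the consensus mutation caller and the line-level QC
#' screens. Defaults follow the consensus-calling conventions of the MA
#' literature; they are deliberately configuration, not constants.
#'
#' @param min_depth_line minimum read depth at a site for a line-level
#'   consensus base (default 10).
#' @param min_consensus_fraction minimum fraction of reads supporting
#'   the majority allele (default 0.8; must exceed 0.5 so a consensus is
#'   unique).
#' @param min_reads_per_strand minimum reads on each strand supporting
#'   the consensus base; applied only when the pileup carries
#'   forward-strand columns (default 2).
#' @param min_lines_for_ancestral minimum number of lines with a called
#'   consensus before an ancestral state is declared (default 3).
#' @param line_min_median_depth lines with median depth below this are
#'   dropped by QC (default 20).
#' @param contamination_shared_fraction Jaccard overlap of two lines'
#'   call sets at or above which the pair is flagged as putative
#'   cross-contamination (default 0.5).
#' @return list of class `caller_config`.
#' @export
caller_config <- function(min_depth_line = 10,
                          min_consensus_fraction = 0.8,
                          min_reads_per_strand = 2,
                          min_lines_for_ancestral = 3,
                          line_min_median_depth = 20,
                          contamination_shared_fraction = 0.5) {
  stopifnot(min_consensus_fraction > 0.5, min_consensus_fraction <= 1,
            contamination_shared_fraction > 0,
            contamination_shared_fraction <= 1,
            min_depth_line >= 1, line_min_median_depth >= 1,
            min_lines_for_ancestral >= 1, min_reads_per_strand >= 0)
  structure(list(min_depth_line = min_depth_line,
                 min_consensus_fraction = min_consensus_fraction,
                 min_reads_per_strand = min_reads_per_strand,
                 min_lines_for_ancestral = min_lines_for_ancestral,
                 line_min_median_depth = line_min_median_depth,
                 contamination_shared_fraction = contamination_shared_fraction),
            class = "caller_config")
}

#' Line-level consensus base at one site
#'
#' Returns the majority base if the site passes the depth, consensus
#' fraction and (when strand counts are supplied) per-strand support
#' filters, otherwise `NA` (no-call).
#'
#' @param counts named numeric vector of read counts with names among
#'   `A`, `C`, `G`, `T`.
#' @param config a [caller_config()].
#' @param fwd optional named vector of forward-strand counts for the
#'   same bases; reverse counts are `counts - fwd`.
#' @return a single base as character, or `NA_character_` for no-call.
#' @export
line_consensus <- function(counts, config = caller_config(), fwd = NULL) {
  full <- setNames(numeric(4), BASES)
  full[names(counts)[names(counts) %in% BASES]] <-
    counts[names(counts) %in% BASES]
  depth <- sum(full)
  if (depth < config$min_depth_line) return(NA_character_)
  maj <- which.max(full)
  if (full[maj] / depth < config$min_consensus_fraction) return(NA_character_)
  if (!is.null(fwd)) {
    f <- setNames(numeric(4), BASES)
    f[names(fwd)[names(fwd) %in% BASES]] <- fwd[names(fwd) %in% BASES]
    if (f[maj] < config$min_reads_per_strand ||
        full[maj] - f[maj] < config$min_reads_per_strand)
      return(NA_character_)
  }
  BASES[maj]
}

#' Ancestral consensus across lines at one site
#'
#' The ancestral state is the strict-majority base (> 50% of called
#' lines); ties and sites with too few called lines give no-call.
#'
#' @param bases character vector of per-line consensus bases; `NA`
#'   entries (no-calls) are ignored.
#' @param config a [caller_config()].
#' @return a single base, or `NA_character_` for no-call.
#' @export
ancestral_consensus <- function(bases, config = caller_config()) {
  bases <- bases[!is.na(bases)]
  n <- length(bases)
  if (n < config$min_lines_for_ancestral) return(NA_character_)
  tab <- table(bases)
  top <- which.max(tab)
  if (tab[top] * 2L <= n) return(NA_character_)
  names(tab)[top]
}

# vectorised per-row consensus over a count matrix (rows = pileup rows,
# cols = A,C,G,T). Returns integer codes 1..4, 0 = no-call.
row_consensus_code <- function(cm, config, fwd = NULL,
                               depth = NULL) {
  if (is.null(depth)) depth <- rowSums(cm)
  # with min_consensus_fraction > 0.5 a tied maximum can never pass the
  # fraction gate, so the first argmax is safe
  code <- max.col(cm, ties.method = "first")
  maxc <- cm[cbind(seq_along(code), code)]
  ok <- depth >= config$min_depth_line &
    maxc >= config$min_consensus_fraction * depth
  if (!is.null(fwd)) {
    fmaj <- fwd[cbind(seq_len(nrow(fwd)), code)]
    ok <- ok & fmaj >= config$min_reads_per_strand &
      (maxc - fmaj) >= config$min_reads_per_strand
  }
  code[!ok] <- 0L
  code
}

# vectorised per-row indel status: 1 = none, 2 = insertion, 3 = deletion,
# 0 = undefined (insufficient depth or ambiguous)
row_indel_status <- function(cm, nIns, nDel, config, depth = NULL) {
  if (is.null(depth)) depth <- rowSums(cm)
  ins_ok <- depth >= config$min_depth_line &
    nIns >= config$min_consensus_fraction * depth
  dd <- depth + nDel
  del_ok <- dd >= config$min_depth_line &
    nDel >= config$min_consensus_fraction * dd
  st <- rep(0L, length(depth))
  st[depth >= config$min_depth_line] <- 1L
  st[ins_ok] <- 2L
  st[del_ok] <- 3L
  st[ins_ok & del_ok] <- 0L
  st
}

# strict-majority code per column of an L x S integer code matrix;
# codes in 1..k, 0 = no-call. Returns 0 where called < min_n or no code
# exceeds half the called lines.
column_majority <- function(m, k, min_n) {
  called <- colSums(m > 0L)
  best <- rep(0L, ncol(m))
  bestc <- rep(0L, ncol(m))
  for (code in seq_len(k)) {
    cnt <- colSums(m == code)
    upd <- cnt > bestc
    best[upd] <- code
    bestc[upd] <- cnt[upd]
  }
  best[bestc * 2L <= called | called < min_n] <- 0L
  best
}

#' Call mutations across MA lines by cross-line consensus
#'
#' For every site, each line's consensus allele is compared with the
#' ancestral state, taken as the strict cross-line majority of line
#' consensuses (so an assembly error in the reference cannot create a
#' call). A base-substitution call is emitted where a line's called
#' consensus differs from a defined ancestral base; insertion/deletion
#' calls are made analogously from the `nIns`/`nDel` columns under the
#' same depth and fraction thresholds. Calls are annotated with their
#' reference-pair context (`AT`/`GC`), one of the six strand-symmetric
#' substitution classes, transition/transversion kind and
#' coding/non-coding region.
#'
#' @param pileups pileup table (see [read_pileup()]) covering one or
#'   more lines.
#' @param genome an [annotated_genome].
#' @param annotation optional CDS data frame overriding `genome$genes`.
#' @param config a [caller_config()].
#' @return list of class `ma_calls` with elements
#'   \describe{
#'     \item{calls}{data frame: `line`, `contig`, `pos`, `ref`, `alt`,
#'       `class` (`BPS`/`INS`/`DEL`), `context`, `bps_type`, `kind`,
#'       `region`.}
#'     \item{n_analyzed}{named integer vector: per line, the number of
#'       sites with both a called line consensus and a defined ancestral
#'       state — the site count entering the rate denominator.}
#'   }
#' @export
call_mutations <- function(pileups, genome, annotation = NULL,
                           config = caller_config()) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!is.null(annotation)) {
    genome$genes <- validate_cds(annotation, genome$contigs)
  }
  pu <- as.data.frame(pileups)
  unknown <- setdiff(unique(pu$contig), names(genome$contigs))
  if (length(unknown))
    stop("pileup references unknown contig '", unknown[1], "'",
         call. = FALSE)
  clen <- nchar(genome$contigs)
  if (any(pu$pos > clen[pu$contig]))
    stop("pileup position beyond contig end", call. = FALSE)

  lines <- sort(unique(pu$line))
  cts <- sort(unique(pu$contig))
  # numeric site key (contig index, position) avoids string pasting on
  # whole-genome pileups; positions stay well under 2^53 / n_contigs
  M <- max(pu$pos) + 1
  key <- if (length(cts) == 1L) pu$pos
         else (match(pu$contig, cts) - 1) * M + pu$pos
  ukey <- if (is.integer(key)) which(tabulate(key, max(key)) > 0L)
          else sort(unique(key))
  sidx <- match(key, ukey)
  lidx <- match(pu$line, lines)
  L <- length(lines); S <- length(ukey)

  cm <- cbind(pu$nA, pu$nC, pu$nG, pu$nT)
  depth <- pu$nA + pu$nC + pu$nG + pu$nT
  fwd <- if (all(PILEUP_FWD_COLS %in% names(pu)))
    cbind(pu$fA, pu$fC, pu$fG, pu$fT) else NULL
  code <- row_consensus_code(cm, config, fwd, depth = depth)
  istat <- row_indel_status(cm, pu$nIns, pu$nDel, config, depth = depth)

  cons <- matrix(0L, L, S)
  cons[cbind(lidx, sidx)] <- code
  ind <- matrix(0L, L, S)
  ind[cbind(lidx, sidx)] <- istat

  anc <- column_majority(cons, 4L, config$min_lines_for_ancestral)
  anc_ind <- column_majority(ind, 3L, config$min_lines_for_ancestral)

  n_analyzed <- setNames(
    as.integer(rowSums(cons > 0L & rep(anc > 0L, each = L))), lines)

  site_pos <- as.integer(ukey %% M)
  site_contig <- cts[as.integer(ukey %/% M) + 1L]

  # base substitutions
  anc_mat <- rep(anc, each = L)
  hit <- which(cons > 0L & anc_mat > 0L & cons != anc_mat)
  bps <- NULL
  if (length(hit)) {
    li <- (hit - 1L) %% L + 1L
    si <- (hit - 1L) %/% L + 1L
    bps <- data.frame(line = lines[li], contig = site_contig[si],
                      pos = site_pos[si], ref = BASES[anc[si]],
                      alt = BASES[cons[hit]], class = "BPS",
                      stringsAsFactors = FALSE)
  }

  # indels: divergence of indel status from ancestral indel status
  anc_imat <- rep(anc_ind, each = L)
  ihit <- which(ind > 0L & anc_imat > 0L & ind != anc_imat)
  idl <- NULL
  if (length(ihit)) {
    li <- (ihit - 1L) %% L + 1L
    si <- (ihit - 1L) %/% L + 1L
    st <- ind[ihit]
    cls <- ifelse(st == 2L, "INS",
                  ifelse(st == 3L, "DEL",
                         ifelse(anc_ind[si] == 2L, "DEL", "INS")))
    refb <- ifelse(anc[si] > 0L, BASES[pmax(anc[si], 1L)],
                   substring(genome$contigs[site_contig[si]],
                             site_pos[si], site_pos[si]))
    idl <- data.frame(line = lines[li], contig = site_contig[si],
                      pos = site_pos[si], ref = refb,
                      alt = NA_character_, class = cls,
                      stringsAsFactors = FALSE)
  }

  calls <- rbind(bps, idl)
  if (is.null(calls))
    calls <- data.frame(line = character(), contig = character(),
                        pos = integer(), ref = character(),
                        alt = character(), class = character(),
                        stringsAsFactors = FALSE)
  calls <- annotate_calls(calls, genome)
  calls <- calls[order(calls$contig, calls$pos, calls$line), ]
  rownames(calls) <- NULL
  structure(list(calls = calls, n_analyzed = n_analyzed),
            class = "ma_calls")
}

#' Annotate calls with context, class and region
#'
#' @param calls data frame with `contig`, `pos`, `ref`, `alt`, `class`.
#' @param genome an [annotated_genome].
#' @return the data frame with `context`, `bps_type`, `kind` and
#'   `region` columns added.
#' @export
annotate_calls <- function(calls, genome) {
  n <- nrow(calls)
  calls$context <- ifelse(calls$ref %in% c("A", "T"), "AT", "GC")
  calls$bps_type <- rep(NA_character_, n)
  is_bps <- calls$class == "BPS"
  if (any(is_bps))
    calls$bps_type[is_bps] <- bps_class(calls$ref[is_bps], calls$alt[is_bps])
  calls$kind <- ifelse(calls$bps_type %in% TRANSITION_CLASSES,
                       "transition",
                       ifelse(is_bps, "transversion", NA))
  calls$region <- ifelse(in_coding_region(genome, calls$contig, calls$pos),
                         "coding", "noncoding")
  calls
}

#' @export
print.ma_calls <- function(x, ...) {
  cat("MA mutation calls:", nrow(x$calls), "call(s) across",
      length(x$n_analyzed), "line(s)\n")
  if (nrow(x$calls)) print(table(x$calls$class))
  cat("analyzed sites per line: median",
      format(stats::median(x$n_analyzed), big.mark = ","), "\n")
  invisible(x)
}

#' Per-line quality control
#'
#' A line is dropped when its median genome-wide depth (sites absent
#' from the pileup count as depth 0) falls below
#' `line_min_median_depth`. Breadth — the fraction of genome sites with
#' at least one read — is reported for reference but is not a drop rule.
#'
#' @param pileups pileup table covering one or more lines.
#' @param genome an [annotated_genome].
#' @param config a [caller_config()].
#' @return data frame with one row per line: `line`, `median_depth`,
#'   `breadth`, `kept`, `reason`.
#' @export
qc_lines <- function(pileups, genome, config = caller_config()) {
  stopifnot(inherits(genome, "annotated_genome"))
  pu <- as.data.frame(pileups)
  G <- genome_size(genome)
  lines <- sort(unique(pu$line))
  res <- lapply(lines, function(l) {
    d <- with(pu[pu$line == l, ], nA + nC + nG + nT + nDel)
    md <- median_with_zeros(d, G)
    breadth <- sum(d > 0) / G
    kept <- md >= config$line_min_median_depth
    data.frame(line = l, median_depth = md, breadth = breadth,
               kept = kept,
               reason = if (kept) "" else
                 sprintf("median depth %g < %g", md,
                         config$line_min_median_depth),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# median of c(d, rep(0, total - length(d))) without materialising zeros
median_with_zeros <- function(d, total) {
  nz <- total - length(d)
  stopifnot(nz >= 0)
  d <- sort(d)
  v <- function(i) if (i <= nz) 0 else d[i - nz]
  if (total %% 2 == 1) v((total + 1) / 2)
  else (v(total / 2) + v(total / 2 + 1)) / 2
}

#' Flag putative cross-contaminated line pairs
#'
#' MA lines accumulate mutations independently, so two lines sharing a
#' large fraction of their calls signal cross-contamination. A pair is
#' flagged when the Jaccard index of their call sets (site + allele)
#' reaches `contamination_shared_fraction` and each line carries at
#' least two calls.
#'
#' @param calls mutation call data frame or an `ma_calls` object.
#' @param config a [caller_config()].
#' @return data frame `line1`, `line2`, `jaccard` of flagged pairs.
#' @export
flag_contamination <- function(calls, config = caller_config()) {
  if (inherits(calls, "ma_calls")) calls <- calls$calls
  out <- data.frame(line1 = character(), line2 = character(),
                    jaccard = numeric(), stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(out)
  key <- paste(calls$contig, calls$pos, calls$class, calls$alt)
  sets <- split(key, calls$line)
  sets <- sets[lengths(sets) >= 2]
  if (length(sets) < 2) return(out)
  ids <- names(sets)
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq(i + 1, length(ids))) {
      a <- sets[[i]]; b <- sets[[j]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      if (jac >= config$contamination_shared_fraction)
        out <- rbind(out, data.frame(line1 = ids[i], line2 = ids[j],
                                     jaccard = jac,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}
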