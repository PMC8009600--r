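#' Build an annotated genome
#'
#' Bundles a set of contig sequences with the CDS gene models used to
#' partition sites into coding/non-coding and to locate four-fold
#' degenerate positions. The GC fraction (fraction of G+C among
#' unambiguous bases) is computed on construction and cached.
#'
#' @param contigs named character vector of contig sequences. Sequences
#'   are uppercased; only the alphabet A, C, G, T, N is accepted.
#' @param genes data frame of CDS features with columns `contig`,
#'   `start`, `end` (1-based inclusive), `strand` (`"+"`/`"-"`) and
#'   `phase` (0, 1 or 2), or `NULL` for an unannotated genome.
#' @return An object of class `annotated_genome`: a list with elements
#'   `contigs`, `genes` and `gc_fraction`.
#' @examples
#' g <- annotated_genome(c(c1 = "ACGTACGTACGT"),
#'                       data.frame(contig = "c1", start = 4, end = 9,
#'                                  strand = "+", phase = 0))
#' g$gc_fraction
#' @export
annotated_genome <- function(contigs, genes = NULL) {
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
    stop("contigs must be a named character vector", call. = FALSE)
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig ids: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "),
         call. = FALSE)
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig '", names(contigs)[bad][1],
         "' contains characters outside A,C,G,T,N", call. = FALSE)
  if (is.null(genes)) {
    genes <- data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        phase = integer())
  } else {
    genes <- validate_cds(genes, contigs)
  }
  structure(list(contigs = contigs, genes = genes,
                 gc_fraction = gc_fraction(contigs)),
            class = "annotated_genome")
}

validate_cds <- function(genes, contigs) {
  need <- c("contig", "start", "end", "strand", "phase")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  genes <- genes[need]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$phase <- as.integer(genes$phase)
  if (any(!genes$contig %in% names(contigs)))
    stop("CDS on unknown contig: ",
         genes$contig[!genes$contig %in% names(contigs)][1], call. = FALSE)
  if (any(genes$start < 1L) || any(genes$start > genes$end))
    stop("CDS with start < 1 or start > end", call. = FALSE)
  lens <- nchar(contigs)[genes$contig]
  if (any(genes$end > lens)) {
    i <- which(genes$end > lens)[1]
    stop("CDS ", genes$contig[i], ":", genes$start[i], "-", genes$end[i],
         " extends beyond contig length ", lens[i], call. = FALSE)
  }
  if (any(!genes$strand %in% c("+", "-")))
    stop("CDS strand must be '+' or '-'", call. = FALSE)
  if (any(!genes$phase %in% 0:2))
    stop("CDS phase must be 0, 1 or 2", call. = FALSE)
  rownames(genes) <- NULL
  genes
}

#' GC fraction of a sequence set
#'
#' Fraction of G+C among unambiguous (non-N) bases, pooled over all
#' sequences.
#'
#' @param contigs character vector of DNA sequences.
#' @return numeric in \[0, 1\].
#' @export
gc_fraction <- function(contigs) {
  tab <- base_composition(contigs)
  acgt <- sum(tab)
  if (acgt == 0) return(NA_real_)
  unname((tab["G"] + tab["C"]) / acgt)
}

# counts of A, C, G, T pooled over sequences (N excluded)
base_composition <- function(contigs) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in contigs) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    t <- table(factor(v, levels = c("A", "C", "G", "T")))
    counts <- counts + as.numeric(t)
  }
  counts
}

#' Context-site composition of a genome
#'
#' Returns the fractions of unambiguous sites in A:T versus G:C context,
#' the denominators used to condition per-type mutation rates.
#'
#' @param genome an [annotated_genome].
#' @return named numeric vector `c(f_AT =, f_GC =)` summing to 1.
#' @export
context_fractions <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  f_gc <- genome$gc_fraction
  c(f_AT = 1 - f_gc, f_GC = f_gc)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("Annotated genome:", length(x$contigs), "contig(s),",
      format(sum(nchar(x$contigs)), big.mark = ","), "bp, GC",
      sprintf("%.2f%%", 100 * x$gc_fraction), "\n")
  cat("  CDS features:", nrow(x$genes), "\n")
  invisible(x)
}

# total genome length in bp
genome_size <- function(genome) sum(nchar(genome$contigs))

# coding site count: union of CDS intervals per contig
coding_site_count <- function(genome) {
  if (nrow(genome$genes) == 0) return(0L)
  total <- 0L
  for (ct in unique(genome$genes$contig)) {
    g <- genome$genes[genome$genes$contig == ct, ]
    iv <- merge_intervals(g$start, g$end)
    total <- total + sum(iv$end - iv$start + 1L)
  }
  total
}

# merge overlapping 1-based inclusive intervals; returns sorted data.frame
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- integer(); oute <- integer()
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= me + 1L) {
        me <- max(me, end[i])
      } else {
        outs <- c(outs, ms); oute <- c(oute, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

# TRUE for each (contig, pos) lying inside any CDS interval
in_coding_region <- function(genome, contig, pos) {
  out <- logical(length(pos))
  if (nrow(genome$genes) == 0) return(out)
  for (ct in unique(contig)) {
    sel <- contig == ct
    g <- genome$genes[genome$genes$contig == ct, ]
    if (nrow(g) == 0) next
    iv <- merge_intervals(g$start, g$end)
    idx <- findInterval(pos[sel], iv$start)
    hit <- idx >= 1L & pos[sel] <= iv$end[pmax(idx, 1L)]
    out[sel] <- hit
  }
  out
}
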