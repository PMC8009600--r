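# dinucleotide prefixes whose codon family is four-fold degenerate
# under the standard genetic code (CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN)
fourfold_prefixes <- function() {
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1, 2))
  keep <- vapply(pre, function(p) {
    aa <- gc[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1L
  }, logical(1))
  pre[keep]
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' Identify four-fold degenerate sites
#'
#' Marks third-codon positions whose codon family encodes the same
#' amino acid for all four third-base choices under the standard
#' genetic code. Minus-strand CDS are evaluated on their reverse
#' complement; the `phase` leading bases of each CDS and any trailing
#' partial codon are skipped. Codons whose first two bases contain `N`
#' are skipped. Positions falling inside another CDS where they are not
#' a four-fold third position (overlapping genes with conflicting
#' classification) are excluded.
#'
#' @param genome an [annotated_genome].
#' @param annotation optional CDS data frame overriding `genome$genes`.
#' @return data frame of class `fourfold_mask` with columns `contig`,
#'   `pos`, sorted by position.
#' @examples
#' g <- annotated_genome(c(c1 = "GCTGCA"),
#'                       data.frame(contig = "c1", start = 1, end = 6,
#'                                  strand = "+", phase = 0))
#' fourfold_sites(g)$pos  # 3 and 6
#' @export
fourfold_sites <- function(genome, annotation = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  genes <- if (is.null(annotation)) genome$genes
           else validate_cds(annotation, genome$contigs)
  ffpre <- fourfold_prefixes()
  out <- list()
  for (ct in unique(genes$contig)) {
    g <- genes[genes$contig == ct, , drop = FALSE]
    clen <- nchar(genome$contigs[[ct]])
    ff_votes <- integer(clen)   # CDS classifying position as four-fold
    coverage <- integer(clen)   # CDS covering position at all
    chars <- strsplit(genome$contigs[[ct]], "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(g))) {
      st <- g$start[i]; en <- g$end[i]
      ph <- g$phase[i]; minus <- g$strand[i] == "-"
      coverage[st:en] <- coverage[st:en] + 1L
      len <- en - st + 1L
      ncod <- (len - ph) %/% 3L
      if (ncod < 1L) next
      k <- seq_len(ncod)
      if (!minus) {
        p1 <- st + ph + 3L * (k - 1L)
        b1 <- chars[p1]; b2 <- chars[p1 + 1L]
        third <- p1 + 2L
      } else {
        p1 <- en - ph - 3L * (k - 1L)
        b1 <- comp_base(chars[p1]); b2 <- comp_base(chars[p1 - 1L])
        third <- p1 - 2L
      }
      ok <- b1 != "N" & b2 != "N" & paste0(b1, b2) %in% ffpre
      ff_votes[third[ok]] <- ff_votes[third[ok]] + 1L
    }
    # keep positions four-fold in every CDS that covers them
    pos <- which(ff_votes > 0L & ff_votes == coverage)
    if (length(pos))
      out[[ct]] <- data.frame(contig = ct, pos = pos,
                              stringsAsFactors = FALSE)
  }
  mask <- if (length(out)) do.call(rbind, out)
          else data.frame(contig = character(), pos = integer())
  rownames(mask) <- NULL
  class(mask) <- c("fourfold_mask", "data.frame")
  mask
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Nucleotide diversity at four-fold degenerate sites
#'
#' Average pairwise heterozygosity over masked alignment columns:
#' per column with n' >= 2 non-gap strains,
#' h = n'/(n' - 1) x (1 - sum of squared allele frequencies), and theta
#' is the mean of h over used columns. The small-sample factor uses the
#' column's own non-gap strain count so missing data does not bias
#' theta downward.
#'
#' @param alignment named character vector of aligned sequences (equal
#'   length; `-` for gaps, `N` treated as missing).
#' @param mask a [fourfold_sites()] mask, or an integer vector of
#'   reference positions.
#' @param ref_strain name of the alignment row through which mask
#'   positions are projected onto columns (columns where that row is
#'   gapped are dropped). `NULL` (default) for alignments in reference
#'   coordinates, where position equals column.
#' @return list of class `diversity_result`: `theta`, `n_sites`
#'   (columns used), `n_snps` (used columns with >= 2 alleles),
#'   `n_strains`, `het` (per-column h), `freqs` (4 x n_sites allele
#'   frequency matrix).
#' @export
theta_fourfold <- function(alignment, mask, ref_strain = NULL) {
  n <- length(alignment)
  stopifnot(n >= 2)
  w <- unique(nchar(alignment))
  if (length(w) != 1)
    stop("alignment rows have unequal lengths", call. = FALSE)
  pos <- if (is.data.frame(mask)) mask$pos else as.integer(mask)
  if (!is.null(ref_strain)) {
    if (!ref_strain %in% names(alignment))
      stop("ref_strain '", ref_strain, "' not in alignment", call. = FALSE)
    refc <- strsplit(alignment[[ref_strain]], "", fixed = TRUE)[[1]]
    nongap <- which(refc != "-")
    cols <- nongap[pos[pos <= length(nongap)]]
  } else {
    cols <- pos[pos <= w]
  }
  cols <- cols[!is.na(cols)]
  if (!length(cols))
    stop("mask is disjoint from the alignment", call. = FALSE)
  m <- matrix(0L, n, length(cols))
  for (i in seq_len(n)) {
    chars <- strsplit(alignment[[i]], "", fixed = TRUE)[[1]][cols]
    m[i, ] <- match(chars, BASES, nomatch = 0L)
  }
  nprime <- colSums(m > 0L)
  cnt <- vapply(1:4, function(b) colSums(m == b), numeric(length(cols)))
  if (length(cols) == 1L) cnt <- matrix(cnt, nrow = 1)
  use <- nprime >= 2L
  if (!any(use))
    stop("no masked column has two or more non-gap strains", call. = FALSE)
  p <- cnt[use, , drop = FALSE] / nprime[use]
  sumsq <- rowSums(p^2)
  np <- nprime[use]
  het <- np / (np - 1) * (1 - sumsq)
  n_snps <- sum(rowSums(cnt[use, , drop = FALSE] > 0) >= 2L)
  structure(list(theta = mean(het), n_sites = sum(use), n_snps = n_snps,
                 n_strains = n, het = het, freqs = t(p)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf(paste0("Nucleotide diversity at four-fold sites: theta = %s",
                     " (%d sites, %d SNPs, %d strains)\n"),
              format(signif(x$theta, 4)), x$n_sites, x$n_snps, x$n_strains))
  invisible(x)
}

#' Effective population size from diversity and mutation rate
#'
#' For a haploid organism at mutation-drift equilibrium,
#' Ne = theta / (2 mu).
#'
#' @param theta nucleotide diversity (e.g. from [theta_fourfold()], or
#'   a `diversity_result`).
#' @param mu mutation rate per site per division (a number or a
#'   [rate_estimate]).
#' @return list of class `ne_estimate` with `ne`, `theta`, `mu`.
#' @examples
#' effective_population_size(8.31e-2, 5.94e-11)
#' @export
effective_population_size <- function(theta, mu) {
  if (inherits(theta, "diversity_result")) theta <- theta$theta
  if (inherits(mu, "rate_estimate")) mu <- mu$rate
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (theta < 0) stop("theta must be non-negative", call. = FALSE)
  structure(list(ne = theta / (2 * mu), theta = theta, mu = mu),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Effective population size: Ne = %s (theta = %s, mu = %s)\n",
              format(signif(x$ne, 3)), format(signif(x$theta, 3)),
              format(signif(x$mu, 3))))
  invisible(x)
}

#' Filter candidate strains by sequence identity to the focal strain
#'
#' Strains whose (e.g. 16S rRNA) identity to the focal strain reaches
#' the threshold are retained for the diversity panel. Identities may
#' be given as fractions in \[0, 1\] or as percentages.
#'
#' @param identities named numeric vector of identities.
#' @param threshold minimum identity (fraction; default 0.95).
#' @return names of retained strains.
#' @export
strain_identity_filter <- function(identities, threshold = 0.95) {
  if (!length(identities)) return(character())
  if (any(identities < 0) || any(identities > 100))
    stop("identities must be fractions or percentages", call. = FALSE)
  if (any(identities > 1)) identities <- identities / 100
  names(identities)[identities >= threshold]
}
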