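#' Read a FASTA file
#'
#' Reads DNA sequences, uppercases them and validates the alphabet.
#' Wrapped lines and CRLF line endings are tolerated. Record ids are the
#' first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("'", path, "': not valid FASTA (",
                                           conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0)
    stop("'", path, "': empty FASTA file", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("'", path, "': duplicate record id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("'", path, "': record '", ids[bad][1],
         "' contains characters outside A,C,G,T,N,-", call. = FALSE)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read CDS features from a GFF3 file
#'
#' Retains only `CDS` rows and validates their coordinates, strand and
#' phase against the genome.
#'
#' @param path path to a GFF3 file.
#' @param genome an [annotated_genome] (gene models are ignored; contigs
#'   are used for bounds checking), or a named character vector of
#'   contig sequences.
#' @return data frame with columns `contig`, `start`, `end`, `strand`,
#'   `phase` (one row per CDS feature).
#' @export
read_gff3 <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  contigs <- if (inherits(genome, "annotated_genome")) genome$contigs else genome
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("'", path, "': not valid GFF3 (",
                                          conditionMessage(e), ")",
                                          call. = FALSE))
  df <- as.data.frame(gr)
  df <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(df) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      phase = integer()))
  if (any(df$strand == "*"))
    stop("'", path, "': CDS with unknown strand at ",
         df$seqnames[df$strand == "*"][1], ":",
         df$start[df$strand == "*"][1], call. = FALSE)
  phase <- if ("phase" %in% names(df)) df$phase else rep(0L, nrow(df))
  phase[is.na(phase)] <- 0L
  out <- data.frame(contig = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    strand = as.character(df$strand),
                    phase = as.integer(phase))
  validate_cds(out, contigs)
}

#' Write CDS features to GFF3
#'
#' @param genes CDS data frame (`contig`, `start`, `end`, `strand`, `phase`).
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "malines") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    id <- sprintf("cds%05d", seq_len(nrow(genes)))
    writeLines(paste(genes$contig, source, "CDS", genes$start, genes$end,
                     ".", genes$strand, genes$phase,
                     paste0("ID=", id), sep = "\t"), con)
  }
  invisible(path)
}

PILEUP_COLS <- c("line", "contig", "pos", "nA", "nC", "nG", "nT", "nIns", "nDel")
PILEUP_FWD_COLS <- c("fA", "fC", "fG", "fT")

#' Read a pileup table
#'
#' The pileup table is a TSV with header columns
#' `line contig pos nA nC nG nT nIns nDel`, one row per (line, site):
#' per-line counts of reads supporting each base, an insertion or a
#' deletion at a 1-based position. Optional columns `fA fC fG fT` carry
#' the forward-strand share of each base count (reverse = total -
#' forward) and enable the per-strand calling filter. Rows with all-zero
#' counts mark uncovered sites.
#'
#' @param path path to the TSV.
#' @return data frame of class `pileup_table`.
#' @seealso [write_pileup()], [call_mutations()]
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("'", path, "': unreadable TSV (",
                                          conditionMessage(e), ")",
                                          call. = FALSE))
  miss <- setdiff(PILEUP_COLS, names(df))
  if (length(miss))
    stop("'", path, "': missing pileup column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  count_cols <- c("pos", PILEUP_COLS[4:9],
                  intersect(PILEUP_FWD_COLS, names(df)))
  for (cl in count_cols) {
    v <- suppressWarnings(as.integer(df[[cl]]))
    if (anyNA(v) && !all(is.na(df[[cl]]) == is.na(v))) {
      i <- which(is.na(v) & !is.na(df[[cl]]))[1]
      stop("'", path, "' line ", i + 1L, ": non-integer value '",
           df[[cl]][i], "' in column ", cl, call. = FALSE)
    }
    if (anyNA(v))
      stop("'", path, "' line ", which(is.na(v))[1] + 1L,
           ": missing value in column ", cl, call. = FALSE)
    df[[cl]] <- v
  }
  neg <- which(Reduce(`|`, lapply(df[count_cols[-1]], function(v) v < 0)))
  if (length(neg))
    stop("'", path, "' line ", neg[1] + 1L, ": negative count", call. = FALSE)
  if (any(df$pos < 1L))
    stop("'", path, "' line ", which(df$pos < 1L)[1] + 1L,
         ": position < 1", call. = FALSE)
  key <- paste(df$line, df$contig, df$pos)
  if (anyDuplicated(key))
    stop("'", path, "' line ", which(duplicated(key))[1] + 1L,
         ": duplicate (line, contig, pos) entry", call. = FALSE)
  as_pileup(df)
}

as_pileup <- function(df) {
  class(df) <- c("pileup_table", "data.frame")
  df
}

#' Write a pileup table
#'
#' @param table pileup data frame as returned by [read_pileup()] or
#'   [simulate_pileups()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(table, path) {
  keep <- c(PILEUP_COLS, intersect(PILEUP_FWD_COLS, names(table)))
  utils::write.table(as.data.frame(table)[keep], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant table
#'
#' Ingests externally called variants (e.g. exported from another caller's VCF) as
#' a TSV with header columns `line contig pos ref alt class`, where
#' `class` is one of `SNP`, `INS`, `DEL`.
#'
#' @param path path to the TSV.
#' @param genome optional [annotated_genome]; when given, reference
#'   alleles of SNPs are checked against the genome sequence.
#' @return data frame with the columns above.
#' @export
read_variant_table <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line", "contig", "pos", "ref", "alt", "class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("'", path, "': missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$pos <- as.integer(df$pos)
  if (any(!df$class %in% c("SNP", "INS", "DEL")))
    stop("'", path, "': variant class must be SNP, INS or DEL",
         call. = FALSE)
  snp <- df$class == "SNP"
  if (any(snp & df$ref == df$alt))
    stop("'", path, "' line ",
         which(snp & df$ref == df$alt)[1] + 1L,
         ": SNP with ref == alt", call. = FALSE)
  if (any(df$ref == "" | df$alt == ""))
    stop("'", path, "': empty allele", call. = FALSE)
  if (!is.null(genome)) {
    at <- substring(genome$contigs[df$contig], df$pos, df$pos)
    bad <- snp & at != df$ref
    if (any(bad)) {
      i <- which(bad)[1]
      stop("'", path, "': ref allele ", df$ref[i], " at ", df$contig[i],
           ":", df$pos[i], " disagrees with genome base ", at[i],
           call. = FALSE)
    }
  }
  df
}

#' Write mutation calls as minimal VCF 4.2
#'
#' Emits CHROM/POS/REF/ALT plus a `LINE` INFO tag identifying the MA
#' line. Indels follow VCF convention: a deletion at position p is
#' anchored at p-1 (REF = anchor+deleted base, ALT = anchor); an
#' insertion is anchored at its site (ALT = anchor followed by the
#' inserted base, `N` when the inserted base is unknown from count data).
#'
#' @param calls mutation call data frame (see [call_mutations()]); needs
#'   columns `line`, `contig`, `pos`, `ref`, `alt`, `class`.
#' @param genome an [annotated_genome], used for anchor bases and to
#'   check SNP reference alleles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, genome, path) {
  stopifnot(inherits(genome, "annotated_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=malines ",
                      as.character(utils::packageVersion("malines"))),
               "##INFO=<ID=LINE,Number=1,Type=String,Description=\"MA line id\">",
               paste(sapply(names(genome$contigs), function(ct)
                 sprintf("##contig=<ID=%s,length=%d>", ct,
                         nchar(genome$contigs[[ct]]))),
                 collapse = "\n"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) == 0) return(invisible(path))
  o <- order(calls$contig, calls$pos, calls$line)
  calls <- calls[o, , drop = FALSE]
  pos <- calls$pos; ref <- calls$ref; alt <- calls$alt
  base_at <- function(ct, p) substring(genome$contigs[ct], p, p)
  for (i in seq_len(nrow(calls))) {
    cl <- calls$class[i]
    if (cl == "BPS" || cl == "SNP") {
      gb <- base_at(calls$contig[i], pos[i])
      if (gb != ref[i])
        stop("call ref ", ref[i], " at ", calls$contig[i], ":", pos[i],
             " disagrees with genome base ", gb, call. = FALSE)
    } else if (cl == "DEL") {
      anchor_pos <- pos[i] - 1L
      if (anchor_pos < 1L)
        stop("deletion at position 1 cannot be anchored", call. = FALSE)
      anchor <- base_at(calls$contig[i], anchor_pos)
      ref[i] <- paste0(anchor, base_at(calls$contig[i], pos[i]))
      alt[i] <- anchor
      pos[i] <- anchor_pos
    } else if (cl == "INS") {
      anchor <- base_at(calls$contig[i], pos[i])
      ins <- if (is.na(alt[i]) || alt[i] == "") "N" else alt[i]
      ref[i] <- anchor
      alt[i] <- paste0(anchor, ins)
    } else stop("unknown variant class: ", cl, call. = FALSE)
  }
  writeLines(paste(calls$contig, pos, ".", ref, alt, ".", "PASS",
                   paste0("LINE=", calls$line), sep = "\t"), con)
  invisible(path)
}
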