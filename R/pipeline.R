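#' Demo simulation configuration
#'
#' A small configuration (50 kb genome, 8 lines, 500 divisions,
#' per-class rates scaled 2000-fold) whose full pipeline run completes
#' in seconds while still yielding a few dozen mutations.
#'
#' @param seed mandatory integer seed.
#' @return a [sim_config()].
#' @export
demo_config <- function(seed = NULL) {
  sim_config(genome_length = 5e4, n_lines = 8, divisions = 500,
             rates = DEFAULT_RATES * 2000, depth_mean = 60,
             depth_dispersion = 10, error_rate = 0.003, n_strains = 6,
             strain_density = 0.042, seed = seed)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full MA analysis pipeline
#'
#' Executes simulate -> QC -> call -> rates/spectrum -> diversity -> Ne
#' and writes every artifact to `outdir`: `genome.fa`, `genes.gff3`,
#' `pileup.tsv`, `truth.tsv`, `cfu.tsv`, `strains.fa` (simulated
#' inputs), `qc.tsv`, `calls.vcf`, `rates.tsv`, `spectrum.tsv`,
#' `theta.tsv`, `ne.txt` and a `manifest.json` recording the
#' configuration, seed, package version and output checksums. Instead
#' of simulating, pre-existing inputs may be supplied as file paths;
#' stages whose inputs are missing abort with the stage named.
#'
#' @param outdir output directory (created if absent).
#' @param config a [sim_config()] for a simulated run, or `NULL` when
#'   supplying `genome_fa`/`gff3`/`pileup` paths.
#' @param genome_fa,gff3,pileup optional paths to a reference FASTA,
#'   GFF3 annotation and pileup TSV for a run on real inputs.
#' @param divisions cell divisions per line for runs on real inputs.
#' @param caller a [caller_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the main results: `qc`, `calls`,
#'   `spectrum`, `summary`, `regions`, `theta`, `ne`.
#' @export
run_pipeline <- function(outdir, config = NULL, genome_fa = NULL,
                         gff3 = NULL, pileup = NULL, divisions = NULL,
                         caller = caller_config(), quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  simulated <- !is.null(config)

  if (simulated) {
    stopifnot(inherits(config, "sim_config"))
    say("[simulate] genome %d bp, %d lines", config$genome_length,
        config$n_lines)
    genome <- run_stage("simulate-genome", generate_genome(config))
    write_fasta(genome$contigs, file.path(outdir, "genome.fa"))
    write_gff3(genome$genes, file.path(outdir, "genes.gff3"))
    truth <- run_stage("simulate-mutations", plant_mutations(genome, config))
    utils::write.table(truth$truth, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pu <- run_stage("simulate-pileups",
                    simulate_pileups(genome, truth, config))
    write_pileup(pu, file.path(outdir, "pileup.tsv"))
    cfu <- run_stage("simulate-cfu",
                     simulate_cfu(19.5, n = 10, sd = 0.5,
                                  seed = config$seed + 3L))
    utils::write.table(data.frame(sample = seq_along(cfu), cfu = cfu),
                       file.path(outdir, "cfu.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    TT <- config$divisions
  } else {
    if (is.null(genome_fa))
      stop("pipeline stage 'load-genome' failed: no genome FASTA supplied",
           call. = FALSE)
    if (is.null(gff3))
      stop("pipeline stage 'load-annotation' failed: no GFF3 supplied",
           call. = FALSE)
    if (is.null(pileup))
      stop("pipeline stage 'load-pileup' failed: no pileup supplied",
           call. = FALSE)
    if (is.null(divisions))
      stop("pipeline stage 'rates' failed: divisions per line required",
           call. = FALSE)
    contigs <- run_stage("load-genome", read_fasta(genome_fa))
    genes <- run_stage("load-annotation",
                       read_gff3(gff3, contigs))
    genome <- annotated_genome(contigs, genes)
    pu <- run_stage("load-pileup", read_pileup(pileup))
    TT <- divisions
  }

  say("[qc] screening %d line(s)", length(unique(pu$line)))
  qc <- run_stage("qc", qc_lines(pu, genome, caller))
  utils::write.table(qc, file.path(outdir, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  kept <- qc$line[qc$kept]
  if (!length(kept))
    stop("pipeline stage 'qc' failed: no line passes QC", call. = FALSE)
  pu_kept <- as_pileup(as.data.frame(pu)[pu$line %in% kept, ])

  say("[call] consensus calling on %d line(s)", length(kept))
  res <- run_stage("call", call_mutations(pu_kept, genome, config = caller))
  contam <- run_stage("contamination", flag_contamination(res, caller))
  if (nrow(contam))
    warning("possible cross-contamination: ",
            paste(contam$line1, contam$line2, sep = "~", collapse = ", "))
  write_variant_vcf(res$calls, genome, file.path(outdir, "calls.vcf"))

  say("[rates] %d call(s)", nrow(res$calls))
  denom <- run_stage("rates",
                     site_divisions(res$n_analyzed, TT))
  sp <- run_stage("spectrum",
                  spectrum_table(res, f_gc = genome$gc_fraction,
                                 denominator = denom))
  spd <- do.call(rbind, lapply(sp$estimates, rate_estimate_row))
  names(spd)[1] <- "class"
  utils::write.table(spd, file.path(outdir, "spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ss <- summary(sp)
  regions <- run_stage("regions", region_rates(res, genome, denom))
  rates_df <- rbind(rate_estimate_row(sp$bps), rate_estimate_row(sp$indel),
                    rate_estimate_row(regions$coding),
                    rate_estimate_row(regions$noncoding))
  utils::write.table(rates_df, file.path(outdir, "rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("[diversity] four-fold sites and strain alignment")
  mask <- run_stage("fourfold", fourfold_sites(genome))
  if (simulated) {
    strains <- run_stage("simulate-strains",
                         simulate_strains(genome, mask,
                                          config$strain_density,
                                          config$n_strains,
                                          seed = config$seed + 4L))
    write_fasta(strains, file.path(outdir, "strains.fa"))
  } else {
    strains <- NULL
  }
  theta <- ne <- NULL
  if (!is.null(strains) && nrow(mask) > 0) {
    theta <- run_stage("theta", theta_fourfold(strains, mask))
    utils::write.table(data.frame(theta = theta$theta,
                                  n_fourfold = theta$n_sites,
                                  n_snps = theta$n_snps),
                       file.path(outdir, "theta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ne <- run_stage("ne", effective_population_size(theta, sp$bps))
    writeLines(sprintf("Ne\t%.6g\ntheta\t%.6g\nmu\t%.6g",
                       ne$ne, ne$theta, ne$mu),
               file.path(outdir, "ne.txt"))
  }

  outputs <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    command = "run_pipeline",
    package = "malines",
    version = as.character(utils::packageVersion("malines")),
    seed = if (simulated) config$seed else NA,
    config = if (simulated) unclass(config) else
      list(genome_fa = genome_fa, gff3 = gff3, pileup = pileup,
           divisions = divisions),
    caller = unclass(caller),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(tools::md5sum(file.path(outdir, outputs)))
  )
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("[done] outputs in %s", outdir)
  invisible(list(qc = qc, calls = res, spectrum = sp, summary = ss,
                 regions = regions, theta = theta, ne = ne))
}
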