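#' Mutation spectrum with per-class conditional rates
#'
#' Fits the per-class mutation-rate table from observed calls (or
#' per-class counts), the genome context composition and the
#' site-division denominator. Each of the six strand-symmetric
#' base-substitution classes gets a conditional rate (count divided by
#' the site-divisions in its A:T or G:C context) with an exact Poisson
#' confidence interval; insertions and deletions are unconditioned.
#' The composition-weighted conditional rates always reconstruct the
#' total base-substitution rate exactly.
#'
#' @param x an `ma_calls` object, a mutation call data frame with a
#'   `class`/`bps_type` annotation, or a named numeric vector of counts
#'   with names among
#'   `"G:C>A:T", "A:T>G:C", "A:T>T:A", "G:C>T:A", "A:T>C:G", "G:C>C:G",
#'   "insertion", "deletion"`.
#' @param f_gc fraction of analyzed sites in G:C context (genome G+C
#'   fraction when per-line analyzed-site composition is unavailable).
#' @param denominator a [site_divisions()] object or total
#'   site-divisions.
#' @param level confidence level for all intervals.
#' @return object of class `ma_spectrum`: per-class counts and
#'   [rate_estimate]s, context fractions, the pooled base-substitution
#'   and indel rate estimates. Methods: `print`, `summary`, `coef`,
#'   `confint`, `plot`.
#' @examples
#' counts <- c("G:C>A:T" = 30, "A:T>G:C" = 7, "A:T>T:A" = 1,
#'             "G:C>T:A" = 23, "A:T>C:G" = 0, "G:C>C:G" = 11,
#'             insertion = 4, deletion = 6)
#' sp <- spectrum_table(counts, f_gc = 0.4239,
#'                      denominator = site_divisions(5171217, 4517,
#'                                                   n_lines = 52))
#' summary(sp)
#' @export
spectrum_table <- function(x, f_gc, denominator, level = 0.95) {
  if (f_gc <= 0 || f_gc >= 1)
    stop("f_gc must be in (0, 1)", call. = FALSE)
  counts <- spectrum_counts(x)
  D <- denom_total(denominator)
  f_at <- 1 - f_gc
  est <- lapply(MUTATION_CLASSES, function(cl) {
    if (cl %in% GC_CONTEXT_CLASSES)
      conditional_rate(counts[[cl]], f_gc, D, label = cl, level = level)
    else if (cl %in% AT_CONTEXT_CLASSES)
      conditional_rate(counts[[cl]], f_at, D, label = cl, level = level)
    else
      mutation_rate(counts[[cl]], D, label = cl, level = level)
  })
  names(est) <- MUTATION_CLASSES
  bps_total <- mutation_rate(sum(counts[BPS_CLASSES]), D,
                             label = "base substitution", level = level)
  indel_total <- mutation_rate(counts[["insertion"]] + counts[["deletion"]],
                               D, label = "indel", level = level)
  structure(list(counts = counts, estimates = est, f_AT = f_at,
                 f_GC = f_gc, denominator = D, bps = bps_total,
                 indel = indel_total, level = level),
            class = "ma_spectrum")
}

spectrum_counts <- function(x) {
  if (inherits(x, "ma_calls")) x <- x$calls
  if (is.data.frame(x)) {
    counts <- setNames(numeric(length(MUTATION_CLASSES)), MUTATION_CLASSES)
    bps <- x[x$class == "BPS", , drop = FALSE]
    if (nrow(bps)) {
      if (any(is.na(bps$bps_type)) ||
          any(!bps$bps_type %in% BPS_CLASSES))
        stop("BPS calls lack a valid bps_type annotation", call. = FALSE)
      ctx_expected <- ifelse(bps$bps_type %in% GC_CONTEXT_CLASSES, "GC", "AT")
      if (!is.null(bps$context) && any(bps$context != ctx_expected))
        stop("call context annotation inconsistent with bps_type",
             call. = FALSE)
      tab <- table(factor(bps$bps_type, levels = BPS_CLASSES))
      counts[BPS_CLASSES] <- as.numeric(tab)
    }
    counts[["insertion"]] <- sum(x$class == "INS")
    counts[["deletion"]] <- sum(x$class == "DEL")
    return(counts)
  }
  if (is.numeric(x) && !is.null(names(x))) {
    unknown <- setdiff(names(x), MUTATION_CLASSES)
    if (length(unknown))
      stop("unknown mutation class: ", unknown[1], call. = FALSE)
    counts <- setNames(numeric(length(MUTATION_CLASSES)), MUTATION_CLASSES)
    counts[names(x)] <- x
    return(counts)
  }
  stop("cannot derive spectrum counts from ", class(x)[1], call. = FALSE)
}

#' @export
print.ma_spectrum <- function(x, digits = 3, ...) {
  cat("Mutation spectrum (rates per site per cell division)\n")
  cat(sprintf("  site-divisions: %s;  f(A:T) = %.4f, f(G:C) = %.4f\n",
              format(x$denominator, digits = 6), x$f_AT, x$f_GC))
  df <- do.call(rbind, lapply(x$estimates, rate_estimate_row))
  df$rate <- signif(df$rate, digits)
  df$ci_low <- signif(df$ci_low, digits)
  df$ci_high <- signif(df$ci_high, digits)
  names(df)[1] <- "class"
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ma_spectrum <- function(object, ...) {
  vapply(object$estimates, function(e) e$rate, numeric(1))
}

#' @export
confint.ma_spectrum <- function(object, parm, level, ...) {
  m <- t(vapply(object$estimates,
                function(e) c(e$ci_low, e$ci_high), numeric(2)))
  colnames(m) <- c("lower", "upper")
  m
}

#' @export
summary.ma_spectrum <- function(object, ...) {
  uv <- gc_direction_rates(object)
  s <- list(spectrum = object,
            mu_bps = object$bps,
            mu_indel = object$indel,
            indel_bps_percent = if (object$bps$count > 0)
              100 * object$indel$count / object$bps$count else NA_real_,
            m = at_bias(object),
            ts_tv = ts_tv(object),
            u = uv[["u"]], v = uv[["v"]],
            p_eq = equilibrium_at(uv[["u"]], uv[["v"]]))
  class(s) <- "summary.ma_spectrum"
  s
}

#' @export
print.summary.ma_spectrum <- function(x, digits = 3, ...) {
  print(x$spectrum, digits = digits)
  cat(sprintf("\nTotal base-substitution rate: %s (95%% CI %s, %s)\n",
              format(signif(x$mu_bps$rate, digits)),
              format(signif(x$mu_bps$ci_low, digits)),
              format(signif(x$mu_bps$ci_high, digits))))
  cat(sprintf("Indel rate: %s (%.2f%% of the base-substitution rate)\n",
              format(signif(x$mu_indel$rate, digits)),
              x$indel_bps_percent))
  cat(sprintf("A/T mutation bias m = %.2f;  ts/tv = %.2f\n", x$m, x$ts_tv))
  cat(sprintf("Equilibrium A+T content: %.2f%%\n", 100 * x$p_eq))
  invisible(x)
}

#' @export
plot.ma_spectrum <- function(x, ...) {
  rates <- coef(x)
  ci <- confint(x)
  bp <- graphics::barplot(rates, las = 2, ylim = c(0, max(ci) * 1.05),
                          ylab = "rate per site per division", ...)
  graphics::arrows(bp, ci[, 1], bp, ci[, 2], angle = 90, code = 3,
                   length = 0.04)
  invisible(bp)
}

# conditional rate sums in the two directions: u = toward G/C
# (A:T>G:C + A:T>C:G), v = toward A/T (G:C>A:T + G:C>T:A)
gc_direction_rates <- function(spectrum) {
  stopifnot(inherits(spectrum, "ma_spectrum"))
  r <- coef(spectrum)
  c(u = unname(r["A:T>G:C"] + r["A:T>C:G"]),
    v = unname(r["G:C>A:T"] + r["G:C>T:A"]))
}

#' Mutation bias toward A/T
#'
#' The ratio m of the A/T-direction conditional rate sum
#' (G:C>A:T + G:C>T:A) to the G/C-direction sum (A:T>G:C + A:T>C:G).
#' m > 1 means mutation pressure pushes the genome toward A+T.
#'
#' @param spectrum an `ma_spectrum`.
#' @return numeric; `Inf` with a warning when no G/C-direction
#'   mutations were observed.
#' @export
at_bias <- function(spectrum) {
  uv <- gc_direction_rates(spectrum)
  if (uv[["u"]] == 0) {
    warning("no mutations in the G/C direction; A/T bias is infinite")
    return(Inf)
  }
  uv[["v"]] / uv[["u"]]
}

#' Transition/transversion ratio
#'
#' Total transitions (G:C>A:T + A:T>G:C) over total transversions
#' (the remaining four classes), from observed counts.
#'
#' @param spectrum an `ma_spectrum`.
#' @return numeric; `Inf` with a warning when no transversions were
#'   observed.
#' @export
ts_tv <- function(spectrum) {
  ts <- sum(spectrum$counts[TRANSITION_CLASSES])
  tv <- sum(spectrum$counts[setdiff(BPS_CLASSES, TRANSITION_CLASSES)])
  if (tv == 0) {
    warning("no transversions observed; ts/tv is infinite")
    return(Inf)
  }
  ts / tv
}

#' Equilibrium A+T content under mutation pressure
#'
#' The A+T fraction the genome would reach under the observed mutation
#' pressure alone: p = v / (u + v), where u is the conditional rate sum
#' toward G/C and v the sum toward A/T.
#'
#' @param u conditional mutation rate toward G/C (A:T>G:C + A:T>C:G).
#' @param v conditional mutation rate toward A/T (G:C>A:T + G:C>T:A).
#' @return numeric in \[0, 1\].
#' @examples
#' equilibrium_at(1, 1)  # 0.5
#' @export
equilibrium_at <- function(u, v) {
  stopifnot(u >= 0, v >= 0)
  if (u + v == 0)
    stop("u + v must be positive", call. = FALSE)
  v / (u + v)
}

#' Coding versus non-coding mutation rates
#'
#' Rates conditioned on the coding/non-coding partition of the genome,
#' with a two-sided Fisher's exact test on the 2x2 table of mutation
#' counts against region site counts (a proxy for non-mutated
#' site-divisions, which differ by the shared division factor only).
#' Under effective neutrality in an MA experiment the two rates should
#' not differ.
#'
#' @param calls mutation call data frame or `ma_calls` (needs a
#'   `region` annotation; see [annotate_calls()]).
#' @param genome an [annotated_genome] with CDS models.
#' @param denominator a [site_divisions()] object or total
#'   site-divisions.
#' @return list with `coding` and `noncoding` [rate_estimate]s and
#'   `fisher_p`.
#' @export
region_rates <- function(calls, genome, denominator) {
  if (inherits(calls, "ma_calls")) calls <- calls$calls
  stopifnot(inherits(genome, "annotated_genome"))
  S_cod <- coding_site_count(genome)
  S_non <- genome_size(genome) - S_cod
  if (S_cod == 0 || S_non == 0)
    stop("genome has a region with zero sites", call. = FALSE)
  f_cod <- S_cod / (S_cod + S_non)
  M_cod <- sum(calls$region == "coding")
  M_non <- sum(calls$region == "noncoding")
  D <- denom_total(denominator)
  tab <- matrix(c(M_cod, M_non, S_cod, S_non), nrow = 2)
  list(coding = conditional_rate(M_cod, f_cod, D, label = "coding"),
       noncoding = conditional_rate(M_non, 1 - f_cod, D,
                                    label = "noncoding"),
       fisher_p = stats::fisher.test(tab)$p.value)
}
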