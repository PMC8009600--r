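BPS_CLASSES <- c("G:C>A:T", "A:T>G:C", "A:T>T:A",
                 "G:C>T:A", "A:T>C:G", "G:C>C:G")
TRANSITION_CLASSES <- c("G:C>A:T", "A:T>G:C")
GC_CONTEXT_CLASSES <- c("G:C>A:T", "G:C>T:A", "G:C>C:G")
AT_CONTEXT_CLASSES <- c("A:T>G:C", "A:T>C:G", "A:T>T:A")
MUTATION_CLASSES <- c(BPS_CLASSES, "insertion", "deletion")

# strand-symmetric substitution class from (ref, alt); vectorised
bps_class <- function(ref, alt) {
  key <- paste0(ref, alt)
  map <- c(GA = "G:C>A:T", CT = "G:C>A:T",
           AG = "A:T>G:C", TC = "A:T>G:C",
           AT = "A:T>T:A", TA = "A:T>T:A",
           GT = "G:C>T:A", CA = "G:C>T:A",
           AC = "A:T>C:G", TG = "A:T>C:G",
           GC = "G:C>C:G", CG = "G:C>C:G")
  out <- unname(map[key])
  if (anyNA(out))
    stop("invalid substitution: ", key[is.na(out)][1], call. = FALSE)
  out
}

#' Cell-division bookkeeping for an MA experiment
#'
#' Each single-cell bottleneck grows a colony whose cell count (CFU)
#' implies log2(CFU) cell divisions. The total number of divisions per
#' line is the mean of the per-colony estimates times the number of
#' transfers. A pre-computed mean may be supplied instead of raw CFU
#' counts (published means are typically rounded, so passing the mean
#' reproduces printed totals only approximately).
#'
#' @param cfu_values numeric vector of colony-forming-unit counts, or
#'   `NULL` when `mean_divisions` is given directly.
#' @param transfers number of single-cell bottlenecks per line.
#' @param mean_divisions optional pre-computed mean divisions per
#'   transfer, used when `cfu_values` is `NULL` or empty.
#' @return list of class `experiment_design`: `transfers`,
#'   `divisions_per_transfer` (per-colony log2(CFU)),
#'   `mean_divisions`, `total_divisions`.
#' @examples
#' estimate_divisions(2^20, transfers = 10)$total_divisions  # 200
#' @export
estimate_divisions <- function(cfu_values = NULL, transfers,
                               mean_divisions = NULL) {
  stopifnot(transfers > 0)
  if (length(cfu_values)) {
    if (any(cfu_values <= 0))
      stop("CFU counts must be positive", call. = FALSE)
    d <- log2(cfu_values)
    mean_divisions <- mean(d)
  } else {
    if (is.null(mean_divisions))
      stop("need CFU values or an explicit mean_divisions", call. = FALSE)
    d <- numeric()
  }
  structure(list(transfers = transfers, divisions_per_transfer = d,
                 mean_divisions = mean_divisions,
                 total_divisions = mean_divisions * transfers),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("MA experiment design:", x$transfers, "transfers,",
      sprintf("%.2f", x$mean_divisions), "divisions/transfer, T =",
      sprintf("%.0f", x$total_divisions), "divisions/line\n")
  invisible(x)
}

#' Exact Poisson confidence interval for a count
#'
#' Two-sided exact (Garwood) interval for the Poisson mean given an
#' observed count, via the chi-squared quantile identity: the lower
#' bound solves P(X >= count | lambda) = alpha/2 (0 for a zero count)
#' and the upper bound solves P(X <= count | lambda) = alpha/2.
#'
#' @param count non-negative integer count.
#' @param level confidence level in (0, 1); default 0.95.
#' @return numeric vector `c(lower, upper)` on the count (mean) scale.
#' @examples
#' poisson_ci(0)   # c(0, -log(0.025)) = c(0, 3.6889)
#' @export
poisson_ci <- function(count, level = 0.95) {
  if (level <= 0 || level >= 1)
    stop("confidence level must be in (0, 1)", call. = FALSE)
  if (length(count) != 1 || is.na(count) || count < 0 ||
      count != round(count))
    stop("count must be a single non-negative integer", call. = FALSE)
  alpha <- 1 - level
  lower <- if (count == 0) 0 else stats::qchisq(alpha / 2, 2 * count) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * count + 2) / 2
  c(lower = lower, upper = upper)
}

#' Site-division denominator
#'
#' The denominator of the mutation-rate estimator: the sum over lines
#' of (analyzed sites x cell divisions).
#'
#' @param n_sites named numeric vector of analyzed site counts per
#'   line, or a single site count shared by all lines (then `n_lines`
#'   must be given).
#' @param divisions cell divisions per line (scalar or per-line vector
#'   aligned with `n_sites`).
#' @param n_lines number of lines when `n_sites` is scalar.
#' @return list of class `site_divisions`: `N`, `T`, `total`.
#' @examples
#' site_divisions(5171217, 4517, n_lines = 52)$total
#' @export
site_divisions <- function(n_sites, divisions, n_lines = NULL) {
  if (length(n_sites) == 1 && !is.null(n_lines))
    n_sites <- rep(n_sites, n_lines)
  stopifnot(all(n_sites >= 0), all(divisions > 0),
            length(divisions) %in% c(1L, length(n_sites)))
  total <- sum(n_sites * divisions)
  if (total <= 0) stop("site-division denominator is zero", call. = FALSE)
  structure(list(N = n_sites, T = divisions, total = total),
            class = "site_divisions")
}

denom_total <- function(denominator) {
  if (inherits(denominator, "site_divisions")) denominator$total
  else as.numeric(denominator)
}

#' Mutation rate with exact Poisson confidence interval
#'
#' rate = M / (sum over lines of N x T), in mutations per site per cell
#' division, with the exact Poisson interval on M scaled by the same
#' denominator.
#'
#' @param M observed mutation count.
#' @param denominator a [site_divisions()] object or the total
#'   site-division count as a number.
#' @param label optional label for printing.
#' @param level confidence level.
#' @return object of class `rate_estimate` with fields `count`,
#'   `denominator`, `rate`, `ci_low`, `ci_high`, `label`.
#' @examples
#' mutation_rate(72, site_divisions(5171217, 4517, n_lines = 52))
#' @export
mutation_rate <- function(M, denominator, label = "mutation rate",
                          level = 0.95) {
  D <- denom_total(denominator)
  if (!is.finite(D) || D <= 0)
    stop("denominator must be positive", call. = FALSE)
  ci <- poisson_ci(M, level)
  structure(list(count = M, denominator = D, rate = M / D,
                 ci_low = ci[["lower"]] / D, ci_high = ci[["upper"]] / D,
                 label = label),
            class = "rate_estimate")
}

#' Conditional (per-context) mutation rate
#'
#' Rate of a mutation class normalized by the sites where it can occur:
#' count / (context_fraction x total site-divisions), the confidence
#' interval scaled identically.
#'
#' @param count observed count in the class.
#' @param context_fraction fraction of analyzed sites in the class's
#'   context (e.g. the genome G+C fraction for G:C-context classes);
#'   must be in (0, 1].
#' @param denominator a [site_divisions()] object or total
#'   site-divisions.
#' @param label optional label.
#' @param level confidence level.
#' @return a `rate_estimate`.
#' @export
conditional_rate <- function(count, context_fraction, denominator,
                             label = "conditional rate", level = 0.95) {
  if (context_fraction <= 0 || context_fraction > 1)
    stop("context_fraction must be in (0, 1]", call. = FALSE)
  mutation_rate(count, denom_total(denominator) * context_fraction,
                label = label, level = level)
}

#' @export
print.rate_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s: %s per site per division (95%% CI %s, %s; count %d)\n",
              x$label, format(signif(x$rate, digits)),
              format(signif(x$ci_low, digits)),
              format(signif(x$ci_high, digits)), x$count))
  invisible(x)
}

rate_estimate_row <- function(x) {
  data.frame(label = x$label, count = x$count, rate = x$rate,
             ci_low = x$ci_low, ci_high = x$ci_high,
             stringsAsFactors = FALSE)
}
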