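#' Digestion-resistance estimate from paired q-PCR threshold cycles
#'
#' For each target/stage/pool the same DNA mass is amplified after digestion
#' with the mark-sensitive enzyme and without digestion. The cycle difference
#' `delta_ct = ct_digested - ct_undigested` measures the template fraction
#' that resisted cleavage: with perfect doubling per cycle the resistant
#' (methylated or hydroxymethylated) proportion is
#' `efficiency^(-delta_ct)`, clamped to `[0, 1]` and flagged when the raw
#' value exceeds 1 (a negative delta Ct).
#'
#' @param records data.frame with columns `target`, `stage`, `pool`,
#'   `ct_digested`, `ct_undigested` (all cycle values > 0).
#' @param efficiency amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @return data.frame with `target`, `stage`, `pool`, `delta_ct`,
#'   `resistant_fraction`, `flag_out_of_range`.
#' @export
resistance <- function(records, efficiency = 2) {
  .stop_if_missing_cols(records, c("target", "stage", "pool", "ct_digested",
                                   "ct_undigested"), "q-PCR table")
  if (any(is.na(records$ct_digested) | is.na(records$ct_undigested))) {
    stop("missing pair member: both aliquot Ct values are required")
  }
  if (any(records$ct_digested <= 0 | records$ct_undigested <= 0)) {
    stop("cycle values must be > 0")
  }
  delta <- records$ct_digested - records$ct_undigested
  raw <- efficiency^(-delta)
  data.frame(target = records$target, stage = records$stage,
             pool = records$pool, delta_ct = delta,
             resistant_fraction = pmin(1, pmax(0, raw)),
             flag_out_of_range = raw > 1, stringsAsFactors = FALSE)
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Enumerates every assignment of the pooled observations into two groups of
#' the observed sizes and computes the exact two-sided p-value of the
#' rank-sum statistic: twice the smaller tail probability, capped at 1. Ties
#' are handled by mid-ranks. For combined sample sizes above `exact_limit`
#' the normal approximation (with tie-corrected variance and continuity
#' correction) is used with a warning.
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @param exact_limit largest combined n for exhaustive enumeration.
#' @return the two-sided p-value.
#' @export
wilcoxon_exact <- function(group_a, group_b, exact_limit = 12L) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  na <- length(group_a)
  x <- c(group_a, group_b)
  n <- length(x)
  r <- rank(x)          # mid-ranks for ties
  w_obs <- sum(r[seq_len(na)])
  if (n <= exact_limit) {
    combs <- combn(n, na)
    w_all <- colSums(matrix(r[combs], nrow = na))
    lo <- mean(w_all <= w_obs + 1e-9)
    hi <- mean(w_all >= w_obs - 1e-9)
    min(1, 2 * min(lo, hi))
  } else {
    warning("combined n exceeds exact enumeration limit; ",
            "using the normal approximation")
    mu <- na * (n + 1) / 2
    ties <- table(r)
    sig2 <- na * (n - na) / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sig2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Between-stage comparison of resistant fractions
#'
#' For each target, the replicate-pool resistant fractions of the two stages
#' are compared with [wilcoxon_exact()]; stages receive significance letter
#' groups at `alpha` (the same letter when not significantly different).
#' Note the exact-test floor: with three pools per stage the smallest
#' attainable two-sided p is 0.1, so fully separated 3-vs-3 data are still
#' "not significant" at 0.05.
#'
#' @param estimates data.frame from [resistance()].
#' @param alpha significance level.
#' @return data.frame with one row per target: `target`, the two stage
#'   means, `p_value`, `significant`, and the per-stage letters
#'   `letter_<stage>`.
#' @export
compare_stages <- function(estimates, alpha = 0.05) {
  stages <- sort(unique(estimates$stage))
  if (length(stages) != 2L) stop("exactly two stages are required, got ",
                                 length(stages))
  out <- list()
  for (tg in unique(estimates$target)) {
    e <- estimates[estimates$target == tg, , drop = FALSE]
    a <- e$resistant_fraction[e$stage == stages[1]]
    b <- e$resistant_fraction[e$stage == stages[2]]
    if (length(a) < 2L || length(b) < 2L) {
      stop("insufficient replicate pools for target ", tg,
           " (need >= 2 per stage)")
    }
    p <- wilcoxon_exact(a, b)
    sig <- p < alpha
    row <- data.frame(target = tg, mean_a = mean(a), mean_b = mean(b),
                      p_value = p, significant = sig,
                      letter_a = "a", letter_b = if (sig) "b" else "a",
                      stringsAsFactors = FALSE)
    names(row)[c(2, 3, 6, 7)] <- c(paste0("mean_", stages),
                                   paste0("letter_", stages))
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a q-PCR Ct table
#'
#' CSV with columns target, stage, pool, ct_digested, ct_undigested.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_qpcr <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  .stop_if_missing_cols(tab, c("target", "stage", "pool", "ct_digested",
                               "ct_undigested"), "q-PCR CSV")
  tab
}
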