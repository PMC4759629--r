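#' Three-region definition for folding-versus-length signals
#'
#' Folding-versus-length (FactSeq-style) signals are interpreted through
#' three codon-index regions: Region I, the first codons where the chain is
#' still inside the exit tunnel and any signal must come from unfolded
#' protein (baseline); Region II, lengths at which the domain is expected
#' to be unfolded; and Region III, lengths at which it is expected to be
#' folded. The intervals must be disjoint, ordered and non-empty.
#'
#' @param region1,region2,region3 Length-2 integer vectors
#'   `c(start, end)`, 1-based inclusive.
#' @return An object of class `region_definition`.
#' @export
region_definition <- function(region1 = c(1, 50), region2, region3) {
  regs <- list(I = as.integer(region1), II = as.integer(region2),
               III = as.integer(region3))
  for (nm in names(regs)) {
    r <- regs[[nm]]
    if (length(r) != 2L || r[1] < 1L || r[2] < r[1]) {
      stop(sprintf("region %s must be c(start, end) with 1 <= start <= end", nm),
           call. = FALSE)
    }
  }
  if (regs$I[2] >= regs$II[1] || regs$II[2] >= regs$III[1]) {
    stop("regions must be ordered and disjoint (I < II < III)", call. = FALSE)
  }
  structure(regs, class = "region_definition")
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided test of location shift. For small samples (all subset
#' assignments enumerable, up to `choose(n1+n2, min(n1,n2)) <= 5e5`) the
#' p-value is computed by exhaustive enumeration of the permutation
#' distribution of the rank sum, which is exact under ties. For larger
#' samples the normal approximation with midranks, tie correction and
#' continuity correction is used. Samples whose pooled values are all tied
#' return p = 1.
#'
#' @param x,y Numeric samples.
#' @return A list with `statistic` (Mann-Whitney U of `x`), `p.value` and
#'   `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])                  # rank sum of x (midranks)
  U <- W - n1 * (n1 + 1) / 2
  EW <- n1 * (n1 + n2 + 1) / 2
  n_comb <- choose(n1 + n2, min(n1, n2))
  if (n_comb <= 5e5) {
    k <- min(n1, n2)
    idx <- utils::combn(n1 + n2, k)
    sums <- colSums(matrix(r[idx], nrow = k))
    if (k != n1) sums <- sum(r) - sums       # rank sums of the x-sized group
    p <- mean(abs(sums - EW) >= abs(W - EW) - 1e-9)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    varW <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (varW <= 0) {
      p <- 1
    } else {
      z <- (abs(W - EW) - 0.5) / sqrt(varW)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    method <- "normal"
  }
  list(statistic = U, p.value = min(p, 1), method = method)
}

# percentile bootstrap CI of the median, chunked to bound memory
bootstrap_median_ci <- function(x, n_boot, conf = 0.95) {
  if (n_boot <= 0) return(c(NA_real_, NA_real_))
  meds <- numeric(n_boot)
  done <- 0L
  chunk <- max(1L, min(n_boot, floor(5e6 / length(x))))
  while (done < n_boot) {
    m <- min(chunk, n_boot - done)
    samp <- matrix(sample(x, m * length(x), replace = TRUE), ncol = m)
    meds[(done + 1L):(done + m)] <- apply(samp, 2, stats::median)
    done <- done + m
  }
  alpha <- (1 - conf) / 2
  unname(stats::quantile(meds, c(alpha, 1 - alpha), type = 7))
}

#' Compare the three regions of a folding-versus-length signal
#'
#' Pairwise two-sided rank-sum tests between the per-codon signals of
#' Regions I, II and III, region medians with percentile-bootstrap
#' confidence intervals, and a same/different verdict per pair at
#' `alpha = 0.05`. An unfolded Region II should be statistically
#' indistinguishable from the Region I baseline, while a folded Region III
#' should differ from both.
#'
#' @param signal Numeric vector of per-codon signal values; must cover all
#'   three regions.
#' @param regions A [region_definition()].
#' @param bootstrap_n Bootstrap replications for the median CIs (default
#'   100000; `0` skips the bootstrap and returns `NA` intervals).
#' @param conf Confidence level for the median CIs.
#' @param alpha Significance level for the verdicts.
#' @return An object of class `region_report`: list with `medians`,
#'   `ci` (2 x 3 matrix), `tests` (data frame of pairs, U, p, verdict) and
#'   `alpha`.
#' @export
compare_regions <- function(signal, regions, bootstrap_n = 100000,
                            conf = 0.95, alpha = 0.05) {
  stopifnot(inherits(regions, "region_definition"), is.numeric(signal))
  if (length(signal) < regions$III[2]) {
    stop("signal does not cover Region III", call. = FALSE)
  }
  vals <- lapply(regions, function(r) signal[r[1]:r[2]])
  if (any(vapply(vals, length, integer(1)) < 3L)) {
    stop("each region must contain at least 3 points", call. = FALSE)
  }
  medians <- vapply(vals, stats::median, numeric(1))
  ci <- vapply(vals, bootstrap_median_ci, numeric(2), n_boot = bootstrap_n,
               conf = conf)
  rownames(ci) <- c("lower", "upper")
  pairs <- list(c("I", "II"), c("I", "III"), c("II", "III"))
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    ts <- rank_sum_test(vals[[pr[1]]], vals[[pr[2]]])
    data.frame(pair = paste(pr, collapse = " vs "),
               U = ts$statistic, p.value = ts$p.value, method = ts$method,
               verdict = if (ts$p.value < alpha) "different" else "same")
  }))
  structure(list(medians = medians, ci = ci, tests = tests, alpha = alpha),
            class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat("<region_report>\n  medians:",
      paste(sprintf("%s = %.4g", names(x$medians), x$medians), collapse = ", "),
      "\n")
  for (i in seq_len(nrow(x$tests))) {
    cat(sprintf("  %s: U = %g, p = %.3g (%s) -> %s\n",
                x$tests$pair[i], x$tests$U[i], x$tests$p.value[i],
                x$tests$method[i], x$tests$verdict[i]))
  }
  invisible(x)
}
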