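# Shared fixtures and independent oracles for the test suite.

# a complete 64-codon table with constant time per codon
flat_table <- function(time = 0.25) {
  codons <- c(names(Biostrings::GENETIC_CODE))
  codon_rate_table(stats::setNames(rep(time, 64), codons), kind = "time")
}

# random CDS of n codons (sense codons + one stop), RNA alphabet
random_cds <- function(n) {
  code <- Biostrings::GENETIC_CODE
  rna <- chartr("T", "U", names(code))
  sense <- rna[code != "*"]
  stops <- rna[code == "*"]
  paste(c(sample(sense, n - 1, replace = TRUE), sample(stops, 1)),
        collapse = "")
}

# Independent brute-force oracle for the steady-state profile: simulates
# chains codon by codon (exponential dwells, explicit folding jump chains)
# and records the folded state at the end of each dwell. Deliberately
# written as a plain per-codon loop, sharing no code with the package
# engines.
brute_force_profile <- function(kA, kF, kU, onset, n_chains) {
  M <- length(kA)
  counts <- numeric(M)
  for (ch in seq_len(n_chains)) {
    folded <- FALSE
    for (i in seq_len(M)) {
      dwell <- stats::rexp(1, kA[i])
      if (i >= onset) {
        t <- 0
        repeat {
          r <- if (folded) kU else kF
          if (r <= 0) break
          t <- t + stats::rexp(1, r)
          if (t >= dwell) break
          folded <- !folded
        }
      }
      if (folded) counts[i] <- counts[i] + 1
    }
  }
  counts / n_chains
}

# Independent permutation oracle for the two-sided rank-sum test: counts
# x>y / tied pairs per subset assignment (no rank vector shared with the
# implementation under test).
permutation_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (N - n1) / 2
  all_u <- apply(utils::combn(N, n1), 2, u_of)
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}
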