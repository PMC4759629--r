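test_that("codon rate tables validate and normalize their input", {
  tab <- codon_rate_table(c(GGT = 0.2, AAA = 0.5), kind = "time")
  expect_setequal(names(tab$values), c("GGU", "AAA"))
  expect_error(codon_rate_table(c(XXX = 1), "time"), "unknown codon")
  expect_error(codon_rate_table(c(GGU = -1), "time"), "strictly positive")
  expect_error(codon_rate_table(c(GGU = 0.1, GGT = 0.2), "time"), "duplicate")

  # time <-> rate conversions are exact reciprocals and invertible
  r <- as_kind(tab, "rate")
  expect_equal(unname(r$values[c("GGU", "AAA")]), c(5, 2))
  expect_equal(as_kind(r, "time")$values, tab$values)
})

test_that("build_schedule maps codons to rates with the stated fallbacks", {
  # complete table: no fallback anywhere
  sched <- build_schedule("GGTAAATAA", flat_table(0.25))
  expect_equal(sched$rates, rep(4, 3))
  expect_length(attr(sched, "fallback_codons"), 0)

  # missing stop codon takes the 256 ms default: k_A,M = 1/0.256 AA/s
  tab <- codon_rate_table(c(GGU = 0.2), kind = "time")
  sched <- build_schedule("GGUGGUUAA", tab, stop_default_time = 0.256)
  expect_equal(sched$rates[3], 1 / 0.256)
  expect_equal(sched$rates[3], 3.906, tolerance = 1e-3)

  # missing sense codons take the table mean (here the single GGU value)
  expect_equal(sched$rates[1:2], c(5, 5))
  sched2 <- build_schedule("AAAGGUUAA", tab)  # AAA absent -> mean time 0.2
  expect_equal(sched2$rates[1], 5)
  expect_setequal(attr(sched2, "fallback_codons"), c("AAA", "UAA"))
  expect_error(build_schedule("AAAGGUUAA", tab, missing = "error"),
               "lacks sense codon")

  # cumulative times are the running mean synthesis time
  expect_equal(sched$tau_cum, cumsum(1 / sched$rates))

  expect_error(build_schedule("GGUGG", flat_table()), "coding-frame")
  expect_error(build_schedule("GGXGGUUAA", flat_table()), "alphabet")
  expect_warning(build_schedule("UAAGGUUAA", flat_table()), "internal stop")
})

test_that("scale_to_target reproduces the arithmetic-mean chi convention", {
  # identity: table already at target
  tab <- flat_table(1 / 3.9)
  res <- scale_to_target(tab, "GGUAAAUAA", target_mean_rate = 3.9)
  expect_equal(res$chi, 1)
  expect_equal(res$achieved_mean_rate, 3.9)

  # scale invariance: doubling all rates halves chi, same scaled table
  tab2 <- codon_rate_table(tab$values / 2, kind = "time")  # times halved = rates doubled
  res2 <- scale_to_target(tab2, "GGUAAAUAA", target_mean_rate = 3.9)
  expect_equal(res2$chi, res$chi / 2)
  expect_equal(res2$table$values, res$table$values)

  # hand-computed 10-codon example: chi = target / arithmetic mean of rates
  set.seed(42)
  cds <- random_cds(10)
  times <- stats::runif(64, 0.05, 0.6)
  names(times) <- names(Biostrings::GENETIC_CODE)
  tab3 <- codon_rate_table(times, kind = "time")
  codons <- substring(chartr("T", "U", cds), seq(1, 28, 3), seq(3, 30, 3))
  hand_mean <- mean(1 / times[chartr("U", "T", codons)])
  res3 <- scale_to_target(tab3, cds, target_mean_rate = 3.9)
  expect_equal(res3$chi, 3.9 / hand_mean)
  expect_equal(res3$achieved_mean_rate, 3.9, tolerance = 1e-12)

  # idempotence: re-scaling the scaled table to the same target gives chi = 1
  res4 <- scale_to_target(res3$table, cds, target_mean_rate = 3.9,
                          stop_default_time = res3$stop_default_time)
  expect_equal(res4$chi, 1, tolerance = 1e-12)

  expect_error(scale_to_target(tab, "GGUAAAUAA", target_mean_rate = 0),
               "positive")
})

test_that("slowest-synonymous recoding preserves the protein exactly", {
  # toy table in which GGG is the slowest glycine codon
  times <- rep(0.2, 64)
  names(times) <- names(Biostrings::GENETIC_CODE)
  times["GGG"] <- 0.9
  tab <- codon_rate_table(times, kind = "time")
  expect_equal(recode_slowest_synonymous("GGUGGCUAA", tab), "GGGGGGUAA")

  # fixed point: a slowest-codon CDS is unchanged
  rec <- recode_slowest_synonymous("GGGGGGUAA", tab)
  expect_equal(rec, "GGGGGGUAA")

  # single-codon amino acids (Met, Trp) and stops are never touched;
  # DNA input comes back in DNA
  expect_equal(recode_slowest_synonymous("ATGTGGTAA", tab), "ATGTGGTAA")

  # property over random instances: protein unchanged (Biostrings oracle)
  # and no per-position rate ever increases (monotone slowdown)
  set.seed(7)
  for (i in 1:15) {
    cds <- random_cds(40)
    t2 <- stats::rlnorm(64, log(0.25), 0.5)
    names(t2) <- names(Biostrings::GENETIC_CODE)
    tab2 <- codon_rate_table(t2, kind = "time")
    rec <- recode_slowest_synonymous(cds, tab2)
    aa_wt <- as.character(Biostrings::translate(
      Biostrings::DNAString(chartr("U", "T", cds))))
    aa_rec <- as.character(Biostrings::translate(
      Biostrings::DNAString(chartr("U", "T", rec))))
    expect_equal(aa_rec, aa_wt)
    expect_true(all(build_schedule(rec, tab2)$rates <=
                      build_schedule(cds, tab2)$rates + 1e-12))
  }
})

test_that("recoding ties break to the lexicographically smallest codon", {
  tab <- flat_table(0.25)  # every synonym tied
  # glycine synonyms GGA/GGC/GGG/GGU all tie -> GGA
  expect_equal(recode_slowest_synonymous("GGUUAA", tab), "GGAUAA")
})
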