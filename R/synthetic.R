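#' Specification for a synthetic test fixture
#'
#' The synthetic-fixtures generator produces self-consistent bundles (CDS,
#' codon rate table, construct, schedule, folding-versus-length signal)
#' spanning the folding/translation timescale regimes that control
#' co-translational folding behaviour: `"fast_folder"` (folding much
#' faster than elongation; `P_F,Co-T > 0.95`), `"slow_folder"`
#' (`P_F,Co-T < 0.05`) and `"marginal"` (bulk folding rate within 10x of
#' the mean translation rate and a short post-onset tail, rejection-sampled
#' until `0.05 < P_F,Co-T < 0.95`, so that synonymous recoding can flip the
#' co/post classification).
#'
#' @param length_codons CDS length in codons including the stop (default
#'   60; must exceed `tunnel_length + 1`).
#' @param regime Folding regime; see Details.
#' @param time_meanlog,time_sdlog Log-normal parameters of the per-codon
#'   translation times in seconds (defaults centred on 0.25 s).
#' @param tunnel_length Exit-tunnel linker length, residues.
#' @param signal_length,signal_baseline,signal_dispersion,signal_shift
#'   Parameters of the FactSeq-like per-codon signal: a nominal protein of
#'   `signal_length` codons with Gaussian baseline noise (truncated at 0)
#'   and an additive shift over Region III.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(length_codons = 60,
                         regime = c("marginal", "fast_folder", "slow_folder"),
                         time_meanlog = log(0.25), time_sdlog = 0.4,
                         tunnel_length = 30,
                         signal_length = 400, signal_baseline = 0.1,
                         signal_dispersion = 0.05, signal_shift = 0.4) {
  regime <- match.arg(regime)
  stopifnot(length_codons >= tunnel_length + 2, time_sdlog >= 0,
            signal_length > 160, signal_dispersion > 0)
  structure(list(length_codons = as.integer(length_codons), regime = regime,
                 time_meanlog = time_meanlog, time_sdlog = time_sdlog,
                 tunnel_length = tunnel_length,
                 signal_length = as.integer(signal_length),
                 signal_baseline = signal_baseline,
                 signal_dispersion = signal_dispersion,
                 signal_shift = signal_shift),
            class = "fixture_spec")
}

#' Generate a synthetic fixture bundle
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed; identical seed and spec give identical
#'   bundles.
#' @param max_tries Rejection-sampling budget for the marginal regime.
#' @return A list with elements `cds`, `table` (a [codon_rate_table()]),
#'   `construct`, `schedule`, `profile` (the [steady_state_profile()] at
#'   the generated rates), `signal`, `regions` and `spec`.
#' @export
generate_fixture <- function(spec, seed = 1, max_tries = 500) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(seed)
  times <- stats::rlnorm(64, meanlog = spec$time_meanlog, sdlog = spec$time_sdlog)
  names(times) <- all_codons()
  table <- codon_rate_table(times, kind = "time", label = "synthetic")
  L <- spec$length_codons
  cds <- paste(c(sample(sense_codons(), L - 1L, replace = TRUE),
                 sample(stop_codons(), 1L)), collapse = "")
  schedule <- build_schedule(cds, table)
  mean_kA <- mean(schedule$rates)

  make <- function(kF, kU, n_tail) {
    onset <- L - n_tail + 1L
    construct("synthetic", M = L,
              domain_start = 1L, domain_end = onset - spec$tunnel_length,
              bulk_kF = kF, bulk_kU = kU, tunnel_length = spec$tunnel_length)
  }
  profile_of <- function(cst) steady_state_profile(build_kinetics(cst), schedule)

  if (spec$regime == "fast_folder") {
    cst <- make(100 * mean_kA, 1e-2 * mean_kA, n_tail = 8L)
    prof <- profile_of(cst)
    if (prof$P_F_CoT <= 0.95) {
      stop("fast_folder fixture failed to reach P_F,Co-T > 0.95", call. = FALSE)
    }
  } else if (spec$regime == "slow_folder") {
    cst <- make(mean_kA / 1000, mean_kA / 1e5, n_tail = 4L)
    prof <- profile_of(cst)
    if (prof$P_F_CoT >= 0.05) {
      stop("slow_folder fixture failed to stay below P_F,Co-T < 0.05",
           call. = FALSE)
    }
  } else {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      n_tail <- sample(2:5, 1L)   # onset must precede the stop codon
      kF <- exp(stats::runif(1, log(mean_kA / 10), log(mean_kA * 10)))
      cst <- make(kF, kF / 100, n_tail)
      prof <- profile_of(cst)
      if (prof$P_F_CoT > 0.05 && prof$P_F_CoT < 0.95) { ok <- TRUE; break }
    }
    if (!ok) {
      stop(sprintf(paste0("marginal regime unsatisfiable after %d tries ",
                          "(mean rate %.3g AA/s, last P_F,Co-T = %.3g)"),
                   max_tries, mean_kA, prof$P_F_CoT), call. = FALSE)
    }
  }

  regions <- region_definition(c(1, 50), c(51, 150), c(151, spec$signal_length))
  signal <- pmax(0, stats::rnorm(spec$signal_length, spec$signal_baseline,
                                 spec$signal_dispersion))
  signal[regions$III[1]:regions$III[2]] <-
    signal[regions$III[1]:regions$III[2]] + spec$signal_shift

  list(cds = cds, table = table, construct = cst, schedule = schedule,
       profile = prof, signal = signal, regions = regions, spec = spec)
}

#' Bundled example constructs with literature-reported parameters
#'
#' Returns the model parameters of the eight constructs whose
#' co-translational folding behaviour has been characterized in vivo:
#' Semliki Forest virus protein (SFVP) wild-type and its N-terminal
#' deletion mutant (pulse-chase, CHO cells; the observable region is
#' bounded by the last radiolabelled Met at residue 255, hence an
#' observable length of 143 = 255 - 112 for the deletion mutant), the
#' Flag-FRB-GFP FKBP12-rapamycin-binding domain and influenza HA1
#' (FactSeq), and four yeast proteins (DHOM, SBA1, EF2, DPP3) whose
#' domains can switch folding class under synonymous recoding. All use a
#' 30-residue exit-tunnel linker; the default uniform translation rate is
#' 3.9 AA per second (attribute `default_rate`).
#'
#' @return Named list of [construct()] objects.
#' @export
construct_presets <- function() {
  presets <- list(
    SFVP_WT = construct("SFVP_WT", M = 1257, domain_start = 1,
                        domain_end = 267, bulk_kF = 20, bulk_kU = 4.34e-5,
                        observable_codons = 1:255, observable_length = 255),
    SFVP_dC = construct("SFVP_dC", M = 1145, domain_start = 1,
                        domain_end = 155, bulk_kF = 20, bulk_kU = 4.34e-5,
                        observable_codons = 1:143, observable_length = 143),
    FRB = construct("FRB", M = 379, domain_start = 11, domain_end = 99,
                    bulk_kF = 15.93, bulk_kU = 0.72,
                    observable_codons = 1:99, observable_length = 99),
    HA1 = construct("HA1", M = 565, domain_start = 53, domain_end = 275,
                    bulk_kF = 0.1378, bulk_kU = 7.58e-5,
                    observable_length = 222),
    DHOM = construct("DHOM", M = 359, domain_start = 1, domain_end = 161,
                     bulk_kF = 0.0240, bulk_kU = 2.48e-8),
    SBA1 = construct("SBA1", M = 216, domain_start = 1, domain_end = 135,
                     bulk_kF = 0.0721, bulk_kU = 5.40e-6),
    EF2 = construct("EF2", M = 842, domain_start = 570, domain_end = 721,
                    bulk_kF = 0.0501, bulk_kU = 1.03e-7,
                    observable_length = 151),
    DPP3 = construct("DPP3", M = 711, domain_start = 431, domain_end = 671,
                     bulk_kF = 0.1811, bulk_kU = 4.33e-9,
                     observable_length = 240))
  attr(presets, "default_rate") <- 3.9
  presets
}
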