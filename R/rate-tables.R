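#' Per-codon translation rate or time table
#'
#' A codon rate table stores one positive value per codon, either as a
#' translation time (seconds per codon) or as a rate (amino acids per
#' second). Tables may be partial (e.g. only the 16 codons reported by some
#' ribosome-profiling analyses); missing codons are filled downstream by
#' [build_schedule()] according to its `missing` policy. DNA and RNA codon
#' spellings are both accepted and normalized to RNA internally.
#'
#' @param values Named numeric vector; names are codons (3-letter, ACGT or
#'   ACGU), values strictly positive and finite.
#' @param kind Either `"time"` (seconds per codon) or `"rate"` (AA per
#'   second).
#' @param label Free-text provenance label.
#' @return An object of class `codon_rate_table`.
#' @seealso [as_kind()], [build_schedule()], [scale_to_target()]
#' @export
codon_rate_table <- function(values, kind = c("time", "rate"), label = "") {
  kind <- match.arg(kind)
  if (!is.numeric(values) || is.null(names(values)) || length(values) == 0L) {
    stop("`values` must be a non-empty named numeric vector", call. = FALSE)
  }
  codons <- normalize_codon(names(values))
  bad <- setdiff(codons, all_codons())
  if (length(bad) > 0L) {
    stop("unknown codon(s) in rate table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(codons)) {
    stop("duplicate codons in rate table after DNA/RNA normalization",
         call. = FALSE)
  }
  v <- as.numeric(values)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all rate-table values must be strictly positive and finite",
         call. = FALSE)
  }
  names(v) <- codons
  structure(list(values = v, kind = kind, label = label),
            class = "codon_rate_table")
}

#' @export
print.codon_rate_table <- function(x, ...) {
  cat(sprintf("<codon_rate_table> %d codons, kind = %s%s\n",
              length(x$values), x$kind,
              if (nzchar(x$label)) paste0(", label = ", x$label) else ""))
  invisible(x)
}

#' Convert a codon rate table between time and rate representations
#'
#' Times and rates are exact reciprocals of one another.
#'
#' @param table A [codon_rate_table()].
#' @param kind Target representation, `"time"` or `"rate"`.
#' @return A `codon_rate_table` in the requested representation.
#' @export
as_kind <- function(table, kind = c("time", "rate")) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "codon_rate_table"))
  if (identical(table$kind, kind)) return(table)
  codon_rate_table(1 / table$values, kind = kind, label = table$label)
}

#' Translation schedule: one rate per codon position
#'
#' A schedule holds the position-resolved elongation rates k_A,i (AA per
#' second) for codon positions 1..M (1-based, the final position being the
#' stop codon when the CDS carries one) and the cumulative mean times
#' tau_cum(i) = sum_{j<=i} 1/k_A,j. tau_cum(M) is the mean synthesis time
#' used throughout the pulse-chase and stochastic engines.
#'
#' @param rates Numeric vector of strictly positive per-position rates.
#' @param codons Optional character vector of codons matching `rates`.
#' @return An object of class `translation_schedule` with fields `rates`,
#'   `tau_cum`, `M` and (optionally) `codons`.
#' @export
translation_schedule <- function(rates, codons = NULL) {
  if (!is.numeric(rates) || length(rates) < 1L) {
    stop("`rates` must be a numeric vector of length >= 1", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all schedule rates must be strictly positive and finite", call. = FALSE)
  }
  if (!is.null(codons) && length(codons) != length(rates)) {
    stop("`codons` must match `rates` in length", call. = FALSE)
  }
  structure(list(rates = as.numeric(rates),
                 tau_cum = cumsum(1 / as.numeric(rates)),
                 M = length(rates),
                 codons = codons),
            class = "translation_schedule")
}

#' Uniform translation schedule
#'
#' Convenience constructor for the common modelling assumption that every
#' codon translates at the cell's average rate.
#'
#' @param M Number of codon positions, including the stop codon.
#' @param rate Global translation rate in AA per second (default 3.9, the
#'   value measured for SFVP synthesis in CHO cells).
#' @return A [translation_schedule()].
#' @export
uniform_schedule <- function(M, rate = 3.9) {
  translation_schedule(rep(rate, M))
}

#' @export
print.translation_schedule <- function(x, ...) {
  cat(sprintf("<translation_schedule> M = %d codons, mean rate = %.4g AA/s, mean synthesis time = %.4g s\n",
              x$M, mean(x$rates), x$tau_cum[x$M]))
  invisible(x)
}

# internal: per-codon rates for a set of codons with fallback bookkeeping
lookup_rates <- function(codons, table, stop_default_time, missing) {
  rates_tab <- as_kind(table, "rate")$values
  stops <- stop_codons()
  out <- rates_tab[codons]
  fallback <- character(0)
  miss <- is.na(out)
  if (any(miss)) {
    miss_stop <- miss & codons %in% stops
    miss_sense <- miss & !miss_stop
    if (any(miss_stop)) {
      out[miss_stop] <- 1 / stop_default_time
      fallback <- c(fallback, codons[miss_stop])
    }
    if (any(miss_sense)) {
      if (identical(missing, "error")) {
        stop("rate table lacks sense codon(s): ",
             paste(unique(codons[miss_sense]), collapse = ", "), call. = FALSE)
      }
      # "table-mean" fill: the mean is taken in the table's own value kind
      # (mirroring the occupancy-1.000 convention of relative time tables)
      # and converted afterwards if needed.
      fill <- mean(table$values)
      if (identical(table$kind, "time")) fill <- 1 / fill
      out[miss_sense] <- fill
      fallback <- c(fallback, codons[miss_sense])
    }
  }
  names(out) <- codons
  attr(out, "fallback_codons") <- unique(fallback)
  out
}

#' Build a per-position translation schedule from a CDS and a rate table
#'
#' Maps each codon of the coding sequence to its translation rate. Sense
#' codons absent from the table are filled according to `missing`: the
#' default `"mean"` policy assigns the table's mean value (computed in the
#' table's own representation, equivalent to assuming relative occupancy
#' 1.000), while `"error"` fails fast. Stop codons absent from the table are
#' assigned `stop_default_time` seconds, defaulting to the 256 ms average
#' codon translation time measured for SFVP in CHO cells.
#'
#' @param cds Coding sequence (DNA or RNA alphabet); length must be a
#'   multiple of 3. An in-frame stop codon before the final position
#'   triggers a warning (polyproteins are legitimate input), not an error.
#' @param table A [codon_rate_table()].
#' @param stop_default_time Fallback dwell time for stop codons, seconds.
#' @param missing Fallback policy for sense codons: `"mean"` or `"error"`.
#' @return A [translation_schedule()] whose attribute `fallback_codons`
#'   lists the codons that required a fallback value.
#' @export
build_schedule <- function(cds, table, stop_default_time = 0.256,
                           missing = c("mean", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(table, "codon_rate_table"))
  if (!is.numeric(stop_default_time) || stop_default_time <= 0) {
    stop("`stop_default_time` must be a positive number of seconds", call. = FALSE)
  }
  codons <- cds_codons(cds)
  M <- length(codons)
  internal_stop <- which(codons %in% stop_codons())
  internal_stop <- internal_stop[internal_stop < M]
  if (length(internal_stop) > 0L) {
    warning(sprintf("internal stop codon(s) at position(s) %s",
                    paste(internal_stop, collapse = ", ")), call. = FALSE)
  }
  rates <- lookup_rates(codons, table, stop_default_time, missing)
  sched <- translation_schedule(as.numeric(rates), codons = codons)
  attr(sched, "fallback_codons") <- attr(rates, "fallback_codons")
  sched
}

#' Scale a codon rate table to a target mean translation rate
#'
#' Computes the arithmetic mean of the per-position translation rates over
#' a reference coding sequence (sum of the rates divided by the number of
#' codons), and the unitless scaling factor chi = target / unscaled mean.
#' Multiplying every rate by chi (equivalently dividing every time by chi)
#' yields a table whose mean rate over the reference CDS equals the target
#' exactly. Note the arithmetic mean of rates is the published scaling
#' convention, although the harmonic mean is what governs synthesis time.
#'
#' Any fallback values used while matching the table to the CDS (missing
#' sense codons, missing stop codons) are scaled by the same chi, so the
#' returned `stop_default_time` is the input value divided by chi.
#'
#' @param table A [codon_rate_table()].
#' @param reference_cds Coding sequence over which the mean is computed.
#' @param target_mean_rate Desired mean translation rate, AA per second.
#' @inheritParams build_schedule
#' @return An object of class `scaling_result` with fields `chi`, `table`
#'   (the scaled table), `stop_default_time` (scaled), `achieved_mean_rate`
#'   and `unscaled_mean_rate`.
#' @export
scale_to_target <- function(table, reference_cds, target_mean_rate = 3.9,
                            stop_default_time = 0.256,
                            missing = c("mean", "error")) {
  missing <- match.arg(missing)
  if (!is.numeric(target_mean_rate) || length(target_mean_rate) != 1L ||
      !is.finite(target_mean_rate) || target_mean_rate <= 0) {
    stop("`target_mean_rate` must be a single positive number", call. = FALSE)
  }
  sched <- build_schedule(reference_cds, table,
                          stop_default_time = stop_default_time,
                          missing = missing)
  unscaled_mean <- mean(sched$rates)
  chi <- target_mean_rate / unscaled_mean
  scaled_values <- if (identical(table$kind, "time")) table$values / chi
                   else table$values * chi
  scaled <- codon_rate_table(scaled_values, kind = table$kind,
                             label = table$label)
  scaled_stop_default <- stop_default_time / chi
  check <- build_schedule(reference_cds, scaled,
                          stop_default_time = scaled_stop_default,
                          missing = missing)
  achieved <- mean(check$rates)
  if (abs(achieved - target_mean_rate) > 1e-9 * target_mean_rate) {
    stop("internal error: scaled mean rate does not match target", call. = FALSE)
  }
  structure(list(chi = chi,
                 table = scaled,
                 stop_default_time = scaled_stop_default,
                 achieved_mean_rate = achieved,
                 unscaled_mean_rate = unscaled_mean,
                 target_mean_rate = target_mean_rate),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("<scaling_result> chi = %.6g; mean rate %.6g -> %.6g AA/s\n",
              x$chi, x$unscaled_mean_rate, x$achieved_mean_rate))
  invisible(x)
}

#' Recode a CDS to its slowest-translating synonymous codons
#'
#' Replaces every sense codon by the synonymous codon with the largest
#' translation time (smallest rate) in the table; stop codons and
#' single-codon amino acids (Met, Trp) are left unchanged, and the encoded
#' protein sequence is preserved exactly. When two synonymous codons tie
#' for slowest, the lexicographically smallest codon is chosen, which makes
#' the recoding deterministic. Sense codons missing from the table take the
#' table-mean fallback value before the comparison.
#'
#' @inheritParams build_schedule
#' @return The recoded coding sequence, in the same alphabet (DNA or RNA)
#'   as the input.
#' @export
recode_slowest_synonymous <- function(cds, table) {
  stopifnot(inherits(table, "codon_rate_table"))
  codons <- cds_codons(cds)
  # complete time per sense codon, table-mean fallback for absentees
  times <- as_kind(table, "time")$values
  fill <- mean(table$values)
  if (identical(table$kind, "rate")) fill <- 1 / fill
  full <- times[sense_codons()]
  names(full) <- sense_codons()
  full[is.na(full)] <- fill
  slowest <- vapply(synonym_sets(), function(syn) {
    t <- full[syn]
    cand <- syn[t == max(t)]
    sort(cand)[1L]                        # lexicographic tie-break
  }, character(1))
  code <- rna_genetic_code()
  aa <- code[codons]
  out <- ifelse(aa == "*", codons, slowest[aa])
  result <- paste(out, collapse = "")
  if (is_dna_alphabet(cds)) result <- chartr("U", "T", result)
  result
}
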