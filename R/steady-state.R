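#' Steady-state nascent-length folding profile
#'
#' Computes the probability `P_F,B(i)` that the domain of interest is
#' folded while the nascent chain is bound to the ribosome at codon
#' position `i`, under steady-state translation, exponentially distributed
#' codon dwell times and two-state folding. With
#' `P_eq,i = kF_i / (kF_i + kU_i)` and
#' `lambda_i = k_A,i / (k_A,i + kF_i + kU_i)` the profile obeys the
#' recursion
#'
#'     P(0) = 0
#'     P(i) = P_eq,i + (P(i-1) - P_eq,i) * lambda_i   when kF_i + kU_i > 0
#'     P(i) = P(i-1)                                  otherwise
#'
#' which is the exact two-state solution averaged over the exponential
#' dwell at codon `i`. The default (`average = "departure"`) reports the
#' folded probability at the moment of elongation away from codon `i`;
#' because the stationary age of an exponential dwell is again exponential
#' this also equals the population-snapshot value measured by
#' folding-versus-length assays. `average = "residence"` instead reports
#' the time-average over the dwell, for which the factor
#' `(k_A/k) * log(1 + k/k_A)` replaces `lambda_i`.
#'
#' The value at the stop codon, `P_F,Co-T = P(M)` (the stop-codon dwell is
#' a real dwell and is included), is the probability that the domain folds
#' co-translationally; see [classify_folding()].
#'
#' @param kinetics A [build_kinetics()] result.
#' @param schedule A [translation_schedule()] of the same length `M`.
#' @param average `"departure"` (default) or `"residence"`; see Details.
#' @return An object of class `steady_state_profile` with fields `values`
#'   (length `M`), `P_F_CoT`, `onset` and `M`.
#' @export
steady_state_profile <- function(kinetics, schedule,
                                 average = c("departure", "residence")) {
  average <- match.arg(average)
  stopifnot(inherits(kinetics, "folding_kinetics"),
            inherits(schedule, "translation_schedule"))
  if (kinetics$M != schedule$M) {
    stop(sprintf("length mismatch: kinetics has M = %d, schedule has M = %d",
                 kinetics$M, schedule$M), call. = FALSE)
  }
  M <- kinetics$M
  kA <- schedule$rates
  k <- kinetics$kF + kinetics$kU
  lambda <- if (average == "departure") {
    kA / (kA + k)
  } else {
    ifelse(k > 0, (kA / k) * log1p(k / kA), 1)
  }
  values <- numeric(M)
  p <- 0
  for (i in seq_len(M)) {
    if (k[i] > 0) {
      peq <- kinetics$P_eq[i]
      p <- peq + (p - peq) * lambda[i]
    }
    values[i] <- p
  }
  structure(list(values = values, P_F_CoT = values[M],
                 onset = kinetics$onset, M = M, average = average),
            class = "steady_state_profile")
}

#' @export
print.steady_state_profile <- function(x, ...) {
  cat(sprintf("<steady_state_profile> M = %d, onset = %d, P_F,Co-T = %.4g (%s)\n",
              x$M, x$onset, x$P_F_CoT, x$average))
  invisible(x)
}

#' Classify a domain as co- or post-translationally folding
#'
#' A domain folds predominantly co-translationally when its probability of
#' being folded at the stop codon, `P_F,Co-T`, is at least `threshold`
#' (inclusive at the boundary); otherwise it folds predominantly
#' post-translationally.
#'
#' @param profile A [steady_state_profile()] (or a bare probability).
#' @param threshold Classification threshold (default 0.5).
#' @return `"co-translational"` or `"post-translational"`.
#' @export
classify_folding <- function(profile, threshold = 0.5) {
  p <- if (inherits(profile, "steady_state_profile")) profile$P_F_CoT
       else as.numeric(profile)
  stopifnot(length(p) == 1L, is.finite(p))
  if (p >= threshold) "co-translational" else "post-translational"
}
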