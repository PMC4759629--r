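#' Pulse-chase protocol parameters
#'
#' Describes the labelling protocol: a pulse of `pulse` seconds during
#' which labelled amino acids are supplied, a chase of `chase` seconds, and
#' an incorporation delay of `delay` seconds that shifts both the start and
#' the end of the incorporation window (label must be taken up by the cell
#' and charged onto tRNA before it appears in nascent chains). With the
#' pulse starting at absolute time 0, labelled residues are incorporated
#' during `[delay, pulse + delay)`. Reported curves use the chase-shifted
#' time axis on which the start of the chase is t = 0.
#'
#' @param pulse Pulse length, seconds (default 45).
#' @param chase Chase length, seconds (default 360).
#' @param delay Incorporation delay, seconds (default 10).
#' @param dt Engine time step, seconds (default 0.1): controls the density
#'   of the initiation-time grid on which labelled cohorts are seeded and
#'   the reporting resolution. The folding relaxation itself is integrated
#'   exactly across piecewise-constant rate intervals.
#' @param report_times Chase-shifted times at which the curve is reported
#'   (default every second of the chase).
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(pulse = 45, chase = 360, delay = 10, dt = 0.1,
                           report_times = seq(0, chase, by = 1)) {
  stopifnot(pulse > 0, chase > 0, dt > 0, delay >= 0)
  report_times <- sort(unique(as.numeric(report_times)))
  structure(list(pulse = pulse, chase = chase, delay = delay, dt = dt,
                 report_times = report_times),
            class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("<pulse_protocol> pulse %g s, chase %g s, delay %g s, dt %g s\n",
              x$pulse, x$chase, x$delay, x$dt))
  invisible(x)
}

#' Mean-field trajectory of a translating ribosome
#'
#' Under the mean-field (cohort) realization of steady-state translation, a
#' ribosome initiating at time `t0` occupies codon `j` during
#' `[t0 + tau_cum(j-1), t0 + tau_cum(j))`, incorporates residue `j` at
#' `t0 + tau_cum(j)` (the end of the dwell, when the peptide bond is
#' complete), and releases the chain at `t0 + tau_cum(M)`.
#'
#' @param schedule A [translation_schedule()].
#' @param t0 Initiation time, seconds (absolute; pulse starts at 0).
#' @return An object of class `cohort_trajectory` with fields `t0`,
#'   `incorporation` (length `M`), `release`, `M`, and a `position(t)`
#'   function returning the occupied codon at time `t` (0 before
#'   initiation, `M + 1` after release).
#' @export
cohort_trajectory <- function(schedule, t0 = 0) {
  stopifnot(inherits(schedule, "translation_schedule"))
  inc <- t0 + schedule$tau_cum
  M <- schedule$M
  structure(list(t0 = t0, incorporation = inc, release = inc[M], M = M,
                 position = function(t) findInterval(t, c(t0, inc)),
                 schedule = schedule),
            class = "cohort_trajectory")
}

#' Is a cohort labelled, and when does it first carry label?
#'
#' A nascent chain is radiolabelled when at least one residue of the
#' observable set is incorporated during the incorporation window
#' `[delay, pulse + delay)`. The labelling time is the earliest such
#' incorporation instant; a cohort only becomes visible to the assay once
#' it has passed.
#'
#' @param trajectory A [cohort_trajectory()].
#' @param observable_codons Codon indices carrying detectable label.
#' @param protocol A [pulse_protocol()].
#' @return A list with elements `labelled` (logical) and `label_time`
#'   (seconds, `NA` when unlabelled).
#' @export
is_labelled <- function(trajectory, observable_codons, protocol) {
  stopifnot(inherits(trajectory, "cohort_trajectory"),
            inherits(protocol, "pulse_protocol"))
  inc <- trajectory$incorporation[observable_codons]
  lo <- protocol$delay
  hi <- protocol$pulse + protocol$delay
  hit <- inc[inc >= lo & inc < hi]
  if (length(hit) == 0L) list(labelled = FALSE, label_time = NA_real_)
  else list(labelled = TRUE, label_time = min(hit))
}

#' Two-state folding probability along a ribosome trajectory
#'
#' Integrates the two-state folding master equation for a single cohort:
#' the folding probability starts at 0, stays 0 while the chain is below
#' the folding onset, relaxes toward `P_eq,i` with rate `kF_i + kU_i`
#' while the ribosome dwells at codon `i`, and relaxes toward the bulk
#' equilibrium with the bulk rates (taken from the last codon position,
#' where the chain has its full-length kinetics) after release. Because the
#' rates are piecewise constant the relaxation is applied as exact
#' exponential updates interval by interval, so the result carries no
#' time-discretization error and no sub-stepping is required.
#'
#' @param kinetics A [build_kinetics()] result.
#' @param trajectory A [cohort_trajectory()] with matching `M`.
#' @param times Absolute times at which to report the probability.
#' @return Numeric vector of folding probabilities, one per time.
#' @export
evolve_folding <- function(kinetics, trajectory, times) {
  stopifnot(inherits(kinetics, "folding_kinetics"),
            inherits(trajectory, "cohort_trajectory"))
  if (kinetics$M != trajectory$M) {
    stop("length mismatch between kinetics and trajectory", call. = FALSE)
  }
  M <- kinetics$M
  bounds <- c(trajectory$t0, trajectory$incorporation)  # interval i: codon i
  # folding probability at the start of each dwell (and at release)
  p_entry <- numeric(M + 1L)
  p <- 0
  for (i in seq_len(M)) {
    p_entry[i] <- p
    k <- kinetics$kF[i] + kinetics$kU[i]
    if (k > 0) {
      peq <- kinetics$P_eq[i]
      p <- peq + (p - peq) * exp(-k * (bounds[i + 1L] - bounds[i]))
    }
  }
  p_entry[M + 1L] <- p
  kF_rel <- kinetics$kF[M]; kU_rel <- kinetics$kU[M]
  k_rel <- kF_rel + kU_rel
  peq_rel <- if (k_rel > 0) kF_rel / k_rel else 0
  vapply(times, function(t) {
    if (t <= bounds[1L]) return(0)
    if (t >= trajectory$release) {
      if (k_rel == 0) return(p_entry[M + 1L])
      return(peq_rel + (p_entry[M + 1L] - peq_rel) *
               exp(-k_rel * (t - trajectory$release)))
    }
    i <- findInterval(t, bounds, rightmost.closed = FALSE)
    k <- kinetics$kF[i] + kinetics$kU[i]
    if (k == 0) return(p_entry[i])
    peq <- kinetics$P_eq[i]
    peq + (p_entry[i] - peq) * exp(-k * (t - bounds[i]))
  }, numeric(1))
}

# Expected folding probability of a chain as a function of its age u
# (time since initiation), averaged over stochastic exponential dwells.
# With two-regime kinetics, folding starts on arrival at the onset codon,
# at age T = sum of the first (onset - 1) dwells, and then relaxes toward
# P_eq with rate k = kF + kU, so
#   q_F(u) = P_eq * E[(1 - exp(-k (u - T))) ; T <= u]
#          = P_eq * (F_T(u) - C(u)),   C(u) = int_0^u f_T(s) e^{-k(u-s)} ds.
# T is Gamma-distributed for uniform schedules (exact) and is represented
# by a moment-matched Gamma otherwise. C is accumulated by an integrator
# that is exact for piecewise-linear f_T. dispersion = "none" collapses T
# to its mean (pure mean-field cohorts).
age_response <- function(construct, schedule, u_max, du = 0.02,
                         dispersion = c("stochastic", "none")) {
  dispersion <- match.arg(dispersion)
  kF <- construct$bulk_kF; kU <- construct$bulk_kU
  k <- kF + kU
  P_eq <- kF / k
  onset <- construct$onset
  pre <- if (onset > 1L) 1 / schedule$rates[seq_len(onset - 1L)] else numeric(0)
  m <- sum(pre)
  u <- seq(0, u_max, by = du)
  if (dispersion == "none" || length(pre) == 0L) {
    q <- P_eq * -expm1(-k * pmax(0, u - m))
  } else {
    v <- sum(pre^2)
    shape <- m^2 / v
    rate <- m / v
    f <- stats::dgamma(u, shape = shape, rate = rate)
    FT <- stats::pgamma(u, shape = shape, rate = rate)
    I0 <- -expm1(-k * du) / k
    I1 <- (du - I0) / k
    x <- (I0 - I1 / du) * f[-length(f)] + (I1 / du) * f[-1L]
    C <- c(0, stats::filter(x, exp(-k * du), method = "recursive"))
    q <- pmin(pmax(P_eq * (FT - C), 0), P_eq)
  }
  list(u = u, q = q, P_eq = P_eq)
}

#' Predict a pulse-chase co-translational folding curve
#'
#' Deterministic engine for the experimentally observable folding curve
#' `P_F(t)`. Under steady-state translation, labelled nascent chains are
#' represented by a dense grid of cohorts, one per initiation time `t0` on
#' a `dt`-spaced grid covering every initiation time that can produce a
#' labelled chain
#' (`[delay - tau_cum(max observable codon), pulse + delay]`). Each cohort
#' follows its mean-field [cohort_trajectory()] for the labelling
#' bookkeeping ([is_labelled()]) and carries the exact expected two-state
#' folding probability of a chain of its age: zero until the chain reaches
#' the folding onset, then relaxation toward the equilibrium `kF/(kF+kU)`
#' with rate `kF + kU`, averaged over the stochastic (exponential-dwell)
#' distribution of onset-arrival times, and continuing with the same bulk
#' rates after release. At each report time `t` (chase-shifted; absolute
#' time `t + pulse`) the curve is the mean folding probability over the
#' labelled cohorts whose labelling time has passed, i.e. a convex
#' combination of cohort probabilities. Report times at which no labelled
#' cohort is yet visible are returned as `NA` and flagged.
#'
#' @param construct A [construct()].
#' @param schedule A [translation_schedule()] with `M` matching the
#'   construct.
#' @param protocol A [pulse_protocol()].
#' @param dispersion `"stochastic"` (default): average each cohort's
#'   folding probability over the exponential-dwell distribution of its
#'   onset-arrival time (exact Gamma for uniform schedules,
#'   moment-matched Gamma otherwise). `"none"`: place the crossing at the
#'   mean arrival time (pure mean-field cohorts), which deterministically
#'   sharpens the corners of the curve.
#' @return An object of class `folding_curve`: a list with `time`
#'   (chase-shifted report times), `value`, `n_visible`, `P_eq` (the bulk
#'   equilibrium folded probability, the curve's plateau), and the cohort
#'   `ledger` (data frame with `t0`, `labelled`, `label_time`,
#'   `onset_time`, `release_time`).
#' @export
predict_pulse_chase <- function(construct, schedule, protocol = pulse_protocol(),
                                dispersion = c("stochastic", "none")) {
  dispersion <- match.arg(dispersion)
  stopifnot(inherits(construct, "construct"),
            inherits(schedule, "translation_schedule"),
            inherits(protocol, "pulse_protocol"))
  if (schedule$M != construct$M) {
    stop(sprintf("length mismatch: construct M = %d, schedule M = %d",
                 construct$M, schedule$M), call. = FALSE)
  }
  obs <- construct$observable_codons
  if (length(obs) == 0L) {
    stop("construct has no observable codons", call. = FALSE)
  }
  tau <- schedule$tau_cum
  d <- protocol$delay; p <- protocol$pulse; dt <- protocol$dt
  tau_obs <- tau[obs]                       # sorted (obs sorted, tau increasing)
  max_obs_tau <- tau_obs[length(tau_obs)]

  # initiation-time grid (midpoint rule) covering all possibly-labelled cohorts
  t0 <- seq(d - max_obs_tau + dt / 2, p + d, by = dt)

  # labelling: earliest observable incorporation inside [d, p + d)
  idx <- findInterval(d - t0, tau_obs) + 1L
  ok <- idx <= length(tau_obs)
  label_tau <- rep(NA_real_, length(t0))
  label_tau[ok] <- tau_obs[idx[ok]]
  label_time <- t0 + label_tau
  labelled <- !is.na(label_time) & label_time < p + d
  label_time[!labelled] <- NA_real_

  onset <- construct$onset
  tau_onset <- if (onset > 1L) tau[onset - 1L] else 0   # arrival at onset codon
  onset_time <- t0 + tau_onset
  release_time <- t0 + tau[schedule$M]

  lab_t0 <- t0[labelled]
  lab_label <- label_time[labelled]
  if (!any(labelled)) {
    stop("no cohort is ever labelled under this protocol", call. = FALSE)
  }

  abs_times <- protocol$report_times + p
  u_max <- max(abs_times) - min(lab_t0) + 1
  resp <- age_response(construct, schedule, u_max, dispersion = dispersion)
  q_of <- stats::approxfun(resp$u, resp$q, rule = 2, yleft = 0)
  P_eq <- resp$P_eq

  n_visible <- integer(length(abs_times))
  value <- rep(NA_real_, length(abs_times))
  for (s in seq_along(abs_times)) {
    t <- abs_times[s]
    vis <- lab_label <= t
    n <- sum(vis)
    n_visible[s] <- n
    if (n > 0L) {
      value[s] <- sum(q_of(t - lab_t0[vis])) / n
    }
  }
  ledger <- data.frame(t0 = t0, labelled = labelled, label_time = label_time,
                       onset_time = onset_time, release_time = release_time)
  structure(list(time = protocol$report_times, value = value,
                 n_visible = n_visible, P_eq = P_eq,
                 ledger = ledger, protocol = protocol,
                 construct = construct$name,
                 undefined_times = protocol$report_times[n_visible == 0L]),
            class = "folding_curve")
}

#' @export
print.folding_curve <- function(x, ...) {
  rng <- range(x$value, na.rm = TRUE)
  cat(sprintf("<folding_curve> %s: %d report times on [%g, %g] s, P_F in [%.4g, %.4g]\n",
              x$construct, length(x$time), min(x$time), max(x$time),
              rng[1], rng[2]))
  if (length(x$undefined_times) > 0L) {
    cat(sprintf("  %d report time(s) precede the first labelled cohort (NA)\n",
                length(x$undefined_times)))
  }
  invisible(x)
}

#' @export
as.data.frame.folding_curve <- function(x, ...) {
  data.frame(time_s = x$time, P_F = x$value, n_visible = x$n_visible)
}

#' Time-dependent fraction of full-length labelled protein
#'
#' From the cohort ledger of a predicted pulse-chase curve, computes
#' `f_L,R(t) = N_L,R(t) / N_L,R(t_final)`: the number of labelled chains
#' released from the ribosome by chase time `t`, normalized by the number
#' released by the final report time. The fraction is nondecreasing, lies
#' in `[0, 1]` and equals 1 at the final time by construction.
#'
#' @param curve A [predict_pulse_chase()] result.
#' @param times Chase-shifted evaluation times; defaults to the curve's
#'   report times.
#' @return A data frame with columns `time_s` and `fraction`.
#' @export
fraction_full_length <- function(curve, times = NULL) {
  stopifnot(inherits(curve, "folding_curve"))
  if (is.null(times)) times <- curve$time
  led <- curve$ledger
  rel <- led$release_time[led$labelled]
  abs_times <- times + curve$protocol$pulse
  n_rel <- vapply(abs_times, function(t) sum(rel <= t), numeric(1))
  total <- n_rel[length(n_rel)]
  if (total == 0) {
    stop("no labelled protein completed synthesis within the experiment",
         call. = FALSE)
  }
  data.frame(time_s = times, fraction = n_rel / total)
}

#' One-at-a-time sensitivity sweep of the pulse-chase prediction
#'
#' Recomputes the folding curve while varying one parameter at a time:
#' multiplicative factors on the bulk folding rate, the bulk unfolding
#' rate or the global translation rates, and absolute exit-tunnel lengths.
#' All other parameters are held at their base values.
#'
#' @param construct,schedule,protocol Base inputs as for
#'   [predict_pulse_chase()].
#' @param kF_factors,kU_factors,kA_factors Numeric vectors of
#'   multiplicative factors (may be `NULL`).
#' @param tunnel_lengths Numeric vector of absolute tunnel lengths in
#'   residues (may be `NULL`).
#' @return A named list of `folding_curve` objects; the unperturbed curve
#'   is included under `"base"`. Each element carries attributes
#'   `parameter` and `value`.
#' @export
sensitivity_sweep <- function(construct, schedule, protocol = pulse_protocol(),
                              kF_factors = NULL, kU_factors = NULL,
                              kA_factors = NULL, tunnel_lengths = NULL) {
  runs <- list(base = predict_pulse_chase(construct, schedule, protocol))
  attr(runs$base, "parameter") <- "base"; attr(runs$base, "value") <- 1
  remake <- function(kF = construct$bulk_kF, kU = construct$bulk_kU,
                     tunnel = construct$tunnel_length) {
    construct(construct$name, construct$M, construct$domain_start,
              construct$domain_end, bulk_kF = kF, bulk_kU = kU,
              tunnel_length = tunnel,
              observable_codons = construct$observable_codons,
              observable_length = construct$observable_length)
  }
  add <- function(runs, name, curve, parameter, value) {
    attr(curve, "parameter") <- parameter; attr(curve, "value") <- value
    runs[[name]] <- curve
    runs
  }
  for (f in kF_factors) {
    runs <- add(runs, sprintf("kF_x%g", f),
                predict_pulse_chase(remake(kF = construct$bulk_kF * f),
                                    schedule, protocol), "kF_factor", f)
  }
  for (f in kU_factors) {
    runs <- add(runs, sprintf("kU_x%g", f),
                predict_pulse_chase(remake(kU = construct$bulk_kU * f),
                                    schedule, protocol), "kU_factor", f)
  }
  for (f in kA_factors) {
    runs <- add(runs, sprintf("kA_x%g", f),
                predict_pulse_chase(construct,
                                    translation_schedule(schedule$rates * f,
                                                         schedule$codons),
                                    protocol), "kA_factor", f)
  }
  for (tl in tunnel_lengths) {
    runs <- add(runs, sprintf("tunnel_%g", tl),
                predict_pulse_chase(remake(tunnel = tl), schedule, protocol),
                "tunnel_length", tl)
  }
  runs
}
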