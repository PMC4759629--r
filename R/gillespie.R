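#' Configuration of the stochastic (Gillespie) translation simulator
#'
#' @param dwell_model `"single_exponential"`: the dwell at codon `i` is
#'   exponential with mean `1/k_A,i`. `"two_exponential"`: the ribosome
#'   passes through a post-translocation state (rate `k1` to the
#'   pre-translocation state) and a pre-translocation state (rate `k2`,
#'   advancing the chain), giving a hypoexponential dwell (equivalently the
#'   difference-of-two-exponentials density). Per codon, both rates are
#'   scaled by a common factor so the mean dwell `1/k1,i + 1/k2,i` equals
#'   the schedule's `1/k_A,i`, preserving the `k2/k1` ratio.
#' @param k1,k2 Base translocation rates, per second. The defaults give a
#'   mean dwell of about 0.2565 s, i.e. 3.9 AA per second.
#' @param initiation `"constant"`: exponential inter-initiation intervals
#'   with rate `k_init`. `"sinusoidal"`: non-steady-state initiation with
#'   instantaneous rate `k_init * (1 + amplitude * sin(2*pi*t/period))`;
#'   by default each interval is drawn exponentially with the rate frozen
#'   at the current time (the sequential-draw method), with exact thinning
#'   available via `thinning = TRUE`.
#' @param k_init Initiation rate, per second. `NULL` (default) uses the
#'   schedule's mean translation rate, which keeps the initiation flux
#'   equal to the steady-state elongation flux implied by the
#'   one-ribosome-per-length initial condition.
#' @param amplitude Relative amplitude `A` of the sinusoidal modulation,
#'   `0 <= A < 1`.
#' @param period Period of the sinusoidal modulation, seconds (default 45).
#' @param replicates Number of virtual experiments averaged (default 20).
#' @param initial `"steady_occupancy"`: one pre-existing ribosome per
#'   nascent-chain length at time 0 (all lengths equally probable);
#'   `"empty"`: no pre-existing ribosomes.
#' @param thinning Use exact thinning for sinusoidal initiation.
#' @return An object of class `gillespie_config`.
#' @export
gillespie_config <- function(dwell_model = c("single_exponential",
                                             "two_exponential"),
                             k1 = 4.7363, k2 = 22.0649,
                             initiation = c("constant", "sinusoidal"),
                             k_init = NULL, amplitude = 0.5, period = 45,
                             replicates = 20,
                             initial = c("steady_occupancy", "empty"),
                             thinning = FALSE) {
  dwell_model <- match.arg(dwell_model)
  initiation <- match.arg(initiation)
  initial <- match.arg(initial)
  stopifnot(k1 > 0, k2 > 0, replicates >= 1, period > 0,
            amplitude >= 0, amplitude < 1)
  if (!is.null(k_init)) stopifnot(k_init > 0)
  structure(list(dwell_model = dwell_model, k1 = k1, k2 = k2,
                 initiation = initiation, k_init = k_init,
                 amplitude = amplitude, period = period,
                 replicates = as.integer(replicates), initial = initial,
                 thinning = thinning),
            class = "gillespie_config")
}

#' Sample stochastic ribosome dwell times
#'
#' @param config A [gillespie_config()].
#' @param rate Target mean translation rate(s) `k_A,i`, AA per second;
#'   recycled against `n`.
#' @param n Number of dwells to draw.
#' @return Numeric vector of dwell times in seconds with mean `1/rate`.
#' @export
sample_dwell <- function(config, rate, n = length(rate)) {
  stopifnot(inherits(config, "gillespie_config"), all(rate > 0))
  if (config$dwell_model == "single_exponential") {
    stats::rexp(n, rate = rate)
  } else {
    # common per-codon scaling keeps the hypoexponential mean at 1/rate
    s <- rate * (1 / config$k1 + 1 / config$k2)
    stats::rexp(n, rate = s * config$k1) + stats::rexp(n, rate = s * config$k2)
  }
}

#' Sample the waiting time to the next translation-initiation event
#'
#' @param config A [gillespie_config()]; `k_init` must be set.
#' @param current_time Absolute time of the previous initiation (or 0).
#' @return Waiting time in seconds.
#' @export
next_initiation <- function(config, current_time = 0) {
  stopifnot(inherits(config, "gillespie_config"))
  k0 <- config$k_init
  if (is.null(k0)) stop("`k_init` is not set in this config", call. = FALSE)
  if (config$initiation == "constant" || config$amplitude == 0) {
    return(stats::rexp(1, rate = k0))
  }
  rate_at <- function(t) k0 * (1 + config$amplitude * sin(2 * pi * t / config$period))
  if (!config$thinning) {
    # sequential-draw method: interval exponential with the rate frozen at
    # the current time (approximately a non-homogeneous Poisson process)
    return(stats::rexp(1, rate = rate_at(current_time)))
  }
  # exact thinning against the rate envelope k0 * (1 + A)
  rmax <- k0 * (1 + config$amplitude)
  t <- current_time
  repeat {
    t <- t + stats::rexp(1, rate = rmax)
    if (stats::runif(1) <= rate_at(t) / rmax) return(t - current_time)
  }
}

# two-state folding jump times on [t_on, t_end], starting unfolded (state0
# = 0) or folded (1); returns the sorted jump instants
sim_two_state_jumps <- function(t_on, t_end, kF, kU, state0 = 0L) {
  jumps <- numeric(0)
  t <- t_on
  state <- state0
  repeat {
    rate <- if (state == 0L) kF else kU
    if (rate <= 0) break
    t <- t + stats::rexp(1, rate = rate)
    if (t >= t_end) break
    jumps <- c(jumps, t)
    state <- 1L - state
  }
  jumps
}

# folded indicator at `times` given onset, jumps and the initial state
folded_state_at <- function(times, t_on, jumps, state0 = 0L) {
  out <- integer(length(times))
  active <- times >= t_on
  out[active] <- (state0 + findInterval(times[active], jumps)) %% 2L
  out
}

#' Stochastic simulation of a pulse-chase experiment
#'
#' Event-driven ground-truth simulation of independent ribosome-nascent
#' chain complexes translating one mRNA: stochastic dwells at each codon
#' (single- or two-exponential, [sample_dwell()]), residue incorporation at
#' bond formation, label bookkeeping per [is_labelled()] semantics,
#' two-state folding switched on when the chain reaches the folding onset
#' and continuing with the bulk rates after release, and stochastic
#' initiation ([next_initiation()]) running until the end of the
#' incorporation window. The folding curve of each replicate is the
#' labelled-molecule estimator `P_F(t) = (1/N(t)) * sum_i delta_t(i)`,
#' where `N(t)` counts labelled molecules visible by time `t` and
#' `delta_t(i)` indicates that labelled molecule `i` is folded at `t`.
#'
#' Ribosome-ribosome interactions are not modelled, so pre-existing chains
#' whose observable codons were all incorporated before the labelling
#' window opens can never contribute to the estimator and are skipped
#' exactly. Pre-existing chains already past the folding onset enter with
#' a folded state drawn from the steady-state profile.
#'
#' @param construct,schedule,protocol As for [predict_pulse_chase()].
#' @param config A [gillespie_config()].
#' @param seed Optional integer seed; identical seed and config give a
#'   bit-identical event sequence.
#' @return An object of class `simulation_result` with fields `time`
#'   (chase-shifted report times), `mean`, `sem`, `replicate_curves`
#'   (times x replicates matrix), `n_labelled` (per replicate),
#'   `N_visible` (mean labelled count per time) and `config`.
#' @export
simulate_pulse_chase_stochastic <- function(construct, schedule,
                                            protocol = pulse_protocol(),
                                            config = gillespie_config(),
                                            seed = NULL) {
  stopifnot(inherits(construct, "construct"),
            inherits(schedule, "translation_schedule"),
            inherits(protocol, "pulse_protocol"),
            inherits(config, "gillespie_config"))
  if (schedule$M != construct$M) {
    stop("length mismatch between construct and schedule", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config$k_init)) config$k_init <- mean(schedule$rates)

  M <- schedule$M
  rates <- schedule$rates
  obs <- construct$observable_codons
  max_obs <- max(obs)
  onset <- construct$onset
  kF <- construct$bulk_kF; kU <- construct$bulk_kU
  d <- protocol$delay; p <- protocol$pulse
  t_end <- p + protocol$chase
  report_abs <- protocol$report_times + p

  # entry folded probability for pre-existing chains already past the onset
  entry_prob <- NULL
  if (config$initial == "steady_occupancy" && max_obs >= onset) {
    entry_prob <- steady_state_profile(build_kinetics(construct), schedule)$values
  }

  R <- config$replicates
  curves <- matrix(NA_real_, nrow = length(report_abs), ncol = R)
  n_labelled <- integer(R)
  N_vis <- matrix(0, nrow = length(report_abs), ncol = R)

  for (r in seq_len(R)) {
    start_pos <- integer(0); start_time <- numeric(0)
    if (config$initial == "steady_occupancy") {
      start_pos <- seq_len(min(max_obs, M - 1L))
      start_time <- rep(0, length(start_pos))
    }
    t <- 0
    repeat {
      t <- t + next_initiation(config, t)
      if (t > p + d) break
      start_pos <- c(start_pos, 1L)
      start_time <- c(start_time, t)
    }
    lab_states <- list(); lab_n <- 0L; lab_times <- numeric(0)
    for (c_i in seq_along(start_pos)) {
      pos0 <- start_pos[c_i]
      ts <- start_time[c_i]
      dwell <- sample_dwell(config, rates[pos0:M])
      inc <- ts + cumsum(dwell)               # residues pos0..M
      obs_here <- obs[obs >= pos0]
      if (length(obs_here) == 0L) next
      inc_obs <- inc[obs_here - pos0 + 1L]
      hit <- inc_obs[inc_obs >= d & inc_obs < p + d]
      if (length(hit) == 0L) next
      lab_n <- lab_n + 1L
      lab_times[lab_n] <- min(hit)
      if (pos0 >= onset) {
        t_on <- ts
        state0 <- if (is.null(entry_prob)) 0L
                  else as.integer(stats::runif(1) < entry_prob[pos0 - 1L])
      } else {
        t_on <- if (onset - 1L >= pos0) inc[onset - 1L - pos0 + 1L] else ts
        state0 <- 0L
      }
      jumps <- sim_two_state_jumps(t_on, t_end, kF, kU, state0)
      lab_states[[lab_n]] <- folded_state_at(report_abs, t_on, jumps, state0)
    }
    n_labelled[r] <- lab_n
    if (lab_n == 0L) {
      warning(sprintf("replicate %d produced no labelled molecule; excluded", r),
              call. = FALSE)
      next
    }
    delta <- matrix(unlist(lab_states), nrow = length(report_abs))
    vis <- outer(report_abs, lab_times, ">=")   # times x molecules
    N_t <- rowSums(vis)
    N_vis[, r] <- N_t
    curves[, r] <- ifelse(N_t > 0, rowSums(delta * vis) / N_t, NA_real_)
  }
  used <- which(n_labelled > 0L)
  mean_curve <- rowMeans(curves[, used, drop = FALSE], na.rm = TRUE)
  sem <- apply(curves[, used, drop = FALSE], 1, stats::sd, na.rm = TRUE) /
    sqrt(length(used))
  structure(list(time = protocol$report_times, mean = mean_curve, sem = sem,
                 replicate_curves = curves, n_labelled = n_labelled,
                 N_visible = rowMeans(N_vis[, used, drop = FALSE]),
                 config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d replicates (%s dwells), %d labelled molecules total\n",
              ncol(x$replicate_curves), x$config$dwell_model,
              sum(x$n_labelled)))
  cat(sprintf("  mean P_F at final time: %.4g (SEM %.2g)\n",
              x$mean[length(x$mean)], x$sem[length(x$sem)]))
  invisible(x)
}

#' Z-scores between a stochastic mean curve and a reference curve
#'
#' Standardizes the pointwise difference between the replicate-averaged
#' stochastic curve and a reference (typically the deterministic
#' prediction) by the replicate standard error of the mean. Because the
#' replicate SEM collapses to zero wherever every labelled molecule is
#' folded in every replicate, it is floored by the binomial standard error
#' of the pooled labelled count (with Agresti-Coull shrinkage), which is
#' the smallest uncertainty the finite sample supports.
#'
#' @param sim A [simulate_pulse_chase_stochastic()] result.
#' @param reference Numeric vector of reference values on the same time
#'   grid.
#' @return Numeric vector of z-scores.
#' @export
oracle_zscores <- function(sim, reference) {
  stopifnot(inherits(sim, "simulation_result"),
            length(reference) == length(sim$mean))
  n_pool <- sum(sim$n_labelled)
  ptilde <- (sim$mean * n_pool + 2) / (n_pool + 4)
  floor_se <- sqrt(ptilde * (1 - ptilde) / n_pool)
  (sim$mean - reference) / pmax(sim$sem, floor_se)
}

#' Stochastic length-resolved folding profile
#'
#' Simulates `n_chains` independent ribosome-nascent chain complexes from
#' initiation to termination and records whether the domain is folded at
#' the moment of elongation away from each codon position. The mean over
#' chains is the stochastic counterpart of [steady_state_profile()] and is
#' used as its ground-truth check.
#'
#' @param construct,schedule As for [predict_pulse_chase()].
#' @param n_chains Number of independent trajectories.
#' @param config A [gillespie_config()] (dwell model only is used).
#' @param seed Optional integer seed.
#' @return A list with `values` (mean folded fraction per codon), `se`
#'   (binomial standard error with an Agresti-Coull floor), and `n_chains`.
#' @export
simulate_length_profile <- function(construct, schedule, n_chains = 10000,
                                    config = gillespie_config(), seed = NULL) {
  stopifnot(inherits(construct, "construct"),
            inherits(schedule, "translation_schedule"))
  if (schedule$M != construct$M) {
    stop("length mismatch between construct and schedule", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  M <- schedule$M
  onset <- construct$onset
  kF <- construct$bulk_kF; kU <- construct$bulk_kU
  counts <- numeric(M)
  for (i in seq_len(n_chains)) {
    inc <- cumsum(sample_dwell(config, schedule$rates))
    t_on <- if (onset > 1L) inc[onset - 1L] else 0
    jumps <- sim_two_state_jumps(t_on, inc[M] + 1e-12, kF, kU, 0L)
    counts <- counts + folded_state_at(inc, t_on, jumps, 0L)
  }
  phat <- counts / n_chains
  ptilde <- (counts + 2) / (n_chains + 4)
  se <- sqrt(ptilde * (1 - ptilde) / n_chains)
  list(values = phat, se = se, n_chains = n_chains)
}
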