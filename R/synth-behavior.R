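#' Learner profile for synthetic Y-maze trial sequences
#'
#' A saturating-exponential learning model: the per-trial success
#' probability rises from `p_start` toward `p_final` with time constant
#' `tau_trials`,
#' `p_t = p_final - (p_final - p_start) exp(-t / tau)`,
#' and each outcome is an independent Bernoulli draw. This matches the
#' concave shape of rodent discrimination learning curves without committing
#' to any particular acquisition theory.
#'
#' @param p_start Initial success probability (chance level is 0.5 for a
#'   two-alternative forced choice).
#' @param p_final Asymptotic success probability; `p_start <= p_final`.
#' @param tau_trials Learning time constant in trials (positive).
#' @param n_trials Sequence length (default 90, one session).
#' @param seed RNG seed.
#' @return A validated `learner_profile` list.
#' @export
learner_profile <- function(p_start = 0.5, p_final = 0.85, tau_trials = 20,
                            n_trials = 90, seed = 1) {
  if (!(p_start >= 0 && p_start <= p_final && p_final <= 1))
    tg_stop("need 0 <= p_start <= p_final <= 1", "tg_parameter_error")
  if (!(tau_trials > 0))
    tg_stop("`tau_trials` must be positive", "tg_parameter_error")
  if (!(n_trials >= 1))
    tg_stop("`n_trials` must be at least 1", "tg_parameter_error")
  structure(list(p_start = p_start, p_final = p_final,
                 tau_trials = tau_trials, n_trials = as.integer(n_trials),
                 seed = seed),
            class = "learner_profile")
}

#' Generate a Bernoulli trial sequence with exponential learning
#'
#' @param profile A [learner_profile()].
#' @param subject_id,group Labels for the emitted table.
#' @return List with `trials` (a [trial_table]) and `ground_truth`
#'   (list with the per-trial success probabilities `p`).
#' @examples
#' sim <- generate_learning_trials(learner_profile(p_final = 0.95, seed = 7))
#' learning_curve(sim$trials)
#' @export
generate_learning_trials <- function(profile, subject_id = "s1", group = "g1") {
  stopifnot(inherits(profile, "learner_profile"))
  t <- seq_len(profile$n_trials)
  p <- profile$p_final - (profile$p_final - profile$p_start) *
    exp(-t / profile$tau_trials)
  correct <- withr::with_seed(profile$seed,
                              as.integer(stats::runif(profile$n_trials) < p))
  list(
    trials = trial_table(data.frame(trial = t, correct = correct),
                         subject_id = subject_id, group = group),
    ground_truth = list(p = p)
  )
}
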