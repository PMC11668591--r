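#' Agent configuration
#'
#' Collects every tunable parameter of the agent in one list.
#'
#' @param epsilon base Dirichlet pseudo-count per cell.  Chosen so that a
#'   single experienced transition count still normalizes above the 0.6
#'   map-confidence floor in the largest supported mazes (S = 23 states:
#'   1.33/(1.33 + 22 eps) = 0.67 at the default 0.03), while staying nonzero
#'   so every normalization is total.
#' @param eta_exp learning rate for experienced transitions/observations.
#' @param eta_im learning rate for imagined (predicted) transitions; kept
#'   below `eta_exp` so imagined links stay weaker than experienced ones.
#' @param eta_neg decrement applied when a collision contradicts a believed
#'   open passage (negative parameter learning).
#' @param kappa_bind pseudo-count used to bind a pose to its state in the
#'   position likelihood, making P(state | pose) effectively one-hot.
#' @param pose_noise reliability mixing weight on the position factor: the
#'   factor used in inference is `(1 - pose_noise) * P(p|s) + pose_noise / P`
#'   (P = number of known positions).  Large enough that one confidently
#'   learned, uniquely identifying observation outweighs a stale pose after
#'   an unnoticed displacement; small enough that the position factor still
#'   dominates observation ties under aliasing.
#' @param conf_threshold posterior-maximum below which the agent declares
#'   itself lost and suspends position information and learning.
#' @param recover_threshold confidence at which a lost agent re-anchors its
#'   pose to the most likely state's bound pose; kept above `conf_threshold`
#'   to avoid mode flapping.
#' @param gamma softmax temperature on negative expected free energy; higher
#'   values make action selection greedier.
#' @param horizon planning horizon H: policies are evaluated over H
#'   predicted steps (at most 14).
#' @param utility_weight weight `w` on the preferred observation; `w = 0`
#'   yields a uniform preference (pure exploration).
#' @param pref_color preferred observation (color name), or `NULL`.
#' @param collision_penalty expected-free-energy penalty per unit of
#'   predicted collision probability (the risk term with binary P(c)).
#' @param negative_learning set `FALSE` to ablate negative parameter
#'   learning (used by the remapping control experiment).
#' @return a list of class `cognav_config`.
#' @export
cognav_config <- function(epsilon = 0.03,
                          eta_exp = 1,
                          eta_im = 0.2,
                          eta_neg = 1,
                          kappa_bind = 1000,
                          pose_noise = 0.3,
                          conf_threshold = 0.5,
                          recover_threshold = 0.7,
                          gamma = 8,
                          horizon = 14,
                          utility_weight = 0,
                          pref_color = NULL,
                          collision_penalty = 4,
                          negative_learning = TRUE) {
  stopifnot(epsilon > 0, eta_exp > 0, eta_im > 0, eta_neg >= 0,
            horizon >= 1, horizon <= 14, utility_weight >= 0,
            conf_threshold <= recover_threshold)
  structure(as.list(environment()), class = "cognav_config")
}
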