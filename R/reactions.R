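#' Mass-action reaction rates of the inhibition and activation reactions
#'
#' Pointwise rates of change of the five species under the two reversible
#' reactions `n + I <-> n0` (forward `k_f`, backward `k_b`) and
#' `n0 + A <-> n + W` (forward `h_f`, backward `h_b`):
#'
#' \deqn{\dot n = -k_f n I + k_b n_0 + h_f n_0 A - h_b n W}
#' \deqn{\dot n_0 = +k_f n I - k_b n_0 - h_f n_0 A + h_b n W}
#' \deqn{\dot I = -k_f n I + k_b n_0}
#' \deqn{\dot A = -h_f n_0 A + h_b n W}
#' \deqn{\dot W = +h_f n_0 A - h_b n W}
#'
#' Three linear combinations are conserved exactly: total monomer `n + n0`,
#' total inhibitor `I + n0 + W` (free, bound in the inactive monomer, and
#' sequestered in waste), and total activator `A + W`.
#'
#' @param state A [field_state()].
#' @param params A [model_params()].
#' @return A list of per-species rate grids `dn`, `dn0`, `dI`, `dA`, `dW`.
#' @examples
#' p <- model_params(k_f = 2, N = 16, L = 16)
#' s <- field_state(array(1, c(16, 16)), I = array(0.5, c(16, 16)), params = p)
#' r <- mass_action_rates(s, p)
#' r$dn[1, 1]  # -k_f * n * I = -1
#' @export
mass_action_rates <- function(state, params) {
  validate_field_state(state, params)
  r1 <- params$k_f * state$n * state$I - params$k_b * state$n0
  r2 <- params$h_f * state$n0 * state$A - params$h_b * state$n * state$W
  list(dn = -r1 + r2, dn0 = r1 - r2, dI = -r1, dA = -r2, dW = r2)
}

# Conserved linear combinations audited during integration.
conserved_totals <- function(state) {
  c(monomer = mean(state$n + state$n0),
    inhibitor = mean(state$I + state$n0 + state$W),
    activator = mean(state$A + state$W))
}
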