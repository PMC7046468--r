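## Simulation of four-population flow-cytometry event clouds.

#' Simulate one well of flow-cytometry events
#'
#' Draws `n_events` events from a four-component mixture of bivariate
#' Gaussians on (log10 FL1, log10 FL3) — one component per Pi/PNA quadrant
#' population — and exports intensities on the linear fluorescence scale.
#'
#' @param config A [flow_sim_config()].
#' @param seed Optional integer seed (defaults to `config$seed`).
#'
#' @return A list with `events` (`data.table`: `FL1_A`, `FL3_A`) and `truth`
#'   (`data.table`: `event_id`, `population` — codes of
#'   [quadrant_populations()]).
#' @export
simulate_flow_well <- function(config = flow_sim_config(), seed = config$seed) {
  validate_flow_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_events
  pops <- quadrant_populations()
  if (n == 0L) {
    return(list(
      events = data.table(FL1_A = numeric(), FL3_A = numeric()),
      truth = data.table(event_id = integer(), population = character())
    ))
  }
  lab <- sample.int(4L, n, replace = TRUE, prob = config$proportions)
  l1 <- rnorm(n, config$centres[lab, 1], config$spreads[lab, 1])
  l3 <- rnorm(n, config$centres[lab, 2], config$spreads[lab, 2])
  list(
    events = data.table(FL1_A = 10^l1, FL3_A = 10^l3),
    truth = data.table(event_id = seq_len(n), population = pops[lab])
  )
}
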