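## Flow simulation, gate derivation, quadrant gating, AR hits and triage.

test_that("flow event simulation respects proportions and determinism", {
  cfg1 <- flow_sim_config(n_events = 500,
                          proportions = c(pi_neg_pna_neg = 1, pi_pos_pna_neg = 0,
                                          pi_pos_pna_pos = 0, pi_neg_pna_pos = 0))
  w <- simulate_flow_well(cfg1, seed = 2)
  expect_true(all(w$truth$population == "pi_neg_pna_neg"))
  expect_equal(nrow(simulate_flow_well(flow_sim_config(n_events = 0))$events), 0)
  cfg <- flow_sim_config(n_events = 10000,
                         proportions = c(pi_neg_pna_neg = 0.55,
                                         pi_pos_pna_neg = 0.2,
                                         pi_pos_pna_pos = 0.15,
                                         pi_neg_pna_pos = 0.1))
  a <- simulate_flow_well(cfg, seed = 7)
  b <- simulate_flow_well(cfg, seed = 7)
  expect_identical(a$events, b$events)
  expect_equal(nrow(a$truth), 10000)
  frac <- table(a$truth$population)[names(cfg$proportions)] / 10000
  for (p in names(cfg$proportions)) {
    sd3 <- 3 * sqrt(cfg$proportions[[p]] * (1 - cfg$proportions[[p]]) / 10000)
    expect_lt(abs(frac[[p]] - cfg$proportions[[p]]), sd3 + 1e-12)
  }
  expect_error(flow_sim_config(proportions = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("gate thresholds land in the valley between the two modes", {
  set.seed(5)
  n <- 6000
  lab <- runif(n) < 0.6
  ev <- data.table::data.table(
    FL1_A = 10^rnorm(n, ifelse(lab, 2, 4), 0.25),
    FL3_A = 10^rnorm(n, ifelse(lab, 2, 4), 0.25))
  g <- derive_gates(ev)
  expect_gt(log10(g$fl1_cut), 2.5)
  expect_lt(log10(g$fl1_cut), 3.5)
  expect_gt(log10(g$fl3_cut), 2.5)
  expect_lt(log10(g$fl3_cut), 3.5)
  ## strictly between the two generating medians
  expect_true(g$fl1_cut > median(ev$FL1_A[lab]) & g$fl1_cut < median(ev$FL1_A[!lab]))
  expect_false(any(g$fallback))
})

test_that("unimodal controls trigger the percentile fallback", {
  set.seed(6)
  ev <- data.table::data.table(FL1_A = 10^rnorm(3000, 2, 0.2),
                               FL3_A = 10^rnorm(3000, 2, 0.2))
  g <- derive_gates(ev)
  expect_true(all(g$fallback))
  expect_equal(unname(g$method["fl1"]), "percentile")
  expect_equal(log10(g$fl1_cut), quantile(log10(ev$FL1_A), 0.995, names = FALSE),
               tolerance = 1e-9)
})

test_that("too few control events fail plate gating", {
  ev <- data.table::data.table(FL1_A = 10^rnorm(100, 2, 0.2),
                               FL3_A = 10^rnorm(100, 2, 0.2))
  expect_error(derive_gates(ev), "gating failure")
})

test_that("quadrant gating is strict, conservative and monotone", {
  thr <- list(fl1_cut = 1000, fl3_cut = 1000)
  ev <- data.table::data.table(FL1_A = c(2000, 1000, 500, 2000),
                               FL3_A = c(500, 500, 2000, 2000))
  q <- gate_events(ev, thr)
  expect_equal(q$pi_neg_pna_pos, 1)   # (2000, 500)
  expect_equal(q$pi_neg_pna_neg, 1)   # boundary FL1 == cut counts negative
  expect_equal(q$pi_pos_pna_neg, 1)
  expect_equal(q$pi_pos_pna_pos, 1)
  expect_equal(q$total, 4)
  empty <- gate_events(ev[0], thr)
  expect_equal(empty$total, 0)
  expect_equal(empty$pi_pos_pna_pos, 0)
  ## conservation and monotonicity on a simulated cloud
  w <- simulate_flow_well(flow_sim_config(n_events = 10000), seed = 3)
  q1 <- gate_events(w$events, thr)
  expect_equal(q1$pi_neg_pna_neg + q1$pi_pos_pna_neg +
                 q1$pi_pos_pna_pos + q1$pi_neg_pna_pos, q1$total)
  q2 <- gate_events(w$events, list(fl1_cut = 3000, fl3_cut = 1000))
  expect_lte(q2$pi_pos_pna_pos + q2$pi_neg_pna_pos,
             q1$pi_pos_pna_pos + q1$pi_neg_pna_pos)
})

test_that("gated fractions recover the generating proportions", {
  cfg <- flow_sim_config(n_events = 10000)
  w <- simulate_flow_well(cfg, seed = 9)
  q <- gate_events(w$events, list(fl1_cut = 1000, fl3_cut = 1000))
  for (p in names(cfg$proportions)) {
    sd3 <- 3 * sqrt(cfg$proportions[[p]] * (1 - cfg$proportions[[p]]) / 10000)
    ## gate misassignment adds a small amount on top of sampling noise
    expect_lt(abs(q[[p]] / q$total - cfg$proportions[[p]]), sd3 + 0.01)
  }
})

test_that("AR well results normalise percentages and apply the event floor", {
  q <- structure(list(pi_neg_pna_neg = 100, pi_pos_pna_neg = 100,
                      pi_pos_pna_pos = 100, pi_neg_pna_pos = 100, total = 400),
                 class = "quadrant_counts")
  r <- ar_well_result(q, well = "B02")
  expect_equal(c(r$pct_pi_neg_pna_neg, r$pct_pi_pos_pna_neg,
                 r$pct_pi_pos_pna_pos, r$pct_pi_neg_pna_pos),
               rep(25, 4))
  expect_equal(r$pct_pi_neg_pna_neg + r$pct_pi_pos_pna_neg +
                 r$pct_pi_pos_pna_pos + r$pct_pi_neg_pna_pos, 100,
               tolerance = 1e-9)
  expect_false(r$excluded)
  ## below the 200-event floor
  q2 <- structure(list(pi_neg_pna_neg = 50, pi_pos_pna_neg = 50,
                       pi_pos_pna_pos = 25, pi_neg_pna_pos = 25, total = 150),
                  class = "quadrant_counts")
  r2 <- ar_well_result(q2)
  expect_true(r2$excluded)
  expect_true(grepl("low_events", r2$flags))
  ## missing Pi-positive staining
  q3 <- structure(list(pi_neg_pna_neg = 380, pi_pos_pna_neg = 2,
                       pi_pos_pna_pos = 2, pi_neg_pna_pos = 16, total = 400),
                  class = "quadrant_counts")
  expect_true(grepl("low_pi_positive", ar_well_result(q3)$flags))
  r0 <- ar_well_result(structure(list(pi_neg_pna_neg = 0, pi_pos_pna_neg = 0,
                                      pi_pos_pna_pos = 0, pi_neg_pna_pos = 0,
                                      total = 0), class = "quadrant_counts"))
  expect_true(r0$excluded)
})

test_that("AR hit calling uses the strict 15% live-reacted threshold", {
  layout <- plate_layout()
  res <- data.table::data.table(
    well = c("A01", "A02", "A03", "A04", "I23"),
    pct_pi_neg_pna_pos = c(65, 14.9, 15, 15.1, 65),
    excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- call_ar_hits(res, layout = layout)
  expect_equal(out[well == "A01", call], "ar_hit")
  expect_equal(out[well == "A02", call], "none")
  expect_equal(out[well == "A03", call], "none")        # strict >
  expect_true(is.na(out[well == "A04", call]))          # excluded
  expect_true(is.na(out[well == "I23", call]))          # A23187 control well
})

test_that("A23187-style induction raises the live-reacted percentage", {
  base <- flow_sim_config(n_events = 5000)
  p <- base$proportions
  p["pi_neg_pna_pos"] <- p["pi_neg_pna_pos"] + 0.10
  p["pi_neg_pna_neg"] <- p["pi_neg_pna_neg"] - 0.10
  induced <- flow_sim_config(n_events = 5000, proportions = p)
  thr <- list(fl1_cut = 1000, fl3_cut = 1000)
  r_dmso <- ar_well_result(gate_events(simulate_flow_well(base, seed = 1)$events, thr))
  r_iono <- ar_well_result(gate_events(simulate_flow_well(induced, seed = 1)$events, thr))
  expect_gt(r_iono$pct_pi_neg_pna_pos, r_dmso$pct_pi_neg_pna_pos)
})

test_that("triage eliminates interfering hits and spares clean ones", {
  layout <- plate_layout()
  hits <- data.table::data.table(
    well = c("A01", "A02", "A03"),
    role = "compound",
    pct_pi_neg_pna_pos = c(40, 45, 50),
    excluded = FALSE,
    call = "ar_hit")
  rec <- simulate_triage_records(layout,
                                 autofluorescent_wells = "A02",
                                 dye_independent_wells = "A03",
                                 seed = 4)
  out <- triage_ar_hits(hits, rec)
  expect_true(out[well == "A01", surviving_hit])          # clean hit survives
  expect_equal(out[well == "A02", interference_flags], "autofluorescent")
  expect_equal(out[well == "A03", interference_flags], "dye_independent")
  expect_equal(sum(out$surviving_hit), 1)
  ## with every hit interfering, none survive (the screen's outcome pattern)
  rec2 <- simulate_triage_records(layout,
                                  autofluorescent_wells = c("A01", "A02"),
                                  dye_independent_wells = "A03", seed = 4)
  expect_equal(sum(triage_ar_hits(hits, rec2)$surviving_hit), 0)
  ## a hit without a triage record is kept but marked
  rec3 <- rec[rec$well != "A01"]
  out3 <- triage_ar_hits(hits, rec3)
  expect_equal(out3[well == "A01", interference_flags], "untriaged")
  expect_true(out3[well == "A01", surviving_hit])
})

test_that("gate derivation is stable across independent simulations", {
  g <- lapply(c(101, 202), function(s) {
    wells <- lapply(1:4, function(i) {
      simulate_flow_well(flow_sim_config(n_events = 4000), seed = s + i)$events
    })
    derive_gates(wells)
  })
  expect_lt(abs(log10(g[[1]]$fl1_cut) - log10(g[[2]]$fl1_cut)), 0.1)
  expect_lt(abs(log10(g[[1]]$fl3_cut) - log10(g[[2]]$fl3_cut)), 0.1)
})
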