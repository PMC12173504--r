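test_that("Fermi probability: symmetry, noise limits, reference value, overflow safety", {
  expect_equal(fermi_probability(3, 3, 0.5), 0.5)
  expect_equal(fermi_probability(10, -5, 0), 0.5)
  # direct high-precision evaluation of the sigmoid at delta = 2, w = 1/6
  expect_equal(fermi_probability(2, 0, 1 / 6), 1 / (1 + exp(-1 / 3)),
               tolerance = 1e-12)
  # complementarity under swapping model and focal
  for (d in c(-3, -0.4, 0, 0.4, 3))
    expect_equal(fermi_probability(d, 0, 0.7) + fermi_probability(0, d, 0.7), 1)
  # monotone in the payoff difference
  p <- fermi_probability(seq(-5, 5, by = 0.5), 0, 1 / 6)
  expect_true(all(diff(p) > 0))
  # no overflow for extreme arguments
  expect_equal(fermi_probability(1e6, 0, 10), 1)
  expect_equal(fermi_probability(0, 1e6, 10), 0)
  expect_error(fermi_probability(1, 0, -1), "w must be")
})

test_that("the five elementary-update outcome probabilities sum to one", {
  for (pi_t in c(0, 0.25, 0.5, 0.9, 1)) for (p in c(0, 0.3, 0.7, 1)) {
    probs <- outcome_probabilities(pi_t, p)
    expect_length(probs, 5)
    expect_true(all(probs >= 0))
    expect_equal(sum(probs), 1)
    if (p == 0) expect_equal(unname(probs[c("pair_from_tri", "tri_from_pair")]),
                             c(0, 0))
    if (p == 1) expect_equal(unname(probs[c("pair_from_pair", "tri_from_tri")]),
                             c(0, 0))
  }
})

test_that("model players are drawn from the focal's co-players", {
  cfg <- dynamics_config(w = 1 / 6, pswitch = 0.5)
  h <- build_full_overlap(30, 4, 2, seed = 51)
  set.seed(1)
  for (i in 1:200) {
    fm <- pick_focal_and_model(h, cfg)
    expect_true(fm[["model"]] %in% co_players(h, fm[["focal"]])$union)
    expect_true(fm[["focal"]] != fm[["model"]])
  }
  # two-node toy: the model is deterministic
  h2 <- hypergraph(2, rbind(c(0, 1)))
  set.seed(2)
  fm <- pick_focal_and_model(h2, cfg)
  expect_equal(unname(fm[["model"]]), 1L - fm[["focal"]])
  # layer rule draws within one layer at a time
  h0 <- hypergraph(6, rbind(c(0, 3), c(0, 4), c(1, 3), c(1, 5), c(2, 4), c(2, 5)),
                   rbind(c(0, 1, 2), c(3, 4, 5)))
  cfgl <- dynamics_config(w = 1 / 6, neighbour_rule = "layer_then_neighbour")
  set.seed(3)
  for (i in 1:100) {
    fm <- pick_focal_and_model(h0, cfgl)
    cp <- co_players(h0, fm[["focal"]])
    expect_true(fm[["model"]] %in% cp$union)
  }
})

test_that("pure-R and compiled update paths are bit-identical from a shared seed", {
  h <- build_full_overlap(30, 4, 2, seed = 5)
  sch <- make_scheme(-0.5)
  cfg <- dynamics_config(w = 1 / 6, pswitch = 0.4)
  set.seed(42)
  st <- initialize_state(30)
  set.seed(99)
  s_ref <- st
  for (i in 1:120) s_ref <- elementary_update(h, s_ref, sch, cfg)$state
  set.seed(99)
  s_cpp <- monte_carlo_step(h, st, sch, cfg)     # 2N = 60 updates
  s_cpp <- monte_carlo_step(h, s_cpp, sch, cfg)  # + 60 more
  expect_identical(s_ref$pair, s_cpp$pair)
  expect_identical(s_ref$tri, s_cpp$tri)

  cfgs <- dynamics_config(w = 1 / 6, mode = "scalar")
  set.seed(7)
  sts <- initialize_state(30, mode = "scalar")
  set.seed(11)
  r_ref <- sts
  for (i in 1:30) r_ref <- scalar_update(h, r_ref, sch, cfgs)$state
  set.seed(11)
  r_cpp <- monte_carlo_step(h, sts, sch, cfgs)   # N = 30 updates
  expect_identical(r_ref$slot, r_cpp$slot)
})

test_that("cross-order copies occur at rate pswitch among accepted imitations", {
  h <- build_full_overlap(30, 4, 2, seed = 61)
  pk <- hypercoop:::pack_hypergraph(h)
  sch <- make_scheme(-0.5)
  set.seed(8)
  st <- initialize_state(30)
  for (p in c(0, 0.4, 1)) {
    cfg <- dynamics_config(w = 0, pswitch = p)  # fermi prob exactly 1/2
    set.seed(123)
    out <- hypercoop:::run_updates_packed(pk, st$pair, st$tri, sch, cfg, 1e5)
    frac_acc <- out$n_accepted / 1e5
    expect_lt(abs(frac_acc - 0.5), binom_ci99(0.5, 1e5))
    frac_cross <- out$n_cross_accepted / out$n_accepted
    # degenerate pswitch values give an exact frequency (CI width 0)
    expect_lte(abs(frac_cross - p),
               binom_ci99(min(max(p, 0.01), 0.99), out$n_accepted))
  }
})

test_that("updates touch at most one focal slot and respect pswitch limits", {
  h <- toy_simplex()
  sch <- make_scheme(-0.5)
  set.seed(31)
  for (p in c(0, 1)) {
    cfg <- dynamics_config(w = 1 / 6, pswitch = p)
    for (i in 1:100) {
      st <- strategy_state(pair = sample(0:1, 3, TRUE),
                           tri = sample(0:1, 3, TRUE))
      res <- elementary_update(h, st, sch, cfg)
      ev <- res$event
      # cross-order source only when pswitch = 1; same-order only at 0
      if (p == 0) expect_identical(ev$source_slot, ev$target_slot)
      if (p == 1) expect_false(ev$source_slot == ev$target_slot)
      # at most one slot of one node (the focal) changed
      changed <- sum(res$state$pair != st$pair) + sum(res$state$tri != st$tri)
      expect_lte(changed, 1)
      if (changed == 1) {
        which_p <- which(res$state$pair != st$pair)
        which_t <- which(res$state$tri != st$tri)
        expect_equal(c(which_p, which_t), ev$focal + 1L)
      }
    }
  }
})

test_that("absorbing-state detection follows the configured trigger", {
  all_c <- strategy_state(pair = rep(1L, 4), tri = rep(1L, 4))
  pair_d_tri_mixed <- strategy_state(pair = rep(0L, 4), tri = c(1L, 0L, 1L, 1L))
  cfg_either <- dynamics_config(w = 1, pswitch = 0.5)
  cfg_joint <- dynamics_config(w = 1, pswitch = 0.5, absorbing_trigger = "joint")
  cfg_joint0 <- dynamics_config(w = 1, pswitch = 0, absorbing_trigger = "joint")

  expect_true(is_absorbing(all_c, cfg_either))
  expect_true(is_absorbing(all_c, cfg_joint))
  # one homogeneous layer absorbs under either_layer ...
  expect_true(is_absorbing(pair_d_tri_mixed, cfg_either))
  # ... but not under joint when cross-order copies can still change slots
  expect_false(is_absorbing(pair_d_tri_mixed, cfg_joint))
  # at pswitch = 0 the layers are separate: both must be homogeneous
  expect_false(is_absorbing(pair_d_tri_mixed, cfg_joint0))
  both_homog <- strategy_state(pair = rep(0L, 4), tri = rep(1L, 4))
  expect_true(is_absorbing(both_homog, cfg_joint0))
  expect_false(is_absorbing(both_homog, cfg_joint))   # cross copies possible
  expect_true(is_absorbing(strategy_state(slot = rep(0L, 4)),
                           dynamics_config(w = 1, mode = "scalar")))
})

test_that("an all-defector population is frozen under scalar updates", {
  h <- toy_simplex()
  sch <- make_scheme(0.2)
  cfg <- dynamics_config(w = 1 / 6, mode = "scalar")
  st <- strategy_state(slot = rep(0L, 3))
  set.seed(4)
  for (i in 1:50) st <- scalar_update(h, st, sch, cfg)$state
  expect_identical(st$slot, rep(0L, 3))
})

test_that("neutral dynamics (w = 0) drift around half cooperation", {
  h <- build_full_overlap(60, 4, 2, seed = 71)
  sch <- make_scheme(-0.5)
  cfg <- dynamics_config(w = 0, pswitch = 0.5)
  set.seed(9)
  ev <- evolve_quasistationary(h, initialize_state(60), sch, cfg, 4000)
  expect_lt(abs(mean(ev$trajectory$rho) - 0.5), 0.1)
})
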