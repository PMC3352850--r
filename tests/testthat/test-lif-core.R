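# Discrete-time LIF engine: membrane update contract, propagation,
# one-cycle delay, and tick-level orchestration.

test_that("membrane update follows the combined add/leak/clamp/threshold contract", {
  # zero input with leak: clamps at zero
  p <- neuron_group_params(threshold = 10, leak = 2, s_plus = 1, s_minus = 1)
  r <- membrane_step(0, 0, 0, p)
  expect_equal(r$M, 0)
  expect_false(r$fired)

  # single excitatory spike through a max-pooling cell: candidate 30 > 1
  p <- neuron_group_params(threshold = 1, leak = 2, s_plus = 32, s_minus = 0)
  r <- membrane_step(0, x = 32, y = 0, params = p)
  expect_true(r$fired)
  expect_equal(r$M, 0) # reset to zero on firing

  # heavily leaky integrator: one spike is cancelled, six cross threshold
  p <- neuron_group_params(threshold = 100, leak = 64, s_plus = 32, s_minus = 0)
  r1 <- membrane_step(0, x = 32, y = 0, params = p)
  expect_false(r1$fired)
  expect_equal(r1$M, 0) # max(0, 32 - 64)
  r6 <- membrane_step(0, x = 6 * 32, y = 0, params = p)
  expect_true(r6$fired) # 192 - 64 = 128 > 100
  expect_equal(r6$M, 0)

  # vectorized over a population
  p <- neuron_group_params(threshold = 5, leak = 1, s_plus = 1, s_minus = 1)
  r <- membrane_step(c(0, 4, 10), x = c(0, 3, 0), y = c(0, 0, 20), p)
  expect_equal(r$M, c(0, 0, 0)) # candidate 6 fires and resets; 10-20 clamps
  expect_equal(r$fired, c(FALSE, TRUE, FALSE))
})

test_that("membrane potential stays non-negative under random input streams", {
  set.seed(42)
  p <- neuron_group_params(threshold = 30, leak = 3, s_plus = 7, s_minus = 11)
  M <- rep(0, 50)
  for (t in 1:200) {
    x <- 7 * rbinom(50, 3, 0.4)
    y <- 11 * rbinom(50, 2, 0.3)
    r <- membrane_step(M, x, y, p)
    expect_true(all(r$M >= 0))
    M <- r$M
  }
})

test_that("linear leak reaches exactly zero in one tick from below the leak", {
  p <- neuron_group_params(threshold = 100, leak = 8, s_plus = 1, s_minus = 1)
  r <- membrane_step(5, 0, 0, p) # M < L
  expect_identical(r$M, 0)
})

test_that("negative weighted input is rejected", {
  p <- neuron_group_params(threshold = 1, leak = 0, s_plus = 1, s_minus = 1)
  expect_error(membrane_step(0, -1, 0, p), "non-negative")
  expect_error(membrane_step(0, 0, -1, p), "non-negative")
})

test_that("propagate computes weighted per-target input", {
  expect_equal(propagate(c(0, 0, 0), matrix(1, 2, 3)), c(0, 0))
  expect_equal(propagate(c(0, 1, 0), diag(3)), c(0, 1, 0))
  W <- matrix(c(1, 0.5, 1), nrow = 1)
  expect_equal(propagate(c(1, 1, 0), W), 1.5)
  expect_error(propagate(c(1, 0), W), "source")
  # batched: one column per parallel trial
  S <- cbind(c(1, 1, 0), c(0, 0, 1))
  expect_equal(as.numeric(propagate(S, W)), c(1.5, 1))
})

test_that("a three-neuron chain matches the hand-simulated membrane table", {
  # A (T=4, L=1, S+=3) is driven by a constant external input of one spike
  # per tick; B and C (T=5, L=0, S+=3) each read the previous neuron with
  # weight 1 and the engine's one-cycle propagation delay. Expected spike
  # times worked out by hand:
  #   A: M = 2, 4 (not > 4), 6 -> fires on ticks 3, 6, 9, ...
  #   B: input arrives one tick after an A spike: M = 3 at t4, 6 > 5 at t7
  #      -> fires on ticks 7, 13, 19, ...
  #   C: fires 7 ticks after each B spike pair: 14, ...
  pA <- neuron_group_params(threshold = 4, leak = 1, s_plus = 3, s_minus = 0)
  pBC <- neuron_group_params(threshold = 5, leak = 0, s_plus = 3, s_minus = 0)
  mA <- mB <- mC <- 0
  sA <- sB <- 0
  fired_at <- list(A = integer(), B = integer(), C = integer())
  for (t in 1:20) {
    pA_spk <- sA
    pB_spk <- sB
    rA <- membrane_step(mA, 3 * 1, 0, pA) # external drive every tick
    rB <- membrane_step(mB, 3 * propagate(pA_spk, matrix(1)), 0, pBC)
    rC <- membrane_step(mC, 3 * propagate(pB_spk, matrix(1)), 0, pBC)
    mA <- rA$M; mB <- rB$M; mC <- rC$M
    sA <- rA$fired + 0; sB <- rB$fired + 0
    if (rA$fired) fired_at$A <- c(fired_at$A, t)
    if (rB$fired) fired_at$B <- c(fired_at$B, t)
    if (rC$fired) fired_at$C <- c(fired_at$C, t)
  }
  expect_equal(fired_at$A, c(3, 6, 9, 12, 15, 18))
  expect_equal(fired_at$B, c(7, 13, 19))
  expect_equal(fired_at$C, c(14))
})

test_that("spikes influence targets only from the next tick (delay contract)", {
  net <- build_network(seed = 5)
  reset_network(net)
  frame <- matrix(0L, 10, 10)
  frame[1, 1:2] <- 1L # a full edge-detector pair
  out1 <- network_tick(net, frame)
  # the retina neuron spikes on the very tick its pixel is on
  expect_true(any(out1$group == "Retina" & out1$neuron == 1))
  expect_true(any(out1$group == "Retina" & out1$neuron == 11))
  # but no downstream group has received any input yet
  expect_true(all(out1$group == "Retina"))
  expect_true(all(net$state$M[["S1-ver"]] == 0))
  out2 <- network_tick(net, matrix(0L, 10, 10))
  # one tick later the S1 cells covering pixel (1,1) have integrated it
  expect_gt(sum(net$state$M[["S1-ver"]]), 0)
  reset_network(net)
  expect_null(net$state)
})

test_that("a blank frame on a resting network produces no spikes anywhere", {
  net <- build_network(seed = 6)
  out <- network_tick(net, matrix(0L, 10, 10))
  expect_equal(nrow(out), 0)
})

test_that("delayed motion input lags the instantaneous pathway by the configured delay", {
  net <- build_network(seed = 7)
  frame <- render_frame(make_stimulus_trial("T", 1), 0)
  st <- neuroburst:::bn_init_state(net, 1L)
  inst_first <- del_first <- NA
  for (t in 1:40) {
    spk <- neuroburst:::bn_tick(net, st, as.numeric(frame))
    if (is.na(inst_first) && sum(spk[["S1-inst"]]) > 0) inst_first <- t
    if (is.na(del_first) && sum(spk[["S1-del"]]) > 0) del_first <- t
  }
  expect_equal(del_first - inst_first, 10) # static input, D = 10 ticks
})
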