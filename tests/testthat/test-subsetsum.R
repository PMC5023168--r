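test_that("instance validation enforces positive values and targets", {
  expect_error(subsetsum_instance(c(0, 2), 3), "positive integers")
  expect_error(subsetsum_instance(c(1, 2), 0), "positive integer")
  expect_error(subsetsum_instance(c(5), 5), "at least two values")
  expect_error(build_subsetsum_system(1), "n >= 2")
})

test_that("the system family has the declared inventory", {
  sys <- build_subsetsum_system(4)
  expect_identical(nrow(sys$neurons), 3L * 4L + 6L)            # 3n + 6
  expect_setequal(sys$neurons$label[sys$neurons$spikes == 1L], c("0", "2", "3"))
  # the completion counter consumes exactly n spikes
  r4 <- resolve_rules(sys$resolver, "4")
  expect_length(r4, 1L)
  expect_identical(r4[[1]]$consume, 4L)
  expect_true(spike_set_contains(r4[[1]]$guard, 4))
  expect_false(spike_set_contains(r4[[1]]$guard, 3))
})

test_that("input trains deposit 3x+3 spikes per value and 2S in the target neuron at step 2n+1", {
  trains <- build_subsetsum_input(subsetsum_example_instance())
  expect_true(all(lengths(trains) == 2L * 4L + 1L))
  expect_identical(trains$in_1[9], 6L)    # 3*1 + 3
  expect_identical(trains$in_4[9], 15L)   # 3*4 + 3
  expect_identical(trains$s[9], 10L)      # 2*5
  expect_true(all(vapply(trains, function(tr) all(tr[1:8] == 0L), TRUE)))
})

test_that("the worked instance enumerates both solution subsets", {
  sol <- solve_subsetsum(subsetsum_example_instance())
  expect_identical(sol$subsets, c("0110", "1001"))
  expect_identical(sol$steps,
                   subsetsum_horizon(subsetsum_example_instance()) +
                     subsetsum_halting_offset())
  expect_identical(sol$subsets, brute_force_subsetsum(subsetsum_example_instance()))
})

test_that("the brute-force oracle enumerates subsets correctly", {
  expect_identical(brute_force_subsetsum(subsetsum_example_instance()),
                   c("0110", "1001"))
  expect_identical(brute_force_subsetsum(subsetsum_instance(c(2, 4), 3)),
                   character(0))                       # parity
  expect_identical(brute_force_subsetsum(subsetsum_instance(c(1, 2, 3), 6)),
                   "111")                              # only the full set
})

test_that("the generation stage of the n=2 family yields four output neurons by step 3", {
  sys <- build_subsetsum_system(2)
  cfg <- ddsn_config(sys)
  for (i in 1:3) cfg <- ddsn_step(cfg, sys)$config
  expect_identical(sum(grepl("^o_[01]{2}$", cfg$label)), 4L)
})

test_that("each completion spike reaches neuron 4 at step 2n+x_i+3 and outputs hold 3*sum(B) after input", {
  inst <- subsetsum_example_instance()
  sol <- solve_subsetsum(inst, trace = TRUE, history = TRUE)
  tr <- sol$run$trace
  to4 <- tr[tr$event == "deliver" & tr$label == "4", ]
  expect_identical(sort(to4$step), sort(2L * inst$n + inst$X + 3L))
  expect_true(all(to4$amount == 1L))
  # spike loads at the end of the input stage (step 2n + x_max + 3)
  h <- sol$run$history
  at <- h[h$step == 2L * inst$n + inst$x_max + 3L & grepl("^o_", h$label), ]
  bits <- do.call(rbind, lapply(strsplit(sub("^o_", "", at$label), ""), as.integer))
  sums <- as.integer(bits %*% inst$X)
  expect_identical(at$spikes, 3L * sums)
})

test_that("the closed-form checking trace reproduces the three-case behaviour", {
  eq <- checking_stage_trace(5, 5)
  expect_true(eq$survives)
  expect_identical(eq$event, "forget-final")
  expect_identical(eq$event_offset, 6L)                  # S + 1
  expect_identical(eq$counts[1:3], c(15L, 17L, 14L))     # forget 5, receive 2
  short <- checking_stage_trace(3, 5)
  expect_false(short$survives)
  expect_identical(short$event, "dissolve-short")
  expect_identical(short$event_offset, 4L)               # sum_B + 1
  expect_identical(short$counts[short$event_offset + 1L], 2L)
  long <- checking_stage_trace(7, 5)
  expect_false(long$survives)
  expect_identical(long$event, "dissolve-long")
  expect_identical(long$event_offset, 6L)                # S + 1
  expect_identical(long$counts[long$event_offset + 1L], 3L * (7L - 5L) + 1L)
  empty <- checking_stage_trace(0, 5)
  expect_identical(empty$event, "dissolve-short")
  expect_identical(empty$event_offset, 1L)
})

test_that("the engine reproduces the closed-form checking trace on sampled cases", {
  for (sum_B in c(0, 2, 5, 9, 13)) {
    for (S in c(1, 5, 9)) {
      run <- ddsn_run(checking_stage_system(sum_B, S), history = TRUE)
      ct <- checking_stage_trace(sum_B, S)
      got <- history_series(run$history, "o_1")
      expect_identical(got[seq_along(ct$counts)], ct$counts,
                       label = sprintf("counts sum_B=%d S=%d", sum_B, S))
      expect_identical(length(run$surviving) == 1L, ct$survives,
                       label = sprintf("survival sum_B=%d S=%d", sum_B, S))
    }
  }
})

test_that("the simulator matches the oracle on a stream of random instances", {
  for (s in 1:30) {
    inst <- subsetsum_stream_instance(s)
    sol <- solve_subsetsum(inst)
    expect_identical(sol$subsets, brute_force_subsetsum(inst),
                     label = sprintf("seed %d", s))
    expect_identical(sol$steps,
                     subsetsum_horizon(inst) + subsetsum_halting_offset(),
                     label = sprintf("seed %d steps", s))
  }
})

test_that("duplicate values yield separate index-based solutions", {
  inst <- subsetsum_instance(c(2, 2, 3), 5)
  sol <- solve_subsetsum(inst)
  expect_identical(sol$subsets, c("011", "101"))
})
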