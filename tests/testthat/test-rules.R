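test_that("rule constructors enforce the structural invariants", {
  expect_error(rule_fire(spike_set(3), consume = 1, produce = 2), "c >= p")
  expect_error(rule_fire(spike_set(1), consume = 2), "at least the consumed")
  expect_error(rule_forget(spike_set(2, 3), consume = 5), "at least the consumed")
  expect_silent(rule_forget(spike_set(5, 3), consume = 5))   # a^2(a^3)^+/a^5
  expect_error(rule_fire(spike_set(1), 1, delay = -1), "nonnegative")
})

test_that("resolution is order-stable and instantiates division child templates", {
  res <- rule_resolver(list(
    rule_block("^o_[01]{1,2}$", list(rule_divide(spike_set(1), "{label}1", "{label}0")),
               regex = TRUE),
    rule_block("^o_[01]+$", list(rule_forget(spike_set(1), 1)), regex = TRUE)))
  got <- resolve_rules(res, "o_10")
  expect_length(got, 2L)
  expect_identical(got[[1]]$kind, "divide")
  expect_identical(got[[1]]$left, "o_101")
  expect_identical(got[[1]]$right, "o_100")
  expect_identical(got[[2]]$kind, "forget")
  # cached second resolution is identical
  expect_identical(resolve_rules(res, "o_10"), got)
  # unresolvable labels own no rules
  expect_length(resolve_rules(res, "zz"), 0L)
})

test_that("selection picks the unique applicable rule of the SAT driver neuron", {
  sys <- ddsn_system(
    neurons = data.frame(label = "d", spikes = 7L, stringsAsFactors = FALSE),
    syn = matrix(character(0), ncol = 2),
    rules = list(rule_block("d", list(rule_fire(spike_set(3, 2), 2)))))
  cfg <- ddsn_config(sys)
  r <- select_rule(sys, cfg, id = 1L)
  expect_identical(r$kind, "fire")
  expect_identical(r$consume, 2L)
})

test_that("selection at 2 spikes in a Subset Sum output neuron is the short-fall dissolution", {
  sys <- checking_stage_system(sum_B = 1, S = 1)
  cfg <- ddsn_config(sys)
  cfg$spikes[cfg$label == "o_1"] <- 2L
  r <- select_rule(sys, cfg, id = which(cfg$label == "o_1"))
  expect_identical(r$kind, "dissolve")
  expect_true(spike_set_contains(r$guard, 2))
  expect_false(spike_set_contains(r$guard, 4))  # not the surplus dissolution
})

test_that("two simultaneously applicable rules raise an ambiguity error in strict mode only", {
  sys <- ddsn_system(
    neurons = data.frame(label = "x", spikes = 1L, stringsAsFactors = FALSE),
    syn = matrix(character(0), ncol = 2),
    rules = list(rule_block("x", list(rule_forget(spike_set(1), 1),
                                      rule_fire(spike_set(1), 1)))))
  cfg <- ddsn_config(sys)
  expect_error(select_rule(sys, cfg, 1L), class = "ddsnp_ambiguity_error")
  expect_error(ddsn_run(sys), class = "ddsnp_ambiguity_error")
  expect_error(ddsn_run(sys, mode = "random"), "seed")
  res <- ddsn_run(sys, mode = "random", seed = 42)
  expect_identical(res$steps, 1L)
})
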