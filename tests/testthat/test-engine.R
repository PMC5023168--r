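test_that("a division blocked by an existing synapse is inapplicable while the other applies", {
  sys <- division_demo_system()
  cfg <- ddsn_config(sys)
  rules <- resolve_rules(sys$resolver, "3")
  id3 <- cfg$id[cfg$label == "3"]
  expect_false(division_allowed(cfg, id3, rules[[1]]))  # [a]_3 -> [ ]_2 || [ ]_3
  expect_true(division_allowed(cfg, id3, rules[[2]]))   # [a]_3 -> [ ]_3 || [ ]_4
  st <- ddsn_step(cfg, sys, trace = TRUE)
  divides <- Filter(function(e) e$event == "divide", st$events)
  expect_length(divides, 1L)
  expect_identical(divides[[1]]$detail, "children=3,4")
})

test_that("division children inherit the parent's synapses and dictionary pairs", {
  res <- ddsn_run(division_demo_system(), max_steps = 5, trace = TRUE)
  expect_identical(res$steps, 1L)
  expect_setequal(res$config$label, c("1", "2", "3", "4"))
  edges <- config_synapses(res$config)
  got <- sort(paste(edges$from_label, edges$to_label, sep = "->"))
  expect_identical(got, c("1->2", "2->3", "2->4"))
  # children start empty and open
  kids <- res$config$label %in% c("3", "4")
  expect_true(all(res$config$spikes[kids] == 0L))
})

test_that("a parent with nothing to inherit divides into unconnected children", {
  sys <- ddsn_system(
    neurons = data.frame(label = "solo", spikes = 1L, stringsAsFactors = FALSE),
    syn = matrix(character(0), ncol = 2),
    rules = list(rule_block("solo", list(rule_divide(spike_set(1), "l", "r")))))
  res <- ddsn_run(sys, max_steps = 3)
  expect_setequal(res$config$label, c("l", "r"))
  expect_length(res$config$syn_from, 0L)
})

test_that("dissolution removes the neuron with its synapses and leaves the rest untouched", {
  res <- ddsn_run(dissolution_demo_system(), max_steps = 5, trace = TRUE)
  expect_identical(res$steps, 1L)
  expect_identical(res$config$label, "2")
  expect_length(res$config$syn_from, 0L)
  expect_identical(res$trace$event[res$trace$label == "1"], "dissolve")
  # isolated dissolution: unrelated neuron keeps its spikes
  cfg <- ddsn_config(dissolution_demo_system())
  cfg$spikes[cfg$label == "2"] <- 4L
  cfg2 <- apply_dissolution(cfg, id = cfg$id[cfg$label == "1"])
  expect_identical(cfg2$spikes[cfg2$label == "2"], 4L)
})

test_that("delays close the neuron, lose incoming spikes, and deliver on reopening", {
  res <- ddsn_run(delay_demo_system(), max_steps = 10, trace = TRUE)
  tr <- res$trace
  # p's step-1 delivery found a closed and was lost
  lost <- tr[tr$event == "lost", ]
  expect_identical(nrow(lost), 1L)
  expect_identical(lost$step, 1L)
  # a's delayed emission reached b at step 4
  dl <- tr[tr$event == "deliver" & tr$label == "b", ]
  expect_identical(dl$step, 4L)
  expect_identical(dl$amount, 1L)
  expect_identical(res$steps, 4L)
  expect_identical(res$config$spikes[res$config$label == "b"], 1L)
})

test_that("halting requires open neurons, no applicable rule, no pending item and no future input", {
  # inert system halts immediately with the initial out-pattern survivors
  sys <- ddsn_system(
    neurons = data.frame(label = c("o_1", "q"), spikes = c(0L, 1L),
                         stringsAsFactors = FALSE),
    syn = matrix(character(0), ncol = 2),
    rules = list(rule_block("q", list(rule_fire(spike_set(3), 3)))),
    out_pattern = "^o_[01]$")
  res <- ddsn_run(sys)
  expect_identical(res$steps, 0L)
  expect_identical(res$surviving, "o_1")
  # a pending delayed emission keeps the system live
  dsys <- delay_demo_system()
  cfg <- ddsn_config(dsys)
  st <- ddsn_step(cfg, dsys)
  expect_false(is_halted(st$config, dsys))
  # a future nonzero input keeps the system live; zero remainders do not
  expect_false(is_halted(ddsn_config(sys), sys, trains = list(q = c(0L, 2L))))
  expect_true(is_halted(ddsn_config(sys), sys, trains = list(q = c(0L, 0L))))
  # exceeding the budget on a non-halting system raises
  loop <- ddsn_system(
    neurons = data.frame(label = c("u", "v"), spikes = c(1L, 0L),
                         stringsAsFactors = FALSE),
    syn = rbind(c("u", "v"), c("v", "u")),
    rules = list(rule_block("u", list(rule_fire(spike_set(1), 1))),
                 rule_block("v", list(rule_fire(spike_set(1), 1)))))
  expect_error(ddsn_run(loop, max_steps = 20), class = "ddsnp_max_steps_error")
})

test_that("spike counts stay nonnegative and synapse endpoints stay live throughout a run", {
  inst <- subsetsum_stream_instance(7)
  sol <- solve_subsetsum(inst, history = TRUE)
  expect_true(all(sol$run$history$spikes >= 0L))
  cfg <- sol$run$config
  expect_true(all(cfg$syn_from %in% cfg$id))
  expect_true(all(cfg$syn_to %in% cfg$id))
  expect_true(all(cfg$syn_from != cfg$syn_to))
})

test_that("replaying trace deltas reproduces the final spike count of every surviving neuron", {
  cases <- list(
    list(sys = build_sat_system(3, 3),
         run = solve_sat(sat_example_instance(), trace = TRUE)$run),
    list(sys = build_subsetsum_system(4),
         run = solve_subsetsum(subsetsum_example_instance(), trace = TRUE)$run))
  for (case in cases) {
    tr <- case$run$trace
    cfg <- case$run$config
    n0 <- nrow(case$sys$neurons)
    for (i in seq_along(cfg$id)) {
      id <- cfg$id[i]
      init <- if (id <= n0) case$sys$neurons$spikes[id] else 0L  # children start empty
      gained <- sum(tr$amount[tr$id == id & tr$event %in% c("deliver", "input")])
      spent <- sum(tr$amount[tr$id == id & tr$event %in% c("fire", "forget")])
      expect_identical(init + gained - spent, cfg$spikes[i],
                       label = sprintf("neuron id %d (%s)", id, cfg$label[i]))
    }
  }
})

test_that("the generation stage doubles the output family every other step", {
  sol <- solve_sat(sat_example_instance(), history = TRUE)
  h <- sol$run$history
  for (k in 1:3) {
    at <- h[h$step == 2L * k - 1L, ]
    expect_identical(sum(grepl(sprintf("^o_[01]{%d}$", k), at$label)), as.integer(2^k),
                     label = sprintf("step %d", 2L * k - 1L))
  }
})
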