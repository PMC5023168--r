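# Micro systems used across test files.

# One source neuron firing immediately at a delayed neuron: "a" applies
# [a -> a; 3] at step 1 (closing itself through step 3), "p" fires [a -> a]
# at step 1 whose delivery finds "a" closed and is lost; "b" finally
# receives a's delayed emission at step 4.
delay_demo_system <- function() {
  ddsn_system(
    neurons = data.frame(label = c("p", "a", "b"), spikes = c(1L, 1L, 0L),
                         stringsAsFactors = FALSE),
    syn = rbind(c("p", "a"), c("a", "b")),
    rules = list(
      rule_block("p", list(rule_fire(spike_set(1), 1))),
      rule_block("a", list(rule_fire(spike_set(1), 1, delay = 3L)))))
}

# Seeded instance streams shared by the property tests and the acceptance
# suite: sizes cycle over 2..8 variables/values.
sat_stream_instance <- function(s) {
  random_cnf(n = 2L + (s %% 7L), m = 1L + (s %% 8L), seed = s)
}

subsetsum_stream_instance <- function(s) {
  random_subsetsum(n = 2L + (s %% 7L), value_max = 8L, seed = 1000L + s,
                   planted = (s %% 2L == 0L))
}

# Start-of-step spike counts of one label from a history data frame.
history_series <- function(history, lbl) {
  as.integer(history$spikes[history$label == lbl])
}
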