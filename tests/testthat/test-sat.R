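test_that("clause encoding maps literal polarity to spike counts", {
  expect_identical(encode_clause(c(-1, 2, 3), 3), c(2L, 1L, 1L))
  expect_identical(encode_clause(c(1, 2), 3), c(1L, 1L, 0L))
  expect_identical(encode_clause(integer(0), 3), c(0L, 0L, 0L))
  expect_identical(encode_clause(c(2, 2, -3), 3), c(0L, 1L, 2L))  # duplicates collapse
  expect_error(encode_clause(c(1, -1), 3), class = "ddsnp_complementary_literal_error")
  expect_error(cnf_instance(3, list(c(2, -2))),
               class = "ddsnp_complementary_literal_error")
})

test_that("instance validation rejects degenerate problems", {
  expect_error(cnf_instance(1, list(1)), "at least two variables")
  expect_error(cnf_instance(3, list()), "at least one clause")
  expect_error(cnf_instance(3, list(c(1, 4))), "1..n", fixed = TRUE)
  expect_error(build_sat_system(1, 3), "n >= 2")
  expect_error(build_sat_system(3, 0), "m >= 1")
})

test_that("the system family has the declared inventory", {
  sys <- build_sat_system(3, 3)
  expect_identical(nrow(sys$neurons), 3L * 3L + 5L)            # 3n + 5
  expect_identical(sys$neurons$spikes[sys$neurons$label == "d"], 6L)  # 2m
  expect_setequal(sys$neurons$label[sys$neurons$spikes == 1L], c("0", "2", "3"))
  sys2 <- build_sat_system(5, 2)
  expect_identical(nrow(sys2$neurons), 3L * 5L + 5L)
  expect_identical(sys2$neurons$spikes[sys2$neurons$label == "d"], 4L)
})

test_that("input trains carry the 2n-step generation prefix then one clause per step", {
  trains <- build_sat_input(sat_example_instance())
  expect_identical(trains$in_x2, c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 2L, 1L))
  expect_true(all(lengths(trains) == 2L * 3L + 3L))
  # a variable absent from every clause has an all-zero suffix
  cnf <- cnf_instance(3, list(c(1, 2), c(-2)))
  expect_identical(build_sat_input(cnf)$in_x3, rep(0L, 8L))
})

test_that("the 3-variable worked instance halts at step 12 with its three satisfying assignments", {
  sol <- solve_sat(sat_example_instance())
  expect_identical(sol$assignments, c("011", "101", "111"))
  expect_identical(sol$steps, 12L)
  expect_identical(sol$steps, unname(sat_steps(3, 3)["ddsn"]))
  expect_identical(sol$assignments, brute_force_sat(sat_example_instance()))
})

test_that("the brute-force oracle enumerates assignments correctly", {
  expect_identical(brute_force_sat(sat_example_instance()), c("011", "101", "111"))
  expect_identical(brute_force_sat(cnf_instance(2, list(1, -1))), character(0))
  expect_identical(brute_force_sat(cnf_instance(3, list(integer(0), c(1)))), character(0))
  one_clause <- cnf_instance(4, list(c(1, 2, 3, 4)))
  expect_length(brute_force_sat(one_clause), 2L^4 - 1L)
})

test_that("clause c dissolves its falsified assignments at step 2n+c+3 and the clock stops after 2n", {
  sol <- solve_sat(sat_example_instance(), trace = TRUE)
  tr <- sol$run$trace
  diss <- tr[tr$event == "dissolve", ]
  by_step <- lapply(split(sub("^o_", "", diss$label), diss$step), sort)
  expect_identical(by_step,
                   list(`10` = c("000", "001"),   # (x1 | x2) false
                        `11` = c("010", "110"),   # (-x2 | x3) false
                        `12` = c("100")))         # (-x1 | x2 | x3) false
  # generation clock: sigma_2 forgets its two spikes at step 2n+1, and
  # neurons 1, 2, 3 never fire after step 2n
  expect_true(any(tr$event == "forget" & tr$label == "2" & tr$step == 7L))
  clock_fires <- tr[tr$event == "fire" & tr$label %in% c("1", "2", "3"), ]
  expect_true(all(clock_fires$step <= 6L))
})

test_that("the gate driver fires once per clause and retains a single spike at halt", {
  cnf <- sat_stream_instance(3)
  n <- cnf$n; m <- length(cnf$clauses)
  sol <- solve_sat(cnf, trace = TRUE)
  tr <- sol$run$trace
  d_fires <- tr[tr$event == "fire" & tr$label == "d", ]
  expect_identical(nrow(d_fires), m)
  expect_identical(sort(d_fires$step), seq(2L * n + 1L, 2L * n + m))
  cfg <- sol$run$config
  expect_identical(cfg$spikes[cfg$label == "d"], 1L)
})

test_that("the simulator matches the oracle on a stream of random instances", {
  for (s in 1:40) {
    cnf <- sat_stream_instance(s)
    sol <- solve_sat(cnf)
    expect_identical(sol$assignments, brute_force_sat(cnf),
                     label = sprintf("seed %d", s))
    f <- 2L * cnf$n + length(cnf$clauses) + 3L
    expect_true(sol$steps %in% c(f - 1L, f), label = sprintf("seed %d steps", s))
  }
})

test_that("a run quiesces one step early only when the final clause delivers nothing", {
  # all output neurons already dissolved, or every survivor satisfies every
  # literal of a clause mentioning all variables; the answer is still final
  # at 2n+m+3
  early <- cnf_instance(2, list(1, 2, c(1, 2)))   # (x1) & (x2) & (x1 | x2)
  sol <- solve_sat(early)
  expect_identical(sol$assignments, "11")
  expect_identical(sol$steps, 9L)                  # 2n+m+2: survivor got no spike
  refuted <- cnf_instance(2, list(1, -1, c(1, 2)))
  sol2 <- solve_sat(refuted)
  expect_identical(sol2$assignments, character(0))
  expect_identical(sol2$steps, 9L)                 # outputs emptied before clause 3
})
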