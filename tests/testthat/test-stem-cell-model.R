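test_that("model parameters validate their constraints", {
  expect_error(model_params(a_min = 0), "a_min")
  expect_error(model_params(r = 1), "exceed 1")
  expect_error(model_params(f_alpha = c(2, 0.5, 18, 0)), "asymptotes")
  expect_error(model_params(alpha_mult = c(host = 1, bulk = 1, A = 1)),
               "missing classes")
  expect_s3_class(model_params(), "model_params")
})

test_that("transition probabilities respect bounds and monotonic structure", {
  p <- model_params()
  # boundary: maximal affinity in an empty niche gives the maximal alpha
  tp_max <- transition_probabilities(p$a_max, 0, 0, p)
  grid_a <- seq(p$a_min, p$a_max, length.out = 25)
  expect_equal(unname(tp_max[1, "alpha"]),
               max(transition_probabilities(grid_a, 0, 0, p)[, "alpha"]))
  # boundary: minimal affinity gives the minimal alpha at any census
  for (na in c(0, 1000, 4000)) {
    tp <- transition_probabilities(grid_a, na, 0, p)
    expect_equal(unname(tp[1, "alpha"]), min(tp[, "alpha"]))
  }
  # alpha increases with affinity, decreases with niche occupancy
  alphas <- transition_probabilities(grid_a, 1000, 0, p)[, "alpha"]
  expect_true(all(diff(alphas) >= 0))
  occ <- transition_probabilities(0.5, seq(0, 4000, 100), 0, p)[, "alpha"]
  expect_true(all(diff(occ) <= 0))
  # omega decreases with affinity
  omegas <- transition_probabilities(grid_a, 0, 100, p)[, "omega"]
  expect_true(all(diff(omegas) <= 0))
  expect_error(transition_probabilities(p$a_max * 2, 0, 0, p), "affinity")
})

test_that("transition probabilities stay in [0,1] over a 10^4-point sweep", {
  p <- model_params()
  set.seed(99)
  n <- 10000
  tp <- transition_probabilities(
    a = stats::runif(n, p$a_min, p$a_max),
    N_A = stats::runif(n, 0, 3 * p$N_bar_A),
    N_Omega = stats::runif(n, 0, 3 * p$N_bar_Omega),
    params = p,
    class = sample(c("host", "bulk", "A", "B"), n, replace = TRUE))
  expect_true(all(tp >= 0 & tp <= 1))
})

test_that("a step leaves a quiescent state unchanged except for the clock", {
  p <- model_params(f_alpha = c(0, 0.5, 18, 0), f_omega = c(0, 0.5, 6, 0))
  cells <- data.frame(clone_id = "host", class = "host", compartment = "A",
                      affinity = p$a_max, cycle = 0, window = 0)[rep(1, 50), ]
  st <- model_state(cells, t = 0)
  st2 <- run_model(st, p, steps = 5, seed = 1)
  expect_equal(st2$t, 5)
  expect_equal(st2$cells$affinity, st$cells$affinity)
  expect_equal(st2$cells$compartment, st$cells$compartment)
  expect_equal(nrow(st2$cells), 50)
})

test_that("a cycling cell at the end of its cycle divides into two daughters", {
  p <- model_params(f_alpha = c(0, 0.5, 18, 0), f_omega = c(0, 0.5, 6, 0))
  cells <- data.frame(clone_id = "L", class = "A", compartment = "Omega",
                      affinity = 0.9, cycle = p$tau_c - p$dt, window = 0)
  st <- run_model(model_state(cells), p, steps = 1, seed = 2)
  expect_equal(nrow(st$cells), 2)
  expect_equal(st$cells$cycle, c(0, 0))
  expect_equal(st$cells$affinity, rep(0.9 / p$d, 2))
})

test_that("cells below minimal affinity differentiate out of the stem pool", {
  p <- model_params(f_alpha = c(0, 0.5, 18, 0), f_omega = c(0, 0.5, 6, 0))
  cells <- data.frame(clone_id = "L", class = "B", compartment = "Omega",
                      affinity = p$a_min * 1.01, cycle = 0, window = 0)
  st <- run_model(model_state(cells), p, steps = 2, seed = 3)
  expect_equal(nrow(st$cells), 0)
  expect_equal(st$diff_out[["L"]], 1)
})

test_that("the per-step conservation ledger balances over a long run", {
  p <- fast_params()
  st <- init_host_state(p, occupancy = 0.6, seed = 4)
  # add a leukemic clone so all code paths are exercised
  st$cells <- rbind(st$cells,
    data.frame(clone_id = "L", class = "A", compartment = "A",
               affinity = 0.5, cycle = 0, window = 0)[rep(1, 5), ])
  st <- model_state(st$cells)
  out <- run_model(st, p, steps = 1000, seed = 5)
  led <- attr(out, "ledger")
  expect_equal(led[, "after"],
               led[, "before"] + led[, "births"] - led[, "diffs"] -
                 led[, "deaths"] - led[, "lost"])
  # steps chain: population at the end of one step enters the next
  expect_equal(unname(led[-1, "before"]), unname(led[-nrow(led), "after"]))
  expect_equal(nrow(out$cells), unname(led[nrow(led), "after"]))
})

test_that("host-only populations converge to a stable niche census", {
  p <- fast_params()
  ss <- run_to_steady_state(p, seed = 6)
  expect_true(ss$converged)
  na <- attr(ss, "n_a_daily")
  w <- utils::tail(na, 10)
  expect_lt(stats::sd(w) / mean(w), 0.05)
  # ergodicity: independent seeds land within 10% of each other
  ss2 <- run_to_steady_state(p, seed = 7)
  n1 <- sum(ss$cells$compartment == "A")
  n2 <- sum(ss2$cells$compartment == "A")
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.10)
})

test_that("an empty initial population stays empty and converges trivially", {
  p <- fast_params()
  ss <- run_to_steady_state(p, seed = 8, occupancy = 0)
  expect_true(ss$converged)
  expect_equal(nrow(ss$cells), 0)
  expect_equal(sum(ss$diff_out), 0)
})

test_that("neutral leukemic labels are exchangeable with host cells", {
  # identity modifiers: labeled cells follow exactly the host dynamics
  p <- fast_params(alpha_mult = c(host = 1, bulk = 1, A = 1, B = 1),
                   omega_mult = c(host = 1, bulk = 1, A = 1, B = 1))
  n0 <- 60
  base <- data.frame(clone_id = rep(c("host", "L"), each = n0),
                     class = rep(c("host", "bulk"), each = n0),
                     compartment = "A", affinity = p$a_max, cycle = 0,
                     window = 0)
  diffs <- vapply(1:200, function(s) {
    st <- run_model(model_state(base), p, steps = 120, seed = s)
    live <- table(factor(st$cells$class, c("host", "bulk")))
    out <- c(st$diff_out[["host"]], st$diff_out[["L"]])
    (live[["host"]] + out[1]) - (live[["bulk"]] + out[2])
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-9)
})

test_that("a stronger proliferation modifier never reduces leukemic burden", {
  p0 <- fast_params()
  ss <- run_to_steady_state(p0, seed = 9)
  burden <- function(om, seeds = 40) {
    p <- fast_params(omega_mult = c(host = 1, bulk = om, A = om, B = om))
    vapply(seq_len(seeds), function(s) {
      cells <- rbind(ss$cells,
        data.frame(clone_id = "L", class = "A", compartment = "A",
                   affinity = 0.6, cycle = 0, window = 0)[rep(1, 3), ])
      st <- run_model(model_state(cells), p, steps = 12 * 24, seed = 1000 + s)
      sum(st$cells$class == "A") + st$diff_out[["L"]]
    }, numeric(1))
  }
  m <- vapply(c(1, 40, 130), function(om) mean(burden(om)), numeric(1))
  expect_true(all(diff(m) >= 0))
})

test_that("model runs are reproducible given a seed", {
  p <- fast_params()
  st <- init_host_state(p, seed = 10)
  a <- run_model(st, p, steps = 100, seed = 123)
  b <- run_model(st, p, steps = 100, seed = 123)
  expect_identical(a$cells, b$cells)
  expect_identical(a$diff_out, b$diff_out)
})

test_that("census matches a recount of the cell table", {
  p <- fast_params()
  st <- run_model(init_host_state(p, seed = 11), p, steps = 200, seed = 12)
  cen <- census(st)
  expect_equal(cen["A", "host"], sum(st$cells$compartment == "A"))
  expect_equal(cen["Omega", "host"], sum(st$cells$compartment == "Omega"))
  expect_equal(cen["differentiated", "host"], unname(st$diff_out[["host"]]))
})
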