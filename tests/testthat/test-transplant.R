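test_that("graft specs validate fractions and pool the bulk remainder", {
  gs <- graft_d29(10000)
  expect_equal(sum(gs$clones$fraction), 1)
  expect_true("bulk" %in% gs$clones$clone_id)
  expect_equal(gs$clones$fraction[gs$clones$clone_id == "A"], 0.0047)
  expect_error(graft_spec(data.frame(clone_id = "A", class = "A",
                                     fraction = 1.2), 100), "\\[0, 1\\]")
  expect_error(graft_spec(data.frame(clone_id = c("A", "B"),
                                     class = c("A", "B"),
                                     fraction = c(0.6, 0.6)), 100),
               "more than 1")
})

test_that("graft sampling is multinomial with the specified expectations", {
  spec <- graft_d29(10000)
  draws <- vapply(1:4000, function(s) {
    g <- sample_graft(spec, seed = s)
    c(g[["A"]], g[["B"]], sum(g))
  }, numeric(3))
  expect_equal(mean(draws[3, ]), 10000) # every draw has exactly n_cells
  expect_lt(abs(mean(draws[1, ]) - 47), 0.5)
  expect_lt(abs(mean(draws[2, ]) - 65), 0.5)
  # A+B cells average about 112, the "approximately 100" transplanted driver dose
  expect_lt(abs(mean(draws[1, ] + draws[2, ]) - 112), 1)
  # degenerate cases
  expect_equal(sum(sample_graft(graft_d29(0), seed = 1)), 0)
  solo <- graft_spec(data.frame(clone_id = "A", class = "A", fraction = 1),
                     n_cells = 500)
  expect_equal(sample_graft(solo, seed = 2)[["A"]], 500)
})

test_that("engraftment models are validated and class means ordered", {
  em <- engraftment_model(mean_bulk = 1e-5, ab_shift = 0.1)
  expect_equal(em$mean[["A"]], em$mean[["B"]])
  expect_gt(em$mean[["A"]], em$mean[["bulk"]])
  expect_error(engraftment_model(mean_bulk = -1), "class means")
  expect_error(engraftment_model(mean_bulk = 0.5, ab_shift = 0.6),
               "class means")
})

test_that("a graft that cannot attach leaves the host trajectory untouched", {
  p <- fast_params()
  host <- run_to_steady_state(p, seed = 20)
  em <- engraftment_model(mean_bulk = 0, ab_shift = 0, window_hours = 48)
  g <- sample_graft(graft_d29(500), seed = 21)
  out <- transplant(host, g, em, p, horizon_days = 4, seed = 22)
  expect_false(out$leukemic)
  expect_equal(sum(out$engrafted_counts), 0)
  expect_equal(out$n_lost, sum(g))
  # control: untransplanted host evolved on the same simulation stream
  ctrl <- host
  set.seed(out$seeds$sim)
  for (d in 1:2) ctrl <- run_model(ctrl, p, steps = 24)
  final_host <- out$final_state$cells
  expect_identical(final_host[final_host$class == "host", , drop = FALSE],
                   ctrl$cells)
  # transplantation restarts output accounting at time zero
  expect_equal(out$final_state$diff_out[["host"]],
               ctrl$diff_out[["host"]] - host$diff_out[["host"]])
})

test_that("transplantation requires a converged host", {
  p <- fast_params()
  host <- init_host_state(p, seed = 1)
  expect_error(
    transplant(host, sample_graft(graft_d29(100), seed = 1),
               engraftment_model(), p),
    "steady state")
})

test_that("cohort summaries are internally consistent", {
  p <- fast_params()
  em <- engraftment_model(mean_bulk = 1e-5, ab_shift = 0.1)
  cs <- run_cohort(graft_d29(1000), em, p, R = 12, seed = 30,
                   horizon_days = 6)
  expect_equal(cs$n_replicates, 12)
  expect_equal(cs$fraction_no + cs$fraction_mono + cs$fraction_bi +
                 cs$fraction_poly, 1, tolerance = 1e-12)
  # fractions reproduce the per-replicate outcome table exactly
  expect_equal(cs$fraction_mono, mean(cs$outcomes$category == "monoclonal"))
  expect_equal(cs$incidence, mean(cs$outcomes$category != "no_leukemia"))
  expect_equal(nrow(cs$outcomes), 12)
  # reproducible given seed
  cs2 <- run_cohort(graft_d29(1000), em, p, R = 12, seed = 30,
                    horizon_days = 6)
  expect_identical(cs$outcomes, cs2$outcomes)
})

test_that("cohort output writers round-trip the summary fractions", {
  p <- fast_params()
  em <- engraftment_model(mean_bulk = 0, ab_shift = 0)
  cs <- run_cohort(graft_d29(100), em, p, R = 4, seed = 31, horizon_days = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(cs, tsv)
  df <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(df$fraction_no, cs$fraction_no)
  js <- withr::local_tempfile(fileext = ".json")
  write_cohort_json(cs, js)
  expect_equal(jsonlite::read_json(js)$n_replicates, 4)
})

test_that("calibration reports infeasibility for impossible targets", {
  p <- fast_params()
  # a cohort of zero transplanted cells cannot produce leukemia
  targets <- list(list(
    spec = graft_spec(data.frame(clone_id = "A", class = "A", fraction = 1),
                      n_cells = 0),
    events = 15, n_animals = 15, horizon_days = 2))
  cal <- calibrate(targets, grid = list(ab_shift = c(0.05, 0.1)),
                   params = p, R = 4, seed = 40)
  expect_false(cal$feasible)
  expect_s3_class(cal, "calibration_result")
  expect_equal(nrow(cal$grid_results), 2)
  inc_cols <- grep("^inc_", names(cal$grid_results))
  expect_true(all(cal$grid_results[, inc_cols] == 0)) # no cells, no leukemia
})

test_that("calibration is deterministic given a seed", {
  p <- fast_params()
  targets <- list(list(spec = graft_d29(200), events = 0, n_animals = 15,
                       horizon_days = 3))
  a <- calibrate(targets, grid = list(ab_shift = c(0.02, 0.1)), params = p,
                 R = 3, seed = 41)
  b <- calibrate(targets, grid = list(ab_shift = c(0.02, 0.1)), params = p,
                 R = 3, seed = 41)
  expect_identical(a$grid_results, b$grid_results)
})

test_that("the enriched late graft yields biclonal leukemia in nearly all recipients", {
  cfg <- calibrated_config()
  cs <- run_cohort(graft_d49(10000), cfg$engraftment, cfg$params, R = 20,
                   seed = 60, horizon_days = 15, criterion = cfg$criterion)
  expect_gte(cs$incidence, 0.9)
  leu <- cs$outcomes[cs$outcomes$category != "no_leukemia", ]
  # both drivers co-dominate in most recipients
  expect_gte(mean(leu$dominant == "A+B"), 0.6)
})

test_that("a bulk-only graft essentially never causes leukemia", {
  cfg <- calibrated_config()
  bulk_only <- graft_spec(data.frame(clone_id = "bulk", class = "bulk",
                                     fraction = 1), n_cells = 10000,
                          label = "bulk_only")
  cs <- run_cohort(bulk_only, cfg$engraftment, cfg$params, R = 100, seed = 61,
                   horizon_days = 25, criterion = cfg$criterion)
  expect_gte(cs$fraction_no, 0.95)
})

test_that("simulated incidence rises with the engraftment location shift", {
  # monotonicity audit of the calibration's main free parameter
  p <- fast_params()
  host <- run_to_steady_state(p, seed = 50)
  inc <- vapply(c(0.01, 0.1, 0.4), function(shift) {
    em <- engraftment_model(mean_bulk = 1e-6, ab_shift = shift)
    cs <- run_cohort(graft_d29(2000), em, p, R = 25, seed = 51,
                     horizon_days = 12, host = host)
    cs$incidence
  }, numeric(1))
  expect_true(all(diff(inc) >= 0))
})
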