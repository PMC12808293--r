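cs <- make_rule_plus_exception()

small_cohort <- function(n = 3, seed = 5, ...) {
  simulate_cohort(simulation_protocol(n_participants = n, seed = seed,
                                      n_blocks = 22, total_trials = 308,
                                      intro_interval = 17, ...), cs)
}

test_that("accuracy summaries handle perfect and chance responders", {
  co <- small_cohort(conditions = "control")
  truth <- cs$stimuli$category[match(co$responses$stimulus_id, cs$stimuli$id)]
  co$responses$response <- truth
  co$responses$correct <- 1L
  acc <- accuracy_by_segment(co, "control")
  expect_true(all(acc$mean_accuracy == 1))
  expect_true(all(acc$sem == 0))
  expect_true(all(acc$n_participants == 3L))
  expect_setequal(unique(acc$item_type), c("all", "exception", "non_exception"))

  co2 <- simulate_cohort(simulation_protocol(c_schedule = rep(0, 11),
                                             n_participants = 12, seed = 6,
                                             conditions = "control",
                                             n_blocks = 22), cs)
  acc2 <- accuracy_by_segment(co2, "control", split_exceptions = FALSE)
  expect_true(all(abs(acc2$mean_accuracy - 0.5) < 0.1))
})

test_that("SSE fit partitions by item type sum exactly to the total", {
  co <- small_cohort(conditions = "control")
  fr <- fit_condition(co, "control", "prototype", "sse_segment",
                      spec = fit_spec(n_restarts = 1, maxit = 5))
  part <- partition_fit_by_item_type(fr, co, "control")
  for (f in fr) {
    rows <- part[part$participant == f$participant & part$segment == f$segment, ]
    tot <- rows$value[rows$item_type == "total"]
    expect_equal(rows$value[rows$item_type == "exception"] +
                   rows$value[rows$item_type == "non_exception"],
                 tot, tolerance = 1e-10)
    expect_equal(tot, f$objective_value, tolerance = 1e-10)
  }
})

test_that("MSE fit partitions reconcile as trial-count-weighted means", {
  co <- small_cohort(conditions = "experimental")
  fr <- fit_condition(co, "experimental", "exemplar", "mse_trials",
                      spec = fit_spec(n_restarts = 1, maxit = 5))
  part <- partition_fit_by_item_type(fr, co, "experimental")
  for (pid in unique(part$participant)) {
    for (s in unique(part$segment)) {
      rows <- part[part$participant == pid & part$segment == s, ]
      exc <- rows[rows$item_type == "exception", ]
      non <- rows[rows$item_type == "non_exception", ]
      tot <- rows[rows$item_type == "total", ]
      expect_equal((exc$value * exc$n + non$value * non$n) / tot$n,
                   tot$value, tolerance = 1e-10)
    }
  }
})

test_that("a model fitting every stimulus equally well splits SSE 2:12", {
  co <- small_cohort(conditions = "control")
  co$responses$response <- "A"                   # p-hat = 1 for every stimulus
  sq <- co$sequences$control[[1]]
  fr <- structure(list(
    params = model_params("prototype", rep(1 / 6, 6), c = 0),  # predicts 0.5
    objective = "sse_segment", objective_value = 14 * 0.25,
    segment = 3L, participant = "p01", condition = "control",
    family = "prototype", converged = TRUE), class = "fit_result")
  part <- partition_fit_by_item_type(list(fr), co, "control")
  exc <- part$value[part$item_type == "exception"]
  non <- part$value[part$item_type == "non_exception"]
  expect_equal(exc / non, 2 / 12, tolerance = 1e-12)
})

test_that("post-introduction filter keeps trials after full coverage", {
  sq_e <- make_powerlaw_sequence(cs, seed = 2)
  df <- data.frame(trial = sq_e$trial, x = seq_len(nrow(sq_e)))
  kept <- post_introduction_filter(sq_e, df)
  expect_equal(min(kept$trial), 457L)            # last introduction is trial 456
  sq_c <- make_uniform_sequence(cs, 44, seed = 2)
  kept_c <- post_introduction_filter(sq_c, data.frame(trial = sq_c$trial))
  expect_equal(min(kept_c$trial), 15L)           # first block covers all stimuli
  expect_equal(nrow(kept_c), 616L - 14L)
  # degenerate one-stimulus sequence: coverage completes on trial 1
  toy <- sequence_from_ids(rep(1L, 5L))
  expect_equal(min(post_introduction_filter(toy, data.frame(trial = 1:5))$trial), 2L)
})

test_that("model recovery report computes trend statistics from its curves", {
  pr <- simulation_protocol(n_participants = 3, seed = 19, n_blocks = 22,
                            total_trials = 308, intro_interval = 17)
  rep_ <- model_recovery(pr, cs, spec = fit_spec(n_restarts = 1, maxit = 15))
  expect_s3_class(rep_, "recovery_report")
  fc <- rep_$fit_curves
  expect_setequal(unique(fc$family), c("prototype", "exemplar"))
  expect_equal(nrow(fc), 2 * 2 * 11)
  tr <- rep_$trends
  for (cond in c("control", "experimental")) {
    row <- tr[tr$condition == cond, ]
    g <- fc[fc$condition == cond, ]
    gap <- g$mean_value[g$family == "prototype"] - g$mean_value[g$family == "exemplar"]
    expect_equal(row$gap_change, gap[11] - gap[1], tolerance = 1e-12)
  }
  expect_type(rep_$flags$control_advantage_grows, "logical")
})

test_that("mixture weight recovery separates prototype- and exemplar-generated data", {
  spec <- fit_spec("mse_trials", n_restarts = 2, seed = 3, maxit = 60)
  for (fam in c("prototype", "exemplar")) {
    co <- simulate_cohort(simulation_protocol(
      model_family = fam, c_schedule = rep(3, 11), n_participants = 1,
      conditions = "control", n_blocks = 30, seed = 23), cs)
    sq <- co$sequences$control[[1]]
    r <- co$responses
    fe <- fit("exemplar", r$response, sq, cs, spec)
    fp <- fit("prototype", r$response, sq, cs, spec)
    fm <- fit("mixture", r$response, sq, cs, spec,
              extra_starts = list(
                model_params("mixture", fe$params$w, c_proto = fe$params$c,
                             c_exem = fe$params$c, alpha = 0),
                model_params("mixture", fp$params$w, c_proto = fp$params$c,
                             c_exem = fp$params$c, alpha = 1)))
    if (fam == "prototype") expect_gt(fm$params$alpha, 0.7)
    else expect_lt(fm$params$alpha, 0.3)
  }
})

test_that("forgetting-vs-mixture comparison returns curves and alpha trajectory", {
  co <- small_cohort(n = 2, conditions = "control")
  cmp <- compare_forgetting_vs_mixture(co, "control",
                                       spec = fit_spec(n_restarts = 1, maxit = 10))
  expect_setequal(unique(cmp$fit_curves$family),
                  c("exemplar_forgetting", "mixture"))
  expect_equal(nrow(cmp$alpha_trajectory), 11L)
  expect_true(all(cmp$alpha_trajectory$mean_alpha >= 0 &
                    cmp$alpha_trajectory$mean_alpha <= 1))
  expect_named(cmp$unidentifiable, c("p01", "p02"))
})
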