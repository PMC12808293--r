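cs <- make_rule_plus_exception()
feats <- feature_matrix(cs)
eq_w <- rep(1 / 6, 6)

test_that("prototype model reproduces closed-form probabilities", {
  p <- model_params("prototype", eq_w, c = 1)
  protoA <- feats[cs$stimuli$role == "prototype" & cs$stimuli$category == "A", ]
  # probe = A prototype: d_A = 0, d_B = 1, P(A) = 1/(1 + e^-1)
  expect_equal(prototype_predict(protoA, p, cs$prototypes), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  # c = 0 flattens everything to 0.5
  p0 <- model_params("prototype", eq_w, c = 0)
  for (i in 1:14)
    expect_equal(prototype_predict(feats[i, ], p0, cs$prototypes), 0.5)
  # A exception: d_A = 5/6, d_B = 1/6 -> P(A) = 1/(1 + e^{4/6}) < 0.5
  excA <- feats[cs$stimuli$role == "exception" & cs$stimuli$category == "A", ]
  pa <- prototype_predict(excA, p, cs$prototypes)
  expect_equal(pa, 1 / (1 + exp(4 / 6)), tolerance = 1e-12)
  expect_lt(pa, 0.5)
  expect_error(prototype_predict(c(0, 1), p, cs$prototypes), "mismatch")
})

test_that("prototype model misclassifies exceptions for every sensitivity", {
  # an exception differs from the opposite prototype on one dimension d*;
  # whenever attention keeps it closer to that prototype (w[d*] < 1/2, which
  # is the premise of calling it "more similar to the alternate category"),
  # no sensitivity c > 0 can push its accuracy above chance
  exc <- which(cs$stimuli$role == "exception")
  # flipped dimension of each exception (where it differs from the opposite
  # prototype): dims 5 and 6 in the default structure
  opp <- ifelse(cs$stimuli$category[exc] == "A", "B", "A")
  d_star <- vapply(seq_along(exc), function(i)
    which(feats[exc[i], ] != cs$prototypes[opp[i], ]), 0L)
  expect_equal(sort(d_star), c(5L, 6L))
  set.seed(41)
  n_ok <- 0L
  while (n_ok < 500L) {
    w <- random_simplex(6)
    if (any(w[d_star] >= 0.5)) next
    n_ok <- n_ok + 1L
    p <- model_params("prototype", w, c = stats::runif(1, 0.01, 30))
    for (j in exc) {
      pa <- prototype_predict(feats[j, ], p, cs$prototypes)
      pcorrect <- if (cs$stimuli$category[j] == "A") pa else 1 - pa
      expect_lt(pcorrect, 0.5)
    }
  }
  # the premise is sharp: attention concentrated on d* rescues that exception,
  # but only at the price of misclassifying the typical sharing the dimension
  w_inv <- rep(0.02, 6); w_inv[d_star[1]] <- 0.9
  p_inv <- model_params("prototype", w_inv, c = 5)
  pa <- prototype_predict(feats[exc[1], ], p_inv, cs$prototypes)
  expect_gt(pa, 0.5)                         # category-A exception now "correct"
  typ_shared <- which(cs$stimuli$role == "typical" &
                        cs$stimuli$category == "A" & feats[, d_star[1]] == 1L)
  pa_typ <- prototype_predict(feats[typ_shared, ], p_inv, cs$prototypes)
  expect_lt(pa_typ, 0.5)                     # the shared-dimension typical breaks
})

test_that("exemplar model sums token similarities; degenerate stores behave", {
  protoA <- feats[1, ]; protoB <- feats[8, ]
  p <- model_params("exemplar", eq_w, c = 1)
  st <- exemplar_store(rbind(protoA, protoB), c("A", "B"))
  expect_equal(exemplar_predict(protoA, p, st), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  empty <- exemplar_store(matrix(numeric(0), 0, 6), character(0), integer(0))
  expect_equal(exemplar_predict(protoA, p, empty), 0.5)
  # duplicating every token k times cancels in the similarity ratio
  set.seed(7)
  toks <- feats[sample(14, 6, replace = TRUE), ]
  cats <- sample(c("A", "B"), 6, replace = TRUE)
  st1 <- exemplar_store(toks, cats)
  st3 <- exemplar_store(toks[rep(1:6, 3), ], rep(cats, 3))
  probe <- feats[3, ]
  expect_equal(exemplar_predict(probe, p, st1), exemplar_predict(probe, p, st3),
               tolerance = 1e-12)
  # one-sided store: absent category contributes a zero sum
  stA <- exemplar_store(rbind(protoA), "A")
  expect_equal(exemplar_predict(probe, p, stA), 1)
})

test_that("memory strength is a power law of delay", {
  expect_equal(memory_strength(1, 0.7), 1)
  expect_equal(memory_strength(1:10, 0), rep(1, 10))
  expect_equal(memory_strength(2, 0.7), 2^-0.7)
  d <- 1:50
  expect_true(all(diff(memory_strength(d, 0.4)) < 0))
  expect_error(memory_strength(0, 0.7))
  expect_error(memory_strength(3, -1))
})

test_that("forgetting weights tokens by delay and nests the exemplar model", {
  p <- model_params("exemplar_forgetting", eq_w, c = 2, beta = 0.7)
  probe <- feats[5, ]
  # identical-feature tokens: similarities cancel, strengths decide
  st <- exemplar_store(rbind(probe, probe), c("B", "A"),
                       stored_at_trial = c(1L, 100L))
  # at trial 101: A token delay 1, B token delay 100
  expect_equal(forgetting_predict(probe, p, st, 101L),
               1 / (1 + 100^-0.7), tolerance = 1e-12)
  # beta = 0 and equal delays both reduce to the base exemplar model
  set.seed(13)
  for (i in 1:20) {
    toks <- feats[sample(14, 8, replace = TRUE), ]
    cats <- sample(c("A", "B"), 8, replace = TRUE)
    w <- random_simplex(6); cc <- stats::runif(1, 0, 8)
    st <- exemplar_store(toks, cats, 1:8)
    pe <- exemplar_predict(probe, model_params("exemplar", w, c = cc), st)
    p0 <- model_params("exemplar_forgetting", w, c = cc, beta = 0)
    expect_equal(forgetting_predict(probe, p0, st, 9L), pe, tolerance = 1e-12)
    st_eq <- exemplar_store(toks, cats, rep(4L, 8L))
    pf <- model_params("exemplar_forgetting", w, c = cc, beta = 1.3)
    # equal delays: common strength cancels
    expect_equal(forgetting_predict(probe, pf, st_eq, 18L), pe, tolerance = 1e-12)
  }
  st_late <- exemplar_store(rbind(probe, probe), c("A", "B"), c(1L, 100L))
  expect_error(forgetting_predict(probe, p, st_late, 50L), "before")
})

test_that("delaying opposite-category tokens raises own-category probability", {
  p <- model_params("exemplar_forgetting", eq_w, c = 2, beta = 0.8)
  probe <- feats[2, ]                       # a category-A typical
  own <- feats[c(1, 3), ]; opp <- feats[c(8, 9), ]
  for (shift in c(0L, 20L, 100L)) {
    st_near <- exemplar_store(rbind(opp, own), c("B", "B", "A", "A"),
                              c(200L - shift, 201L - shift, 202L, 203L))
    if (shift == 0L) base <- forgetting_predict(probe, p, st_near, 210L)
    else expect_gt(forgetting_predict(probe, p, st_near, 210L), base)
  }
})

test_that("mixture blends component predictions through alpha", {
  st <- exemplar_store(feats[c(1, 8, 2), ], c("A", "B", "A"), 1:3)
  probe <- feats[7, ]
  for (i in 1:10) {
    set.seed(i)
    w <- random_simplex(6)
    cp <- stats::runif(1, 0, 10); ce <- stats::runif(1, 0, 10)
    pp <- prototype_predict(probe, model_params("prototype", w, c = cp), cs$prototypes)
    pe <- exemplar_predict(probe, model_params("exemplar", w, c = ce), st)
    m1 <- model_params("mixture", w, c_proto = cp, c_exem = ce, alpha = 1)
    m0 <- model_params("mixture", w, c_proto = cp, c_exem = ce, alpha = 0)
    mh <- model_params("mixture", w, c_proto = cp, c_exem = ce, alpha = 0.3)
    expect_equal(mixture_predict(probe, m1, st, cs$prototypes), pp, tolerance = 1e-12)
    expect_equal(mixture_predict(probe, m0, st, cs$prototypes), pe, tolerance = 1e-12)
    expect_equal(mixture_predict(probe, mh, st, cs$prototypes),
                 0.3 * pp + 0.7 * pe, tolerance = 1e-12)
  }
  mv <- model_params("mixture", eq_w, c_proto = 1, c_exem = 1, alpha = c(0.2, 0.9))
  expect_error(mixture_predict(probe, mv, st, cs$prototypes, current_segment = 3L),
               "alpha")
})

test_that("free-parameter counts are 6/6/7/8 for the default structure", {
  expect_equal(n_free_parameters(model_params("prototype", eq_w, c = 1)), 6L)
  expect_equal(n_free_parameters(model_params("exemplar", eq_w, c = 1)), 6L)
  expect_equal(n_free_parameters(
    model_params("exemplar_forgetting", eq_w, c = 1, beta = 0.7)), 7L)
  expect_equal(n_free_parameters(
    model_params("mixture", eq_w, c_proto = 1, c_exem = 1, alpha = 0.5)), 8L)
})

test_that("sequence predictions match the naive store-rebuilding oracle", {
  set.seed(99)
  for (i in 1:12) {
    T_ <- sample(5:25, 1)
    sq <- sequence_from_ids(sample(cs$stimuli$id, T_, replace = TRUE))
    w <- random_simplex(6)
    cc <- stats::runif(1, 0, 10)
    bb <- stats::runif(1, 0, 2)
    pe <- model_params("exemplar", w, c = cc)
    pf <- model_params("exemplar_forgetting", w, c = cc, beta = bb)
    expect_equal(predict_sequence(pe, sq, cs), oracle_trace("exemplar", sq, cs, w, cc),
                 tolerance = 1e-12)
    expect_equal(predict_sequence(pf, sq, cs),
                 oracle_trace("forgetting", sq, cs, w, cc, bb), tolerance = 1e-12)
  }
})

test_that("sequence-level traces: empty store, history independence, bounds", {
  sq <- make_uniform_sequence(cs, 6, seed = 3)
  pe <- model_params("exemplar", eq_w, c = 4)
  tr <- predict_sequence(pe, sq, cs)
  expect_equal(tr[1], 0.5)
  expect_true(all(tr >= 0 & tr <= 1))
  # prototype traces depend only on the stimulus shown, never on history
  pp <- model_params("prototype", eq_w, c = 2)
  tr_p <- predict_sequence(pp, sq, cs)
  sq2 <- make_uniform_sequence(cs, 6, seed = 4)
  tr_p2 <- predict_sequence(pp, sq2, cs)
  expect_equal(tr_p[match(1:14, sq$stimulus_id)],
               tr_p2[match(1:14, sq2$stimulus_id)], tolerance = 1e-12)
  # exemplar traces drift as tokens accumulate
  reps <- which(sq$stimulus_id == sq$stimulus_id[1])
  expect_gt(stats::sd(tr[reps]), 0)
})

test_that("per-segment parameter vectors are resolved via the assignment", {
  sq <- make_uniform_sequence(cs, 4, seed = 8)
  a <- assign_segments(sq, "sequential", 4)
  c_sched <- c(1, 3, 5, 7)
  pv <- model_params("exemplar_forgetting", eq_w, c = c_sched, beta = 0.5)
  tr <- predict_sequence(pv, sq, cs, segment_assignment = a)
  for (s in 1:4) {
    ps <- model_params("exemplar_forgetting", eq_w, c = c_sched[s], beta = 0.5)
    trs <- predict_sequence(ps, sq, cs,
                            eval_trials = which(a$segment_of_trial == s))
    expect_equal(tr[a$segment_of_trial == s], trs, tolerance = 1e-12)
  }
  expect_error(predict_sequence(pv, sq, cs), "segment")
})
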