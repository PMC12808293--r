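#' Simulation protocols
#'
#' Describes how a synthetic response cohort is generated: the generating
#' model family, its parameters, the per-segment sensitivity schedule that
#' emulates learning, and the presentation-schedule settings of each
#' condition. The defaults are the demonstration protocol: equal attention
#' weights of one-sixth, sensitivity increasing from 5.5 to 10.5 in steps of
#' 0.5 across the 11 segments (sequential segments in the control condition,
#' power-law segments in the experimental condition — the same schedule in
#' both), and a forgetting rate of `beta = 0.7`.
#'
#' @param model_family Generating family (default `"exemplar_forgetting"`).
#' @param weights Attention weights (default equal, `1/M` each; resolved at
#'   simulation time from the structure when `NULL`).
#' @param c_schedule Per-segment sensitivities (length `n_segments`).
#' @param beta Forgetting rate (used by `exemplar_forgetting`).
#' @param alpha Mixture weight (used by `mixture`).
#' @param n_participants Participants per condition.
#' @param conditions Conditions to simulate.
#' @param n_segments Number of analysis segments (default 11).
#' @param n_blocks Control-condition permutation blocks (default 44).
#' @param total_trials,intro_interval,decay_gamma Experimental-condition
#'   schedule settings (defaults 616, 35, 1).
#' @param shared_sequence If `TRUE` all participants share one presentation
#'   sequence per condition; by default each participant gets an independent
#'   seeded sequence.
#' @param seed Master seed; participant-level seeds are derived from it.
#' @return A list of class `simulation_protocol`.
#' @export
simulation_protocol <- function(model_family = "exemplar_forgetting",
                                weights = NULL,
                                c_schedule = seq(5.5, 10.5, by = 0.5),
                                beta = 0.7, alpha = 0.5,
                                n_participants = 30L,
                                conditions = c("control", "experimental"),
                                n_segments = 11L, n_blocks = 44L,
                                total_trials = 616L, intro_interval = 35L,
                                decay_gamma = 1, shared_sequence = FALSE,
                                seed = 1L) {
  if (length(c_schedule) != n_segments)
    stop("c_schedule must have one sensitivity per segment")
  if (any(c_schedule < 0)) stop("sensitivities must be >= 0")
  structure(list(model_family = model_family, weights = weights,
                 c_schedule = as.numeric(c_schedule), beta = beta,
                 alpha = alpha, n_participants = as.integer(n_participants),
                 conditions = conditions, n_segments = as.integer(n_segments),
                 n_blocks = as.integer(n_blocks),
                 total_trials = as.integer(total_trials),
                 intro_interval = as.integer(intro_interval),
                 decay_gamma = decay_gamma,
                 shared_sequence = isTRUE(shared_sequence),
                 seed = as.integer(seed)),
            class = "simulation_protocol")
}

protocol_params <- function(protocol, structure) {
  w <- protocol$weights
  if (is.null(w)) w <- rep(1 / structure$n_features, structure$n_features)
  switch(protocol$model_family,
    prototype = model_params("prototype", w, c = protocol$c_schedule),
    exemplar = model_params("exemplar", w, c = protocol$c_schedule),
    exemplar_forgetting = model_params("exemplar_forgetting", w,
                                       c = protocol$c_schedule,
                                       beta = protocol$beta),
    mixture = model_params("mixture", w, c_proto = protocol$c_schedule,
                           c_exem = protocol$c_schedule,
                           alpha = protocol$alpha),
    stop("unknown model_family: ", protocol$model_family))
}

condition_scheme <- function(condition)
  if (condition == "control") "sequential" else "power_law"

protocol_sequence <- function(protocol, structure, condition, seed) {
  if (condition == "control")
    make_uniform_sequence(structure, protocol$n_blocks, seed)
  else
    make_powerlaw_sequence(structure, protocol$total_trials,
                           protocol$intro_interval, protocol$decay_gamma, seed)
}

#' Noiseless prediction trace under a protocol
#'
#' The per-trial `P(A)` values a protocol implies for one sequence: trial
#' `t`'s sensitivity is `c_schedule[segment(t)]` under the condition-
#' appropriate segment scheme (sequential for control, power-law for
#' experimental). This is [simulate_cohort()] without the Bernoulli sampling
#' step.
#'
#' @param protocol A [simulation_protocol()].
#' @param structure A `category_structure`.
#' @param sequence A [trial_sequence].
#' @return Numeric vector of `P(A)` values, one per trial.
#' @export
simulate_trace_only <- function(protocol, structure, sequence) {
  params <- protocol_params(protocol, structure)
  assign_ <- assign_segments(sequence, condition_scheme(sequence$condition[1L]),
                             protocol$n_segments)
  predict_sequence(params, sequence, structure, segment_assignment = assign_)
}

#' Simulate a response cohort
#'
#' For each participant and condition, generates (or reuses) a presentation
#' sequence, computes the generating model's per-trial `P(A)` (with the
#' sensitivity of each trial's segment), and samples each response as
#' Bernoulli(`P(A)`). Feedback is the true category, so `correct = 1` iff
#' the response matches the stimulus's category. Fully reproducible from the
#' protocol seed.
#'
#' @param protocol A [simulation_protocol()].
#' @param structure A `category_structure`.
#' @param sequences Optional pre-built sequences: a named list per condition,
#'   each a list of one [trial_sequence] per participant. Generated from the
#'   protocol when `NULL`.
#' @return A list of class `cohort`: `responses` (data frame with
#'   `participant`, `condition`, `trial`, `stimulus_id`, `response`,
#'   `correct`, `p_A`), `sequences` (per-condition lists of per-participant
#'   sequences), `protocol`, `structure`.
#' @export
simulate_cohort <- function(protocol, structure, sequences = NULL) {
  stopifnot(inherits(protocol, "simulation_protocol"),
            inherits(structure, "category_structure"))
  true_cat <- structure$stimuli$category
  names(true_cat) <- structure$stimuli$id
  pids <- sprintf("p%02d", seq_len(protocol$n_participants))

  all_rows <- list()
  seq_store <- list()
  ci <- 0L
  for (cond in protocol$conditions) {
    ci <- ci + 1L
    seq_store[[cond]] <- list()
    for (i in seq_along(pids)) {
      sq <- if (!is.null(sequences)) {
        sequences[[cond]][[i]]
      } else {
        sseed <- if (protocol$shared_sequence)
          child_seed(protocol$seed, ci * 100000L)
        else child_seed(protocol$seed, ci * 100000L + i)
        protocol_sequence(protocol, structure, cond, sseed)
      }
      seq_store[[cond]][[pids[i]]] <- sq
      p_a <- simulate_trace_only(protocol, structure, sq)
      resp <- with_seed(child_seed(protocol$seed, ci * 1000000L + 31L * i), {
        ifelse(stats::runif(length(p_a)) < p_a, "A", "B")
      })
      all_rows[[length(all_rows) + 1L]] <- data.frame(
        participant = pids[i], condition = cond, trial = sq$trial,
        stimulus_id = sq$stimulus_id, response = resp,
        correct = as.integer(resp == true_cat[as.character(sq$stimulus_id)]),
        p_A = p_a)
    }
  }
  structure(list(responses = do.call(rbind, all_rows), sequences = seq_store,
                 protocol = protocol, structure = structure),
            class = "cohort")
}

#' Export / import cohort responses as CSV
#'
#' @param cohort A `cohort` (or its `responses` data frame).
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the responses data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- if (inherits(cohort, "cohort")) cohort$responses else cohort
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
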