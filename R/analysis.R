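sem <- function(x) stats::sd(x) / sqrt(length(x))

item_type_of <- function(structure, stimulus_id) {
  role <- structure$stimuli$role[match(stimulus_id, structure$stimuli$id)]
  ifelse(role == "exception", "exception", "non_exception")
}

#' Accuracy by segment and item type
#'
#' Per-participant accuracy is averaged within each segment (and item type
#' when `split_exceptions`), then averaged across participants with the
#' standard error of the mean taken across participants. Segments are the
#' condition-appropriate scheme: sequential (contiguous) for control,
#' power-law (presentation-index) for experimental.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param condition `"control"` or `"experimental"`.
#' @param split_exceptions Also summarise exception and non-exception items
#'   separately (default `TRUE`).
#' @param n_segments Number of segments (default: the cohort protocol's).
#' @return Data frame with `condition`, `segment`, `item_type` (`"all"`,
#'   `"exception"`, `"non_exception"`), `mean_accuracy`, `sem`,
#'   `n_participants`. Cells with no trials for any participant are flagged
#'   by `n_participants = 0` and `NA` accuracy.
#' @export
accuracy_by_segment <- function(cohort, condition, split_exceptions = TRUE,
                                n_segments = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(n_segments)) n_segments <- cohort$protocol$n_segments
  seqs <- cohort$sequences[[condition]]
  resp <- cohort$responses[cohort$responses$condition == condition, ]
  scheme <- condition_scheme(condition)

  per <- list()
  for (pid in names(seqs)) {
    sq <- seqs[[pid]]
    seg <- assign_segments(sq, scheme, n_segments)$segment_of_trial
    r <- resp[resp$participant == pid, ]
    r <- r[order(r$trial), ]
    itype <- item_type_of(cohort$structure, r$stimulus_id)
    per[[pid]] <- data.frame(participant = pid, segment = seg,
                             item_type = itype, correct = r$correct)
  }
  df <- do.call(rbind, per)

  summarise_cells <- function(d, label) {
    out <- lapply(seq_len(n_segments), function(s) {
      cell <- d[d$segment == s, ]
      acc <- tapply(cell$correct, cell$participant, mean)
      acc <- acc[!is.na(acc)]
      data.frame(condition = condition, segment = s, item_type = label,
                 mean_accuracy = if (length(acc)) mean(acc) else NA_real_,
                 sem = if (length(acc) > 1L) sem(as.numeric(acc)) else NA_real_,
                 n_participants = length(acc))
    })
    do.call(rbind, out)
  }
  res <- summarise_cells(df, "all")
  if (split_exceptions) {
    res <- rbind(res,
                 summarise_cells(df[df$item_type == "exception", ], "exception"),
                 summarise_cells(df[df$item_type == "non_exception", ], "non_exception"))
  }
  rownames(res) <- NULL
  res
}

# trace at the fitted parameters of a fit_result, over given eval trials
fitted_trace <- function(fr, sq, structure, assign_, eval_trials = NULL) {
  predict_sequence(fr$params, sq, structure, segment_assignment = assign_,
                   eval_trials = eval_trials)
}

#' Partition model fits by item type
#'
#' Splits each fit's objective into the contributions of exception and
#' non-exception items. For aggregated (`sse_segment`) fits the SSE is a sum
#' over stimuli and partitions exactly: exception SSE + non-exception SSE =
#' total. For trial-level (`mse_trials`) fits the split is the MSE over each
#' item type's trials within each segment; the trial-count-weighted mean of
#' the parts reconstructs the segment MSE.
#'
#' @param results A list of `fit_result`s from [fit_condition()].
#' @param cohort The `cohort` the fits were computed on.
#' @param condition `"control"` or `"experimental"`.
#' @param n_segments Number of segments (default: the cohort protocol's).
#' @return Data frame with `participant`, `condition`, `family`, `segment`,
#'   `item_type` (`"exception"`, `"non_exception"`, `"total"`), `value`, and
#'   `n` (stimuli summed over for SSE, trials for MSE).
#' @export
partition_fit_by_item_type <- function(results, cohort, condition,
                                       n_segments = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(n_segments)) n_segments <- cohort$protocol$n_segments
  structure_ <- cohort$structure
  seqs <- cohort$sequences[[condition]]
  resp <- cohort$responses[cohort$responses$condition == condition, ]
  scheme <- condition_scheme(condition)

  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  for (fr in results) {
    pid <- fr$participant
    sq <- seqs[[pid]]
    assign_ <- assign_segments(sq, scheme, n_segments)
    seg <- assign_$segment_of_trial
    r <- resp[resp$participant == pid, ]
    r <- r[order(r$trial), ]
    ra <- response_a_indicator(r$response)
    itype <- item_type_of(structure_, sq$stimulus_id)

    if (fr$objective == "sse_segment") {
      trials <- which(seg == fr$segment)
      tr <- fitted_trace(fr, sq, structure_, assign_, trials)
      sid <- sq$stimulus_id[trials]
      terms <- (tapply(tr, sid, mean) - tapply(ra[trials], sid, mean))^2
      exc_ids <- structure_$stimuli$id[structure_$stimuli$role == "exception"]
      is_exc <- as.integer(names(terms)) %in% exc_ids
      add_row(participant = pid, condition = condition, family = fr$family,
              segment = fr$segment, item_type = "exception",
              value = sum(terms[is_exc]), n = sum(is_exc))
      add_row(participant = pid, condition = condition, family = fr$family,
              segment = fr$segment, item_type = "non_exception",
              value = sum(terms[!is_exc]), n = sum(!is_exc))
      add_row(participant = pid, condition = condition, family = fr$family,
              segment = fr$segment, item_type = "total",
              value = sum(terms), n = length(terms))
    } else {
      tr <- fitted_trace(fr, sq, structure_, assign_)
      sq_err <- (tr - ra)^2
      for (s in seq_len(n_segments)) {
        for (lab in c("exception", "non_exception", "total")) {
          sel <- seg == s & (lab == "total" | itype == lab)
          if (!any(sel)) next
          add_row(participant = pid, condition = condition, family = fr$family,
                  segment = s, item_type = lab,
                  value = mean(sq_err[sel]), n = sum(sel))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-segment fit curves from a set of fit results
#'
#' For per-segment (`sse_segment`) fits, each result already carries its
#' segment's objective value. For whole-experiment (`mse_trials`) fits, the
#' fitted model's trace is re-evaluated and the MSE computed within each
#' segment of the condition-appropriate scheme (the plotting convention for
#' the experimental condition).
#'
#' @inheritParams partition_fit_by_item_type
#' @return Data frame with `condition`, `family`, `segment`, `mean_value`,
#'   `sem`, `n_participants`.
#' @export
fit_curves_by_segment <- function(results, cohort, condition,
                                  n_segments = NULL) {
  if (is.null(n_segments)) n_segments <- cohort$protocol$n_segments
  seqs <- cohort$sequences[[condition]]
  resp <- cohort$responses[cohort$responses$condition == condition, ]
  scheme <- condition_scheme(condition)

  vals <- list()  # vals[[family]][[segment]] -> per-participant values
  for (fr in results) {
    pid <- fr$participant
    if (fr$objective == "sse_segment") {
      key <- paste(fr$family, fr$segment)
      vals[[key]] <- c(vals[[key]], fr$objective_value)
    } else {
      sq <- seqs[[pid]]
      assign_ <- assign_segments(sq, scheme, n_segments)
      seg <- assign_$segment_of_trial
      r <- resp[resp$participant == pid, ]
      r <- r[order(r$trial), ]
      ra <- response_a_indicator(r$response)
      tr <- fitted_trace(fr, sq, cohort$structure, assign_)
      for (s in seq_len(n_segments)) {
        key <- paste(fr$family, s)
        vals[[key]] <- c(vals[[key]], mean((tr[seg == s] - ra[seg == s])^2))
      }
    }
  }
  fams <- unique(vapply(results, `[[`, "", "family"))
  out <- list()
  for (fam in fams) for (s in seq_len(n_segments)) {
    v <- vals[[paste(fam, s)]]
    out[[length(out) + 1L]] <- data.frame(
      condition = condition, family = fam, segment = s,
      mean_value = mean(v), sem = if (length(v) > 1L) sem(v) else NA_real_,
      n_participants = length(v))
  }
  do.call(rbind, out)
}

trend_stats <- function(curves, condition) {
  wide <- split(curves, curves$family)
  gap <- wide$prototype$mean_value - wide$exemplar$mean_value
  segs <- wide$prototype$segment
  data.frame(condition = condition,
             gap_first = gap[which.min(segs)], gap_last = gap[which.max(segs)],
             gap_change = gap[which.max(segs)] - gap[which.min(segs)],
             spearman_rho = suppressWarnings(
               stats::cor(segs, gap, method = "spearman")))
}

#' Model-recovery experiment
#'
#' Simulates a cohort from the generating protocol (by default the
#' exemplar-forgetting demonstration protocol), fits the base prototype and
#' exemplar models under the per-condition policy (control: per-sequential-
#' segment aggregated SSE; experimental: whole-experiment trial-level MSE,
#' plotted per power-law segment), and summarises the per-segment fit curves
#' and the prototype-minus-exemplar fit gap trends.
#'
#' The qualitative flags are computed from first-versus-last-segment gap
#' differences (positive gap = exemplar advantage): `control_advantage_grows`
#' is `TRUE` when the exemplar advantage is larger in the last control
#' segment than the first; `experimental_advantage_shrinks` when it is
#' larger in the first experimental segment than the last.
#'
#' @param protocol A [simulation_protocol()].
#' @param structure A `category_structure` (default: the standard 14-stimulus
#'   structure).
#' @param spec Optional [fit_spec()] carried into all fits.
#' @return A list of class `recovery_report`: `cohort`, `fit_curves`,
#'   `accuracy`, `trends`, `flags`, `fits`.
#' @export
model_recovery <- function(protocol = simulation_protocol(),
                           structure = make_rule_plus_exception(),
                           spec = NULL) {
  cohort <- simulate_cohort(protocol, structure)
  curves <- list(); fits <- list(); trends <- list(); acc <- list()
  for (cond in protocol$conditions) {
    objective <- if (cond == "control") "sse_segment" else "mse_trials"
    cond_curves <- list()
    for (fam in c("prototype", "exemplar")) {
      fr <- fit_condition(cohort, cond, fam, objective, spec = spec,
                          n_segments = protocol$n_segments)
      fits[[paste(cond, fam)]] <- fr
      cond_curves[[fam]] <- fit_curves_by_segment(fr, cohort, cond,
                                                  protocol$n_segments)
    }
    cc <- do.call(rbind, cond_curves)
    curves[[cond]] <- cc
    trends[[cond]] <- trend_stats(cc, cond)
    acc[[cond]] <- accuracy_by_segment(cohort, cond,
                                       n_segments = protocol$n_segments)
  }
  trends <- do.call(rbind, trends)
  flags <- list(
    control_advantage_grows =
      "control" %in% trends$condition &&
      trends$gap_change[trends$condition == "control"] > 0,
    experimental_advantage_shrinks =
      "experimental" %in% trends$condition &&
      trends$gap_change[trends$condition == "experimental"] < 0)
  structure(list(cohort = cohort, fit_curves = do.call(rbind, curves),
                 accuracy = do.call(rbind, acc), trends = trends,
                 flags = flags, fits = fits),
            class = "recovery_report")
}

#' Restrict data to trials after full stimulus coverage
#'
#' Drops every trial up to and including the first trial at which all
#' stimuli of the sequence have appeared at least once, keeping only trials
#' on which the exemplar store already contains every stimulus. For the
#' default experimental design (introductions every 35 trials) the retained
#' trials start at trial 457; for a control permutation-block sequence they
#' start at trial 15.
#'
#' @param seq The [trial_sequence] the data are aligned to.
#' @param data A data frame with a `trial` column (responses, traces, ...).
#' @return The rows of `data` whose trials come after full coverage.
#' @export
post_introduction_filter <- function(seq, data) {
  stopifnot(inherits(seq, "trial_sequence"))
  first_seen <- seq$trial[seq$presentation_index == 1L]
  t_complete <- max(first_seen)
  data[data$trial > t_complete, , drop = FALSE]
}

#' Compare the exemplar-forgetting and mixture models on a cohort
#'
#' Fits both families to each participant of one condition under a shared
#' objective and the nested-start policy (the forgetting optimum's weights
#' seed a mixture start at `alpha = 0`), and returns per-segment fit curves
#' for both families together with the fitted mixture-weight trajectory
#' (`alpha` per segment). When a participant's fitted prototype and exemplar
#' component predictions are numerically indistinguishable, `alpha` is
#' unidentifiable and the participant is flagged.
#'
#' @param cohort A `cohort`.
#' @param condition `"control"` or `"experimental"`.
#' @param objective Fit statistic for both families (default `"mse_trials"`).
#' @param spec Optional [fit_spec()].
#' @return A list of class `mixture_comparison`: `fit_curves` (both
#'   families), `alpha_trajectory` (mean fitted `alpha` per segment),
#'   `unidentifiable` (named logical per participant), `fits`.
#' @export
compare_forgetting_vs_mixture <- function(cohort, condition,
                                          objective = "mse_trials",
                                          spec = NULL) {
  if (is.null(spec)) spec <- fit_spec()
  n_segments <- cohort$protocol$n_segments
  spec_mix <- spec
  spec_mix$alpha_by_segment <- TRUE

  fr_forget <- fit_condition(cohort, condition, "exemplar_forgetting",
                             objective, spec = spec, n_segments = n_segments)
  # nested starts: seed the mixture from each participant's forgetting optimum
  extra <- lapply(fr_forget, function(fr)
    model_params("mixture", fr$params$w, c_proto = fr$params$c,
                 c_exem = fr$params$c, alpha = 0))
  names(extra) <- vapply(fr_forget, `[[`, "", "participant")
  fr_mix <- fit_condition(cohort, condition, "mixture", objective,
                          spec = spec_mix, n_segments = n_segments,
                          extra_starts_by_participant = lapply(extra, list))

  curves <- rbind(
    fit_curves_by_segment(fr_forget, cohort, condition, n_segments),
    fit_curves_by_segment(fr_mix, cohort, condition, n_segments))

  alpha_mat <- do.call(rbind, lapply(fr_mix, function(fr)
    rep_len(fr$params$alpha, n_segments)))
  alpha_traj <- data.frame(condition = condition, segment = seq_len(n_segments),
                           mean_alpha = colMeans(alpha_mat),
                           sem = apply(alpha_mat, 2L, sem))

  unident <- vapply(fr_mix, function(fr) {
    pid <- fr$participant
    sq <- cohort$sequences[[condition]][[pid]]
    assign_ <- assign_segments(sq, condition_scheme(condition), n_segments)
    pp <- predict_sequence(model_params("prototype", fr$params$w,
                                        c = fr$params$c_proto),
                           sq, cohort$structure, assign_)
    pe <- predict_sequence(model_params("exemplar", fr$params$w,
                                        c = fr$params$c_exem),
                           sq, cohort$structure, assign_)
    max(abs(pp - pe)) < 1e-8
  }, TRUE)
  names(unident) <- vapply(fr_mix, `[[`, "", "participant")

  structure(list(fit_curves = curves, alpha_trajectory = alpha_traj,
                 unidentifiable = unident,
                 fits = list(exemplar_forgetting = fr_forget, mixture = fr_mix)),
            class = "mixture_comparison")
}
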