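#' Fit specifications
#'
#' Bundles the choices that define a model fit: the objective (aggregated
#' per-stimulus sum-squared error within a segment, or trial-level mean
#' squared error), the fitting scope, parameter bounds, and the multi-start
#' policy of the constrained optimizer.
#'
#' @param objective `"sse_segment"` (per-stimulus response proportions within
#'   a segment) or `"mse_trials"` (per-trial squared error).
#' @param scope `"per_sequential_segment"` or `"whole_experiment"`.
#' @param n_restarts Number of optimizer starts (first start is a fixed
#'   equal-weight start, the rest are seeded random draws; any
#'   `extra_starts` passed to [fit()] are appended).
#' @param seed Seed for the random starts.
#' @param c_max,beta_max Upper bounds for sensitivity and decay rate.
#' @param beta_fixed If non-`NULL`, the forgetting rate is held at this value
#'   rather than estimated.
#' @param alpha_by_segment For the mixture family: estimate one `alpha` per
#'   segment (requires a segment assignment in [fit()]) instead of a scalar.
#' @param maxit Iteration cap per optimizer start.
#' @return A list of class `fit_spec`.
#' @export
fit_spec <- function(objective = c("sse_segment", "mse_trials"),
                     scope = c("whole_experiment", "per_sequential_segment"),
                     n_restarts = 10L, seed = 1L, c_max = 30, beta_max = 5,
                     beta_fixed = NULL, alpha_by_segment = FALSE,
                     maxit = 100L) {
  structure(list(objective = match.arg(objective), scope = match.arg(scope),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 c_max = c_max, beta_max = beta_max, beta_fixed = beta_fixed,
                 alpha_by_segment = isTRUE(alpha_by_segment),
                 maxit = as.integer(maxit)),
            class = "fit_spec")
}

# normalize responses to a 0/1 category-A indicator
response_a_indicator <- function(responses) {
  if (is.numeric(responses)) {
    if (any(!responses %in% c(0, 1))) stop("numeric responses must be 0/1")
    return(as.numeric(responses))
  }
  if (!all(responses %in% c("A", "B"))) stop("responses must be 'A'/'B' or 0/1")
  as.numeric(responses == "A")
}

#' Aggregated sum-squared-error objective
#'
#' For each stimulus appearing in the segment, the observed proportion of
#' category-A responses is compared with the model's predicted proportion
#' (the mean of its per-trial predictions for that stimulus within the
#' segment); the objective is the sum of squared differences. Stimuli absent
#' from the segment contribute no term.
#'
#' @param trace Per-trial `P(A)` predictions aligned with `stimulus_ids`.
#' @param responses Observed responses (`"A"`/`"B"` or 0/1 category-A
#'   indicators), aligned with `trace`.
#' @param stimulus_ids Stimulus shown on each trial.
#' @param segment_trials Indices (into `trace`) of the segment's trials
#'   (default: all).
#' @return The SSE, a non-negative scalar.
#' @export
sse_objective <- function(trace, responses, stimulus_ids,
                          segment_trials = seq_along(trace)) {
  if (length(segment_trials) == 0L) stop("empty segment")
  ra <- response_a_indicator(responses)[segment_trials]
  pr <- trace[segment_trials]
  sid <- stimulus_ids[segment_trials]
  obs <- tapply(ra, sid, mean)
  pred <- tapply(pr, sid, mean)
  sum((pred - obs)^2)
}

#' Trial-level mean-squared-error objective
#'
#' Mean of `(P(A) - R_A)^2` over the trial set, where `R_A` is 1 for a
#' category-A response and 0 otherwise.
#'
#' @param trace Per-trial `P(A)` predictions.
#' @param responses Observed responses (`"A"`/`"B"` or 0/1), aligned with
#'   `trace`.
#' @param trial_set Indices of the trials entering the mean (default: all).
#' @return The MSE, a non-negative scalar.
#' @export
mse_objective <- function(trace, responses, trial_set = seq_along(trace)) {
  if (length(trial_set) == 0L) stop("empty trial set")
  ra <- response_a_indicator(responses)[trial_set]
  mean((trace[trial_set] - ra)^2)
}

# ---- parameter vector <-> theta transform --------------------------------

# The simplex constraint on the attention weights is enforced by a softmax
# reparameterisation (M - 1 unconstrained logits, the last fixed at 0);
# scalar parameters get box bounds. The optimizer is bound-constrained
# quasi-Newton (L-BFGS-B) from multiple seeded starts.
softmax_w <- function(z) {
  e <- exp(c(z, 0) - max(z, 0))
  e / sum(e)
}
w_to_z <- function(w) {
  w <- pmax(w, 1e-8); log(w[-length(w)] / w[length(w)])
}

theta_layout <- function(family, M, spec, n_alpha = 1L) {
  zb <- 16
  nms <- paste0("z", seq_len(M - 1L))
  lower <- rep(-zb, M - 1L); upper <- rep(zb, M - 1L)
  add <- function(n, lo, hi) {
    nms <<- c(nms, n); lower <<- c(lower, lo); upper <<- c(upper, hi)
  }
  if (family %in% c("prototype", "exemplar", "exemplar_forgetting"))
    add("c", 0, spec$c_max)
  if (family == "exemplar_forgetting" && is.null(spec$beta_fixed))
    add("beta", 0, spec$beta_max)
  if (family == "mixture") {
    add("c_proto", 0, spec$c_max)
    add("c_exem", 0, spec$c_max)
    for (i in seq_len(n_alpha)) add(paste0("alpha", i), 0, 1)
  }
  list(names = nms, lower = lower, upper = upper, M = M, n_alpha = n_alpha)
}

theta_to_params <- function(theta, family, layout, spec) {
  names(theta) <- layout$names
  w <- softmax_w(theta[seq_len(layout$M - 1L)])
  switch(family,
    prototype = model_params("prototype", w, c = theta[["c"]]),
    exemplar = model_params("exemplar", w, c = theta[["c"]]),
    exemplar_forgetting = model_params("exemplar_forgetting", w,
      c = theta[["c"]],
      beta = if (is.null(spec$beta_fixed)) theta[["beta"]] else spec$beta_fixed),
    mixture = model_params("mixture", w,
      c_proto = theta[["c_proto"]], c_exem = theta[["c_exem"]],
      alpha = unname(theta[grep("^alpha", layout$names)])))
}

params_to_theta <- function(params, layout, spec) {
  z <- w_to_z(params$w)
  th <- switch(params$family,
    prototype = c(z, params$c),
    exemplar = c(z, params$c),
    exemplar_forgetting = c(z, params$c,
      if (is.null(spec$beta_fixed)) params$beta),
    mixture = c(z, params$c_proto, params$c_exem,
      rep_len(params$alpha, layout$n_alpha)))
  pmin(pmax(th, layout$lower), layout$upper)
}

random_theta <- function(layout) {
  w <- stats::rgamma(layout$M, 1); w <- w / sum(w)
  th <- w_to_z(w)
  sc <- setdiff(seq_along(layout$names), seq_len(layout$M - 1L))
  for (i in sc) {
    hi <- layout$upper[i]
    th <- c(th, stats::runif(1, 0, min(hi, if (layout$names[i] == "beta") 2 else 15)))
  }
  th
}

#' Fit a model to one participant's responses
#'
#' Minimises the chosen objective over the family's parameters under the
#' simplex constraint on attention weights and box bounds on the scalar
#' parameters, using a bound-constrained quasi-Newton optimizer (simplex via
#' softmax reparameterisation) from `n_restarts` seeded starts plus any
#' `extra_starts`. The best start is returned; results are deterministic
#' given the spec's seed. If every start fails the best evaluated point is
#' returned flagged as non-converged.
#'
#' @param model_family Model family to fit.
#' @param responses Observed responses over the whole sequence (`"A"`/`"B"`
#'   or 0/1 category-A indicators), one per trial.
#' @param seq A [trial_sequence].
#' @param structure The `category_structure`.
#' @param spec A [fit_spec()].
#' @param segment_assignment Optional `segment_assignment` (required for
#'   `sse_segment` with a `segment`, and for per-segment `alpha`).
#' @param segment If non-`NULL`, restrict the objective to this segment's
#'   trials (predictions still condition on the full presentation history).
#' @param extra_starts List of `model_params` used as additional optimizer
#'   starts (e.g. the optimum of a nested model).
#' @return A list of class `fit_result`: `params`, `objective_value`,
#'   `converged`, `restarts_used`, `family`, `objective`, `segment`.
#' @export
fit <- function(model_family, responses, seq, structure, spec = fit_spec(),
                segment_assignment = NULL, segment = NULL,
                extra_starts = list()) {
  T_ <- nrow(seq)
  ra <- response_a_indicator(responses)
  if (length(ra) != T_) stop("responses/sequence length mismatch")
  seg_of_trial <- if (!is.null(segment_assignment))
    segment_assignment$segment_of_trial
  trials <- if (is.null(segment)) seq_len(T_) else {
    if (is.null(seg_of_trial)) stop("segment requires a segment_assignment")
    which(seg_of_trial == segment)
  }
  if (length(trials) == 0L) stop("empty segment")

  n_alpha <- if (model_family == "mixture" && spec$alpha_by_segment) {
    if (is.null(segment_assignment)) stop("alpha_by_segment requires a segment_assignment")
    segment_assignment$n_segments
  } else 1L
  layout <- theta_layout(model_family, structure$n_features, spec, n_alpha)
  tracer <- make_trace_fn(model_family, seq, structure, seg_of_trial,
                          eval_trials = trials)
  sid <- seq$stimulus_id[trials]
  ra_t <- ra[trials]
  grp <- split(seq_along(sid), sid)        # trials of each stimulus, once
  obs_prop <- vapply(grp, function(ix) mean(ra_t[ix]), 0)
  agg <- matrix(0, length(grp), length(sid))   # group-mean aggregation
  for (g in seq_along(grp)) agg[g, grp[[g]]] <- 1 / length(grp[[g]])

  # hot path: parameters are read straight from theta (validation happens
  # once, in the returned fit_result)
  nz <- layout$M - 1L
  i_c <- which(layout$names == "c")
  i_beta <- which(layout$names == "beta")
  i_cp <- which(layout$names == "c_proto")
  i_ce <- which(layout$names == "c_exem")
  i_alpha <- grep("^alpha", layout$names)
  objective_at <- function(theta) {
    w <- softmax_w(theta[seq_len(nz)])
    tr <- switch(model_family,
      prototype = tracer(w, theta[i_c]),
      exemplar = tracer(w, theta[i_c]),
      exemplar_forgetting = tracer(w, theta[i_c],
        if (length(i_beta)) theta[i_beta] else spec$beta_fixed),
      mixture = tracer(w, c_proto = theta[i_cp], c_exem = theta[i_ce],
                       alpha = theta[i_alpha]))
    if (spec$objective == "sse_segment") {
      sum((agg %*% tr - obs_prop)^2)
    } else {
      mean((tr - ra_t)^2)
    }
  }

  starts <- with_seed(spec$seed, {
    s <- list(rep(0, length(layout$names)))   # equal weights, scalars at 0
    s[[1]][layout$names == "c"] <- 5
    s[[1]][layout$names %in% c("c_proto", "c_exem")] <- 5
    s[[1]][layout$names == "beta"] <- 0.5
    s[[1]][grep("^alpha", layout$names)] <- 0.5
    if (spec$n_restarts > 1L)
      s <- c(s, lapply(seq_len(spec$n_restarts - 1L), function(i) random_theta(layout)))
    s
  })
  for (ps in extra_starts)
    starts <- c(starts, list(params_to_theta(ps, layout, spec)))

  best <- NULL; best_val <- Inf; any_conv <- FALSE
  for (th0 in starts) {
    res <- tryCatch(
      stats::optim(th0, objective_at, method = "L-BFGS-B",
                   lower = layout$lower, upper = layout$upper,
                   control = list(maxit = spec$maxit, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) {
      v <- tryCatch(objective_at(th0), error = function(e) Inf)
      if (v < best_val) { best_val <- v; best <- th0 }
    } else {
      if (res$convergence == 0) any_conv <- TRUE
      if (res$value < best_val) { best_val <- res$value; best <- res$par }
    }
  }
  structure(list(params = theta_to_params(best, model_family, layout, spec),
                 objective_value = best_val, converged = any_conv,
                 restarts_used = length(starts), family = model_family,
                 objective = spec$objective, segment = segment),
            class = "fit_result")
}

#' Fit a cohort under the per-condition fitting policy
#'
#' Control-condition fits with the aggregated objective (`sse_segment`) are
#' performed per participant and per sequential segment (one result each);
#' control fits with the trial-level objective and all experimental-condition
#' fits are performed per participant over all trials simultaneously. For the
#' mixture family in the experimental condition, `alpha` varies across
#' power-law segments (one entry per segment) while all other parameters are
#' shared.
#'
#' @param cohort A cohort from [simulate_cohort()], or any list with elements
#'   `responses` (data frame with `participant`, `condition`, `trial`,
#'   `response`), `sequences` (per-condition list of per-participant
#'   [trial_sequence]s) and `structure`.
#' @param condition `"control"` or `"experimental"`.
#' @param model_family Family to fit.
#' @param objective `"sse_segment"` or `"mse_trials"`.
#' @param spec Optional [fit_spec()]; its objective/scope fields are
#'   overridden by the policy above.
#' @param n_segments Number of analysis segments (default 11).
#' @param extra_starts_by_participant Optional named list (by participant) of
#'   lists of `model_params` used as additional optimizer starts — e.g. each
#'   participant's optimum under a nested model.
#' @return A list of `fit_result`s, one per participant (x segment for
#'   per-segment fits), each annotated with `participant` and `condition`.
#' @export
fit_condition <- function(cohort, condition, model_family,
                          objective = c("sse_segment", "mse_trials"),
                          spec = NULL, n_segments = 11L,
                          extra_starts_by_participant = NULL) {
  objective <- match.arg(objective)
  if (!condition %in% c("control", "experimental")) stop("unknown condition")
  seqs <- cohort$sequences[[condition]]
  if (is.null(seqs)) return(list())
  structure_ <- cohort$structure
  resp <- cohort$responses[cohort$responses$condition == condition, ]
  per_segment <- condition == "control" && objective == "sse_segment"
  scheme <- if (condition == "control") "sequential" else "power_law"

  if (is.null(spec)) spec <- fit_spec()
  spec$objective <- objective
  spec$scope <- if (per_segment) "per_sequential_segment" else "whole_experiment"
  if (model_family == "mixture" && condition == "experimental")
    spec$alpha_by_segment <- TRUE

  out <- list()
  for (pid in names(seqs)) {
    sq <- seqs[[pid]]
    assign_ <- assign_segments(sq, scheme, n_segments)
    r <- resp[resp$participant == pid, ]
    r <- r[order(r$trial), ]
    if (nrow(r) != nrow(sq)) stop("responses do not cover the sequence for participant ", pid)
    pspec <- spec
    pspec$seed <- child_seed(spec$seed, match(pid, names(seqs)))
    starts_p <- if (!is.null(extra_starts_by_participant))
      extra_starts_by_participant[[pid]] else list()
    if (is.null(starts_p)) starts_p <- list()
    if (per_segment) {
      for (s in seq_len(n_segments)) {
        fr <- fit(model_family, r$response, sq, structure_, pspec,
                  segment_assignment = assign_, segment = s,
                  extra_starts = starts_p)
        fr$participant <- pid; fr$condition <- condition
        out[[length(out) + 1L]] <- fr
      }
    } else {
      fr <- fit(model_family, r$response, sq, structure_, pspec,
                segment_assignment = assign_, extra_starts = starts_p)
      fr$participant <- pid; fr$condition <- condition
      out[[length(out) + 1L]] <- fr
    }
  }
  out
}

#' Flatten fit results to a table
#'
#' @param results A list of `fit_result`s (e.g. from [fit_condition()]).
#' @return A data frame with one row per result: `participant`, `condition`,
#'   `segment`, `family`, `objective`, `value`, `converged`, and flattened
#'   parameters (`w1..wM`, `c`, `beta`, `c_proto`, `c_exem`,
#'   `alpha1..alphaS` as applicable).
#' @export
fit_results_table <- function(results) {
  rows <- lapply(results, function(fr) {
    p <- fr$params
    row <- data.frame(
      participant = if (is.null(fr$participant)) NA_character_ else fr$participant,
      condition = if (is.null(fr$condition)) NA_character_ else fr$condition,
      segment = if (is.null(fr$segment)) NA_integer_ else fr$segment,
      family = fr$family, objective = fr$objective,
      value = fr$objective_value, converged = fr$converged)
    for (i in seq_along(p$w)) row[[paste0("w", i)]] <- p$w[i]
    for (nm in c("c", "beta", "c_proto", "c_exem"))
      if (!is.null(p[[nm]])) row[[nm]] <- p[[nm]]
    if (!is.null(p$alpha))
      for (i in seq_along(p$alpha)) row[[paste0("alpha", i)]] <- p$alpha[i]
    row
  })
  do.call(rbind, lapply(rows, function(r) {
    all_cols <- unique(unlist(lapply(rows, names)))
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  }))
}
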