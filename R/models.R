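#' Model parameter sets
#'
#' Constructs a validated parameter set for one of the four model families.
#' All families share an attention-weight simplex `w` over the feature
#' dimensions (`w_m >= 0`, `sum(w) = 1`). The prototype and exemplar models
#' add a sensitivity `c >= 0`; the exemplar-forgetting model adds a memory
#' decay rate `beta >= 0`; the mixture model has two sensitivities (`c_proto`,
#' `c_exem`) and a mixing weight `alpha` in `[0, 1]` (scalar, or one value
#' per analysis segment).
#'
#' With `M` feature dimensions the free-parameter counts are `M - 1 + 1`
#' for the prototype and exemplar models (the simplex removes one weight),
#' one more for forgetting (`beta`), and `M - 1 + 3` for the mixture with a
#' scalar `alpha` — 6, 7 and 8 for the default `M = 6`.
#'
#' @param family One of `"prototype"`, `"exemplar"`, `"exemplar_forgetting"`,
#'   `"mixture"`.
#' @param w Attention weights (non-negative, summing to 1 within `1e-6`).
#' @param c Sensitivity (prototype/exemplar/forgetting). May be a vector with
#'   one value per segment; [predict_sequence()] then applies the segment's
#'   sensitivity to each trial.
#' @param beta Memory decay rate (forgetting only).
#' @param alpha Mixture weight on the prototype component (mixture only);
#'   scalar or per-segment vector.
#' @param c_proto,c_exem Component sensitivities (mixture only).
#' @return A list of class `model_params`.
#' @export
model_params <- function(family = c("prototype", "exemplar",
                                    "exemplar_forgetting", "mixture"),
                         w, c = NULL, beta = NULL, alpha = NULL,
                         c_proto = NULL, c_exem = NULL) {
  family <- match.arg(family)
  w <- as.numeric(w)
  if (any(!is.finite(w)) || any(w < -1e-9) || abs(sum(w) - 1) > 1e-6)
    stop("attention weights must be non-negative and sum to 1")
  w <- pmax(w, 0); w <- w / sum(w)
  chk_pos <- function(x, nm) {
    if (is.null(x)) stop(nm, " is required for family '", family, "'")
    if (any(!is.finite(x)) || any(x < 0)) stop(nm, " must be >= 0")
    as.numeric(x)
  }
  p <- list(family = family, w = w)
  if (family %in% c("prototype", "exemplar", "exemplar_forgetting"))
    p$c <- chk_pos(c, "c")
  if (family == "exemplar_forgetting")
    p$beta <- chk_pos(beta, "beta")
  if (family == "mixture") {
    p$c_proto <- chk_pos(c_proto, "c_proto")
    p$c_exem <- chk_pos(c_exem, "c_exem")
    if (is.null(alpha) || any(!is.finite(alpha)) || any(alpha < 0 | alpha > 1))
      stop("alpha must lie in [0, 1]")
    p$alpha <- as.numeric(alpha)
  }
  class(p) <- "model_params"
  p
}

#' Number of free parameters of a parameter set
#'
#' @param params A `model_params`.
#' @return Integer count: independent attention weights (`M - 1`) plus the
#'   family's scalar parameters (each per-segment vector parameter counts
#'   once per segment).
#' @export
n_free_parameters <- function(params) {
  stopifnot(inherits(params, "model_params"))
  n <- length(params$w) - 1L
  n <- n + switch(params$family,
    prototype = length(params$c),
    exemplar = length(params$c),
    exemplar_forgetting = length(params$c) + 1L,
    mixture = length(params$c_proto) + length(params$c_exem) + length(params$alpha))
  as.integer(n)
}

# weighted city-block distance between two binary feature vectors
weighted_dist <- function(f1, f2, w) sum(w * abs(f1 - f2))

#' Prototype-model classification probability
#'
#' Distance of the probe to each category prototype is the attention-weighted
#' city-block distance `d_iA = sum_m w_m |x_im - P_Am|`; similarity is
#' `exp(-c d)`; the category-A response probability is the similarity ratio
#' `s_A / (s_A + s_B)`.
#'
#' @param features Binary feature vector of the probe.
#' @param params `model_params` with `family = "prototype"` (scalar `c`).
#' @param prototypes 2 x M matrix of prototype feature vectors, rows A and B
#'   (e.g. `structure$prototypes`).
#' @return `P(A)`, a probability in `[0, 1]`.
#' @export
prototype_predict <- function(features, params, prototypes) {
  stopifnot(inherits(params, "model_params"), params$family == "prototype")
  if (length(features) != length(params$w)) stop("feature/weight dimension mismatch")
  dA <- weighted_dist(features, prototypes["A", ], params$w)
  dB <- weighted_dist(features, prototypes["B", ], params$w)
  sA <- exp(-params$c * dA); sB <- exp(-params$c * dB)
  sA / (sA + sB)
}

#' Exemplar stores
#'
#' A token store holds one entry per previously experienced trial: the
#' exemplar's feature vector, its feedback (true) category and the trial at
#' which it was stored.
#'
#' @param features Matrix of token feature vectors (one row per token); may
#'   have zero rows.
#' @param category Character vector of token categories (`"A"`/`"B"`).
#' @param stored_at_trial Integer vector of storage trials, non-decreasing
#'   (a sequence-built store has one token per past trial, hence strictly
#'   increasing; hand-built stores may share a storage trial).
#' @return A list of class `exemplar_store`.
#' @export
exemplar_store <- function(features, category, stored_at_trial = seq_along(category)) {
  features <- if (is.null(dim(features))) matrix(features, nrow = length(category),
                                                 byrow = TRUE) else as.matrix(features)
  if (nrow(features) != length(category) || length(category) != length(stored_at_trial))
    stop("token fields must have equal length")
  if (length(stored_at_trial) > 1L && any(diff(stored_at_trial) < 0))
    stop("stored_at_trial must be non-decreasing")
  structure(list(features = features, category = as.character(category),
                 stored_at_trial = as.integer(stored_at_trial)),
            class = "exemplar_store")
}

#' Exemplar-model classification probability
#'
#' The probe is compared to every stored token: pairwise attention-weighted
#' distances, exponential-decay similarities `exp(-c d)`, and a summed-
#' similarity ratio over the two categories. An empty store (or a store whose
#' total similarity is zero) yields 0.5; if one category is absent its sum is
#' simply 0.
#'
#' @param features Binary feature vector of the probe.
#' @param params `model_params` with `family = "exemplar"` (scalar `c`).
#' @param store An [exemplar_store].
#' @return `P(A)`.
#' @export
exemplar_predict <- function(features, params, store) {
  stopifnot(inherits(params, "model_params"), params$family == "exemplar")
  summed_similarity_ratio(features, params$w, params$c, store, weights = NULL)
}

summed_similarity_ratio <- function(features, w, c, store, weights = NULL) {
  stopifnot(inherits(store, "exemplar_store"))
  n <- nrow(store$features)
  if (n == 0L) return(0.5)
  if (ncol(store$features) != length(features)) stop("feature dimension mismatch")
  d <- as.vector(abs(store$features - matrix(features, n, length(features),
                                             byrow = TRUE)) %*% w)
  s <- exp(-c * d)
  if (!is.null(weights)) s <- s * weights
  sA <- sum(s[store$category == "A"]); sB <- sum(s[store$category == "B"])
  if (sA + sB == 0) return(0.5)
  sA / (sA + sB)
}

#' Power-law memory strength
#'
#' The strength of a stored exemplar after a delay of `j` trials is
#' `M_j = j^(-beta)`: 1 at delay 1, strictly decreasing in delay for
#' `beta > 0`, and identically 1 when `beta = 0` (no forgetting).
#'
#' @param delay Integer delay(s) in trials, `>= 1`.
#' @param beta Decay rate, `>= 0`.
#' @return Memory strength(s) in `(0, 1]`.
#' @export
memory_strength <- function(delay, beta) {
  if (any(delay < 1)) stop("delay must be >= 1")
  if (beta < 0) stop("beta must be >= 0")
  delay^(-beta)
}

#' Exemplar-forgetting classification probability
#'
#' As [exemplar_predict()], but each token's similarity is multiplied by its
#' power-law memory strength `(current_trial - stored_at_trial)^(-beta)`
#' before summation. With `beta = 0` this reduces exactly to the base
#' exemplar model.
#'
#' @param features Binary feature vector of the probe.
#' @param params `model_params` with `family = "exemplar_forgetting"`.
#' @param store An [exemplar_store]; every token must predate `current_trial`.
#' @param current_trial The trial index at which the probe is classified.
#' @return `P(A)`.
#' @export
forgetting_predict <- function(features, params, store, current_trial) {
  stopifnot(inherits(params, "model_params"),
            params$family == "exemplar_forgetting")
  if (nrow(store$features) > 0L && any(store$stored_at_trial >= current_trial))
    stop("all tokens must be stored strictly before current_trial")
  m <- if (nrow(store$features) > 0L)
    memory_strength(current_trial - store$stored_at_trial, params$beta) else NULL
  summed_similarity_ratio(features, params$w, params$c, store, weights = m)
}

#' Prototype-exemplar mixture classification probability
#'
#' A weighted combination `alpha * P_prototype + (1 - alpha) * P_exemplar`
#' with a shared attention-weight simplex and separate sensitivities for the
#' two components. `alpha` may be a per-segment vector, indexed by
#' `current_segment`.
#'
#' @param features Binary feature vector of the probe.
#' @param params `model_params` with `family = "mixture"`.
#' @param store An [exemplar_store] for the exemplar component.
#' @param prototypes 2 x M prototype matrix for the prototype component.
#' @param current_segment Segment index selecting the entry of a vector
#'   `alpha` (ignored for scalar `alpha`).
#' @return `P(A)`.
#' @export
mixture_predict <- function(features, params, store, prototypes,
                            current_segment = 1L) {
  stopifnot(inherits(params, "model_params"), params$family == "mixture")
  a <- if (length(params$alpha) == 1L) params$alpha else {
    if (current_segment < 1L || current_segment > length(params$alpha))
      stop("current_segment outside the alpha vector")
    params$alpha[current_segment]
  }
  pp <- prototype_predict(features,
                          model_params("prototype", params$w, c = params$c_proto),
                          prototypes)
  pe <- summed_similarity_ratio(features, params$w, params$c_exem, store)
  a * pp + (1 - a) * pe
}

# ---- sequence-level prediction -------------------------------------------

# Precompute everything that does not depend on parameters and return a
# closure trace(w, c, beta, alpha, c_proto, c_exem) -> P(A) at eval_trials.
# c / alpha may be scalars or per-segment vectors (segment_of_trial required
# for vectors). Token labels are the true (feedback) categories; the store at
# trial t holds exactly one token per trial 1..t-1.
make_trace_fn <- function(family, seq, structure, segment_of_trial = NULL,
                          eval_trials = NULL) {
  feats <- feature_matrix(structure)
  T_ <- nrow(seq)
  stim <- match(seq$stimulus_id, structure$stimuli$id)
  if (anyNA(stim)) stop("sequence refers to stimulus ids absent from the structure")
  is_a <- structure$stimuli$category[stim] == "A"
  if (is.null(eval_trials)) eval_trials <- seq_len(T_)
  eval_trials <- as.integer(eval_trials)

  ne <- length(eval_trials)
  st_eval <- stim[eval_trials]
  # resolve a scalar or per-segment parameter to one value per evaluated trial
  per_trial <- function(x, nm) {
    if (length(x) == 1L) return(rep.int(x, ne))
    if (is.null(segment_of_trial))
      stop("per-segment ", nm, " requires a segment assignment")
    if (max(segment_of_trial) > length(x))
      stop("segment index outside the ", nm, " vector")
    x[segment_of_trial[eval_trials]]
  }

  # per-dimension 0/1 mismatch columns: weighted distances are one %*% away
  K <- nrow(feats)
  M <- ncol(feats)
  fd <- vapply(seq_len(M), function(m)
    as.numeric(abs(outer(feats[, m], feats[, m], `-`))), numeric(K * K))
  pa <- abs(feats - matrix(structure$prototypes["A", ], K, M, byrow = TRUE))
  pb <- abs(feats - matrix(structure$prototypes["B", ], K, M, byrow = TRUE))

  proto_trace <- function(w, ct) {
    dA <- (pa %*% w)[st_eval]; dB <- (pb %*% w)[st_eval]
    sA <- exp(-ct * dA); sB <- exp(-ct * dB)
    sA / (sA + sB)
  }
  exem_trace <- function(w, ct, beta) {
    d14 <- matrix(fd %*% w, K, K)
    # similarity rows are only needed at evaluated trials
    sim <- exp(-ct * d14[st_eval, , drop = FALSE])
    mtab <- if (T_ > 1L) (seq_len(T_ - 1L))^(-beta) else numeric(0)
    exemplar_trace_cpp(stim, is_a, sim, mtab, eval_trials)
  }

  switch(family,
    prototype = function(w, c, ...) proto_trace(w, per_trial(c, "c")),
    exemplar = function(w, c, ...) exem_trace(w, per_trial(c, "c"), 0),
    exemplar_forgetting = function(w, c, beta, ...)
      exem_trace(w, per_trial(c, "c"), beta),
    mixture = function(w, c_proto, c_exem, alpha, ...) {
      a <- per_trial(alpha, "alpha")
      a * proto_trace(w, per_trial(c_proto, "c_proto")) +
        (1 - a) * exem_trace(w, per_trial(c_exem, "c_exem"), 0)
    },
    stop("unknown family: ", family))
}

#' Per-trial classification probabilities along a sequence
#'
#' Walks a trial sequence in order. Before trial `t` is predicted, the token
#' store contains exactly one token per trial `1..t-1`, labelled with the
#' feedback (true) category of the stimulus shown on that trial; the current
#' trial's stimulus is excluded from its own store. The prototype component
#' always uses the fixed true prototypes. On trial 1 the exemplar families
#' return 0.5 (empty store).
#'
#' Per-segment parameter vectors (`c`, or `alpha` for the mixture) are
#' resolved through `segment_assignment`: trial `t` uses the value of its
#' assigned segment.
#'
#' @param params A `model_params`.
#' @param seq A [trial_sequence].
#' @param structure The `category_structure` the sequence presents.
#' @param segment_assignment Optional `segment_assignment`; required when any
#'   parameter is a per-segment vector.
#' @param eval_trials Optional integer vector of trials to evaluate
#'   (default: all trials).
#' @return Numeric vector of `P(A)` values, one per evaluated trial.
#' @export
predict_sequence <- function(params, seq, structure, segment_assignment = NULL,
                             eval_trials = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(seq, "trial_sequence"))
  seg <- if (!is.null(segment_assignment)) segment_assignment$segment_of_trial
  fn <- make_trace_fn(params$family, seq, structure, seg, eval_trials)
  p <- switch(params$family,
    prototype = fn(params$w, params$c),
    exemplar = fn(params$w, params$c),
    exemplar_forgetting = fn(params$w, params$c, params$beta),
    mixture = fn(params$w, c_proto = params$c_proto, c_exem = params$c_exem,
                 alpha = params$alpha))
  as.numeric(p)
}

#' Export a prediction trace as CSV aligned with a sequence
#'
#' @param trace Numeric vector of `P(A)` values (one per trial of `seq`).
#' @param seq The [trial_sequence] the trace is aligned to.
#' @param path File path.
#' @param participant Participant label stored in the file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, seq, path, participant = 1L) {
  if (length(trace) != nrow(seq)) stop("trace/sequence length mismatch")
  df <- data.frame(participant = participant, condition = seq$condition,
                   trial = seq$trial, stimulus_id = seq$stimulus_id, p_A = trace)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
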