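# shared fixtures and independent oracles, built in code

default_structure <- function() make_rule_plus_exception(6, 1)

# build an annotated trial_sequence directly from a stimulus-id vector
sequence_from_ids <- function(ids, condition = "control") {
  recatmem:::new_trial_sequence(as.integer(ids), condition, NA_integer_,
                                length(unique(ids)))
}

# naive per-trial double-loop oracle for the exemplar families: rebuilds the
# store trial by trial and calls the scalar predictors
oracle_trace <- function(family, seq, structure, w, c_vec, beta = 0) {
  feats <- feature_matrix(structure)
  idx <- match(seq$stimulus_id, structure$stimuli$id)
  cats <- structure$stimuli$category[idx]
  T_ <- nrow(seq)
  if (length(c_vec) == 1L) c_vec <- rep(c_vec, T_)
  out <- numeric(T_)
  for (t in seq_len(T_)) {
    store <- if (t == 1L)
      exemplar_store(matrix(numeric(0), 0L, ncol(feats)), character(0), integer(0))
    else
      exemplar_store(feats[idx[seq_len(t - 1L)], , drop = FALSE],
                     cats[seq_len(t - 1L)], seq_len(t - 1L))
    out[t] <- if (family == "exemplar") {
      exemplar_predict(feats[idx[t], ],
                       model_params("exemplar", w, c = c_vec[t]), store)
    } else {
      forgetting_predict(feats[idx[t], ],
                         model_params("exemplar_forgetting", w, c = c_vec[t],
                                      beta = beta),
                         store, t)
    }
  }
  out
}

# random interior point of the weight simplex
random_simplex <- function(m) { w <- stats::rgamma(m, 1) + 0.05; w / sum(w) }
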