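#' Presentation schedules and recency diagnostics
#'
#' A trial sequence is a data frame (class `trial_sequence`) with one row per
#' trial: `condition` (`"control"` or `"experimental"`), `trial`,
#' `stimulus_id`, `presentation_index` (1-based count of that stimulus's
#' appearances so far, inclusive) and `delay` (trials since the stimulus's
#' previous appearance; `NA` on its first appearance). The generator seed is
#' kept as attribute `seed` and the stimulus count as `n_stimuli`.
#'
#' @name trial_sequence
NULL

# build the annotated data frame from a raw stimulus-id vector
new_trial_sequence <- function(stim, condition, seed, n_stimuli) {
  T_ <- length(stim)
  pres <- integer(T_)
  delay <- rep(NA_integer_, T_)
  m <- max(stim)                       # ids need not be contiguous
  last <- rep(NA_integer_, m)
  count <- integer(m)
  for (t in seq_len(T_)) {
    s <- stim[t]
    count[s] <- count[s] + 1L
    pres[t] <- count[s]
    if (!is.na(last[s])) delay[t] <- t - last[s]
    last[s] <- t
  }
  out <- data.frame(condition = condition, trial = seq_len(T_),
                    stimulus_id = stim, presentation_index = pres, delay = delay)
  attr(out, "seed") <- seed
  attr(out, "n_stimuli") <- n_stimuli
  class(out) <- c("trial_sequence", "data.frame")
  out
}

#' Uniform (permutation-block) presentation sequence
#'
#' Every consecutive block of `N` trials (`N` = number of stimuli) is an
#' independent random permutation of all stimuli, so each stimulus appears
#' exactly once per block and `n_blocks` times in total.
#'
#' @param structure A `category_structure`.
#' @param n_blocks Number of permutation blocks (default 44, giving
#'   44 x 14 = 616 trials for the default structure).
#' @param seed Integer RNG seed; regenerating with the same arguments is
#'   bit-identical.
#' @return A [trial_sequence] with `condition = "control"`.
#' @export
make_uniform_sequence <- function(structure, n_blocks = 44L, seed = 1L) {
  stopifnot(inherits(structure, "category_structure"))
  n_blocks <- as.integer(n_blocks)
  if (is.na(n_blocks) || n_blocks < 1L) stop("n_blocks must be >= 1")
  n <- nrow(structure$stimuli)
  stim <- with_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) sample.int(n)), use.names = FALSE)
  })
  new_trial_sequence(structure$stimuli$id[stim], "control", seed, n)
}

#' Power-law presentation sequence
#'
#' New stimuli are introduced one at a time every `intro_interval` trials (in
#' a randomized order). Each stimulus then re-appears on a power-law
#' schedule: its k-th inter-presentation gap grows as `k^decay_gamma`
#' (jittered log-normally and scaled to span the trials remaining after its
#' introduction), so re-presentations are initially frequent and become
#' rarer as the stimulus ages. Total presentations are near-equal across
#' stimuli (`total_trials / n_stimuli` each, earlier-introduced stimuli
#' absorbing any remainder), mirroring the uniform condition's exposure.
#' The per-stimulus schedules are interleaved greedily: every non-
#' introduction trial shows the already-introduced stimulus whose next
#' scheduled re-presentation is earliest.
#'
#' @param structure A `category_structure`.
#' @param total_trials Total number of trials (default 616).
#' @param intro_interval Trials between successive introductions (default 35;
#'   with 14 stimuli the last introduction falls on trial 456).
#' @param decay_gamma Growth exponent of the inter-presentation gaps
#'   (default 1): the gap before a stimulus's k-th presentation is
#'   proportional to `k^decay_gamma`, i.e. its presentation rate decays as a
#'   power law of its age. Larger values make late re-presentations rarer.
#' @param jitter_sd Standard deviation of the log-normal jitter applied to
#'   each scheduled gap (default 0.25); 0 gives deterministic per-stimulus
#'   spacing (introduction order remains randomized).
#' @param seed Integer RNG seed.
#' @return A [trial_sequence] with `condition = "experimental"`.
#' @export
make_powerlaw_sequence <- function(structure, total_trials = 616L,
                                   intro_interval = 35L, decay_gamma = 1,
                                   seed = 1L, jitter_sd = 0.25) {
  stopifnot(inherits(structure, "category_structure"))
  T_ <- as.integer(total_trials)
  iv <- as.integer(intro_interval)
  n <- nrow(structure$stimuli)
  if (is.na(T_) || T_ < 1L) stop("total_trials must be >= 1")
  if (is.na(iv) || iv < 1L || iv * n > T_)
    stop("intro_interval * n_stimuli must not exceed total_trials")
  if (!is.finite(decay_gamma) || decay_gamma <= 0) stop("decay_gamma must be > 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")

  stim <- with_seed(seed, {
    intro_order <- sample.int(n)          # intro_order[s]: stimulus introduced s-th
    intro_trial <- (seq_len(n) - 1L) * iv + 1L
    quota <- rep(T_ %/% n, n)             # presentations per stimulus,
    extra <- T_ %% n                      # earlier introductions absorb remainder
    if (extra > 0L) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L

    # per-stimulus target times of presentations 2..quota after introduction:
    # gaps ~ k^decay_gamma * lognormal jitter, scaled to the remaining span
    targets <- vector("list", n)          # indexed by introduction rank
    for (s in seq_len(n)) {
      q <- quota[s]
      if (q < 2L) { targets[[s]] <- numeric(0); next }
      k <- seq.int(2L, q)
      g <- k^decay_gamma
      if (jitter_sd > 0) g <- g * exp(stats::rnorm(length(g), 0, jitter_sd))
      span <- T_ - intro_trial[s]
      targets[[s]] <- intro_trial[s] + span * cumsum(g) / sum(g)
    }

    out <- integer(T_)
    next_event <- rep(1L, n)              # pointer into targets[[s]]
    next_intro <- 1L
    for (t in seq_len(T_)) {
      if (next_intro <= n && t == intro_trial[next_intro]) {
        s <- next_intro
        next_intro <- next_intro + 1L
      } else {
        avail <- which(seq_len(n) < next_intro &
                         next_event <= lengths(targets))
        if (length(avail) == 0L) stop("no re-presentation available at trial ", t)
        nxt <- vapply(avail, function(i) targets[[i]][next_event[i]], 0)
        s <- avail[which.min(nxt)]
        next_event[s] <- next_event[s] + 1L
      }
      out[t] <- intro_order[s]
    }
    out
  })
  new_trial_sequence(structure$stimuli$id[stim], "experimental", seed, n)
}

#' Assign trials to analysis segments
#'
#' Sequential segments are contiguous equal-length blocks (the final block
#' absorbs any remainder). Power-law segments group trials at similar points
#' along each stimulus's re-presentation curve: cut-points on
#' `presentation_index` are chosen by greedy balancing of the empirical
#' presentation-index histogram so per-segment trial counts are as equal as
#' possible, and the segment is non-decreasing in presentation index.
#'
#' @param seq A [trial_sequence].
#' @param scheme `"sequential"` or `"power_law"`.
#' @param n_segments Number of segments (default 11).
#' @return A list of class `segment_assignment`: `scheme`, `n_segments`, and
#'   `segment_of_trial` (integer vector, one entry per trial, values in
#'   `1..n_segments`).
#' @export
assign_segments <- function(seq, scheme = c("sequential", "power_law"),
                            n_segments = 11L) {
  scheme <- match.arg(scheme)
  S <- as.integer(n_segments)
  T_ <- nrow(seq)
  if (is.na(S) || S < 1L || S > T_) stop("n_segments must be in 1..n_trials")

  if (scheme == "sequential") {
    base <- T_ %/% S
    seg <- pmin(S, (seq$trial - 1L) %/% base + 1L)
  } else {
    target <- T_ / S
    pi_vals <- sort(unique(seq$presentation_index))
    counts <- tabulate(match(seq$presentation_index, pi_vals), length(pi_vals))
    cum_before <- cumsum(c(0, counts[-length(counts)]))
    seg_of_pi <- pmin(S, floor(cum_before / target) + 1L)
    seg <- seg_of_pi[match(seq$presentation_index, pi_vals)]
  }
  structure(list(scheme = scheme, n_segments = S,
                 segment_of_trial = as.integer(seg)),
            class = "segment_assignment")
}

#' Recency diagnostics of a presentation sequence
#'
#' Computes (1) the need-odds profile: for each recency lag `r`, the
#' empirical probability `p_stim` that the stimulus shown `r` trials ago is
#' shown again now, transformed to odds `p_stim / (1 - p_stim)`; (2) the
#' per-segment mean delay between repeated presentations (trials with no
#' defined delay, i.e. first appearances, are excluded); and (3) the
#' per-segment mean number of prior presentations of the tested stimulus.
#'
#' @param seq A [trial_sequence].
#' @param assignment A `segment_assignment` for `seq`.
#' @param max_recency Largest recency lag tabulated (default 30).
#' @return A list of class `recency_profile`: `need_odds` (data frame with
#'   `recency_bin`, `p_stim`, `need_odds`) and `by_segment` (data frame with
#'   `segment`, `n_trials`, `mean_delay`, `mean_prior_presentations`).
#' @export
recency_profile <- function(seq, assignment, max_recency = 30L) {
  stopifnot(inherits(seq, "trial_sequence"), inherits(assignment, "segment_assignment"))
  T_ <- nrow(seq)
  stim <- seq$stimulus_id
  lags <- seq_len(min(max_recency, T_ - 1L))
  p <- vapply(lags, function(r)
    mean(stim[(r + 1L):T_] == stim[seq_len(T_ - r)]), 0)
  need_odds <- data.frame(recency_bin = lags, p_stim = p,
                          need_odds = p / (1 - p))

  seg <- assignment$segment_of_trial
  if (length(seg) != T_) stop("assignment does not match sequence length")
  segs <- seq_len(assignment$n_segments)
  n_trials <- vapply(segs, function(s) sum(seg == s), 0L)
  if (any(n_trials == 0L)) stop("empty segment in assignment")
  mean_delay <- vapply(segs, function(s)
    mean(seq$delay[seg == s], na.rm = TRUE), 0)
  mean_prior <- vapply(segs, function(s)
    mean(seq$presentation_index[seg == s] - 1L), 0)
  by_segment <- data.frame(segment = segs, n_trials = n_trials,
                           mean_delay = mean_delay,
                           mean_prior_presentations = mean_prior)
  structure(list(need_odds = need_odds, by_segment = by_segment),
            class = "recency_profile")
}

#' Export / import trial sequences as CSV
#'
#' Schema: `participant`, `condition`, `trial`, `stimulus_id`,
#' `presentation_index`, `delay`, `segment_sequential`, `segment_powerlaw`.
#'
#' @param seq A [trial_sequence].
#' @param path File path.
#' @param participant Participant label stored in the file (default 1).
#' @param n_segments Number of segments used for both segment columns.
#' @return `write_sequence_csv` returns `path` invisibly;
#'   `read_sequence_csv` returns a [trial_sequence] (segment columns are
#'   dropped; recompute them with [assign_segments()]).
#' @export
write_sequence_csv <- function(seq, path, participant = 1L, n_segments = 11L) {
  stopifnot(inherits(seq, "trial_sequence"))
  df <- data.frame(participant = participant, condition = seq$condition,
                   trial = seq$trial, stimulus_id = seq$stimulus_id,
                   presentation_index = seq$presentation_index, delay = seq$delay,
                   segment_sequential =
                     assign_segments(seq, "sequential", n_segments)$segment_of_trial,
                   segment_powerlaw =
                     assign_segments(seq, "power_law", n_segments)$segment_of_trial)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @export
read_sequence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_trial_sequence(df$stimulus_id, df$condition[1L], NA_integer_,
                     length(unique(df$stimulus_id)))
}
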