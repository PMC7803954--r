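#' Specify the event-related speaker-identification design
#'
#' Describes one subject's scanning session: a fully crossed word-by-speaker
#' factor repeated in every run, self-paced responses inside a fixed answer
#' window, and truncated-exponential inter-stimulus intervals. Defaults match
#' a 4-run session of 36 trials per run (12 disyllabic words spoken by 3
#' speakers), a 5-s answer window, TR = 0.955 s and 366 volumes per run.
#'
#' @param n_runs number of functional runs.
#' @param words character vector of word labels; each word occurs once per
#'   speaker in every run.
#' @param speakers character vector of speaker labels (the classes decoded
#'   downstream).
#' @param isi_bounds numeric pair, lower/upper bound in seconds of the
#'   inter-stimulus interval.
#' @param isi_rate rate of the exponential law the ISIs are drawn from before
#'   truncation to `isi_bounds` (per second).
#' @param answer_window seconds allowed for the button press after stimulus
#'   offset.
#' @param tr repetition time in seconds.
#' @param n_volumes_per_run EPI volumes acquired per run; together with `tr`
#'   this fixes the run duration the trials must fit into.
#' @param max_consecutive_same_speaker longest permitted run of identical
#'   speakers in the trial sequence.
#' @param stimulus_duration word duration in seconds (boxcar length for the
#'   trial regressors).
#' @param initial_delay seconds of silence before the first onset.
#' @param seed integer seed making the design reproducible, or NULL.
#' @return An object of class `design_spec`.
#' @seealso [generate_design()], [generate_learning_design()]
#' @export
design_spec <- function(n_runs = 4L,
                        words = sprintf("word%02d", 1:12),
                        speakers = c("s1", "s2", "s3"),
                        isi_bounds = c(3, 5),
                        isi_rate = 1,
                        answer_window = 5,
                        tr = 0.955,
                        n_volumes_per_run = 366L,
                        max_consecutive_same_speaker = 2L,
                        stimulus_duration = 0.7,
                        initial_delay = 2,
                        seed = NULL) {
  vl_assert(is_count(n_runs) && n_runs >= 1, "n_runs must be a count >= 1")
  vl_assert(length(words) >= 1 && anyDuplicated(words) == 0,
            "words must be distinct labels")
  vl_assert(length(speakers) >= 1 && anyDuplicated(speakers) == 0,
            "speakers must be distinct labels")
  vl_assert(length(isi_bounds) == 2 && isi_bounds[1] < isi_bounds[2],
            "isi_bounds must satisfy lower < upper")
  vl_assert(isi_rate > 0, "isi_rate must be positive")
  vl_assert(answer_window > 0, "answer_window must be positive")
  vl_assert(tr > 0 && is_count(n_volumes_per_run),
            "tr must be positive and n_volumes_per_run a count")
  vl_assert(is_count(max_consecutive_same_speaker),
            "max_consecutive_same_speaker must be a count")
  vl_assert(stimulus_duration > 0, "stimulus_duration must be positive")
  structure(
    list(n_runs = as.integer(n_runs), words = as.character(words),
         speakers = as.character(speakers), isi_bounds = as.numeric(isi_bounds),
         isi_rate = isi_rate, answer_window = answer_window, tr = tr,
         n_volumes_per_run = as.integer(n_volumes_per_run),
         max_consecutive_same_speaker = as.integer(max_consecutive_same_speaker),
         stimulus_duration = stimulus_duration, initial_delay = initial_delay,
         seed = seed),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Speaker-identification design:",
      x$n_runs, "run(s) x", length(x$words) * length(x$speakers),
      "trials (", length(x$words), "words x", length(x$speakers),
      "speakers )\n")
  cat("  ISI ~ Exp(", x$isi_rate, ") truncated to [",
      x$isi_bounds[1], ",", x$isi_bounds[2], "] s; answer window",
      x$answer_window, "s\n")
  cat("  TR", x$tr, "s;", x$n_volumes_per_run, "volumes/run\n")
  invisible(x)
}

# Inverse-CDF sampling from Exp(rate) truncated to [lo, hi].
rtrunc_exp <- function(n, rate, lo, hi) {
  p_lo <- stats::pexp(lo, rate)
  p_hi <- stats::pexp(hi, rate)
  stats::qexp(p_lo + stats::runif(n) * (p_hi - p_lo), rate)
}

longest_run <- function(x) max(rle(as.character(x))$lengths)

# Pseudo-random speaker order with bounded repetition, by rejection sampling.
sample_speaker_sequence <- function(speakers, n_per_speaker, max_consec,
                                    max_attempts = 10000L) {
  slots <- rep(speakers, each = n_per_speaker)
  n_other <- length(slots) - n_per_speaker
  if (max_consec < 1 ||
      n_per_speaker > max_consec * (n_other + 1)) {
    vl_error("speaker-order constraint is infeasible for this design",
             "voicelight_constraint_error")
  }
  for (a in seq_len(max_attempts)) {
    seq_try <- sample(slots)
    if (longest_run(seq_try) <= max_consec) return(seq_try)
  }
  vl_error("could not satisfy speaker-order constraint after max_attempts",
           "voicelight_constraint_error")
}

new_event_table <- function(df, spec) {
  structure(df,
            class = c("event_table", "data.frame"),
            answer_window = spec$answer_window,
            speakers = spec$speakers,
            words = spec$words,
            tr = spec$tr,
            n_volumes_per_run = spec$n_volumes_per_run)
}

#' Generate a scanning-session event table
#'
#' Emits one trial per (word, speaker) pair per run, in pseudo-random order
#' with at most `max_consecutive_same_speaker` repetitions of a speaker in a
#' row. Consecutive onsets are separated by the stimulus duration, the full
#' answer window, and an ISI drawn from a truncated exponential law, so every
#' trial (including its response window) fits inside the acquired volumes.
#'
#' @param spec a [design_spec()].
#' @param seed overrides `spec$seed` when non-NULL.
#' @return An `event_table` data frame with columns `run`, `trial`, `onset`,
#'   `duration`, `speaker`, `word` (onsets in seconds from run start).
#' @export
generate_design <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  seed <- if (is.null(seed)) spec$seed else seed
  with_seed(seed, {
    n_w <- length(spec$words)
    runs <- lapply(seq_len(spec$n_runs), function(r) {
      spk <- sample_speaker_sequence(spec$speakers, n_w,
                                     spec$max_consecutive_same_speaker)
      wrd <- character(length(spk))
      for (s in spec$speakers) {
        wrd[spk == s] <- sample(spec$words, n_w)
      }
      n_tr <- length(spk)
      isi <- rtrunc_exp(n_tr - 1L, spec$isi_rate,
                        spec$isi_bounds[1], spec$isi_bounds[2])
      gaps <- spec$stimulus_duration + spec$answer_window + isi
      onset <- spec$initial_delay + c(0, cumsum(gaps))
      run_len <- spec$n_volumes_per_run * spec$tr
      if (onset[n_tr] + spec$stimulus_duration + spec$answer_window > run_len) {
        vl_error("trials do not fit within the run duration",
                 "voicelight_design_error")
      }
      data.frame(run = r, trial = seq_len(n_tr), onset = onset,
                 duration = spec$stimulus_duration,
                 speaker = spk, word = wrd, stringsAsFactors = FALSE)
    })
    new_event_table(do.call(rbind, runs), spec)
  })
}

#' Generate a learning-phase event table
#'
#' The familiarization design before scanning: `n_sessions` blocks, each a
#' full word-by-speaker crossing under the same ordering constraint as the
#' scanning runs (two sessions of 12 words x 3 speakers give the standard 72
#' identification trials).
#'
#' @param spec a [design_spec()] (its run count is ignored).
#' @param n_sessions number of learning sessions.
#' @param seed optional integer seed.
#' @return An `event_table` whose `run` column indexes the session.
#' @export
generate_learning_design <- function(spec, n_sessions = 2L, seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  vl_assert(is_count(n_sessions) && n_sessions >= 1,
            "n_sessions must be a count >= 1")
  spec$n_runs <- as.integer(n_sessions)
  generate_design(spec, seed = seed)
}
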