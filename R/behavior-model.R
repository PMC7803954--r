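#' Behavioural response model for the speaker-identification task
#'
#' Parameterizes a subject's button presses: a per-trial probability of a
#' correct answer, a row-stochastic error kernel giving where wrong answers
#' land conditional on the presented speaker, a rate of missed (no-press)
#' trials, and a lognormal reaction-time law truncated at the answer window.
#' The default error kernel routes 70% of the errors made on speakers 2 and 3
#' onto each other, reproducing the mutual confusability of the two
#' harder-to-tell-apart voices; the default ability of 0.624 matches a mean
#' percent-correct of 62.4%.
#'
#' @param ability probability in `[0, 1]` that an answered trial is correct.
#' @param error_kernel square row-stochastic matrix with zero diagonal; row i
#'   is the answer distribution given an error on presented speaker i. NULL
#'   builds the 3-speaker default described above.
#' @param miss_rate probability that no response occurs inside the answer
#'   window.
#' @param rt_meanlog,rt_sdlog location and scale (log-seconds) of the
#'   reaction-time lognormal (defaults give mean ~1.3 s, sd ~0.5 s).
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(ability = 0.624,
                           error_kernel = NULL,
                           miss_rate = 0.05,
                           rt_meanlog = 0.19,
                           rt_sdlog = 0.37) {
  vl_assert(ability >= 0 && ability <= 1, "ability must lie in [0, 1]")
  vl_assert(miss_rate >= 0 && miss_rate < 1, "miss_rate must lie in [0, 1)")
  vl_assert(rt_sdlog > 0, "rt_sdlog must be positive")
  if (is.null(error_kernel)) {
    error_kernel <- matrix(c(0.0, 0.5, 0.5,
                             0.3, 0.0, 0.7,
                             0.3, 0.7, 0.0), 3, 3, byrow = TRUE)
  }
  error_kernel <- as.matrix(error_kernel)
  vl_assert(nrow(error_kernel) == ncol(error_kernel),
            "error_kernel must be square")
  vl_assert(all(abs(diag(error_kernel)) < 1e-12),
            "error_kernel must have zero diagonal")
  vl_assert(all(error_kernel >= 0) &&
              all(abs(rowSums(error_kernel) - 1) < 1e-9),
            "error_kernel rows must be probability vectors summing to 1")
  structure(list(ability = ability, error_kernel = error_kernel,
                 miss_rate = miss_rate, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog),
            class = "behavior_model")
}

#' @export
print.behavior_model <- function(x, ...) {
  cat("Behaviour model: P(correct | answered) =", x$ability,
      "; miss rate =", x$miss_rate, "\n")
  invisible(x)
}

#' Simulate button-press responses for an event table
#'
#' Each trial is missed with probability `miss_rate`; otherwise the answer is
#' the presented speaker with probability `ability` and a draw from the
#' presented speaker's error-kernel row otherwise. Reaction times are
#' lognormal, truncated at the answer window by inverse-CDF sampling, and
#' independent of correctness.
#'
#' @param design an `event_table` with a `speaker` column.
#' @param model a [behavior_model()].
#' @param seed optional integer seed.
#' @return The event table with added columns `response`, `response_time`
#'   (both NA on missed trials) and logical `missing`.
#' @export
simulate_responses <- function(design, model, seed = NULL) {
  stopifnot(inherits(design, "event_table"), inherits(model, "behavior_model"))
  speakers <- attr(design, "speakers")
  vl_assert(length(speakers) == nrow(model$error_kernel),
            "error_kernel dimension must match the number of speakers")
  window <- attr(design, "answer_window")
  with_seed(seed, {
    n <- nrow(design)
    presented <- match(design$speaker, speakers)
    missing <- stats::runif(n) < model$miss_rate
    correct <- stats::runif(n) < model$ability
    answer <- presented
    for (i in which(!correct)) {
      answer[i] <- sample.int(length(speakers), 1L,
                              prob = model$error_kernel[presented[i], ])
    }
    p_max <- stats::plnorm(window, model$rt_meanlog, model$rt_sdlog)
    rt <- stats::qlnorm(stats::runif(n) * p_max,
                        model$rt_meanlog, model$rt_sdlog)
    design$response <- ifelse(missing, NA_character_, speakers[answer])
    design$response_time <- ifelse(missing, NA_real_, rt)
    design$missing <- missing
    design
  })
}
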