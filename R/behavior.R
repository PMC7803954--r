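#' Percent-correct and reaction-time summary of an event table
#'
#' Percent correct overall, per speaker and per run; mean reaction times
#' (answered trials only); percentage of missing responses.
#'
#' @param events `event_table` with `response` (and optionally
#'   `response_time`, `missing`) columns.
#' @param missing_policy "exclude" drops missed trials from the percent
#'   correct denominator; "count_as_error" keeps them as incorrect.
#' @return An object of class `behavior_summary`: list with `pc_overall`,
#'   `pc_per_speaker`, `rt_mean_overall`, `rt_mean_per_speaker`,
#'   `missing_rate` (all percentages / seconds) and a `per_run` data frame.
#' @export
percent_correct <- function(events,
                            missing_policy = c("exclude", "count_as_error")) {
  missing_policy <- match.arg(missing_policy)
  vl_assert("response" %in% names(events), "events lack a response column")
  missing <- if ("missing" %in% names(events)) events$missing
             else is.na(events$response)
  answered <- !missing
  if (!any(answered)) {
    vl_error("no answered trials", "voicelight_data_error")
  }
  correct <- !missing & events$response == events$speaker
  denom_idx <- if (missing_policy == "exclude") answered
               else rep(TRUE, nrow(events))
  pc <- function(idx) 100 * sum(correct[idx]) / sum(idx)
  speakers <- attr(events, "speakers")
  if (is.null(speakers)) speakers <- sort(unique(events$speaker))
  pc_spk <- vapply(speakers,
                   function(s) pc(denom_idx & events$speaker == s), numeric(1))
  has_rt <- "response_time" %in% names(events)
  rt_spk <- if (has_rt) {
    vapply(speakers, function(s) {
      mean(events$response_time[answered & events$speaker == s])
    }, numeric(1))
  } else rep(NA_real_, length(speakers))
  runs <- sort(unique(events$run))
  per_run <- data.frame(
    run = runs,
    pc = vapply(runs, function(r) pc(denom_idx & events$run == r), numeric(1)),
    missing_pct = vapply(runs, function(r) {
      100 * mean(missing[events$run == r])
    }, numeric(1)))
  structure(list(pc_overall = pc(denom_idx),
                 pc_per_speaker = stats::setNames(pc_spk, speakers),
                 rt_mean_overall = if (has_rt)
                   mean(events$response_time[answered]) else NA_real_,
                 rt_mean_per_speaker = stats::setNames(rt_spk, speakers),
                 missing_rate = 100 * mean(missing),
                 n_trials = nrow(events), n_answered = sum(answered),
                 missing_policy = missing_policy, per_run = per_run),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("Behavioural summary (", x$n_answered, "answered /", x$n_trials,
      "trials )\n")
  cat("  percent correct:", round(x$pc_overall, 1), "%  ( per speaker:",
      paste(names(x$pc_per_speaker),
            round(x$pc_per_speaker, 1), collapse = ", "), ")\n")
  cat("  missing:", round(x$missing_rate, 1), "% ; mean RT:",
      round(x$rt_mean_overall, 2), "s\n")
  invisible(x)
}

#' Presented-vs-answered confusion matrix
#'
#' 3 x 3 (presented speaker x answered speaker) table of answered trials as
#' percentages normalized so the nine cells sum to 100: a perfect responder
#' in a balanced design has 33.33% in each diagonal cell, a uniform random
#' one 11.11% everywhere. Missed trials have no answer cell and are excluded.
#'
#' @param events `event_table` with responses.
#' @return A `confusion_matrix3` (matrix subclass with `n_trials` attribute).
#' @export
confusion_matrix <- function(events) {
  vl_assert("response" %in% names(events), "events lack a response column")
  answered <- !is.na(events$response)
  if (!any(answered)) {
    vl_error("no answered trials", "voicelight_data_error")
  }
  speakers <- attr(events, "speakers")
  if (is.null(speakers)) {
    speakers <- sort(unique(c(events$speaker, events$response[answered])))
  }
  counts <- table(factor(events$speaker[answered], speakers),
                  factor(events$response[answered], speakers))
  new_confusion_matrix3(unclass(counts), speakers)
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  cat("Confusion matrix (% of", attr(x, "n_trials"),
      "answered trials; cells sum to 100):\n")
  m <- round(unclass(x), 2)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  print(m)
  invisible(x)
}

#' Rank correlation between two confusion matrices
#'
#' Spearman correlation between the cell vectors of two confusion matrices
#' (all nine cells by default, or the six off-diagonal error cells), with a
#' one-tailed p-value for positive association. For nine or fewer cells the
#' p-value is exact, by enumeration of all permutations of one vector;
#' otherwise the t approximation is used.
#'
#' @param cm_a,cm_b `confusion_matrix3` objects (or plain matrices of equal
#'   shape).
#' @param cells "all9" or "offdiag6".
#' @return List with `rho`, `p_one_tailed`, `n_cells`, `method`.
#' @export
confusion_correlation <- function(cm_a, cm_b, cells = c("all9", "offdiag6")) {
  cells <- match.arg(cells)
  a <- as.matrix(unclass(cm_a))
  b <- as.matrix(unclass(cm_b))
  vl_assert(all(dim(a) == dim(b)), "matrices must have equal shape")
  if (cells == "offdiag6") {
    sel <- row(a) != col(a)
    va <- a[sel]; vb <- b[sel]
  } else {
    va <- as.numeric(a); vb <- as.numeric(b)
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    vl_error("constant cell vector: rank correlation undefined",
             "voicelight_degenerate_error")
  }
  ra <- rank(va); rb <- rank(vb)
  rho <- stats::cor(ra, rb)
  n <- length(va)
  if (n <= 9) {
    perms <- all_permutations(n)
    # rho under permutation of one vector's entries; compare to observed
    rho_perm <- (matrix(rb[perms], nrow(perms)) %*% ra - n * mean(ra) *
                   mean(rb)) /
      ((n - 1) * stats::sd(ra) * stats::sd(rb))
    p <- mean(rho_perm >= rho - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- stats::pt(tstat, n - 2, lower.tail = FALSE)
    method <- "t approximation"
  }
  list(rho = rho, p_one_tailed = p, n_cells = n, method = method)
}

# All permutations of 1..n as an n! x n matrix (n <= 9).
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  P <- matrix(1L, 1, 1)
  for (k in 2:max(2, n)) {
    if (n == 1) break
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1) * m + seq_len(m)
      if (pos > 1) out[rows, seq_len(pos - 1)] <- P[, seq_len(pos - 1)]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1):k] <- P[, pos:(k - 1), drop = FALSE]
    }
    P <- out
  }
  P
}
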