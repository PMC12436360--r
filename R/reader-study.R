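# Two-session observer-study analysis: five-point confidence scores per
# reader per session, AUROC on the ordinal scores, dichotomized confusion
# metrics, and session-to-session DeLong / McNemar comparisons.

#' Simulate two-session reader records with given confusion margins
#'
#' Builds a synthetic reader-record table whose dichotomized (scores >= 4)
#' session-level confusion matrices equal the requested counts exactly.
#' Within the positive-call bin scores are drawn from {4, 5} and within the
#' negative-call bin from {1, 2, 3}, seeded; which truth-positive /
#' truth-negative cases are called positive in session 2 is re-drawn at
#' random so the two sessions disagree on individual cases while keeping
#' their margins.
#'
#' @param session1,session2 integer vectors `c(tp, fp, fn, tn)`; the two
#'   sessions must imply the same case composition
#'   (`tp + fn` and `fp + tn` equal across sessions).
#' @param readerId reader identifier.
#' @param seed integer seed.
#' @return data.frame with columns case_id, truth, reader_id, session,
#'   score — one row per case per session.
#' @export
simulateReaderRecords <- function(session1, session2, readerId = "reader1",
                                  seed = 1L) {
  s1 <- as.integer(session1); s2 <- as.integer(session2)
  stopifnot(length(s1) == 4L, length(s2) == 4L, all(s1 >= 0L), all(s2 >= 0L))
  nPos <- s1[1] + s1[3]; nNeg <- s1[2] + s1[4]
  if (nPos != s2[1] + s2[3] || nNeg != s2[2] + s2[4])
    stop("sessions imply different case compositions", call. = FALSE)
  caseId <- sprintf("case_%03d", seq_len(nPos + nNeg))
  truth <- c(rep(1L, nPos), rep(0L, nNeg))
  withSeed(seed, {
    callsFor <- function(tp, fp) {
      call <- integer(nPos + nNeg)
      if (nPos) call[sample(which(truth == 1L), tp)] <- 1L
      if (nNeg) call[sample(which(truth == 0L), fp)] <- 1L
      call
    }
    score <- function(call)
      ifelse(call == 1L, sample(4:5, length(call), replace = TRUE),
             sample(1:3, length(call), replace = TRUE))
    rbind(
      data.frame(case_id = caseId, truth = truth, reader_id = readerId,
                 session = 1L, score = score(callsFor(s1[1], s1[2]))),
      data.frame(case_id = caseId, truth = truth, reader_id = readerId,
                 session = 2L, score = score(callsFor(s2[1], s2[2]))))
  })
}

#' Per-reader, per-session diagnostic performance table
#'
#' For every reader and session: AUROC computed on the five-point scores
#' (with a DeLong-variance CI), and sensitivity / specificity / PPV / NPV
#' with exact binomial CIs after dichotomizing at scores >= 4. Sessions are
#' compared per reader by the DeLong test on the five-point scores and by
#' exact McNemar tests on the dichotomized calls — discordant pairs among
#' truth-positive cases for sensitivity, among truth-negative cases for
#' specificity.
#'
#' @param records data.frame with columns case_id, truth, reader_id,
#'   session (1 or 2), score (1..5); every case needs both session scores.
#' @return list with `metrics` (long data.frame: reader_id, session,
#'   metric, value, ci_low, ci_high) and `tests` (reader_id, comparison,
#'   statistic columns, p).
#' @export
readerStudyTable <- function(records) {
  need <- c("case_id", "truth", "reader_id", "session", "score")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!records$score %in% 1:5))
    stop("reader scores must lie in 1..5", call. = FALSE)
  metrics <- NULL; tests <- NULL
  for (rd in unique(records$reader_id)) {
    rr <- records[records$reader_id == rd, , drop = FALSE]
    s1 <- rr[rr$session == 1L, ]; s2 <- rr[rr$session == 2L, ]
    if (!setequal(s1$case_id, s2$case_id) || anyDuplicated(s1$case_id) ||
        !nrow(s1) || !nrow(s2))
      stop("reader ", rd, " is missing a session score for some case",
           call. = FALSE)
    s2 <- s2[match(s1$case_id, s2$case_id), ]
    truth <- as.integer(s1$truth)
    for (ss in 1:2) {
      sc <- if (ss == 1L) s1$score else s2$score
      a <- aurocCi(sc, truth)
      d <- dichotomizeScores(sc)
      ms <- metricsFromConfusion(confusionCounts(d, truth, 1L))
      ms <- ms[ms$metric %in% c("sensitivity", "specificity", "ppv", "npv"), ]
      metrics <- rbind(metrics,
        data.frame(reader_id = rd, session = ss,
                   metric = c("auroc", ms$metric),
                   value = c(a$auc, ms$value),
                   ci_low = c(a$ci[1], ms$ci_low),
                   ci_high = c(a$ci[2], ms$ci_high)))
    }
    dl <- delongTest(s2$score, s1$score, truth)
    d1 <- dichotomizeScores(s1$score); d2 <- dichotomizeScores(s2$score)
    mcn <- function(keep) mcnemarTest(sum(d1[keep] == 1L & d2[keep] == 0L),
                                      sum(d1[keep] == 0L & d2[keep] == 1L))
    tests <- rbind(tests,
      data.frame(reader_id = rd,
                 comparison = c("auroc_delong", "sensitivity_mcnemar",
                                "specificity_mcnemar"),
                 delta = c(dl$diff, NA, NA),
                 ci_low = c(dl$ci[1], NA, NA), ci_high = c(dl$ci[2], NA, NA),
                 p = c(dl$p, mcn(truth == 1L), mcn(truth == 0L))))
  }
  list(metrics = metrics, tests = tests)
}

#' Write a reader-study report as a session-by-reader CSV
#'
#' One row per metric (AUROC plus the dichotomized percentages), one column
#' per reader and session with `value (ci_low-ci_high)` cells, and the
#' session-comparison p values appended — the conventional layout of a
#' two-session observer-performance table.
#'
#' @param report output of [readerStudyTable()].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeReaderReport <- function(report, path) {
  m <- report$metrics
  readers <- unique(m$reader_id)
  fmt <- function(v, lo, hi, pct) {
    if (pct) sprintf("%.1f (%.1f-%.1f)", 100 * v, 100 * lo, 100 * hi)
    else sprintf("%.3f (%.3f-%.3f)", v, lo, hi)
  }
  rows <- c("auroc", "sensitivity", "specificity", "ppv", "npv")
  out <- data.frame(metric = rows)
  for (rd in readers) for (ss in 1:2) {
    col <- vapply(rows, function(mt) {
      r <- m[m$reader_id == rd & m$session == ss & m$metric == mt, ]
      fmt(r$value, r$ci_low, r$ci_high, mt != "auroc")
    }, character(1))
    out[[paste0(rd, "_session", ss)]] <- col
  }
  for (rd in readers) {
    t <- report$tests[report$tests$reader_id == rd, ]
    out[[paste0(rd, "_p")]] <- vapply(rows, function(mt) {
      cmp <- switch(mt, auroc = "auroc_delong",
                    sensitivity = "sensitivity_mcnemar",
                    specificity = "specificity_mcnemar", NA_character_)
      if (is.na(cmp)) return("")
      sprintf("%.3g", t$p[t$comparison == cmp])
    }, character(1))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
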