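#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from Beta quantiles:
#' lower = qbeta(alpha/2, k, n - k + 1), upper = qbeta(1 - alpha/2,
#' k + 1, n - k), with lower = 0 when k = 0 and upper = 1 when k = n.
#' This is the interval behind all per-fraction damage and
#' consensus-support statistics.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (n >= 1).
#' @param level Confidence level, default 0.95.
#' @return A list of class `binomial_ci` with fields `k`, `n`,
#'   `estimate`, `lower`, `upper`, `level`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L) stop("k and n must be scalars")
  k <- as.numeric(k); n <- as.numeric(n)
  if (is.na(n) || n < 1) stop("undefined interval: n must be >= 1")
  if (is.na(k) || k < 0 || k > n) stop("k must lie in [0, n]")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(
    list(k = k, n = n, estimate = k / n, lower = lower, upper = upper,
         level = level),
    class = "binomial_ci"
  )
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.0f%% CI: %.1f-%.1f%%)\n", x$k, x$n,
              100 * x$estimate, 100 * x$level, 100 * x$lower,
              100 * x$upper))
  invisible(x)
}

# ref/read base at a molecule-end offset, one row per fragment.
# end = "5p" or "3p"; offset 0 is the terminal base. `wins` can carry a
# precomputed reference_window() to avoid recomputation across offsets.
terminal_bases <- function(fragments, panel, end = c("5p", "3p"),
                           offset = 0L, wins = NULL) {
  end <- match.arg(end)
  if (is.null(wins)) wins <- reference_window(fragments, panel)
  len <- nchar(fragments$sequence)
  pos <- if (end == "5p") rep_len(offset + 1L, nrow(fragments))
         else len - offset
  ok <- pos >= 1L & pos <= len
  ref_base <- read_base <- rep(NA_character_, nrow(fragments))
  ref_base[ok] <- substr(wins[ok], pos[ok], pos[ok])
  read_base[ok] <- substr(fragments$sequence[ok], pos[ok], pos[ok])
  data.frame(fragment_id = fragments$fragment_id, ref_base = ref_base,
             read_base = read_base, stringsAsFactors = FALSE)
}

#' Terminal C-to-T substitution counts
#'
#' Counts, at a given offset from the molecule 5' or 3' end, the
#' fragments whose reference base there is C (`n`) and, among those, the
#' fragments reading T (`k`). The ratio k/n is the standard proxy for
#' the cytosine deamination rate at the molecule ends; positions whose
#' reference base is not C are excluded from `n`.
#'
#' @param fragments An [aligned_fragments()] table (one reference).
#' @param panel The matching [reference_panel()].
#' @param end `"5p"` or `"3p"`: which molecule end.
#' @param offset Offset from that end, default 0 (the terminal base).
#' @return List with integer fields `k` and `n`.
#' @export
terminal_ct_counts <- function(fragments, panel, end = c("5p", "3p"),
                               offset = 0L, wins = NULL) {
  end <- match.arg(end)
  tb <- terminal_bases(fragments, panel, end, offset, wins)
  is_c <- !is.na(tb$ref_base) & tb$ref_base == "C" & tb$read_base != "N"
  list(k = sum(is_c & tb$read_base == "T"), n = sum(is_c))
}

#' Classify a family profile as ancient or other
#'
#' A (fraction, family) bin counts as ancient when the exact binomial
#' lower confidence bound on the terminal C-to-T frequency exceeds the
#' threshold (default 10%) at BOTH molecule ends; otherwise `other`.
#' Ends with no informative (reference-C) terminal positions cannot
#' clear the bar, and the result carries `no_terminal_info = TRUE`.
#'
#' @param k5,n5 Terminal C->T counts at the 5' end.
#' @param k3,n3 Terminal C->T counts at the 3' end.
#' @param threshold Deamination frequency that must be exceeded.
#' @param level Confidence level of the intervals.
#' @return List with `status` ("ancient"/"other"), the two
#'   `binomial_ci`s (`ci5`, `ci3`, NULL when n = 0) and
#'   `no_terminal_info`.
#' @export
classify_ancient <- function(k5, n5, k3, n3, threshold = 0.10,
                             level = 0.95) {
  ci5 <- if (n5 >= 1) clopper_pearson(k5, n5, level) else NULL
  ci3 <- if (n3 >= 1) clopper_pearson(k3, n3, level) else NULL
  no_info <- is.null(ci5) || is.null(ci3)
  ancient <- !no_info && ci5$lower > threshold && ci3$lower > threshold
  list(status = if (ancient) "ancient" else "other",
       ci5 = ci5, ci3 = ci3, no_terminal_info = no_info)
}

#' Per-offset terminal C-to-T damage profile
#'
#' Tabulates the C-to-T substitution rate at offsets `0..max_offset`
#' from each molecule end, with exact binomial intervals: the numbers
#' behind a standard ancient-DNA damage plot. Offsets beyond every
#' fragment length yield `n = 0` rows flagged `informative = FALSE`.
#'
#' @inheritParams terminal_ct_counts
#' @param max_offset Largest offset tabulated from each end.
#' @param level Confidence level for the intervals.
#' @return Data frame with columns `end`, `offset`, `k`, `n`, `rate`,
#'   `lower`, `upper`, `informative`.
#' @export
damage_profile <- function(fragments, panel, max_offset = 25L,
                           level = 0.95) {
  rows <- list()
  wins <- reference_window(fragments, panel)
  for (end in c("5p", "3p")) {
    for (off in 0:max_offset) {
      ct <- terminal_ct_counts(fragments, panel, end, off, wins)
      if (ct$n > 0) {
        ci <- clopper_pearson(ct$k, ct$n, level)
        rows[[length(rows) + 1L]] <- data.frame(
          end = end, offset = off, k = ct$k, n = ct$n,
          rate = ci$estimate, lower = ci$lower, upper = ci$upper,
          informative = TRUE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          end = end, offset = off, k = 0L, n = 0L, rate = NA_real_,
          lower = NA_real_, upper = NA_real_, informative = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
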