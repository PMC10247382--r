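#' Call a consensus mitochondrial sequence
#'
#' Majority-rule consensus over a pileup of deduplicated fragments:
#' position `i` is called as base `b` when coverage is at least
#' `min_cov` and `b` carries at least a `majority` fraction of the
#' reads there; every other position is `N`.
#'
#' @param fragments A deduplicated [aligned_fragments()] table aligned
#'   to one reference.
#' @param panel The [reference_panel()].
#' @param ref_id Reference to call against (defaults to the single
#'   reference present in `fragments`).
#' @param min_cov Minimum coverage for a call (default 10).
#' @param majority Minimum base frequency among reads (default 0.75).
#' @return Object of class `consensus_sequence`: list with
#'   `reference_id`, `calls` (character vector, reference orientation),
#'   `coverage` (integer vector).
#' @export
call_consensus <- function(fragments, panel, ref_id = NULL,
                           min_cov = 10L, majority = 0.75) {
  if (is.null(ref_id)) {
    ref_id <- unique(fragments$reference_id)
    if (length(ref_id) != 1L) {
      stop("fragments span several references; give ref_id")
    }
  }
  fragments <- fragments[fragments$reference_id == ref_id, , drop = FALSE]
  L <- panel_lengths(panel)[[ref_id]]
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  seqs <- fragments$sequence
  minus <- fragments$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  idx_parts <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    b <- base_code[strsplit(seqs[i], "", fixed = TRUE)[[1]]]
    pos <- (seq.int(fragments$start[i], fragments$end[i] - 1L) %% L)
    ok <- !is.na(b)  # skip N
    idx_parts[[i]] <- pos[ok] * 4L + b[ok]
  }
  tab <- tabulate(unlist(idx_parts), nbins = 4L * L)
  counts[] <- matrix(tab, nrow = L, ncol = 4L, byrow = TRUE)
  cov <- rowSums(counts)
  calls <- rep("N", L)
  has <- cov >= min_cov
  if (any(has)) {
    best <- max.col(counts[has, , drop = FALSE], ties.method = "first")
    best_n <- counts[cbind(which(has), best)]
    pass <- best_n / cov[has] >= majority
    calls[which(has)[pass]] <- c("A", "C", "G", "T")[best[pass]]
  }
  structure(list(reference_id = ref_id, calls = calls,
                 coverage = as.integer(cov)),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat("Consensus on", x$reference_id, "-", length(x$calls), "bp,",
      sum(x$calls != "N"), "called,",
      sprintf("mean coverage %.1f\n", mean(x$coverage)))
  invisible(x)
}

#' Consensus as a string
#' @param consensus A `consensus_sequence`.
#' @return Character scalar (N at uncalled positions).
#' @export
consensus_string <- function(consensus) {
  paste(consensus$calls, collapse = "")
}

#' Write a consensus sequence to FASTA
#' @param consensus A `consensus_sequence`.
#' @param path Output path.
#' @param id Record id (defaults to the reference id).
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensus, path, id = NULL) {
  x <- Biostrings::DNAStringSet(consensus_string(consensus))
  names(x) <- if (is.null(id)) consensus$reference_id else id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Find diagnostic positions against a comparison panel
#'
#' A position is diagnostic when the consensus carries a called base
#' whose frequency in the comparison panel is at most `max_panel_freq`
#' (default 0: the allele is absent from every panel sequence).
#' Differences that deamination can mimic (C<->T or G<->A against the
#' modal panel allele) are flagged `damage_ambiguous`.
#'
#' @param consensus A `consensus_sequence`.
#' @param comparison Character vector of sequences aligned to the same
#'   coordinates as the consensus (equal length).
#' @param max_panel_freq Maximum panel frequency of the consensus
#'   allele at a diagnostic site.
#' @return Data frame: `pos` (0-based), `consensus`, `modal_panel`,
#'   `panel_freq`, `damage_ambiguous`.
#' @export
find_diagnostic_sites <- function(consensus, comparison,
                                  max_panel_freq = 0) {
  if (length(comparison) == 0L) stop("comparison panel is empty")
  L <- length(consensus$calls)
  if (any(nchar(comparison) != L)) {
    stop("comparison sequences must be aligned to the consensus length")
  }
  pmat <- do.call(rbind, strsplit(toupper(comparison), "", fixed = TRUE))
  rows <- list()
  for (i in which(consensus$calls != "N")) {
    col <- pmat[, i]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) next
    freq <- mean(col == consensus$calls[i])
    if (freq <= max_panel_freq) {
      modal <- names(sort(table(col), decreasing = TRUE))[1]
      pair <- paste0(consensus$calls[i], modal)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = i - 1L, consensus = consensus$calls[i],
        modal_panel = modal, panel_freq = freq,
        damage_ambiguous = pair %in% c("CT", "TC", "GA", "AG"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pos = integer(), consensus = character(),
                      modal_panel = character(), panel_freq = numeric(),
                      damage_ambiguous = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# reference-orientation read base of each fragment at one reference
# position; NA where the fragment does not cover it or reads N
read_base_at <- function(fragments, panel, ref_id, pos) {
  L <- panel_lengths(panel)[[ref_id]]
  span <- fragments$end - fragments$start
  off <- (pos - fragments$start) %% L
  covers <- fragments$reference_id == ref_id & off < span
  at <- ifelse(fragments$strand == "+", off + 1L, span - off)
  b <- rep(NA_character_, nrow(fragments))
  b[covers] <- substr(fragments$sequence[covers], at[covers], at[covers])
  minus <- covers & fragments$strand == "-"
  b[minus] <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[b[minus]]
  b[!is.na(b) & b == "N"] <- NA_character_
  b
}

#' Per-fraction support for the consensus at diagnostic positions
#'
#' Every overlap of a fragment with a diagnostic site contributes one
#' observation when the read base there is not N (one fragment spanning
#' two sites contributes twice). Support is the fraction of
#' observations matching the consensus allele, with an exact binomial
#' interval. Damage-ambiguous sites are excluded by default because
#' deamination mimics the difference. The verdict is `indeterminate`
#' below `min_informative` observations, `supports` when the interval
#' lower bound exceeds 0.5, otherwise `mixed`.
#'
#' @param fragments An [aligned_fragments()] table for one fraction.
#' @param panel The [reference_panel()].
#' @param sites Data frame from [find_diagnostic_sites()].
#' @param ref_id Reference the sites live on.
#' @param min_informative Observation floor below which the verdict is
#'   `indeterminate`.
#' @param include_ambiguous Include damage-ambiguous sites.
#' @param level Confidence level.
#' @param fraction Label stored on the estimate.
#' @return List of class `support_estimate`: `fraction`, `n_match`,
#'   `n_informative`, `ci` (`binomial_ci` or NULL), `verdict`.
#' @export
support_at_diagnostics <- function(fragments, panel, sites, ref_id,
                                   min_informative = 5L,
                                   include_ambiguous = FALSE,
                                   level = 0.95, fraction = "F1") {
  if (!include_ambiguous) {
    sites <- sites[!sites$damage_ambiguous, , drop = FALSE]
  }
  n_match <- 0L
  n_informative <- 0L
  for (j in seq_len(nrow(sites))) {
    obs <- read_base_at(fragments, panel, ref_id, sites$pos[j])
    obs <- obs[!is.na(obs)]
    n_informative <- n_informative + length(obs)
    n_match <- n_match + sum(obs == sites$consensus[j])
  }
  ci <- if (n_informative >= 1L) {
    clopper_pearson(n_match, n_informative, level)
  } else NULL
  verdict <- if (n_informative < min_informative) "indeterminate"
             else if (ci$lower > 0.5) "supports" else "mixed"
  structure(list(fraction = fraction, n_match = n_match,
                 n_informative = n_informative, ci = ci,
                 verdict = verdict),
            class = "support_estimate")
}

#' @export
print.support_estimate <- function(x, ...) {
  if (is.null(x$ci)) {
    cat(sprintf("[%s] support indeterminate (0 observations)\n",
                x$fraction))
  } else {
    cat(sprintf("[%s] %d/%d = %.1f%% (95%% CI: %.1f-%.1f%%) -> %s\n",
                x$fraction, x$n_match, x$n_informative,
                100 * x$ci$estimate, 100 * x$ci$lower,
                100 * x$ci$upper, x$verdict))
  }
  invisible(x)
}

#' Present-day contamination from conditional damage rates
#'
#' A two-component mixture estimator standing in for full
#' damage-pattern modelling: `r_all` is the terminal C->T rate over
#' all fragments, `r_cond` the rate among fragments already carrying a
#' C->T at the opposite terminal (a subset strongly enriched for
#' endogenous, deaminated molecules). Under the mixture, `r_all ~
#' (1-c) * r_cond`, giving `c_hat = 1 - r_all / r_cond`, clipped to
#' [0, 1]. The interval is a percentile bootstrap over fragments.
#'
#' @param fragments An [aligned_fragments()] table on one reference.
#' @param panel The [reference_panel()].
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level.
#' @return List of class `contamination_estimate`: `method`,
#'   `estimate`, `lower`, `upper`, `n_fragments`, `indeterminate`.
#' @export
estimate_contamination_conditional <- function(fragments, panel,
                                               n_boot = 1000L, seed = 1L,
                                               level = 0.95) {
  wins <- reference_window(fragments, panel)
  tb5 <- terminal_bases(fragments, panel, "5p", wins = wins)
  tb3 <- terminal_bases(fragments, panel, "3p", wins = wins)
  c5 <- !is.na(tb5$ref_base) & tb5$ref_base == "C" & tb5$read_base != "N"
  c3 <- !is.na(tb3$ref_base) & tb3$ref_base == "C" & tb3$read_base != "N"
  t5 <- c5 & tb5$read_base == "T"
  t3 <- c3 & tb3$read_base == "T"
  if (sum(c5) + sum(c3) == 0L) {
    stop("no informative terminal positions for contamination estimation")
  }
  est_from <- function(idx) {
    k_all <- sum(t5[idx]) + sum(t3[idx])
    n_all <- sum(c5[idx]) + sum(c3[idx])
    k_cond <- sum(t5[idx] & t3[idx]) + sum(t3[idx] & t5[idx])
    n_cond <- sum(c5[idx] & t3[idx]) + sum(c3[idx] & t5[idx])
    if (n_all == 0L || n_cond == 0L) return(NA_real_)
    r_all <- k_all / n_all
    r_cond <- k_cond / n_cond
    if (r_cond == 0) return(NA_real_)
    min(1, max(0, 1 - r_all / r_cond))
  }
  all_idx <- seq_len(nrow(fragments))
  point <- est_from(all_idx)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    est_from(sample(all_idx, replace = TRUE))
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  alpha <- 1 - level
  ci <- if (length(boot) >= 2L) {
    stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  } else c(NA_real_, NA_real_)
  structure(list(method = "conditional-damage", estimate = point,
                 lower = if (is.na(point)) NA_real_
                         else min(ci[1], point, na.rm = TRUE),
                 upper = if (is.na(point)) NA_real_
                         else max(ci[2], point, na.rm = TRUE),
                 n_fragments = nrow(fragments),
                 indeterminate = is.na(point)),
            class = "contamination_estimate")
}

#' Present-day contamination from diagnostic positions
#'
#' The complement view of [support_at_diagnostics()]: among the same
#' fragment-site observations, the fraction NOT matching the consensus
#' allele is attributed to contamination (with unambiguous biallelic
#' sites and low sequencing error, these are the observations carrying
#' the contaminant allele). The two estimates on the same fragments
#' therefore sum to one exactly.
#'
#' @inheritParams support_at_diagnostics
#' @return List of class `contamination_estimate` with a `binomial_ci`
#'   in `lower`/`upper`, plus `n_fragments` (informative observations).
#' @export
estimate_contamination_diagnostic <- function(fragments, panel, sites,
                                              ref_id,
                                              include_ambiguous = FALSE,
                                              level = 0.95) {
  sup <- support_at_diagnostics(fragments, panel, sites, ref_id,
                                min_informative = 1L,
                                include_ambiguous = include_ambiguous,
                                level = level)
  n <- sup$n_informative
  if (n == 0L) {
    return(structure(list(method = "diagnostic-allele",
                          estimate = NA_real_, lower = NA_real_,
                          upper = NA_real_, n_fragments = 0L,
                          indeterminate = TRUE),
                     class = "contamination_estimate"))
  }
  k <- n - sup$n_match
  ci <- clopper_pearson(k, n, level)
  structure(list(method = "diagnostic-allele", estimate = ci$estimate,
                 lower = ci$lower, upper = ci$upper, n_fragments = n,
                 indeterminate = FALSE),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  if (x$indeterminate) {
    cat(sprintf("contamination (%s): indeterminate\n", x$method))
  } else {
    cat(sprintf("contamination (%s): %.1f%% (CI: %.1f-%.1f%%), n=%d\n",
                x$method, 100 * x$estimate, 100 * x$lower,
                100 * x$upper, x$n_fragments))
  }
  invisible(x)
}
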