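#' Root-to-tip distances via the outgroup
#'
#' Pairwise distance of every tip to the designated outgroup, computed
#' over ungapped, unambiguous (A/C/G/T in both sequences) columns as a
#' Hamming proportion, optionally Jukes-Cantor corrected
#' (`-3/4 log(1 - 4p/3)`; the default). Under a strict clock this
#' distance decreases linearly with tip age.
#'
#' @param aln A `dated_alignment` (see [simulate_clock_alignment()] or
#'   [read_dated_alignment()]).
#' @param correction `"JC"` or `"raw"`.
#' @param min_columns Minimum usable columns per pair.
#' @return Named numeric vector of distances (outgroup excluded).
#' @export
root_to_tip_distances <- function(aln, correction = c("JC", "raw"),
                                  min_columns = 50L) {
  correction <- match.arg(correction)
  stats <- pairwise_mismatch(aln)
  usable <- colSums(stats$usable)
  if (any(usable < min_columns)) {
    stop("fewer than ", min_columns, " usable alignment columns for: ",
         paste(names(usable)[usable < min_columns], collapse = ", "))
  }
  p <- colSums(stats$mismatch) / usable
  if (correction == "JC") {
    if (any(p >= 0.75)) stop("distance saturated: p >= 0.75")
    p <- -0.75 * log(1 - 4 * p / 3)
  }
  p
}

# per-column mismatch/usable indicator matrices (columns = tips,
# rows = alignment columns) against the outgroup
pairwise_mismatch <- function(aln) {
  tips <- setdiff(names(aln$seqs), aln$outgroup)
  out_b <- strsplit(aln$seqs[[aln$outgroup]], "", fixed = TRUE)[[1]]
  L <- length(out_b)
  ok_out <- out_b %in% c("A", "C", "G", "T")
  usable <- mism <- matrix(FALSE, L, length(tips),
                           dimnames = list(NULL, tips))
  for (tp in tips) {
    b <- strsplit(aln$seqs[[tp]], "", fixed = TRUE)[[1]]
    if (length(b) != L) stop("alignment columns differ in length: ", tp)
    u <- ok_out & b %in% c("A", "C", "G", "T")
    usable[, tp] <- u
    mism[, tp] <- u & b != out_b
  }
  list(usable = usable, mismatch = mism)
}

#' Fit a strict molecular clock by root-to-tip regression
#'
#' Least-squares fit of `distance_i = a - r * age_i` over the dated
#' tips: older tips sit closer to the root, so a usable clock has a
#' positive rate `r`. Fewer than three dated tips, or no age spread,
#' is an error; a non-positive fitted rate flags the data as
#' unclocklike.
#'
#' @param distances Named distances from [root_to_tip_distances()].
#' @param ages Named ages (years before present) of the dated tips.
#' @return List with `rate`, `intercept`, `unclocklike`, `n_tips`.
#' @export
fit_clock <- function(distances, ages) {
  ages <- ages[!is.na(ages)]
  tips <- intersect(names(distances), names(ages))
  if (length(tips) < 3L) stop("need at least 3 dated tips")
  a <- ages[tips]; d <- distances[tips]
  if (stats::sd(a) == 0) stop("all tip ages equal: rate unidentifiable")
  fit <- stats::lm(d ~ a)
  rate <- -unname(stats::coef(fit)[2])
  list(rate = rate, intercept = unname(stats::coef(fit)[1]),
       unclocklike = !is.finite(rate) || rate <= 0,
       n_tips = length(tips))
}

#' Estimate the age of the undated query sequence
#'
#' Fits the strict clock on the dated tips and inverts it at the
#' query's root-to-tip distance: `age = (a - d_query) / r`. The
#' interval is a percentile bootstrap over alignment columns
#' (distances, clock fit and inversion recomputed per replicate);
#' negative ages are truncated at 0 and flagged. The returned interval
#' is widened, if needed, to contain the point estimate.
#'
#' @param aln A `dated_alignment` with one query tip.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param correction Distance correction, as in
#'   [root_to_tip_distances()].
#' @return List of class `age_estimate`: `age`, `lower`, `upper`,
#'   `rate`, `n_variable_sites`, `truncated`.
#' @export
estimate_age <- function(aln, n_boot = 1000L, seed = 1L, level = 0.95,
                         correction = c("JC", "raw")) {
  correction <- match.arg(correction)
  if (is.null(aln$query)) stop("alignment has no query tip")
  dated <- names(aln$ages)[!is.na(aln$ages)]
  stats_m <- pairwise_mismatch(aln)
  age_from <- function(cols) {
    u <- colSums(stats_m$usable[cols, , drop = FALSE])
    if (any(u == 0)) return(NA_real_)
    p <- colSums(stats_m$mismatch[cols, , drop = FALSE]) / u
    if (correction == "JC") {
      if (any(p >= 0.75)) return(NA_real_)
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    fit <- tryCatch(fit_clock(p[dated], aln$ages[dated]),
                    error = function(e) NULL)
    if (is.null(fit) || fit$unclocklike) return(NA_real_)
    (fit$intercept - p[[aln$query]]) / fit$rate
  }
  L <- nrow(stats_m$usable)
  point <- age_from(seq_len(L))
  if (is.na(point)) stop("unclocklike fit: cannot estimate an age")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    age_from(sample.int(L, L, replace = TRUE))
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  alpha <- 1 - level
  qs <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  lower <- min(qs[1], point)
  upper <- max(qs[2], point)
  truncated <- point < 0 || lower < 0
  full_fit <- fit_clock(
    root_to_tip_distances(aln, correction)[dated], aln$ages[dated])
  tipmat <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  n_var <- sum(apply(tipmat, 2L, function(cc) {
    cc <- cc[cc %in% c("A", "C", "G", "T")]
    length(unique(cc)) > 1L
  }))
  structure(list(age = max(0, point), lower = max(0, lower),
                 upper = max(0, upper), rate = full_fit$rate,
                 n_variable_sites = n_var, truncated = truncated),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf(
    "query age: %.0f y (95%% interval %.0f-%.0f), rate %.3g/site/y%s\n",
    x$age, x$lower, x$upper, x$rate,
    if (x$truncated) " [truncated at 0]" else ""))
  invisible(x)
}

#' Read a dated alignment from FASTA plus an age table
#'
#' @param fasta Aligned FASTA of equal-length sequences.
#' @param ages_tsv TSV with columns `tip_id`, `age`, `is_query`
#'   (age empty/NA for the query), matching the FASTA ids.
#' @param outgroup Id of the outgroup sequence.
#' @return A `dated_alignment`.
#' @export
read_dated_alignment <- function(fasta, ages_tsv, outgroup) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  seqs <- stats::setNames(toupper(as.character(seqs)), nm)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must have equal length")
  }
  at <- utils::read.delim(ages_tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("tip_id", "age", "is_query") %in% names(at)))
  if (!outgroup %in% nm) stop("outgroup not in alignment: ", outgroup)
  query <- at$tip_id[as.logical(at$is_query)]
  if (length(query) != 1L) stop("exactly one query tip required")
  ages <- stats::setNames(rep(NA_real_, length(nm)), nm)
  dated <- at[!as.logical(at$is_query), ]
  ages[dated$tip_id] <- as.numeric(dated$age)
  ages[outgroup] <- NA_real_
  structure(list(seqs = seqs, ages = ages, query = query,
                 outgroup = outgroup, truth = NULL),
            class = "dated_alignment")
}

#' Export a neighbour-joining tree of the alignment (visualisation only)
#'
#' @param aln A `dated_alignment`.
#' @param path Output Newick path.
#' @return `path`, invisibly. Requires the ape package.
#' @export
write_nj_tree <- function(aln, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("ape is required for tree export")
  }
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "JC69",
                     pairwise.deletion = TRUE)
  tr <- ape::nj(d)
  ape::write.tree(tr, path)
  invisible(path)
}
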