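#' @title Family-level taxonomic assignment
#'
#' @description Fragments are assigned to biological families by a
#' competitive best-hit search against every panel reference, on both
#' strands, accepting the family of the unique best hit when its
#' mismatch fraction is at or below a threshold. A tie in best score
#' across different families leaves the fragment unassigned
#' (conservative lowest-common-ancestor behaviour); so does exceeding
#' the mismatch threshold everywhere.
#'
#' @name taxonomic-binning
NULL

# concatenated search subject over all (unwrapped) references, with N
# spacers so no inexact match can bridge two references undetected
build_search_index <- function(panel, spacer = 60L) {
  pieces <- character(length(panel$ids))
  regions <- data.frame(ref_id = panel$ids, family = panel$families,
                        start = NA_integer_, len = NA_integer_,
                        stringsAsFactors = FALSE)
  offset <- 0L
  for (i in seq_along(panel$ids)) {
    s <- panel$sequences[[i]]
    if (panel$circular[i]) {
      # unwrap: append L-1 leading bases so origin-spanning hits exist
      s <- paste0(s, substr(s, 1L, nchar(s) - 1L))
    }
    pieces[i] <- s
    regions$start[i] <- offset + 1L
    regions$len[i] <- nchar(s)
    offset <- offset + nchar(s) + spacer
  }
  subject <- Biostrings::DNAString(
    paste(pieces, collapse = strrep("N", spacer))
  )
  list(subject = subject, regions = regions)
}

# best family for one sequence given a prebuilt index
assign_one <- function(seq, index, max_mismatch_frac) {
  len <- nchar(seq)
  k <- floor(max_mismatch_frac * len)
  best_mm <- k + 1L
  best_fams <- character(0)
  for (s in c(seq, revcomp(seq))) {
    pat <- Biostrings::DNAString(s)
    m <- Biostrings::matchPattern(pat, index$subject, max.mismatch = k)
    if (length(m) == 0L) next
    st <- IRanges::start(m)
    region <- findInterval(st, index$regions$start)
    inside <- region >= 1 &
      st + len - 1L <= index$regions$start[region] +
        index$regions$len[region] - 1L
    if (!any(inside)) next
    st <- st[inside]; region <- region[inside]
    mm <- Biostrings::neditStartingAt(pat, index$subject, starting.at = st)
    for (j in seq_along(st)) {
      if (mm[j] < best_mm) {
        best_mm <- mm[j]
        best_fams <- index$regions$family[region[j]]
      } else if (mm[j] == best_mm) {
        best_fams <- union(best_fams, index$regions$family[region[j]])
      }
    }
  }
  if (length(best_fams) == 1L) best_fams else NA_character_
}

#' Assign a single fragment sequence to a family
#'
#' @param sequence Fragment residue string (molecule orientation).
#' @param panel A [reference_panel()].
#' @param max_mismatch_frac Maximum tolerated mismatch fraction of the
#'   best hit (default 0.1).
#' @return Family label, or `NA` if unassigned (no acceptable hit, or a
#'   best-score tie across families).
#' @export
assign_fragment <- function(sequence, panel, max_mismatch_frac = 0.1) {
  if (is.na(sequence) || nchar(sequence) == 0L) {
    stop("cannot assign an empty sequence")
  }
  index <- build_search_index(panel)
  assign_one(toupper(sequence), index, max_mismatch_frac)
}

#' Assign every fragment in a table to a family
#'
#' Vectorised form of [assign_fragment()]; identical sequences are
#' searched once.
#'
#' @param fragments An [aligned_fragments()] table (the stored
#'   alignment coordinates are ignored: assignment is by sequence).
#' @param panel A [reference_panel()].
#' @param max_mismatch_frac Maximum tolerated mismatch fraction.
#' @return Character vector of family labels (`NA` = unassigned),
#'   parallel to `fragments`.
#' @export
assign_fragments <- function(fragments, panel, max_mismatch_frac = 0.1) {
  index <- build_search_index(panel)
  seqs <- fragments$sequence
  uniq <- unique(seqs)
  fam_u <- vapply(uniq, assign_one, character(1), index = index,
                  max_mismatch_frac = max_mismatch_frac)
  unname(fam_u[match(seqs, uniq)])
}

#' Collapse PCR duplicates
#'
#' One representative is kept per alignment key (reference id, start,
#' end, strand): sequence variants of one molecule created by damage or
#' sequencing error collapse onto the same placement. The number of
#' raw fragments behind each representative is attached as the
#' `dup_count` attribute.
#'
#' @param fragments An [aligned_fragments()] table.
#' @return The deduplicated table, with attribute `dup_count` (integer
#'   vector parallel to the result).
#' @export
deduplicate <- function(fragments) {
  key <- paste(fragments$reference_id, fragments$start, fragments$end,
               fragments$strand, sep = "\r")
  first <- !duplicated(key)
  out <- fragments[first, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dup_count") <- as.integer(table(key)[key[first]])
  out
}

#' Per-family detection profiles with the three detection filters
#'
#' Builds one profile per assigned family in a fraction and applies the
#' detection filters: at least `min_unique` unique fragments, together
#' covering at least `min_positions` reference positions, and
#' representing at least `min_share` of all taxonomically assigned
#' unique fragments. Families failing any filter get status
#' `"filtered"`; survivors are classified `"ancient"` or `"other"` by
#' the terminal-deamination criterion of [classify_ancient()]. All
#' three filters are evaluated on the unfiltered counts, so they are
#' idempotent and order-independent.
#'
#' @param fragments A deduplicated [aligned_fragments()] table.
#' @param families Family per fragment, from [assign_fragments()]
#'   (`NA` = unassigned, excluded).
#' @param panel The [reference_panel()].
#' @param fraction Fraction label stored on the profiles.
#' @param min_unique Minimum unique fragments per family.
#' @param min_positions Minimum covered reference positions.
#' @param min_share Minimum share of assigned unique fragments.
#' @param damage_threshold Deamination rate that the CI lower bounds
#'   must exceed for `"ancient"` status.
#' @param level Confidence level of the damage intervals.
#' @return Data frame with one row per family: `fraction`, `family`,
#'   `n_unique`, `positions_covered`, `share_of_assigned`,
#'   `share_detected` (renormalised over non-filtered families),
#'   `k5`, `n5`, `k3`, `n3`, `lower5`, `lower3`, `status`.
#' @export
profile_families <- function(fragments, families, panel, fraction = "F1",
                             min_unique = 3L, min_positions = 105L,
                             min_share = 0.01, damage_threshold = 0.10,
                             level = 0.95) {
  keep <- !is.na(families)
  fragments <- fragments[keep, , drop = FALSE]
  families <- families[keep]
  n_assigned <- nrow(fragments)
  fams <- sort(unique(families))
  Ls <- panel_lengths(panel)
  rows <- lapply(fams, function(f) {
    fr <- fragments[families == f, , drop = FALSE]
    covered <- unique(unlist(lapply(seq_len(nrow(fr)), function(i) {
      L <- Ls[[fr$reference_id[i]]]
      paste(fr$reference_id[i],
            (seq.int(fr$start[i], fr$end[i] - 1L) %% L))
    })))
    ct5 <- terminal_ct_counts(fr, panel, "5p")
    ct3 <- terminal_ct_counts(fr, panel, "3p")
    share <- nrow(fr) / n_assigned
    passed <- nrow(fr) >= min_unique &&
      length(covered) >= min_positions && share >= min_share
    cls <- classify_ancient(ct5$k, ct5$n, ct3$k, ct3$n,
                            threshold = damage_threshold, level = level)
    data.frame(
      fraction = fraction, family = f, n_unique = nrow(fr),
      positions_covered = length(covered), share_of_assigned = share,
      share_detected = NA_real_,
      k5 = ct5$k, n5 = ct5$n, k3 = ct3$k, n3 = ct3$n,
      lower5 = if (is.null(cls$ci5)) NA_real_ else cls$ci5$lower,
      lower3 = if (is.null(cls$ci3)) NA_real_ else cls$ci3$lower,
      status = if (!passed) "filtered" else cls$status,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(fraction = character(), family = character(),
                      n_unique = integer(), positions_covered = integer(),
                      share_of_assigned = numeric(),
                      share_detected = numeric(), k5 = integer(),
                      n5 = integer(), k3 = integer(), n3 = integer(),
                      lower5 = numeric(), lower3 = numeric(),
                      status = character(), stringsAsFactors = FALSE)
    return(out)
  }
  det <- out$status != "filtered"
  if (any(det)) {
    out$share_detected[det] <- out$n_unique[det] / sum(out$n_unique[det])
  }
  rownames(out) <- NULL
  out
}
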