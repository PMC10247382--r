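# Shared in-code fixtures: a tiny deterministic panel and hand-built
# fragment tables used across module tests.

tiny_panel <- function() {
  reference_panel(
    ids = c("r1", "r2"),
    families = c("Cervidae", "Ursidae"),
    sequences = c(
      r1 = strrep("ACGT", 10),          # 40 bp
      r2 = strrep("GGTACA", 7)          # 42 bp
    ),
    circular = c(FALSE, FALSE)
  )
}

# one fragment table on tiny_panel(); sequence defaults to the exact
# reference slice (plus strand) unless given
tiny_frags <- function(panel, start, end, strand = "+", seq = NULL,
                       ref = "r1", ids = NULL) {
  n <- length(start)
  if (is.null(seq)) {
    seq <- vapply(seq_len(n), function(i) {
      s <- reference_slice(panel, ref, start[i], end[i])
      if (strand[min(i, length(strand))] == "-") {
        chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(s, "")[[1]]), collapse = ""))
      } else s
    }, character(1))
  }
  if (is.null(ids)) ids <- paste0("f", seq_len(n))
  aligned_fragments(data.frame(
    fragment_id = ids, library_id = "lib1", reference_id = ref,
    start = start, end = end, strand = rep_len(strand, n),
    sequence = seq, stringsAsFactors = FALSE
  ), panel)
}

# standard simulated world used by several tests
sim_world <- function(seed = 11, length = 8000, n_families = 2) {
  make_panel(n_families, length = length, seed = seed)
}
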