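#' Aligned sequence fragments
#'
#' Fragments are stored as a data frame with one row per sequenced
#' molecule and columns `fragment_id`, `library_id`, `reference_id`,
#' `start`, `end` (0-based half-open reference coordinates), `strand`
#' (`+`/`-`) and `sequence`.
#'
#' The `sequence` column always holds the molecule read 5' to 3': a
#' minus-strand fragment stores the reverse complement of the reference
#' window, so terminal offsets refer to the ends of the sequenced
#' molecule, where cytosine deamination acts, not to reference
#' orientation. For circular references a fragment spanning the origin
#' has `end > L` (positions are taken modulo the reference length).
#'
#' @param df Data frame with the columns above.
#' @param panel A [reference_panel()] used for validation.
#' @return The validated data frame with class `aligned_fragments`.
#' @export
aligned_fragments <- function(df, panel) {
  req <- c("fragment_id", "library_id", "reference_id", "start", "end",
           "strand", "sequence")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing fragment columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$fragment_id <- as.character(df$fragment_id)
  df$library_id <- as.character(df$library_id)
  df$reference_id <- as.character(df$reference_id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  df$sequence <- toupper(as.character(df$sequence))
  if (nrow(df)) {
    idx <- match(df$reference_id, panel$ids)
    if (anyNA(idx)) {
      stop("fragment references unknown reference id: ",
           paste(unique(df$reference_id[is.na(idx)]), collapse = ", "))
    }
    L <- nchar(panel$sequences)[idx]
    circ <- panel$circular[idx]
    bad <- df$start < 0L | df$start >= df$end |
      (!circ & df$end > L) | (circ & (df$start >= L | df$end > df$start + L))
    if (any(bad)) {
      stop("fragment coordinates outside reference: ",
           paste(df$fragment_id[bad][seq_len(min(3, sum(bad)))],
                 collapse = ", "))
    }
    if (any(nchar(df$sequence) != df$end - df$start)) {
      stop("read length must equal end - start")
    }
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (anyDuplicated(df$fragment_id)) stop("fragment ids must be unique")
  }
  rownames(df) <- NULL
  class(df) <- c("aligned_fragments", "data.frame")
  df
}

revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# split panel sequences into character vectors once, for fast indexing
panel_chars <- function(panel) {
  lapply(panel$sequences, function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

#' Reference bases under each fragment, in molecule orientation
#'
#' Returns, for every fragment, the reference bases it covers read in the
#' orientation of the sequenced molecule (complemented and reversed for
#' minus-strand fragments). Position `i` of the result lines up with
#' position `i` of the fragment's `sequence`.
#'
#' @param fragments An [aligned_fragments()] table.
#' @param panel The matching [reference_panel()].
#' @return Character vector of reference windows, one per fragment.
#' @export
reference_window <- function(fragments, panel) {
  chars <- panel_chars(panel)
  Ls <- panel_lengths(panel)
  n <- nrow(fragments)
  out <- character(n)
  lens <- fragments$end - fragments$start
  minus <- fragments$strand == "-"
  for (ref in unique(fragments$reference_id)) {
    rows <- which(fragments$reference_id == ref)
    L <- Ls[[ref]]
    l <- lens[rows]
    m <- minus[rows]
    # descending raw positions for minus strand give the window already
    # reversed; one chartr() complement then yields molecule orientation
    raw <- sequence(l,
                    from = ifelse(m, fragments$end[rows],
                                  fragments$start[rows] + 1L),
                    by = ifelse(m, -1L, 1L))
    pos <- ((raw - 1L) %% L) + 1L
    bases <- chars[[ref]][pos]
    grp <- factor(rep.int(seq_along(rows), l), levels = seq_along(rows))
    w <- vapply(split(bases, grp), paste, character(1), collapse = "")
    w[m] <- chartr("ACGTN", "TGCAN", w[m])
    out[rows] <- w
  }
  out
}

#' Per-fragment substitution records
#'
#' Substitutions are recomputed from the read against the reference,
#' never trusted from a file. Bases are reported in molecule orientation
#' (a deamination event is C->T on either strand); `ref_pos` is the
#' 0-based reference coordinate, `off5`/`off3` the offsets from the
#' molecule 5' and 3' ends.
#'
#' @inheritParams reference_window
#' @return Data frame with columns `fragment_id`, `ref_pos`, `ref_base`,
#'   `read_base`, `off5`, `off3`.
#' @export
fragment_substitutions <- function(fragments, panel) {
  wins <- reference_window(fragments, panel)
  L <- panel_lengths(panel)
  res <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    rb <- strsplit(wins[i], "", fixed = TRUE)[[1]]
    qb <- strsplit(fragments$sequence[i], "", fixed = TRUE)[[1]]
    d <- which(rb != qb & rb != "N" & qb != "N")
    if (!length(d)) next
    len <- length(qb)
    off5 <- d - 1L
    refL <- L[[fragments$reference_id[i]]]
    ref_pos <- if (fragments$strand[i] == "+") {
      (fragments$start[i] + d - 1L) %% refL
    } else {
      (fragments$end[i] - d) %% refL
    }
    res[[i]] <- data.frame(
      fragment_id = fragments$fragment_id[i], ref_pos = ref_pos,
      ref_base = rb[d], read_base = qb[d],
      off5 = off5, off3 = len - d, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(fragment_id = character(), ref_pos = integer(),
                      ref_base = character(), read_base = character(),
                      off5 = integer(), off3 = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read fragments from the tab-separated exchange format
#'
#' Columns: `fragment_id`, `library_id`, `reference_id`, `start`, `end`,
#' `strand`, `sequence`, with a header line. Coordinates are 0-based
#' half-open.
#'
#' @param path Path to a TSV file.
#' @param panel The [reference_panel()] the fragments are aligned to.
#' @return An [aligned_fragments()] table.
#' @export
read_fragments <- function(path, panel) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  aligned_fragments(df, panel)
}

#' Write fragments to the tab-separated exchange format
#' @param fragments An [aligned_fragments()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(fragments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fragments from a SAM/BAM alignment
#'
#' Requires the Rsamtools package. Only ungapped alignments (CIGAR of a
#' single `M`/`=`/`X` run) are accepted, matching the aligned-fragment
#' model; 1-based SAM `POS` is converted to the package's 0-based
#' convention at this boundary. Minus-strand records are converted back
#' to molecule orientation (SAM stores reference-orientation SEQ).
#'
#' @param path Path to a SAM or BAM file.
#' @param panel The [reference_panel()] the fragments are aligned to.
#' @param library_id Library label to assign (SAM carries none here).
#' @return An [aligned_fragments()] table.
#' @export
read_fragments_sam <- function(path, panel, library_id = "lib1") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for SAM/BAM input")
  }
  if (!file.exists(path)) stop("file does not exist: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "strand", "seq", "cigar")
    )
  )[[1]]
  keep <- !is.na(rec$pos)
  cig <- rec$cigar[keep]
  if (any(!grepl("^[0-9]+[MX=]$", cig))) {
    stop("only ungapped single-run CIGAR alignments are supported")
  }
  seqs <- as.character(rec$seq)[keep]
  strand <- as.character(rec$strand)[keep]
  minus <- strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  df <- data.frame(
    fragment_id = rec$qname[keep], library_id = library_id,
    reference_id = as.character(rec$rname)[keep],
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + nchar(seqs),
    strand = strand, sequence = seqs, stringsAsFactors = FALSE
  )
  aligned_fragments(df, panel)
}
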