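#' Reference panel of family-level mitochondrial genomes
#'
#' A reference panel bundles one or more mitochondrial reference sequences,
#' each tagged with the biological family it represents and a flag marking
#' the genome as circular. Fragments are aligned and taxonomically binned
#' against this panel.
#'
#' @param ids Character vector of unique reference identifiers.
#' @param families Character vector of family labels, one per reference.
#' @param sequences Character vector of residue sequences over {A,C,G,T,N}.
#' @param circular Logical vector (recycled) marking circular genomes.
#'
#' @return An object of class `reference_panel`: a list with elements
#'   `ids`, `families`, `sequences` (named character) and `circular`.
#' @export
reference_panel <- function(ids, families, sequences, circular = TRUE) {
  ids <- as.character(ids)
  families <- as.character(families)
  sequences <- toupper(as.character(sequences))
  if (length(ids) == 0L) stop("reference panel must contain at least one entry")
  if (anyDuplicated(ids)) stop("reference ids must be unique")
  if (length(families) != length(ids) || length(sequences) != length(ids)) {
    stop("ids, families and sequences must have equal length")
  }
  if (any(nchar(sequences) == 0L)) stop("reference sequences must be non-empty")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("reference sequence contains characters outside {A,C,G,T,N}: ",
         paste(ids[bad], collapse = ", "))
  }
  circular <- rep_len(as.logical(circular), length(ids))
  names(sequences) <- ids
  structure(
    list(ids = ids, families = families, sequences = sequences,
         circular = circular),
    class = "reference_panel"
  )
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel:", length(x$ids), "sequence(s),",
      length(unique(x$families)), "family/families\n")
  df <- data.frame(id = x$ids, family = x$families,
                   length = nchar(x$sequences), circular = x$circular,
                   row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' @export
length.reference_panel <- function(x) length(x$ids)

#' Lengths of the panel references
#' @param panel A `reference_panel`.
#' @return Named integer vector of sequence lengths.
#' @export
panel_lengths <- function(panel) {
  stats::setNames(nchar(panel$sequences), panel$ids)
}

#' Family label for each reference id
#' @param panel A `reference_panel`.
#' @param ids Reference ids to look up.
#' @return Character vector of family labels.
#' @export
panel_family <- function(panel, ids) {
  idx <- match(ids, panel$ids)
  if (anyNA(idx)) stop("unknown reference id: ",
                       paste(unique(ids[is.na(idx)]), collapse = ", "))
  panel$families[idx]
}

#' Read a reference panel from FASTA
#'
#' Headers carry the family label as a `fam=<label>` key (delimiter
#' configurable), e.g. `>r1 fam=Cervidae`. Lowercase residues are
#' normalised to uppercase. A `circular=<true|false>` key is honoured and
#' defaults to circular, the mitochondrial case.
#'
#' @param path Path to a FASTA file.
#' @param family_key Header key holding the family label.
#' @return A [reference_panel()].
#' @export
read_fasta <- function(path, family_key = "fam") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  fam_pat <- paste0(".*\\b", family_key, "=([^\\s]+).*")
  has_fam <- grepl(paste0("\\b", family_key, "="), headers)
  if (!all(has_fam)) {
    stop("FASTA record without ", family_key, "= family label: ",
         ids[which(!has_fam)[1]])
  }
  families <- sub(fam_pat, "\\1", headers, perl = TRUE)
  circ <- rep(TRUE, length(ids))
  has_circ <- grepl("\\bcircular=", headers)
  circ[has_circ] <- tolower(sub(".*\\bcircular=([^\\s]+).*", "\\1",
                                headers[has_circ], perl = TRUE)) %in%
    c("true", "t", "1", "yes")
  if (anyDuplicated(ids)) {
    stop("duplicate reference id in ", path, ": ",
         ids[which(duplicated(ids))[1]])
  }
  reference_panel(ids, families, as.character(seqs), circ)
}

#' Write a reference panel to FASTA
#'
#' Inverse of [read_fasta()]; the round trip is lossless.
#'
#' @param panel A `reference_panel`.
#' @param path Output path.
#' @param family_key Header key to use for the family label.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(panel, path, family_key = "fam") {
  stopifnot(inherits(panel, "reference_panel"))
  headers <- sprintf("%s %s=%s circular=%s", panel$ids, family_key,
                     panel$families, tolower(as.character(panel$circular)))
  x <- Biostrings::DNAStringSet(panel$sequences)
  names(x) <- headers
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Extract a reference slice with circular unwrapping
#'
#' Returns the reference-orientation bases covered by `[start, end)`
#' (0-based half-open). For circular references the coordinates may run
#' past the sequence end (or be given as a fragment spanning the origin
#' with `start > end` resolved as `end + L`): positions are taken modulo
#' the reference length.
#'
#' @param panel A `reference_panel`.
#' @param ref_id Single reference id.
#' @param start,end 0-based half-open coordinates.
#' @return Character scalar of reference bases.
#' @export
reference_slice <- function(panel, ref_id, start, end) {
  idx <- match(ref_id, panel$ids)
  if (is.na(idx)) stop("unknown reference id: ", ref_id)
  L <- nchar(panel$sequences[[idx]])
  if (end <= start) stop("end must exceed start after unwrapping")
  if (start < 0L) stop("negative start coordinate")
  if (!panel$circular[idx] && end > L) {
    stop("coordinates outside linear reference ", ref_id)
  }
  if (end - start > L) stop("slice longer than reference ", ref_id)
  pos <- (seq.int(start, end - 1L) %% L) + 1L
  paste(strsplit(panel$sequences[[idx]], "", fixed = TRUE)[[1]][pos],
        collapse = "")
}
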