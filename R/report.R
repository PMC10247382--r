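#' Aggregate per-fraction family profiles into a report table
#'
#' Stacks the per-fraction profile tables and appends one `total` row
#' per family summing fragment counts and damage counts over fractions
#' (the tabular twin of a per-object taxonomic composition figure).
#'
#' @param profiles A data frame of profiles from [profile_families()],
#'   or a list of such data frames (one per fraction).
#' @return Data frame: the input rows plus rows with
#'   `fraction == "total"`.
#' @export
report_table <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  all <- do.call(rbind, lapply(profiles, as.data.frame))
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(fraction = character(), family = character(),
                      n_unique = integer(), positions_covered = integer(),
                      share_of_assigned = numeric(),
                      share_detected = numeric(), k5 = integer(),
                      n5 = integer(), k3 = integer(), n3 = integer(),
                      lower5 = numeric(), lower3 = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  totals <- lapply(split(all, all$family), function(d) {
    data.frame(fraction = "total", family = d$family[1],
               n_unique = sum(d$n_unique),
               positions_covered = NA_integer_,
               share_of_assigned = NA_real_, share_detected = NA_real_,
               k5 = sum(d$k5), n5 = sum(d$n5), k3 = sum(d$k3),
               n3 = sum(d$n3), lower5 = NA_real_, lower3 = NA_real_,
               status = NA_character_, stringsAsFactors = FALSE)
  })
  out <- rbind(all, do.call(rbind, totals))
  rownames(out) <- NULL
  out
}

#' Write the per-fraction, per-family report
#'
#' @param profiles As in [report_table()].
#' @param path Output TSV path.
#' @return The report data frame, invisibly.
#' @export
write_report <- function(profiles, path) {
  tab <- report_table(profiles)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to ", path)
  invisible(tab)
}

#' Read / write the pipeline configuration
#'
#' A single JSON file carries all tunable parameters and one global
#' random seed propagated to every stochastic operation.
#'
#' @param path Path to a JSON config file.
#' @return Named list of configuration values merged over defaults.
#' @export
read_config <- function(path) {
  defaults <- list(
    seed = 1L, max_mismatch_frac = 0.1, min_unique = 3L,
    min_positions = 105L, min_share = 0.01, damage_threshold = 0.10,
    ci_level = 0.95, min_coverage = 10L, majority = 0.75,
    min_informative = 5L, n_blocks = 20L
  )
  if (missing(path) || is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file does not exist: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(defaults, user)
}

#' @rdname read_config
#' @param config Named list to serialise.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
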