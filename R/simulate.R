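#' Terminal deamination model parameters
#'
#' Single-stranded library damage model: the probability that a cytosine
#' at offset `i` from a molecule end reads as thymine is
#' `baseline + d_max * exp(-lambda * i)`, contributions from the two
#' ends added and capped at 1. Both ends show C->T, as in
#' single-stranded library preparations; set `double_stranded = TRUE`
#' for the double-stranded variant (C->T at 5', G->A at 3').
#'
#' @param d_max Terminal C->T rate amplitude, in [0, 1].
#' @param lambda Exponential decay per base from the end, >= 0.
#' @param baseline Offset-independent C->T rate, >= 0.
#' @param eps Per-base sequencing error rate (substitution to a
#'   uniformly chosen different base).
#' @param double_stranded Use the double-stranded damage signature.
#' @return A list of class `damage_params`.
#' @export
damage_params <- function(d_max = 0.4, lambda = 0.3, baseline = 0.01,
                          eps = 0.001, double_stranded = FALSE) {
  stopifnot(d_max >= 0, d_max <= 1, lambda >= 0, baseline >= 0,
            eps >= 0, eps <= 1)
  structure(list(d_max = d_max, lambda = lambda, baseline = baseline,
                 eps = eps, double_stranded = double_stranded),
            class = "damage_params")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# default family labels for simulated panels
.families <- c("Cervidae", "Elephantidae", "Ursidae", "Bovidae",
               "Equidae", "Hyaenidae", "Felidae", "Canidae")

#' Simulate a reference panel with a human haplotype pair
#'
#' Generates one random circular mitochondrial-like reference per
#' non-human family, plus a Hominidae pair created with
#' [make_human_pair()]: an endogenous haplotype (panel id
#' `"human_endo"`) and a contaminant haplotype (`"human_cont"`)
#' differing at `n_diag` diagnostic positions. Independent random
#' references diverge at roughly 75% of sites, far above any realistic
#' family-divergence floor.
#'
#' @param n_families Number of non-human families (>= 1).
#' @param length Reference length in bp (>= 1000).
#' @param seed Integer seed; same seed, same panel.
#' @param n_diag Number of human diagnostic positions.
#' @return List with `panel` (a [reference_panel()] including both human
#'   haplotypes), `human` (the [make_human_pair()] result) and
#'   `families` (the non-human family labels).
#' @export
make_panel <- function(n_families, length = 16000L, seed = 1L,
                       n_diag = 7L) {
  if (n_families < 1) stop("n_families must be >= 1")
  if (length < 1000) stop("reference length must be >= 1000")
  set.seed(seed)
  fams <- if (n_families <= length(.families)) .families[seq_len(n_families)]
          else paste0("Family", seq_len(n_families))
  seqs <- vapply(fams, function(f) random_dna(length), character(1))
  human_ref <- random_dna(length)
  pair <- make_human_pair(human_ref, n_diag = n_diag,
                          seed = sample.int(2^30, 1))
  panel <- reference_panel(
    ids = c(paste0("ref_", fams), "human_endo", "human_cont"),
    families = c(fams, "Hominidae", "Hominidae"),
    sequences = c(unname(seqs), pair$endogenous, pair$contaminant),
    circular = TRUE
  )
  list(panel = panel, human = pair, families = fams)
}

#' Create an endogenous/contaminant human haplotype pair
#'
#' Mutates the reference at `n_diag` well-spaced positions to obtain a
#' contaminant haplotype; the endogenous haplotype is the reference
#' itself. The two differ at exactly the diagnostic positions, whose
#' truth table (position, endogenous and contaminant alleles, whether
#' the difference is damage-ambiguous, i.e. C<->T or G<->A) is
#' returned.
#'
#' @param reference Residue string used as the endogenous haplotype.
#' @param n_diag Number of diagnostic positions (>= 1).
#' @param seed Integer seed.
#' @param min_spacing Minimum distance between diagnostic positions.
#' @return List with `endogenous`, `contaminant`, and `diagnostics`
#'   (data frame: `pos` 0-based, `endo`, `cont`, `damage_ambiguous`).
#' @export
make_human_pair <- function(reference, n_diag = 7L, seed = 1L,
                            min_spacing = 100L) {
  if (n_diag < 1) stop("n_diag must be >= 1")
  L <- nchar(reference)
  if (n_diag * min_spacing > L) {
    stop("n_diag diagnostic positions cannot be spaced >= ", min_spacing,
         " bp apart on a ", L, " bp reference")
  }
  set.seed(seed)
  # rejection-sample spaced positions
  for (try in 1:1000) {
    pos <- sort(sample.int(L, n_diag)) - 1L
    if (n_diag == 1L || min(diff(pos)) >= min_spacing) break
    if (try == 1000) stop("could not place spaced diagnostic positions")
  }
  endo <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  cont <- endo
  for (i in seq_along(pos)) {
    cont[pos[i] + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                        endo[pos[i] + 1L]), 1L)
  }
  amb <- (endo[pos + 1L] == "C" & cont[pos + 1L] == "T") |
    (endo[pos + 1L] == "T" & cont[pos + 1L] == "C") |
    (endo[pos + 1L] == "G" & cont[pos + 1L] == "A") |
    (endo[pos + 1L] == "A" & cont[pos + 1L] == "G")
  list(endogenous = paste(endo, collapse = ""),
       contaminant = paste(cont, collapse = ""),
       diagnostics = data.frame(pos = pos, endo = endo[pos + 1L],
                                cont = cont[pos + 1L],
                                damage_ambiguous = amb,
                                stringsAsFactors = FALSE))
}

#' Fraction composition
#'
#' Describes the expected mixture of sources in one extraction
#' fraction. Each source has a label, the family and panel reference it
#' aligns to, whether its molecules carry ancient-DNA damage, its
#' expected share, and optionally the true template sequence when it
#' differs from the alignment reference (the human contaminant aligns
#' to the endogenous reference but derives from the contaminant
#' haplotype).
#'
#' @param labels,ref_ids,damaged,shares Parallel vectors describing the
#'   sources.
#' @param source_seqs Optional named list (by label) of template
#'   sequences overriding the panel reference.
#' @return Data frame of class `fraction_composition`.
#' @export
fraction_composition <- function(labels, ref_ids, damaged, shares,
                                 source_seqs = list()) {
  shares <- as.numeric(shares)
  if (any(shares < 0)) stop("shares must be >= 0")
  if (abs(sum(shares) - 1) > 1e-8) stop("shares must sum to 1")
  df <- data.frame(label = labels, ref_id = ref_ids,
                   damaged = as.logical(damaged), share = shares,
                   stringsAsFactors = FALSE)
  attr(df, "source_seqs") <- source_seqs
  class(df) <- c("fraction_composition", "data.frame")
  df
}

#' Default composition emulating one extraction fraction
#'
#' A convenience wrapper around [fraction_composition()] for panels made
#' by [make_panel()]: an ancient (damaged) component per requested
#' family, a damaged endogenous human component, and an undamaged
#' present-day human contaminant derived from the contaminant haplotype
#' but aligned to the endogenous reference.
#'
#' @param sim A [make_panel()] result.
#' @param family_shares Named numeric vector of shares for ancient
#'   family components (names among `sim$families`).
#' @param endo_share Share of damaged endogenous human fragments.
#' @param cont_share Share of undamaged contaminant human fragments.
#' @return A [fraction_composition()].
#' @export
default_composition <- function(sim, family_shares, endo_share,
                                cont_share) {
  stopifnot(all(names(family_shares) %in% sim$families))
  fraction_composition(
    labels = c(names(family_shares), "human_endogenous",
               "human_contaminant"),
    ref_ids = c(paste0("ref_", names(family_shares)), "human_endo",
                "human_endo"),
    damaged = c(rep(TRUE, length(family_shares)), TRUE, FALSE),
    shares = c(unname(family_shares), endo_share, cont_share),
    source_seqs = list(human_contaminant = sim$human$contaminant)
  )
}

# p(C->T) at molecule offsets off5/off3 under the additive capped model
ct_prob <- function(off5, off3, dp) {
  pmin(1, dp$baseline + dp$d_max * exp(-dp$lambda * off5) +
         dp$d_max * exp(-dp$lambda * off3))
}

# apply terminal deamination to one molecule-orientation base vector
apply_damage <- function(bases, dp) {
  n <- length(bases)
  off5 <- seq_len(n) - 1L
  off3 <- n - seq_len(n)
  p <- ct_prob(off5, off3, dp)
  hit <- stats::runif(n) < p
  if (dp$double_stranded) {
    # C->T driven from the 5' end, G->A from the 3' end
    p5 <- pmin(1, dp$baseline + dp$d_max * exp(-dp$lambda * off5))
    p3 <- pmin(1, dp$baseline + dp$d_max * exp(-dp$lambda * off3))
    ct <- bases == "C" & stats::runif(n) < p5
    ga <- bases == "G" & stats::runif(n) < p3
    bases[ct] <- "T"
    bases[ga] <- "A"
    return(bases)
  }
  bases[bases == "C" & hit] <- "T"
  bases
}

# uniform substitution error: each base replaced by a different base w.p. eps
apply_seq_error <- function(bases, eps) {
  if (eps <= 0) return(bases)
  hit <- which(stats::runif(length(bases)) < eps)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  bases
}

#' Simulate one extraction fraction of aligned fragments
#'
#' Draws fragment sources from the composition, fragment lengths from a
#' shifted geometric (default, mean 55 nt, minimum 30 nt) or lognormal
#' distribution, uniform start positions on the (circular) alignment
#' reference and random strands. Damaged sources receive terminal C->T
#' deamination per [damage_params()]; all sources receive sequencing
#' error `eps`. A truth table records each fragment's source and
#' damaged flag; no downstream analysis reads it.
#'
#' @param panel A [reference_panel()].
#' @param composition A [fraction_composition()].
#' @param damage A [damage_params()].
#' @param n_fragments Number of fragments to draw (> 0).
#' @param length_dist List: `type` ("geometric" or "lognormal") plus
#'   `mean`, `min` (geometric) or `meanlog`, `sdlog`, `min`
#'   (lognormal).
#' @param seed Integer seed.
#' @param library_id Library label stored on the fragments.
#' @return List with `fragments` (an [aligned_fragments()] table) and
#'   `truth` (data frame: `fragment_id`, `label`, `family`, `damaged`).
#' @export
simulate_fraction <- function(panel, composition, damage, n_fragments,
                              length_dist = list(type = "geometric",
                                                 mean = 55, min = 30),
                              seed = 1L, library_id = "lib1") {
  if (n_fragments <= 0) stop("n_fragments must be > 0")
  stopifnot(inherits(panel, "reference_panel"),
            inherits(damage, "damage_params"))
  set.seed(seed)
  src_idx <- sample.int(nrow(composition), n_fragments, replace = TRUE,
                        prob = composition$share)
  lens <- switch(
    length_dist$type,
    geometric = length_dist$min +
      stats::rgeom(n_fragments,
                   prob = 1 / (length_dist$mean - length_dist$min + 1)),
    lognormal = pmax(length_dist$min,
                     round(stats::rlnorm(n_fragments, length_dist$meanlog,
                                         length_dist$sdlog))),
    stop("unknown length distribution type: ", length_dist$type)
  )
  source_seqs <- attr(composition, "source_seqs")
  Ls <- panel_lengths(panel)
  tmpl_chars <- new.env(parent = emptyenv())
  get_template <- function(label, ref_id) {
    key <- paste0(label, "\r", ref_id)
    if (!is.null(tmpl_chars[[key]])) return(tmpl_chars[[key]])
    s <- if (!is.null(source_seqs[[label]])) source_seqs[[label]]
         else panel$sequences[[ref_id]]
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    tmpl_chars[[key]] <- v
    v
  }
  seqs <- character(n_fragments)
  starts <- integer(n_fragments)
  strands <- sample(c("+", "-"), n_fragments, replace = TRUE)
  lab_v <- composition$label[src_idx]
  ref_v <- composition$ref_id[src_idx]
  dam_v <- composition$damaged[src_idx]
  comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (i in seq_len(n_fragments)) {
    tmpl <- get_template(lab_v[i], ref_v[i])
    L <- Ls[[ref_v[i]]]
    len <- min(lens[i], L)
    lens[i] <- len
    start <- sample.int(L, 1L) - 1L  # circular: any start
    pos <- ((start + seq_len(len) - 1L) %% L) + 1L
    bases <- tmpl[pos]
    if (strands[i] == "-") bases <- rev(comp_map[bases])
    if (dam_v[i]) bases <- apply_damage(bases, damage)
    bases <- apply_seq_error(bases, damage$eps)
    seqs[i] <- paste(bases, collapse = "")
    starts[i] <- start
  }
  ids <- sprintf("frag%06d", seq_len(n_fragments))
  frags <- aligned_fragments(data.frame(
    fragment_id = ids, library_id = library_id,
    reference_id = composition$ref_id[src_idx],
    start = starts, end = starts + lens, strand = strands,
    sequence = seqs, stringsAsFactors = FALSE
  ), panel)
  fam <- panel_family(panel, composition$ref_id)
  truth <- data.frame(fragment_id = ids,
                      label = composition$label[src_idx],
                      family = fam[src_idx],
                      damaged = composition$damaged[src_idx],
                      stringsAsFactors = FALSE)
  list(fragments = frags, truth = truth)
}

#' Population graph specification
#'
#' A rooted population tree given as an edge table with per-branch
#' drift, plus at most one admixture edge. Drift along a branch follows
#' the Balding-Nichols model: a child's allele frequency is a Beta draw
#' with mean the parent frequency and variance `p(1-p)F`.
#'
#' @param edges Data frame with columns `parent`, `child`, `F`
#'   (drift in (0, 1); use something tiny like 1e-6 for "no drift").
#' @param outgroup Name of the designated outgroup leaf.
#' @param admixture Optional list `(source, target, alpha)`: leaf
#'   `target`'s frequency becomes `(1-alpha) * tree + alpha * source`.
#' @return A list of class `graph_spec` with `edges`, `outgroup`,
#'   `admixture`, `root`, `leaves`.
#' @export
graph_spec <- function(edges, outgroup, admixture = NULL) {
  stopifnot(all(c("parent", "child", "F") %in% names(edges)))
  if (any(edges$F <= 0 | edges$F >= 1)) {
    stop("drift F must lie strictly in (0, 1)")
  }
  nodes <- unique(c(edges$parent, edges$child))
  root <- setdiff(edges$parent, edges$child)
  if (length(root) != 1L) stop("graph must have exactly one root")
  leaves <- setdiff(edges$child, edges$parent)
  if (!outgroup %in% leaves) stop("outgroup must be a leaf")
  if (!is.null(admixture)) {
    stopifnot(all(c("source", "target", "alpha") %in% names(admixture)))
    if (admixture$alpha < 0 || admixture$alpha > 1) {
      stop("admixture proportion alpha must lie in [0, 1]")
    }
    if (!admixture$target %in% leaves) stop("admixture target must be a leaf")
    if (!admixture$source %in% nodes) stop("unknown admixture source node")
  }
  structure(list(edges = edges, outgroup = outgroup,
                 admixture = admixture, root = root, leaves = leaves),
            class = "graph_spec")
}

#' Simulate genotypes under a drift/admixture graph
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95) per site; each
#' branch transforms the frequency by a Balding-Nichols Beta draw with
#' its drift parameter; an optional admixture edge mixes a leaf's
#' frequency with another node's. Diploid genotypes are sampled
#' binomially for `n_ind` individuals per leaf and stored as per-group
#' allele counts.
#'
#' @param graph A [graph_spec()].
#' @param n_sites Number of biallelic sites.
#' @param seed Integer seed.
#' @param n_ind Diploid individuals sampled per leaf population.
#' @return A [genotype_matrix()] whose groups are the graph's leaves,
#'   with attribute `truth` holding the graph and the per-leaf
#'   frequencies.
#' @export
simulate_genotypes <- function(graph, n_sites, seed = 1L, n_ind = 10L) {
  stopifnot(inherits(graph, "graph_spec"), n_sites >= 1)
  set.seed(seed)
  p0 <- stats::runif(n_sites, 0.05, 0.95)
  freq <- list()
  freq[[graph$root]] <- p0
  # edges are drifted in topological order from the root
  remaining <- graph$edges
  while (nrow(remaining)) {
    ready <- remaining$parent %in% names(freq)
    if (!any(ready)) stop("graph edges are not a connected rooted tree")
    for (j in which(ready)) {
      p <- freq[[remaining$parent[j]]]
      F <- remaining$F[j]
      if (F < 1e-9) {
        freq[[remaining$child[j]]] <- p
      } else {
        a <- p * (1 - F) / F
        b <- (1 - p) * (1 - F) / F
        freq[[remaining$child[j]]] <- stats::rbeta(n_sites, a, b)
      }
    }
    remaining <- remaining[!ready, , drop = FALSE]
  }
  if (!is.null(graph$admixture)) {
    adm <- graph$admixture
    freq[[adm$target]] <- (1 - adm$alpha) * freq[[adm$target]] +
      adm$alpha * freq[[adm$source]]
  }
  leaves <- graph$leaves
  alt <- sapply(leaves, function(l) {
    stats::rbinom(n_sites, 2L * n_ind, freq[[l]])
  })
  tot <- matrix(2L * n_ind, n_sites, length(leaves),
                dimnames = list(NULL, leaves))
  sites <- data.frame(chrom = "1", pos = seq_len(n_sites),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, alt, tot)
  attr(gm, "truth") <- list(graph = graph, freq = freq[leaves])
  gm
}

#' Simulate X and autosomal fragment counts
#'
#' Fragment counts over SNP sites are Poisson with mean proportional to
#' ploidy x mean depth x number of sites: an XX individual carries two
#' X copies, an XY individual one.
#'
#' @param sites_X,sites_aut Numbers of X-linked and autosomal SNP sites.
#' @param karyotype `"XX"` or `"XY"`.
#' @param mean_depth Mean fragment depth per diploid site.
#' @param seed Integer seed.
#' @return List with `nX`, `nAut`, `sites_X`, `sites_aut` and the truth
#'   `karyotype`.
#' @export
simulate_sex_counts <- function(sites_X, sites_aut,
                                karyotype = c("XX", "XY"),
                                mean_depth = 5, seed = 1L) {
  karyotype <- match.arg(karyotype)
  if (sites_X <= 0 || sites_aut <= 0) stop("site counts must be > 0")
  set.seed(seed)
  ploidy_x <- if (karyotype == "XX") 2 else 1
  nX <- stats::rpois(1L, mean_depth * sites_X * ploidy_x / 2)
  nAut <- stats::rpois(1L, mean_depth * sites_aut)
  list(nX = nX, nAut = nAut, sites_X = sites_X, sites_aut = sites_aut,
       karyotype = karyotype)
}

#' Simulate a dated mitochondrial alignment under a strict clock
#'
#' From a random root sequence, each tip accumulates
#' `Poisson(rate x (root_age - tip_age) x seq_len)` substitutions at
#' uniformly chosen sites. An outgroup diverged `outgroup_extra` years
#' before the root is included, and an optional undated query tip of
#' known true age. Ages are years before present.
#'
#' @param rate Substitution rate per site per year.
#' @param tip_ages Named numeric vector of dated tip ages.
#' @param seq_len Alignment length in bp.
#' @param seed Integer seed.
#' @param root_age Age of the root; default `2 * max(tip_ages)`.
#' @param query_age Optional true age of an undated query tip.
#' @param outgroup_extra Extra divergence time of the outgroup beyond
#'   the root, in years.
#' @return A list of class `dated_alignment`: `seqs` (named character),
#'   `ages` (named; `NA` for query and outgroup), `query`, `outgroup`,
#'   and `truth` (`rate`, `root_age`, `query_age`).
#' @export
simulate_clock_alignment <- function(rate, tip_ages, seq_len, seed = 1L,
                                     root_age = NULL, query_age = NULL,
                                     outgroup_extra = NULL) {
  stopifnot(rate >= 0, seq_len >= 1, length(tip_ages) >= 1,
            !is.null(names(tip_ages)))
  if (is.null(root_age)) root_age <- 2 * max(tip_ages, query_age, 1)
  if (any(tip_ages > root_age)) stop("tip age exceeds root age")
  if (!is.null(query_age) && query_age > root_age) {
    stop("query age exceeds root age")
  }
  if (is.null(outgroup_extra)) outgroup_extra <- 2 * root_age
  set.seed(seed)
  root <- strsplit(random_dna(seq_len), "", fixed = TRUE)[[1]]
  evolve <- function(time) {
    n_sub <- stats::rpois(1L, rate * time * seq_len)
    s <- root
    if (n_sub > 0) {
      at <- sample.int(seq_len, n_sub, replace = TRUE)
      for (i in at) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
    }
    paste(s, collapse = "")
  }
  seqs <- c(outgroup = evolve(root_age + 2 * outgroup_extra))
  ages <- c(outgroup = NA_real_)
  for (nm in names(tip_ages)) {
    seqs[nm] <- evolve(root_age - tip_ages[[nm]])
    ages[nm] <- tip_ages[[nm]]
  }
  query <- NULL
  if (!is.null(query_age)) {
    seqs["query"] <- evolve(root_age - query_age)
    ages["query"] <- NA_real_
    query <- "query"
  }
  structure(list(seqs = seqs, ages = ages, query = query,
                 outgroup = "outgroup",
                 truth = list(rate = rate, root_age = root_age,
                              query_age = query_age)),
            class = "dated_alignment")
}
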