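#' Genotype matrix of per-group allele counts
#'
#' Sites by groups container for f-statistics, PCA and sex inference:
#' a site table (`chrom`, `pos`, `ref`, `alt`) plus two matrices of
#' alternative-allele counts and total allele counts per group.
#' Missing data in a group is encoded as total 0.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`;
#'   positions strictly increasing within each chromosome.
#' @param alt,tot Numeric matrices, sites x groups, with
#'   `0 <= alt <= tot`; identical column names.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, alt, tot) {
  alt <- as.matrix(alt); tot <- as.matrix(tot)
  stopifnot(nrow(sites) == nrow(alt), dim(alt)[2] == dim(tot)[2],
            nrow(alt) == nrow(tot))
  if (is.null(colnames(alt))) stop("alt matrix needs group column names")
  colnames(tot) <- colnames(alt)
  if (any(alt < 0 | alt > tot)) stop("need 0 <= alt <= total")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  structure(list(sites = as.data.frame(sites), alt = alt, tot = tot),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$sites), "sites x",
      ncol(x$alt), "groups (", paste(colnames(x$alt), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Groups of a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Character vector of group names.
#' @export
gm_groups <- function(gm) colnames(gm$alt)

# per-group allele frequency; NA where total = 0
gm_freq <- function(gm, group) {
  a <- gm$alt[, group]; t <- gm$tot[, group]
  ifelse(t > 0, a / t, NA_real_)
}

#' Read an EIGENSTRAT genotype triplet
#'
#' `.geno` holds one line per SNP with one character per individual;
#' codes are taken as counts of the alternative allele (0/1/2, 9 =
#' missing). `.snp` columns: id, chromosome, genetic position,
#' physical position, ref allele, alt allele. `.ind` columns: id, sex,
#' population. Individuals are collapsed into per-population allele
#' counts; the individual-level codes are kept in attributes so the
#' round trip through [write_eigenstrat()] is lossless.
#'
#' @param geno,snp,ind Paths to the three files.
#' @return A [genotype_matrix()] grouped by population, with
#'   attributes `ind` (the individual table) and `codes` (sites x
#'   individuals integer matrix).
#' @export
read_eigenstrat <- function(geno, snp, ind) {
  for (p in c(geno, snp, ind)) {
    if (!file.exists(p)) stop("file does not exist: ", p)
  }
  ind_df <- utils::read.table(ind, col.names = c("id", "sex", "pop"),
                              stringsAsFactors = FALSE)
  snp_df <- utils::read.table(snp, stringsAsFactors = FALSE)
  if (ncol(snp_df) < 6L) stop("snp file needs 6 columns: ", snp)
  names(snp_df)[1:6] <- c("id", "chrom", "genpos", "pos", "ref", "alt")
  glines <- readLines(geno)
  if (length(glines) != nrow(snp_df)) {
    stop("geno has ", length(glines), " lines but snp lists ",
         nrow(snp_df), " sites: ", geno)
  }
  nc <- nchar(glines)
  if (any(nc != nrow(ind_df))) {
    stop("geno line ", which(nc != nrow(ind_df))[1], " has ",
         nc[which(nc != nrow(ind_df))[1]], " genotypes but ind lists ",
         nrow(ind_df), " individuals: ", geno)
  }
  codes <- matrix(
    as.integer(unlist(strsplit(glines, "", fixed = TRUE))),
    nrow = length(glines), byrow = TRUE
  )
  if (any(!codes %in% c(0L, 1L, 2L, 9L))) {
    stop("geno codes must be 0, 1, 2 or 9: ", geno)
  }
  pops <- unique(ind_df$pop)
  alt <- sapply(pops, function(p) {
    cols <- which(ind_df$pop == p)
    m <- codes[, cols, drop = FALSE]
    rowSums(ifelse(m == 9L, 0L, m))
  })
  tot <- sapply(pops, function(p) {
    cols <- which(ind_df$pop == p)
    m <- codes[, cols, drop = FALSE]
    2L * rowSums(m != 9L)
  })
  if (nrow(snp_df) == 1L) {  # sapply drops to vector for one site
    alt <- matrix(alt, nrow = 1L, dimnames = list(NULL, pops))
    tot <- matrix(tot, nrow = 1L, dimnames = list(NULL, pops))
  }
  sites <- snp_df[, c("chrom", "pos", "ref", "alt")]
  sites$chrom <- as.character(sites$chrom)
  gm <- genotype_matrix(sites, alt, tot)
  attr(gm, "ind") <- ind_df
  attr(gm, "codes") <- codes
  attr(gm, "snp_ids") <- snp_df$id
  attr(gm, "genpos") <- snp_df$genpos
  gm
}

#' Write an EIGENSTRAT genotype triplet
#'
#' Requires a matrix read by [read_eigenstrat()] (or carrying the same
#' individual-level attributes); the round trip is bit-exact.
#'
#' @param gm A `genotype_matrix` with `ind`/`codes` attributes.
#' @param geno,snp,ind Output paths.
#' @return Invisibly, the three paths.
#' @export
write_eigenstrat <- function(gm, geno, snp, ind) {
  codes <- attr(gm, "codes")
  ind_df <- attr(gm, "ind")
  if (is.null(codes) || is.null(ind_df)) {
    stop("matrix lacks individual-level codes; cannot write EIGENSTRAT")
  }
  writeLines(apply(codes, 1L, paste, collapse = ""), geno)
  ids <- attr(gm, "snp_ids")
  if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(gm$sites)))
  genpos <- attr(gm, "genpos")
  if (is.null(genpos)) genpos <- 0
  utils::write.table(
    data.frame(ids, gm$sites$chrom, genpos, gm$sites$pos,
               gm$sites$ref, gm$sites$alt),
    snp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(ind_df, ind, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(geno = geno, snp = snp, ind = ind))
}

#' Pseudo-haploidise one group
#'
#' Standard practice for a low-coverage ancient individual: at every
#' site with data, one allele is drawn at random with probability
#' proportional to the observed counts, leaving total 1 (missing sites
#' stay missing). Allele frequencies are preserved in expectation.
#'
#' @param gm A `genotype_matrix`.
#' @param group Group to pseudo-haploidise.
#' @param seed Integer seed.
#' @return The modified `genotype_matrix`.
#' @export
pseudo_haploid <- function(gm, group, seed = 1L) {
  if (!group %in% gm_groups(gm)) stop("unknown group: ", group)
  set.seed(seed)
  a <- gm$alt[, group]; t <- gm$tot[, group]
  has <- t > 0
  draw <- stats::rbinom(sum(has), 1L, a[has] / t[has])
  gm$alt[has, group] <- draw
  gm$tot[has, group] <- 1L
  gm
}

#' Weighted block jackknife standard error
#'
#' Sites are split into `n_blocks` contiguous blocks of (as near as
#' possible) equal size; the statistic is the ratio
#' `sum(values) / sum(weights)`. The delete-one-block variance follows
#' Busing et al. (1999), which reduces to the textbook delete-1
#' jackknife when all blocks carry equal weight.
#'
#' @param values Per-site numerator contributions.
#' @param weights Per-site denominator contributions (use 1s for a
#'   plain mean).
#' @param n_blocks Number of contiguous blocks (>= 2).
#' @return List with `se`, `estimate`, `n_blocks` (after capping at
#'   the number of sites).
#' @export
block_jackknife <- function(values, weights = rep(1, length(values)),
                            n_blocks = 20L) {
  if (n_blocks < 2L) stop("n_blocks must be >= 2")
  n <- length(values)
  stopifnot(length(weights) == n, n >= 2L)
  n_blocks <- min(n_blocks, n)
  block <- factor(ceiling(seq_len(n) / (n / n_blocks)),
                  levels = seq_len(n_blocks))
  theta <- sum(values) / sum(weights)
  tv <- sum(values); tw <- sum(weights)
  bv <- as.numeric(tapply(values, block, sum))
  bw <- as.numeric(tapply(weights, block, sum))
  theta_j <- (tv - bv) / (tw - bw)
  m_j <- tabulate(block, nbins = n_blocks)
  h_j <- n / m_j
  g <- n_blocks
  theta_dot <- g * theta - sum((1 - 1 / h_j) * theta_j)
  tau <- h_j * theta - (h_j - 1) * theta_j
  var_hat <- sum((tau - theta_dot)^2 / (h_j - 1)) / g
  list(se = sqrt(var_hat), estimate = theta, n_blocks = g)
}

fstat_result <- function(stat, args, value, se, n_blocks, n_sites) {
  structure(list(stat = stat, args = args, value = value, se = se,
                 z = if (!is.na(se) && se > 0) value / se else NA_real_,
                 n_blocks = n_blocks, n_sites = n_sites),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6f  SE %.6f  Z %.2f  (%d sites, %d blocks)\n",
              x$stat, paste(x$args, collapse = ", "), x$value, x$se,
              x$z, x$n_sites, x$n_blocks))
  invisible(x)
}

#' Outgroup f3 statistic
#'
#' `f3(C; A, B) = mean over sites of (c - a)(c - b)` with per-site
#' allele frequencies `a`, `b`, `c`; for an outgroup/target `C` it
#' measures the shared genetic drift of `A` and `B` relative to `C`.
#' Standard error by weighted block jackknife over contiguous site
#' blocks. Left unnormalised (no target-heterozygosity denominator;
#' rankings among outgroup-f3 values are unaffected).
#'
#' @param gm A `genotype_matrix`.
#' @param C,A,B Group names: target, and the two compared groups.
#' @param n_blocks Jackknife blocks.
#' @return An `fstat_result`.
#' @export
f3 <- function(gm, C, A, B, n_blocks = 20L) {
  a <- gm_freq(gm, A); b <- gm_freq(gm, B); c <- gm_freq(gm, C)
  use <- !is.na(a) & !is.na(b) & !is.na(c)
  if (!any(use)) stop("no sites with data in all three groups")
  terms <- (c[use] - a[use]) * (c[use] - b[use])
  if (length(terms) < 2L) {
    return(fstat_result("f3", c(C = C, A = A, B = B), mean(terms),
                        NA_real_, 0L, sum(use)))
  }
  jk <- block_jackknife(terms, rep(1, length(terms)), n_blocks)
  fstat_result("f3", c(C = C, A = A, B = B), jk$estimate, jk$se,
               jk$n_blocks, sum(use))
}

#' ABBA-BABA D statistic
#'
#' `D(W, X; Y, Z) = sum (w - x)(y - z) / sum (w + x - 2wx)(y + z -
#' 2yz)` over sites with data in all four groups; 0 in expectation
#' when (W, X) are a clade unaffected by gene flow from (Y, Z).
#' Jackknife SE over contiguous blocks of the ratio estimator.
#'
#' @param gm A `genotype_matrix`.
#' @param W,X,Y,Z Group names.
#' @param n_blocks Jackknife blocks.
#' @return An `fstat_result`.
#' @export
dstat <- function(gm, W, X, Y, Z, n_blocks = 20L) {
  w <- gm_freq(gm, W); x <- gm_freq(gm, X)
  y <- gm_freq(gm, Y); z <- gm_freq(gm, Z)
  use <- !is.na(w) & !is.na(x) & !is.na(y) & !is.na(z)
  if (!any(use)) stop("no sites with data in all four groups")
  num <- (w[use] - x[use]) * (y[use] - z[use])
  den <- (w[use] + x[use] - 2 * w[use] * x[use]) *
    (y[use] + z[use] - 2 * y[use] * z[use])
  if (sum(den) == 0) stop("D statistic denominator is zero at all sites")
  if (length(num) < 2L) {
    return(fstat_result("D", c(W = W, X = X, Y = Y, Z = Z),
                        sum(num) / sum(den), NA_real_, 0L, sum(use)))
  }
  jk <- block_jackknife(num, den, n_blocks)
  fstat_result("D", c(W = W, X = X, Y = Y, Z = Z), jk$estimate, jk$se,
               jk$n_blocks, sum(use))
}

#' Project a partially missing sample onto reference principal components
#'
#' Reference individuals (complete at the used sites) are centred by
#' twice the allele frequency and scaled by `sqrt(p(1-p))`; principal
#' components come from the singular value decomposition. The sample
#' (genotypes 0/1/2 with NA for missing) is projected by least squares
#' restricted to its non-missing sites — the usual projection for
#' low-coverage ancient individuals (no shrinkage correction).
#'
#' @param ref_geno Reference genotype matrix, individuals x sites,
#'   values 0/1/2, no missingness.
#' @param sample_geno Numeric vector of length `ncol(ref_geno)` with NA
#'   at missing sites. May also be a matrix of several samples (rows).
#' @param n_pcs Number of components returned.
#' @return List with `reference` (individuals x n_pcs coordinates),
#'   `samples` (rows x n_pcs), `sdev` (singular values / sqrt(n-1)).
#' @export
pca_project <- function(ref_geno, sample_geno, n_pcs = 2L) {
  ref_geno <- as.matrix(ref_geno)
  if (is.null(dim(sample_geno))) {
    sample_geno <- matrix(sample_geno, nrow = 1L)
  }
  stopifnot(ncol(sample_geno) == ncol(ref_geno))
  p <- colMeans(ref_geno) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic sites in the reference")
  ref <- ref_geno[, keep, drop = FALSE]
  smp <- sample_geno[, keep, drop = FALSE]
  p <- p[keep]
  sc <- sqrt(p * (1 - p))
  X <- sweep(sweep(ref, 2L, 2 * p), 2L, sc, "/")
  sv <- svd(X)
  n_pcs <- min(n_pcs, length(sv$d))
  ref_coord <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  V <- sv$v[, seq_len(n_pcs), drop = FALSE]
  smp_coord <- matrix(NA_real_, nrow(smp), n_pcs)
  for (i in seq_len(nrow(smp))) {
    obs <- !is.na(smp[i, ])
    if (!any(obs)) stop("sample ", i, " is missing at every used site")
    yv <- (smp[i, obs] - 2 * p[obs]) / sc[obs]
    smp_coord[i, ] <- stats::lsfit(V[obs, , drop = FALSE], yv,
                                   intercept = FALSE)$coefficients
  }
  rownames(ref_coord) <- rownames(ref_geno)
  list(reference = ref_coord, samples = smp_coord,
       sdev = sv$d / sqrt(max(1, nrow(ref) - 1)))
}

#' Genetic sex from X versus autosomal fragment counts
#'
#' The ratio `R = nX / (nX + nAut)` carries an exact binomial interval;
#' its expectation is `sX / (sX + sA)` for an XX karyotype (two X
#' copies) and `sX / (sX + 2 sA)` for XY (one X copy), with `sX`/`sA`
#' the numbers of X and autosomal SNP sites. The call is whichever
#' expectation falls inside the calling interval; both or neither
#' inside gives `indeterminate`.
#'
#' The reported interval uses `level` (0.95, matching the error bars
#' one would plot); the karyotype call itself uses the stricter
#' `call_level`, because with the large fragment counts typical of SNP
#' capture a 95% interval excludes the true expectation in ~5% of
#' datasets — an unacceptable indeterminate rate for a binary call
#' whose two alternatives lie many interval-widths apart.
#'
#' @param nX,nAut Fragment counts over X-linked and autosomal sites.
#' @param sites_X,sites_aut Numbers of targeted sites.
#' @param level Confidence level of the reported interval.
#' @param call_level Confidence level used for the karyotype call.
#' @return List of class `sex_assignment`: `ratio`, `ci`,
#'   `expected_XX`, `expected_XY`, `call`.
#' @export
infer_sex <- function(nX, nAut, sites_X, sites_aut, level = 0.95,
                      call_level = 0.999) {
  if (sites_X <= 0 || sites_aut <= 0) stop("site counts must be > 0")
  if (nX < 0 || nAut < 0) stop("counts must be >= 0")
  if (nX + nAut == 0) stop("no fragments to infer sex from")
  ci <- clopper_pearson(nX, nX + nAut, level)
  cci <- clopper_pearson(nX, nX + nAut, call_level)
  r_xx <- sites_X / (sites_X + sites_aut)
  r_xy <- sites_X / (sites_X + 2 * sites_aut)
  in_xx <- cci$lower <= r_xx && r_xx <= cci$upper
  in_xy <- cci$lower <= r_xy && r_xy <= cci$upper
  call <- if (in_xx && !in_xy) "XX-consistent"
          else if (in_xy && !in_xx) "XY-consistent"
          else "indeterminate"
  structure(list(nX = nX, nAut = nAut, sites_X = sites_X,
                 sites_aut = sites_aut, ratio = ci$estimate, ci = ci,
                 expected_XX = r_xx, expected_XY = r_xy, call = call),
            class = "sex_assignment")
}

#' @export
print.sex_assignment <- function(x, ...) {
  cat(sprintf(
    "X/(X+aut) = %.4f (CI %.4f-%.4f); E[XX]=%.4f E[XY]=%.4f -> %s\n",
    x$ratio, x$ci$lower, x$ci$upper, x$expected_XX, x$expected_XY,
    x$call))
  invisible(x)
}
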