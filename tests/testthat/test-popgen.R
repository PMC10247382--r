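# small helper: EIGENSTRAT triplet written from explicit codes
write_es <- function(dir, codes, pops, chrom = "1") {
  n_ind <- ncol(codes)
  geno <- file.path(dir, "d.geno"); snp <- file.path(dir, "d.snp")
  ind <- file.path(dir, "d.ind")
  writeLines(apply(codes, 1, paste, collapse = ""), geno)
  write.table(data.frame(paste0("rs", seq_len(nrow(codes))), chrom, 0,
                         seq_len(nrow(codes)), "A", "G"),
              snp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(paste0("i", seq_len(n_ind)), "U", pops),
              ind, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  list(geno = geno, snp = snp, ind = ind)
}

test_that("EIGENSTRAT reading groups individuals and honours missingness", {
  dir <- withr::local_tempdir()
  f <- write_es(dir, matrix(c(2L, 9L), nrow = 2, ncol = 1), "PopA")
  gm <- read_eigenstrat(f$geno, f$snp, f$ind)
  expect_equal(unname(gm$alt[1, "PopA"]), 2)   # code 2 -> alt 2 of 2
  expect_equal(unname(gm$tot[1, "PopA"]), 2)
  expect_equal(unname(gm$tot[2, "PopA"]), 0)   # code 9 -> missing

  # round trip is lossless
  f2 <- list(geno = file.path(dir, "o.geno"), snp = file.path(dir, "o.snp"),
             ind = file.path(dir, "o.ind"))
  write_eigenstrat(gm, f2$geno, f2$snp, f2$ind)
  gm2 <- read_eigenstrat(f2$geno, f2$snp, f2$ind)
  expect_equal(gm2$alt, gm$alt)
  expect_equal(gm2$tot, gm$tot)
  expect_identical(readLines(f$geno), readLines(f2$geno))

  # mismatched dimensions are reported with the offending file
  bad <- write_es(dir, matrix(0L, 2, 2), c("A", "B"))
  writeLines("00", file.path(dir, "d.geno"))  # now 1 line vs 2 snps
  expect_error(read_eigenstrat(f$geno, bad$snp, bad$ind), "geno")
})

test_that("pseudo-haploidisation keeps one allele and preserves frequency", {
  sites <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "G")
  alt <- matrix(c(2L, 0L, 1L, 0L), ncol = 1,
                dimnames = list(NULL, "S"))
  tot <- matrix(c(2L, 2L, 2L, 0L), ncol = 1,
                dimnames = list(NULL, "S"))
  gm <- genotype_matrix(sites, alt, tot)
  ph <- pseudo_haploid(gm, "S", seed = 5)
  expect_equal(unname(ph$tot[1:3, "S"]), rep(1, 3))
  expect_equal(unname(ph$alt[1, "S"]), 1)  # homozygous alt preserved
  expect_equal(unname(ph$alt[2, "S"]), 0)  # homozygous ref preserved
  expect_true(ph$alt[3, "S"] %in% c(0, 1)) # het: one random allele
  expect_equal(unname(ph$tot[4, "S"]), 0)  # missing stays missing

  # frequency preserved in expectation over many het sites
  n <- 4000
  gm2 <- genotype_matrix(
    data.frame(chrom = "1", pos = 1:n, ref = "A", alt = "G"),
    matrix(1L, n, 1, dimnames = list(NULL, "S")),
    matrix(2L, n, 1, dimnames = list(NULL, "S")))
  ph2 <- pseudo_haploid(gm2, "S", seed = 6)
  expect_lt(abs(mean(ph2$alt[, "S"]) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("f3 and D match a brute-force per-site oracle to machine precision", {
  set.seed(77)
  n <- 100
  pops <- c("W", "X", "Y", "Z")
  alt <- sapply(pops, function(p) rbinom(n, 20, runif(n, 0.1, 0.9)))
  tot <- matrix(20L, n, 4, dimnames = list(NULL, pops))
  tot[sample(n, 10), "X"] <- 0L  # some missingness
  alt[tot == 0L] <- 0L
  gm <- genotype_matrix(
    data.frame(chrom = "1", pos = 1:n, ref = "A", alt = "G"), alt, tot)

  # brute-force loops, written independently of the implementation
  use <- tot[, "W"] > 0 & tot[, "X"] > 0 & tot[, "Y"] > 0 & tot[, "Z"] > 0
  f3_terms <- c(); num <- c(); den <- c()
  for (i in which(use)) {
    w <- alt[i, "W"] / tot[i, "W"]; x <- alt[i, "X"] / tot[i, "X"]
    y <- alt[i, "Y"] / tot[i, "Y"]; z <- alt[i, "Z"] / tot[i, "Z"]
    f3_terms <- c(f3_terms, (w - x) * (w - y))
    num <- c(num, (w - x) * (y - z))
    den <- c(den, (w + x - 2 * w * x) * (y + z - 2 * y * z))
  }
  expect_equal(f3(gm, "W", "X", "Y")$value, mean(f3_terms),
               tolerance = 1e-12)
  expect_equal(dstat(gm, "W", "X", "Y", "Z")$value,
               sum(num) / sum(den), tolerance = 1e-12)
})

test_that("f3 and D honour their arithmetic identities", {
  # single site, c=1, a=0, b=0 -> f3 = 1
  mk <- function(freqs) {
    pops <- names(freqs)
    genotype_matrix(
      data.frame(chrom = "1", pos = 1, ref = "A", alt = "G"),
      matrix(unlist(freqs) * 10, 1, length(freqs),
             dimnames = list(NULL, pops)),
      matrix(10, 1, length(freqs), dimnames = list(NULL, pops)))
  }
  gm1 <- mk(list(C = 1, A = 0, B = 0))
  expect_equal(suppressWarnings(f3(gm1, "C", "A", "B")$value), 1)

  # A identical to C -> f3 value 0
  gm0 <- mk(list(C = 0.4, A = 0.4, B = 0.9))
  expect_equal(suppressWarnings(f3(gm0, "C", "A", "B")$value), 0)

  # single site w=0, x=1, y=1, z=0 -> D = -1
  gmd <- mk(list(W = 0, X = 1, Y = 1, Z = 0))
  expect_equal(suppressWarnings(dstat(gmd, "W", "X", "Y", "Z")$value), -1)

  # D argument swaps flip the sign exactly; identical Y,Z gives 0
  set.seed(11)
  n <- 200
  pops <- c("W", "X", "Y", "Z")
  alt <- sapply(pops, function(p) rbinom(n, 20, runif(n, 0.1, 0.9)))
  alt[, "Z"] <- alt[, "Y"]
  tot <- matrix(20L, n, 4, dimnames = list(NULL, pops))
  gm <- genotype_matrix(
    data.frame(chrom = "1", pos = 1:n, ref = "A", alt = "G"), alt, tot)
  expect_equal(dstat(gm, "W", "X", "Y", "Z")$value, 0)
  alt[, "Z"] <- rbinom(n, 20, 0.5)
  gm2 <- genotype_matrix(
    data.frame(chrom = "1", pos = 1:n, ref = "A", alt = "G"), alt, tot)
  d <- dstat(gm2, "W", "X", "Y", "Z")$value
  expect_equal(dstat(gm2, "X", "W", "Y", "Z")$value, -d)
  expect_equal(dstat(gm2, "W", "X", "Z", "Y")$value, -d)
})

test_that("block jackknife equals brute-force delete-one recomputation", {
  set.seed(21)
  n <- 100
  v <- rnorm(n); w <- rep(1, n)
  jk <- block_jackknife(v, w, n_blocks = 10)
  # textbook equal-block delete-1 oracle
  blocks <- rep(1:10, each = 10)
  th <- sapply(1:10, function(j) mean(v[blocks != j]))
  se_oracle <- sqrt((10 - 1) / 10 * sum((th - mean(th))^2))
  expect_equal(jk$se, se_oracle, tolerance = 1e-12)

  # weighted ratio case against direct delete-one recomputation
  wts <- runif(n, 0.5, 2)
  jkw <- block_jackknife(v, wts, n_blocks = 10)
  th_w <- sapply(1:10, function(j) {
    sum(v[blocks != j]) / sum(wts[blocks != j])
  })
  theta <- sum(v) / sum(wts)
  m_j <- rep(10, 10); h_j <- n / m_j; g <- 10
  theta_dot <- g * theta - sum((1 - 1 / h_j) * th_w)
  tau <- h_j * theta - (h_j - 1) * th_w
  expect_equal(jkw$se, sqrt(sum((tau - theta_dot)^2 / (h_j - 1)) / g),
               tolerance = 1e-12)

  # identical blocks -> SE 0
  expect_equal(block_jackknife(rep(2, 40), rep(1, 40), 4)$se, 0)
  expect_error(block_jackknife(v, w, 1), "n_blocks")

  # SE shrinks like 1/sqrt(n) on iid data
  set.seed(31)
  se_small <- block_jackknife(rnorm(1000), n_blocks = 20)$se
  se_big <- block_jackknife(rnorm(16000), n_blocks = 20)$se
  expect_lt(se_big, se_small / 2)
})

test_that("f3 detects shared drift and D detects admixture on simulations", {
  # A and B are sisters; C is the outgroup-target
  edges <- data.frame(parent = c("R", "R", "I", "I"),
                      child = c("C", "I", "A", "B"),
                      F = c(0.02, 0.05, 0.02, 0.02))
  g <- graph_spec(edges, outgroup = "C")
  gm <- simulate_genotypes(g, 50000, seed = 41)
  r <- f3(gm, "C", "A", "B")
  expect_gt(r$value, 0)
  expect_gt(r$z, 3)

  # symmetric tree without gene flow: D consistent with 0
  edges4 <- data.frame(
    parent = c("R", "R", "P1", "P1", "P2", "P2"),
    child = c("P1", "P2", "W", "X", "Y", "Z"),
    F = rep(0.02, 6))
  g4 <- graph_spec(edges4, outgroup = "Z")
  gm4 <- simulate_genotypes(g4, 20000, seed = 42)
  d0 <- dstat(gm4, "W", "X", "Y", "Z")
  expect_lt(abs(d0$z), 3)

  # admixture from Y's lineage into W -> positive D with strong Z
  g4a <- graph_spec(edges4, outgroup = "Z",
                    admixture = list(source = "Y", target = "W",
                                     alpha = 0.1))
  gm4a <- simulate_genotypes(g4a, 100000, seed = 43)
  da <- dstat(gm4a, "W", "X", "Y", "Z")
  expect_gt(da$value, 0)
  expect_gt(da$z, 3)
})

test_that("PCA projection reproduces scores and separates populations", {
  set.seed(51)
  n_sites <- 500
  pa <- runif(n_sites, 0.1, 0.9)
  pb <- pmin(0.95, pmax(0.05, pa + sample(c(-1, 1), n_sites, TRUE) * 0.3))
  ga <- t(replicate(15, rbinom(n_sites, 2, pa)))
  gb <- t(replicate(15, rbinom(n_sites, 2, pb)))
  ref <- rbind(ga, gb)

  # a complete sample equal to a reference individual projects onto it
  pr <- pca_project(ref, ref[1, ], n_pcs = 2)
  expect_equal(unname(pr$samples[1, ]), unname(pr$reference[1, ]),
               tolerance = 1e-8)

  # PC1 separates the populations; an admixed sample lands between
  adm <- rbinom(n_sites, 2, (pa + pb) / 2)
  adm[sample(n_sites, 200)] <- NA  # heavy missingness
  pr2 <- pca_project(ref, adm, n_pcs = 2)
  pc1_a <- mean(pr2$reference[1:15, 1])
  pc1_b <- mean(pr2$reference[16:30, 1])
  expect_gt(abs(pc1_a - pc1_b),
            2 * (sd(pr2$reference[1:15, 1]) + sd(pr2$reference[16:30, 1])))
  expect_gt(pr2$samples[1, 1], min(pc1_a, pc1_b))
  expect_lt(pr2$samples[1, 1], max(pc1_a, pc1_b))
  expect_error(pca_project(ref, rep(NA_real_, n_sites)), "missing")
})

test_that("sex inference separates XX from XY by coverage ratio", {
  # equal site counts: R = 0.5 is XX-like, R = 1/3 is XY-like
  s <- infer_sex(500, 500, 1000, 1000)
  expect_equal(s$call, "XX-consistent")
  expect_equal(s$expected_XX, 0.5)
  s2 <- infer_sex(250, 500, 1000, 1000)
  expect_equal(s2$call, "XY-consistent")
  expect_equal(s2$expected_XY, 1 / 3)
  expect_error(infer_sex(0, 0, 10, 10), "no fragments")

  # simulated recovery at depth 5 with 10,000 sites each
  calls <- sapply(1:100, function(r) {
    xx <- simulate_sex_counts(10000, 10000, "XX", 5, seed = 2 * r)
    xy <- simulate_sex_counts(10000, 10000, "XY", 5, seed = 2 * r + 1)
    c(infer_sex(xx$nX, xx$nAut, 10000, 10000)$call,
      infer_sex(xy$nX, xy$nAut, 10000, 10000)$call)
  })
  expect_gte(mean(calls[1, ] == "XX-consistent"), 0.99)
  expect_gte(mean(calls[2, ] == "XY-consistent"), 0.99)
})
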