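test_that("consensus calling enforces the coverage floor and majority rule", {
  p <- tiny_panel()
  mk <- function(n, seq) {
    tiny_frags(p, start = rep(0L, n), end = rep(8L, n),
               seq = rep(seq, n), ids = paste0("x", seq_len(n)))
  }
  all_t <- paste0("T", substr(reference_slice(p, "r1", 0L, 8L), 2, 8))

  # coverage 9 -> N even if unanimous
  cons9 <- call_consensus(mk(9L, all_t), p, "r1")
  expect_equal(cons9$calls[1], "N")
  # coverage 10, all T -> T
  cons10 <- call_consensus(mk(10L, all_t), p, "r1")
  expect_equal(cons10$calls[1], "T")
  # coverage 10, 6 T / 4 C: 0.6 < 0.75 majority -> N
  ref8 <- reference_slice(p, "r1", 0L, 8L)
  six_four <- rbind(as.data.frame(mk(6L, all_t)),
                    as.data.frame(tiny_frags(p, start = rep(0L, 4),
                                             end = rep(8L, 4),
                                             seq = rep(paste0("C",
                                               substr(ref8, 2, 8)), 4),
                                             ids = paste0("y", 1:4))))
  cons64 <- call_consensus(aligned_fragments(six_four, p), p, "r1")
  expect_equal(cons64$calls[1], "N")
  # uncovered positions are N
  expect_true(all(cons10$calls[21:40] == "N"))
})

test_that("error-free simulation reproduces the endogenous haplotype exactly", {
  sim <- sim_world(seed = 61, length = 3000)
  dp <- damage_params(d_max = 0, baseline = 0, eps = 0)
  comp <- fraction_composition("endo", "human_endo", TRUE, 1)
  fr <- simulate_fraction(sim$panel, comp, dp, 3000, seed = 62)
  cons <- call_consensus(deduplicate(fr$fragments), sim$panel,
                         "human_endo")
  truth <- strsplit(sim$panel$sequences[["human_endo"]], "")[[1]]
  called <- cons$calls != "N"
  expect_true(all(cons$coverage[called] >= 10))
  expect_identical(cons$calls[called], truth[called])
  # with damage, deaminated reads can break majority but never flip a
  # call to a wrong base when the majority rule is met
  fr2 <- simulate_fraction(sim$panel, comp, damage_params(), 3000,
                           seed = 63)
  cons2 <- call_consensus(deduplicate(fr2$fragments), sim$panel,
                          "human_endo")
  called2 <- cons2$calls != "N" & truth != "C" & truth != "G"
  expect_identical(cons2$calls[called2], truth[called2])
})

test_that("diagnostic site discovery matches the simulated truth table", {
  sim <- sim_world(seed = 71, length = 3000)
  dp <- damage_params(d_max = 0, baseline = 0, eps = 0)
  comp <- fraction_composition("endo", "human_endo", TRUE, 1)
  fr <- simulate_fraction(sim$panel, comp, dp, 3000, seed = 72)
  cons <- call_consensus(deduplicate(fr$fragments), sim$panel,
                         "human_endo")
  sites <- find_diagnostic_sites(cons, sim$human$contaminant)
  truthd <- sim$human$diagnostics
  covered <- truthd$pos[cons$calls[truthd$pos + 1] != "N"]
  expect_setequal(sites$pos, covered)
  m <- merge(sites, truthd, by = "pos")
  expect_equal(m$damage_ambiguous.x, m$damage_ambiguous.y)
  # consensus identical to the panel -> no diagnostic sites
  none <- find_diagnostic_sites(cons, sim$panel$sequences[["human_endo"]])
  expect_equal(nrow(none), 0L)
  # N at a differing position excludes the site
  cons_n <- cons
  cons_n$calls[truthd$pos + 1] <- "N"
  expect_equal(nrow(find_diagnostic_sites(cons_n,
                                          sim$human$contaminant)), 0L)
  expect_error(find_diagnostic_sites(cons, character(0)), "empty")
})

test_that("support at diagnostic positions carries exact binomial intervals", {
  sim <- sim_world(seed = 81, length = 3000)
  dp <- damage_params(d_max = 0, baseline = 0, eps = 0)
  comp <- fraction_composition(
    c("endo", "cont"), c("human_endo", "human_endo"), c(FALSE, FALSE),
    c(0.75, 0.25), source_seqs = list(cont = sim$human$contaminant))
  fr <- simulate_fraction(sim$panel, comp, dp, 4000, seed = 82)
  cons <- call_consensus(deduplicate(fr$fragments), sim$panel,
                         "human_endo")
  sites <- find_diagnostic_sites(cons, sim$human$contaminant)
  sup <- support_at_diagnostics(fr$fragments, sim$panel, sites,
                                "human_endo")
  expect_equal(sup$ci$estimate, sup$n_match / sup$n_informative)
  # support should sit near the endogenous share
  expect_gt(sup$ci$estimate, 0.6)
  expect_lt(sup$ci$estimate, 0.9)

  # no overlapping fragments -> indeterminate
  far <- fr$fragments[1:2, ]
  far$start <- 0L; far$end <- 40L
  far$sequence <- substr(sim$panel$sequences[["human_endo"]], 1, 40)
  far$strand <- "+"
  sites_far <- sites[sites$pos > 100, , drop = FALSE]
  if (nrow(sites_far)) {
    sup0 <- support_at_diagnostics(aligned_fragments(as.data.frame(far),
                                                     sim$panel),
                                   sim$panel, sites_far, "human_endo")
    expect_equal(sup0$verdict, "indeterminate")
  }

  # all informative fragments match -> estimate 1 with upper bound 1
  endo_only <- fr$fragments[fr$truth$label == "endo", ]
  sup1 <- support_at_diagnostics(endo_only, sim$panel, sites,
                                 "human_endo")
  expect_equal(sup1$ci$estimate, 1)
  expect_equal(sup1$ci$upper, 1)

  # support and the diagnostic contamination estimate are exact
  # complements on the same fragments
  contam <- estimate_contamination_diagnostic(fr$fragments, sim$panel,
                                              sites, "human_endo")
  expect_equal(sup$ci$estimate + contam$estimate, 1)
  expect_equal(contam$n_fragments, sup$n_informative)
})

test_that("diagnostic contamination recovers a simulated mixture", {
  sim <- sim_world(seed = 91, length = 3000)
  dp <- damage_params(d_max = 0, baseline = 0, eps = 0)
  c_true <- 0.2
  comp <- fraction_composition(
    c("endo", "cont"), c("human_endo", "human_endo"), c(FALSE, FALSE),
    c(1 - c_true, c_true),
    source_seqs = list(cont = sim$human$contaminant))
  fr <- simulate_fraction(sim$panel, comp, dp, 6000, seed = 92)
  cons <- call_consensus(deduplicate(fr$fragments), sim$panel,
                         "human_endo")
  sites <- find_diagnostic_sites(cons, sim$human$contaminant)
  est <- estimate_contamination_diagnostic(fr$fragments, sim$panel,
                                           sites, "human_endo")
  expect_gte(c_true, est$lower)
  expect_lte(c_true, est$upper)
})

test_that("conditional-damage contamination estimator behaves as a mixture", {
  sim <- sim_world(seed = 95, length = 4000)
  dp <- damage_params(d_max = 0.4, lambda = 0.3, baseline = 0.01,
                      eps = 0)
  # pure endogenous: r_all = r_cond in expectation -> estimate near 0
  comp0 <- fraction_composition("endo", "human_endo", TRUE, 1)
  fr0 <- simulate_fraction(sim$panel, comp0, dp, 8000, seed = 96)
  est0 <- estimate_contamination_conditional(fr0$fragments, sim$panel,
                                             n_boot = 100, seed = 1)
  expect_lt(est0$estimate, 0.1)

  # mixture: truth within the bootstrap interval
  c_true <- 0.3
  comp <- fraction_composition(
    c("endo", "cont"), c("human_endo", "human_endo"), c(TRUE, FALSE),
    c(1 - c_true, c_true),
    source_seqs = list(cont = sim$human$contaminant))
  fr <- simulate_fraction(sim$panel, comp, dp, 20000, seed = 97)
  est <- estimate_contamination_conditional(fr$fragments, sim$panel,
                                            n_boot = 300, seed = 2)
  expect_false(est$indeterminate)
  expect_gte(c_true, est$lower - 0.02)
  expect_lte(c_true, est$upper + 0.02)

  # no informative terminals errors
  p <- tiny_panel()
  fr_a <- tiny_frags(p, start = 0L, end = 4L)  # ACGT: A/T terminals
  expect_error(estimate_contamination_conditional(fr_a, p),
               "no informative")
})

test_that("conditional estimator error shrinks with sample size", {
  sim <- sim_world(seed = 99, length = 4000)
  dp <- damage_params(d_max = 0.4, lambda = 0.3, baseline = 0.01,
                      eps = 0)
  c_true <- 0.3
  comp <- fraction_composition(
    c("endo", "cont"), c("human_endo", "human_endo"), c(TRUE, FALSE),
    c(1 - c_true, c_true),
    source_seqs = list(cont = sim$human$contaminant))
  err <- sapply(c(1000, 20000), function(n) {
    e <- sapply(1:4, function(r) {
      fr <- simulate_fraction(sim$panel, comp, dp, n, seed = 1000 + r)
      estimate_contamination_conditional(fr$fragments, sim$panel,
                                         n_boot = 2, seed = r)$estimate
    })
    mean(abs(e - c_true))
  })
  expect_lt(err[2], err[1])
})
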