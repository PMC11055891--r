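test_that("compartments pair fork and transcription direction with matched orientation", {
  rdc <- GRanges("chr1", IRanges(9.5e6, 11.0e6))
  fk <- c(mk_fork(10.2e6 + 1, 11.0e6, "rightward"),
          mk_fork(9.4e6, 10.0e6, "leftward"))
  genes <- mk_genes(c(9.5e6, 10.3e6), c(10.0e6, 10.9e6), c("-", "-"), c(1, 1))
  comp <- assign_compartments(rdc, fk, genes)
  expect_length(comp, 2)
  right <- comp[mcols(comp)$fork_direction == "rightward"]
  left <- comp[mcols(comp)$fork_direction == "leftward"]
  expect_equal(mcols(right)$mode, "head_on")       # rightward fork, leftward gene
  expect_equal(mcols(right)$matched_orientation, "Dcen")
  expect_equal(mcols(left)$mode, "co_directional") # leftward fork, leftward gene
  expect_equal(mcols(left)$matched_orientation, "Dtel")

  # sub-threshold expression contributes no compartment
  weak <- mk_genes(c(9.5e6, 10.3e6), c(10.0e6, 10.9e6), c("-", "-"), c(0.01, 1))
  expect_length(assign_compartments(rdc, fk, weak), 1)
  silent <- mk_genes(9.5e6, 10.9e6, "-", 0.001)
  expect_length(assign_compartments(rdc, fk, silent), 0)
})

test_that("P_HO and P_CD are complementary percentages of matched junctions", {
  rdc <- GRanges("chr1", IRanges(9.5e6, 11.0e6))
  fk <- c(mk_fork(10.2e6 + 1, 11.0e6, "rightward"),
          mk_fork(9.4e6, 10.0e6, "leftward"))
  genes <- mk_genes(c(9.5e6, 10.3e6), c(10.0e6, 10.9e6), c("-", "-"), c(1, 1))
  comp <- assign_compartments(rdc, fk, genes)
  set.seed(21)
  jx <- mk_junctions(rep("chr1", 200),
                     c(runif(100, 9.5e6, 10.0e6), runif(100, 10.35e6, 10.9e6)),
                     c(rep("Dtel", 60), rep("Dcen", 40),
                       rep("Dcen", 60), rep("Dtel", 40)))
  pr <- trc_proportions(jx, comp)
  expect_equal(pr$N_HO, 60)   # matched Dcen in the head-on compartment
  expect_equal(pr$N_CD, 60)   # matched Dtel in the co-directional compartment
  expect_equal(pr$P_HO, 50)
  expect_equal(pr$P_HO + pr$P_CD, 100)

  # all matched junctions head-on
  jho <- mk_junctions(rep("chr1", 10), runif(10, 10.35e6, 10.9e6), rep("Dcen", 10))
  expect_equal(trc_proportions(jho, comp)$P_HO, 100)

  # 60/40 split
  j64 <- c(mk_junctions(rep("chr1", 60), runif(60, 10.35e6, 10.9e6), rep("Dcen", 60)),
           mk_junctions(rep("chr1", 40), runif(40, 9.55e6, 9.95e6), rep("Dtel", 40)))
  pr64 <- trc_proportions(j64, comp)
  expect_equal(pr64$P_HO, 60)
  expect_equal(pr64$P_CD, 40)

  # no matched junctions: undefined, flagged
  junm <- mk_junctions("chr1", 5e6, "Dcen")
  expect_message(pr0 <- trc_proportions(junm, comp), "undefined")
  expect_true(is.na(pr0$P_HO))

  # weights scale the counts
  prw <- trc_proportions(j64, comp, weights = c(rep(2, 60), rep(1, 40)))
  expect_equal(prw$P_HO, 100 * 120 / 160)

  # complementarity holds across random configurations
  set.seed(22)
  for (i in 1:20) {
    jr <- mk_junctions(rep("chr1", 50), runif(50, 9.4e6, 11e6),
                       sample(c("Dcen", "Dtel"), 50, TRUE))
    p <- suppressMessages(trc_proportions(jr, comp))
    if (!is.na(p$P_HO)) expect_equal(p$P_HO + p$P_CD, 100)
  }
})

test_that("relative replication speed counts bins per distinct fraction", {
  ft <- mk_fractions(c(rep(4, 3), 5, 6, 7, 8, 9, 10, 11))
  comp10 <- GRanges("chr1", IRanges(1, 10 * 50000))
  expect_equal(relative_replication_speed(comp10, ft), 10 / 8)  # 1.25

  ft1 <- mk_fractions(7)
  expect_equal(relative_replication_speed(GRanges("chr1", IRanges(1, 50000)), ft1), 1)

  # doubling bins at a fixed fraction span doubles Rs
  ftA <- mk_fractions(c(3, 3, 4, 4))
  ftB <- mk_fractions(c(3, 3, 3, 3, 4, 4, 4, 4))
  rsA <- relative_replication_speed(GRanges("chr1", IRanges(1, 4 * 50000)), ftA)
  rsB <- relative_replication_speed(GRanges("chr1", IRanges(1, 8 * 50000)), ftB)
  expect_equal(rsB, 2 * rsA)

  ftNA <- mk_fractions(rep(NA_integer_, 4))
  expect_error(relative_replication_speed(GRanges("chr1", IRanges(1, 200000)), ftNA))
})

test_that("relative DSB counts are log2 ratios to the cross-dose mean with 0.5 pseudocount", {
  expect_equal(unname(relative_dsb_count(c(10, 10, 10, 10, 10))), rep(0, 5))
  r <- relative_dsb_count(c(5, 10, 15, 20, 50))
  expect_equal(unname(r[5]), log2(2.5), tolerance = 1e-12)
  rz <- relative_dsb_count(c(0, 10, 10, 10, 10))
  expect_equal(unname(rz[1]), log2(0.5 / 8), tolerance = 1e-12)
  expect_equal(unname(rz[1]), -4, tolerance = 1e-12)
  expect_error(relative_dsb_count(c(0, 0, 0, 0, 0)), "excluded")
  # permutation of equal counts is the zero vector
  expect_equal(unname(relative_dsb_count(rep(7, 5)[sample(5)])), rep(0, 5))
})

test_that("dual-strand hybrid counting and tertile stratification follow the rules", {
  rdcs <- GRanges("chr1", IRanges((0:5) * 1e6 + 1, width = 5e5))
  counts <- c(1, 2, 5, 8, 20, 30)
  plus <- GRanges(); minus <- GRanges()
  for (i in 1:6) {
    at <- seq(start(rdcs)[i], by = 3000, length.out = counts[i])
    plus <- c(plus, GRanges("chr1", IRanges(at, width = 1000), strand = "+"))
    minus <- c(minus, GRanges("chr1", IRanges(at, width = 1000), strand = "-"))
  }
  hs <- hybrid_stratify(rdcs, plus, minus)
  expect_equal(hs$count, counts)
  expect_equal(hs$group, c("low", "low", "mid", "mid", "high", "high"))

  # a plus peak with no minus overlap is not a dual-strand hybrid
  solo_plus <- GRanges("chr1", IRanges(1, 1000), strand = "+")
  hs0 <- hybrid_stratify(GRanges("chr1", IRanges(1, 5e5)), solo_plus, GRanges())
  expect_equal(hs0$count, 0L)
  expect_equal(hs0$group, "low")
})

test_that("peak densities and the Mann-Whitney test match an exhaustive oracle", {
  g <- GRanges("chr1", IRanges(1, 200000))
  pk <- GRanges("chr1", IRanges(c(1000, 2000, 3000, 4000), width = 100))
  d <- peak_density_compare(g, GRanges("chr1", IRanges(1e6, 1e6 + 2e5)), pk)
  expect_equal(d$density_rdc, 2)  # 4 peaks / 2 x 100 kb

  # tiny vectors against the full permutation distribution
  mk_density_genes <- function(dens) {
    # genes of 100 kb with `dens` peaks each
    GRanges("chr2", IRanges((seq_along(dens) - 1) * 2e5 + 1, width = 1e5))
  }
  ga <- mk_density_genes(1:3); gb <- mk_density_genes(4:6)
  gb <- shift(gb, 1e7)
  peaks <- GRanges()
  for (i in 1:3) peaks <- c(peaks, GRanges("chr2",
    IRanges(start(ga)[i] + seq_len(i) * 100, width = 10)))
  for (i in 1:3) peaks <- c(peaks, GRanges("chr2",
    IRanges(start(gb)[i] + seq_len(i + 3) * 100, width = 10)))
  res <- peak_density_compare(ga, gb, peaks)
  orc <- oracle_mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), orc$U)
  expect_equal(res$p_value, orc$p, tolerance = 1e-9)

  expect_error(peak_density_compare(GRanges(), gb, peaks), "non-empty")

  # identical density vectors are indistinguishable
  gc <- shift(ga, 5e6)
  peaks_same <- peaks
  for (i in 1:3) peaks_same <- c(peaks_same, GRanges("chr2",
    IRanges(start(gc)[i] + seq_len(i) * 100, width = 10)))
  same <- peak_density_compare(ga, gc, peaks_same)
  expect_gt(same$p_value, 0.99)
})

test_that("two-group comparisons match closed-form t statistics and handle degeneracy", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  # hand computation: pooled-variance t
  sp2 <- (var(a) * 3 + var(b) * 3) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(abs(t_hand), df = 6, lower.tail = FALSE)
  expect_equal(group_compare(a, b), p_hand, tolerance = 1e-12)

  expect_equal(group_compare(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_lt(group_compare(c(0, 0, 0), c(1, 1, 1)), 1e-6)
  expect_gt(group_compare(c(1, 2, 3), c(1, 2, 3), test = "mann_whitney"), 0.99)
})
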