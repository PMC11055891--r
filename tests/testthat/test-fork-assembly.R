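test_that("IZ edges connect to the nearest termination anchors on each side", {
  iz <- GRanges("chr1", IRanges(10.0e6 + 1, 10.2e6))
  fk <- assemble_forks(iz, tz_pos = c(9.4e6, 11.0e6, 12e6, 8e6))
  expect_length(fk, 2)
  r <- fk[mcols(fk)$direction == "rightward"]
  l <- fk[mcols(fk)$direction == "leftward"]
  expect_equal(start(r), 10.2e6 + 1)
  expect_equal(end(r), 11.0e6)     # nearest anchor on the right
  expect_equal(start(l), 9.4e6)    # nearest anchor on the left
  expect_equal(end(l), 10.0e6)

  # a 40-kb fork cannot be resolved
  fk2 <- suppressWarnings(assemble_forks(iz, tz_pos = 10.24e6))
  expect_false(any(mcols(fk2)$direction == "rightward"))

  # two IZs sharing an anchor produce converging segments that meet there
  iz2 <- GRanges("chr1", IRanges(c(1e6, 5e6), c(1.2e6, 5.2e6)))
  fk3 <- suppressWarnings(assemble_forks(iz2, tz_pos = 3e6))
  conv <- fk3[mcols(fk3)$source == "iz-to-tz"]
  expect_equal(end(conv[mcols(conv)$direction == "rightward"]), 3e6)
  expect_equal(start(conv[mcols(conv)$direction == "leftward"]), 3e6)

  # one-sided assembly warns
  expect_warning(assemble_forks(iz, tz_pos = 9e6), "one-sided")

  # TTR features contribute segments with their own direction
  ttr <- GRanges("chr1", IRanges(2e6, 2.5e6), strand = "+")
  mcols(ttr)$kind <- "TTR"; mcols(ttr)$direction <- "rightward"
  fk4 <- assemble_forks(iz, tz_pos = c(9.4e6, 11.0e6), ttr = ttr)
  expect_true(any(mcols(fk4)$source == "ttr"))
})

test_that("consensus keeps base pairs where replicates agree in direction", {
  a <- mk_fork(1e6, 2e6, "rightward", replicate = "r1")
  b <- mk_fork(1e6, 2e6, "rightward", replicate = "r2")
  expect_equal(width(consensus_forks(a, b)), 1e6 + 1)

  # opposite directions over the same interval cancel out
  expect_length(consensus_forks(a, mk_fork(1e6, 2e6, "leftward")), 0)

  # partial same-direction overlap survives re-segmentation
  c300 <- consensus_forks(mk_fork(1e6, 2e6, "rightward"),
                          mk_fork(1.7e6, 3e6, "rightward"))
  expect_equal(start(c300), 1.7e6)
  expect_equal(end(c300), 2e6)

  # commutativity
  r1 <- c(mk_fork(1e6, 2e6, "rightward"), mk_fork(3e6, 4e6, "leftward"))
  r2 <- c(mk_fork(1.5e6, 2.4e6, "rightward"), mk_fork(2.9e6, 3.6e6, "leftward"))
  ab <- consensus_forks(r1, r2); ba <- consensus_forks(r2, r1)
  expect_equal(start(ab), start(ba))
  expect_equal(end(ab), end(ba))
  expect_equal(mcols(ab)$direction, mcols(ba)$direction)

  # sub-bin leftovers are dropped
  tiny <- consensus_forks(mk_fork(1e6, 1.04e6, "rightward"),
                          mk_fork(1e6, 1.04e6, "rightward"))
  expect_length(tiny, 0)
})

test_that("fork configurations classify into the five RDC classes (20 fixtures)", {
  rdc <- GRanges("chr1", IRanges(10e6, 12e6))
  cases <- list(
    # inward: converging pairs (rightward left of leftward)
    list(f = c(mk_fork(10e6, 11e6, "rightward"), mk_fork(11e6, 12e6, "leftward")), k = "inward"),
    list(f = c(mk_fork(9.5e6, 10.8e6, "rightward"), mk_fork(11.2e6, 12.5e6, "leftward")), k = "inward"),
    list(f = c(mk_fork(10.2e6, 10.9e6, "rightward"), mk_fork(10.95e6, 11.8e6, "leftward")), k = "inward"),
    list(f = c(mk_fork(10e6, 11.5e6, "rightward"), mk_fork(11.6e6, 12e6, "leftward")), k = "inward"),
    # unidirectional: one direction only (1 or 2 segments)
    list(f = mk_fork(10e6, 12e6, "rightward"), k = "unidirectional"),
    list(f = mk_fork(10e6, 12e6, "leftward"), k = "unidirectional"),
    list(f = mk_fork(10.5e6, 11.1e6, "rightward"), k = "unidirectional"),
    list(f = c(mk_fork(10e6, 10.6e6, "leftward"), mk_fork(11e6, 11.6e6, "leftward")), k = "unidirectional"),
    list(f = c(mk_fork(10e6, 10.6e6, "rightward"), mk_fork(11e6, 11.6e6, "rightward")), k = "unidirectional"),
    list(f = mk_fork(9e6, 13e6, "leftward"), k = "unidirectional"),
    # outward: diverging pairs (leftward left of rightward)
    list(f = c(mk_fork(10e6, 10.9e6, "leftward"), mk_fork(11.1e6, 12e6, "rightward")), k = "outward"),
    list(f = c(mk_fork(9.5e6, 10.5e6, "leftward"), mk_fork(11.5e6, 12.5e6, "rightward")), k = "outward"),
    list(f = c(mk_fork(10.1e6, 10.7e6, "leftward"), mk_fork(10.8e6, 11.9e6, "rightward")), k = "outward"),
    # complex: three or more segments
    list(f = c(mk_fork(10e6, 10.6e6, "rightward"), mk_fork(10.7e6, 11.2e6, "leftward"),
               mk_fork(11.3e6, 12e6, "rightward")), k = "complex"),
    list(f = c(mk_fork(10e6, 10.5e6, "leftward"), mk_fork(10.6e6, 11e6, "rightward"),
               mk_fork(11.1e6, 11.5e6, "leftward"), mk_fork(11.6e6, 12e6, "rightward")), k = "complex"),
    list(f = c(mk_fork(10e6, 10.5e6, "rightward"), mk_fork(10.6e6, 11e6, "rightward"),
               mk_fork(11.1e6, 12e6, "leftward")), k = "complex"),
    # undetermined: nothing usable overlaps
    list(f = GRanges(), k = "undetermined"),
    list(f = mk_fork(20e6, 21e6, "rightward"), k = "undetermined"),
    list(f = mk_fork(1e6, 2e6, "leftward"), k = "undetermined"),
    # sub-bin overlap does not count
    list(f = mk_fork(9e6, 10.02e6, "rightward"), k = "undetermined")
  )
  expect_length(cases, 20)
  for (i in seq_along(cases)) {
    got <- classify_rdc(rdc, cases[[i]]$f)$klass
    expect_equal(got, cases[[i]]$k, label = sprintf("fixture %d: %s", i, got))
  }
})

test_that("classification flags features and mirrors with the genome", {
  rdc <- GRanges("chr1", IRanges(10e6, 12e6))
  ttr <- GRanges("chr1", IRanges(10.5e6, 11.5e6), strand = "+")
  mcols(ttr)$kind <- "TTR"; mcols(ttr)$direction <- "rightward"
  bigctr <- GRanges("chr1", IRanges(10.8e6, 11.9e6))
  mcols(bigctr)$kind <- "lateCTR"; mcols(bigctr)$direction <- "none"
  feats <- suppressWarnings(c(ttr, bigctr))
  cl <- classify_rdc(rdc, mk_fork(10e6, 12e6, "rightward"), feats)
  expect_true(cl$contains_ttr)
  expect_true(cl$contains_broad_lateCTR)  # 1.1 Mb > 500 kb

  # mirror: reflect all coordinates around the chromosome midpoint
  L <- 22e6
  mirror <- function(gr, dirflip = TRUE) {
    m <- GRanges("chr1", IRanges(L - end(gr) + 1, L - start(gr) + 1))
    if (dirflip && length(gr) > 0) {
      mcols(m)$direction <- ifelse(mcols(gr)$direction == "rightward",
                                   "leftward", "rightward")
    }
    m
  }
  inward <- c(mk_fork(10e6, 10.9e6, "rightward"), mk_fork(11.1e6, 12e6, "leftward"))
  outward <- c(mk_fork(10e6, 10.9e6, "leftward"), mk_fork(11.1e6, 12e6, "rightward"))
  uni <- mk_fork(10e6, 12e6, "rightward")
  rdc_m <- mirror(rdc, dirflip = FALSE)
  expect_equal(classify_rdc(rdc_m, mirror(inward))$klass, "inward")
  expect_equal(classify_rdc(rdc_m, mirror(outward))$klass, "outward")
  um <- classify_rdc(rdc_m, mirror(uni))
  expect_equal(um$klass, "unidirectional")
  expect_equal(mcols(um$forks)$direction, "leftward")
})

test_that("the pulse-label span exceeds one Repli-seq bin per fork", {
  expect_equal(fork_label_span(), 54)
  expect_gte(fork_label_span(1.8, 30), 50)
  expect_error(fork_label_span(0, 30))
})
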