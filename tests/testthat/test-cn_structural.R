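test_that("minimum-event distance handles the canonical small cases", {
  expect_equal(min_event_distance(make_profile(c(2, 2, 2)),
                                  make_profile(c(2, 2, 2))), 0L)
  # one +1 event spanning two segments
  expect_equal(min_event_distance(make_profile(c(2, 2, 2)),
                                  make_profile(c(3, 3, 2))), 1L)
  # two separate +1 events around an already-correct segment
  expect_equal(min_event_distance(make_profile(c(2, 3, 2)),
                                  make_profile(c(3, 3, 3))), 2L)
  # zero segments act as barriers between events
  expect_equal(min_event_distance(make_profile(c(2, 0, 2)),
                                  make_profile(c(3, 0, 3))), 2L)
  # a lost segment cannot regain copies
  expect_warning(
    d <- min_event_distance(make_profile(c(0, 2)), make_profile(c(1, 2))),
    "cannot regain")
  expect_true(is.na(d))
})

test_that("linear-scan distance equals BFS shortest path on random profiles", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(2:6, 1L)
    a <- sample(0:4, n, replace = TRUE)
    b <- sample(0:4, n, replace = TRUE)
    got <- suppressWarnings(min_event_distance(make_profile(a),
                                               make_profile(b)))
    expect_equal(got, bfs_event_distance(a, b),
                 info = paste(paste(a, collapse = ","), "->",
                              paste(b, collapse = ",")))
  }
})

test_that("distance is a sane dissimilarity: zero on self, bounded below", {
  set.seed(29)
  for (i in 1:50) {
    n <- sample(2:6, 1L)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    pa <- make_profile(a); pb <- make_profile(b)
    expect_equal(min_event_distance(pa, pa), 0L)
    d <- min_event_distance(pa, pb)
    expect_gte(d, max(abs(a - b)))
  }
})

test_that("profiles are intersected onto a shared grid; misaligned ones error", {
  a <- cn_profile(data.frame(chrom = "1", start = c(0, 50), end = c(50, 100),
                             absolute_copy_number = c(2L, 3L)), "A", ploidy = 2)
  b <- cn_profile(data.frame(chrom = "1", start = c(0, 30), end = c(30, 100),
                             absolute_copy_number = c(2L, 3L)), "B", ploidy = 2)
  # differing breakpoints are fine: union grid [0,30,50,100)
  expect_equal(min_event_distance(a, b), 1L)
  cshort <- cn_profile(data.frame(chrom = "1", start = 0, end = 60,
                                  absolute_copy_number = 2L), "C", ploidy = 2)
  expect_error(min_event_distance(a, cshort), "not alignable")
  d2 <- cn_profile(data.frame(chrom = "2", start = 0, end = 100,
                              absolute_copy_number = 2L), "D", ploidy = 2)
  expect_error(min_event_distance(a, d2), "different chromosomes")
})

test_that("copy-number profile invariants are enforced", {
  expect_error(cn_profile(data.frame(chrom = "1", start = c(0, 40),
                                     end = c(50, 90),
                                     absolute_copy_number = c(2L, 3L)), "A"),
               "overlapping")
  expect_error(cn_profile(data.frame(chrom = "1", start = 0, end = 50,
                                     absolute_copy_number = -1), "A"),
               "non-negative")
})

mk_rr <- function(lesion, pos1, pos2, strand1 = "+", strand2 = "-",
                  chrom1 = "1", chrom2 = "1", name = "e") {
  data.frame(lesion_id = lesion, chrom1 = chrom1, pos1 = pos1,
             strand1 = strand1, chrom2 = chrom2, pos2 = pos2,
             strand2 = strand2, name = name, stringsAsFactors = FALSE)
}

test_that("rearrangement matching respects class, strands and tolerance", {
  e1 <- mk_rr("L1", 1000000, 2000000)
  # identical lists: everything common
  res <- match_rearrangements(list(e1, mk_rr("L2", 1000000, 2000000)), 500L)
  expect_equal(res$fraction_common, 1)
  # jitter within tolerance: common; 10 kb off: private
  res <- match_rearrangements(list(e1, mk_rr("L2", 1000200, 1999800)), 500L)
  expect_equal(res$fraction_common, 1)
  res <- match_rearrangements(list(e1, mk_rr("L2", 1010000, 2010000)), 500L)
  expect_equal(res$fraction_common, 0)
  # same breakpoints, different strand pattern: no match
  res <- match_rearrangements(list(e1, mk_rr("L2", 1000000, 2000000,
                                             strand1 = "-", strand2 = "+")),
                              500L)
  expect_equal(res$fraction_common, 0)
  # an event present in only one of two lesions is private to it
  res <- match_rearrangements(list(
    rbind(e1, mk_rr("L1", 5000000, 5400000, "-", "+", name = "dup")),
    mk_rr("L2", 1000000, 2000000)), 500L)
  expect_equal(nrow(res$common_events), 2L)  # the matched pair
  priv <- do.call(rbind, res$private_events)
  expect_equal(priv$name, "dup")
  expect_equal(priv$rr_class, "tandem-duplication-type")
})

test_that("common fraction is invariant under lesion order", {
  set.seed(37)
  lesions <- lapply(c("L1", "L2", "L3"), function(l) {
    ev <- mk_rr(l, 1000000, 2000000)
    if (l != "L3") ev <- rbind(ev, mk_rr(l, runif(1, 3e6, 4e6), 5e6))
    ev
  })
  f1 <- match_rearrangements(lesions, 500L)$fraction_common
  f2 <- match_rearrangements(rev(lesions), 500L)$fraction_common
  expect_equal(f1, f2)
})

test_that("SCNA comparison finds private focal losses and common events", {
  # lesion A loses a PTEN-containing region; lesion B stays diploid there;
  # both share a gain on chromosome 2
  segA <- data.frame(
    chrom = c("1", "1", "1", "2"),
    start = c(0, 3e7, 6e7, 0), end = c(3e7, 6e7, 1e8, 1e8),
    absolute_copy_number = c(2L, 1L, 2L, 3L))
  segB <- data.frame(chrom = c("1", "2"), start = c(0, 0), end = c(1e8, 1e8),
                     absolute_copy_number = c(2L, 3L))
  A <- cn_profile(segA, "A", ploidy = 2)
  B <- cn_profile(segB, "B", ploidy = 2)
  regions <- data.frame(chrom = "1", start = 4e7, end = 4.5e7, gene = "PTEN",
                        expected_direction = "loss", stringsAsFactors = FALSE)
  res <- compare_scna(list(A, B), focal_regions = regions, overlap_min = 0.5)
  loss <- res$aberrations[res$aberrations$direction == "loss", ]
  expect_equal(loss$lesion_id, "A")
  expect_false(loss$common)
  gain <- res$aberrations[res$aberrations$direction == "gain", ]
  expect_true(all(gain$common))
  expect_equal(res$focal_calls$A, "loss")
  expect_equal(res$focal_calls$B, "neutral")
  expect_false(res$focal_calls$common)
  # identical profiles: everything common
  res2 <- compare_scna(list(A, cn_profile(segA, "A2", ploidy = 2)))
  expect_true(all(res2$aberrations$common))
})

test_that("SCNA common calls are invariant to re-segmentation", {
  set.seed(43)
  base <- data.frame(chrom = "1", start = c(0, 2e7, 5e7, 8e7),
                     end = c(2e7, 5e7, 8e7, 1e8),
                     absolute_copy_number = c(2L, 3L, 2L, 1L))
  resegment <- function(seg) {
    rows <- list()
    for (i in seq_len(nrow(seg))) {
      cuts <- sort(c(seg$start[i], seg$end[i],
                     runif(sample(0:2, 1L), seg$start[i], seg$end[i])))
      for (j in seq_len(length(cuts) - 1L))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = seg$chrom[i], start = cuts[j], end = cuts[j + 1L],
          absolute_copy_number = seg$absolute_copy_number[i])
    }
    do.call(rbind, rows)
  }
  A <- cn_profile(base, "A", ploidy = 2)
  for (i in 1:10) {
    B <- cn_profile(resegment(base), "B", ploidy = 2)
    res <- compare_scna(list(A, B), overlap_min = 0.5)
    expect_true(all(res$aberrations$common))
  }
})

test_that("direction calls flip when copies are reflected around the baseline", {
  seg <- data.frame(chrom = "1", start = c(0, 4e7), end = c(4e7, 1e8),
                    absolute_copy_number = c(3L, 1L))
  refl <- seg
  refl$absolute_copy_number <- 4L - seg$absolute_copy_number
  r1 <- compare_scna(list(cn_profile(seg, "A", ploidy = 2),
                          cn_profile(seg, "B", ploidy = 2)))
  r2 <- compare_scna(list(cn_profile(refl, "A", ploidy = 2),
                          cn_profile(refl, "B", ploidy = 2)))
  d1 <- r1$aberrations$direction[order(r1$aberrations$start)]
  d2 <- r2$aberrations$direction[order(r2$aberrations$start)]
  expect_equal(d2, rev(c("gain", "loss"))[match(d1, c("gain", "loss"))])
})

test_that("focal-region tables validate their schema", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgene\texpected_direction",
               "10\t89000000\t90000000\tPTEN\tloss",
               "8\t127000000\t129000000\tMYC\tgain"), f)
  fr <- read_focal_regions(f)
  expect_equal(fr$gene, c("PTEN", "MYC"))
  writeLines(c("chrom\tstart\tend\tgene\texpected_direction",
               "10\t1\t2\tPTEN\tdown"), f)
  expect_error(read_focal_regions(f), "gain or loss")
})

test_that("BEDPE files round-trip through the reader", {
  f <- tempfile(fileext = ".bedpe")
  writeLines(c("1\t1000000\t1000001\t1\t2000000\t2000001\tdel1\t0\t+\t-",
               "2\t500000\t500001\t3\t700000\t700001\ttra1\t0\t+\t+"), f)
  ev <- read_bedpe(f, "L1")
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$rr_class, c("deletion-type", "inter-chromosomal"))
  expect_equal(ev$pos1, c(1000000L, 500000L))
})
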