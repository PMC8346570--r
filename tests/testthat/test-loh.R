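test_that("segment validation enforces ordering and allele arithmetic", {
  seg <- data.frame(sample_id = "S", chrom = "1",
                    start = c(1, 201), end = c(100, 300),
                    cn_total = c(2L, 2L), cn_minor = c(0L, 1L))
  prof <- segment_profile(seg)
  expect_equal(prof$covered_length, 200)
  expect_equal(prof$segments$loh, c(TRUE, FALSE))

  bad <- seg; bad$end[1] <- 0
  expect_error(segment_profile(bad), "start > end")
  overlapping <- seg; overlapping$start[2] <- 50
  expect_error(segment_profile(overlapping), "overlapping")
  minor_heavy <- seg; minor_heavy$cn_minor[1] <- 2L
  expect_error(segment_profile(minor_heavy), "major")

  # copy-neutral LOH, deletion LOH and homozygous deletion all count
  states <- data.frame(sample_id = "S", chrom = "1",
                       start = c(1, 101, 201, 301),
                       end = c(100, 200, 300, 400),
                       cn_total = c(2L, 1L, 0L, 3L),
                       cn_minor = c(0L, 0L, 0L, 1L))
  expect_equal(segment_profile(states)$segments$loh,
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("LOH fractions use the requested denominator", {
  seg <- data.frame(sample_id = "S", chrom = "1",
                    start = c(1, 3e7 + 1), end = c(3e7, 1e8),
                    cn_total = c(2L, 2L), cn_minor = c(0L, 1L))
  prof <- segment_profile(seg)
  expect_equal(loh_fraction(prof), 0.30)
  expect_equal(loh_fraction(prof, "autosome_total"),
               3e7 / sum(autosome_lengths()$length))

  no_loh <- segment_profile(data.frame(sample_id = "S", chrom = "1",
                                       start = 1, end = 100,
                                       cn_total = 2L, cn_minor = 1L))
  expect_equal(loh_fraction(no_loh), 0)

  full <- segment_profile(data.frame(sample_id = "S", chrom = "1",
                                     start = 1, end = 100,
                                     cn_total = 1L, cn_minor = 0L))
  expect_equal(loh_fraction(full), 1.0)
})

test_that("three-way shared LOH uses inclusive interval arithmetic", {
  len <- 1e4
  p1 <- toy_profile(data.frame(start = 100, end = 200), len)
  p2 <- toy_profile(data.frame(start = 150, end = 300), len)
  p3 <- toy_profile(data.frame(start = 180, end = 220), len)
  sh <- shared_loh(p1, p2, p3)
  expect_equal(sh$segments$start, 180)
  expect_equal(sh$segments$end, 200)
  expect_equal(sh$fraction, 21 / len)

  empty <- toy_profile(data.frame(start = integer(0), end = integer(0)),
                       len)
  expect_equal(nrow(shared_loh(p1, p2, empty)$segments), 0)
  expect_equal(shared_loh(p1, p2, empty)$fraction, 0)
})

test_that("interval intersection matches the per-base oracle and is symmetric", {
  len <- 1e4
  set.seed(17)
  for (trial in 1:25) {
    ints <- lapply(1:3, function(i) random_intervals(len))
    profs <- lapply(ints, toy_profile, len = len)
    sh <- shared_loh(profs[[1]], profs[[2]], profs[[3]])
    masks <- lapply(ints, perbase_mask, len = len)
    expect_equal(sh$fraction,
                 sum(masks[[1]] & masks[[2]] & masks[[3]]) / len)
    # commutativity over profile order
    perm <- sample(3)
    sh2 <- shared_loh(profs[[perm[1]]], profs[[perm[2]]],
                      profs[[perm[3]]])
    expect_equal(sh2$fraction, sh$fraction)
    expect_equal(sh2$segments, sh$segments)
  }
})

test_that("chromosome-level profiles are length-weighted consistently", {
  genome <- autosome_lengths()
  chr18 <- data.frame(chrom = "18", start = 1,
                      end = genome$length[genome$chrom == "18"])
  prof <- chromosome_loh_profile(chr18)
  expect_equal(unname(prof[["18"]]), 1.0)
  expect_equal(sum(prof > 0), 1)

  none <- chromosome_loh_profile(chr18[0, ])
  expect_true(all(none == 0))

  set.seed(23)
  segs <- do.call(rbind, lapply(sample(genome$chrom, 8), function(ch) {
    l <- genome$length[genome$chrom == ch]
    s <- sort(sample.int(l, 2))
    data.frame(chrom = ch, start = s[1], end = s[2])
  }))
  byc <- chromosome_loh_profile(segs)
  genomewide <- sum(segs$end - segs$start + 1) / sum(genome$length)
  expect_equal(sum(byc * genome$length) / sum(genome$length), genomewide)

  expect_error(chromosome_loh_profile(data.frame(chrom = "X", start = 1,
                                                 end = 10)),
               "unknown chromosome")
})

test_that("LOH profile clustering recovers simulated groups deterministically", {
  set.seed(31)
  high <- t(replicate(4, pmin(1, abs(rnorm(22, 0.45, 0.1)))))
  low <- t(replicate(4, abs(rnorm(22, 0.02, 0.01))))
  mat <- rbind(high, low)
  rownames(mat) <- paste0("S", 1:8)
  cl <- cluster_loh_profiles(mat)
  expect_equal(length(unique(cl$labels[1:4])), 1)
  expect_equal(length(unique(cl$labels[5:8])), 1)
  expect_false(cl$labels[1] == cl$labels[5])

  # identical profiles merge at height zero
  twin <- rbind(a = rep(0.2, 22), b = rep(0.2, 22))
  expect_equal(min(cluster_loh_profiles(twin)$hclust$height), 0)

  # permutation invariance of the merge structure
  perm <- sample(8)
  cl2 <- cluster_loh_profiles(mat[perm, ])
  d1 <- as.matrix(stats::cophenetic(cl$hclust))
  d2 <- as.matrix(stats::cophenetic(cl2$hclust))
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
})

test_that("SEG round-trip preserves the profile", {
  seg <- data.frame(sample_id = "S1", chrom = c("1", "2"),
                    start = c(1, 500), end = c(400, 900),
                    cn_total = c(2L, 1L), cn_minor = c(1L, 0L))
  path <- tempfile(fileext = ".seg")
  write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_seg(path)
  expect_equal(back$loh, c(FALSE, TRUE))
  expect_equal(back[names(seg)], seg)
})
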