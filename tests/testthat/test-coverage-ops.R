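sam_header <- function(seqids = "chr1", len = 100000L) {
  c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", seqids, len))
}

sam_line <- function(qname, flag, rname, pos, cigar, len = 10L) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
          qname, flag, rname, pos, cigar, strrep("A", len))
}

write_sam <- function(lines) {
  p <- tempfile(fileext = ".sam")
  writeLines(lines, p)
  p
}

test_that("CIGAR reference spans: M consumes, N splits, I/S do not consume", {
  p <- write_sam(c(sam_header(),
                   sam_line("r1", 0L, "chr1", 100L, "10M"),
                   sam_line("r2", 0L, "chr1", 100L, "5M3N5M"),
                   sam_line("r3", 0L, "chr1", 200L, "3S5M2I2M", len = 12L),
                   sam_line("r4", 0L, "chr1", 300L, "4M2D4M", len = 8L)))
  iv <- alignments_to_intervals(p)
  expect_equal(iv[iv$start == 100 & iv$end == 109, ]$seqid, "chr1")
  # spliced read becomes two intervals
  expect_true(any(iv$start == 100 & iv$end == 104))
  expect_true(any(iv$start == 108 & iv$end == 112))
  # soft clips and insertions consume nothing: 5M2I2M from 200 -> (200,206)
  expect_true(any(iv$start == 200 & iv$end == 206))
  # deletions consume reference and are covered by default: (300,309)
  expect_true(any(iv$start == 300 & iv$end == 309))
  # ... but can be excluded
  iv2 <- alignments_to_intervals(p, include_deletions = FALSE)
  expect_true(any(iv2$start == 300 & iv2$end == 303))
  expect_true(any(iv2$start == 306 & iv2$end == 309))
})

test_that("unmapped, secondary and supplementary records are excluded", {
  p <- write_sam(c(sam_header(),
                   sam_line("r1", 0L, "chr1", 100L, "10M"),
                   "u1\t4\t*\t0\t0\t*\t*\t0\t0\tAAAAAAAAAA\t*",
                   sam_line("r2", 256L, "chr1", 200L, "10M"),
                   sam_line("r3", 2048L, "chr1", 300L, "10M"),
                   sam_line("r4", 1024L, "chr1", 400L, "10M")))
  iv <- alignments_to_intervals(p)
  expect_equal(nrow(iv), 2L)  # primary + duplicate (kept by default)
  expect_equal(nrow(alignments_to_intervals(p, drop_duplicates = TRUE)), 1L)
})

test_that("sorted and shuffled alignment input give identical intervals", {
  p1 <- tempfile(fileext = ".sam"); p2 <- tempfile(fileext = ".sam")
  generate_alignments(p1, n_reads = 300L, sorted = TRUE, seed = 71L)
  generate_alignments(p2, n_reads = 300L, sorted = FALSE, seed = 71L)
  expect_equal(alignments_to_intervals(p1), alignments_to_intervals(p2))
})

test_that("interval merging is exact, bookended-aware, and order-checked", {
  m <- merge_intervals(c(1, 40), c(50, 60))
  expect_equal(m, list(starts = 1, ends = 60))
  m2 <- merge_intervals(c(1, 7), c(5, 9))
  expect_equal(m2$starts, c(1, 7))  # gap at 6: not merged
  m3 <- merge_intervals(c(1, 6), c(5, 9))
  expect_equal(m3, list(starts = 1, ends = 9))  # bookended: merged
  expect_error(merge_intervals(c(5, 1), c(9, 3)),
               class = "annodex_contract_error")
  # union size equals a per-base bitmap oracle
  set.seed(73)
  s <- sort(sample.int(5e4, 2000L, replace = TRUE))
  e <- s + sample.int(300L, 2000L, replace = TRUE)
  m4 <- merge_intervals(s, e)
  bitmap <- logical(max(e))
  for (i in seq_along(s)) bitmap[s[i]:e[i]] <- TRUE
  expect_equal(sum(m4$ends - m4$starts + 1), sum(bitmap))
  expect_true(all(m4$starts[-1] > m4$ends[-length(m4$ends)] + 1))
})

test_that("the worked breadth/depth example is exact", {
  # target 1-100 with reads 1-50 and 40-60: covered 60, breadth 0.6, depth 71
  p <- write_sam(c(sam_header(),
                   sam_line("r1", 0L, "chr1", 1L, "50M", len = 50L),
                   sam_line("r2", 0L, "chr1", 40L, "21M", len = 21L)))
  tg <- data.frame(seqid = "chr1", start = 1, end = 100, name = "t1")
  cv <- coverage_breadth(p, targets = tg)
  expect_equal(cv$covered_bases, 60)
  expect_equal(cv$breadth, 0.6)
  dp <- coverage_depth(p, targets = tg)
  expect_equal(dp$depth_sum, 71)
  expect_equal(dp$mean_depth, 0.71)
})

test_that("no alignments give zero coverage; double full overlap gives mean 2", {
  tg <- data.frame(seqid = "chr1", start = 1, end = 100)
  p0 <- write_sam(sam_header())
  cv <- coverage_breadth(p0, targets = tg)
  expect_equal(cv$covered_bases, 0)
  expect_equal(cv$breadth, 0)
  p2 <- write_sam(c(sam_header(),
                    sam_line("r1", 0L, "chr1", 1L, "100M", len = 100L),
                    sam_line("r2", 0L, "chr1", 1L, "100M", len = 100L)))
  dp <- coverage_depth(p2, targets = tg)
  expect_equal(dp$mean_depth, 2)
  cv2 <- coverage_breadth(p2, targets = tg)
  expect_equal(cv2$breadth, 1)
})

test_that("breadth and depth equal the per-base oracle on random fixtures", {
  for (seed in c(81L, 82L)) {
    sam <- tempfile(fileext = ".sam")
    generate_alignments(sam, n_reads = 800L, seqid_len = 1e5, spliced_p = 0.3,
                        seed = seed)
    bed <- tempfile()
    generate_bed(bed, n = 60L, seqid_len = 1e5, length_range = c(50L, 3000L),
                 seed = seed + 1L)
    tg <- parse_bed4(bed)
    iv <- alignments_to_intervals(sam)
    cv <- coverage_breadth(iv, targets = tg)
    dp <- coverage_depth(iv, targets = tg)
    for (i in seq_len(nrow(tg))) {
      r <- iv[iv$seqid == tg$seqid[i], , drop = FALSE]
      want <- per_base_coverage(tg$start[i], tg$end[i], r$start, r$end)
      expect_equal(cv$covered_bases[i], want$covered)
      expect_equal(dp$depth_sum[i], want$depth_sum)
    }
  }
})

test_that("depth histograms count bases at each integer depth", {
  p <- write_sam(c(sam_header(),
                   sam_line("r1", 0L, "chr1", 1L, "50M", len = 50L),
                   sam_line("r2", 0L, "chr1", 40L, "21M", len = 21L)))
  tg <- data.frame(seqid = "chr1", start = 1, end = 100)
  dp <- coverage_depth(p, targets = tg, report = "histogram")
  h <- dp$histogram[[1]]
  expect_equal(h$bases[h$depth == 0], 40)  # 61-100
  expect_equal(h$bases[h$depth == 1], 49)  # 1-39 and 51-60
  expect_equal(h$bases[h$depth == 2], 11)  # 40-50
})

test_that("results are invariant to slice size, worker count, and sort order", {
  sam_sorted <- tempfile(fileext = ".sam")
  sam_shuf <- tempfile(fileext = ".sam")
  generate_alignments(sam_sorted, n_reads = 600L, seqid_len = 2e5,
                      sorted = TRUE, seed = 91L)
  generate_alignments(sam_shuf, n_reads = 600L, seqid_len = 2e5,
                      sorted = FALSE, seed = 91L)
  bed <- tempfile()
  generate_bed(bed, n = 50L, seqid_len = 2e5, seed = 92L)
  tg <- parse_bed4(bed)

  render <- function(sam, max_slice, workers) {
    f <- tempfile()
    write_coverage_table(
      coverage_breadth(sam, targets = tg, max_slice = max_slice,
                       workers = workers), f)
    g <- tempfile()
    write_coverage_table(
      coverage_depth(sam, targets = tg, max_slice = max_slice,
                     workers = workers), g)
    c(readLines(f), readLines(g))
  }
  ref <- render(sam_sorted, Inf, 1L)
  expect_identical(render(sam_sorted, 1e3, 1L), ref)
  expect_identical(render(sam_sorted, 1e4, 1L), ref)
  expect_identical(render(sam_sorted, 1e4, 4L), ref)
  expect_identical(render(sam_shuf, Inf, 1L), ref)
})

test_that("slices never split a target and cover every target once", {
  set.seed(97)
  s <- sort(sample.int(1e5, 200L))
  e <- s + sample.int(2000L, 200L, replace = TRUE)
  for (ms in c(1e3, 1e4, Inf)) {
    slices <- partition_slices(s, e, ms)
    idx <- unlist(lapply(slices, `[[`, "idx"))
    expect_setequal(idx, seq_along(s))
    expect_equal(length(idx), length(s))
    for (sl in slices) {
      expect_true(all(s[sl$idx] >= sl$lo & e[sl$idx] <= sl$hi))
    }
  }
  # a single target longer than max_slice stretches its slice
  sl <- partition_slices(10, 5000, max_slice = 100)
  expect_equal(sl[[1]]$lo, 10)
  expect_equal(sl[[1]]$hi, 5000)
})

test_that("targets can be drawn from the annotation by feature type", {
  fx <- new_gff_fixture(n_genes = 15L, seed = 87L)
  sam <- tempfile(fileext = ".sam")
  generate_alignments(sam, n_reads = 300L, seqid_len = 1e5, seed = 88L)
  cv <- coverage_breadth(sam, gff_path = fx$path, target_type = "gene")
  genes <- fx$manifest[fx$manifest$ftype == "gene", ]
  expect_equal(cv$target_id, genes$id)
  expect_equal(cv$start, genes$start)
  expect_true(all(cv$breadth >= 0 & cv$breadth <= 1))
  cvm <- coverage_breadth(sam, gff_path = fx$path, target_type = "mRNA")
  expect_equal(nrow(cvm), sum(fx$manifest$ftype == "mRNA"))
})
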