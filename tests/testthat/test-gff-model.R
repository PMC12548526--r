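test_that("parse_feature_line maps the nine columns and decodes attributes", {
  rec <- parse_feature_line("chr1\t.\tgene\t100\t200\t.\t+\t.\tID=g1\n")
  expect_equal(rec$seqid, "chr1")
  expect_equal(rec$ftype, "gene")
  expect_equal(rec$start, 100)
  expect_equal(rec$end, 200)
  expect_equal(rec$byte_start, 0)
  expect_equal(rec$byte_end, nchar("chr1\t.\tgene\t100\t200\t.\t+\t.\tID=g1\n"))
  expect_equal(rec$attributes[[1]][["ID"]], "g1")

  rec2 <- parse_feature_line(
    "chr1\t.\tgene\t1\t2\t.\t+\t.\tNote=a%3Bb;X=p%3Dq%2Cr%25s\n")
  expect_equal(unname(rec2$attributes[[1]]["Note"]), "a;b")
  expect_equal(unname(rec2$attributes[[1]]["X"]), "p=q,r%s")
  # attribute key order is preserved
  expect_equal(names(rec2$attributes[[1]]), c("Note", "X"))
})

test_that("malformed lines are rejected with their line number", {
  expect_error(parse_feature_line("chr1\tgene\t100\t200\n", line_no = 7L),
               class = "annodex_malformed_error")
  err <- tryCatch(parse_feature_line("chr1\tgene\t100\t200\n", line_no = 7L),
                  annodex_malformed_error = identity)
  expect_equal(err$line_no, 7L)
  expect_error(parse_feature_line("chr1\t.\tgene\t200\t100\t.\t+\t.\tID=x\n"),
               class = "annodex_malformed_error")
  expect_error(parse_feature_line("chr1\t.\tgene\tabc\t100\t.\t+\t.\tID=x\n"),
               class = "annodex_malformed_error")
})

test_that("scan_gff records exact byte spans and stops at ##FASTA", {
  path <- write_gff_lines(c("##gff-version 3",
                            "chr1\t.\tgene\t1\t10\t.\t+\t.\tID=a",
                            "# a comment",
                            "chr1\t.\tgene\t20\t30\t.\t+\t.\tID=b",
                            "chr2\t.\tgene\t5\t9\t.\t-\t.\tID=c",
                            "##FASTA",
                            ">chr1", "ACGT"))
  s <- scan_gff(path)
  expect_equal(nrow(s$records), 3L)
  expect_equal(s$seqids, c("chr1", "chr2"))
  raw <- readBin(path, "raw", file.size(path))
  expect_equal(s$fasta_boundary,
               gregexpr("##FASTA", rawToChar(raw), fixed = TRUE)[[1]][1] - 1)
  # byte fidelity: slicing the file at [byte_start, byte_end) reproduces lines
  for (i in seq_len(nrow(s$records))) {
    slice <- rawToChar(raw[(s$records$byte_start[i] + 1):s$records$byte_end[i]])
    expect_equal(slice, paste0(readLines(path)[s$records$line_no[i]], "\n"))
  }
})

test_that("scan_gff handles comment-only and empty files", {
  p1 <- write_gff_lines(c("##gff-version 3", "# nothing here"))
  s1 <- scan_gff(p1)
  expect_equal(nrow(s1$records), 0L)
  expect_equal(s1$seqids, character(0))
  p2 <- tempfile(); file.create(p2)
  expect_equal(nrow(scan_gff(p2)$records), 0L)
})

test_that("byte fidelity holds on a generated fixture", {
  fx <- new_gff_fixture(n_genes = 40L, seed = 11L, indexed = FALSE)
  s <- scan_gff(fx$path)
  raw <- readBin(fx$path, "raw", file.size(fx$path))
  txt <- rawToChar(raw)
  for (i in sample.int(nrow(s$records), 25L)) {
    slice <- substr(txt, s$records$byte_start[i] + 1, s$records$byte_end[i])
    expect_true(endsWith(slice, "\n"))
    expect_equal(nchar(slice), s$records$byte_end[i] - s$records$byte_start[i])
  }
})

test_that("hierarchy resolution follows Parent chains to the root", {
  path <- write_gff_lines(c(
    "chr1\t.\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\t.\texon\t1\t50\t.\t+\t.\tParent=t1",
    "chr1\t.\tgene\t200\t300\t.\t+\t.\tID=g2"))
  s <- scan_gff(path)
  tb <- resolve_hierarchy(s$records)
  expect_equal(tb$root_of, c(1, 1, 1, 4))
  expect_equal(tb$parent_of, c(NA, 1, 2, NA))
  # root_of[i] == i exactly when parent_of[i] is none
  expect_equal(which(tb$root_of == seq_len(tb$n_features)),
               which(is.na(tb$parent_of)))
})

test_that("hierarchy matches the transitive-closure oracle on random forests", {
  for (seed in c(3L, 4L)) {
    fx <- new_gff_fixture(n_genes = 50L, seed = seed, indexed = FALSE,
                          interleave_fraction = 0.3)
    s <- scan_gff(fx$path)
    tb <- resolve_hierarchy(s$records)
    expect_equal(tb$root_of, transitive_root(tb$parent_of))
    # generator manifest agrees with the parser (cross-check)
    expect_equal(tb$string_ids[tb$root_of], fx$manifest$root_id)
  }
})

test_that("dangling parents and cycles are rejected", {
  p <- write_gff_lines(c("chr1\t.\tmRNA\t1\t10\t.\t+\t.\tID=t1;Parent=ghost"))
  expect_error(resolve_hierarchy(scan_gff(p)$records),
               class = "annodex_data_error")
  p2 <- write_gff_lines(c("chr1\t.\tx\t1\t10\t.\t+\t.\tID=a;Parent=b",
                          "chr1\t.\tx\t1\t10\t.\t+\t.\tID=b;Parent=a"))
  expect_error(resolve_hierarchy(scan_gff(p2)$records),
               class = "annodex_cycle_error")
})

test_that("multiple parents use the first and warn when roots differ", {
  p <- write_gff_lines(c("chr1\t.\tgene\t1\t100\t.\t+\t.\tID=g1",
                         "chr1\t.\tgene\t200\t300\t.\t+\t.\tID=g2",
                         "chr1\t.\texon\t10\t20\t.\t+\t.\tID=e1;Parent=g1,g2"))
  s <- scan_gff(p)
  expect_warning(tb <- resolve_hierarchy(s$records),
                 class = "annodex_multiparent_warning")
  expect_equal(tb$root_of[3], 1)
})

test_that("blocks partition features and follow byte contiguity", {
  path <- new_toy_gff(indexed = FALSE)
  s <- scan_gff(path)
  tb <- resolve_hierarchy(s$records)
  bl <- delineate_blocks(tb, s$records)
  expect_equal(nrow(bl), 2L)
  # every feature in exactly one block
  expect_setequal(unlist(bl$members), seq_len(tb$n_features))
  expect_equal(sum(lengths(bl$members)), tb$n_features)
  # the two models are interleaved once each -> 2 byte ranges per block;
  # spans cover all members
  expect_equal(vapply(bl$byte_ranges, nrow, 0L), c(2L, 2L))
  expect_equal(bl$span_start, c(100, 600))
  expect_equal(bl$span_end, c(500, 900))
  # block numbering monotone in root appearance order
  expect_true(!is.unsorted(bl$block_no))
})

test_that("block byte ranges reproduce exactly the member lines (label oracle)", {
  fx <- new_gff_fixture(n_genes = 40L, seed = 9L, indexed = FALSE,
                        interleave_fraction = 0.4)
  s <- scan_gff(fx$path)
  tb <- resolve_hierarchy(s$records)
  bl <- delineate_blocks(tb, s$records)
  raw <- rawToChar(readBin(fx$path, "raw", file.size(fx$path)))
  # oracle: label every feature line by its root via the manifest
  lines <- gff_feature_lines(fx$path)
  labels <- fx$manifest$root_id
  for (b in seq_len(nrow(bl))) {
    got <- unlist(lapply(seq_len(nrow(bl$byte_ranges[[b]])), function(r) {
      rr <- bl$byte_ranges[[b]][r, ]
      strsplit(sub("\n$", "", substr(raw, rr[1] + 1, rr[2])), "\n")[[1]]
    }))
    root_id <- tb$string_ids[bl$block_no[b]]
    expect_equal(got, lines[labels == root_id])
  }
})

test_that("a contiguous model yields exactly one byte range", {
  p <- write_gff_lines(c("chr1\t.\tgene\t1\t100\t.\t+\t.\tID=g1",
                         "chr1\t.\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
                         "chr1\t.\texon\t1\t50\t.\t+\t.\tParent=t1",
                         "chr1\t.\texon\t60\t100\t.\t+\t.\tParent=t1"))
  s <- scan_gff(p)
  bl <- delineate_blocks(resolve_hierarchy(s$records), s$records)
  expect_equal(nrow(bl), 1L)
  expect_equal(nrow(bl$byte_ranges[[1]]), 1L)
})
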