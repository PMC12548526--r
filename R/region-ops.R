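# BED-driven region intersection. BED is 0-based half-open; everything
# internal is 1-based inclusive (GFF3 native), converted at the I/O boundary:
# BED (99, 200) -> (100, 200).

#' Parse a BED3/BED4 interval file
#'
#' @param path Path to a tab-separated BED file with 3 or 4 columns.
#' @return Data frame of query regions with columns `seqid`, `start`, `end`
#'   (converted to 1-based inclusive) and `name` (`NA` when absent).
#'   Zero-length intervals (`chromStart == chromEnd`) are rejected.
#' @export
parse_bed4 <- function(path) {
  if (!file.exists(path)) adx_data_error(sprintf("cannot read '%s'", path))
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  if (!length(keep)) {
    return(data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  cols <- strsplit(lines[keep], "\t", fixed = TRUE)
  nc <- lengths(cols)
  if (any(nc < 3L)) {
    bad <- which(nc < 3L)[1L]
    adx_malformed_error(sprintf("BED line %d: fewer than 3 columns", keep[bad]),
                        line_no = keep[bad])
  }
  seqid <- vapply(cols, `[[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(cols, `[[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(cols, `[[`, "", 3L)))
  if (any(is.na(s0) | is.na(e0))) {
    bad <- which(is.na(s0) | is.na(e0))[1L]
    adx_malformed_error(sprintf("BED line %d: non-numeric coordinates", keep[bad]),
                        line_no = keep[bad])
  }
  if (any(s0 >= e0)) {
    bad <- which(s0 >= e0)[1L]
    adx_malformed_error(sprintf(
      "BED line %d: chromStart >= chromEnd (zero-length or inverted interval)",
      keep[bad]), line_no = keep[bad])
  }
  name <- vapply(cols, function(x) if (length(x) >= 4L) x[[4L]] else NA_character_, "")
  data.frame(seqid = seqid, start = s0 + 1, end = e0, name = name,
             stringsAsFactors = FALSE)
}

#' Write query regions back to BED4
#' @param regions Data frame as returned by [parse_bed4()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed4 <- function(regions, path) {
  nm <- ifelse(is.na(regions$name), ".", regions$name)
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s",
                     regions$seqid, regions$start - 1, regions$end, nm),
             path)
  invisible(path)
}

#' Intersect query regions with indexed annotation
#'
#' Regions are pre-bucketed by seqid and sorted by start; each seqid's
#' interval tree is loaded once and queried per region. The union of hit
#' blocks is emitted deduplicated in file order, so output is invariant to
#' the input region order. In `mode = "feature"`, member lines of hit blocks
#' are re-parsed and only features whose own span overlaps at least one
#' query region are emitted (lines stay verbatim; coordinates are never
#' clipped). A region on a seqid absent from the index scores zero hits and
#' is reported, not an error.
#'
#' @param regions Data frame from [parse_bed4()], or any data frame with
#'   `seqid`, `start`, `end` in 1-based inclusive coordinates (`name`
#'   optional).
#' @param gff_path Path to the indexed GFF3 file.
#' @param mode `"block"` (default: whole annotation models) or `"feature"`.
#' @param out Optional path or connection for streaming GFF3 output.
#' @return A list with `text` (output lines; `NULL` when streamed to `out`),
#'   `report` (per-region data frame with `n_blocks` hit), and `block_nos`.
#' @export
intersect_regions <- function(regions, gff_path, mode = c("block", "feature"),
                              out = NULL) {
  mode <- match.arg(mode)
  if (is.null(regions$name)) regions$name <- NA_character_
  if (any(regions$start > regions$end)) {
    adx_usage_error("query region with start > end")
  }
  bundle <- load_bundle(gff_path, c("gof", "prt", "sqs", "rix", "rit"))

  n_blocks <- integer(nrow(regions))
  all_hits <- numeric(0)
  for (s in unique(regions$seqid)) {        # pre-bucket by seqid
    idx <- which(regions$seqid == s)
    idx <- idx[order(regions$start[idx])]   # sort by start within the bucket
    tree <- bundle_tree(bundle, s)
    for (i in idx) {
      res <- query_overlaps(tree, regions$start[i], regions$end[i])
      n_blocks[i] <- length(res$block_nos)
      all_hits <- c(all_hits, res$block_nos)
    }
  }
  blocks <- sort(unique(all_hits))

  filter <- NULL
  if (mode == "feature") {
    filter <- function(lines) {
      recs <- parse_feature_lines(lines, seq_along(lines), seq_along(lines),
                                  seq_along(lines))
      vapply(seq_len(nrow(recs)), function(i) {
        q <- regions[regions$seqid == recs$seqid[i], , drop = FALSE]
        any(q$start <= recs$end[i] & q$end >= recs$start[i])
      }, TRUE)
    }
  }

  report <- data.frame(seqid = regions$seqid, start = regions$start,
                       end = regions$end, name = regions$name,
                       n_blocks = n_blocks, stringsAsFactors = FALSE)
  if (!is.null(out)) {
    with_output_con(out, "##gff-version 3", function(con) {
      emit_blocks(bundle, blocks, filter, con = con)
    })
    return(list(text = NULL, report = report, block_nos = blocks))
  }
  list(text = c("##gff-version 3", emit_blocks(bundle, blocks, filter)),
       report = report, block_nos = blocks)
}

# "chr:start-end" (1-based inclusive) -> one-row region data frame.
parse_region_string <- function(spec) {
  m <- regmatches(spec, regexec("^(.+):([0-9]+)-([0-9]+)$", spec))[[1L]]
  if (length(m) != 4L) {
    adx_usage_error(sprintf("bad region '%s'; expected chr:start-end", spec))
  }
  start <- as.numeric(m[3L]); end <- as.numeric(m[4L])
  if (start < 1 || start > end) {
    adx_usage_error(sprintf("bad region '%s': need 1 <= start <= end", spec))
  }
  data.frame(seqid = m[2L], start = start, end = end, name = NA_character_,
             stringsAsFactors = FALSE)
}
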