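# Coverage breadth and depth of targets from SAM/BAM alignments.
#
# Pipeline: alignments -> reference-space intervals (CIGAR M/=/X/D consume
# reference and are covered; N splits a record into several intervals; I, S,
# H, P consume none) -> per-seqid slices cut between targets -> per slice,
# interval merging + a two-pointer sweep for breadth and a difference-array
# sweep for depth. Slice size, worker count, and input sort order never
# change the result; per-slice rows are reassembled in target input order.

#' Convert alignments to reference-space intervals
#'
#' Reads a SAM or BAM file and emits one 1-based inclusive interval per
#' reference-consuming run of each kept alignment. Skipped regions (CIGAR
#' `N`) split a record into multiple intervals; deletions (`D`) are covered
#' by default (reference-span semantics) and can be excluded. Unmapped,
#' secondary (0x100) and supplementary (0x800) records are dropped;
#' duplicates (0x400) are kept unless `drop_duplicates`.
#'
#' Output is fully sorted by (seqid, start, end), so coordinate-sorted and
#' unsorted inputs yield identical interval tables.
#'
#' @param path SAM or BAM file with a header.
#' @param drop_duplicates Drop records flagged as PCR/optical duplicates.
#' @param include_deletions Count CIGAR `D` bases as covered (default).
#' @return Data frame with `seqid`, `start`, `end`, one row per interval.
#' @export
alignments_to_intervals <- function(path, drop_duplicates = FALSE,
                                    include_deletions = TRUE) {
  if (!file.exists(path)) adx_data_error(sprintf("cannot read '%s'", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
      error = function(e) adx_data_error(sprintf(
        "cannot parse SAM '%s' (missing/invalid header?): %s", path, conditionMessage(e)))
    )
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (drop_duplicates) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  keep <- !is.na(rec$pos) & !is.na(rec$cigar)
  if (!any(keep)) {
    return(data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  rl <- GenomicAlignments::extractAlignmentRangesOnReference(
    rec$cigar[keep], pos = rec$pos[keep],
    drop.D.ranges = !include_deletions)
  counts <- S4Vectors::elementNROWS(rl)
  flat <- unlist(rl, use.names = FALSE)
  out <- data.frame(
    seqid = rep(as.character(rec$rname[keep]), counts),
    start = as.numeric(IRanges::start(flat)),
    end = as.numeric(IRanges::end(flat)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$seqid, out$start, out$end, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge sorted intervals into a disjoint set
#'
#' Overlapping or bookended intervals (`end + 1 == next start`) are merged,
#' so a fully tiled target reaches breadth exactly 1. Input must be sorted
#' by start (single seqid); total covered bases are preserved.
#'
#' @param starts,ends Interval coordinates sorted by `starts`.
#' @return List with disjoint sorted `starts` and `ends`.
#' @export
merge_intervals <- function(starts, ends) {
  n <- length(starts)
  if (n == 0L) return(list(starts = numeric(0), ends = numeric(0)))
  if (is.unsorted(starts)) {
    adx_error("annodex_contract_error", "merge_intervals requires start-sorted input")
  }
  hi <- cummax(ends)
  new_run <- c(TRUE, starts[-1L] > hi[-n] + 1)
  grp <- cumsum(new_run)
  list(starts = starts[new_run],
       ends = as.numeric(tapply(ends, grp, max)))
}

# Two-pointer co-linear sweep: covered bases of each target against a
# disjoint, sorted merged-interval set. Both inputs sorted by start.
sweep_breadth <- function(t_start, t_end, m_start, m_end) {
  nt <- length(t_start); nm <- length(m_start)
  covered <- numeric(nt)
  j <- 1L
  for (i in seq_len(nt)) {
    while (j <= nm && m_end[j] < t_start[i]) j <- j + 1L
    k <- j
    acc <- 0
    while (k <= nm && m_start[k] <= t_end[i]) {
      acc <- acc + min(m_end[k], t_end[i]) - max(m_start[k], t_start[i]) + 1
      k <- k + 1L
    }
    covered[i] <- acc
  }
  covered
}

# Difference-array depth over one slice [lo, hi]: per-target summed depth,
# and optionally the per-depth base-count histogram.
slice_depth <- function(t_start, t_end, iv_start, iv_end, lo, hi,
                        histogram = FALSE) {
  len <- hi - lo + 1
  d <- numeric(len + 1L)
  if (length(iv_start)) {
    s <- pmax(iv_start, lo) - lo + 1
    e <- pmin(iv_end, hi) - lo + 1
    ok <- s <= e
    for (i in which(ok)) {
      d[s[i]] <- d[s[i]] + 1
      d[e[i] + 1L] <- d[e[i] + 1L] - 1
    }
  }
  cov <- cumsum(d[seq_len(len)])
  pre <- c(0, cumsum(cov))
  depth_sum <- pre[t_end - lo + 2] - pre[t_start - lo + 1]
  hist <- NULL
  if (histogram) {
    hist <- lapply(seq_along(t_start), function(i) {
      v <- cov[(t_start[i] - lo + 1):(t_end[i] - lo + 1)]
      tb <- table(v)
      data.frame(depth = as.numeric(names(tb)), bases = as.numeric(tb))
    })
  }
  list(depth_sum = depth_sum, histogram = hist)
}

#' Partition targets of one seqid into independent slices
#'
#' Slices are cut only at coordinates not interior to any target: targets
#' are clustered by overlap, and clusters are packed greedily into slices of
#' at most `max_slice` bases (a single cluster longer than `max_slice` gets
#' its own, stretched slice — a target is never split). Every alignment
#' interval is assigned to every slice it overlaps, so per-slice results
#' concatenate to exactly the unpartitioned result.
#'
#' @param t_start,t_end Target coordinates (one seqid), sorted by start.
#' @param max_slice Maximum slice span in bp (`Inf` = one slice).
#' @return List of slices: `lo`, `hi`, `idx` (indices into the sorted
#'   targets).
#' @export
partition_slices <- function(t_start, t_end, max_slice = Inf) {
  nt <- length(t_start)
  if (nt == 0L) return(list())
  hi <- cummax(t_end)
  new_cluster <- c(TRUE, t_start[-1L] > hi[-nt])
  cl <- cumsum(new_cluster)
  ncl <- cl[nt]
  cl_lo <- t_start[new_cluster]
  cl_hi <- as.numeric(tapply(t_end, cl, max))

  slices <- list()
  cur <- 1L
  while (cur <= ncl) {
    last <- cur
    while (last + 1L <= ncl && cl_hi[last + 1L] - cl_lo[cur] + 1 <= max_slice) {
      last <- last + 1L
    }
    slices[[length(slices) + 1L]] <- list(
      lo = cl_lo[cur], hi = max(cl_hi[cur:last]),
      idx = which(cl >= cur & cl <= last)
    )
    cur <- last + 1L
  }
  slices
}

resolve_targets <- function(gff_path, bam_path, targets = NULL,
                            target_type = "gene") {
  if (!is.null(targets)) {
    nm <- targets$name
    if (is.null(nm)) nm <- rep(NA_character_, nrow(targets))
    id <- ifelse(is.na(nm),
                 sprintf("%s:%.0f-%.0f", targets$seqid, targets$start, targets$end),
                 nm)
    return(data.frame(target_id = id, seqid = targets$seqid,
                      start = targets$start, end = targets$end,
                      stringsAsFactors = FALSE))
  }
  if (is.null(gff_path)) {
    adx_usage_error("need either an annotation file (--input) or a BED target file")
  }
  bundle <- load_bundle(gff_path, c("fts", "prt", "gof"))
  feats <- which(bundle$fts$ftype_of == target_type)
  if (!length(feats)) {
    adx_data_error(sprintf("no features of type '%s' in the annotation", target_type))
  }
  roots <- unique(bundle$prt$root_of[feats])
  sel <- sort(match(roots, bundle$gof$block_no))
  rows <- list()
  for (b in sel) {
    text <- read_byte_ranges(gff_path, bundle$gof$byte_ranges[[b]])
    ln <- block_lines(text)
    recs <- parse_feature_lines(ln, seq_along(ln), seq_along(ln), seq_along(ln))
    recs <- recs[recs$ftype == target_type, , drop = FALSE]
    if (!nrow(recs)) next
    id <- attr_or_na(recs$attributes, "ID")
    id <- ifelse(is.na(id),
                 sprintf("%s:%.0f-%.0f", recs$seqid, recs$start, recs$end), id)
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = id, seqid = recs$seqid, start = recs$start, end = recs$end,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

profile_slices <- function(targets, intervals, max_slice, workers, fun) {
  n <- nrow(targets)
  out <- vector("list", 0L)
  jobs <- list()
  for (s in unique(targets$seqid)) {
    ti <- which(targets$seqid == s)
    ord <- ti[order(targets$start[ti], targets$end[ti], method = "radix")]
    iv <- intervals[intervals$seqid == s, , drop = FALSE]
    slices <- partition_slices(targets$start[ord], targets$end[ord], max_slice)
    for (sl in slices) {
      tidx <- ord[sl$idx]
      keep <- iv$start <= sl$hi & iv$end >= sl$lo
      jobs[[length(jobs) + 1L]] <- list(
        tidx = tidx,
        t_start = targets$start[tidx], t_end = targets$end[tidx],
        iv_start = iv$start[keep], iv_end = iv$end[keep],
        lo = sl$lo, hi = sl$hi)
    }
  }
  run <- function(job) fun(job)
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(jobs, run, mc.cores = workers)
  } else {
    lapply(jobs, run)
  }
  list(jobs = jobs, results = res)
}

#' Coverage breadth of targets
#'
#' For every target, the number of its bases covered by at least one
#' alignment interval and the covered fraction (breadth). Alignment
#' intervals are merged per slice and swept against the slice's targets with
#' two co-linear pointers; results are exact.
#'
#' @param alignments Path to a SAM/BAM file, or a precomputed interval data
#'   frame from [alignments_to_intervals()].
#' @param gff_path Indexed GFF3 whose features supply the targets (used when
#'   `targets` is `NULL`).
#' @param targets Optional target regions (data frame with `seqid`, `start`,
#'   `end`, optional `name`; 1-based inclusive), e.g. from [parse_bed4()].
#' @param target_type Feature type drawn from the annotation when `targets`
#'   is `NULL`.
#' @param max_slice Maximum slice span in bp for partitioned processing.
#' @param workers Number of parallel workers over slices.
#' @param drop_duplicates,include_deletions Passed to
#'   [alignments_to_intervals()].
#' @return Data frame with one row per target, in target input order:
#'   `target_id`, `seqid`, `start`, `end`, `length`, `covered_bases`,
#'   `breadth`.
#' @export
coverage_breadth <- function(alignments, gff_path = NULL, targets = NULL,
                             target_type = "gene", max_slice = Inf,
                             workers = 1L, drop_duplicates = FALSE,
                             include_deletions = TRUE) {
  tg <- resolve_targets(gff_path, alignments, targets, target_type)
  iv <- if (is.data.frame(alignments)) alignments else
    alignments_to_intervals(alignments, drop_duplicates, include_deletions)
  pr <- profile_slices(tg, iv, max_slice, workers, function(job) {
    m <- merge_intervals(job$iv_start, job$iv_end)
    sweep_breadth(job$t_start, job$t_end, m$starts, m$ends)
  })
  covered <- numeric(nrow(tg))
  for (k in seq_along(pr$jobs)) covered[pr$jobs[[k]]$tidx] <- pr$results[[k]]
  len <- tg$end - tg$start + 1
  data.frame(target_id = tg$target_id, seqid = tg$seqid,
             start = tg$start, end = tg$end, length = len,
             covered_bases = covered, breadth = covered / len,
             stringsAsFactors = FALSE)
}

#' Coverage depth of targets
#'
#' For every target, the summed per-base alignment depth (every overlapping
#' base of every kept alignment counts once per alignment) and the mean
#' depth over the target. Computed exactly with a difference array per
#' slice; `report = "histogram"` additionally returns, per target, the
#' number of bases at each integer depth.
#'
#' @inheritParams coverage_breadth
#' @param report `"mean"` or `"histogram"`.
#' @return Data frame in target input order: `target_id`, `seqid`, `start`,
#'   `end`, `length`, `depth_sum`, `mean_depth`, and (histogram mode) a list
#'   column `histogram` of per-depth base counts.
#' @export
coverage_depth <- function(alignments, gff_path = NULL, targets = NULL,
                           target_type = "gene", max_slice = Inf,
                           workers = 1L, report = c("mean", "histogram"),
                           drop_duplicates = FALSE, include_deletions = TRUE) {
  report <- match.arg(report)
  tg <- resolve_targets(gff_path, alignments, targets, target_type)
  iv <- if (is.data.frame(alignments)) alignments else
    alignments_to_intervals(alignments, drop_duplicates, include_deletions)
  histo <- report == "histogram"
  pr <- profile_slices(tg, iv, max_slice, workers, function(job) {
    slice_depth(job$t_start, job$t_end, job$iv_start, job$iv_end,
                job$lo, job$hi, histogram = histo)
  })
  depth_sum <- numeric(nrow(tg))
  hist <- if (histo) vector("list", nrow(tg)) else NULL
  for (k in seq_along(pr$jobs)) {
    depth_sum[pr$jobs[[k]]$tidx] <- pr$results[[k]]$depth_sum
    if (histo) hist[pr$jobs[[k]]$tidx] <- pr$results[[k]]$histogram
  }
  len <- tg$end - tg$start + 1
  out <- data.frame(target_id = tg$target_id, seqid = tg$seqid,
                    start = tg$start, end = tg$end, length = len,
                    depth_sum = depth_sum, mean_depth = depth_sum / len,
                    stringsAsFactors = FALSE)
  if (histo) out$histogram <- I(hist)
  out
}

#' Write a coverage/depth table as TSV
#'
#' Deterministic text rendering (fractions with up to six significant
#' digits), so identical results are byte-identical on disk.
#'
#' @param df Result of [coverage_breadth()] or [coverage_depth()].
#' @param out Path or connection.
#' @return Invisibly, the formatted lines.
#' @export
write_coverage_table <- function(df, out = stdout()) {
  df <- df[setdiff(names(df), "histogram")]
  num <- vapply(df, is.numeric, TRUE)
  cells <- df
  for (j in which(num)) {
    cells[[j]] <- ifelse(df[[j]] == round(df[[j]]),
                         sprintf("%.0f", df[[j]]),
                         sprintf("%.6g", df[[j]]))
  }
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(as.list(cells)), sep = "\t")))
  if (inherits(out, "connection")) writeLines(lines, out)
  else writeLines(lines, out)
  invisible(lines)
}
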