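# The index bundle: eight binary files written next to the source GFF.
#
#   .fts  feature table: string IDs and feature types, in appearance order
#   .prt  hierarchy: parent and root feature numbers
#   .gof  per-block byte-offset ranges, seqid and span
#   .atn  attribute value table (sorted by raw bytes) + indexed key names
#   .a2f  value-table position -> feature numbers
#   .sqs  seqid strings in order of first appearance
#   .rit  interval-tree nodes, laid out sequentially per seqid
#   .rix  per-seqid directory of offsets into .rit
#
# Each file carries the common header (source size + xxHash64 checksum), so
# any modification of the source GFF after indexing is detected as staleness
# at load time. Building twice from the same source yields byte-identical
# files.

INDEX_KINDS <- c("fts", "prt", "gof", "atn", "a2f", "sqs", "rit", "rix")

index_path <- function(gff_path, kind) paste0(gff_path, ".", kind)

#' Build the full index bundle for a GFF3 file
#'
#' One forward scan of the file produces the feature table, the annotation
#' blocks with their byte-offset ranges, the attribute value index over the
#' requested keys, the seqid table, and one augmented interval tree per
#' seqid over the block spans. Use [write_bundle()] to persist the bundle
#' and [load_bundle()] to read it back on demand.
#'
#' A member feature lying on a different seqid than its root stays in the
#' root's block, but its interval is indexed under its own seqid (pointing
#' at the same block), so region queries find it where it lies.
#'
#' @param gff_path Path to the source GFF3 file.
#' @param attribute_keys Attribute keys to index for [search_attribute()].
#' @return An environment of class `annodex_bundle` holding all tables.
#' @export
build_index_bundle <- function(gff_path, attribute_keys = c("ID", "Name")) {
  scan <- scan_gff(gff_path)
  records <- scan$records
  if (nrow(records) >= 2^31) {
    adx_error("annodex_capacity_error",
              "feature count exceeds 32-bit index capacity")
  }
  table <- resolve_hierarchy(records)
  blocks <- delineate_blocks(table, records)
  seqids <- scan$seqids

  # Attribute index: (key, value) pairs over the requested keys, sorted by
  # raw value bytes (ties by key position), each mapping to feature numbers.
  atn_key <- integer(0); atn_val <- character(0); a2f <- list()
  if (nrow(records) > 0L && length(attribute_keys)) {
    ks <- integer(0); vs <- character(0); fs <- integer(0)
    for (ki in seq_along(attribute_keys)) {
      v <- attr_or_na(records$attributes, attribute_keys[ki])
      hit <- which(!is.na(v))
      ks <- c(ks, rep(ki, length(hit))); vs <- c(vs, v[hit]); fs <- c(fs, hit)
    }
    if (length(vs)) {
      grp <- paste0(ks, "\r", vs)
      first <- !duplicated(grp)
      o <- order(vs[first], ks[first], method = "radix")
      atn_key <- ks[first][o]
      atn_val <- vs[first][o]
      feat_by_grp <- split(fs, grp)
      a2f <- unname(feat_by_grp[grp[first][o]])
    }
  }

  # Interval per (block, member seqid): min/max member coordinates on that
  # seqid, pointing at the block.
  trees <- list()
  if (length(seqids)) {
    iv_seqid <- character(0); iv_start <- numeric(0); iv_end <- numeric(0)
    iv_block <- numeric(0)
    if (nrow(blocks) > 0L) {
      for (b in seq_len(nrow(blocks))) {
        m <- blocks$members[[b]]
        sq <- records$seqid[m]
        for (s in unique(sq)) {
          sel <- m[sq == s]
          iv_seqid <- c(iv_seqid, s)
          iv_start <- c(iv_start, min(records$start[sel]))
          iv_end <- c(iv_end, max(records$end[sel]))
          iv_block <- c(iv_block, blocks$block_no[b])
        }
      }
    }
    trees <- lapply(seqids, function(s) {
      sel <- iv_seqid == s
      build_interval_tree(iv_start[sel], iv_end[sel], iv_block[sel])
    })
    names(trees) <- seqids
  }

  bundle <- new.env(parent = emptyenv())
  bundle$gff_path <- gff_path
  bundle$source_size <- file.size(gff_path)
  bundle$checksum <- source_checksum(gff_path)
  bundle$fts <- list(string_ids = table$string_ids, ftype_of = table$ftype_of)
  bundle$prt <- list(parent_of = table$parent_of, root_of = table$root_of)
  bundle$gof <- blocks[c("block_no", "seqid", "span_start", "span_end",
                         "byte_ranges")]
  bundle$atn <- list(keys = attribute_keys, key_pos = atn_key, values = atn_val)
  bundle$a2f <- a2f
  bundle$sqs <- seqids
  bundle$trees <- trees
  bundle$loaded <- INDEX_KINDS
  bundle$audit <- character(0)
  class(bundle) <- "annodex_bundle"
  bundle
}

#' Write an index bundle to disk
#'
#' Serializes every table of the bundle into its own compact binary file
#' next to the source GFF (extensions `.fts .prt .gof .atn .a2f .sqs .rit
#' .rix`). The byte layout is deterministic: building and writing twice from
#' the same source produces byte-identical files.
#'
#' @param bundle Bundle from [build_index_bundle()].
#' @param base_path Path prefix for the index files; defaults to the source
#'   GFF path.
#' @return Invisibly, the written file paths.
#' @export
write_bundle <- function(bundle, base_path = bundle$gff_path) {
  sz <- bundle$source_size; ck <- bundle$checksum
  paths <- character(0)
  wopen <- function(kind) {
    p <- index_path(base_path, kind)
    paths <<- c(paths, p)
    con <- file(p, "wb")
    write_header(con, sz, ck)
    con
  }

  n <- length(bundle$fts$string_ids)
  con <- wopen("fts")
  write_u64(con, n)
  write_str(con, bundle$fts$string_ids)
  write_str(con, bundle$fts$ftype_of)
  close(con)

  con <- wopen("prt")
  write_u64(con, n)
  write_featno(con, bundle$prt$parent_of)
  write_featno(con, bundle$prt$root_of)
  close(con)

  con <- wopen("gof")
  gof <- bundle$gof
  write_u64(con, nrow(gof))
  for (b in seq_len(nrow(gof))) {
    write_featno(con, gof$block_no[b])
    write_u32(con, match(gof$seqid[b], bundle$sqs) - 1L)
    write_u64(con, c(gof$span_start[b], gof$span_end[b]))
    r <- gof$byte_ranges[[b]]
    write_u64(con, nrow(r))
    write_u64(con, as.vector(t(r)))
  }
  close(con)

  con <- wopen("atn")
  write_u32(con, length(bundle$atn$keys))
  write_str(con, bundle$atn$keys)
  write_u64(con, length(bundle$atn$values))
  for (i in seq_along(bundle$atn$values)) {
    write_u32(con, bundle$atn$key_pos[i] - 1L)
    write_str(con, bundle$atn$values[i])
  }
  close(con)

  con <- wopen("a2f")
  write_u64(con, length(bundle$a2f))
  for (fl in bundle$a2f) {
    write_u64(con, length(fl))
    write_featno(con, fl)
  }
  close(con)

  con <- wopen("sqs")
  write_u64(con, length(bundle$sqs))
  write_str(con, bundle$sqs)
  close(con)

  write_rit_rix(bundle$trees, bundle$sqs,
                index_path(base_path, "rit"), index_path(base_path, "rix"),
                sz, ck)
  paths <- c(paths, index_path(base_path, "rit"), index_path(base_path, "rix"))
  invisible(paths)
}

# Per-process bundle cache: indices are loaded once and reused across
# operations. Keyed by the index base path.
.bundle_cache <- new.env(parent = emptyenv())

#' Drop all cached index bundles
#'
#' Loaded bundles are cached per process so repeated queries reuse them.
#' Call this after re-indexing a file in the same session.
#' @export
flush_bundle_cache <- function() {
  rm(list = ls(.bundle_cache), envir = .bundle_cache)
  invisible(NULL)
}

#' Load index files on demand
#'
#' Reads only the requested index kinds from disk; within one process,
#' repeated requests for the same source return the same bundle object, with
#' further kinds loaded incrementally. Every file actually read is appended
#' to the bundle's `audit` vector, which tests and callers can use to verify
#' that each operation touches only its own subset of the indices. Interval
#' trees are loaded per seqid on first use ([bundle_tree()]), reading only
#' that seqid's byte range of `.rit`.
#'
#' @param gff_path Path to the source GFF3 file.
#' @param needed Character vector of index kinds (subset of
#'   `c("fts","prt","gof","atn","a2f","sqs","rit","rix")`).
#' @param base_path Index path prefix (defaults to `gff_path`).
#' @return An `annodex_bundle` environment with the requested tables set.
#' @export
load_bundle <- function(gff_path, needed = INDEX_KINDS, base_path = gff_path) {
  if (length(needed)) needed <- match.arg(needed, INDEX_KINDS, several.ok = TRUE)
  key <- paste0(normalizePath(base_path, mustWork = FALSE), "\r",
                normalizePath(gff_path, mustWork = FALSE))
  bundle <- .bundle_cache[[key]]
  if (is.null(bundle)) {
    bundle <- new.env(parent = emptyenv())
    bundle$gff_path <- gff_path
    bundle$base_path <- base_path
    bundle$loaded <- character(0)
    bundle$audit <- character(0)
    bundle$trees <- list()
    class(bundle) <- "annodex_bundle"
    .bundle_cache[[key]] <- bundle
  }
  for (kind in setdiff(needed, bundle$loaded)) {
    load_index_file(bundle, kind)
  }
  bundle
}

load_index_file <- function(bundle, kind) {
  p <- index_path(bundle$base_path, kind)
  if (!file.exists(p)) {
    adx_missing_index_error(
      sprintf("missing index file '%s'; run the index step first", p),
      extension = kind)
  }
  con <- file(p, "rb"); on.exit(close(con))
  header <- read_header(con, p)
  check_header_fresh(header, bundle$gff_path, p)
  bundle$source_size <- header$source_size
  bundle$checksum <- header$checksum

  if (kind == "fts") {
    n <- read_u64(con)
    bundle$fts <- list(string_ids = read_str(con, n), ftype_of = read_str(con, n))
  } else if (kind == "prt") {
    n <- read_u64(con)
    bundle$prt <- list(parent_of = read_featno(con, n),
                       root_of = read_featno(con, n))
  } else if (kind == "gof") {
    nb <- read_u64(con)
    block_no <- numeric(nb); seqid_pos <- numeric(nb)
    span_start <- numeric(nb); span_end <- numeric(nb)
    byte_ranges <- vector("list", nb)
    for (b in seq_len(nb)) {
      block_no[b] <- read_featno(con)
      seqid_pos[b] <- read_u32(con)
      sp <- read_u64(con, 2L)
      span_start[b] <- sp[1L]; span_end[b] <- sp[2L]
      nr <- read_u64(con)
      rr <- read_u64(con, 2L * nr)
      byte_ranges[[b]] <- matrix(rr, ncol = 2L, byrow = TRUE,
                                 dimnames = list(NULL, c("start", "end")))
    }
    bundle$gof_seqid_pos <- seqid_pos
    bundle$gof <- data.frame(block_no = block_no,
                             seqid = rep(NA_character_, nb),
                             span_start = span_start, span_end = span_end,
                             byte_ranges = I(byte_ranges),
                             stringsAsFactors = FALSE)
    if (!is.null(bundle$sqs)) bundle$gof$seqid <- bundle$sqs[seqid_pos + 1L]
  } else if (kind == "atn") {
    nk <- read_u32(con)
    keys <- read_str(con, nk)
    nv <- read_u64(con)
    key_pos <- numeric(nv); values <- character(nv)
    for (i in seq_len(nv)) {
      key_pos[i] <- read_u32(con) + 1
      values[i] <- read_str(con)
    }
    bundle$atn <- list(keys = keys, key_pos = key_pos, values = values)
  } else if (kind == "a2f") {
    nv <- read_u64(con)
    bundle$a2f <- lapply(seq_len(nv), function(i) {
      nf <- read_u64(con)
      read_featno(con, nf)
    })
  } else if (kind == "sqs") {
    bundle$sqs <- read_str(con, read_u64(con))
    if (!is.null(bundle$gof)) bundle$gof$seqid <- bundle$sqs[bundle$gof_seqid_pos + 1L]
  } else if (kind == "rix") {
    close(con); on.exit(NULL)
    rx <- read_rix(p, load_bundle_seqids(bundle))
    bundle$rix <- rx$directory
  } else if (kind == "rit") {
    # Directory-driven: nodes are read per seqid on demand by bundle_tree().
  }
  bundle$loaded <- union(bundle$loaded, kind)
  bundle$audit <- union(bundle$audit, kind)
  invisible(bundle)
}

load_bundle_seqids <- function(bundle) {
  if (is.null(bundle$sqs)) load_index_file(bundle, "sqs")
  bundle$sqs
}

#' Fetch (lazily load) one seqid's interval tree from a bundle
#'
#' Reads only the requested seqid's byte range of the `.rit` file on first
#' use; a seqid absent from the index yields an empty tree (queries on
#' unannotated contigs are legal and return no hits).
#'
#' @param bundle Bundle with `rix` (and `rit` on disk) available.
#' @param seqid Seqid name.
#' @return An `annodex_itree`.
#' @export
bundle_tree <- function(bundle, seqid) {
  if (!is.null(bundle$trees[[seqid]])) return(bundle$trees[[seqid]])
  if (is.null(bundle$rix)) {
    # fully in-memory bundle with no serialized trees: unknown seqid -> empty
    return(build_interval_tree(numeric(0), numeric(0), numeric(0)))
  }
  entry <- bundle$rix[[seqid]]
  if (is.null(entry)) {
    return(build_interval_tree(numeric(0), numeric(0), numeric(0)))
  }
  tr <- read_tree_nodes(index_path(bundle$base_path, "rit"), entry)
  bundle$audit <- union(bundle$audit, "rit")
  bundle$trees[[seqid]] <- tr
  tr
}

#' Ensure a GFF3 file is indexed and fresh
#'
#' Builds (or rebuilds) the index bundle when any index file is missing or
#' stale with respect to the current source bytes.
#'
#' @param gff_path Path to the source GFF3 file.
#' @param attribute_keys Keys to index if (re)building.
#' @param auto_index If `FALSE`, raise the missing/stale error instead of
#'   rebuilding.
#' @return Invisibly, `TRUE` if an index build was performed.
#' @export
ensure_index <- function(gff_path, attribute_keys = c("ID", "Name"),
                         auto_index = TRUE) {
  ok <- tryCatch({
    for (kind in INDEX_KINDS) {
      p <- index_path(gff_path, kind)
      if (!file.exists(p)) {
        adx_missing_index_error(sprintf("missing index file '%s'", p),
                                extension = kind)
      }
      con <- file(p, "rb")
      header <- tryCatch(read_header(con, p), finally = close(con))
      check_header_fresh(header, gff_path, p)
    }
    TRUE
  }, annodex_data_error = function(e) if (auto_index) FALSE else stop(e))
  if (!ok) {
    write_bundle(build_index_bundle(gff_path, attribute_keys))
    flush_bundle_cache()
    return(invisible(TRUE))
  }
  invisible(FALSE)
}

#' @export
print.annodex_bundle <- function(x, ...) {
  cat("<annodex_bundle>", x$gff_path, "\n  loaded:",
      paste(x$loaded, collapse = " "), "\n")
  invisible(x)
}
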