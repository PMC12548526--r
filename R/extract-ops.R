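# ID-based model extraction and attribute search. Output lines are copied
# verbatim from the source file via the block byte ranges — never
# re-serialized — so extracted GFF3 is byte-identical to the source lines.

read_byte_ranges <- function(gff_path, ranges) {
  con <- file(gff_path, "rb"); on.exit(close(con))
  parts <- character(nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    seek(con, ranges[i, 1L])
    parts[i] <- readChar(con, ranges[i, 2L] - ranges[i, 1L], useBytes = TRUE)
  }
  paste(parts, collapse = "")
}

# Block text -> individual feature lines (no trailing newline on each).
block_lines <- function(text) {
  strsplit(sub("\n$", "", text), "\n", fixed = TRUE)[[1L]]
}

# ID -> feature number lookup honouring the last-definition-wins rule.
id_lookup <- function(string_ids) {
  def <- which(!is.na(string_ids))
  last <- def[!duplicated(string_ids[def], fromLast = TRUE)]
  stats::setNames(last, string_ids[last])
}

# Emit blocks in file order; with `con`, each block is written as soon as it
# is resolved (streaming: memory does not grow with output size).
emit_blocks <- function(bundle, block_nos, line_filter = NULL, con = NULL) {
  gof <- bundle$gof
  sel <- sort(match(block_nos, gof$block_no))  # file order = root order
  out <- character(0)
  for (b in sel) {
    text <- read_byte_ranges(bundle$gff_path, gof$byte_ranges[[b]])
    ln <- block_lines(text)
    if (!is.null(line_filter)) ln <- ln[line_filter(ln)]
    if (is.null(con)) out <- c(out, ln) else writeLines(ln, con)
  }
  out
}

with_output_con <- function(out, header, body) {
  con <- if (inherits(out, "connection")) out else file(out, "w")
  if (!inherits(out, "connection")) on.exit(close(con))
  writeLines(header, con)
  body(con)
}

#' Extract annotation blocks by feature identifier
#'
#' Resolves each string ID to its feature, maps it through the hierarchy to
#' its root, and emits the root's complete annotation block (the whole gene
#' model) by copying the block's byte ranges verbatim from the source file.
#' A block requested via several of its members is emitted once; blocks
#' appear in file order. In `mode = "feature"` only the named feature's own
#' line(s) are emitted instead of the full block.
#'
#' @param ids Character vector of feature IDs.
#' @param gff_path Path to the indexed GFF3 file.
#' @param mode `"block"` (default) or `"feature"`.
#' @param strict If `TRUE`, any unknown ID is an error; otherwise unknown IDs
#'   produce a warning and are skipped (an error is raised only if all IDs
#'   are unknown).
#' @param out Optional path or connection; blocks are streamed there as they
#'   are resolved and the text is not accumulated.
#' @return Character vector of output lines, starting with
#'   `"##gff-version 3"` (invisibly when `out` is given).
#' @export
extract_by_ids <- function(ids, gff_path, mode = c("block", "feature"),
                           strict = FALSE, out = NULL) {
  mode <- match.arg(mode)
  bundle <- load_bundle(gff_path, c("fts", "prt", "gof"))
  lookup <- id_lookup(bundle$fts$string_ids)
  feat <- lookup[ids]
  unknown <- ids[is.na(feat)]
  if (length(unknown)) {
    msg <- sprintf("unknown feature ID(s): %s",
                   paste(utils::head(unknown, 5L), collapse = ", "))
    if (strict) adx_data_error(msg)
    adx_warn(msg, class = "annodex_unknown_id_warning")
    if (all(is.na(feat))) {
      adx_data_error("none of the requested IDs are present in the index")
    }
  }
  feat <- feat[!is.na(feat)]
  roots <- unique(bundle$prt$root_of[feat])

  filter <- NULL
  if (mode == "feature") {
    wanted <- unique(names(feat))
    filter <- function(lines) {
      recs <- parse_feature_lines(lines, seq_along(lines), seq_along(lines),
                                  seq_along(lines))
      attr_or_na(recs$attributes, "ID") %in% wanted
    }
  }
  if (!is.null(out)) {
    with_output_con(out, "##gff-version 3", function(con) {
      emit_blocks(bundle, roots, filter, con = con)
    })
    return(invisible(NULL))
  }
  c("##gff-version 3", emit_blocks(bundle, roots, filter))
}

#' Search indexed attribute values
#'
#' Looks a pattern up in the sorted attribute value table for one indexed
#' key. Exact mode is a byte-equality binary search of the sorted table;
#' fuzzy mode is a case-insensitive substring scan. Matched values map
#' through the value-to-feature index to features, then to their blocks,
#' which are emitted deduplicated in file order.
#'
#' @param key Attribute key; must have been among `attribute_keys` at index
#'   build time, otherwise a not-indexed error asks for re-indexing.
#' @param pattern Search pattern.
#' @param gff_path Path to the indexed GFF3 file.
#' @param mode `"exact"` (default) or `"fuzzy"`.
#' @param out Optional path or connection for streaming output.
#' @return A list with `text` (output GFF3 lines incl. the version header),
#'   `report` (data frame: matched `value`, `feature_id`, `block_no`), and
#'   `n_matches`. An empty result is not an error.
#' @export
search_attribute <- function(key, pattern, gff_path,
                             mode = c("exact", "fuzzy"), out = NULL) {
  mode <- match.arg(mode)
  bundle <- load_bundle(gff_path, c("atn", "a2f", "fts", "prt", "gof"))
  kpos <- match(key, bundle$atn$keys)
  if (is.na(kpos)) {
    adx_data_error(sprintf(
      "attribute key '%s' is not indexed (indexed: %s); re-index with this key",
      key, paste(bundle$atn$keys, collapse = ", ")))
  }
  values <- bundle$atn$values
  if (mode == "exact") {
    hit <- bsearch_range(values, pattern)
    hit <- hit[bundle$atn$key_pos[hit] == kpos]
  } else {
    hit <- which(grepl(tolower(pattern), tolower(values), fixed = TRUE) &
                   bundle$atn$key_pos == kpos)
  }
  feats <- unique(unlist(bundle$a2f[hit], use.names = FALSE))
  report <- data.frame(
    value = rep(values[hit], lengths(bundle$a2f[hit])),
    feature_id = bundle$fts$string_ids[unlist(bundle$a2f[hit], use.names = FALSE)],
    block_no = bundle$prt$root_of[unlist(bundle$a2f[hit], use.names = FALSE)],
    stringsAsFactors = FALSE
  )
  roots <- unique(bundle$prt$root_of[feats])
  if (!is.null(out)) {
    with_output_con(out, "##gff-version 3", function(con) {
      emit_blocks(bundle, roots, con = con)
    })
    lines <- NULL
  } else {
    lines <- c("##gff-version 3", emit_blocks(bundle, roots))
  }
  list(text = lines, report = report, n_matches = length(hit))
}

# Left/right bound binary search over a table sorted by raw bytes.
bsearch_range <- function(sorted, pattern) {
  n <- length(sorted)
  if (n == 0L) return(integer(0))
  cmp_lt <- function(a, b) {
    # byte-order comparison, locale-independent
    o <- order(c(a, b), method = "radix")
    a != b && o[1L] == 1L
  }
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {  # first index with sorted[i] >= pattern
    mid <- (lo + hi) %/% 2L
    if (cmp_lt(sorted[mid], pattern)) lo <- mid + 1L else hi <- mid
  }
  first <- lo
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {  # first index with sorted[i] > pattern
    mid <- (lo + hi) %/% 2L
    if (!cmp_lt(pattern, sorted[mid])) lo <- mid + 1L else hi <- mid
  }
  if (first >= lo) integer(0) else seq.int(first, lo - 1L)
}
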