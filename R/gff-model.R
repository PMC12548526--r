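#' Parse one GFF3 feature line
#'
#' Decodes a single physical GFF3 line (nine tab-separated columns) into a
#' one-row feature record carrying the byte span of the line in its source
#' file, so the original bytes can later be recovered verbatim.
#'
#' Attribute values are percent-decoded per the GFF3 escaping rules
#' (\verb{\%3B}, \verb{\%3D}, \verb{\%26}, \verb{\%2C}, \verb{\%09},
#' \verb{\%0A}, \verb{\%0D}, \verb{\%25}, and any other \verb{\%XX} token).
#' Attribute order is preserved.
#'
#' @param line A single physical line, including its terminating newline if
#'   present. Must not be a directive (`#`-prefixed) line.
#' @param byte_start 0-based byte offset of the first byte of the line in the
#'   source file.
#' @param line_no 1-based line number, used in error messages.
#' @return A one-row data frame with columns `seqid`, `source`, `ftype`,
#'   `start`, `end`, `score`, `strand`, `phase`, `byte_start`, `byte_end`,
#'   `line_no`, and a list column `attributes` holding a named character
#'   vector in file order.
#' @examples
#' rec <- parse_feature_line("chr1\t.\tgene\t100\t200\t.\t+\t.\tID=g1\n")
#' rec$start; rec$attributes[[1]][["ID"]]
#' @export
parse_feature_line <- function(line, byte_start = 0, line_no = 1L) {
  nb <- nchar(line, type = "bytes")
  parse_feature_lines(sub("\n$", "", line), byte_start, byte_start + nb, line_no)
}

# Vectorised core shared by parse_feature_line() and scan_gff().
parse_feature_lines <- function(lines, byte_starts, byte_ends, line_nos) {
  cols <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(cols)
  if (any(nc != 9L)) {
    bad <- which(nc != 9L)[1L]
    adx_malformed_error(
      sprintf("line %d: expected 9 tab-separated columns, found %d",
              line_nos[bad], nc[bad]),
      line_no = line_nos[bad])
  }
  m <- matrix(unlist(cols, use.names = FALSE), ncol = 9L, byrow = TRUE)
  start_s <- m[, 4L]; end_s <- m[, 5L]
  ok <- grepl("^[0-9]+$", start_s) & grepl("^[0-9]+$", end_s)
  if (any(!ok)) {
    bad <- which(!ok)[1L]
    adx_malformed_error(
      sprintf("line %d: non-integer coordinates '%s'..'%s'",
              line_nos[bad], start_s[bad], end_s[bad]),
      line_no = line_nos[bad])
  }
  start <- as.numeric(start_s); end <- as.numeric(end_s)
  if (any(start < 1 | start > end)) {
    bad <- which(start < 1 | start > end)[1L]
    adx_malformed_error(
      sprintf("line %d: invalid coordinates start=%s end=%s (need 1 <= start <= end)",
              line_nos[bad], start_s[bad], end_s[bad]),
      line_no = line_nos[bad])
  }
  data.frame(
    seqid = m[, 1L], source = m[, 2L], ftype = m[, 3L],
    start = start, end = end,
    score = ifelse(m[, 6L] == ".", NA_character_, m[, 6L]),
    strand = m[, 7L],
    phase = suppressWarnings(as.integer(ifelse(m[, 8L] == ".", NA, m[, 8L]))),
    byte_start = as.numeric(byte_starts), byte_end = as.numeric(byte_ends),
    line_no = as.integer(line_nos),
    attributes = I(parse_attribute_column(m[, 9L])),
    stringsAsFactors = FALSE
  )
}

# Decode any %XX token (the GFF3-reserved set and beyond) in place.
percent_decode <- function(x) {
  has <- grepl("%", x, fixed = TRUE)
  if (!any(has)) return(x)
  y <- x[has]
  m <- gregexpr("%[0-9A-Fa-f]{2}", y)
  regmatches(y, m) <- lapply(regmatches(y, m), function(tok) {
    if (!length(tok)) return(tok)
    vapply(tok, function(t) rawToChar(as.raw(strtoi(substring(t, 2L, 3L), 16L))),
           "", USE.NAMES = FALSE)
  })
  x[has] <- y
  x
}

parse_attribute_column <- function(attr_col) {
  lapply(attr_col, function(a) {
    if (a == "." || a == "") return(stats::setNames(character(0), character(0)))
    parts <- strsplit(a, ";", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    eq <- regexpr("=", parts, fixed = TRUE)
    keys <- ifelse(eq > 0L, substring(parts, 1L, eq - 1L), parts)
    vals <- ifelse(eq > 0L, substring(parts, eq + 1L), "")
    stats::setNames(percent_decode(vals), keys)
  })
}

#' Scan a GFF3 file, recording byte offsets
#'
#' Single forward pass over a GFF3 file: every feature line becomes a record
#' with its exact byte span, directives and comments are skipped, and parsing
#' stops at a `##FASTA` directive (its byte offset is reported so downstream
#' byte-range reads never enter the sequence section).
#'
#' @param path Path to a GFF3 file (1-based, inclusive coordinates).
#' @return A list with elements `records` (feature records in file order, as
#'   returned by [parse_feature_line()]), `seqids` (seqid strings in order of
#'   first appearance), and `fasta_boundary` (0-based byte offset of the
#'   `##FASTA` line, or `NA` if absent).
#' @export
scan_gff <- function(path) {
  if (!file.exists(path)) adx_data_error(sprintf("cannot read '%s'", path))
  size <- file.size(path)
  txt <- readChar(path, size, useBytes = TRUE)
  if (size == 0 || txt == "") {
    return(list(records = empty_records(), seqids = character(0),
                fasta_boundary = NA_real_))
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  nbytes <- nchar(lines, type = "bytes") + 1L
  ends_with_nl <- substr(txt, size, size) == "\n"
  if (!ends_with_nl) nbytes[length(nbytes)] <- nbytes[length(nbytes)] - 1L
  byte_end <- cumsum(as.numeric(nbytes))
  byte_start <- byte_end - nbytes
  line_no <- seq_along(lines)

  fasta_boundary <- NA_real_
  fa <- which(startsWith(lines, "##FASTA"))
  if (length(fa)) {
    fasta_boundary <- byte_start[fa[1L]]
    keep_upto <- fa[1L] - 1L
    lines <- lines[seq_len(keep_upto)]
    byte_start <- byte_start[seq_len(keep_upto)]
    byte_end <- byte_end[seq_len(keep_upto)]
    line_no <- line_no[seq_len(keep_upto)]
  }

  is_feat <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(is_feat)) {
    return(list(records = empty_records(), seqids = character(0),
                fasta_boundary = fasta_boundary))
  }
  records <- parse_feature_lines(lines[is_feat], byte_start[is_feat],
                                 byte_end[is_feat], line_no[is_feat])
  list(records = records, seqids = unique(records$seqid),
       fasta_boundary = fasta_boundary)
}

empty_records <- function() {
  data.frame(seqid = character(0), source = character(0), ftype = character(0),
             start = numeric(0), end = numeric(0), score = character(0),
             strand = character(0), phase = integer(0),
             byte_start = numeric(0), byte_end = numeric(0),
             line_no = integer(0), attributes = I(list()),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

attr_or_na <- function(attributes, key) {
  vapply(attributes, function(a) {
    v <- a[names(a) == key]
    if (length(v)) v[[1L]] else NA_character_
  }, "")
}

#' Resolve the feature hierarchy of a GFF3 scan
#'
#' Assigns numeric feature numbers in order of appearance, resolves `Parent`
#' links through the `ID` table, and computes each feature's root (the
#' parentless ancestor that anchors its annotation block). Features without
#' an `ID` are numbered but cannot be looked up by string identifier; when a
#' feature lists several parents, the first one determines block membership
#' (a warning names the feature if the listed parents resolve to different
#' roots); duplicate `ID` definitions resolve to the last occurrence, with a
#' warning.
#'
#' @param records Feature records in file order, from [scan_gff()].
#' @return An object of class `annodex_feature_table`: a list with
#'   `n_features`, `string_ids` (ID or `NA` per feature), `parent_of`
#'   (feature number of the parent, `NA` for roots), `root_of`, and
#'   `ftype_of`. Feature numbers are 1-based in R.
#' @export
resolve_hierarchy <- function(records) {
  n <- nrow(records)
  string_ids <- attr_or_na(records$attributes, "ID")
  ftype_of <- records$ftype
  if (n == 0L) {
    return(structure(list(n_features = 0L, string_ids = character(0),
                          parent_of = numeric(0), root_of = numeric(0),
                          ftype_of = character(0)),
                     class = "annodex_feature_table"))
  }

  defined <- which(!is.na(string_ids))
  if (anyDuplicated(string_ids[defined])) {
    # Repeated IDs with the same type and Parent are one discontinuous
    # feature (legal GFF3, e.g. multi-line CDS); only conflicting
    # redefinitions are worth a warning.
    pa <- attr_or_na(records$attributes, "Parent")[defined]
    sig <- paste(records$ftype[defined], pa, sep = "\r")
    dup_ids <- unique(string_ids[defined][duplicated(string_ids[defined])])
    conflicting <- vapply(dup_ids, function(id) {
      length(unique(sig[string_ids[defined] == id])) > 1L
    }, TRUE)
    if (any(conflicting)) {
      adx_warn(sprintf("conflicting duplicate ID definition(s): %s (last definition wins)",
                       paste(utils::head(dup_ids[conflicting], 5L), collapse = ", ")),
               class = "annodex_duplicate_id_warning")
    }
  }
  last_def <- defined[!duplicated(string_ids[defined], fromLast = TRUE)]
  id_map <- stats::setNames(last_def, string_ids[last_def])

  parent_attr <- attr_or_na(records$attributes, "Parent")
  parent_tokens <- strsplit(parent_attr, ",", fixed = TRUE)
  first_parent <- vapply(parent_tokens,
                         function(t) if (length(t)) t[[1L]] else NA_character_, "")
  has_parent <- !is.na(first_parent)

  all_tokens <- unique(unlist(parent_tokens[has_parent], use.names = FALSE))
  unknown <- setdiff(all_tokens, names(id_map))
  if (length(unknown)) {
    off <- which(has_parent &
                   vapply(parent_tokens, function(t) any(t %in% unknown), TRUE))[1L]
    adx_data_error(sprintf(
      "line %d: Parent refers to undefined ID '%s'",
      records$line_no[off],
      intersect(parent_tokens[[off]], unknown)[1L]))
  }

  parent_of <- rep(NA_real_, n)
  parent_of[has_parent] <- unname(id_map[first_parent[has_parent]])

  # Pointer-jumping to the root; a cycle never stabilises.
  jump <- ifelse(is.na(parent_of), seq_len(n), parent_of)
  root_of <- jump
  for (iter in seq_len(64L)) {
    nxt <- jump[root_of]
    if (identical(nxt, root_of)) break
    root_of <- nxt
    if (iter == 64L) {
      adx_error("annodex_cycle_error",
                "cycle detected in Parent links; hierarchy is not a forest")
    }
  }
  if (!identical(jump[root_of], root_of)) {
    adx_error("annodex_cycle_error",
              "cycle detected in Parent links; hierarchy is not a forest")
  }

  multi <- which(lengths(parent_tokens) > 1L & has_parent)
  for (i in multi) {
    roots <- unique(root_of[unname(id_map[parent_tokens[[i]]])])
    if (length(roots) > 1L) {
      adx_warn(sprintf(
        "feature %s (line %d) lists parents with different roots; first parent used for block membership",
        string_ids[i] %||% sprintf("#%d", i), records$line_no[i]),
        class = "annodex_multiparent_warning")
    }
  }

  structure(list(n_features = n, string_ids = string_ids,
                 parent_of = parent_of, root_of = root_of,
                 ftype_of = ftype_of),
            class = "annodex_feature_table")
}

#' Delineate annotation blocks
#'
#' Partitions the features into annotation blocks — one block per root
#' (parentless) feature, containing the root and all its descendants: the
#' minimal complete gene/transcript model that extraction returns as a unit.
#' Each block records the byte ranges covering exactly its member lines as
#' the minimal list of maximal contiguous runs (a fully contiguous model
#' yields a single range; interleaved models yield several).
#'
#' @param table Feature table from [resolve_hierarchy()].
#' @param records The matching feature records from [scan_gff()].
#' @return A data frame with one row per block, in root-appearance order:
#'   `block_no` (= root feature number), `seqid` (the root's), `span_start`,
#'   `span_end` (min/max over all members), plus list columns `byte_ranges`
#'   (two-column matrix of `[byte_start, byte_end)` pairs) and `members`
#'   (member feature numbers in file order).
#' @export
delineate_blocks <- function(table, records) {
  if (table$n_features == 0L) {
    return(data.frame(block_no = numeric(0), seqid = character(0),
                      span_start = numeric(0), span_end = numeric(0),
                      byte_ranges = I(list()), members = I(list()),
                      stringsAsFactors = FALSE))
  }
  members_by_root <- split(seq_len(table$n_features), table$root_of)
  roots <- as.numeric(names(members_by_root))
  ord <- order(roots)
  roots <- roots[ord]
  members_by_root <- members_by_root[ord]

  cross <- vapply(seq_along(roots), function(i) {
    any(records$seqid[members_by_root[[i]]] != records$seqid[roots[i]])
  }, TRUE)
  if (any(cross)) {
    adx_warn(sprintf(
      "%d block(s) have members on a different seqid than their root; members kept in the block",
      sum(cross)), class = "annodex_crossseqid_warning")
  }

  byte_ranges <- lapply(members_by_root, function(m) {
    bs <- records$byte_start[m]; be <- records$byte_end[m]
    o <- order(bs)
    bs <- bs[o]; be <- be[o]
    brk <- c(TRUE, bs[-1L] != be[-length(be)])
    grp <- cumsum(brk)
    cbind(start = bs[!duplicated(grp)],
          end = vapply(split(be, grp), max, 0))
  })

  data.frame(
    block_no = roots,
    seqid = records$seqid[roots],
    span_start = vapply(members_by_root, function(m) min(records$start[m]), 0),
    span_end = vapply(members_by_root, function(m) max(records$end[m]), 0),
    byte_ranges = I(unname(byte_ranges)),
    members = I(unname(members_by_root)),
    stringsAsFactors = FALSE
  )
}
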