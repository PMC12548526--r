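# Augmented interval tree over block spans, one tree per seqid.
#
# The tree is static (the index is write-once/read-many): intervals are
# sorted by (start, end, block_no) and a balanced BST is built by recursive
# median split, so depth <= ceiling(log2(N+1)). Nodes are stored in a flat
# array in in-order sequence (= sorted order), which is also the on-disk
# layout. Each node carries max_end, the maximum interval endpoint in its
# subtree; a query prunes any subtree whose max_end lies left of the query
# and skips right children whose start lies right of it, giving
# O(log N + k) visited nodes for k reported overlaps.

#' Build an augmented interval tree
#'
#' @param starts,ends Interval coordinates, 1-based inclusive.
#' @param block_nos Payload block numbers, one per interval.
#' @return An object of class `annodex_itree`: parallel vectors `start`,
#'   `end`, `max_end`, `left`, `right` (child indices, `NA` = none),
#'   `block_no`, and the scalar `root` (`NA` for an empty tree). Nodes are in
#'   in-order (sorted) sequence.
#' @export
build_interval_tree <- function(starts, ends, block_nos) {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  block_nos <- as.numeric(block_nos)
  stopifnot(length(starts) == length(ends), length(starts) == length(block_nos))
  if (any(starts > ends)) {
    adx_data_error("invalid interval: start > end")
  }
  n <- length(starts)
  if (n == 0L) {
    return(structure(list(start = numeric(0), end = numeric(0),
                          max_end = numeric(0), left = integer(0),
                          right = integer(0), block_no = numeric(0),
                          root = NA_integer_),
                     class = "annodex_itree"))
  }
  o <- order(starts, ends, block_nos, method = "radix")
  start <- starts[o]; end <- ends[o]; block_no <- block_nos[o]
  left <- rep(NA_integer_, n); right <- rep(NA_integer_, n)
  max_end <- end

  build <- function(lo, hi) {
    if (lo > hi) return(NA_integer_)
    mid <- (lo + hi) %/% 2L
    l <- build(lo, mid - 1L)
    r <- build(mid + 1L, hi)
    left[mid] <<- l
    right[mid] <<- r
    me <- end[mid]
    if (!is.na(l)) me <- max(me, max_end[l])
    if (!is.na(r)) me <- max(me, max_end[r])
    max_end[mid] <<- me
    mid
  }
  root <- build(1L, n)
  structure(list(start = start, end = end, max_end = max_end,
                 left = left, right = right, block_no = block_no,
                 root = root),
            class = "annodex_itree")
}

#' Query an interval tree for overlaps
#'
#' Reports every indexed interval overlapping the query (`start <= q_end`
#' and `end >= q_start`, 1-based inclusive on both sides). Traversal prunes
#' a subtree whenever its `max_end` is left of the query and skips the right
#' child whenever the node's start is right of it.
#'
#' @param tree An `annodex_itree` from [build_interval_tree()].
#' @param q_start,q_end Query interval, 1-based inclusive.
#' @param count_visits If `TRUE`, attach the number of nodes visited as
#'   attribute `"visits"` (used to check the logarithmic traversal bound).
#' @return A list with `block_nos` (sorted unique block numbers hit) and
#'   `intervals` (matrix of the hit intervals with their block numbers).
#' @export
query_overlaps <- function(tree, q_start, q_end, count_visits = FALSE) {
  if (is.na(q_start) || is.na(q_end) || q_start > q_end) {
    adx_usage_error("invalid query: need q_start <= q_end")
  }
  hits <- integer(0)
  visits <- 0L
  # Descend into a subtree only if it can contain an overlap: its max_end
  # must reach the query start (otherwise the whole subtree is pruned), and
  # the right subtree is skipped when the node itself starts past the query.
  walk <- function(i) {
    visits <<- visits + 1L
    l <- tree$left[i]
    if (!is.na(l) && tree$max_end[l] >= q_start) walk(l)
    if (tree$start[i] <= q_end) {
      if (tree$end[i] >= q_start) hits <<- c(hits, i)
      r <- tree$right[i]
      if (!is.na(r) && tree$max_end[r] >= q_start) walk(r)
    }
  }
  if (!is.na(tree$root) && tree$max_end[tree$root] >= q_start) walk(tree$root)
  res <- list(
    block_nos = sort(unique(tree$block_no[hits])),
    intervals = cbind(start = tree$start[hits], end = tree$end[hits],
                      block_no = tree$block_no[hits])
  )
  if (count_visits) attr(res, "visits") <- visits
  res
}

itree_depth <- function(tree) {
  if (is.na(tree$root)) return(0L)
  d <- function(i) if (is.na(i)) 0L else 1L + max(d(tree$left[i]), d(tree$right[i]))
  d(tree$root)
}

# --- serialization -----------------------------------------------------------
# .rit: header + all trees' node records laid out sequentially, per seqid:
#   start u64 | end u64 | max_end u64 | left u32 | right u32 | block_no u32
# (child indices and block numbers 0-based on disk, sentinel 0xFFFFFFFF).
# .rix: header + u64 count + per seqid:
#   seqid_pos u32 | node_offset u64 (into the .rit payload) | node_count u32 |
#   root u32
RIT_NODE_BYTES <- 36

# Pack/unpack a whole node array as one vector of 32-bit words
# (9 words per node), so serialization is a single writeBin/readBin.
u64_words <- function(x) {
  hi <- floor(x / 2^32)
  lo <- x - hi * 2^32
  rbind(lo, hi)
}
words_from_u64 <- function(lo, hi) hi * 2^32 + lo

pack_nodes <- function(tr) {
  n <- length(tr$start)
  featno_word <- function(v) {
    v <- as.numeric(v) - 1
    v[is.na(v)] <- U32_SENTINEL
    v
  }
  w <- rbind(u64_words(tr$start), u64_words(tr$end), u64_words(tr$max_end),
             featno_word(tr$left), featno_word(tr$right),
             featno_word(tr$block_no))
  w <- as.vector(w)
  w[w >= 2^31] <- w[w >= 2^31] - 2^32
  as.integer(w)
}

unpack_nodes <- function(words, n, root) {
  w <- as.numeric(words)
  w[w < 0] <- w[w < 0] + 2^32
  m <- matrix(w, nrow = 9L)
  featno <- function(v) {
    v[v == U32_SENTINEL] <- NA
    v + 1
  }
  structure(list(
    start = words_from_u64(m[1L, ], m[2L, ]),
    end = words_from_u64(m[3L, ], m[4L, ]),
    max_end = words_from_u64(m[5L, ], m[6L, ]),
    left = as.integer(featno(m[7L, ])),
    right = as.integer(featno(m[8L, ])),
    block_no = featno(m[9L, ]),
    root = as.integer(root)
  ), class = "annodex_itree")
}

write_rit_rix <- function(trees, seqids, rit_path, rix_path, source_size, checksum) {
  con <- file(rit_path, "wb"); on.exit(close(con), add = TRUE)
  write_header(con, source_size, checksum)
  offsets <- numeric(length(trees))
  off <- 0
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    offsets[k] <- off
    n <- length(tr$start)
    if (n) writeBin(pack_nodes(tr), con, size = 4L, endian = "little")
    off <- off + n * RIT_NODE_BYTES
  }
  close(con); on.exit(NULL)

  con2 <- file(rix_path, "wb"); on.exit(close(con2), add = TRUE)
  write_header(con2, source_size, checksum)
  write_u64(con2, length(trees))
  for (k in seq_along(trees)) {
    write_u32(con2, match(names(trees)[k], seqids) - 1L)
    write_u64(con2, offsets[k])
    write_u32(con2, length(trees[[k]]$start))
    write_featno(con2, trees[[k]]$root)
  }
  invisible(c(rit_path, rix_path))
}

read_rix <- function(rix_path, seqids) {
  con <- file(rix_path, "rb"); on.exit(close(con))
  header <- read_header(con, rix_path)
  n <- read_u64(con)
  dir <- vector("list", n)
  nm <- character(n)
  for (k in seq_len(n)) {
    pos <- read_u32(con)
    node_offset <- read_u64(con)
    node_count <- read_u32(con)
    root <- read_featno(con)
    nm[k] <- seqids[pos + 1L]
    dir[[k]] <- list(node_offset = node_offset, node_count = node_count,
                     root = as.integer(root))
  }
  names(dir) <- nm
  list(header = header, directory = dir)
}

# Read only the byte range of one seqid's subtree from .rit.
read_tree_nodes <- function(rit_path, entry) {
  n <- entry$node_count
  if (n == 0) {
    return(structure(list(start = numeric(0), end = numeric(0),
                          max_end = numeric(0), left = integer(0),
                          right = integer(0), block_no = numeric(0),
                          root = NA_integer_),
                     class = "annodex_itree"))
  }
  con <- file(rit_path, "rb"); on.exit(close(con))
  seek(con, header_nbytes() + entry$node_offset)
  words <- readBin(con, "integer", n = 9L * n, size = 4L, endian = "little")
  if (length(words) < 9L * n) adx_data_error("truncated .rit index")
  unpack_nodes(words, n, entry$root)
}
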