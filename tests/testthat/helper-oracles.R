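# Deliberately naive reference implementations, independent of the package's
# algorithms. They share no code with R/: linear scans, per-base counting
# arrays, repeated parent lookups.

# Linear-scan overlap oracle: indices of intervals overlapping the query.
brute_force_overlap <- function(starts, ends, q_start, q_end) {
  which(starts <= q_end & ends >= q_start)
}

# Per-base coverage oracle: for one target, count covered bases and summed
# depth by marking every base of every read.
per_base_coverage <- function(t_start, t_end, r_starts, r_ends) {
  len <- t_end - t_start + 1
  depth <- integer(len)
  for (i in seq_along(r_starts)) {
    s <- max(r_starts[i], t_start)
    e <- min(r_ends[i], t_end)
    if (s <= e) {
      idx <- (s - t_start + 1):(e - t_start + 1)
      depth[idx] <- depth[idx] + 1L
    }
  }
  list(covered = sum(depth > 0L), depth_sum = sum(depth), depth = depth)
}

# Transitive-closure root oracle: chase parent pointers one step at a time.
transitive_root <- function(parent_of) {
  vapply(seq_along(parent_of), function(i) {
    seen <- integer(0)
    while (!is.na(parent_of[i])) {
      if (i %in% seen) stop("cycle")
      seen <- c(seen, i)
      i <- parent_of[i]
    }
    i
  }, 0)
}

# Full-file attribute scan oracle: feature line indices whose attribute
# column contains key=value verbatim (exact) on re-parsing the raw text.
naive_attribute_scan <- function(gff_path, key, value) {
  lines <- readLines(gff_path)
  feat <- which(!startsWith(lines, "#") & nzchar(lines))
  fa <- which(startsWith(lines, "##FASTA"))
  if (length(fa)) feat <- feat[feat < fa[1L]]
  hits <- logical(length(feat))
  for (k in seq_along(feat)) {
    col9 <- strsplit(lines[feat[k]], "\t", fixed = TRUE)[[1L]][9L]
    kv <- strsplit(col9, ";", fixed = TRUE)[[1L]]
    hits[k] <- any(kv == paste0(key, "=", value))
  }
  feat[hits]
}

# Feature lines of a GFF file as raw text (file order), for diff oracles.
gff_feature_lines <- function(gff_path) {
  lines <- readLines(gff_path)
  fa <- which(startsWith(lines, "##FASTA"))
  if (length(fa)) lines <- lines[seq_len(fa[1L] - 1L)]
  lines[!startsWith(lines, "#") & nzchar(lines)]
}
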