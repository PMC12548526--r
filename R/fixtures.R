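# Deterministic synthetic-data generators. Each generator is a pure function
# of its parameters and seed (the caller's RNG state is untouched), so the
# same call always produces byte-identical files — the basis for every
# oracle-backed test in the package. The GFF generator also emits a
# ground-truth manifest (feature -> root/block assignment and span) that is
# computed from the simulation itself, independently of the parser.

#' Generate a synthetic GFF3 annotation file
#'
#' Emits nested gene -> mRNA -> exon/CDS models with `ID`/`Parent`/`Name`
#' attributes. Exon lines carry no `ID` (as in real annotations); the CDS
#' lines of one mRNA share a single `ID` (a discontinuous feature). A stated
#' fraction of adjacent gene pairs is interleaved line-wise, producing
#' multi-range annotation blocks.
#'
#' @param path Output GFF3 path.
#' @param n_genes Number of gene models.
#' @param seqids Seqid names; genes are assigned randomly.
#' @param seed RNG seed; same seed, same parameters: byte-identical output.
#' @param interleave_fraction Fraction of adjacent gene pairs whose lines are
#'   interleaved.
#' @param multi_transcript_p Probability that a gene has two mRNAs.
#' @param seqid_len Length of every seqid in bp.
#' @param fasta_section If `TRUE`, append a `##FASTA` section.
#' @return A list with `path`, `manifest` (data frame: `id`, `ftype`,
#'   `seqid`, `start`, `end`, `root_id`, one row per feature line in file
#'   order), and `manifest_path` (TSV next to the GFF).
#' @export
generate_gff3 <- function(path, n_genes = 50L, seqids = c("chr1", "chr2"),
                          seed = 1L, interleave_fraction = 0.1,
                          multi_transcript_p = 0.3, seqid_len = 1e6,
                          fasta_section = FALSE) {
  with_seed(seed, {
    genes <- vector("list", n_genes)
    cursor <- stats::setNames(rep(1000, length(seqids)), seqids)
    for (g in seq_len(n_genes)) {
      sq <- sample(seqids, 1L)
      glen <- sample(500:5000, 1L)
      gstart <- cursor[[sq]] + sample(100:2000, 1L)
      if (gstart + glen > seqid_len) gstart <- sample(1000:5000, 1L)  # wrap
      cursor[[sq]] <- gstart + glen
      gid <- sprintf("gene%04d", g)
      gname <- if (g %% 2L == 0L) sprintf("GENE%04d-like", g) else sprintf("Gene%04d", g)
      strand <- sample(c("+", "-"), 1L)

      lines <- sprintf("%s\tannodex\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       sq, gstart, gstart + glen, strand, gid, gname)
      man <- data.frame(id = gid, ftype = "gene", seqid = sq,
                        start = gstart, end = gstart + glen, root_id = gid,
                        stringsAsFactors = FALSE)
      n_mrna <- 1L + (stats::runif(1) < multi_transcript_p)
      for (t in seq_len(n_mrna)) {
        tid <- sprintf("%s.t%d", gid, t)
        tstart <- gstart + sample(0:50, 1L)
        tend <- gstart + glen - sample(0:50, 1L)
        lines <- c(lines, sprintf(
          "%s\tannodex\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
          sq, tstart, tend, strand, tid, gid))
        man <- rbind(man, data.frame(id = tid, ftype = "mRNA", seqid = sq,
                                     start = tstart, end = tend, root_id = gid,
                                     stringsAsFactors = FALSE))
        n_exon <- sample(2:4, 1L)
        cuts <- sort(sample(seq(tstart + 10, tend - 10, by = 1), 2L * n_exon - 2L))
        bounds <- matrix(c(tstart, cuts, tend), ncol = 2L, byrow = TRUE)
        cds_id <- sprintf("%s.cds", tid)
        for (e in seq_len(n_exon)) {
          lines <- c(lines, sprintf(
            "%s\tannodex\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
            sq, bounds[e, 1L], bounds[e, 2L], strand, tid))
          man <- rbind(man, data.frame(id = NA_character_, ftype = "exon",
                                       seqid = sq, start = bounds[e, 1L],
                                       end = bounds[e, 2L], root_id = gid,
                                       stringsAsFactors = FALSE))
          if (e < n_exon || n_exon == 1L) {
            lines <- c(lines, sprintf(
              "%s\tannodex\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;Parent=%s",
              sq, bounds[e, 1L], bounds[e, 2L], strand, cds_id, tid))
            man <- rbind(man, data.frame(id = cds_id, ftype = "CDS",
                                         seqid = sq, start = bounds[e, 1L],
                                         end = bounds[e, 2L], root_id = gid,
                                         stringsAsFactors = FALSE))
          }
        }
      }
      genes[[g]] <- list(lines = lines, manifest = man)
    }

    # Interleave a fraction of adjacent (disjoint) gene pairs line-wise.
    out_lines <- character(0)
    out_man <- list()
    g <- 1L
    while (g <= n_genes) {
      if (g < n_genes && stats::runif(1) < interleave_fraction) {
        a <- genes[[g]]; b <- genes[[g + 1L]]
        out_lines <- c(out_lines, a$lines[1L], b$lines[1L],
                       a$lines[-1L], b$lines[-1L])
        out_man <- c(out_man, list(a$manifest[1L, ], b$manifest[1L, ],
                                   a$manifest[-1L, ], b$manifest[-1L, ]))
        g <- g + 2L
      } else {
        out_lines <- c(out_lines, genes[[g]]$lines)
        out_man <- c(out_man, list(genes[[g]]$manifest))
        g <- g + 1L
      }
    }

    header <- c("##gff-version 3",
                sprintf("##sequence-region %s 1 %d", seqids, as.integer(seqid_len)))
    body <- out_lines
    if (fasta_section) {
      body <- c(body, "##FASTA",
                paste0(">", seqids[1L]), "ACGTACGTACGTACGT")
    }
    writeLines(c(header, body), path, sep = "\n")

    manifest <- if (length(out_man)) do.call(rbind, out_man) else
      data.frame(id = character(0), ftype = character(0), seqid = character(0),
                 start = numeric(0), end = numeric(0), root_id = character(0))
    rownames(manifest) <- NULL
    manifest_path <- paste0(path, ".manifest.tsv")
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(path = path, manifest = manifest, manifest_path = manifest_path)
  })
}

#' Generate a random BED4 interval file
#'
#' @param path Output path.
#' @param n Number of intervals.
#' @param seqids Seqid names, sampled uniformly.
#' @param seqid_len Length of every seqid in bp.
#' @param length_range Interval length range in bp (BED lengths).
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
generate_bed <- function(path, n = 100L, seqids = c("chr1", "chr2"),
                         seqid_len = 1e6, length_range = c(100L, 20000L),
                         seed = 1L) {
  with_seed(seed, {
    if (n == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    sq <- sample(seqids, n, replace = TRUE)
    len <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
    start0 <- vapply(len, function(l) sample.int(seqid_len - l, 1L) - 1L, 0L)
    writeLines(sprintf("%s\t%d\t%d\tr%05d", sq, start0, start0 + len, seq_len(n)),
               path)
    invisible(path)
  })
}

#' Generate a synthetic SAM alignment file
#'
#' Primary mapped records with CIGARs of the form `<m>M` or `<m1>M<n>N<m2>M`
#' (a spliced read). The header declares every seqid; with `sorted = TRUE`
#' records are coordinate-sorted, otherwise they are shuffled.
#'
#' @param path Output SAM path.
#' @param n_reads Number of reads.
#' @param seqids Reference names.
#' @param seqid_len Reference length in bp.
#' @param read_len Read length (reference-consuming bases per read).
#' @param spliced_p Probability that a read is spliced (one `N` gap).
#' @param sorted Coordinate-sort the output records.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
generate_alignments <- function(path, n_reads = 1000L,
                                seqids = c("chr1", "chr2"), seqid_len = 1e6,
                                read_len = 100L, spliced_p = 0.2,
                                sorted = TRUE, seed = 1L) {
  with_seed(seed, {
    header <- c("@HD\tVN:1.6",
                sprintf("@SQ\tSN:%s\tLN:%d", seqids, as.integer(seqid_len)))
    if (n_reads == 0L) {
      writeLines(header, path)
      return(invisible(path))
    }
    sq <- sample(seqids, n_reads, replace = TRUE)
    spliced <- stats::runif(n_reads) < spliced_p
    m1 <- ifelse(spliced, sample(20:(read_len - 20L), n_reads, replace = TRUE),
                 read_len)
    gap <- ifelse(spliced, sample(50:500, n_reads, replace = TRUE), 0L)
    span <- read_len + gap
    pos <- vapply(span, function(s) sample.int(seqid_len - s, 1L), 0L)
    cigar <- ifelse(spliced,
                    sprintf("%dM%dN%dM", m1, gap, read_len - m1),
                    sprintf("%dM", read_len))
    seq <- strrep("A", read_len)
    rows <- sprintf("r%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                    seq_len(n_reads), sq, pos, cigar, seq)
    if (sorted) {
      o <- order(match(sq, seqids), pos, method = "radix")
      rows <- rows[o]
    } else {
      rows <- rows[sample.int(n_reads)]
    }
    writeLines(c(header, rows), path)
    invisible(path)
  })
}
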