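# Shared fixture construction. Everything is generated in tempdir() at test
# time; nothing is read from outside the repository.

new_gff_fixture <- function(n_genes = 30L, seed = 1L, indexed = TRUE, ...) {
  path <- tempfile(fileext = ".gff3")
  fx <- generate_gff3(path, n_genes = n_genes, seed = seed, ...)
  if (indexed) {
    write_bundle(build_index_bundle(path))
    flush_bundle_cache()
  }
  fx
}

write_gff_lines <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

# A small hand-written annotation with known structure:
# two genes on chr1; gene gB's model is interleaved with gA's.
# The two gene lines come first, then each model's children as a contiguous
# run: both blocks have their contiguity broken exactly once (2 byte ranges).
toy_gff_lines <- c(
  "##gff-version 3",
  "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=gA;Name=AlphaGene",
  "chr1\tsrc\tgene\t600\t900\t.\t-\t.\tID=gB;Name=BRCA2-like",
  "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=gA.t1;Parent=gA",
  "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=gA.t1",
  "chr1\tsrc\texon\t400\t500\t.\t+\t.\tParent=gA.t1",
  "chr1\tsrc\tmRNA\t600\t900\t.\t-\t.\tID=gB.t1;Parent=gB",
  "chr1\tsrc\texon\t600\t900\t.\t-\t.\tParent=gB.t1"
)

new_toy_gff <- function(indexed = TRUE) {
  path <- write_gff_lines(toy_gff_lines)
  if (indexed) {
    write_bundle(build_index_bundle(path))
    flush_bundle_cache()
  }
  path
}
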