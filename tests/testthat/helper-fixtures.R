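# In-code fixtures shared across test files.

# genotype matrix from a compact string spec: rows = samples, entries in
# {0, 1, 2, N} (N = missing), e.g. geno("012N", "2210")
geno <- function(..., samples = NULL, snps = NULL) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(r) {
    v <- strsplit(r, "")[[1]]
    out <- rep(NA_integer_, length(v))
    out[v != "N"] <- as.integer(v[v != "N"])
    out
  }))
  rownames(m) <- samples %||% sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- snps %||% sprintf("m%02d", seq_len(ncol(m)))
  sweepscan::genotype_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flat_map <- function(g, lg = "LG01", spacing = 1) {
  data.frame(snp_id = colnames(g), lg = lg,
             cm = spacing * (seq_len(ncol(g)) - 1))
}

two_pop_assignment <- function(g, n1) {
  data.frame(sample_id = rownames(g),
             subpop = rep(c("pop1", "pop2"), c(n1, nrow(g) - n1)))
}

write_test_vcf <- function(path, extra_record = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4",
    "1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1\t./.",
    "1\t200\tsnpB\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1\t0/1")
  if (!is.null(extra_record)) lines <- c(lines, extra_record)
  writeLines(lines, path)
  path
}
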