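#' Construct a genotype matrix
#'
#' A genotype matrix holds diploid calls at biallelic SNPs for a panel of
#' samples. Internally calls are stored as allele-B dosages: 0 (AA), 1 (AB),
#' 2 (BB), `NA` (missing). Rows are samples, columns SNPs; both dimensions
#' carry unique identifiers.
#'
#' @param calls matrix of calls, samples in rows, SNPs in columns. Either an
#'   integer/numeric matrix of dosages in `{0, 1, 2, NA}` or a character
#'   matrix with entries `"AA"`, `"AB"`, `"BB"`, `NA`.
#' @return an integer matrix of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if (is.character(calls)) {
    dos <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
    dos[calls == "AA"] <- 0L
    dos[calls == "AB"] <- 1L
    dos[calls == "BB"] <- 2L
    bad <- !is.na(calls) & !(calls %in% c("AA", "AB", "BB"))
    if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("invalid call '%s' at sample %s, SNP %s",
                   calls[bad][1L], rownames(calls)[ij[1L]] %||% ij[1L],
                   colnames(calls)[ij[2L]] %||% ij[2L]))
    }
    calls <- dos
  }
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dosage %d at sample %s, SNP %s", calls[bad][1L],
                 rownames(calls)[ij[1L]] %||% ij[1L],
                 colnames(calls)[ij[2L]] %||% ij[2L]))
  }
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("SNP%05d", seq_len(ncol(calls)))
  if (anyDuplicated(rownames(calls))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(calls))) stop("duplicate SNP identifiers")
  structure(calls, class = c("genotype_matrix", class(calls)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.1f%% missing, %.2f%% het)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x)),
              100 * sum(x == 1L, na.rm = TRUE) / max(1L, sum(!is.na(x)))))
  invisible(x)
}

# subsetting keeps the class and a matrix shape
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("genotype_matrix", class(out))
  out
}

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect has one header row of SNP identifiers, the first column a
#' sample identifier, and calls coded `A` (AA), `B` (BB), `H` (AB) or `-`
#' (missing). Lines starting with `#` are comments. The VCF path uses the GT
#' field of biallelic records; multi-allelic records are skipped with a
#' warning (the count is kept in attribute `n_skipped`).
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, colClasses = "character")
  samples <- tab[[1L]]
  if (anyDuplicated(samples))
    stop("duplicate sample id in ", path, ": ", samples[duplicated(samples)][1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- samples
  dos <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  dos[m == "A"] <- 0L
  dos[m == "H"] <- 1L
  dos[m == "B"] <- 2L
  bad <- !(m %in% c("A", "H", "B", "-"))
  if (any(bad)) {
    ij <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed call token '%s' at sample '%s', SNP '%s'",
                 m[ij[1L], ij[2L]], rownames(m)[ij[1L]], colnames(m)[ij[2L]]))
  }
  genotype_matrix(dos)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  n_skipped <- sum(!bi)
  if (n_skipped > 0) {
    warning(n_skipped, " multi-allelic record(s) skipped")
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids) || any(ids == ".")) {
    fix <- vcfR::getFIX(vcf)
    auto <- paste(fix[, "CHROM"], fix[, "POS"], sep = "_")
    ids <- ifelse(is.null(ids) | is.na(ids) | ids == ".", auto, ids)
  }
  core <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow(core), ncol(core))
  dos[core %in% c("0/0")] <- 0L
  dos[core %in% c("0/1", "1/0")] <- 1L
  dos[core %in% c("1/1")] <- 2L
  dos <- t(dos)
  rownames(dos) <- colnames(gt)
  colnames(dos) <- ids
  out <- genotype_matrix(dos)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a genotype matrix in the TSV dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes_tsv <- function(g, path) {
  sym <- matrix("-", nrow(g), ncol(g))
  sym[!is.na(g) & g == 0L] <- "A"
  sym[!is.na(g) & g == 1L] <- "H"
  sym[!is.na(g) & g == 2L] <- "B"
  df <- data.frame(sample_id = rownames(g), sym, check.names = FALSE)
  colnames(df) <- c("sample_id", colnames(g))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map
#'
#' Expects tab-separated columns `snp_id`, `lg`, `cm` (comment lines start
#' with `#`). Positions are centimorgans within a linkage group.
#'
#' @param path file to read.
#' @return data.frame with columns `snp_id`, `lg`, `cm`, sorted by group and
#'   position.
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_genetic_map(map)
}

validate_genetic_map <- function(map) {
  need <- c("snp_id", "lg", "cm")
  if (!all(need %in% names(map)))
    stop("genetic map needs columns: ", paste(need, collapse = ", "))
  map$snp_id <- as.character(map$snp_id)
  map$lg <- as.character(map$lg)
  map$cm <- as.numeric(map$cm)
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP id in genetic map")
  if (any(!is.finite(map$cm)) || any(map$cm < 0))
    stop("map positions must be finite and >= 0")
  map <- map[order(map$lg, map$cm), , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' Total genetic map length
#'
#' Sum over linkage groups of (max - min) marker position.
#'
#' @param map a genetic map data.frame (`snp_id`, `lg`, `cm`).
#' @return length in cM.
#' @export
map_length <- function(map) {
  spans <- tapply(map$cm, map$lg, function(x) max(x) - min(x))
  sum(spans)
}

#' Read a subpopulation assignment table
#'
#' Tab-separated columns `sample_id`, `subpop`; the label `"excluded"` marks
#' samples (e.g. admixed accessions) left out of two-population contrasts.
#'
#' @param path file to read.
#' @return data.frame with columns `sample_id`, `subpop`.
#' @export
read_subpop_assignment <- function(path) {
  a <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "subpop") %in% names(a)))
    stop("assignment needs columns sample_id, subpop")
  a$sample_id <- as.character(a$sample_id)
  a$subpop <- as.character(a$subpop)
  if (anyDuplicated(a$sample_id)) stop("duplicate sample id in assignment")
  a
}

#' Read a trait-locus catalog
#'
#' Tab-separated columns `locus_id`, `trait`, `lg`, `cm`, `mode` (one of
#' `"gwas"`, `"qualitative"`) and optionally `source`. Positions must be on
#' the same genetic map as the scan.
#'
#' @param path file to read.
#' @return data.frame of the catalog.
#' @export
read_trait_catalog <- function(path) {
  cat_ <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("locus_id", "trait", "lg", "cm", "mode")
  if (!all(need %in% names(cat_)))
    stop("catalog needs columns: ", paste(need, collapse = ", "))
  if (!all(cat_$mode %in% c("gwas", "qualitative")))
    stop("catalog mode must be 'gwas' or 'qualitative'")
  cat_$lg <- as.character(cat_$lg)
  cat_$cm <- as.numeric(cat_$cm)
  cat_
}

# tab-separated writer with '#'-prefixed metadata header lines
write_scan_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", names(meta), ": ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_scan_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
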