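#' SNP filter specification
#'
#' Thresholds for per-SNP quality filtering: maximum missing-call fraction,
#' maximum heterozygous fraction (among non-missing calls) and minimum minor
#' allele frequency (from allele counts over non-missing calls).
#'
#' Two presets mirror common usage on inbred panels: `"panel"` (diversity
#' panel: missing <= 0.20, het <= 0.20, MAF >= 0.01) and `"ril"` (biparental
#' RIL mapping: missing <= 0.20, het <= 0.10, MAF >= 0.25).
#'
#' @param max_missing_rate,max_het_rate,min_maf fractions in `[0, 1]`.
#' @return a list of class `filter_spec`.
#' @export
filter_spec <- function(max_missing_rate = 0.2, max_het_rate = 0.2,
                        min_maf = 0.01) {
  vals <- c(max_missing_rate, max_het_rate, min_maf)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("filter thresholds must lie in [0, 1]")
  structure(list(max_missing_rate = max_missing_rate,
                 max_het_rate = max_het_rate, min_maf = min_maf),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param preset `"panel"` or `"ril"`.
#' @export
filter_preset <- function(preset = c("panel", "ril")) {
  switch(match.arg(preset),
         panel = filter_spec(0.2, 0.2, 0.01),
         ril = filter_spec(0.2, 0.1, 0.25))
}

#' Per-SNP quality statistics
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with `snp_id`, `missing_rate`, `het_rate` (fraction of
#'   heterozygous calls among non-missing; `NaN` if all missing) and `maf`
#'   (minor allele frequency; each non-missing diploid call contributes two
#'   allele observations, AB one of each).
#' @export
snp_quality <- function(g) {
  n_samp <- nrow(g)
  n_called <- colSums(!is.na(g))
  n_het <- colSums(g == 1L, na.rm = TRUE)
  n_b <- colSums(g, na.rm = TRUE)           # allele-B observations
  n_alle <- 2 * n_called
  f_b <- ifelse(n_alle > 0, n_b / n_alle, NaN)
  data.frame(snp_id = colnames(g),
             missing_rate = 1 - n_called / n_samp,
             het_rate = ifelse(n_called > 0, n_het / n_called, NaN),
             maf = pmin(f_b, 1 - f_b),
             stringsAsFactors = FALSE)
}

#' Filter SNPs by missingness, heterozygosity and MAF
#'
#' All three criteria are applied jointly in one pass: a SNP failing any one
#' is removed, so the result is order-independent and idempotent. Counts of
#' SNPs failing each criterion are kept in attribute `filter_log`.
#'
#' @param g a [genotype_matrix()].
#' @param spec a [filter_spec()].
#' @return the filtered [genotype_matrix()].
#' @export
filter_snps <- function(g, spec = filter_preset("panel")) {
  stopifnot(inherits(spec, "filter_spec"))
  q <- snp_quality(g)
  fail_missing <- q$missing_rate > spec$max_missing_rate
  fail_het <- is.nan(q$het_rate) | q$het_rate > spec$max_het_rate
  fail_maf <- is.nan(q$maf) | q$maf < spec$min_maf
  keep <- !(fail_missing | fail_het | fail_maf)
  out <- g[, keep, drop = FALSE]
  log <- list(n_input = ncol(g), n_retained = sum(keep),
              n_removed = sum(!keep), fail_missing = sum(fail_missing),
              fail_het = sum(fail_het), fail_maf = sum(fail_maf))
  if (log$n_retained == 0) message("filter_snps: no SNPs retained")
  attr(out, "filter_log") <- log
  out
}

#' Panel heterozygosity rate
#'
#' Fraction of heterozygous (AB) calls among all non-missing calls of the
#' whole matrix.
#'
#' @param g a [genotype_matrix()].
#' @return a fraction in `[0, 1]`.
#' @export
heterozygosity_rate <- function(g) {
  n_called <- sum(!is.na(g))
  if (n_called == 0) stop("all calls missing")
  sum(g == 1L, na.rm = TRUE) / n_called
}
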