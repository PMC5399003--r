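#' Per-site nucleotide diversity from allele counts
#'
#' For a biallelic site with allele counts \eqn{n_i} and total
#' \eqn{n = \sum_i n_i}, diversity is \eqn{\pi = 1 - \sum_i n_i^2 / n^2}:
#' the probability that two allele observations drawn (with replacement)
#' from the sample differ. Each non-missing diploid call contributes two
#' observations; a heterozygote contributes one of each allele.
#'
#' @param n_a,n_b allele counts (vectors are accepted; recycled pairwise).
#' @return \eqn{\pi} in `[0, 0.5]` for biallelic sites; `NA` where
#'   `n_a + n_b == 0`.
#' @export
site_pi <- function(n_a, n_b) {
  n <- n_a + n_b
  ifelse(n > 0, 1 - (n_a^2 + n_b^2) / n^2, NA_real_)
}

#' Per-site F_ST with unequal subpopulation sizes
#'
#' Estimates differentiation at one site from subpopulation allele counts as
#' \deqn{F_{ST} = 1 - \frac{\sum_j n_j^2 \pi_j}{\pi \, \sum_j n_j^2}}
#' where \eqn{n_j} is the number of allele observations in subpopulation
#' \eqn{j}, \eqn{\pi_j} its within-subpopulation diversity and \eqn{\pi} the
#' pooled-sample diversity. The squared-size weights downweight small
#' subpopulations. The value is not clamped: it can be negative when
#' subpopulation diversity exceeds pooled diversity, and is `NA` (undefined,
#' to be substituted later) when the pooled site is monomorphic.
#'
#' @param counts_a,counts_b matrices (or vectors) of allele-A and allele-B
#'   counts with one row (element) per site and one column per
#'   subpopulation; at least two subpopulation columns.
#' @return per-site F_ST values, `NA` where pooled \eqn{\pi = 0}.
#' @export
site_fst <- function(counts_a, counts_b) {
  if (is.vector(counts_a)) counts_a <- matrix(counts_a, nrow = 1L)
  if (is.vector(counts_b)) counts_b <- matrix(counts_b, nrow = 1L)
  stopifnot(all(dim(counts_a) == dim(counts_b)))
  if (ncol(counts_a) < 2) stop("need at least 2 subpopulations")
  n_j <- counts_a + counts_b
  pi_j <- ifelse(n_j > 0, 1 - (counts_a^2 + counts_b^2) / n_j^2, 0)
  pooled_a <- rowSums(counts_a)
  pooled_b <- rowSums(counts_b)
  pi_pooled <- site_pi(pooled_a, pooled_b)
  num <- rowSums(n_j^2 * pi_j)
  den <- pi_pooled * rowSums(n_j^2)
  ifelse(!is.na(pi_pooled) & pi_pooled > 0, 1 - num / den, NA_real_)
}

#' Per-SNP diversity and differentiation table
#'
#' Computes allele counts per subpopulation, within- and pooled-sample
#' \eqn{\pi} and the unbalanced-size F_ST at every mapped SNP. Samples
#' labelled `"excluded"` in the assignment are dropped; the first two
#' subpopulation labels (or `pops`) define the contrast, with the first
#' label the \eqn{\pi}-ratio numerator.
#'
#' @param g a [genotype_matrix()].
#' @param map genetic map data.frame (`snp_id`, `lg`, `cm`); genotyped SNPs
#'   absent from the map are dropped with a message.
#' @param assignment data.frame (`sample_id`, `subpop`).
#' @param pops optional character vector of length 2 selecting and ordering
#'   the subpopulation labels.
#' @return data.frame with columns `snp_id`, `lg`, `cm`, `n_pop1`, `n_pop2`
#'   (allele observations), `pi_pop1`, `pi_pop2`, `pi_pooled`, `fst`,
#'   `substituted`, sorted by group and position. Attribute `pops` records
#'   the contrast.
#' @export
site_stats <- function(g, map, assignment, pops = NULL) {
  map <- validate_genetic_map(map)
  keep_snp <- colnames(g) %in% map$snp_id
  if (any(!keep_snp)) {
    message(sum(!keep_snp), " genotyped SNP(s) not on the map: excluded")
    g <- g[, keep_snp, drop = FALSE]
  }
  if (ncol(g) == 0) stop("no mapped SNPs")
  lab <- assignment$subpop[match(rownames(g), assignment$sample_id)]
  if (anyNA(lab)) {
    message(sum(is.na(lab)), " sample(s) absent from assignment: excluded")
  }
  lab[is.na(lab)] <- "excluded"
  if (is.null(pops)) {
    pops <- setdiff(unique(lab), "excluded")
    if (length(pops) < 2) stop("need at least two non-excluded subpopulations")
    pops <- pops[1:2]
  }
  cnt <- lapply(pops, function(p) {
    rows <- lab == p
    if (sum(rows) < 2) stop("subpopulation '", p, "' has fewer than 2 samples")
    sub <- unclass(g)[rows, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    n_b <- colSums(sub, na.rm = TRUE)
    cbind(a = 2 * n_called - n_b, b = n_b)
  })
  ca <- cbind(cnt[[1L]][, "a"], cnt[[2L]][, "a"])
  cb <- cbind(cnt[[1L]][, "b"], cnt[[2L]][, "b"])
  mpos <- map[match(colnames(g), map$snp_id), ]
  out <- data.frame(
    snp_id = colnames(g), lg = mpos$lg, cm = mpos$cm,
    n_pop1 = ca[, 1L] + cb[, 1L], n_pop2 = ca[, 2L] + cb[, 2L],
    pi_pop1 = site_pi(ca[, 1L], cb[, 1L]),
    pi_pop2 = site_pi(ca[, 2L], cb[, 2L]),
    pi_pooled = site_pi(rowSums(ca), rowSums(cb)),
    fst = site_fst(ca, cb),
    substituted = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$lg, out$cm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pops") <- pops
  out
}

#' Replace undefined per-site F_ST values with the genomic mean
#'
#' Sites where the pooled sample is monomorphic have an undefined F_ST
#' (zero denominator); each such value is replaced by the arithmetic mean of
#' all defined per-site F_ST values genome-wide, and flagged in the
#' `substituted` column. Defined values are untouched.
#'
#' @param sites a [site_stats()] data.frame.
#' @return the data.frame with `fst` filled and `substituted` set.
#' @export
substitute_undefined_fst <- function(sites) {
  undef <- is.na(sites$fst)
  if (all(undef)) stop("no defined F_ST value to form a genomic mean")
  if (any(undef)) {
    sites$fst[undef] <- mean(sites$fst[!undef])
    sites$substituted[undef] <- TRUE
  }
  sites
}

#' Genome-wide summary of per-site statistics
#'
#' Arithmetic means over all mapped SNP records (F_ST post-substitution).
#' The alternative ratio-of-sums F_ST aggregate (one minus the summed
#' numerator over the summed denominator of the per-site estimator) is
#' selectable.
#'
#' @param sites a [site_stats()] data.frame (after
#'   [substitute_undefined_fst()] if undefined sites exist).
#' @param fst_aggregate `"site_mean"` (default) or `"ratio_of_sums"`.
#' @return list with `mean_fst`, `mean_pi_pop1`, `mean_pi_pop2`,
#'   `mean_pi_pooled`, `n_sites`, `n_substituted`, `fst_aggregate`.
#' @export
genomewide_summary <- function(sites, fst_aggregate = c("site_mean", "ratio_of_sums")) {
  fst_aggregate <- match.arg(fst_aggregate)
  if (nrow(sites) < 1) stop("empty site table")
  mean_fst <- if (fst_aggregate == "site_mean") {
    mean(sites$fst, na.rm = TRUE)
  } else {
    ok <- !sites$substituted & !is.na(sites$fst) & sites$pi_pooled > 0
    w <- sites$n_pop1[ok]^2 + sites$n_pop2[ok]^2
    num <- (1 - sites$fst[ok]) * sites$pi_pooled[ok] * w
    1 - sum(num) / sum(sites$pi_pooled[ok] * w)
  }
  list(mean_fst = mean_fst,
       mean_pi_pop1 = mean(sites$pi_pop1, na.rm = TRUE),
       mean_pi_pop2 = mean(sites$pi_pop2, na.rm = TRUE),
       mean_pi_pooled = mean(sites$pi_pooled, na.rm = TRUE),
       n_sites = nrow(sites), n_substituted = sum(sites$substituted),
       fst_aggregate = fst_aggregate)
}
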