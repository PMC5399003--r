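#' Pairwise genetic distance between samples
#'
#' Identity-by-state distance for inbred panels: for each SNP non-missing in
#' both samples the shared-allele score is 1 for identical homozygotes, 0 for
#' opposite homozygotes and 0.5 whenever either call is heterozygous; the
#' distance is one minus the mean score. Pairs with no jointly non-missing
#' SNP are undefined (`NA`); their count is kept in attribute `n_undefined`.
#'
#' @param g a [genotype_matrix()] with at least two samples.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(g) {
  if (nrow(g) < 2) stop("need at least 2 samples")
  m <- unclass(g)
  valid <- !is.na(m)
  a0 <- valid & m == 0L
  a2 <- valid & m == 2L
  het <- valid & m == 1L
  storage.mode(valid) <- "double"
  storage.mode(a0) <- "double"
  storage.mode(a2) <- "double"
  storage.mode(het) <- "double"
  n_joint <- tcrossprod(valid)
  hom_match <- tcrossprod(a0) + tcrossprod(a2)
  # SNPs where at least one of the pair is het (both non-missing)
  het_any <- tcrossprod(het, valid) + tcrossprod(valid, het) - tcrossprod(het)
  shared <- hom_match + 0.5 * het_any
  d <- 1 - shared / n_joint
  d[n_joint == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  attr(d, "n_undefined") <- sum(is.na(d[upper.tri(d)]))
  d
}

#' Linkage disequilibrium between two SNPs
#'
#' Squared Pearson correlation of allele-B dosages (AA = 0, AB = 1, BB = 2)
#' across samples non-missing at both SNPs.
#'
#' @param g a [genotype_matrix()].
#' @param snp1,snp2 SNP identifiers or column indices.
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) when either SNP
#'   has zero dosage variance among the jointly non-missing samples.
#' @export
ld_r2 <- function(g, snp1, snp2) {
  x <- g[, snp1]
  y <- g[, snp2]
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0) {
    warning("ld_r2 undefined: zero variance or too few joint calls")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Linkage disequilibrium decay with genetic distance
#'
#' All intra-linkage-group SNP pairs separated by at most `max_cm` are binned
#' by map distance, and mean r-squared is reported per bin together with the
#' pair count. The decay distance is the smallest bin midpoint at which mean
#' r-squared drops to `r2_threshold` or below (`NA` when never reached).
#'
#' @param g a [genotype_matrix()].
#' @param map genetic map data.frame (`snp_id`, `lg`, `cm`).
#' @param max_cm maximum pair distance considered (cM).
#' @param bin_cm bin width (cM).
#' @param r2_threshold decay threshold on mean r-squared.
#' @param thin keep every `thin`-th mapped SNP per group (speed knob for
#'   dense maps); 1 keeps all.
#' @return data.frame (`bin_lo`, `bin_hi`, `bin_mid`, `mean_r2`, `n_pairs`)
#'   with the decay distance in attribute `decay_cm`.
#' @export
ld_decay_curve <- function(g, map, max_cm = 10, bin_cm = 0.25,
                           r2_threshold = 0.2, thin = 1L) {
  map <- map[map$snp_id %in% colnames(g), , drop = FALSE]
  breaks <- seq(0, max_cm, by = bin_cm)
  if (breaks[length(breaks)] < max_cm) breaks <- c(breaks, max_cm)
  nb <- length(breaks) - 1L
  sum_r2 <- numeric(nb)
  n_pair <- integer(nb)
  for (grp in unique(map$lg)) {
    sub <- map[map$lg == grp, , drop = FALSE]
    sub <- sub[order(sub$cm), , drop = FALSE]
    if (thin > 1L) sub <- sub[seq(1L, nrow(sub), by = thin), , drop = FALSE]
    if (nrow(sub) < 2) next
    x <- matrix(as.numeric(unclass(g)[, sub$snp_id, drop = FALSE]), nrow = nrow(g))
    r2 <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))^2
    dmat <- abs(outer(sub$cm, sub$cm, "-"))
    ut <- upper.tri(dmat)
    sel <- ut & dmat <= max_cm & !is.na(r2)
    if (!any(sel)) next
    idx <- findInterval(dmat[sel], breaks, rightmost.closed = TRUE,
                        left.open = TRUE)
    idx[dmat[sel] == 0] <- 1L     # co-segregating bin markers land in bin 1
    sum_r2 <- sum_r2 + as.numeric(tapply(r2[sel], factor(idx, levels = seq_len(nb)),
                                         sum, default = 0))
    n_pair <- n_pair + as.integer(tapply(rep(1L, sum(sel)),
                                         factor(idx, levels = seq_len(nb)),
                                         sum, default = 0L))
  }
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                    bin_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
                    mean_r2 = ifelse(n_pair > 0, sum_r2 / pmax(n_pair, 1L), NA_real_),
                    n_pairs = n_pair)
  out <- out[out$n_pairs > 0, , drop = FALSE]
  rownames(out) <- NULL
  below <- which(!is.na(out$mean_r2) & out$mean_r2 <= r2_threshold)
  attr(out, "decay_cm") <- if (length(below)) out$bin_mid[below[1L]] else NA_real_
  attr(out, "r2_threshold") <- r2_threshold
  out
}
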