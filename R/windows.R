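#' Sliding-window scan configuration
#'
#' Defaults follow common practice for dense consensus maps: 0.15 cM windows
#' advanced in 0.03 cM steps, outliers called at bootstrap P <= 0.05 from one
#' million resampling replicates. Smoothing is an unweighted window mean by
#' default; a truncated Gaussian kernel (sigma = window/3) is available.
#'
#' @param window_cm window width (cM), > 0.
#' @param step_cm step between window centers (cM), in `(0, window_cm]`.
#' @param alpha significance level on bootstrap p-values.
#' @param n_boot bootstrap replicates per statistic (>= 100).
#' @param kernel `"uniform"` or `"gaussian"`.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(window_cm = 0.15, step_cm = 0.03, alpha = 0.05,
                        n_boot = 1e6, kernel = c("uniform", "gaussian")) {
  kernel <- match.arg(kernel)
  if (!(window_cm > 0)) stop("window_cm must be > 0")
  if (!(step_cm > 0 && step_cm <= window_cm))
    stop("step_cm must be in (0, window_cm]")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (n_boot < 100) stop("n_boot must be >= 100")
  structure(list(window_cm = window_cm, step_cm = step_cm, alpha = alpha,
                 n_boot = as.integer(n_boot), kernel = kernel),
            class = "scan_config")
}

#' Genome-scale constants for unit conversion
#'
#' @param map_length_cm total genetic map length in cM.
#' @param genome_mb physical genome size in Mb.
#' @return a list of class `genome_spec`.
#' @export
genome_spec <- function(map_length_cm = 837.11, genome_mb = 630) {
  if (!(map_length_cm > 0 && genome_mb > 0)) stop("both sizes must be > 0")
  structure(list(map_length_cm = map_length_cm, genome_mb = genome_mb),
            class = "genome_spec")
}

#' Build sliding windows over a genetic map
#'
#' Window centers on each linkage group run from the smallest marker
#' position in `step_cm` increments until they reach or pass the largest;
#' spans are half-open `[center - w/2, center + w/2)`.
#'
#' @param map genetic map data.frame (`snp_id`, `lg`, `cm`).
#' @param cfg a [scan_config()].
#' @return data.frame with `lg`, `center_cm`, `start_cm`, `end_cm`.
#' @export
make_windows <- function(map, cfg = scan_config()) {
  if (nrow(map) == 0) stop("empty map")
  half <- cfg$window_cm / 2
  eps <- 1e-9
  parts <- lapply(split(map$cm, map$lg), function(pos) {
    lo <- min(pos)
    hi <- max(pos)
    n <- if (hi > lo) ceiling((hi - lo) / cfg$step_cm - eps) else 0L
    centers <- lo + cfg$step_cm * (0:n)
    data.frame(center_cm = centers, start_cm = centers - half,
               end_cm = centers + half)
  })
  out <- do.call(rbind, Map(cbind, lg = names(parts), parts))
  rownames(out) <- NULL
  out[, c("lg", "center_cm", "start_cm", "end_cm")]
}

# index ranges of sorted positions falling in half-open [start, end)
.window_ranges <- function(pos, starts, ends) {
  lo <- findInterval(starts, pos, left.open = TRUE) + 1L   # first pos >= start
  hi <- findInterval(ends, pos, left.open = TRUE)          # last pos < end
  cbind(lo = lo, hi = hi, k = hi - lo + 1L)
}

#' Kernel-smooth per-site statistics into windows
#'
#' For each window, per-site values whose map position falls in the
#' half-open span are combined: an unweighted mean for the uniform kernel,
#' or a Gaussian-weighted mean (sigma = window/3, truncated at the span) for
#' the Gaussian kernel. Windows holding no site get `NA` and `k = 0`.
#'
#' @param sites data.frame with `lg`, `cm` and the columns named in
#'   `value_cols`; values must be finite where present.
#' @param windows output of [make_windows()].
#' @param value_cols names of the site columns to smooth.
#' @param cfg a [scan_config()].
#' @return `windows` with an added SNP count `k` and one smoothed column per
#'   entry of `value_cols` (same names).
#' @export
smooth_statistic <- function(sites, windows, value_cols, cfg = scan_config()) {
  stopifnot(all(value_cols %in% names(sites)))
  windows$k <- 0L
  for (v in value_cols) windows[[v]] <- NA_real_
  sigma <- cfg$window_cm / 3
  for (grp in unique(windows$lg)) {
    wi <- which(windows$lg == grp)
    sub <- sites[sites$lg == grp, , drop = FALSE]
    if (nrow(sub) == 0) next
    ord <- order(sub$cm)
    sub <- sub[ord, , drop = FALSE]
    rng <- .window_ranges(sub$cm, windows$start_cm[wi], windows$end_cm[wi])
    windows$k[wi] <- pmax(rng[, "k"], 0L)
    if (cfg$kernel == "uniform") {
      for (v in value_cols) {
        cs <- c(0, cumsum(sub[[v]]))
        tot <- cs[rng[, "hi"] + 1L] - cs[rng[, "lo"]]
        windows[[v]][wi] <- ifelse(rng[, "k"] >= 1L, tot / rng[, "k"], NA_real_)
      }
    } else {
      centers <- windows$center_cm[wi]
      for (j in seq_along(wi)) {
        if (rng[j, "k"] < 1L) next
        idx <- rng[j, "lo"]:rng[j, "hi"]
        w <- exp(-((sub$cm[idx] - centers[j])^2) / (2 * sigma^2))
        for (v in value_cols)
          windows[[v]][wi[j]] <- sum(w * sub[[v]][idx]) / sum(w)
      }
    }
  }
  windows
}

#' Window diversity ratio
#'
#' Ratio of the two smoothed window diversities (subpopulation 1 over
#' subpopulation 2). Undefined (`NA`) when the denominator is zero or either
#' window mean is missing; undefined windows are excluded from outlier
#' ranking.
#'
#' @param windows data.frame with smoothed `pi_pop1`, `pi_pop2` columns.
#' @return `windows` with an added `pi_ratio` column.
#' @export
window_pi_ratio <- function(windows) {
  windows$pi_ratio <- ifelse(
    !is.na(windows$pi_pop1) & !is.na(windows$pi_pop2) & windows$pi_pop2 > 0,
    windows$pi_pop1 / windows$pi_pop2, NA_real_)
  windows
}

#' Bootstrap p-values for window statistics
#'
#' Significance of each window mean is assessed against a null built by
#' resampling the genome-wide pool of per-site values: for every distinct
#' SNP count `k` present among the windows, `n_boot` replicates are drawn,
#' each the mean of `k` sites resampled with replacement from the pool (for
#' the diversity ratio, `k` (pi1, pi2) site pairs are resampled and the
#' ratio of means formed). Replicate banks are computed once per `k` and
#' shared by all windows of that count, so p-values do not depend on window
#' order. The upper-tail p-value uses the add-one estimator
#' `p = (1 + #\{replicate >= observed\}) / (1 + n_boot)`.
#'
#' @param windows data.frame with `k` and smoothed `fst` (and `pi_ratio` if
#'   requested) columns.
#' @param sites a [site_stats()] data.frame post-substitution; supplies the
#'   resampling pools (`fst`, and the (`pi_pop1`, `pi_pop2`) pairs).
#' @param cfg a [scan_config()].
#' @param seed integer seed making the replicate banks reproducible.
#' @param statistics which statistics to test.
#' @return `windows` with `p_fst` / `p_ratio` columns filled (`NA` for
#'   windows with `k = 0` or an undefined observed value).
#' @export
bootstrap_pvalues <- function(windows, sites, cfg = scan_config(), seed = 1L,
                              statistics = c("fst", "pi_ratio")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (any(is.na(sites$fst))) stop("sites contain undefined F_ST: substitute first")
  n_pool <- nrow(sites)
  if (n_pool < 2) stop("pool must hold at least 2 sites")
  n_boot <- cfg$n_boot
  if ("fst" %in% statistics) windows$p_fst <- NA_real_
  if ("pi_ratio" %in% statistics) windows$p_ratio <- NA_real_
  ks <- sort(unique(windows$k[windows$k >= 1L]))
  set.seed(seed)
  for (k in ks) {
    rows <- which(windows$k == k)
    if ("fst" %in% statistics) {
      reps <- colMeans(matrix(sites$fst[sample.int(n_pool, k * n_boot, replace = TRUE)],
                              nrow = k))
      reps <- sort(reps)
      obs <- windows$fst[rows]
      n_ge <- n_boot - findInterval(obs, reps, left.open = TRUE)
      windows$p_fst[rows] <- ifelse(is.na(obs), NA_real_, (1 + n_ge) / (1 + n_boot))
    }
    if ("pi_ratio" %in% statistics) {
      idx <- sample.int(n_pool, k * n_boot, replace = TRUE)
      num <- colMeans(matrix(sites$pi_pop1[idx], nrow = k))
      den <- colMeans(matrix(sites$pi_pop2[idx], nrow = k))
      reps <- num / den
      reps[is.nan(reps)] <- Inf      # 0/0 window mean: counts toward the tail
      reps <- sort(reps)
      obs <- windows$pi_ratio[rows]
      n_ge <- n_boot - findInterval(obs, reps, left.open = TRUE)
      windows$p_ratio[rows] <- ifelse(is.na(obs), NA_real_, (1 + n_ge) / (1 + n_boot))
    }
  }
  windows
}

# merge sorted half-open intervals, joining overlapping or abutting spans
.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1L]
  me <- end[1L]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Call outlier regions from significant windows
#'
#' Windows with bootstrap p-value at or below `alpha` are marked significant
#' per statistic; overlapping or abutting significant windows on the same
#' linkage group are merged, the region span being the union of member
#' window spans clipped to the mapped extent of the group. Total region
#' length per statistic is reported both as the clipped span union and as
#' the center-to-center extent of member windows.
#'
#' @param windows data.frame with `p_fst` / `p_ratio` filled.
#' @param cfg a [scan_config()].
#' @param map optional genetic map used to clip region spans to
#'   `[min, max]` marker position per group; without it spans are unclipped.
#' @param statistics which statistics to call regions for.
#' @return list with `windows` (plus `sig_*` flags), `regions` (data.frame
#'   `lg`, `start_cm`, `end_cm`, `statistic`, `length_cm`) and `totals`
#'   (per-statistic summed `total_length_cm` and `total_center_span_cm`).
#' @export
call_outlier_regions <- function(windows, cfg = scan_config(), map = NULL,
                                 statistics = c("fst", "pi_ratio")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  pcol <- c(fst = "p_fst", pi_ratio = "p_ratio")
  scol <- c(fst = "sig_fst", pi_ratio = "sig_ratio")
  bounds <- NULL
  if (!is.null(map)) {
    bounds <- do.call(rbind, lapply(split(map$cm, map$lg), range))
  }
  regions <- list()
  totals <- list()
  for (st in statistics) {
    p <- windows[[pcol[[st]]]]
    sig <- !is.na(p) & p <= cfg$alpha
    windows[[scol[[st]]]] <- sig
    tot_len <- 0
    tot_center <- 0
    for (grp in unique(windows$lg[sig])) {
      wi <- sig & windows$lg == grp
      mrg <- .merge_intervals(windows$start_cm[wi], windows$end_cm[wi])
      # center-to-center extent of the member windows of each raw region
      cspan <- vapply(seq_len(nrow(mrg)), function(i) {
        inside <- wi & windows$center_cm >= mrg[i, "start"] &
          windows$center_cm < mrg[i, "end"]
        diff(range(windows$center_cm[inside]))
      }, numeric(1))
      if (!is.null(bounds) && grp %in% rownames(bounds)) {
        mrg[, "start"] <- pmax(mrg[, "start"], bounds[grp, 1L])
        mrg[, "end"] <- pmin(mrg[, "end"], bounds[grp, 2L])
      }
      keep <- mrg[, "end"] > mrg[, "start"]
      mrg <- mrg[keep, , drop = FALSE]
      cspan <- cspan[keep]
      if (nrow(mrg) == 0) next
      regions[[length(regions) + 1L]] <- data.frame(
        lg = grp, start_cm = mrg[, "start"], end_cm = mrg[, "end"],
        statistic = st, length_cm = mrg[, "end"] - mrg[, "start"],
        stringsAsFactors = FALSE)
      tot_len <- tot_len + sum(mrg[, "end"] - mrg[, "start"])
      tot_center <- tot_center + sum(cspan)
    }
    totals[[st]] <- data.frame(statistic = st, total_length_cm = tot_len,
                               total_center_span_cm = tot_center,
                               stringsAsFactors = FALSE)
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(lg = character(), start_cm = numeric(), end_cm = numeric(),
               statistic = character(), length_cm = numeric(),
               stringsAsFactors = FALSE)
  regions <- regions[order(regions$statistic, regions$lg, regions$start_cm), ,
                     drop = FALSE]
  rownames(regions) <- NULL
  list(windows = windows, regions = regions, totals = do.call(rbind, totals))
}

#' Fraction of the genetic map covered by regions
#'
#' @param total_length_cm summed region length (cM).
#' @param spec a [genome_spec()].
#' @return percentage of the total map length.
#' @export
genome_fraction <- function(total_length_cm, spec = genome_spec()) {
  if (total_length_cm < 0) stop("length must be >= 0")
  100 * total_length_cm / spec$map_length_cm
}

#' Convert genetic distance to approximate physical distance
#'
#' Uses the genome-wide average ratio of physical to genetic length.
#'
#' @param distance_cm genetic distance (cM).
#' @param spec a [genome_spec()].
#' @return distance in Kb.
#' @export
cm_to_kb <- function(distance_cm, spec = genome_spec()) {
  if (any(distance_cm < 0)) stop("distance must be >= 0")
  distance_cm * (spec$genome_mb * 1000) / spec$map_length_cm
}
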