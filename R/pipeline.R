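#' Run the full selection-scan pipeline
#'
#' Validates inputs, computes per-site diversity and F_ST for the configured
#' subpopulation contrast, applies the genomic-mean substitution for
#' undefined F_ST sites, smooths the statistics into sliding windows,
#' assigns bootstrap p-values, and merges significant windows into outlier
#' regions. Fully deterministic given `seed`.
#'
#' @param g a [genotype_matrix()].
#' @param map genetic map data.frame (`snp_id`, `lg`, `cm`).
#' @param assignment data.frame (`sample_id`, `subpop`); samples labelled
#'   `"excluded"` or absent are dropped with a message.
#' @param cfg a [scan_config()].
#' @param filter optional [filter_spec()] applied to the SNPs first.
#' @param pops optional length-2 subpopulation selection/order.
#' @param seed integer seed for the bootstrap.
#' @param out_dir optional directory; when given, per-site, window and
#'   region TSVs plus a JSON run manifest are written there.
#' @return list of class `sweep_scan` with `sites`, `windows`, `regions`,
#'   `totals`, `summary` (from [genomewide_summary()]) and `manifest`.
#' @export
run_scan <- function(g, map, assignment, cfg = scan_config(), filter = NULL,
                     pops = NULL, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "scan_config"))
  map <- validate_genetic_map(map)
  n_input <- ncol(g)
  filter_log <- NULL
  if (!is.null(filter)) {
    g <- filter_snps(g, filter)
    filter_log <- attr(g, "filter_log")
    message("filter: retained ", filter_log$n_retained, " of ",
            filter_log$n_input, " SNPs")
  }
  sites <- site_stats(g, map, assignment, pops = pops)
  pops_used <- attr(sites, "pops")
  sites <- substitute_undefined_fst(sites)
  windows <- make_windows(map[map$snp_id %in% sites$snp_id, , drop = FALSE], cfg)
  windows <- smooth_statistic(sites, windows,
                              c("fst", "pi_pop1", "pi_pop2"), cfg)
  windows <- window_pi_ratio(windows)
  windows <- bootstrap_pvalues(windows, sites, cfg, seed = seed)
  called <- call_outlier_regions(windows, cfg, map = map)
  summary <- genomewide_summary(sites)
  manifest <- list(
    tool = "sweepscan", version = as.character(utils::packageVersion("sweepscan")),
    seed = as.integer(seed), pops = pops_used,
    window_cm = cfg$window_cm, step_cm = cfg$step_cm, alpha = cfg$alpha,
    n_boot = cfg$n_boot, kernel = cfg$kernel,
    n_snps_input = n_input, n_snps_used = nrow(sites),
    n_substituted = summary$n_substituted,
    n_samples = nrow(g), n_windows = nrow(called$windows),
    filter = if (is.null(filter)) NULL else unclass(filter),
    filter_log = filter_log,
    mean_fst = summary$mean_fst,
    mean_pi = c(summary$mean_pi_pop1, summary$mean_pi_pop2))
  out <- structure(list(sites = sites, windows = called$windows,
                        regions = called$regions, totals = called$totals,
                        summary = summary, manifest = manifest),
                   class = "sweep_scan")
  if (!is.null(out_dir)) write_scan(out, out_dir)
  out
}

#' Write scan outputs to a directory
#'
#' Writes `sites.tsv`, `windows.tsv`, `regions.tsv` (tab-separated with
#' `#`-prefixed metadata headers; region coordinates are centimorgans, not
#' base pairs) and `manifest.json`.
#'
#' @param scan a `sweep_scan` result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_scan <- function(scan, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- scan$manifest
  meta <- c(tool = m$tool, seed = m$seed, window_cm = m$window_cm,
            step_cm = m$step_cm, alpha = m$alpha, n_boot = m$n_boot,
            kernel = m$kernel, pops = paste(m$pops, collapse = ","))
  write_scan_tsv(scan$sites, file.path(out_dir, "sites.tsv"), meta)
  write_scan_tsv(scan$windows, file.path(out_dir, "windows.tsv"), meta)
  write_scan_tsv(scan$regions, file.path(out_dir, "regions.tsv"),
                 c(meta, coordinates = "centimorgan"))
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare two scans' regions against a trait-locus catalog
#'
#' Thin wrapper over [coincidence_report()] for region sets produced by
#' [run_scan()] (or read back from `regions.tsv`).
#'
#' @param regions_a,regions_b region data.frames; `regions_b` may be `NULL`
#'   for a single-scan report.
#' @param catalog a trait-locus catalog data.frame.
#' @param scan_names names for the two scans.
#' @param focal_trait trait counted separately in the region summary.
#' @param ld_halfwidth_cm LD-block half width for GWAS loci (cM).
#' @return a [coincidence_report()] list.
#' @export
run_overlap <- function(regions_a, regions_b = NULL, catalog,
                        scan_names = c("scan_a", "scan_b"),
                        focal_trait = "pod length", ld_halfwidth_cm = 2.0) {
  regs <- list(regions_a)
  names(regs) <- scan_names[1L]
  if (!is.null(regions_b)) {
    regs[[scan_names[2L]]] <- regions_b
  }
  coincidence_report(catalog, regs, focal_trait = focal_trait,
                     ld_halfwidth_cm = ld_halfwidth_cm)
}

#' @export
print.sweep_scan <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("sweep_scan: %d SNPs, %d samples, %d windows (%.2f cM / %.2f cM)\n",
              m$n_snps_used, m$n_samples, m$n_windows, m$window_cm, m$step_cm))
  cat(sprintf("  contrast %s vs %s | mean F_ST %.3f | mean pi %.3f / %.3f\n",
              m$pops[1L], m$pops[2L], x$summary$mean_fst,
              x$summary$mean_pi_pop1, x$summary$mean_pi_pop2))
  for (i in seq_len(nrow(x$totals)))
    cat(sprintf("  %s: %d region(s), %.2f cM\n", x$totals$statistic[i],
                sum(x$regions$statistic == x$totals$statistic[i]),
                x$totals$total_length_cm[i]))
  invisible(x)
}
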