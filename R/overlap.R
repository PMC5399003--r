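#' Chain associated SNPs into LD-block clusters
#'
#' Within each linkage group SNPs are sorted by map position and chained by
#' single linkage: consecutive SNPs closer than `gap_cm` (strictly) belong
#' to the same cluster. Unmapped SNPs (`NA` group or position) are excluded
#' with a warning.
#'
#' @param snps data.frame with `snp_id`, `lg`, `cm` (extra columns kept
#'   aside).
#' @param gap_cm chaining distance; consecutive SNPs at `>= gap_cm` start a
#'   new cluster.
#' @return data.frame (`cluster_id`, `lg`, `start_cm`, `end_cm`, `n_snps`,
#'   `snp_ids`) with the number of linkage groups represented in attribute
#'   `n_linkage_groups` and the excluded-SNP count in `n_unmapped`.
#' @export
cluster_snps <- function(snps, gap_cm = 2.0) {
  unmapped <- is.na(snps$lg) | is.na(snps$cm)
  if (any(unmapped)) {
    warning(sum(unmapped), " unmapped SNP(s) excluded from clustering")
    snps <- snps[!unmapped, , drop = FALSE]
  }
  if (nrow(snps) == 0) {
    out <- data.frame(cluster_id = integer(), lg = character(),
                      start_cm = numeric(), end_cm = numeric(),
                      n_snps = integer(), snp_ids = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_linkage_groups") <- 0L
    attr(out, "n_unmapped") <- sum(unmapped)
    return(out)
  }
  snps <- snps[order(snps$lg, snps$cm), , drop = FALSE]
  new_cluster <- c(TRUE, snps$lg[-1L] != snps$lg[-nrow(snps)] |
                     diff(snps$cm) >= gap_cm)
  cid <- cumsum(new_cluster)
  out <- do.call(rbind, lapply(split(seq_len(nrow(snps)), cid), function(i) {
    data.frame(lg = snps$lg[i[1L]], start_cm = min(snps$cm[i]),
               end_cm = max(snps$cm[i]), n_snps = length(i),
               snp_ids = paste(snps$snp_id[i], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "n_linkage_groups") <- length(unique(out$lg))
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Test trait loci for coincidence with sweep regions
#'
#' A qualitative locus coincides with a region when its position lies inside
#' the region's half-open span on the same linkage group. A GWAS locus is
#' widened to its LD block `[cm - ld_halfwidth_cm, cm + ld_halfwidth_cm]`
#' and coincides when the closed block overlaps (or touches) a region.
#' Loci on linkage groups absent from the region set's map are skipped with
#' a warning (`coincident = NA`).
#'
#' @param catalog data.frame (`locus_id`, `trait`, `lg`, `cm`, `mode`).
#' @param regions data.frame of regions (`lg`, `start_cm`, `end_cm`, and
#'   optionally `statistic`).
#' @param ld_halfwidth_cm LD-block half width around a GWAS locus (cM).
#' @param known_lgs optional character vector of valid linkage-group labels;
#'   defaults to the groups present in `regions`, plus those in the catalog.
#' @return `catalog` with logical `coincident` and a comma-separated
#'   `matched_regions` column (`"lg:start-end"` per match).
#' @export
coincide_loci <- function(catalog, regions, ld_halfwidth_cm = 2.0,
                          known_lgs = NULL) {
  catalog$coincident <- FALSE
  catalog$matched_regions <- ""
  if (!is.null(known_lgs)) {
    unknown <- !(catalog$lg %in% known_lgs)
    if (any(unknown)) {
      warning(sum(unknown), " locus/loci on unknown linkage group(s) skipped")
      catalog$coincident[unknown] <- NA
    }
  }
  if (nrow(regions) == 0) return(catalog)
  for (i in seq_len(nrow(catalog))) {
    if (is.na(catalog$coincident[i])) next
    r <- regions[regions$lg == catalog$lg[i], , drop = FALSE]
    if (nrow(r) == 0) next
    hit <- if (catalog$mode[i] == "qualitative") {
      catalog$cm[i] >= r$start_cm & catalog$cm[i] < r$end_cm
    } else {
      # closed LD block; touching a region boundary counts as overlap
      (catalog$cm[i] + ld_halfwidth_cm) >= r$start_cm &
        (catalog$cm[i] - ld_halfwidth_cm) <= r$end_cm
    }
    if (any(hit)) {
      catalog$coincident[i] <- TRUE
      catalog$matched_regions[i] <- paste(
        sprintf("%s:%.3f-%.3f", r$lg[hit], r$start_cm[hit], r$end_cm[hit]),
        collapse = ",")
    }
  }
  catalog
}

# do two half-open interval sets share any overlap on matching groups?
.regions_overlap <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    r <- b[b$lg == a$lg[i], , drop = FALSE]
    any(r$start_cm < a$end_cm[i] & r$end_cm > a$start_cm[i])
  }, logical(1))
}

#' Coincidence report across scans
#'
#' For each scan's merged region set, reports which catalog loci coincide,
#' counts regions coincident with the focal trait versus any other trait,
#' and flags regions specific to one scan (no overlap with any region of
#' the other scans).
#'
#' @param catalog data.frame (`locus_id`, `trait`, `lg`, `cm`, `mode`).
#' @param regions_by_scan named list of region data.frames (one per scan,
#'   e.g. domestication and improvement contrasts).
#' @param focal_trait trait label counted separately (default
#'   `"pod length"`).
#' @param ld_halfwidth_cm LD-block half width for GWAS loci (cM).
#' @return list with `per_locus` (scan x locus coincidence table),
#'   `region_summary` (per scan: region counts coincident with
#'   focal / other traits), and `scan_specific` (regions found in exactly
#'   one scan).
#' @export
coincidence_report <- function(catalog, regions_by_scan,
                               focal_trait = "pod length",
                               ld_halfwidth_cm = 2.0) {
  stopifnot(is.list(regions_by_scan), length(regions_by_scan) >= 1)
  if (is.null(names(regions_by_scan)))
    names(regions_by_scan) <- paste0("scan", seq_along(regions_by_scan))
  per_locus <- list()
  region_summary <- list()
  for (sc in names(regions_by_scan)) {
    reg <- regions_by_scan[[sc]]
    called <- coincide_loci(catalog, reg, ld_halfwidth_cm)
    per_locus[[sc]] <- cbind(scan = sc, called)
    n_focal <- 0L
    n_other <- 0L
    if (nrow(reg) > 0) {
      for (i in seq_len(nrow(reg))) {
        hits <- called[!is.na(called$coincident) & called$coincident &
                         called$lg == reg$lg[i], , drop = FALSE]
        if (nrow(hits) == 0) next
        inreg <- vapply(seq_len(nrow(hits)), function(j) {
          if (hits$mode[j] == "qualitative")
            hits$cm[j] >= reg$start_cm[i] && hits$cm[j] < reg$end_cm[i]
          else
            (hits$cm[j] + ld_halfwidth_cm) >= reg$start_cm[i] &&
              (hits$cm[j] - ld_halfwidth_cm) <= reg$end_cm[i]
        }, logical(1))
        if (!any(inreg)) next
        traits <- unique(hits$trait[inreg])
        if (focal_trait %in% traits) n_focal <- n_focal + 1L
        if (length(setdiff(traits, focal_trait)) > 0) n_other <- n_other + 1L
      }
    }
    region_summary[[sc]] <- data.frame(
      scan = sc, n_regions = nrow(reg),
      n_regions_focal_trait = n_focal, n_regions_other_trait = n_other,
      n_loci_coincident = sum(called$coincident, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  scan_specific <- list()
  if (length(regions_by_scan) >= 2) {
    for (sc in names(regions_by_scan)) {
      a <- regions_by_scan[[sc]]
      if (nrow(a) == 0) next
      others <- do.call(rbind, regions_by_scan[setdiff(names(regions_by_scan), sc)])
      spec <- if (is.null(others) || nrow(others) == 0) rep(TRUE, nrow(a)) else
        !.regions_overlap(a, others)
      if (any(spec))
        scan_specific[[sc]] <- cbind(scan = sc, a[spec, , drop = FALSE])
    }
  }
  list(per_locus = do.call(rbind, c(per_locus, list(make.row.names = FALSE))),
       region_summary = do.call(rbind, c(region_summary, list(make.row.names = FALSE))),
       scan_specific = if (length(scan_specific))
         do.call(rbind, c(scan_specific, list(make.row.names = FALSE))) else
           data.frame())
}
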