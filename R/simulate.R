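#' Configuration for the two-subpopulation panel simulator
#'
#' The generator emulates a diversity panel of essentially homozygous inbred
#' lines drawn from two diverged subpopulations. Ancestral allele
#' frequencies are uniform on `anc_freq_range` (array SNPs are ascertained
#' to be polymorphic, which pushes frequencies toward intermediate values);
#' subpopulation frequencies follow the Balding-Nichols model: a Beta
#' distribution with mean `p` and variance `F * p * (1 - p)`, with a
#' divergence parameter `F` per subpopulation. Planted sweep intervals use
#' an elevated `sweep_F` for both subpopulations and additionally push
#' subpopulation-2 frequencies toward the nearer boundary by factor
#' `diversity_loss`, depressing its diversity.
#'
#' The defaults reproduce a cowpea-like germplasm panel: 79 + 99 lines,
#' 25 873 SNPs on 11 linkage groups of ~76.1 cM, residual heterozygosity
#' 2\%, and per-subpopulation divergence `F = c(0.20, 0.70)`, which yields
#' mean per-site diversity near 0.31 and 0.13 in the two subpopulations and
#' a mean per-site F_ST near 0.26.
#'
#' @param n_pop1,n_pop2 number of inbred lines per subpopulation.
#' @param n_lg number of linkage groups.
#' @param map_length_per_lg length of each linkage group (cM).
#' @param n_snps total SNP count, spread uniformly over the groups.
#' @param background_F Balding-Nichols divergence outside sweeps; a single
#'   value (both subpopulations) or a length-2 vector `c(F1, F2)`.
#' @param sweeps `NULL`, or a data.frame with columns `lg`, `start_cm`,
#'   `end_cm`, `sweep_F`, `diversity_loss` describing planted sweeps.
#' @param het_rate residual heterozygous-call rate.
#' @param missing_rate missing-call rate.
#' @param anc_freq_range range of the uniform ancestral frequency.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pop1 = 79, n_pop2 = 99, n_lg = 11,
                       map_length_per_lg = 76.1, n_snps = 25873,
                       background_F = c(0.20, 0.70), sweeps = NULL,
                       het_rate = 0.02, missing_rate = 0.05,
                       anc_freq_range = c(0.10, 0.90), seed = 1L) {
  if (length(background_F) == 1L) background_F <- rep(background_F, 2L)
  stopifnot(length(background_F) == 2L, all(background_F >= 0),
            all(background_F < 1), n_pop1 >= 2, n_pop2 >= 2, n_lg >= 1,
            map_length_per_lg > 0, n_snps >= 1,
            het_rate >= 0, het_rate <= 1, missing_rate >= 0, missing_rate <= 1,
            length(anc_freq_range) == 2L, anc_freq_range[1L] > 0,
            anc_freq_range[2L] < 1, anc_freq_range[1L] < anc_freq_range[2L])
  if (!is.null(sweeps)) {
    need <- c("lg", "start_cm", "end_cm", "sweep_F", "diversity_loss")
    if (!all(need %in% names(sweeps)))
      stop("sweeps needs columns: ", paste(need, collapse = ", "))
    if (any(sweeps$lg < 1 | sweeps$lg > n_lg))
      stop("sweep on a linkage group outside 1..n_lg")
    if (any(sweeps$start_cm < 0 | sweeps$end_cm > map_length_per_lg |
              sweeps$start_cm >= sweeps$end_cm))
      stop("sweep interval outside map bounds")
    if (any(sweeps$sweep_F < 0 | sweeps$sweep_F >= 1 |
              sweeps$diversity_loss < 0 | sweeps$diversity_loss > 1))
      stop("sweep_F must be in [0,1), diversity_loss in [0,1]")
  }
  structure(list(n_pop1 = n_pop1, n_pop2 = n_pop2, n_lg = n_lg,
                 map_length_per_lg = map_length_per_lg, n_snps = n_snps,
                 background_F = background_F, sweeps = sweeps,
                 het_rate = het_rate, missing_rate = missing_rate,
                 anc_freq_range = anc_freq_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted-sweep set
#'
#' Six sweeps of 1.5-3 cM spread over alternate linkage groups, with strong
#' local divergence (`sweep_F = 0.9`) and severe subpopulation-2 diversity
#' loss (0.9), totalling about 13.5 cM -- the order of magnitude a
#' domestication scan flags on a map of this size.
#'
#' @param n_lg number of linkage groups available.
#' @param map_length_per_lg group length (cM).
#' @return a sweeps data.frame for [sim_config()].
#' @export
default_sweeps <- function(n_lg = 11, map_length_per_lg = 76.1) {
  lgs <- if (n_lg >= 11L) seq(1L, n_lg, by = 2L)[1:6] else seq_len(n_lg)
  len <- rep(c(3, 2, 1.5), length.out = length(lgs))
  start <- rep(c(0.25, 0.55, 0.75), length.out = length(lgs)) * map_length_per_lg
  start <- pmin(start, map_length_per_lg - len - 1)
  data.frame(lg = lgs, start_cm = start, end_cm = start + len,
             sweep_F = 0.9, diversity_loss = 0.9)
}

# Balding-Nichols draw: Beta with mean p and variance F p (1 - p)
.bn_draw <- function(p, F) {
  f <- p
  v <- F > 0
  if (any(v)) {
    shape <- (1 - F[v]) / F[v]
    f[v] <- stats::rbeta(sum(v), p[v] * shape, (1 - p[v]) * shape)
  }
  f
}

# push frequencies toward the nearer boundary by factor d
.push_boundary <- function(f, d) ifelse(f < 0.5, f * (1 - d), f + (1 - f) * d)

# inbred-line genotypes at allele-B frequency f, with het/missing contamination
.draw_genotypes <- function(f, n, het_rate, missing_rate, prefix) {
  g <- matrix(2L * stats::rbinom(n * length(f), 1L, rep(f, each = n)), nrow = n)
  if (het_rate > 0)
    g[matrix(stats::runif(length(g)) < het_rate, nrow = n)] <- 1L
  if (missing_rate > 0)
    g[matrix(stats::runif(length(g)) < missing_rate, nrow = n)] <- NA_integer_
  rownames(g) <- sprintf("%s_%03d", prefix, seq_len(n))
  g
}

#' Simulate a two-subpopulation inbred genotype panel
#'
#' Draws SNP map positions uniformly on each linkage group, ancestral and
#' subpopulation allele frequencies under the Balding-Nichols model (with
#' planted sweeps as configured), and genotypes for homozygous inbred lines
#' contaminated by residual heterozygosity and missing calls. Fully
#' reproducible from the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_panel` with `genotypes`
#'   (a [genotype_matrix()]), `map`, `assignment` and `truth` (a list:
#'   `snps` with per-SNP ancestral/subpopulation frequencies and sweep
#'   membership, and `sweeps`, the planted spans).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_snps
  lg <- sort(sample.int(cfg$n_lg, n, replace = TRUE))
  cm <- stats::runif(n, 0, cfg$map_length_per_lg)
  ord <- order(lg, cm)
  lg <- lg[ord]
  cm <- cm[ord]
  snp_id <- sprintf("SNP_%02d_%05d", lg, stats::ave(seq_len(n), lg, FUN = seq_along))
  p <- stats::runif(n, cfg$anc_freq_range[1L], cfg$anc_freq_range[2L])

  F1 <- rep(cfg$background_F[1L], n)
  F2 <- rep(cfg$background_F[2L], n)
  d <- numeric(n)
  in_sweep <- logical(n)
  if (!is.null(cfg$sweeps)) {
    for (i in seq_len(nrow(cfg$sweeps))) {
      s <- cfg$sweeps[i, ]
      hit <- lg == s$lg & cm >= s$start_cm & cm < s$end_cm
      in_sweep[hit] <- TRUE
      F1[hit] <- s$sweep_F
      F2[hit] <- s$sweep_F
      d[hit] <- s$diversity_loss
    }
  }
  f1 <- .bn_draw(p, F1)
  f2 <- .push_boundary(.bn_draw(p, F2), d)

  g1 <- .draw_genotypes(f1, cfg$n_pop1, cfg$het_rate, cfg$missing_rate, "P1")
  g2 <- .draw_genotypes(f2, cfg$n_pop2, cfg$het_rate, cfg$missing_rate, "P2")
  g <- rbind(g1, g2)
  colnames(g) <- snp_id
  g <- genotype_matrix(g)

  map <- data.frame(snp_id = snp_id, lg = sprintf("LG%02d", lg), cm = cm,
                    stringsAsFactors = FALSE)
  assignment <- data.frame(
    sample_id = rownames(g),
    subpop = rep(c("pop1", "pop2"), c(cfg$n_pop1, cfg$n_pop2)),
    stringsAsFactors = FALSE)
  truth_snps <- data.frame(snp_id = snp_id, lg = map$lg, cm = cm, p_anc = p,
                           f_pop1 = f1, f_pop2 = f2, in_sweep = in_sweep,
                           stringsAsFactors = FALSE)
  truth_sweeps <- if (is.null(cfg$sweeps)) NULL else
    transform(cfg$sweeps, lg = sprintf("LG%02d", lg))
  structure(list(genotypes = g, map = map, assignment = assignment,
                 truth = list(snps = truth_snps, sweeps = truth_sweeps),
                 config = cfg),
            class = "sim_panel")
}

#' Build a trait-locus catalog from simulation truth
#'
#' Places `n_true` loci inside the planted sweep spans and `n_decoy` loci at
#' least `buffer_cm` away from every sweep, alternating GWAS and qualitative
#' detection modes, for end-to-end tests of coincidence calling.
#'
#' @param truth the `truth` element of a [simulate_panel()] result (needs
#'   planted sweeps for `n_true > 0`).
#' @param n_true,n_decoy locus counts inside / away from sweeps.
#' @param seed integer seed.
#' @param buffer_cm minimum distance of a decoy from any sweep interval on
#'   the same linkage group (cM).
#' @param focal_trait trait label given to half of the true loci.
#' @return a catalog data.frame (`locus_id`, `trait`, `lg`, `cm`, `mode`,
#'   `source`).
#' @export
make_catalog <- function(truth, n_true = 10, n_decoy = 10, seed = 1L,
                         buffer_cm = 2.5, focal_trait = "pod length") {
  set.seed(seed)
  sweeps <- truth$sweeps
  if (n_true > 0 && (is.null(sweeps) || nrow(sweeps) == 0))
    stop("no planted sweeps available for true loci")
  other_traits <- c("seed size", "seed coat colour", "flower colour",
                    "leaf shape", "nematode resistance")
  rows <- list()
  if (n_true > 0) {
    si <- rep_len(seq_len(nrow(sweeps)), n_true)
    pos <- stats::runif(n_true, sweeps$start_cm[si], sweeps$end_cm[si])
    rows$true <- data.frame(
      locus_id = sprintf("TRUE_%02d", seq_len(n_true)),
      trait = ifelse(seq_len(n_true) %% 2L == 1L, focal_trait,
                     rep_len(other_traits, n_true)),
      lg = sweeps$lg[si], cm = pos,
      mode = rep_len(c("gwas", "qualitative"), n_true),
      source = "true_sweep", stringsAsFactors = FALSE)
  }
  if (n_decoy > 0) {
    lgs <- sort(unique(truth$snps$lg))
    got <- 0L
    dec <- list()
    while (got < n_decoy) {
      grp <- sample(lgs, 1L)
      pos <- stats::runif(1L, 0, max(truth$snps$cm[truth$snps$lg == grp]))
      near <- FALSE
      if (!is.null(sweeps))
        near <- any(sweeps$lg == grp & pos > sweeps$start_cm - buffer_cm &
                      pos < sweeps$end_cm + buffer_cm)
      if (near) next
      got <- got + 1L
      dec[[got]] <- data.frame(
        locus_id = sprintf("DECOY_%02d", got),
        trait = rep_len(other_traits, n_decoy)[got], lg = grp, cm = pos,
        mode = c("gwas", "qualitative")[1L + got %% 2L],
        source = "decoy", stringsAsFactors = FALSE)
    }
    rows$decoy <- do.call(rbind, dec)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_id = character(), trait = character(),
                      lg = character(), cm = numeric(), mode = character(),
                      source = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
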