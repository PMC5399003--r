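#' Reference design for planted-sweep recovery validation
#'
#' A scaled-down two-group scenario used to validate the scan end-to-end
#' against known truth: 6000 SNPs on two 40 cM linkage groups (about 11
#' SNPs per 0.15 cM window), a low background divergence (F = 0.05, as for
#' recently separated gene pools) and four planted sweeps totalling 11 cM
#' with strong local divergence (sweep F = 0.85) and near-complete
#' subpopulation-2 diversity loss (0.95). The low background keeps the
#' per-site F_ST noise floor well below the planted signal, which is what
#' makes recovery statistically identifiable at this window size; see the
#' methods vignette for the power analysis behind these choices.
#'
#' @param seed integer seed for the generator.
#' @return a [sim_config()].
#' @export
recovery_design <- function(seed = 1L) {
  sweeps <- data.frame(lg = c(1, 1, 2, 2),
                       start_cm = c(10, 28, 6, 22),
                       end_cm = c(13, 30.5, 8.5, 25),
                       sweep_F = 0.85, diversity_loss = 0.95)
  sim_config(n_snps = 6000, n_lg = 2, map_length_per_lg = 40,
             background_F = 0.05, sweeps = sweeps, seed = seed)
}

#' Score a scan against planted-sweep truth
#'
#' Window recall counts the significant fraction of windows whose center
#' lies inside a planted sweep span; the false-length fraction is the part
#' of the called F_ST region length falling outside every planted span.
#'
#' @param scan a [run_scan()] result.
#' @param truth the `truth` element of the [simulate_panel()] that produced
#'   the scanned genotypes (must contain planted sweeps).
#' @return list with `recall_fst`, `recall_ratio`, `false_length_fraction_fst`,
#'   `called_cm_fst`, `called_inside_cm_fst` and `n_sweep_windows`.
#' @export
evaluate_recovery <- function(scan, truth) {
  tr <- truth$sweeps
  if (is.null(tr) || nrow(tr) == 0) stop("truth has no planted sweeps")
  w <- scan$windows
  in_sweep <- rep(FALSE, nrow(w))
  for (i in seq_len(nrow(tr)))
    in_sweep <- in_sweep | (w$lg == tr$lg[i] & w$center_cm >= tr$start_cm[i] &
                              w$center_cm < tr$end_cm[i])
  reg <- scan$regions[scan$regions$statistic == "fst", , drop = FALSE]
  inside <- 0
  for (i in seq_len(nrow(reg))) {
    s <- tr[tr$lg == reg$lg[i], , drop = FALSE]
    if (nrow(s))
      inside <- inside + sum(pmax(0, pmin(reg$end_cm[i], s$end_cm) -
                                    pmax(reg$start_cm[i], s$start_cm)))
  }
  tot <- sum(reg$length_cm)
  list(recall_fst = mean(w$sig_fst[in_sweep]),
       recall_ratio = mean(w$sig_ratio[in_sweep]),
       false_length_fraction_fst = if (tot > 0) (tot - inside) / tot else 0,
       called_cm_fst = tot, called_inside_cm_fst = inside,
       n_sweep_windows = sum(in_sweep))
}
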