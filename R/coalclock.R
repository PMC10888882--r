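#' Exclude individuals with outgroup-continent admixture
#'
#' Individuals whose outgroup-related ancestry fraction (estimated
#' externally, e.g. by ADMIXTURE) strictly exceeds the threshold are
#' removed before clock estimation, to minimise the effect of recent gene
#' flow on the coalescence estimate. The boundary value is retained
#' (strict `>` filter).
#'
#' @param individuals character vector of ids.
#' @param fractions named numeric vector of ancestry fractions; every
#'   individual must be present.
#' @param threshold exclusion threshold (default 0.01 = 1%).
#' @return the retained ids, with attribute `n_removed`.
#' @export
exclude_admixed <- function(individuals, fractions, threshold = 0.01) {
  missing <- setdiff(individuals, names(fractions))
  if (length(missing) > 0) {
    stop("missing ancestry fraction for: ", paste(missing, collapse = ", "))
  }
  keep <- individuals[fractions[individuals] <= threshold]
  message(length(individuals) - length(keep), " of ", length(individuals),
          " individuals removed at ancestry threshold ", threshold)
  attr(keep, "n_removed") <- length(individuals) - length(keep)
  keep
}

#' Human-state emission rate of a haplotype, excluding archaic windows
#'
#' Maximum-likelihood Poisson rate per unit window,
#' `sum(obs) / sum(exposure)`, over windows not overlapped by
#' high-confidence archaic segments. Exposure is
#' `weight * callable / window_size`, with near-uncallable windows masked
#' as in the HMM.
#'
#' @param track an observation track.
#' @param archaic_segments optional segment table (typically called at
#'   posterior cutoff 0.9) whose windows are excluded.
#' @param min_callable_frac emission mask threshold.
#' @return the estimated human-state rate (per unit window).
#' @export
lambda_h_estimate <- function(track, archaic_segments = NULL,
                              min_callable_frac = 0.1) {
  wsize <- attr(track, "window_size")
  if (is.null(wsize)) wsize <- 1000
  ew <- track$weight * track$callable / wsize
  ew[track$callable < min_callable_frac * wsize] <- 0
  keep <- ew > 0
  if (!is.null(archaic_segments) && nrow(archaic_segments) > 0) {
    win_gr <- GenomicRanges::GRanges(
      track$chrom, IRanges::IRanges(track$start + 1, track$start + wsize))
    hit <- IRanges::overlapsAny(
      win_gr, .gr(archaic_segments[, c("chrom", "start", "end")]))
    keep <- keep & !hit
  }
  if (sum(ew[keep]) <= 0) stop("no usable windows for rate estimation")
  sum(track$obs[keep]) / sum(ew[keep])
}

#' Correct the human-state emission rate for bioinformatic losses
#'
#' Phasing drop-out and multi-allelic site removal delete true private
#' variants independently; the corrected rate divides by the joint survival
#' probability: `lambda / ((1 - phasing_dropout) *
#' (1 - multiallelic_removed))`. Archaic-ancestry contamination is handled
#' upstream by estimating the rate over non-archaic windows only
#' ([lambda_h_estimate()]).
#'
#' @param lambda_h human-state rate per unit window.
#' @param phasing_dropout fraction of true heterozygous private variants
#'   lost to phasing, in `[0, 1)`.
#' @param multiallelic_removed fraction of sites removed as multi-allelic,
#'   in `[0, 1)`.
#' @return the corrected rate.
#' @export
corrected_rate <- function(lambda_h, phasing_dropout = 0,
                           multiallelic_removed = 0) {
  if (phasing_dropout >= 1 || multiallelic_removed >= 1 ||
      phasing_dropout < 0 || multiallelic_removed < 0) {
    stop("correction fractions must be in [0, 1)")
  }
  lambda_h / ((1 - phasing_dropout) * (1 - multiallelic_removed))
}

#' Convert an emission rate to a minimum coalescence time
#'
#' Private derived variants accumulate on a haplotype at
#' `mu_yr * T` per bp since its coalescence with the outgroup, so
#' `T_min = lambda / (mu_yr * window_callable_bp)` years. This is the exact
#' inverse of the generative model's private-variant law and is reported as
#' a lower bound on the coalescence time.
#'
#' @param lambda_corrected corrected emission rate per unit window.
#' @param mu_yr mutation rate per bp per year (default 0.45e-9).
#' @param window_callable_bp effective bp per unit window (default 1000).
#' @return minimum coalescence time in years.
#' @export
rate_to_time <- function(lambda_corrected, mu_yr = 0.45e-9,
                         window_callable_bp = 1000) {
  if (mu_yr <= 0 || window_callable_bp <= 0) {
    stop("mu_yr and window_callable_bp must be > 0")
  }
  lambda_corrected / (mu_yr * window_callable_bp)
}

#' Cohort minimum-coalescence estimate with bootstrap interval
#'
#' Per individual, pools the two haplotypes' observation tracks (excluding
#' high-confidence archaic windows), corrects the emission rate and
#' converts it to years; the cohort summary is the mean with a percentile
#' bootstrap interval over individuals.
#'
#' @param tracks named list of observation tracks (`<ind>_h1`, `<ind>_h2`).
#' @param archaic_segments optional stringent segment table (cutoff 0.9).
#' @param mu_yr mutation rate per bp per year.
#' @param window_callable_bp effective bp per unit window.
#' @param phasing_dropout,multiallelic_removed correction fractions.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list with `per_individual` (data.frame id, lambda_corrected,
#'   t_min_yr), `mean_t_yr`, `ci` (2.5/97.5 percentiles), `n`.
#' @export
coalescence_estimate <- function(tracks, archaic_segments = NULL,
                                 mu_yr = 0.45e-9, window_callable_bp = 1000,
                                 phasing_dropout = 0,
                                 multiallelic_removed = 0,
                                 n_boot = 1000, seed = 1) {
  inds <- unique(sub("_h[12]$", "", names(tracks)))
  per <- lapply(inds, function(id) {
    hs <- tracks[names(tracks) %in% paste0(id, c("_h1", "_h2"))]
    lam <- vapply(names(hs), function(h) {
      seg <- if (is.null(archaic_segments)) NULL else
        archaic_segments[archaic_segments$hap == h, , drop = FALSE]
      lambda_h_estimate(hs[[h]], seg)
    }, numeric(1))
    lc <- corrected_rate(mean(lam), phasing_dropout, multiallelic_removed)
    data.frame(id = id, lambda_corrected = lc,
               t_min_yr = rate_to_time(lc, mu_yr, window_callable_bp))
  })
  per <- do.call(rbind, per)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    mean(per$t_min_yr[sample.int(nrow(per), replace = TRUE)])
  }, numeric(1))
  list(per_individual = per, mean_t_yr = mean(per$t_min_yr),
       ci = unname(quantile(boots, c(0.025, 0.975))), n = nrow(per))
}

#' Admissible contribution of an earlier out-of-Africa wave
#'
#' Under a two-wave model where a fraction `alpha` of the (non-archaic)
#' genome coalesces with the outgroup at `T_old` and the rest at `T_main`,
#' the expected emission rate is
#' `lambda(alpha) = mu_yr * w * ((1 - alpha) T_main + alpha T_old)`.
#' A grid value of `alpha` is admissible when `lambda(alpha)` falls inside
#' the observed cohort confidence interval of the corrected rate.
#'
#' @param lambdas per-individual corrected emission rates.
#' @param t_main,t_old main and earlier-wave coalescence times in years
#'   (`t_old > t_main > 0`).
#' @param alpha_grid candidate fractions (default 0 to 0.2 by 0.001).
#' @param mu_yr mutation rate per bp per year.
#' @param window_callable_bp effective bp per unit window.
#' @param conf confidence level for the cohort interval on the mean rate
#'   (percentile bootstrap, seeded).
#' @param n_boot,seed bootstrap controls.
#' @return list with `admissible` (the admissible alpha sub-interval, or
#'   empty), `grid` (data.frame alpha, lambda_expected, admissible),
#'   `ci_lambda`.
#' @export
earlier_wave_bound <- function(lambdas, t_main, t_old,
                               alpha_grid = seq(0, 0.2, by = 0.001),
                               mu_yr = 0.45e-9, window_callable_bp = 1000,
                               conf = 0.95, n_boot = 1000, seed = 1) {
  if (length(alpha_grid) == 0) stop("empty alpha grid")
  if (!(t_old > t_main && t_main > 0)) stop("need t_old > t_main > 0")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    mean(lambdas[sample.int(length(lambdas), replace = TRUE)])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(a, 1 - a)))
  lam_exp <- mu_yr * window_callable_bp *
    ((1 - alpha_grid) * t_main + alpha_grid * t_old)
  adm <- lam_exp >= ci[1] & lam_exp <= ci[2]
  grid <- data.frame(alpha = alpha_grid, lambda_expected = lam_exp,
                     admissible = adm)
  list(admissible = if (any(adm)) range(alpha_grid[adm]) else numeric(0),
       grid = grid, ci_lambda = ci)
}

#' Convert generations to years
#'
#' @param g number of generations (>= 0).
#' @param gen_time mean human generation time in years (default 28).
#' @return years.
#' @export
generations_to_years <- function(g, gen_time = 28) {
  if (any(g < 0)) stop("g must be >= 0")
  g * gen_time
}
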