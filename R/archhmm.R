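#' Two-state HMM parameters
#'
#' State 1 is "modern human", state 2 "archaic". Emissions are Poisson with
#' mean `emit_rates[s] * weight_w * callable_w / window_size` per window.
#'
#' @param start_probs length-2 probability simplex.
#' @param trans 2x2 row-stochastic transition matrix.
#' @param emit_rates expected private variants per fully callable
#'   unit-weight window, `c(human, archaic)`.
#' @param ll_trace optional log-likelihood trace from training.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(start_probs, trans, emit_rates, ll_trace = NULL) {
  start_probs <- as.numeric(start_probs)
  trans <- matrix(as.numeric(trans), 2, 2)
  emit_rates <- as.numeric(emit_rates)
  if (abs(sum(start_probs) - 1) > 1e-12 ||
      any(abs(rowSums(trans) - 1) > 1e-12)) {
    stop("probability rows must sum to 1")
  }
  if (any(start_probs < 0) || any(trans < 0)) {
    stop("probabilities must be in [0, 1]")
  }
  if (any(emit_rates < 0)) stop("emission rates must be >= 0")
  structure(list(start_probs = start_probs, trans = trans,
                 emit_rates = emit_rates, ll_trace = ll_trace),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Two-state archaic-introgression HMM\n")
  cat(sprintf("  emission rates: human %.5f, archaic %.5f (per unit window)\n",
              x$emit_rates[1], x$emit_rates[2]))
  cat(sprintf("  transitions: stay-human %.6f, stay-archaic %.6f\n",
              x$trans[1, 1], x$trans[2, 2]))
  if (!is.null(x$ll_trace)) {
    cat(sprintf("  trained: %d EM iterations, log-likelihood %.2f\n",
                length(x$ll_trace), tail(x$ll_trace, 1)))
  }
  invisible(x)
}

# flatten a track (or list of tracks) into obs / exposure / chain-start
# vectors. Windows with callable below min_callable_frac of the window are
# masked from emission (exposure 0): they carry no observation information.
.flatten_tracks <- function(tracks, min_callable_frac = 0.1) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  obs <- vector("list", length(tracks))
  ew <- vector("list", length(tracks))
  starts <- vector("list", length(tracks))
  index <- vector("list", length(tracks))
  off <- 0L
  for (t in seq_along(tracks)) {
    tr <- tracks[[t]]
    wsize <- attr(tr, "window_size")
    if (is.null(wsize)) wsize <- 1000
    e <- tr$weight * tr$callable / wsize
    e[tr$callable < min_callable_frac * wsize] <- 0
    obs[[t]] <- as.integer(tr$obs)
    ew[[t]] <- e
    cs <- which(c(TRUE, tr$chrom[-1] != tr$chrom[-nrow(tr)]))
    starts[[t]] <- off + cs - 1L
    index[[t]] <- off + seq_len(nrow(tr))
    off <- off + nrow(tr)
  }
  list(obs = unlist(obs), ew = unlist(ew),
       starts = as.integer(unlist(starts)), index = index)
}

#' Default HMM initialisation
#'
#' The human rate starts at 96% of the genome-wide mean observation rate
#' per unit exposure, the archaic rate at 10x that; transitions favour long
#' dwell times (stay-human 0.999, stay-archaic 0.98); the start
#' distribution is the stationary distribution of the transition matrix.
#' This places the initial point far from the symmetric saddle and near
#' typical human/archaic density ratios.
#'
#' @param tracks an observation track or list of tracks.
#' @param min_callable_frac windows with callable bp below this fraction of
#'   the window are treated as missing.
#' @return an `hmm_params` object.
#' @export
hmm_init <- function(tracks, min_callable_frac = 0.1) {
  fl <- .flatten_tracks(tracks, min_callable_frac)
  tot_e <- sum(fl$ew)
  if (tot_e <= 0) stop("no callable windows")
  lam <- sum(fl$obs[fl$ew > 0]) / tot_e
  if (lam <= 0) {
    stop("all observation counts are zero: archaic rate inestimable; ",
         "fit a single-state model instead")
  }
  trans <- rbind(c(0.999, 0.001), c(0.02, 0.98))
  statio <- c(trans[2, 1], trans[1, 2]) / (trans[1, 2] + trans[2, 1])
  hmm_params(statio, trans, c(0.96 * lam, 9.6 * lam))
}

#' Train the two-state HMM by Baum-Welch
#'
#' Expectation-maximisation with Poisson emissions of mean
#' `rate_state * weight_w * callable_w / window_size`. Chromosomes (and
#' separate tracks, when a list is given) are treated as independent chains
#' re-initialised from the start distribution. The log-likelihood is
#' non-decreasing across iterations; training stops when the improvement
#' falls below `tol` or after `max_iter` iterations.
#'
#' @param tracks an observation track or list of tracks (shared parameters
#'   are fitted across all of them).
#' @param init optional `hmm_params` initialisation (default [hmm_init()]).
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param max_iter maximum EM iterations (default 1000).
#' @param min_callable_frac emission mask threshold, see [hmm_init()].
#' @param rate_floor lower bound applied to emission rates for numerical
#'   stability.
#' @return trained `hmm_params` with the log-likelihood trace attached.
#' @export
hmm_train <- function(tracks, init = NULL, tol = 1e-4, max_iter = 1000,
                      min_callable_frac = 0.1, rate_floor = 1e-8) {
  fl <- .flatten_tracks(tracks, min_callable_frac)
  if (length(fl$obs) == 0) stop("empty observation track")
  if (is.null(init)) init <- hmm_init(tracks, min_callable_frac)
  fit <- cpp_hmm_em(fl$obs, fl$ew, fl$starts, init$start_probs, init$trans,
                    init$emit_rates, tol, max_iter, rate_floor)
  ll <- fit$ll_trace
  if (any(diff(ll) < -1e-6 * pmax(1, abs(ll[-length(ll)])))) {
    stop("internal error: EM log-likelihood decreased")
  }
  # report states in (human, archaic) order: human is the sparser state
  ord <- order(fit$emit_rates)
  hmm_params(fit$start_probs[ord], fit$trans[ord, ord],
             fit$emit_rates[ord], ll_trace = ll)
}

#' Posterior probability of the archaic state per window
#'
#' Forward-backward decoding with per-window scaling. Windows with zero
#' exposure (masked or near-fully uncallable) carry no emission
#' information; their posterior is driven by the transitions alone.
#'
#' @param track an observation track from [count_private()].
#' @param params trained `hmm_params`.
#' @param min_callable_frac emission mask threshold, as in training.
#' @return the track with an added `posterior` column (archaic-state
#'   probability in `[0, 1]`; the human-state posterior is its complement).
#' @export
hmm_posterior <- function(track, params, min_callable_frac = 0.1) {
  stopifnot(inherits(params, "hmm_params"))
  if (any(is.na(track$obs)) || any(is.na(track$weight))) {
    bad <- which(is.na(track$obs) | is.na(track$weight))[1]
    stop("NaN in observation track at ", track$chrom[bad], ":",
         track$start[bad])
  }
  fl <- .flatten_tracks(track, min_callable_frac)
  r <- cpp_hmm_fb(fl$obs, fl$ew, fl$starts, params$start_probs,
                  params$trans, params$emit_rates)
  track$posterior <- r$posterior
  attr(track, "loglik") <- r$loglik
  track
}

#' Call archaic segments from window posteriors
#'
#' Segments are maximal runs of consecutive windows whose archaic posterior
#' exceeds 0.5 (a tie at exactly 0.5 is assigned to the human state);
#' a run is retained iff its mean posterior reaches the cutoff. Segment
#' coordinates snap to window bounds.
#'
#' @param posterior a track with a `posterior` column ([hmm_posterior()]).
#' @param cutoff minimum mean posterior for a retained segment; 0.8
#'   standard, 0.9 stringent. Must lie in `(0.5, 1]`.
#' @return data.frame hap, chrom, start, end (bp, 0-based half-open),
#'   mean_posterior, n_obs, window_count.
#' @export
call_segments <- function(posterior, cutoff = 0.8) {
  if (cutoff <= 0.5 || cutoff > 1) stop("cutoff must be in (0.5, 1]")
  wsize <- attr(posterior, "window_size")
  if (is.null(wsize)) wsize <- 1000
  hap <- attr(posterior, "hap")
  if (is.null(hap)) hap <- "hap"
  out <- list()
  for (ch in unique(posterior$chrom)) {
    tr <- posterior[posterior$chrom == ch, , drop = FALSE]
    arc <- tr$posterior > 0.5
    if (!any(arc)) next
    r <- rle(arc)
    ends_i <- cumsum(r$lengths)
    starts_i <- c(0, head(ends_i, -1)) + 1
    for (j in which(r$values)) {
      idx <- starts_i[j]:ends_i[j]
      mp <- mean(tr$posterior[idx])
      if (mp < cutoff) next
      out[[length(out) + 1]] <- data.frame(
        hap = hap, chrom = ch,
        start = tr$start[idx[1]],
        end = tr$start[idx[length(idx)]] + wsize,
        mean_posterior = mp,
        n_obs = sum(tr$obs[idx]),
        window_count = length(idx)
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(hap = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      mean_posterior = numeric(), n_obs = integer(),
                      window_count = integer()))
  }
  do.call(rbind, out)
}

#' Per-individual archaic genome fraction
#'
#' Two accounting conventions are implemented. `"per-haplotype"` (default):
#' summed segment bp over both haplotypes divided by twice the callable
#' genome, so one fully archaic haplotype in an otherwise human individual
#' gives 0.5. `"union"`: bp covered by the union of the two haplotypes'
#' segments divided by the callable genome.
#'
#' @param segments segment table from [call_segments()] (column `hap`
#'   formatted `<individual>_h1` / `<individual>_h2`).
#' @param callable_bp callable genome length in bp (haploid).
#' @param individuals optional character vector of individual ids to report
#'   (individuals without segments get 0).
#' @param convention `"per-haplotype"` or `"union"`.
#' @return named numeric vector of archaic fractions per individual.
#' @export
individual_fraction <- function(segments, callable_bp,
                                individuals = NULL,
                                convention = c("per-haplotype", "union")) {
  convention <- match.arg(convention)
  if (callable_bp <= 0) stop("callable_bp must be > 0")
  ind <- sub("_h[12]$", "", segments$hap)
  if (is.null(individuals)) individuals <- sort(unique(ind))
  vapply(setNames(individuals, individuals), function(id) {
    seg <- segments[ind == id, , drop = FALSE]
    if (nrow(seg) == 0) return(0)
    if (convention == "per-haplotype") {
      sum(seg$end - seg$start) / (2 * callable_bp)
    } else {
      u <- interval_union(seg[, c("chrom", "start", "end")])
      sum(u$end - u$start) / callable_bp
    }
  }, numeric(1))
}

#' False-positive fraction of called archaic bases against truth tracts
#'
#' For simulated cohorts with known introgressed tracts: the fraction of
#' called archaic bases that lie outside the true tracts of the same
#' haplotype.
#'
#' @param segments called segment table (columns hap, chrom, start, end).
#' @param truth_tracts truth tract table (same columns).
#' @return list with `fpr` (fraction in `[0, 1]`), `called_bp`, `fp_bp`.
#' @export
segment_fpr <- function(segments, truth_tracts) {
  called <- 0; fp <- 0
  for (h in unique(segments$hap)) {
    sg <- segments[segments$hap == h, , drop = FALSE]
    th <- truth_tracts[truth_tracts$hap == h, , drop = FALSE]
    g <- .gr(sg[, c("chrom", "start", "end")])
    tg <- .gr(th[, c("chrom", "start", "end")])
    called <- called + sum(GenomicRanges::width(g))
    fp <- fp + sum(GenomicRanges::width(GenomicRanges::setdiff(g, tg)))
  }
  list(fpr = if (called > 0) fp / called else NA_real_,
       called_bp = called, fp_bp = fp)
}
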