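#' Build the outgroup variant set
#'
#' Collects every derived allele observed in the outgroup panel (or present
#' above `min_frequency`). Membership is by (chrom, position, derived
#' allele), not position only, so triallelic artifacts do not leak through.
#' Variants present in this set are excluded from "private" counts.
#'
#' @param x an `arch_cohort` (the simulated outgroup panel is used) or a
#'   path to a VCF with phased outgroup genotypes (biallelic SNVs; REF is
#'   taken as ancestral unless an `AA` INFO tag is present).
#' @param min_frequency minimum derived-allele frequency (fraction of
#'   haplotypes) for inclusion; the default 0 means any single carrier
#'   excludes a site, matching a strict "not found in the outgroup" rule.
#' @return an object of class `outgroup_set`: list with `keys`
#'   (chrom:pos:alt strings, 0-based positions) and `n_haplotypes`.
#' @export
build_outgroup_set <- function(x, min_frequency = 0) {
  if (inherits(x, "arch_cohort")) {
    nh <- length(x$outgroup_sites)
    if (nh == 0) stop("zero samples in outgroup panel")
    counts <- table(unlist(x$outgroup_sites))
    ids <- as.integer(names(counts))[counts / nh > min_frequency]
    keys <- .site_key(x$sites$chrom[ids], x$sites$pos[ids], x$sites$alt[ids])
  } else {
    v <- .read_phased_vcf(x)
    nh <- ncol(v$gt)
    if (nh == 0) stop("zero samples in outgroup panel")
    cnt <- rowSums(v$gt, na.rm = TRUE)
    keep <- cnt / nh > min_frequency
    keys <- .site_key(v$sites$chrom[keep], v$sites$pos[keep],
                      v$sites$alt[keep])
  }
  structure(list(keys = unique(keys), n_haplotypes = nh),
            class = "outgroup_set")
}

# read a phased VCF into 0-based biallelic sites + haplotype carrier matrix.
# Columns of gt are haplotypes named <sample>_h1 / <sample>_h2.
.read_phased_vcf <- function(path, allow_unphased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(alt) == 1 & nchar(ref) == 1
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) {
    return(list(sites = data.frame(chrom = fix[biallelic, "CHROM"],
                                   pos = as.numeric(fix[biallelic, "POS"]) - 1,
                                   ref = ref[biallelic], alt = alt[biallelic]),
                gt = matrix(0L, sum(biallelic), 0)))
  }
  gt <- gt[biallelic, , drop = FALSE]
  unphased <- matrix(grepl("/", gt) & !grepl("\\.", gt), nrow = nrow(gt))
  if (any(unphased)) {
    if (!allow_unphased) {
      w <- which(unphased, arr.ind = TRUE)[1, ]
      stop("unphased genotype at ", fix[biallelic, "CHROM"][w[1]], ":",
           fix[biallelic, "POS"][w[1]], " sample ", colnames(gt)[w[2]])
    }
    gt[unphased] <- NA_character_
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  to_int <- function(a) ifelse(a == ".", NA_integer_, as.integer(a == "1"))
  hap <- matrix(0L, nrow(gt), 2 * ncol(gt))
  hap[, seq(1, 2 * ncol(gt), 2)] <- to_int(a1)
  hap[, seq(2, 2 * ncol(gt), 2)] <- to_int(a2)
  colnames(hap) <- paste0(rep(colnames(gt), each = 2), "_h", 1:2)
  list(sites = data.frame(chrom = fix[biallelic, "CHROM"],
                          pos = as.numeric(fix[biallelic, "POS"]) - 1,
                          ref = ref[biallelic], alt = alt[biallelic]),
       gt = hap)
}

# per-window callable bp from a mask data.frame (chrom, start, end)
.window_callable <- function(mask, chrom, length, window_size) {
  nwin <- ceiling(length / window_size)
  call_bp <- numeric(nwin)
  mv <- mask[mask$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(mv))) {
    s <- max(0, mv$start[i]); e <- min(length, mv$end[i])
    if (e <= s) next
    w0 <- s %/% window_size; w1 <- (e - 1) %/% window_size
    ws <- w0:w1
    ov <- pmin(e, (ws + 1) * window_size) - pmax(s, ws * window_size)
    call_bp[ws + 1] <- call_bp[ws + 1] + ov
  }
  call_bp
}

#' Count private derived variants per window for one haplotype
#'
#' Windows tile each chromosome in half-open `[w, w + window_size)`
#' intervals of 0-based bp. A variant is counted if the haplotype carries
#' the derived allele, the allele is absent from the outgroup set, and the
#' site falls inside the callable mask.
#'
#' @param variants data.frame with columns chrom, pos (0-based), alt for
#'   derived alleles carried by the haplotype.
#' @param outgroup an [build_outgroup_set()] object.
#' @param mask callable mask, data.frame chrom/start/end (0-based
#'   half-open).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param window_size window size in bp (default 1000).
#' @param weights optional per-window weight vector from
#'   [estimate_weights()]; defaults to 1 in callable windows.
#' @param hap haplotype identifier stored on the track.
#' @return an observation track: data.frame chrom, start, obs, callable,
#'   weight with attributes `hap` and `window_size`.
#' @export
count_private <- function(variants, outgroup, mask, chrom_lengths,
                          window_size = 1000, weights = NULL, hap = "hap") {
  stopifnot(inherits(outgroup, "outgroup_set"))
  chroms <- names(chrom_lengths)
  keep <- !(.site_key(variants$chrom, variants$pos, variants$alt) %in%
              outgroup$keys)
  v <- variants[keep, , drop = FALSE]
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    L <- chrom_lengths[[i]]
    call_bp <- .window_callable(mask, chroms[i], L, window_size)
    nwin <- length(call_bp)
    vc <- v[v$chrom == chroms[i], , drop = FALSE]
    # callable-mask membership per site
    if (nrow(vc) > 0) {
      mv <- mask[mask$chrom == chroms[i], , drop = FALSE]
      mv <- mv[order(mv$start), , drop = FALSE]
      inside <- rep(FALSE, nrow(vc))
      if (nrow(mv) > 0) {
        j <- findInterval(vc$pos, mv$start)
        inside <- j >= 1 & vc$pos < mv$end[pmax(j, 1)]
      }
      vc <- vc[inside, , drop = FALSE]
    }
    obs <- integer(nwin)
    if (nrow(vc) > 0) {
      tb <- tabulate(vc$pos %/% window_size + 1, nbins = nwin)
      obs <- as.integer(tb)
    }
    out[[i]] <- data.frame(chrom = chroms[i],
                           start = (seq_len(nwin) - 1) * window_size,
                           obs = obs, callable = call_bp)
  }
  track <- do.call(rbind, out)
  track$weight <- if (is.null(weights)) ifelse(track$callable > 0, 1, 0) else
    weights
  stopifnot(all(track$obs[track$callable == 0] == 0))
  attr(track, "hap") <- hap
  attr(track, "window_size") <- window_size
  track
}

#' Per-window mutation-rate weights from outgroup SNP density
#'
#' SNP density is a proxy for local mutation rate. Density is measured in
#' coarse bins (default 1 Mb) over the outgroup panel's polymorphic sites
#' and broadcast to the analysis windows; weights are normalised so their
#' mean over callable windows is 1. Raw per-bin ratios are shrunk toward 1
#' by the ratio of their Poisson sampling variance to the observed
#' between-bin variance (empirical-Bayes), so that sparse panels do not
#' inject spurious rate variation; set `shrink = FALSE` for raw ratios.
#'
#' @param x an `arch_cohort`, a VCF path, or a data.frame of sites with
#'   columns chrom, pos (unique polymorphic positions).
#' @param mask callable mask data.frame.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window_size analysis window size in bp.
#' @param bin_size density estimation bin in bp (default 1e6).
#' @param shrink apply empirical-Bayes shrinkage of bin ratios toward 1
#'   (default `TRUE`).
#' @return numeric weight vector aligned with the window tiling used by
#'   [count_private()] (windows with zero callable bp get weight 0).
#' @export
estimate_weights <- function(x, mask, chrom_lengths, window_size = 1000,
                             bin_size = 1e6, shrink = TRUE) {
  sites <- if (inherits(x, "arch_cohort")) {
    ids <- sort(unique(unlist(x$outgroup_sites)))
    x$sites[ids, c("chrom", "pos")]
  } else if (is.character(x)) {
    .read_phased_vcf(x)$sites[, c("chrom", "pos")]
  } else {
    x[, c("chrom", "pos")]
  }
  if (nrow(sites) == 0) stop("all-zero SNP density: cannot estimate weights")
  chroms <- names(chrom_lengths)
  counts <- list(); lens <- list()
  for (i in seq_along(chroms)) {
    L <- chrom_lengths[[i]]
    nbin <- ceiling(L / bin_size)
    sc <- sites[sites$chrom == chroms[i], , drop = FALSE]
    counts[[i]] <- tabulate(sc$pos %/% bin_size + 1, nbins = nbin)
    lens[[i]] <- pmin(seq_len(nbin) * bin_size, L) -
      (seq_len(nbin) - 1) * bin_size
  }
  cnt <- unlist(counts); blen <- unlist(lens)
  rbar <- sum(cnt) / sum(blen)
  ratio <- (cnt / blen) / rbar
  if (shrink) {
    # Poisson sampling variance of each ratio vs between-bin variance
    noise <- 1 / (blen * rbar)
    signal <- max(0, stats::var(ratio) - mean(noise))
    ratio <- 1 + (ratio - 1) * signal / (signal + noise)
  }
  off <- c(0, cumsum(vapply(counts, length, integer(1))))
  w_all <- list()
  for (i in seq_along(chroms)) {
    L <- chrom_lengths[[i]]
    nwin <- ceiling(L / window_size)
    wbin <- ratio[(off[i] + 1):off[i + 1]]
    win_bin <- ((seq_len(nwin) - 1) * window_size) %/% bin_size + 1
    call_bp <- .window_callable(mask, chroms[i], L, window_size)
    w <- wbin[win_bin]
    w[call_bp == 0] <- 0
    w_all[[i]] <- list(w = w, callable = call_bp > 0)
  }
  w <- unlist(lapply(w_all, `[[`, "w"))
  callable <- unlist(lapply(w_all, `[[`, "callable"))
  m <- mean(w[callable])
  if (!is.finite(m) || m == 0) stop("all-zero SNP density in callable windows")
  w / m
}

#' Observation tracks for every haplotype of a cohort
#'
#' Convenience wrapper building one [count_private()] track per test
#' haplotype of a simulated cohort, with shared [estimate_weights()]
#' computed from the outgroup panel.
#'
#' @param cohort an `arch_cohort`.
#' @param outgroup optional pre-built outgroup set (default: built from the
#'   cohort at `min_frequency = 0`).
#' @param window_size window size in bp.
#' @param uniform_weights if `TRUE`, skip density weighting (weight 1 in
#'   callable windows); default `FALSE`.
#' @return named list of observation tracks.
#' @export
cohort_tracks <- function(cohort, outgroup = NULL, window_size = 1000,
                          uniform_weights = FALSE) {
  stopifnot(inherits(cohort, "arch_cohort"))
  if (is.null(outgroup)) outgroup <- build_outgroup_set(cohort)
  lens <- setNames(cohort$chroms$length, cohort$chroms$chrom)
  mask <- cohort$masks$callable
  weights <- if (uniform_weights) NULL else
    estimate_weights(cohort, mask, lens, window_size)
  lapply(setNames(names(cohort$hap_sites), names(cohort$hap_sites)),
         function(h) {
    ids <- cohort$hap_sites[[h]]
    count_private(cohort$sites[ids, c("chrom", "pos", "alt")], outgroup,
                  mask, lens, window_size, weights = weights, hap = h)
  })
}
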