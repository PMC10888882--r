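#' Window tiling of a genome
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window size in bp.
#' @return data.frame chrom, start (0-based window starts), with attribute
#'   `window_size`.
#' @export
make_windows <- function(chrom_lengths, window_size = 1000) {
  out <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    nwin <- ceiling(chrom_lengths[[ch]] / window_size)
    data.frame(chrom = ch, start = (seq_len(nwin) - 1) * window_size)
  }))
  attr(out, "window_size") <- window_size
  out
}

#' Archaic carrier frequency along the genome
#'
#' Per window, the fraction of haplotypes whose called segments (optionally
#' restricted to one source) overlap the window.
#'
#' @param segments segment table (columns hap, chrom, start, end and
#'   optionally source_label).
#' @param haplotypes character vector: the full haplotype roster (carriers
#'   are counted out of this denominator).
#' @param windows window tiling from [make_windows()].
#' @param source optional source label filter (requires a `source_label`
#'   column).
#' @param missing optional logical vector flagging windows with no callable
#'   bp; their frequency is set `NA`.
#' @return data.frame chrom, start, n_carriers, freq with attributes
#'   `n_haplotypes` and `window_size`.
#' @export
frequency_track <- function(segments, haplotypes, windows, source = NULL,
                            missing = NULL) {
  if (length(haplotypes) == 0) stop("empty haplotype roster")
  if (!is.null(source)) {
    segments <- segments[segments$source_label == source, , drop = FALSE]
  }
  wsize <- attr(windows, "window_size")
  win_gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1, windows$start + wsize))
  counts <- integer(nrow(windows))
  for (h in intersect(unique(segments$hap), haplotypes)) {
    seg <- segments[segments$hap == h, c("chrom", "start", "end")]
    hits <- IRanges::overlapsAny(win_gr, GenomicRanges::reduce(.gr(seg)))
    counts <- counts + hits
  }
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    n_carriers = counts,
                    freq = counts / length(haplotypes))
  if (!is.null(missing)) out$freq[missing] <- NA_real_
  attr(out, "n_haplotypes") <- length(haplotypes)
  attr(out, "window_size") <- wsize
  out
}

# merge consecutive same-chromosome window runs flagged TRUE into regions
.runs_to_regions <- function(track, flag, wsize) {
  out <- list()
  for (ch in unique(track$chrom)) {
    sel <- track$chrom == ch
    f <- flag[sel]; st <- track$start[sel]; fr <- track$freq[sel]
    f[is.na(f)] <- FALSE
    r <- rle(f)
    ends_i <- cumsum(r$lengths); starts_i <- c(0, head(ends_i, -1)) + 1
    for (j in which(r$values)) {
      idx <- starts_i[j]:ends_i[j]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = st[idx[1]], end = st[idx[length(idx)]] + wsize,
        statistic = mean(fr[idx], na.rm = TRUE))
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), statistic = numeric()))
  }
  do.call(rbind, out)
}

#' Archaic-ancestry enriched regions (mean + 2 sd rule)
#'
#' The enrichment threshold is the genome-wide mean frequency plus two
#' standard deviations, computed over non-missing windows; maximal runs of
#' adjacent windows strictly above the threshold are merged into regions.
#'
#' @param track a [frequency_track()].
#' @return data.frame chrom, start, end, kind = "enriched", statistic
#'   (mean frequency of the region); attribute `threshold`.
#' @export
enriched_regions <- function(track) {
  f <- track$freq[!is.na(track$freq)]
  if (length(f) < 2) stop("need at least two non-missing windows")
  mu <- mean(f); sig <- sd(f)
  if (sig == 0) {
    warning("zero variance in frequency track: no enriched regions called")
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), statistic = numeric())
    out$kind <- character(0)
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- mu + 2 * sig
  wsize <- attr(track, "window_size")
  out <- .runs_to_regions(track, track$freq > thr, wsize)
  if (nrow(out) > 0) out$kind <- "enriched" else out$kind <- character(0)
  attr(out, "threshold") <- thr
  out
}

#' Archaic-ancestry deserts
#'
#' Maximal runs of windows whose frequency is below `limit`, retained when
#' their genomic length reaches `min_len`. Missing windows do not break a
#' run and count toward its genomic length by default (deserts are genomic
#' regions); set `break_on_missing = TRUE` to end runs at missing windows.
#'
#' @param track a [frequency_track()].
#' @param limit frequency limit (default 0.001 = 0.1%).
#' @param min_len minimum region length in bp (default 10 Mb).
#' @param break_on_missing see above.
#' @return data.frame chrom, start, end, kind = "desert", statistic (mean
#'   frequency over non-missing windows).
#' @export
desert_scan <- function(track, limit = 0.001, min_len = 1e7,
                        break_on_missing = FALSE) {
  wsize <- attr(track, "window_size")
  if (min_len < wsize) stop("min_len must be at least the window size")
  below <- track$freq < limit
  below[is.na(below)] <- !break_on_missing
  out <- .runs_to_regions(track, below, wsize)
  out <- out[out$end - out$start >= min_len, , drop = FALSE]
  if (nrow(out) > 0) out$kind <- "desert" else out$kind <- character(0)
  rownames(out) <- NULL
  out
}

# Hudson (1992) FST with sample-size correction (Bhatia et al. 2013 form);
# n1, n2 are haplotype counts
.hudson_fst <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(den > 0, num / den, 0)
  pmin(pmax(fst, 0), 1 - 1e-9)
}

#' Population branch statistic on archaic carrier frequencies
#'
#' Per window, pairwise Hudson FST between the three populations' archaic
#' frequencies, branch lengths `T = -ln(1 - FST)`, and
#' `PBS_A = (T_AB + T_AC - T_BC) / 2`: the frequency change specific to
#' population A since its divergence from the references B and C.
#'
#' @param track_a,track_b,track_c [frequency_track()]s on identical
#'   windows (A is the focal population).
#' @return data.frame chrom, start, f_a, f_b, f_c, fst_ab, fst_ac, fst_bc,
#'   pbs.
#' @export
pbs_scan <- function(track_a, track_b, track_c) {
  if (!identical(track_a$chrom, track_b$chrom) ||
      !identical(track_a$start, track_b$start) ||
      !identical(track_a$chrom, track_c$chrom) ||
      !identical(track_a$start, track_c$start)) {
    stop("frequency tracks must share an identical window tiling")
  }
  na <- attr(track_a, "n_haplotypes"); nb <- attr(track_b, "n_haplotypes")
  nc <- attr(track_c, "n_haplotypes")
  fab <- .hudson_fst(track_a$freq, na, track_b$freq, nb)
  fac <- .hudson_fst(track_a$freq, na, track_c$freq, nc)
  fbc <- .hudson_fst(track_b$freq, nb, track_c$freq, nc)
  tab <- -log(1 - fab); tac <- -log(1 - fac); tbc <- -log(1 - fbc)
  data.frame(chrom = track_a$chrom, start = track_a$start,
             f_a = track_a$freq, f_b = track_b$freq, f_c = track_c$freq,
             fst_ab = fab, fst_ac = fac, fst_bc = fbc,
             pbs = (tab + tac - tbc) / 2)
}

#' Scan for derived alleles uniquely shared with one archaic clade
#'
#' Counts, per region, the sites where at least one test haplotype carries
#' the derived allele, at least one genome of the target clade carries it,
#' no genome of the other clade carries it (missing genotypes do not count
#' as carrying), and the outgroup lacks it.
#'
#' @param carrier_sites data.frame chrom, pos, alt: sites at which at least
#'   one test haplotype carries the derived allele.
#' @param panel an [archaic_panel()].
#' @param target_clade `"Denisovan"` or `"Neanderthal"`.
#' @param outgroup an `outgroup_set`.
#' @param regions data.frame chrom, start, end (0-based half-open).
#' @return `regions` with added `count` and `percentile` (rank of the
#'   region's count among all scanned regions).
#' @export
unique_shared_scan <- function(carrier_sites, panel, target_clade,
                               outgroup, regions) {
  ptab <- panel$table
  cl <- panel$clades[ptab$genome]
  keys <- .site_key(carrier_sites$chrom, carrier_sites$pos,
                    carrier_sites$alt)
  ok <- !(keys %in% outgroup$keys)
  tgt_keys <- unique(ptab$key[cl == target_clade & !is.na(ptab$carries) &
                                ptab$carries == 1L])
  oth_keys <- unique(ptab$key[cl != target_clade & !is.na(ptab$carries) &
                                ptab$carries == 1L])
  qual <- ok & (keys %in% tgt_keys) & !(keys %in% oth_keys)
  qs <- carrier_sites[qual, , drop = FALSE]
  counts <- vapply(seq_len(nrow(regions)), function(i) {
    sum(qs$chrom == regions$chrom[i] & qs$pos >= regions$start[i] &
          qs$pos < regions$end[i])
  }, numeric(1))
  regions$count <- counts
  regions$percentile <- 100 * rank(counts, ties.method = "average") /
    length(counts)
  regions
}

#' Regional haplotype statistics by group
#'
#' For a candidate region, per group of haplotypes: the carrier frequency
#' of segments overlapping the region, the lengths of those segments, and
#' a two-proportion z-score (pooled variance) of the group against all
#' other groups combined.
#'
#' @param segments segment table.
#' @param region list or one-row data.frame with chrom, start, end.
#' @param groups data.frame with columns hap, group covering the full
#'   haplotype roster.
#' @return data.frame group, n_haplotypes, n_carriers, freq, mean_len, z;
#'   attribute `lengths` holds the per-group segment length vectors.
#' @export
region_haplotype_stats <- function(segments, region, groups) {
  if (any(table(groups$group) == 0)) stop("group with zero haplotypes")
  ov <- segments$chrom == region$chrom & segments$end > region$start &
    segments$start < region$end
  seg <- segments[ov, , drop = FALSE]
  gs <- split(groups$hap, groups$group)
  lens <- list()
  rows <- lapply(names(gs), function(g) {
    haps <- gs[[g]]
    carriers <- unique(seg$hap[seg$hap %in% haps])
    l <- seg$end[seg$hap %in% haps] - seg$start[seg$hap %in% haps]
    lens[[g]] <<- l
    data.frame(group = g, n_haplotypes = length(haps),
               n_carriers = length(carriers),
               freq = length(carriers) / length(haps),
               mean_len = if (length(l)) mean(l) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$z <- vapply(seq_len(nrow(out)), function(i) {
    x1 <- out$n_carriers[i]; n1 <- out$n_haplotypes[i]
    x2 <- sum(out$n_carriers[-i]); n2 <- sum(out$n_haplotypes[-i])
    if (n2 == 0) return(NA_real_)
    two_proportion_z(x1, n1, x2, n2)
  }, numeric(1))
  attr(out, "lengths") <- lens
  out
}

#' Two-proportion z statistic with pooled variance
#'
#' `z = (p1 - p2) / sqrt(p(1-p) (1/n1 + 1/n2))` with `p` the pooled
#' proportion.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return the z statistic (0 when the pooled variance is 0).
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  v <- p * (1 - p) * (1 / n1 + 1 / n2)
  if (v <= 0) return(0)
  (p1 - p2) / sqrt(v)
}

#' Probability of a long shared haplotype under incomplete lineage sorting
#'
#' Tests whether a shared archaic-like haplotype of length `m` can be
#' explained by retained ancestral polymorphism rather than introgression.
#' Under ILS the expected tract length is `L = 1/(r * t_split)`; the length
#' law is Gamma with shape 2 and mean `2L` (the standard construction for
#' this test; an Exponential alternative with mean `L` is available). The
#' p-value is the upper-tail probability of observing length `>= m`, and is
#' monotone decreasing in `m`.
#'
#' @param m observed haplotype length in bp.
#' @param r per-bp per-generation recombination rate.
#' @param t_split generations since the archaic-modern split.
#' @param law `"gamma"` (default) or `"exponential"`.
#' @return the ILS p-value.
#' @export
ils_pvalue <- function(m, r, t_split, law = c("gamma", "exponential")) {
  law <- match.arg(law)
  if (any(c(m, r, t_split) <= 0)) stop("m, r and t_split must be > 0")
  rate <- r * t_split
  if (law == "gamma") {
    pgamma(m, shape = 2, rate = rate, lower.tail = FALSE)
  } else {
    pexp(m, rate = rate, lower.tail = FALSE)
  }
}
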