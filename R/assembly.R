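#' Union of genomic segments
#'
#' Merges a set of (possibly overlapping) segments into a sorted,
#' non-overlapping interval set; adjacent intervals (`end == start`) are
#' merged. This is the "assembled introgressing genome" of a group of
#' haplotypes.
#'
#' @param segments data.frame with columns chrom, start, end (0-based
#'   half-open bp).
#' @return data.frame chrom, start, end, sorted and disjoint, with
#'   attribute `total_bp`.
#' @export
interval_union <- function(segments) {
  if (nrow(segments) > 0 && any(segments$end < segments$start)) {
    stop("negative-length interval")
  }
  out <- .gr_df(GenomicRanges::reduce(.gr(segments)))
  attr(out, "total_bp") <- sum(out$end - out$start)
  out
}

#' Total bp covered by a segment set
#'
#' @param segments data.frame chrom/start/end.
#' @return total union bp (overlaps counted once).
#' @export
union_bp <- function(segments) {
  u <- interval_union(segments)
  sum(u$end - u$start)
}

# merged per-individual interval set: both haplotypes of an individual are
# merged first, so a homozygous archaic tract counts once
.per_individual_sets <- function(segments) {
  ind <- sub("_h[12]$", "", segments$hap)
  lapply(split(segments[, c("chrom", "start", "end")], ind),
         function(df) GenomicRanges::reduce(.gr(df)))
}

#' Sharing partition of per-population interval sets
#'
#' Assigns every base of the global union to exactly one non-empty subset
#' of populations (the populations whose set covers it). Singleton subsets
#' are "unique" sequence, subsets of size two or more "shared".
#'
#' @param sets named list of interval-set data.frames (chrom, start, end),
#'   one per population.
#' @return data.frame subset (population names joined by `+`), n_pops, bp,
#'   fraction (of the global union); attribute `union_bp`.
#' @export
sharing_partition <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("population sets must have unique names")
  }
  if (length(sets) < 2) stop("need at least two populations")
  grl <- lapply(sets, .gr)
  all_gr <- GenomicRanges::reduce(do.call(c, unname(grl)))
  if (length(all_gr) == 0) {
    out <- data.frame(subset = character(), n_pops = integer(),
                      bp = numeric(), fraction = numeric())
    attr(out, "union_bp") <- 0
    return(out)
  }
  pieces <- GenomicRanges::disjoin(
    do.call(c, c(unname(grl), list(all_gr)))
  )
  member <- vapply(grl, function(g) {
    IRanges::overlapsAny(pieces, g)
  }, logical(length(pieces)))
  if (length(pieces) == 1) member <- matrix(member, nrow = 1)
  keys <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "+"))
  widths <- GenomicRanges::width(pieces)
  keep <- keys != ""
  bp <- tapply(widths[keep], keys[keep], sum)
  out <- data.frame(subset = names(bp), bp = as.numeric(bp),
                    row.names = NULL)
  out$n_pops <- lengths(strsplit(out$subset, "+", fixed = TRUE))
  total <- sum(GenomicRanges::width(all_gr))
  out$fraction <- out$bp / total
  out <- out[order(-out$bp), c("subset", "n_pops", "bp", "fraction")]
  rownames(out) <- NULL
  attr(out, "union_bp") <- as.numeric(total)
  out
}

#' Rarefaction of assembled archaic sequence vs sample size
#'
#' For each sample size `n`, draws `n_boot` random subsets of individuals
#' without replacement and averages the bp of the union of their merged
#' segment sets. The curve is non-decreasing in `n` within any fixed draw.
#'
#' @param segments segment table with `hap` column
#'   (`<individual>_h1/_h2`); both haplotypes of an individual are merged
#'   first.
#' @param sample_sizes integer vector of subset sizes.
#' @param n_boot bootstrap draws per size (a size equal to the full cohort
#'   is computed exactly, without sampling).
#' @param seed integer seed.
#' @return data.frame n, mean_bp, lo, hi (2.5/97.5 percentiles).
#' @export
rarefaction <- function(segments, sample_sizes, n_boot = 50, seed = 1) {
  sets <- .per_individual_sets(segments)
  n_ind <- length(sets)
  if (max(sample_sizes) > n_ind) {
    stop("sample size exceeds cohort (", n_ind, " individuals)")
  }
  set.seed(seed)
  rows <- lapply(sort(sample_sizes), function(n) {
    if (n == n_ind) {
      bp <- sum(GenomicRanges::width(
        GenomicRanges::reduce(do.call(c, unname(sets)))))
      return(data.frame(n = n, mean_bp = bp, lo = bp, hi = bp))
    }
    vals <- vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(n_ind, n)
      sum(GenomicRanges::width(
        GenomicRanges::reduce(do.call(c, unname(sets[pick])))))
    }, numeric(1))
    data.frame(n = n, mean_bp = mean(vals),
               lo = unname(quantile(vals, 0.025)),
               hi = unname(quantile(vals, 0.975)))
  })
  do.call(rbind, rows)
}

#' Compare assembled sequence between two cohorts at equal sample size
#'
#' Paired bootstrap (sampling individuals with replacement) of the union bp
#' recovered from `n` individuals of each cohort; reports the mean
#' difference (A minus B) with a percentile confidence interval.
#'
#' @param segments_a,segments_b segment tables with `hap` columns.
#' @param n downsampled number of individuals (must not exceed either
#'   cohort).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list with `diff_bp` (mean difference), `ci` (percentile
#'   interval), `n`, `n_boot`.
#' @export
downsample_compare <- function(segments_a, segments_b, n, n_boot = 200,
                               seed = 1, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  sa <- .per_individual_sets(segments_a)
  sb <- .per_individual_sets(segments_b)
  if (n > length(sa) || n > length(sb)) {
    stop("n exceeds a cohort size (", length(sa), " vs ", length(sb), ")")
  }
  set.seed(seed)
  ubp <- function(sets, pick) {
    sum(GenomicRanges::width(
      GenomicRanges::reduce(do.call(c, unname(sets[pick])))))
  }
  d <- vapply(seq_len(n_boot), function(b) {
    ubp(sa, sample.int(length(sa), n, replace = TRUE)) -
      ubp(sb, sample.int(length(sb), n, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(diff_bp = mean(d),
       ci = unname(quantile(d, c(alpha, 1 - alpha))),
       n = n, n_boot = n_boot)
}
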