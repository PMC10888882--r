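#' Load an IBD/HBD segment table with quality filters
#'
#' Reads a hap-IBD-dialect TSV (columns id1, hap1, id2, hap2, chrom,
#' start_bp, end_bp, length_cM), drops segments shorter than `min_cM`
#' (false-positive control) and segments overlapping a centromere interval
#' by any amount. HBD segments are encoded as rows with `id1 == id2`.
#'
#' @param path TSV path (no header expected; a header row starting with
#'   "id1" is tolerated). A data.frame may be given directly.
#' @param min_cM minimum segment length in cM (default 2).
#' @param centromeres optional data.frame chrom/start/end (0-based
#'   half-open) of centromere intervals.
#' @return the filtered segment table, with attribute `n_dropped`
#'   (short, centromeric).
#' @export
load_ibd_segments <- function(path, min_cM = 2.0, centromeres = NULL) {
  cols <- c("id1", "hap1", "id2", "hap2", "chrom", "start_bp", "end_bp",
            "length_cM")
  if (is.data.frame(path)) {
    df <- path
  } else {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (nrow(raw) > 0 && raw[1, 1] == "id1") raw <- raw[-1, , drop = FALSE]
    if (ncol(raw) < 8) stop("expected 8 columns, got ", ncol(raw))
    df <- data.frame(id1 = raw[[1]], hap1 = suppressWarnings(as.integer(raw[[2]])),
                     id2 = raw[[3]], hap2 = suppressWarnings(as.integer(raw[[4]])),
                     chrom = raw[[5]],
                     start_bp = suppressWarnings(as.numeric(raw[[6]])),
                     end_bp = suppressWarnings(as.numeric(raw[[7]])),
                     length_cM = suppressWarnings(as.numeric(raw[[8]])),
                     stringsAsFactors = FALSE)
    bad <- which(is.na(df$start_bp) | is.na(df$end_bp) | is.na(df$length_cM) |
                   df$end_bp <= df$start_bp | df$id1 == "" | df$id2 == "")
    if (length(bad) > 0) stop("malformed segment row at line ", bad[1])
  }
  stopifnot(all(cols %in% names(df)))
  n0 <- nrow(df)
  df <- df[df$length_cM >= min_cM, , drop = FALSE]
  n_short <- n0 - nrow(df)
  n_cen <- 0
  if (!is.null(centromeres) && nrow(df) > 0) {
    seg_gr <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start_bp + 1, df$end_bp))
    hit <- IRanges::overlapsAny(seg_gr, .gr(centromeres))
    n_cen <- sum(hit)
    df <- df[!hit, , drop = FALSE]
  }
  message("IBD filter: ", n_short, " segments < ", min_cM, " cM and ",
          n_cen, " centromere-overlapping segments dropped (", nrow(df),
          " retained)")
  rownames(df) <- NULL
  attr(df, "n_dropped") <- c(short = n_short, centromere = n_cen)
  df
}

#' Length-stratified homozygosity-by-descent profile per individual
#'
#' Long HBD segments (length at or above the threshold, default 8 cM)
#' indicate recent consanguinity; short segments mostly reflect historical
#' founder events.
#'
#' @param table segment table ([load_ibd_segments()]); HBD rows have
#'   `id1 == id2`.
#' @param long_threshold length threshold in cM (8 standard, 20
#'   alternative).
#' @param roster optional ids to report (individuals without HBD rows get
#'   zeros).
#' @return data.frame id, total_hbd_cM, short_hbd_cM, long_hbd_cM,
#'   long_fraction.
#' @export
hbd_profile <- function(table, long_threshold = 8.0, roster = NULL) {
  hbd <- table[table$id1 == table$id2, , drop = FALSE]
  ids <- if (is.null(roster)) sort(unique(hbd$id1)) else roster
  out <- lapply(ids, function(id) {
    l <- hbd$length_cM[hbd$id1 == id]
    tot <- sum(l); lng <- sum(l[l >= long_threshold])
    data.frame(id = id, total_hbd_cM = tot, short_hbd_cM = tot - lng,
               long_hbd_cM = lng,
               long_fraction = if (tot > 0) lng / tot else 0)
  })
  do.call(rbind, out)
}

# total pairwise IBD (cM) between distinct individuals, summed over all
# haplotype-pair combinations, no cap at genome length
.pair_totals <- function(table) {
  ibd <- table[table$id1 != table$id2, , drop = FALSE]
  if (nrow(ibd) == 0) {
    return(data.frame(a = character(), b = character(), cm = numeric()))
  }
  a <- pmin(ibd$id1, ibd$id2); b <- pmax(ibd$id1, ibd$id2)
  agg <- stats::aggregate(ibd$length_cM, by = list(a = a, b = b), FUN = sum)
  names(agg)[3] <- "cm"
  agg
}

#' Closest-relative sharing curve
#'
#' For each roster individual, finds the partner sharing the largest total
#' IBD (summed over all segments and haplotype pairs); the curve reports,
#' for each grid value `x`, the fraction of individuals whose closest
#' partner shares at least `x` cM. With `exclude_same_ssu = TRUE` only
#' cross-SSU (sampling unit) pairs are eligible, removing sampling-induced
#' relatedness.
#'
#' @param table IBD segment table.
#' @param roster character vector of individual ids (individuals absent
#'   from the table share 0).
#' @param x_grid grid of total-IBD values in cM (default 0..4000 by 1).
#' @param ssu optional named vector mapping id to sampling unit.
#' @param exclude_same_ssu restrict to cross-SSU pairs.
#' @return list with `x`, `fraction` (survival curve), `closest` (named
#'   per-individual maxima).
#' @export
closest_relative_curve <- function(table, roster, x_grid = seq(0, 4000, 1),
                                   ssu = NULL, exclude_same_ssu = FALSE) {
  if (length(roster) < 2) stop("need at least two individuals")
  pt <- .pair_totals(table)
  pt <- pt[pt$a %in% roster & pt$b %in% roster, , drop = FALSE]
  if (exclude_same_ssu) {
    if (is.null(ssu)) stop("ssu map required when exclude_same_ssu = TRUE")
    pt <- pt[ssu[pt$a] != ssu[pt$b], , drop = FALSE]
  }
  closest <- setNames(numeric(length(roster)), roster)
  if (nrow(pt) > 0) {
    for (side in c("a", "b")) {
      mx <- tapply(pt$cm, pt[[side]], max)
      ids <- names(mx)
      closest[ids] <- pmax(closest[ids], mx)
    }
  }
  frac <- vapply(x_grid, function(x) mean(closest >= x), numeric(1))
  list(x = x_grid, fraction = frac, closest = closest)
}

#' Bootstrap band for the closest-relative curve
#'
#' Repeatedly subsamples `n_sub` individuals without replacement,
#' recomputes the closest-relative curve within the subsample only, and
#' reports the mean and percentile band. Subsampling makes curves
#' comparable across cohorts of different size (fewer candidate relatives
#' lower the curve).
#'
#' @param table IBD segment table.
#' @param roster individual ids (must have at least `n_sub`).
#' @param n_sub subsample size (default 500).
#' @param n_boot replicates (default 100).
#' @param seed integer seed.
#' @param x_grid grid of total-IBD values in cM.
#' @param ssu,exclude_same_ssu as in [closest_relative_curve()].
#' @return list with `x`, `mean`, `lo`, `hi` (2.5/97.5 percentiles).
#' @export
bootstrap_curve <- function(table, roster, n_sub = 500, n_boot = 100,
                            seed = 1, x_grid = seq(0, 4000, 1), ssu = NULL,
                            exclude_same_ssu = FALSE) {
  if (n_sub > length(roster)) stop("n_sub exceeds the roster size")
  set.seed(seed)
  mat <- vapply(seq_len(n_boot), function(b) {
    sub <- if (n_sub == length(roster)) roster else sample(roster, n_sub)
    closest_relative_curve(table, sub, x_grid, ssu,
                           exclude_same_ssu)$fraction
  }, numeric(length(x_grid)))
  if (length(x_grid) == 1) mat <- matrix(mat, nrow = 1)
  list(x = x_grid, mean = rowMeans(mat),
       lo = apply(mat, 1, quantile, 0.025),
       hi = apply(mat, 1, quantile, 0.975))
}

#' Expected total IBD for kth-degree cousins
#'
#' Closed form `2 G (1/2)^(2(k+1))` with `G` the diploid autosomal genome
#' size in cM: siblings (k = 0) share half the diploid genome, and each
#' additional degree divides the expectation by 4.
#'
#' @param k cousin degree (integer >= 0, vectorised).
#' @param G diploid autosomal genome size in cM (default 6,782).
#' @return expected total IBD in cM.
#' @export
cousin_expectation <- function(k, G = 6782.0) {
  if (any(k < 0)) stop("cousin degree k must be >= 0")
  2 * G * 0.5^(2 * (k + 1))
}

#' Putative cousin degree from total IBD sharing
#'
#' The smallest degree `k` whose expectation is at most the observed total
#' ("kth-degree cousin or closer"); a total exactly at an expectation is
#' assigned the closer degree. Totals below the `k_max` expectation are
#' unrelated at that resolution (`NA`).
#'
#' @param total_cM observed total IBD in cM (vectorised).
#' @param G diploid genome size in cM.
#' @param k_max deepest degree considered (default 10).
#' @return integer vector of degrees (`NA` = unrelated at `k_max`).
#' @export
classify_degree <- function(total_cM, G = 6782.0, k_max = 10) {
  if (any(total_cM < 0)) stop("total_cM must be >= 0")
  message("note: cousin-degree expectations assume a random-mating ",
          "population; founder events inflate sharing and these degrees ",
          "should be interpreted with caution")
  exps <- cousin_expectation(0:k_max, G)
  vapply(total_cM, function(tot) {
    k <- which(exps <= tot)
    if (length(k) == 0) NA_integer_ else as.integer(k[1] - 1)
  }, integer(1))
}
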