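# Minimal VCF 4.2 text writer for simulated phased cohorts. REF is the
# ancestral allele by construction (AA INFO tag set accordingly).
.write_vcf <- function(path, chroms, sites_df, gt_mat, sample_names) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=archscan-simgen",
    sprintf("##contig=<ID=%s,length=%d>", chroms$chrom,
            as.integer(chroms$length)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele (equals REF by simulation convention)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAA=%s\tGT", sites_df$chrom,
                  as.integer(sites_df$pos) + 1L, sites_df$ref, sites_df$alt,
                  sites_df$ref)
  if (length(sample_names) > 0) {
    body <- paste(body, apply(gt_mat, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
}

# carrier list (per haplotype, site-row ids) -> per-variant phased GT matrix
.gt_matrix <- function(uniq_index, n_uniq, hap_sites) {
  n_ind <- length(hap_sites) / 2
  gt <- matrix("0|0", n_uniq, n_ind)
  for (i in seq_len(n_ind)) {
    c1 <- logical(n_uniq); c2 <- logical(n_uniq)
    c1[uniq_index[hap_sites[[2 * i - 1]]]] <- TRUE
    c2[uniq_index[hap_sites[[2 * i]]]] <- TRUE
    gt[, i] <- paste0(as.integer(c1), "|", as.integer(c2))
  }
  gt
}

#' Write a simulated cohort to disk
#'
#' Writes `test.vcf`, `outgroup.vcf`, one `archaic_<genome>.vcf` per
#' reference genome, `callable.bed`, `centromeres.bed` and the truth tracts
#' under `truth/`. All coordinates follow the standard conventions (VCF
#' 1-based, BED 0-based half-open); genotypes are phased (`0|1`).
#'
#' @param cohort an `arch_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "arch_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sites <- cohort$sites
  key <- paste(sites$chrom, sites$pos, sep = ":")
  uniq <- !duplicated(key)
  uniq_rows <- which(uniq)
  uniq_index <- match(key, key[uniq])          # site row -> variant index
  ord <- order(match(sites$chrom[uniq_rows], cohort$chroms$chrom),
               sites$pos[uniq_rows])
  uniq_rows <- uniq_rows[ord]
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  uniq_index <- rank[uniq_index]               # in coordinate order
  usites <- sites[uniq_rows, ]
  n_uniq <- length(uniq_rows)

  inds <- sprintf("ind%03d", seq_len(cohort$params$n_test_individuals))
  gt <- .gt_matrix(uniq_index, n_uniq, cohort$hap_sites)
  .write_vcf(file.path(dir, "test.vcf"), cohort$chroms, usites, gt, inds)

  # outgroup panel: restrict to sites any outgroup haplotype carries
  og_rows <- sort(unique(unlist(cohort$outgroup_sites)))
  og_var <- sort(unique(uniq_index[og_rows]))
  pos_map <- match(seq_len(n_uniq), og_var)    # variant idx -> og row
  ogs <- sprintf("og%03d", seq_len(cohort$params$n_outgroup))
  og_lists <- lapply(cohort$outgroup_sites, function(ids) {
    as.integer(stats::na.omit(pos_map[uniq_index[ids]]))
  })
  gt_og <- .gt_matrix(seq_along(og_var), length(og_var), og_lists)
  .write_vcf(file.path(dir, "outgroup.vcf"), cohort$chroms,
             usites[og_var, ], gt_og, ogs)

  for (g in names(cohort$archaic)) {
    a <- cohort$archaic[[g]]
    v <- sort(unique(uniq_index[a$site]))
    carr <- a$carries[match(v, uniq_index[a$site])]
    gt_a <- matrix(ifelse(is.na(carr), "./.",
                          ifelse(carr == 1L, "1|1", "0|0")),
                   ncol = 1)
    .write_vcf(file.path(dir, paste0("archaic_", g, ".vcf")), cohort$chroms,
               usites[v, ], gt_a, g)
  }

  .write_bed(cohort$masks$callable, file.path(dir, "callable.bed"))
  .write_bed(cohort$masks$centromeres, file.path(dir, "centromeres.bed"))
  write_truth(cohort$truth, file.path(dir, "truth"))
  invisible(dir)
}

#' Write observation tracks as TSV files
#'
#' One file per haplotype with columns chrom, window_start, obs,
#' callable_bp, weight (tab-separated, deterministic row order).
#'
#' @param tracks named list of observation tracks.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_tracks <- function(tracks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(names(tracks), function(h) {
    f <- file.path(dir, paste0(h, ".obs.tsv"))
    tr <- tracks[[h]]
    df <- data.frame(chrom = tr$chrom, window_start = tr$start,
                     obs = tr$obs, callable_bp = tr$callable,
                     weight = sprintf("%.6g", tr$weight))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }, character(1))
  invisible(files)
}

#' Read observation tracks written by [write_tracks()]
#'
#' @param dir directory of `*.obs.tsv` files.
#' @param window_size window size used when the tracks were built.
#' @return named list of observation tracks.
#' @export
read_tracks <- function(dir, window_size = 1000) {
  files <- sort(list.files(dir, pattern = "\\.obs\\.tsv$",
                           full.names = TRUE))
  out <- lapply(files, function(f) {
    df <- utils::read.table(f, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    tr <- data.frame(chrom = df$chrom, start = df$window_start,
                     obs = df$obs, callable = df$callable_bp,
                     weight = as.numeric(df$weight))
    attr(tr, "hap") <- sub("\\.obs\\.tsv$", "", basename(f))
    attr(tr, "window_size") <- window_size
    tr
  })
  names(out) <- sub("\\.obs\\.tsv$", "", basename(files))
  out
}

#' Write a segment table as TSV
#'
#' @param segments segment table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_segments <- function(segments, path) {
  df <- segments
  if ("mean_posterior" %in% names(df)) {
    df$mean_posterior <- sprintf("%.6f", df$mean_posterior)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
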