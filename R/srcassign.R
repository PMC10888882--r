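#' Archaic reference panel
#'
#' Per archaic genome, whether it carries the derived allele at each site.
#' Missing genotypes are explicit (`NA`). Sites absent from the panel table
#' are treated as missing for that genome.
#'
#' @param x either an `arch_cohort` (the simulated archaic references are
#'   used), a data.frame site table with columns chrom, pos (0-based), alt,
#'   genome, carries (0/1/NA), or a named character vector of VCF paths
#'   (one single-sample VCF per genome).
#' @param clades named character vector mapping genome name to clade
#'   (`"Neanderthal"` or `"Denisovan"`). Defaults cover the four published
#'   high-coverage genomes and the simulated panel names.
#' @return an object of class `archaic_panel`: list with `table` (long site
#'   table keyed chrom:pos:alt), `genomes`, `clades`.
#' @export
archaic_panel <- function(x, clades = NULL) {
  if (inherits(x, "arch_cohort")) {
    tab <- do.call(rbind, lapply(names(x$archaic), function(g) {
      a <- x$archaic[[g]]
      data.frame(genome = g, chrom = x$sites$chrom[a$site],
                 pos = x$sites$pos[a$site], alt = x$sites$alt[a$site],
                 carries = a$carries)
    }))
  } else if (is.data.frame(x)) {
    tab <- x[, c("genome", "chrom", "pos", "alt", "carries")]
  } else {
    tab <- do.call(rbind, lapply(names(x), function(g) {
      v <- .read_phased_vcf(x[[g]], allow_unphased = TRUE)
      carries <- if (ncol(v$gt) >= 2) {
        as.integer(pmax(v$gt[, 1], v$gt[, 2], na.rm = TRUE))
      } else if (ncol(v$gt) == 1) {
        as.integer(v$gt[, 1])
      } else {
        rep(NA_integer_, nrow(v$sites))
      }
      data.frame(genome = g, chrom = v$sites$chrom, pos = v$sites$pos,
                 alt = v$sites$alt, carries = carries)
    }))
  }
  genomes <- unique(tab$genome)
  if (is.null(clades)) {
    known <- c(AltaiNea = "Neanderthal", Chagyrskaya = "Neanderthal",
               Vindija = "Neanderthal", AltaiDen = "Denisovan")
    clades <- known[genomes]
    names(clades) <- genomes
    clades[is.na(clades)] <- "Neanderthal"
  }
  tab$key <- .site_key(tab$chrom, tab$pos, tab$alt)
  structure(list(table = tab, genomes = genomes, clades = clades),
            class = "archaic_panel")
}

#' DAV match rates of called segments against archaic reference genomes
#'
#' Derived archaic variants (DAVs) are the private derived variants falling
#' inside a called segment. For each archaic genome, the match rate is the
#' fraction of DAVs with a non-missing genotype (informative sites) at
#' which the genome carries the derived allele. Rates are `NA` (flagged)
#' when a segment has no informative site for a genome.
#'
#' @param segments segment table from [call_segments()].
#' @param hap_variants named list (by haplotype) of data.frames chrom, pos,
#'   alt giving the derived alleles each haplotype carries.
#' @param outgroup an `outgroup_set`; variants present in it are not DAVs.
#' @param panel an [archaic_panel()].
#' @return a match-profile data.frame: one row per segment x genome with
#'   segment_id, hap, chrom, start, end, genome, n_dav, n_informative,
#'   n_shared, rate.
#' @export
match_rates <- function(segments, hap_variants, outgroup, panel) {
  stopifnot(inherits(panel, "archaic_panel"))
  if (nrow(segments) == 0) {
    return(data.frame(segment_id = integer(), hap = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), genome = character(),
                      n_dav = integer(), n_informative = integer(),
                      n_shared = integer(), rate = numeric()))
  }
  ptab <- panel$table
  out <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    v <- hap_variants[[seg$hap]]
    dav <- v[v$chrom == seg$chrom & v$pos >= seg$start & v$pos < seg$end, ,
             drop = FALSE]
    if (nrow(dav) > 0) {
      keys <- .site_key(dav$chrom, dav$pos, dav$alt)
      keys <- keys[!(keys %in% outgroup$keys)]
    } else {
      keys <- character(0)
    }
    out[[i]] <- do.call(rbind, lapply(panel$genomes, function(g) {
      gt <- ptab[ptab$genome == g, ]
      carr <- gt$carries[match(keys, gt$key)]
      n_inf <- sum(!is.na(carr))
      n_sh <- sum(carr == 1L, na.rm = TRUE)
      data.frame(segment_id = i, hap = seg$hap, chrom = seg$chrom,
                 start = seg$start, end = seg$end, genome = g,
                 n_dav = length(keys), n_informative = n_inf,
                 n_shared = n_sh,
                 rate = if (n_inf > 0) n_sh / n_inf else NA_real_)
    }))
  }
  do.call(rbind, out)
}

#' Classify a segment's archaic source from its match profile
#'
#' A segment is Neanderthal if its best Neanderthal-genome rate reaches
#' `min_rate` and exceeds the best Denisovan rate by at least `margin`
#' (symmetrically for Denisovan); Ambiguous if both clades are high within
#' the margin; Unknown if all rates are below `min_rate` or too few
#' informative sites exist.
#'
#' @param profile match-profile rows for one or more segments
#'   ([match_rates()]).
#' @param panel the [archaic_panel()] (for the genome-to-clade map).
#' @param min_informative minimum informative DAVs for a clade's rate to
#'   count (default 5).
#' @param min_rate minimum match rate (default 0.3).
#' @param margin rate margin separating the clades (default 0.1).
#' @return data.frame segment_id, hap, chrom, start, end, rate_nea,
#'   rate_den, source_label in
#'   `c("Neanderthal","Denisovan","Ambiguous","Unknown")`.
#' @export
classify_source <- function(profile, panel, min_informative = 5,
                            min_rate = 0.3, margin = 0.1) {
  best <- function(rows) {
    ok <- rows$n_informative >= min_informative & !is.na(rows$rate)
    if (!any(ok)) return(NA_real_)
    max(rows$rate[ok])
  }
  ids <- unique(profile$segment_id)
  out <- lapply(ids, function(id) {
    rows <- profile[profile$segment_id == id, ]
    rn <- best(rows[panel$clades[rows$genome] == "Neanderthal", ])
    rd <- best(rows[panel$clades[rows$genome] == "Denisovan", ])
    nea_hi <- !is.na(rn) && rn >= min_rate
    den_hi <- !is.na(rd) && rd >= min_rate
    lab <- if (nea_hi && (!den_hi || rn - rd >= margin)) {
      "Neanderthal"
    } else if (den_hi && (!nea_hi || rd - rn >= margin)) {
      "Denisovan"
    } else if (nea_hi && den_hi) {
      "Ambiguous"
    } else {
      "Unknown"
    }
    data.frame(segment_id = id, hap = rows$hap[1], chrom = rows$chrom[1],
               start = rows$start[1], end = rows$end[1],
               rate_nea = rn, rate_den = rd, source_label = lab)
  })
  do.call(rbind, out)
}

#' Stringent source assignment from clade-diagnostic sites
#'
#' Uses only sites where exactly one clade carries the derived allele
#' (every genome of the other clade has an observed ancestral genotype);
#' the segment is assigned by majority vote among its diagnostic matches,
#' requiring at least `min_sites` of them, otherwise Unknown.
#'
#' @param segments segment table.
#' @param hap_variants,outgroup,panel as in [match_rates()].
#' @param min_sites minimum diagnostic matches (default 3).
#' @return data.frame segment_id, n_nea_diag, n_den_diag, source_label.
#' @export
diagnostic_assignment <- function(segments, hap_variants, outgroup, panel,
                                  min_sites = 3) {
  ptab <- panel$table
  # clade-diagnostic status per panel site
  by_key <- split(ptab[, c("genome", "carries")], ptab$key)
  diag_of <- vapply(by_key, function(d) {
    cl <- panel$clades[d$genome]
    nea <- d$carries[cl == "Neanderthal"]
    den <- d$carries[cl == "Denisovan"]
    nea_car <- any(nea == 1L, na.rm = TRUE)
    den_car <- any(den == 1L, na.rm = TRUE)
    nea_anc <- length(nea) > 0 && all(!is.na(nea)) && all(nea == 0L)
    den_anc <- length(den) > 0 && all(!is.na(den)) && all(den == 0L)
    if (nea_car && den_anc) "Neanderthal"
    else if (den_car && nea_anc) "Denisovan"
    else "none"
  }, character(1))
  out <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    v <- hap_variants[[seg$hap]]
    dav <- v[v$chrom == seg$chrom & v$pos >= seg$start & v$pos < seg$end, ,
             drop = FALSE]
    keys <- .site_key(dav$chrom, dav$pos, dav$alt)
    keys <- keys[!(keys %in% outgroup$keys)]
    d <- diag_of[match(keys, names(diag_of))]
    n_nea <- sum(d == "Neanderthal", na.rm = TRUE)
    n_den <- sum(d == "Denisovan", na.rm = TRUE)
    lab <- if (n_nea + n_den >= min_sites && n_nea > n_den) "Neanderthal"
    else if (n_nea + n_den >= min_sites && n_den > n_nea) "Denisovan"
    else "Unknown"
    data.frame(segment_id = i, n_nea_diag = n_nea, n_den_diag = n_den,
               source_label = lab)
  })
  do.call(rbind, out)
}

#' One- vs two-pulse clustering of segment match rates
#'
#' Fits 1- and 2-component Gaussian mixtures to per-segment match rates
#' against a reference genome and chooses the model by BIC. Two clusters of
#' match rates indicate two introgressing source populations at different
#' divergence from the sequenced reference.
#'
#' @param rates numeric vector of per-segment match rates.
#' @param k_max maximum number of components (default 2).
#' @param var_floor variance floor; rate sets with total variance below it
#'   are reported as a single cluster without fitting (default 1e-4).
#' @return list with `k` (chosen number of clusters), `means`, `weights`,
#'   `sd`, `bic` (per candidate k).
#' @export
pulse_clustering <- function(rates, k_max = 2, var_floor = 1e-4) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < 10) {
    stop("too few match-rate profiles for mixture fitting (need >= 10)")
  }
  if (stats::var(rates) < var_floor) {
    return(list(k = 1L, means = mean(rates), weights = 1,
                sd = stats::sd(rates), bic = NA_real_))
  }
  bic <- mclust::mclustBIC(rates, G = 1:k_max, modelNames = c("E", "V"),
                           verbose = FALSE)
  fit <- mclust::Mclust(rates, x = bic, verbose = FALSE)
  ord <- order(fit$parameters$mean, decreasing = TRUE)
  list(k = as.integer(fit$G),
       means = as.numeric(fit$parameters$mean)[ord],
       weights = as.numeric(fit$parameters$pro)[ord],
       sd = sqrt(as.numeric(fit$parameters$variance$sigmasq))[
         if (length(fit$parameters$variance$sigmasq) > 1) ord else 1],
       bic = fit$BIC)
}
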