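#' Simulation parameters for a synthetic phased cohort
#'
#' Defines the demographic and mutational model used by [simulate_cohort()].
#' Test haplotypes carry archaic introgressed tracts laid down by a two-state
#' Markov renewal process: tract lengths are Exponential with mean
#' `1/(recomb_rate * admix_time_gens * (1 - admix_prop))` bp and tract starts
#' occur so that the expected archaic fraction equals `admix_prop`. Outside
#' tracts, private derived variants (absent from the outgroup) arise as a
#' Poisson process with per-bp rate `mut_rate_yr * human_coal_time_yr`;
#' inside tracts the rate is `mut_rate_yr * archaic_coal_time_yr`. Each tract
#' variant is carried by archaic reference genome `r` with probability
#' `dav_share[[source]][[r]]`.
#'
#' @param n_test_individuals number of diploid test individuals.
#' @param n_outgroup number of diploid outgroup individuals (carry no archaic
#'   ancestry by construction).
#' @param chrom_lengths_bp numeric vector of chromosome lengths in bp.
#' @param recomb_rate per-bp per-generation recombination rate.
#' @param admix_time_gens generations since the archaic admixture pulse.
#' @param admix_prop introgressed genome fraction `p` in `[0, 1]`.
#' @param archaic_coal_time_yr coalescence depth (years) of the archaic
#'   lineage; sets the private-variant density inside tracts.
#' @param human_coal_time_yr minimum coalescence (years) of test vs outgroup;
#'   sets the private-variant density outside tracts.
#' @param mut_rate_yr mutation rate per bp per year (default `0.45e-9`).
#' @param n_sources number of archaic sources (1 or 2).
#' @param dav_share list (one element per source) of named vectors giving,
#'   per archaic reference genome, the probability that a tract variant is
#'   carried by that genome. Defaults emulate a Neanderthal-like source that
#'   shares most derived variants with three Neanderthal references and few
#'   with the Denisovan; with `n_sources = 2`, a Denisovan-close (0.84) and a
#'   Denisovan-distant (0.47) source.
#' @param shared_site_rate per-bp rate of outgroup-shared polymorphic sites.
#' @param multiallelic_thinning probability an emitted variant is removed,
#'   emulating multi-allelic site filtering.
#' @param phase_switch_rate per-site probability that the two haplotypes of
#'   an individual swap from that site onwards (phasing switch error).
#' @param phase_dropout_rate probability a private variant is lost during
#'   phasing (used by the coalescence-clock corrections).
#' @param arch_missing_rate probability an archaic reference genotype is
#'   missing at a tract site.
#' @param early_wave_prop fraction of the non-archaic genome coalescing at
#'   `early_wave_T_yr` instead of `human_coal_time_yr` (an earlier
#'   out-of-Africa wave); 0 disables.
#' @param early_wave_T_yr coalescence time (years) of the earlier wave.
#' @param early_wave_time_gens generations used for earlier-wave block
#'   lengths.
#' @param centromere_bp centromere gap length per chromosome (masked from
#'   the callable genome).
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_test_individuals = 50,
                       n_outgroup = 30,
                       chrom_lengths_bp = rep(50e6, 4),
                       recomb_rate = 1e-8,
                       admix_time_gens = 1500,
                       admix_prop = 0.02,
                       archaic_coal_time_yr = 648000,
                       human_coal_time_yr = 54000,
                       mut_rate_yr = 0.45e-9,
                       n_sources = 1,
                       dav_share = NULL,
                       shared_site_rate = 1e-4,
                       multiallelic_thinning = 0,
                       phase_switch_rate = 0,
                       phase_dropout_rate = 0,
                       arch_missing_rate = 0.05,
                       early_wave_prop = 0,
                       early_wave_T_yr = 74000,
                       early_wave_time_gens = 800,
                       centromere_bp = 1e6,
                       seed = 1) {
  if (length(chrom_lengths_bp) == 0) {
    stop("chrom_lengths_bp must contain at least one chromosome")
  }
  if (any(chrom_lengths_bp <= 0)) stop("chromosome lengths must be > 0")
  if (admix_prop < 0 || admix_prop > 1) stop("admix_prop must be in [0, 1]")
  if (admix_prop > 0 && admix_time_gens <= 0) {
    stop("admix_prop > 0 with admix_time_gens = 0: tract length undefined")
  }
  if (archaic_coal_time_yr <= human_coal_time_yr || human_coal_time_yr <= 0) {
    stop("need archaic_coal_time_yr > human_coal_time_yr > 0")
  }
  if (any(c(recomb_rate, mut_rate_yr, shared_site_rate) < 0)) {
    stop("rates must be >= 0")
  }
  if (!n_sources %in% c(1, 2)) stop("n_sources must be 1 or 2")
  if (is.null(dav_share)) {
    dav_share <- if (n_sources == 1) {
      list(c(AltaiNea = 0.78, Chagyrskaya = 0.80, Vindija = 0.83,
             AltaiDen = 0.10))
    } else {
      list(c(AltaiDen = 0.84, Vindija = 0.05),
           c(AltaiDen = 0.47, Vindija = 0.05))
    }
  }
  if (length(dav_share) != n_sources) {
    stop("dav_share must have one element per source")
  }
  if (any(unlist(dav_share) < 0 | unlist(dav_share) > 1)) {
    stop("dav_share values must be in [0, 1]")
  }
  for (frac in c(multiallelic_thinning, phase_switch_rate, phase_dropout_rate,
                 arch_missing_rate, early_wave_prop)) {
    if (frac < 0 || frac >= 1) stop("probability parameters must be in [0, 1)")
  }
  p <- list(
    n_test_individuals = as.integer(n_test_individuals),
    n_outgroup = as.integer(n_outgroup),
    chrom_lengths_bp = as.numeric(chrom_lengths_bp),
    recomb_rate = recomb_rate, admix_time_gens = admix_time_gens,
    admix_prop = admix_prop, archaic_coal_time_yr = archaic_coal_time_yr,
    human_coal_time_yr = human_coal_time_yr, mut_rate_yr = mut_rate_yr,
    n_sources = as.integer(n_sources), dav_share = dav_share,
    shared_site_rate = shared_site_rate,
    multiallelic_thinning = multiallelic_thinning,
    phase_switch_rate = phase_switch_rate,
    phase_dropout_rate = phase_dropout_rate,
    arch_missing_rate = arch_missing_rate,
    early_wave_prop = early_wave_prop, early_wave_T_yr = early_wave_T_yr,
    early_wave_time_gens = early_wave_time_gens,
    centromere_bp = centromere_bp, seed = as.integer(seed)
  )
  structure(p, class = "sim_params")
}

# alternating exponential renewal process on [0, L); returns matrix of
# (start, end) for the "on" state with stationary on-fraction frac and mean
# on-length mean_len
.sim_renewal <- function(L, mean_len, frac) {
  if (frac <= 0) return(matrix(numeric(0), ncol = 2))
  mean_gap <- mean_len * (1 - frac) / frac
  pos <- 0
  on <- runif(1) < frac
  starts <- numeric(0); ends <- numeric(0)
  # stationary start: first segment length-biased residual ~ Exp (memoryless)
  while (pos < L) {
    len <- rexp(1, 1 / if (on) mean_len else mean_gap)
    if (on) {
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + len, L))
    }
    pos <- pos + len
    on <- !on
  }
  cbind(starts, ends)
}

# Poisson variant positions on piecewise-constant rate intervals.
# intervals: matrix (start, end); returns sorted integer positions
.sim_positions <- function(intervals, rate) {
  if (nrow(intervals) == 0 || rate <= 0) return(numeric(0))
  lens <- intervals[, 2] - intervals[, 1]
  n <- rpois(length(lens), lens * rate)
  if (sum(n) == 0) return(numeric(0))
  idx <- rep(seq_along(lens), n)
  sort(floor(intervals[idx, 1] + runif(sum(n)) * lens[idx]))
}

# complement of 'on' intervals within [0, L)
.interval_complement <- function(iv, L) {
  if (nrow(iv) == 0) return(matrix(c(0, L), ncol = 2))
  bounds <- c(0, t(iv), L)
  out <- matrix(bounds, ncol = 2, byrow = TRUE)
  out[out[, 2] - out[, 1] > 0, , drop = FALSE]
}

#' Simulate a phased synthetic cohort with known introgressed tracts
#'
#' Generates phased test individuals carrying archaic tracts, an outgroup
#' panel free of archaic ancestry, archaic reference genotypes at tract
#' sites, callability/centromere masks, and a machine-readable truth set.
#' See [sim_params()] for the generative model. Deterministic given the seed.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `arch_cohort`: a list with elements `params`,
#'   `chroms` (name/length table), `sites` (one row per emitted variant:
#'   chrom, pos (0-based), ref, alt, origin in
#'   `c("private","tract","early","shared")`, source, freq), `hap_sites`
#'   (named list per test haplotype of row indices into `sites`),
#'   `outgroup_sites` (same, per outgroup haplotype; shared sites only),
#'   `archaic` (named list per reference genome: data.frame site, carries),
#'   `truth` (tracts, per-individual realized fractions, site labels),
#'   `masks` (callable and centromere intervals, 0-based half-open) and
#'   `meta` (loss fractions for the clock corrections).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- params
  nchrom <- length(p$chrom_lengths_bp)
  chroms <- data.frame(chrom = paste0("chr", seq_len(nchrom)),
                       length = p$chrom_lengths_bp)

  # masks: everything callable except a centromere gap mid-chromosome
  cen_len <- pmin(p$centromere_bp, chroms$length * 0.1)
  cen <- data.frame(chrom = chroms$chrom,
                    start = floor(chroms$length / 2 - cen_len / 2),
                    end = floor(chroms$length / 2 + cen_len / 2))
  callable <- do.call(rbind, lapply(seq_len(nchrom), function(i) {
    data.frame(chrom = chroms$chrom[i],
               start = c(0, cen$end[i]),
               end = c(cen$start[i], chroms$length[i]))
  }))

  r_h <- p$mut_rate_yr * p$human_coal_time_yr
  r_a <- p$mut_rate_yr * p$archaic_coal_time_yr
  r_e <- p$mut_rate_yr * p$early_wave_T_yr
  tract_mean <- if (p$admix_prop > 0) {
    1 / (p$recomb_rate * p$admix_time_gens * (1 - p$admix_prop))
  } else {
    Inf
  }
  early_mean <- 1 / (p$recomb_rate * p$early_wave_time_gens)

  haps <- paste0(rep(sprintf("ind%03d", seq_len(p$n_test_individuals)),
                     each = 2), "_h", 1:2)

  sites_list <- list()
  hap_sites <- setNames(vector("list", length(haps)), haps)
  tracts_list <- list()
  n_dropout_lost <- 0; n_true_private <- 0

  for (h in seq_along(haps)) {
    hs <- list()
    for (ci in seq_len(nchrom)) {
      L <- chroms$length[ci]
      tr <- .sim_renewal(L, tract_mean, p$admix_prop)
      if (nrow(tr) > 0) {
        tracts_list[[length(tracts_list) + 1]] <- data.frame(
          hap = haps[h], chrom = chroms$chrom[ci],
          start = tr[, 1], end = tr[, 2],
          source = sample.int(p$n_sources, nrow(tr), replace = TRUE)
        )
      }
      nontract <- .interval_complement(tr, L)
      # earlier-wave blocks live on the non-archaic background
      ew <- if (p$early_wave_prop > 0) {
        ewall <- .sim_renewal(L, early_mean, p$early_wave_prop)
        .intersect_intervals(ewall, nontract)
      } else {
        matrix(numeric(0), ncol = 2)
      }
      human <- if (nrow(ew) > 0) .subtract_intervals(nontract, ew) else nontract
      pos_h <- .sim_positions(human, r_h)
      pos_e <- .sim_positions(ew, r_e)
      pos_a <- .sim_positions(tr, r_a)
      if (length(pos_h) + length(pos_e) + length(pos_a) > 0) {
        src <- integer(length(pos_a))
        if (length(pos_a) > 0 && nrow(tr) > 0) {
          ti <- findInterval(pos_a, tr[, 1])
          src <- tracts_list[[length(tracts_list)]]$source[ti]
        }
        hs[[ci]] <- data.frame(
          chrom = chroms$chrom[ci],
          pos = c(pos_h, pos_e, pos_a),
          origin = rep(c("private", "early", "tract"),
                       c(length(pos_h), length(pos_e), length(pos_a))),
          source = c(integer(length(pos_h)), integer(length(pos_e)), src)
        )
      }
    }
    hdf <- do.call(rbind, hs)
    if (!is.null(hdf) && nrow(hdf) > 0) {
      n_true_private <- n_true_private + nrow(hdf)
      # multi-allelic thinning then phasing drop-out, both recorded in meta
      keep <- runif(nrow(hdf)) >= p$multiallelic_thinning
      hdf <- hdf[keep, , drop = FALSE]
      drop2 <- runif(nrow(hdf)) < p$phase_dropout_rate
      n_dropout_lost <- n_dropout_lost + sum(drop2)
      hdf <- hdf[!drop2, , drop = FALSE]
      if (nrow(hdf) > 0) {
        hdf$hap <- haps[h]
        sites_list[[length(sites_list) + 1]] <- hdf
      }
    }
  }

  priv <- if (length(sites_list)) do.call(rbind, sites_list) else
    data.frame(chrom = character(), pos = numeric(), origin = character(),
               source = integer(), hap = character())

  # outgroup-shared polymorphism, present in the outgroup panel by
  # construction (each site has >= 1 outgroup carrier)
  genome_bp <- sum(chroms$length)
  n_shared <- rpois(1, genome_bp * p$shared_site_rate)
  og_haps <- if (p$n_outgroup > 0) {
    paste0(rep(sprintf("og%03d", seq_len(p$n_outgroup)), each = 2),
           "_h", 1:2)
  } else {
    character(0)
  }
  shared <- data.frame(chrom = character(0), pos = numeric(0),
                       freq = numeric(0))
  og_sites <- setNames(vector("list", length(og_haps)), og_haps)
  shared_carrier <- NULL
  if (n_shared > 0) {
    gpos <- floor(runif(n_shared) * genome_bp)
    cum <- c(0, cumsum(chroms$length))
    ci <- findInterval(gpos, cum, rightmost.closed = TRUE)
    shared <- data.frame(chrom = chroms$chrom[ci], pos = gpos - cum[ci],
                         freq = runif(n_shared, 0.1, 0.9))
    keep <- runif(n_shared) >= p$multiallelic_thinning
    # shared sites never reuse a private/tract position (or each other's),
    # so outgroup membership stays exact with respect to the truth labels
    keep <- keep & !duplicated(paste(shared$chrom, shared$pos)) &
      !(paste(shared$chrom, shared$pos) %in% paste(priv$chrom, priv$pos))
    shared <- shared[keep, , drop = FALSE]
    n_shared <- nrow(shared)
    og_mat <- matrix(rbinom(n_shared * length(og_haps), 1,
                            rep(shared$freq, length(og_haps))),
                     nrow = n_shared)
    none <- length(og_haps) > 0 & rowSums(og_mat) == 0
    if (any(none)) {
      og_mat[cbind(which(none),
                   sample.int(length(og_haps), sum(none), replace = TRUE))] <- 1L
    }
    shared_carrier <- matrix(rbinom(n_shared * length(haps), 1,
                                    rep(shared$freq, length(haps))),
                             nrow = n_shared)
  }

  # assemble the global site table; row index is the site id
  ns_priv <- nrow(priv)
  sites <- data.frame(
    chrom = c(priv$chrom, shared$chrom),
    pos = c(priv$pos, shared$pos),
    origin = c(priv$origin, rep("shared", n_shared)),
    source = c(priv$source, integer(n_shared)),
    freq = c(rep(NA_real_, ns_priv), shared$freq)
  )
  # alleles are a deterministic function of position (REF = ancestral)
  bases <- c("A", "C", "G", "T")
  ri <- (sites$pos %% 4) + 1
  sites$ref <- bases[ri]
  sites$alt <- bases[(ri + (sites$pos %/% 4) %% 3) %% 4 + 1]

  for (h in seq_along(haps)) {
    own <- which(priv$hap == haps[h])
    sh <- if (n_shared > 0) ns_priv + which(shared_carrier[, h] == 1L) else
      integer(0)
    hap_sites[[h]] <- sort(c(own, sh))
  }
  if (n_shared > 0) {
    for (g in seq_along(og_haps)) {
      og_sites[[g]] <- ns_priv + which(og_mat[, g] == 1L)
    }
  }

  # archaic reference genotypes at tract sites
  genomes <- unique(unlist(lapply(p$dav_share, names)))
  tract_rows <- which(sites$origin == "tract")
  archaic <- setNames(lapply(genomes, function(g) {
    if (length(tract_rows) == 0) {
      return(data.frame(site = integer(0), carries = integer(0)))
    }
    share <- vapply(p$dav_share, function(s) {
      if (g %in% names(s)) s[[g]] else 0
    }, numeric(1))
    pr <- share[sites$source[tract_rows]]
    carries <- as.integer(rbinom(length(tract_rows), 1, pr))
    carries[runif(length(tract_rows)) < p$arch_missing_rate] <- NA_integer_
    data.frame(site = tract_rows, carries = carries)
  }), genomes)

  # phase switch errors applied last, per individual
  if (p$phase_switch_rate > 0) {
    for (i in seq_len(p$n_test_individuals)) {
      h1 <- 2 * i - 1; h2 <- 2 * i
      s1 <- hap_sites[[h1]]; s2 <- hap_sites[[h2]]
      allpos <- sort(unique(c(s1, s2)))
      if (length(allpos) < 2) next
      flips <- cumsum(runif(length(allpos)) < p$phase_switch_rate) %% 2 == 1
      swap <- allpos[flips]
      a1 <- union(setdiff(s1, swap), intersect(s2, swap))
      a2 <- union(setdiff(s2, swap), intersect(s1, swap))
      hap_sites[[h1]] <- sort(a1)
      hap_sites[[h2]] <- sort(a2)
    }
  }

  tracts <- if (length(tracts_list)) do.call(rbind, tracts_list) else
    data.frame(hap = character(), chrom = character(), start = numeric(),
               end = numeric(), source = integer())
  inds <- sprintf("ind%03d", seq_len(p$n_test_individuals))
  frac <- vapply(inds, function(id) {
    tr <- tracts[startsWith(tracts$hap, paste0(id, "_")), , drop = FALSE]
    sum(tr$end - tr$start) / (2 * genome_bp)
  }, numeric(1))

  structure(list(
    params = p, chroms = chroms, sites = sites, hap_sites = hap_sites,
    outgroup_sites = og_sites, archaic = archaic,
    truth = list(tracts = tracts, true_fraction = frac,
                 true_T_h = p$human_coal_time_yr, site_labels = sites$origin),
    masks = list(callable = callable, centromeres = cen),
    meta = list(
      multiallelic_removed = p$multiallelic_thinning,
      phasing_dropout = if (n_true_private > 0)
        n_dropout_lost / (n_true_private * (1 - p$multiallelic_thinning))
      else 0
    )
  ), class = "arch_cohort")
}

# intersection of two interval matrices (start, end)
.intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(numeric(0), ncol = 2))
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1]); e <- pmin(a[i, 2], b[, 2])
    keep <- e > s
    if (any(keep)) out[[length(out) + 1]] <- cbind(s[keep], e[keep])
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

# a minus b for interval matrices
.subtract_intervals <- function(a, b) {
  if (nrow(b) == 0) return(a)
  out <- list()
  for (i in seq_len(nrow(a))) {
    cur_s <- a[i, 1]; cur_e <- a[i, 2]
    ov <- b[b[, 2] > cur_s & b[, 1] < cur_e, , drop = FALSE]
    ov <- ov[order(ov[, 1]), , drop = FALSE]
    pos <- cur_s
    for (j in seq_len(nrow(ov))) {
      if (ov[j, 1] > pos) out[[length(out) + 1]] <- c(pos, ov[j, 1])
      pos <- max(pos, ov[j, 2])
    }
    if (pos < cur_e) out[[length(out) + 1]] <- c(pos, cur_e)
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 2))
  matrix(unlist(out), ncol = 2, byrow = TRUE)
}

#' Parameters for pedigree cousin-pair simulation
#'
#' @param k cousin degree (0 = siblings, 1 = first cousins, ...).
#' @param n_pairs number of independent cousin pairs to simulate.
#' @param genetic_map named numeric vector of per-chromosome genetic lengths
#'   in cM (haploid map). The diploid autosomal genome size used by the
#'   closed-form expectation is `G = 2 * sum(genetic_map)`. Default: a
#'   22-chromosome human-like map scaled so that `G = 6782` cM.
#' @param bp_per_cM physical scale used to report segment bp coordinates.
#' @param seed integer seed.
#' @return an object of class `pedigree_sim_params`.
#' @export
pedigree_sim_params <- function(k, n_pairs, genetic_map = NULL,
                                bp_per_cM = 1e6, seed = 1) {
  if (k < 0) stop("cousin degree k must be >= 0")
  if (is.null(genetic_map)) genetic_map <- default_genetic_map()
  if (sum(genetic_map) <= 0) stop("total genetic length G must be > 0")
  if (is.null(names(genetic_map))) {
    names(genetic_map) <- paste0("chr", seq_along(genetic_map))
  }
  structure(list(k = as.integer(k), n_pairs = as.integer(n_pairs),
                 genetic_map = genetic_map, bp_per_cM = bp_per_cM,
                 seed = as.integer(seed)),
            class = "pedigree_sim_params")
}

#' Human-like autosomal genetic map
#'
#' Per-chromosome cM lengths (haploid), proportional to the HapMap autosomal
#' map and scaled so the diploid total is `G` cM.
#'
#' @param G diploid autosomal genome size in cM (default 6,782).
#' @return named numeric vector of 22 chromosome lengths summing to `G / 2`.
#' @export
default_genetic_map <- function(G = 6782) {
  raw <- c(286, 269, 223, 214, 204, 192, 187, 168, 166, 181, 158, 175,
           126, 119, 141, 134, 128, 117, 108, 108, 62, 74)
  m <- raw / sum(raw) * G / 2
  setNames(m, paste0("chr", seq_along(raw)))
}

# one meiosis: recombine haplotypes A and B (each list(ends, labs) over
# [0, L] cM) with Poisson(L/100) crossovers at uniform positions (Haldane,
# no interference)
.meiosis <- function(A, B, L) {
  nx <- rpois(1, L / 100)
  cuts <- if (nx > 0) sort(runif(nx, 0, L)) else numeric(0)
  bounds <- c(0, cuts, L)
  first <- sample.int(2, 1)
  ends <- numeric(0); labs <- integer(0)
  par <- list(A, B)
  for (i in seq_len(length(bounds) - 1)) {
    src <- par[[(first + i) %% 2 + 1]]
    s <- bounds[i]; e <- bounds[i + 1]
    if (e <= s) next
    idx <- which(src$ends > s & c(0, head(src$ends, -1)) < e)
    seg_ends <- pmin(src$ends[idx], e)
    ends <- c(ends, seg_ends)
    labs <- c(labs, src$labs[idx])
  }
  # merge equal adjacent labels
  if (length(labs) > 1) {
    keep <- c(labs[-length(labs)] != labs[-1], TRUE)
    ends <- ends[keep]; labs <- labs[keep]
  }
  list(ends = ends, labs = labs)
}

# IBD intervals (label equality, label != 0) between two haplotypes
.hap_ibd <- function(h1, h2) {
  ends <- sort(unique(c(h1$ends, h2$ends)))
  starts <- c(0, head(ends, -1))
  mid <- (starts + ends) / 2
  l1 <- h1$labs[findInterval(mid, c(0, h1$ends), left.open = TRUE)]
  l2 <- h2$labs[findInterval(mid, c(0, h2$ends), left.open = TRUE)]
  same <- l1 == l2 & l1 != 0L
  if (!any(same)) return(matrix(numeric(0), ncol = 2))
  r <- rle(same)
  ce <- cumsum(r$lengths)
  cs <- c(0, head(ce, -1)) + 1
  on <- which(r$values)
  cbind(starts[cs[on]], ends[ce[on]])
}

#' Simulate IBD segments shared by kth-degree cousin pairs
#'
#' Gene-dropping through the pedigree connecting two kth-degree cousins to a
#' shared ancestral couple: each meiosis recombines the two parental
#' haplotypes with a Poisson crossover count (Haldane model, no
#' interference). IBD segments are the intervals where the two cousins
#' inherited the same ancestral-couple haplotype. The mean total IBD over
#' pairs converges to the closed form `2 * G * (1/2)^(2 * (k + 1))` with
#' `G` the diploid genome size in cM (see [cousin_expectation()]).
#'
#' @param params a [pedigree_sim_params()] object.
#' @return a data.frame in hap-IBD dialect: `id1, hap1, id2, hap2, chrom,
#'   start_bp, end_bp, length_cM`, one row per shared segment.
#' @export
simulate_cousin_pairs <- function(params) {
  stopifnot(inherits(params, "pedigree_sim_params"))
  set.seed(params$seed)
  k <- params$k
  map <- params$genetic_map
  acc <- list(id1 = list(), hap1 = list(), id2 = list(), hap2 = list(),
              chrom = list(), s = list(), e = list())
  for (pair in seq_len(params$n_pairs)) {
    id1 <- sprintf("pair%05d_a", pair); id2 <- sprintf("pair%05d_b", pair)
    for (ci in seq_along(map)) {
      L <- map[[ci]]
      founders <- lapply(1:4, function(l) list(ends = L, labs = l))
      cousins <- lapply(1:2, function(side) {
        cur <- list(.meiosis(founders[[1]], founders[[2]], L),
                    .meiosis(founders[[3]], founders[[4]], L))
        if (k > 0) {
          for (g in seq_len(k)) {
            gam <- .meiosis(cur[[1]], cur[[2]], L)
            cur <- list(gam, list(ends = L, labs = 0L))
          }
        }
        cur
      })
      for (a in 1:2) for (b in 1:2) {
        ib <- .hap_ibd(cousins[[1]][[a]], cousins[[2]][[b]])
        if (nrow(ib) > 0) {
          n <- length(acc$s) + 1
          acc$id1[[n]] <- rep(id1, nrow(ib))
          acc$hap1[[n]] <- rep(a, nrow(ib))
          acc$id2[[n]] <- rep(id2, nrow(ib))
          acc$hap2[[n]] <- rep(b, nrow(ib))
          acc$chrom[[n]] <- rep(names(map)[ci], nrow(ib))
          acc$s[[n]] <- ib[, 1]
          acc$e[[n]] <- ib[, 2]
        }
      }
    }
  }
  s <- unlist(acc$s); e <- unlist(acc$e)
  if (is.null(s)) s <- e <- numeric(0)
  data.frame(
    id1 = as.character(unlist(acc$id1)), hap1 = as.integer(unlist(acc$hap1)),
    id2 = as.character(unlist(acc$id2)), hap2 = as.integer(unlist(acc$hap2)),
    chrom = as.character(unlist(acc$chrom)),
    start_bp = round(s * params$bp_per_cM),
    end_bp = round(e * params$bp_per_cM),
    length_cM = e - s,
    stringsAsFactors = FALSE
  )
}

#' Write truth tracts as BED files
#'
#' One 0-based half-open BED file per haplotype plus one merged file per
#' individual; round-trips losslessly through [read_bed()].
#'
#' @param truth the `truth` element of an `arch_cohort` (or any data.frame
#'   with columns hap, chrom, start, end).
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_truth <- function(truth, dir) {
  tracts <- if (is.data.frame(truth)) truth else truth$tracts
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir)
  }
  files <- character(0)
  for (h in unique(tracts$hap)) {
    f <- file.path(dir, paste0(h, ".bed"))
    .write_bed(tracts[tracts$hap == h, c("chrom", "start", "end")], f)
    files <- c(files, f)
  }
  inds <- unique(sub("_h[12]$", "", tracts$hap))
  for (id in inds) {
    tr <- tracts[startsWith(tracts$hap, paste0(id, "_h")), , drop = FALSE]
    merged <- interval_union(tr[, c("chrom", "start", "end")])
    f <- file.path(dir, paste0(id, ".merged.bed"))
    .write_bed(merged, f)
    files <- c(files, f)
  }
  invisible(files)
}

.write_bed <- function(df, path) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d", df$chrom, as.integer(df$start),
                   as.integer(df$end))
  writeLines(lines, path)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED file path (first three columns used).
#' @return data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
             end = as.numeric(df[[3]]))
}
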