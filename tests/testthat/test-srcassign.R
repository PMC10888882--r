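# minimal panel: two Neanderthals, one Denisovan, explicit carriage table
make_panel <- function(tab) {
  archaic_panel(tab, clades = c(Vindija = "Neanderthal",
                                AltaiNea = "Neanderthal",
                                AltaiDen = "Denisovan"))
}

test_that("match rates count shared and informative DAVs correctly", {
  seg <- data.frame(hap = "i_h1", chrom = "chr1", start = 0, end = 10000)
  vars <- list(i_h1 = data.frame(chrom = "chr1",
                                 pos = c(100, 200, 300, 20000), alt = "G"))
  og <- toy_outgroup("chr1", 300, "G")   # one DAV removed by the outgroup
  tab <- expand.grid(genome = c("Vindija", "AltaiDen"),
                     pos = c(100, 200), stringsAsFactors = FALSE)
  tab$chrom <- "chr1"; tab$alt <- "G"
  tab$carries <- ifelse(tab$genome == "Vindija", 1L, 0L)
  prof <- match_rates(seg, vars, og, make_panel(tab))
  vin <- prof[prof$genome == "Vindija", ]
  den <- prof[prof$genome == "AltaiDen", ]
  expect_equal(vin$n_dav, 2)            # pos 300 outgroup, 20000 outside
  expect_equal(vin$n_informative, 2)
  expect_equal(vin$rate, 1.0)
  expect_equal(den$rate, 0.0)
  # genome with no coverage at the DAVs is uninformative, not zero
  alt <- make_panel(within(tab, carries[genome == "AltaiDen"] <- NA))
  prof2 <- match_rates(seg, vars, og, alt)
  expect_true(is.na(prof2$rate[prof2$genome == "AltaiDen"]))
  expect_equal(prof2$n_informative[prof2$genome == "AltaiDen"], 0)
})

test_that("segments with no DAVs get an all-undefined profile", {
  seg <- data.frame(hap = "i_h1", chrom = "chr1", start = 0, end = 1000)
  vars <- list(i_h1 = data.frame(chrom = character(), pos = numeric(),
                                 alt = character()))
  tab <- data.frame(genome = "Vindija", chrom = "chr1", pos = 5, alt = "G",
                    carries = 1L)
  prof <- match_rates(seg, vars, toy_outgroup(), make_panel(tab))
  expect_true(all(is.na(prof$rate)))
  lab <- classify_source(prof, make_panel(tab))
  expect_equal(lab$source_label, "Unknown")
})

test_that("classification thresholds and margins behave as documented", {
  panel <- make_panel(data.frame(genome = "Vindija", chrom = "chr1", pos = 5,
                                 alt = "G", carries = 1L))
  mk <- function(rates) {
    data.frame(segment_id = 1, hap = "h", chrom = "chr1", start = 0,
               end = 1000, genome = names(rates), n_dav = 20,
               n_informative = 20, n_shared = round(20 * unlist(rates)),
               rate = unlist(rates))
  }
  lab <- function(p) classify_source(p, panel)$source_label
  expect_equal(lab(mk(c(Vindija = 0.9, AltaiDen = 0.1))), "Neanderthal")
  expect_equal(lab(mk(c(Vindija = 0.1, AltaiDen = 0.9))), "Denisovan")
  expect_equal(lab(mk(c(Vindija = 0.05, AltaiDen = 0.05))), "Unknown")
  expect_equal(lab(mk(c(Vindija = 0.85, AltaiDen = 0.82))), "Ambiguous")
  # order of genomes must not matter
  p <- mk(c(Vindija = 0.9, AltaiNea = 0.7, AltaiDen = 0.2))
  expect_equal(lab(p), lab(p[c(3, 1, 2), ]))
  # too few informative sites -> Unknown
  p2 <- mk(c(Vindija = 1.0))
  p2$n_informative <- 3
  expect_equal(lab(p2), "Unknown")
})

test_that("diagnostic sites give a stringent majority-vote label", {
  # 10 Neanderthal-diagnostic sites, 0 Denisovan-diagnostic
  tab <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(genome = c("Vindija", "AltaiNea", "AltaiDen"), chrom = "chr1",
               pos = i * 10, alt = "G", carries = c(1L, 0L, 0L))
  }))
  panel <- make_panel(tab)
  seg <- data.frame(hap = "i_h1", chrom = "chr1", start = 0, end = 1000)
  vars <- list(i_h1 = data.frame(chrom = "chr1", pos = (1:10) * 10,
                                 alt = "G"))
  d <- diagnostic_assignment(seg, vars, toy_outgroup(), panel)
  expect_equal(d$source_label, "Neanderthal")
  expect_equal(d$n_nea_diag, 10)
  expect_equal(d$n_den_diag, 0)
  # no diagnostic coverage -> Unknown
  vars0 <- list(i_h1 = data.frame(chrom = "chr1", pos = 999, alt = "G"))
  expect_equal(diagnostic_assignment(seg, vars0, toy_outgroup(),
                                     panel)$source_label, "Unknown")
  # a site where the other clade is missing (not observed ancestral) is
  # not diagnostic
  tab_na <- within(tab, carries[genome == "AltaiDen"] <- NA)
  d_na <- diagnostic_assignment(seg, vars, toy_outgroup(), make_panel(tab_na))
  expect_equal(d_na$n_nea_diag, 0)
})

test_that("mixture model distinguishes one pulse from two", {
  set.seed(61)
  one <- pmin(pmax(rnorm(200, 0.84, 0.03), 0), 1)
  fit1 <- pulse_clustering(one)
  expect_equal(fit1$k, 1L)
  expect_lt(abs(fit1$means[1] - 0.84), 0.01)
  two <- c(pmin(rnorm(150, 0.84, 0.03), 1), pmax(rnorm(150, 0.47, 0.05), 0))
  fit2 <- pulse_clustering(two)
  expect_equal(fit2$k, 2L)
  expect_lt(abs(fit2$means[1] - 0.84), 0.03)
  expect_lt(abs(fit2$means[2] - 0.47), 0.03)
  # degenerate identical rates fall back to one cluster via variance floor
  flat <- pulse_clustering(rep(0.8, 60))
  expect_equal(flat$k, 1L)
  expect_error(pulse_clustering(c(0.5, 0.6)), "too few")
})

test_that("simulated tracts are assigned to their true source", {
  co <- memo("twosource_cohort", function() {
    simulate_cohort(sim_params(
      n_test_individuals = 6, n_outgroup = 5,
      chrom_lengths_bp = rep(20e6, 2), n_sources = 2,
      dav_share = list(
        c(AltaiNea = 0.78, Chagyrskaya = 0.80, Vindija = 0.83,
          AltaiDen = 0.10),
        c(AltaiNea = 0.08, Chagyrskaya = 0.08, Vindija = 0.08,
          AltaiDen = 0.84)),
      seed = 17))
  })
  og <- build_outgroup_set(co)
  panel <- archaic_panel(co)
  tr <- co$truth$tracts
  segs <- data.frame(hap = tr$hap, chrom = tr$chrom, start = tr$start,
                     end = tr$end)
  vars <- lapply(co$hap_sites, function(ids) {
    co$sites[ids, c("chrom", "pos", "alt")]
  })
  prof <- match_rates(segs, vars, og, panel)
  lab <- classify_source(prof, panel)
  truth_lab <- ifelse(tr$source == 1, "Neanderthal", "Denisovan")
  # evaluate segments with enough informative DAVs
  informative <- tapply(prof$n_informative, prof$segment_id, max) >= 10
  ok <- lab$source_label[informative] == truth_lab[informative]
  expect_gt(mean(ok), 0.95)
  # Denisovan-close source tracts share ~84% of DAVs with the reference
  den_rates <- prof$rate[prof$genome == "AltaiDen" &
                           prof$segment_id %in% which(tr$source == 2) &
                           prof$n_informative >= 10]
  expect_gt(length(den_rates), 20)
  expect_lt(abs(mean(den_rates) - 0.84), 0.03)
})
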