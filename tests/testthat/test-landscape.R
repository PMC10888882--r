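win10 <- function(n = 10, len = 1000) {
  w <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * len)
  attr(w, "window_size") <- len
  w
}

test_that("frequency track counts carrier haplotypes per window", {
  wins <- win10(10)
  roster <- paste0("i", 1:10, "_h1")
  empty <- frequency_track(
    data.frame(hap = character(), chrom = character(), start = numeric(),
               end = numeric()), roster, wins)
  expect_equal(empty$freq, rep(0, 10))
  one <- frequency_track(
    data.frame(hap = "i1_h1", chrom = "chr1", start = 0, end = 10000),
    roster, wins)
  expect_equal(one$freq, rep(0.1, 10))
  expect_equal(one$n_carriers, rep(1L, 10))
  expect_error(frequency_track(one, character(0), wins), "empty")
  # carrier count times the roster size is integral
  expect_true(all(abs(one$freq * 10 - round(one$freq * 10)) < 1e-12))
})

test_that("enrichment uses the mean + 2 sd threshold over windows", {
  n <- 10000
  wins <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000)
  attr(wins, "window_size") <- 1000
  tr <- structure(data.frame(chrom = wins$chrom, start = wins$start,
                             n_carriers = 0L, freq = 0),
                  n_haplotypes = 10, window_size = 1000)
  tr$freq[5000] <- 1.0
  out <- enriched_regions(tr)
  mu <- 1 / n; sig <- sd(tr$freq)
  expect_equal(attr(out, "threshold"), mu + 2 * sig)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(4999000, 5000000))
  # constant track: zero variance, warning and no calls
  tr0 <- tr; tr0$freq <- 0.3
  expect_warning(out0 <- enriched_regions(tr0), "zero variance")
  expect_equal(nrow(out0), 0)
})

test_that("a seeded high-frequency tract is recovered as enriched", {
  # background: 2% of 50 haplotypes carry scattered short segments;
  # positive control: 30% share one 100 kb tract
  set.seed(101)
  roster <- paste0("i", sprintf("%02d", 1:50), "_h1")
  bg <- do.call(rbind, lapply(roster, function(h) {
    n <- rpois(1, 4)
    if (n == 0) return(NULL)
    st <- floor(runif(n) * 9.9e6)
    data.frame(hap = h, chrom = "chr1", start = st, end = st + 50000)
  }))
  hot <- data.frame(hap = sample(roster, 15), chrom = "chr1",
                    start = 5e6, end = 5.1e6)
  wins <- data.frame(chrom = "chr1", start = seq(0, 10e6 - 1000, 1000))
  attr(wins, "window_size") <- 1000
  tr <- frequency_track(rbind(bg, hot), roster, wins)
  out <- enriched_regions(tr)
  covers <- any(out$start <= 5e6 & out$end >= 5.1e6)
  expect_true(covers)
})

test_that("desert scanning follows the run and length rules", {
  mk <- function(freqs, len = 1000) {
    tr <- data.frame(chrom = "chr1",
                     start = (seq_along(freqs) - 1) * len, freq = freqs,
                     n_carriers = 0L)
    attr(tr, "window_size") <- len
    tr
  }
  # all-zero 20 Mb: one desert spanning everything
  tr <- mk(rep(0, 20000))
  d <- desert_scan(tr)
  expect_equal(nrow(d), 1)
  expect_equal(d$end - d$start, 20e6)
  # uniform 5%: nothing
  expect_equal(nrow(desert_scan(mk(rep(0.05, 20000)))), 0)
  # one 1% window at the midpoint of 25 Mb: both flanks >= 10 Mb
  f <- rep(0, 25000); f[12500] <- 0.01
  d2 <- desert_scan(mk(f))
  expect_equal(nrow(d2), 2)
  expect_true(all(d2$end - d2$start >= 1e7))
  # same spike on 15 Mb: flanks are ~7.5 Mb, too short
  f3 <- rep(0, 15000); f3[7500] <- 0.01
  expect_equal(nrow(desert_scan(mk(f3))), 0)
  expect_error(desert_scan(mk(rep(0, 100)), min_len = 10), "window size")
  # missing windows count toward length but not the mean
  f4 <- rep(0, 12000); f4[6000] <- NA
  d4 <- desert_scan(mk(f4))
  expect_equal(nrow(d4), 1)
  expect_equal(d4$statistic, 0)
})

test_that("PBS matches the written-out Hudson formula", {
  mk <- function(f, n) {
    tr <- data.frame(chrom = "chr1", start = 0, freq = f, n_carriers = 0L)
    attr(tr, "n_haplotypes") <- n
    attr(tr, "window_size") <- 1000
    tr
  }
  # identical frequencies: zero branch length
  z <- pbs_scan(mk(0.3, 100), mk(0.3, 100), mk(0.3, 100))
  expect_equal(z$pbs, 0, tolerance = 1e-12)
  # independent arithmetic oracle at f_A=0.5, f_B=f_C=0.1, n=1000
  hud <- function(p1, n1, p2, n2) {
    ((p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)) /
      (p1 * (1 - p2) + p2 * (1 - p1))
  }
  t_ab <- -log(1 - hud(0.5, 1000, 0.1, 1000))
  t_bc <- -log(1 - hud(0.1, 1000, 0.1, 1000))
  want <- (t_ab + t_ab - max(t_bc, 0)) / 2
  got <- pbs_scan(mk(0.5, 1000), mk(0.1, 1000), mk(0.1, 1000))
  expect_equal(got$pbs, want, tolerance = 1e-9)
  # symmetric in the two reference populations
  a <- mk(0.4, 200); b <- mk(0.05, 150); c3 <- mk(0.2, 120)
  expect_equal(pbs_scan(a, b, c3)$pbs, pbs_scan(a, c3, b)$pbs,
               tolerance = 1e-12)
  expect_error(pbs_scan(a, mk(c(0.1, 0.2), 10), b), "tiling")
})

test_that("uniquely shared derived alleles are counted per region", {
  # 1000 candidate sites; qualification checked against a direct site scan
  set.seed(111)
  pos <- sort(sample(0:99999, 1000))
  carrier <- data.frame(chrom = "chr1", pos = pos, alt = "G")
  den_car <- rbinom(1000, 1, 0.4)
  nea_car <- rbinom(1000, 1, 0.3)
  in_og <- rbinom(1000, 1, 0.2) == 1
  tab <- rbind(
    data.frame(genome = "AltaiDen", chrom = "chr1", pos = pos, alt = "G",
               carries = den_car),
    data.frame(genome = "Vindija", chrom = "chr1", pos = pos, alt = "G",
               carries = nea_car))
  panel <- archaic_panel(tab, clades = c(AltaiDen = "Denisovan",
                                         Vindija = "Neanderthal"))
  og <- toy_outgroup(rep("chr1", sum(in_og)), pos[in_og],
                     rep("G", sum(in_og)))
  regions <- data.frame(chrom = "chr1", start = c(0, 50000),
                        end = c(50000, 100000))
  out <- unique_shared_scan(carrier, panel, "Denisovan", og, regions)
  want <- den_car == 1 & nea_car == 0 & !in_og
  expect_equal(out$count[1], sum(want & pos < 50000))
  expect_equal(out$count[2], sum(want & pos >= 50000))
  # a constructed 13.2 kb region holding exactly 78 qualifying sites
  qpos <- sort(sample(200000:213199, 78))
  carrier2 <- data.frame(chrom = "chr1", pos = qpos, alt = "G")
  tab2 <- rbind(
    data.frame(genome = "AltaiDen", chrom = "chr1", pos = qpos, alt = "G",
               carries = 1L),
    data.frame(genome = "Vindija", chrom = "chr1", pos = qpos, alt = "G",
               carries = 0L))
  panel2 <- archaic_panel(tab2, clades = c(AltaiDen = "Denisovan",
                                           Vindija = "Neanderthal"))
  r2 <- data.frame(chrom = "chr1", start = 200000, end = 213200)
  expect_equal(unique_shared_scan(carrier2, panel2, "Denisovan",
                                  toy_outgroup(), r2)$count, 78)
})

test_that("regional haplotype stats give calibrated z-scores", {
  groups <- data.frame(
    hap = paste0("h", 1:2000),
    group = rep(c("North", "South"), each = 1000))
  carriers <- c(paste0("h", 1:348), paste0("h", 1001:1250))
  segs <- data.frame(hap = carriers, chrom = "chr1", start = 1000,
                     end = 60000)
  region <- list(chrom = "chr1", start = 0, end = 100000)
  st <- region_haplotype_stats(segs, region, groups)
  north <- st[st$group == "North", ]
  expect_equal(north$freq, 0.348)
  # closed-form two-proportion z, written out independently
  p <- (348 + 250) / 2000
  z_want <- (0.348 - 0.250) / sqrt(p * (1 - p) * (1 / 1000 + 1 / 1000))
  expect_equal(north$z, z_want, tolerance = 1e-12)
  expect_equal(st$z[st$group == "South"], -z_want, tolerance = 1e-12)
  # equal groups: z = 0
  segs_eq <- data.frame(hap = c(paste0("h", 1:100), paste0("h", 1001:1100)),
                        chrom = "chr1", start = 0, end = 50000)
  st_eq <- region_haplotype_stats(segs_eq, region, groups)
  expect_equal(st_eq$z, c(0, 0), tolerance = 1e-12)
})

test_that("ILS p-values match numeric integration and are monotone", {
  r <- 1e-8; t_split <- 20000
  p <- ils_pvalue(50000, r, t_split)
  oracle <- stats::integrate(function(x) dgamma(x, shape = 2,
                                                rate = r * t_split),
                             50000, Inf, rel.tol = 1e-10)$value
  expect_equal(p, oracle, tolerance = 1e-8)
  expect_equal(ils_pvalue(1e-9, r, t_split), 1, tolerance = 1e-6)
  ms <- c(1e4, 5e4, 1e5, 5e5)
  expect_true(all(diff(ils_pvalue(ms, r, t_split)) < 0))
  pe <- ils_pvalue(50000, r, t_split, law = "exponential")
  expect_equal(pe, exp(-r * t_split * 50000), tolerance = 1e-12)
  expect_error(ils_pvalue(-1, r, t_split), "must be > 0")
})
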