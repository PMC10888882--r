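test_that("outgroup set contains shared alleles and no private ones", {
  co <- small_cohort()
  og <- build_outgroup_set(co)
  shared_keys <- with(co$sites[co$sites$origin == "shared", ],
                      paste(chrom, pos, alt, sep = ":"))
  priv_keys <- with(co$sites[co$sites$origin != "shared", ],
                    paste(chrom, pos, alt, sep = ":"))
  # every site carried by an outgroup haplotype must be in the set
  carried <- unique(unlist(co$outgroup_sites))
  carried_keys <- with(co$sites[carried, ], paste(chrom, pos, alt, sep = ":"))
  expect_true(all(carried_keys %in% og$keys))
  expect_true(all(og$keys %in% shared_keys))
  expect_false(any(priv_keys %in% og$keys))
  expect_equal(og$n_haplotypes, 20)
})

test_that("window counting uses the half-open 0-based convention", {
  og <- toy_outgroup()
  mask <- data.frame(chrom = "chr1", start = 0, end = 4000)
  v <- data.frame(chrom = "chr1", pos = c(0, 999, 1000, 1999, 3999),
                  alt = "G")
  tr <- count_private(v, og, mask, c(chr1 = 4000))
  expect_equal(tr$obs, c(2L, 2L, 0L, 1L))
  expect_equal(tr$start, c(0, 1000, 2000, 3000))
  expect_equal(tr$callable, rep(1000, 4))
})

test_that("variants in the outgroup or outside the mask are not counted", {
  og <- toy_outgroup("chr1", 500, "G")
  mask <- data.frame(chrom = "chr1", start = c(0, 2500), end = c(1000, 3000))
  v <- data.frame(chrom = "chr1", pos = c(500, 600, 1500, 2600), alt = "G")
  tr <- count_private(v, og, mask, c(chr1 = 3000))
  # pos 500 in outgroup, 1500 unmasked; 600 and 2600 remain
  expect_equal(sum(tr$obs), 2L)
  expect_equal(tr$obs[1], 1L)
  expect_equal(tr$obs[3], 1L)
  expect_equal(tr$callable, c(1000, 0, 500))
  expect_true(all(tr$obs[tr$callable == 0] == 0))
})

test_that("window counts match a direct per-site scan (conservation)", {
  set.seed(21)
  lens <- c(chr1 = 50000, chr2 = 30000)
  v <- data.frame(
    chrom = sample(names(lens), 400, replace = TRUE),
    pos = NA, alt = sample(c("G", "T"), 400, replace = TRUE))
  v$pos <- floor(runif(400) * lens[v$chrom])
  og <- toy_outgroup(v$chrom[1:50], v$pos[1:50], v$alt[1:50])
  mask <- rbind(data.frame(chrom = "chr1", start = c(0, 30000),
                           end = c(20000, 50000)),
                data.frame(chrom = "chr2", start = 5000, end = 25000))
  tr <- count_private(v, og, mask, lens)
  # oracle: direct qualification test per site
  qual <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    in_og <- paste(v$chrom[i], v$pos[i], v$alt[i], sep = ":") %in% og$keys
    m <- mask[mask$chrom == v$chrom[i], ]
    in_mask <- any(v$pos[i] >= m$start & v$pos[i] < m$end)
    qual[i] <- !in_og && in_mask
  }
  expect_equal(sum(tr$obs), sum(qual))
  # and per window
  for (w in sample(nrow(tr), 25)) {
    inw <- qual & v$chrom == tr$chrom[w] & v$pos >= tr$start[w] &
      v$pos < tr$start[w] + 1000
    expect_equal(tr$obs[w], sum(inw))
  }
})

test_that("shrinking the callable mask never increases any window count", {
  set.seed(22)
  lens <- c(chr1 = 40000)
  v <- data.frame(chrom = "chr1", pos = sort(floor(runif(300) * 40000)),
                  alt = "G")
  og <- toy_outgroup()
  full <- data.frame(chrom = "chr1", start = 0, end = 40000)
  sub <- data.frame(chrom = "chr1", start = c(2000, 21000),
                    end = c(15000, 33000))
  t_full <- count_private(v, og, full, lens)
  t_sub <- count_private(v, og, sub, lens)
  expect_true(all(t_sub$obs <= t_full$obs))
  expect_true(all(t_sub$callable <= t_full$callable))
})

test_that("weights reflect density ratios and average to one", {
  lens <- c(chr1 = 10e6)
  mask <- data.frame(chrom = "chr1", start = 0, end = 10e6)
  # bins 1..10: bin 3 twice the density of the others
  set.seed(23)
  base <- lapply(1:10, function(b) {
    n <- if (b == 3) 2000 else 1000
    data.frame(chrom = "chr1", pos = (b - 1) * 1e6 + floor(runif(n) * 1e6))
  })
  sites <- do.call(rbind, base)
  w <- estimate_weights(sites, mask, lens, window_size = 1000,
                        shrink = FALSE)
  expect_lt(abs(mean(w) - 1), 1e-9)
  w_bin <- tapply(w, (seq_along(w) - 1) %/% 1000, mean)
  expect_equal(unname(w_bin[3] / w_bin[1]), 2, tolerance = 1e-12)
  # exact ratio definition: density / mean density
  expect_equal(unname(w_bin[[3]]), 2000 / 1100, tolerance = 1e-12)
})

test_that("shrinkage pulls pure-noise weights toward one", {
  co <- small_cohort()
  lens <- setNames(co$chroms$length, co$chroms$chrom)
  w_raw <- estimate_weights(co, co$masks$callable, lens, shrink = FALSE)
  w_shr <- estimate_weights(co, co$masks$callable, lens, shrink = TRUE)
  # the simulated mutation rate is uniform: deviations from 1 are noise
  expect_lt(sd(w_shr[w_shr > 0]), sd(w_raw[w_raw > 0]) + 1e-12)
  expect_lt(abs(mean(w_shr[w_shr > 0]) - 1), 1e-9)
})

test_that("degenerate panels are rejected", {
  co_no_og <- simulate_cohort(sim_params(n_test_individuals = 2,
                                         n_outgroup = 0,
                                         chrom_lengths_bp = c(1e6),
                                         seed = 2))
  expect_error(build_outgroup_set(co_no_og), "zero samples")
  mask <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  expect_error(estimate_weights(data.frame(chrom = character(),
                                           pos = numeric()),
                                mask, c(chr1 = 1e6)), "density")
})

test_that("phased VCFs round-trip through write_cohort", {
  co <- simulate_cohort(sim_params(n_test_individuals = 3, n_outgroup = 3,
                                   chrom_lengths_bp = c(2e6, 2e6),
                                   seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("test.vcf", "outgroup.vcf", "callable.bed", "centromeres.bed")))))
  # outgroup set built from the written VCF equals the in-memory one
  og_mem <- build_outgroup_set(co)
  og_vcf <- build_outgroup_set(file.path(dir, "outgroup.vcf"))
  expect_setequal(og_vcf$keys, og_mem$keys)
  expect_equal(og_vcf$n_haplotypes, og_mem$n_haplotypes)
  # haplotype variants read back from the test VCF match the truth
  v <- archscan:::.read_phased_vcf(file.path(dir, "test.vcf"))
  for (h in c("ind001_h1", "ind002_h2")) {
    got <- v$sites[v$gt[, h] == 1L, c("chrom", "pos")]
    want <- unique(co$sites[co$hap_sites[[h]], c("chrom", "pos")])
    got <- got[order(got$chrom, got$pos), ]
    want <- want[order(want$chrom, want$pos), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
  # archaic reference VCFs carry one pseudo-diploid sample with missing data
  a <- archscan:::.read_phased_vcf(file.path(dir, "archaic_Vindija.vcf"),
                                   allow_unphased = TRUE)
  expect_equal(ncol(a$gt), 2)
  # unphased genotypes are rejected by default
  bad <- file.path(dir, "bad.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", sep = "\t"),
               "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"), bad)
  expect_error(build_outgroup_set(bad), "unphased")
})
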