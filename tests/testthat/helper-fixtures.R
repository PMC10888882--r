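# Shared fixtures. Expensive objects are built once per session and cached.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# small cohort: quick, enough tracts for distributional checks
small_cohort <- function() {
  memo("small_cohort", function() {
    simulate_cohort(sim_params(n_test_individuals = 10, n_outgroup = 10,
                               chrom_lengths_bp = rep(20e6, 2), seed = 7))
  })
}

# small end-to-end pipeline: tracks, trained HMM, posteriors, segments
small_pipeline <- function() {
  memo("small_pipeline", function() {
    co <- small_cohort()
    tracks <- cohort_tracks(co)
    fit <- hmm_train(tracks)
    posts <- lapply(tracks, hmm_posterior, params = fit)
    segs <- do.call(rbind, lapply(posts, call_segments, cutoff = 0.8))
    rownames(segs) <- NULL
    list(cohort = co, tracks = tracks, fit = fit, posts = posts,
         segs = segs)
  })
}

# hand-built observation track
toy_track <- function(obs, weight = rep(1, length(obs)),
                      callable = rep(1000, length(obs)),
                      chrom = rep("chr1", length(obs)), window_size = 1000) {
  start <- (stats::ave(seq_along(obs), chrom, FUN = seq_along) - 1) *
    window_size
  tr <- data.frame(chrom = chrom, start = start, obs = as.integer(obs),
                   callable = callable, weight = weight)
  attr(tr, "hap") <- "toy_h1"
  attr(tr, "window_size") <- window_size
  tr
}

# exhaustive-path posterior oracle for <= 12 windows (independent of the
# package's forward-backward)
brute_posterior <- function(obs, ew, sp, tr, rates) {
  n <- length(obs)
  emis <- function(o, e, lam) if (e <= 0) 1 else stats::dpois(o, lam * e)
  post <- numeric(n); tot <- 0
  for (mask in 0:(2^n - 1)) {
    st <- as.integer(intToBits(mask))[1:n] + 1L
    pr <- sp[st[1]] * emis(obs[1], ew[1], rates[st[1]])
    if (n > 1) {
      for (w in 2:n) {
        pr <- pr * tr[st[w - 1], st[w]] * emis(obs[w], ew[w], rates[st[w]])
      }
    }
    tot <- tot + pr
    post[st == 2] <- post[st == 2] + pr
  }
  post / tot
}

# per-base bitmap oracle for interval algebra on small coordinates
bitmap_union_bp <- function(df, chrom_len) {
  total <- 0
  for (ch in names(chrom_len)) {
    bit <- logical(chrom_len[[ch]])
    d <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (d$end[i] > d$start[i]) bit[(d$start[i] + 1):d$end[i]] <- TRUE
    }
    total <- total + sum(bit)
  }
  total
}

bitmap_partition <- function(sets, chrom_len) {
  out <- list()
  for (ch in names(chrom_len)) {
    lab <- matrix(FALSE, chrom_len[[ch]], length(sets))
    for (p in seq_along(sets)) {
      d <- sets[[p]][sets[[p]]$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(d))) {
        if (d$end[i] > d$start[i]) lab[(d$start[i] + 1):d$end[i], p] <- TRUE
      }
    }
    covered <- rowSums(lab) > 0
    keys <- apply(lab[covered, , drop = FALSE], 1, function(m) {
      paste(names(sets)[m], collapse = "+")
    })
    for (k in unique(keys)) {
      out[[k]] <- (if (is.null(out[[k]])) 0 else out[[k]]) + sum(keys == k)
    }
  }
  out
}

# random segment fixture
random_intervals <- function(n, chrom_len, max_len = 400, seed = 1) {
  set.seed(seed)
  ch <- sample(names(chrom_len), n, replace = TRUE)
  st <- floor(runif(n) * (unlist(chrom_len)[ch] - max_len))
  data.frame(chrom = ch, start = st,
             end = st + 1 + floor(runif(n) * (max_len - 1)))
}

# minimal outgroup set object from explicit sites
toy_outgroup <- function(chrom = character(), pos = numeric(),
                         alt = character(), n_haplotypes = 10) {
  structure(list(keys = paste(chrom, pos, alt, sep = ":"),
                 n_haplotypes = n_haplotypes), class = "outgroup_set")
}
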