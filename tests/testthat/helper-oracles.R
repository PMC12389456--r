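# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive explicit loops over sorted values, sharing no
# code with the package internals.

# linear-interpolation percentile thresholds from first principles
bf_quintile_thresholds <- function(v) {
  s <- sort(v)
  n <- length(s)
  vapply(c(0.2, 0.4, 0.6, 0.8), function(p) {
    hpos <- (n - 1) * p + 1
    lo <- floor(hpos)
    fr <- hpos - lo
    if (lo >= n) s[n] else s[lo] + fr * (s[lo + 1] - s[lo])
  }, numeric(1))
}

# brute-force signed quintile scoring of a whole intake matrix
bf_hpds <- function(intake, taxonomy) {
  n <- nrow(intake)
  G <- nrow(taxonomy$groups)
  subs <- matrix(0L, n, G)
  for (j in seq_len(G)) {
    th <- bf_quintile_thresholds(intake[, j])
    d <- taxonomy$groups$direction[j]
    for (i in seq_len(n)) {
      r <- 0L
      for (t in th) if (intake[i, j] > t) r <- r + 1L
      subs[i, j] <- as.integer(d * (r - 2L))
    }
  }
  list(subscores = subs, totals = rowSums(subs))
}

# Benjamini-Hochberg by exhaustive evaluation of the step-up definition
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rejected <- logical(m)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  list(p_adjusted = adj, rejected = rejected)
}

# write a toy taxonomy config and load it (reduced group count allowed)
toy_taxonomy <- function(groups, ignore_items = list("ignored_item")) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "toy", groups = groups,
                        ignore_items = ignore_items), path)
  load_taxonomy(path, check_group_count = FALSE)
}

# random zero-inflated intake matrix over the packaged 22 groups
random_intake <- function(n, taxonomy, zero_frac = 0.3) {
  G <- nrow(taxonomy$groups)
  m <- matrix(ifelse(stats::runif(n * G) < zero_frac, 0,
                     stats::rlnorm(n * G, meanlog = 4, sdlog = 1)),
              n, G, dimnames = list(sprintf("p%04d", seq_len(n)),
                                    taxonomy$groups$group_id))
  m
}
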