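# Shared fixtures: small synthetic references and designs built in code.

write_ref_fixture <- function(dir, organism, length = 20000L, gc = 0.5,
                              seed = 1L, n_contigs = 1L) {
  ref <- generate_random_reference(organism, n_contigs, length, gc, seed)
  path <- file.path(dir, paste0(organism, ".fasta"))
  write_fasta(ref, path)
  path
}

# A two-organism host/pathogen design rooted in `dir` (files written there).
host_pathogen_design <- function(dir, total = 10000L, pathogen_reads = 500L,
                                 seed = 42L, host_len = 200000L,
                                 pathogen_len = 6000L, profile = "perfect") {
  host_fa <- write_ref_fixture(dir, "host", host_len, 0.45, seed = 101L)
  path_fa <- write_ref_fixture(dir, "pathogen", pathogen_len, 0.5, seed = 102L)
  sample_design(
    entries = list(
      organism_spec("host", host_fa, host = TRUE, fill_remainder = TRUE),
      organism_spec("pathogen", path_fa,
                    abundance_spec("absolute", pathogen_reads))),
    total_reads = total, scenario = "host_microbiome",
    length_model = length_model(2000, 200),
    profile = profile, seed = seed, name = "hp")
}

rdirichlet_test <- function(n) {
  g <- rgamma(n, 1)
  g / sum(g)
}

# Floor/ceil apportionment oracle: any allocation with a count outside
# {floor(share), floor(share)+1} has max deviation > 1, worse than any
# floor/ceil allocation, so restricting the search is exact. Independent
# of largest_remainder(): scores every subset choice directly.
oracle_apportion_fc <- function(percent, total) {
  shares <- percent / 100 * total
  lo <- floor(shares)
  extra <- total - sum(lo)
  n <- length(shares)
  stopifnot(extra >= 0, extra <= n)
  best <- NULL
  best_key <- NULL
  for (mask in 0:(2^n - 1)) {
    up <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (sum(up) != extra) next
    a <- lo + up
    dev <- abs(a - shares)
    key <- c(max(dev), sum(dev), -a)
    if (is.null(best_key)) {
      best <- a; best_key <- key
    } else {
      for (j in seq_along(key)) {
        if (key[j] < best_key[j] - 1e-9) { best <- a; best_key <- key; break }
        if (key[j] > best_key[j] + 1e-9) break
      }
    }
  }
  as.integer(best)
}

# Brute-force apportionment oracle: enumerate every nonnegative integer
# allocation summing to `total` and pick the one minimising the largest
# absolute deviation from the exact shares (then total deviation, then
# giving larger counts to earlier-declared categories). Independent of
# largest_remainder().
oracle_apportion <- function(percent, total) {
  n <- length(percent)
  shares <- percent / 100 * total
  key_less <- function(k1, k2) { # strict lexicographic k1 < k2
    for (j in seq_along(k1)) {
      if (k1[j] < k2[j] - 1e-9) return(TRUE)
      if (k1[j] > k2[j] + 1e-9) return(FALSE)
    }
    FALSE
  }
  best <- NULL
  best_key <- NULL
  rec <- function(i, left, acc) {
    if (i == n) {
      a <- c(acc, left)
      dev <- abs(a - shares)
      key <- c(max(dev), sum(dev), -a)
      if (is.null(best_key) || key_less(key, best_key)) {
        best <<- a
        best_key <<- key
      }
      return(invisible())
    }
    for (v in 0:left) rec(i + 1L, left - v, c(acc, v))
  }
  rec(1L, total, integer(0))
  best
}
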