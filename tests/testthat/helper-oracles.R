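# Independent oracles: deliberately naive implementations used only to
# cross-check the package's algorithms on small inputs.

# quadratic homopolymer scanner: tests every position for being the start of
# a maximal run, walking forward base by base (circular indexing on demand)
brute_force_runs <- function(s, min_len, bases = c("A", "C", "G", "T"),
                             circular = FALSE) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(ch)
  at <- function(i) ch[((i - 1) %% n) + 1]
  out <- list()
  if (all(ch == ch[1]) && circular) {
    if (ch[1] %in% bases && n >= min_len)
      return(data.frame(base = ch[1], start = 0L, length = n,
                        wraps_origin = FALSE, stringsAsFactors = FALSE))
    return(data.frame(base = character(), start = integer(),
                      length = integer(), wraps_origin = logical(),
                      stringsAsFactors = FALSE))
  }
  for (p in seq_len(n)) {
    b <- ch[p]
    if (!(b %in% bases)) next
    prev_same <- if (p == 1) { if (circular) at(0) == b else FALSE }
                 else ch[p - 1] == b
    if (prev_same) next                      # not a run start
    len <- 1
    while (TRUE) {
      nxt <- p + len
      if (!circular && nxt > n) break
      if (at(nxt) != b) break
      len <- len + 1
      if (len >= n) break
    }
    wraps <- circular && (p + len - 1) > n
    if (len >= min_len)
      out[[length(out) + 1]] <- data.frame(base = b, start = p - 1L,
                                           length = len,
                                           wraps_origin = wraps,
                                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(base = character(), start = integer(),
                      length = integer(), wraps_origin = logical(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$start), , drop = FALSE]
}

# naive ORF enumerator for linear sequences: walks every frame on both
# strands codon by codon with substr, no vectorization shared with the
# implementation
brute_force_orfs <- function(s, code, min_aa, mode) {
  s <- toupper(s)
  rc <- function(x) {
    paste(rev(chartr("ACGT", "TGCA",
                     strsplit(x, "", fixed = TRUE)[[1]])), collapse = "")
  }
  out <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else rc(s)
    n <- nchar(ss)
    for (f in 0:2) {
      m <- (n - f) %/% 3
      if (m < 1) next
      # indices of stop codons in this frame
      stops <- integer()
      for (a in seq_len(m)) {
        cod <- substr(ss, f + 3 * (a - 1) + 1, f + 3 * a)
        if (cod %in% code$stops) stops <- c(stops, a)
      }
      bounds <- c(0, stops, m + 1)
      for (k in seq_len(length(bounds) - 1)) {
        a <- bounds[k] + 1
        b <- bounds[k + 1] - 1
        if (b < a) next
        has_stop <- bounds[k + 1] <= m
        if (mode == "start-to-stop") {
          first_start <- NA
          for (x in a:b) {
            cod <- substr(ss, f + 3 * (x - 1) + 1, f + 3 * x)
            if (cod %in% code$starts) { first_start <- x; break }
          }
          if (is.na(first_start)) next
          a <- first_start
        }
        n_aa <- b - a + 1
        if (n_aa < min_aa) next
        p1 <- f + 3 * (a - 1) + 1
        p2 <- f + 3 * (if (has_stop) b + 1 else b)
        if (strand == "-") { tmp <- p1; p1 <- n - p2 + 1; p2 <- n - tmp + 1 }
        out[[length(out) + 1]] <- data.frame(
          start = as.integer(p1), end = as.integer(p2), strand = strand,
          n_aa = as.integer(n_aa), has_stop = has_stop,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_aa = integer(),
                      has_stop = logical(), stringsAsFactors = FALSE))
  df <- unique(do.call(rbind, out))
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

# plain-R affine-gap local alignment (score only), written as three
# explicit Gotoh matrices with R loops; the gap cost convention matches
# scoring_scheme(): a gap of length k costs gap_open + (k - 1) * gap_extend
sw_score_oracle <- function(q, t, match = 5, mismatch = -4,
                            gap_open = -10, gap_extend = -0.5) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  m <- length(qc); n <- length(tc)
  NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open, F[i - 1, j] + gap_extend)
      sub <- if (qc[i - 1] == tc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# exhaustive local-alignment enumeration for tiny sequences: recursion over
# all monotone alignment paths between all substring pairs (no DP tables);
# used to validate sw_score_oracle itself
sw_score_exhaustive <- function(q, t, match = 5, mismatch = -4,
                                gap_open = -10, gap_extend = -0.5) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  # best global score aligning q[i..m2] with t[j..n2]; state: last op
  rec <- function(i, m2, j, n2, last) {
    if (i > m2 && j > n2) return(0)
    sc <- -Inf
    if (i <= m2 && j <= n2) {
      sub <- if (qc[i] == tc[j]) match else mismatch
      sc <- max(sc, sub + rec(i + 1, m2, j + 1, n2, "M"))
    }
    if (i <= m2) {
      pen <- if (identical(last, "I")) gap_extend else gap_open
      sc <- max(sc, pen + rec(i + 1, m2, j, n2, "I"))
    }
    if (j <= n2) {
      pen <- if (identical(last, "D")) gap_extend else gap_open
      sc <- max(sc, pen + rec(i, m2, j + 1, n2, "D"))
    }
    sc
  }
  best <- 0
  for (i1 in seq_along(qc)) for (i2 in i1:length(qc))
    for (j1 in seq_along(tc)) for (j2 in j1:length(tc)) {
      best <- max(best, rec(i1, i2, j1, j2, NULL))
    }
  best
}

# small simulation spec used across tests (kept modest so property loops
# stay fast)
small_spec <- function(seed, n_genes = 3) {
  simulation_spec(n_genes = n_genes, gene_length_range = c(40, 90),
                  minus_strand_fraction = 0.3,
                  insertion_count_range = c(1, 4),
                  insertion_length_range = c(7, 12),
                  spacer_length_range = c(7, 15),
                  control_region_length = 300, seed = seed)
}

random_dna <- function(n, at_rich = TRUE) {
  p <- if (at_rich) c(0.35, 0.15, 0.15, 0.35) else rep(0.25, 4)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}
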