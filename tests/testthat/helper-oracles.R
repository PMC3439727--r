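# Independent brute-force oracles used to freeze expected values. Each one
# follows the definition directly and shares no code path with the package
# implementation it checks.

# base-4 value of a window built digit by digit, reduced mod q at each step
oracle_fingerprint <- function(codes, p, b, q) {
  v <- 0
  for (j in (p + 1L):(p + b)) v <- (v * 4 + codes[j]) %% q
  v
}

# textbook full-matrix Smith-Waterman with linear gaps
oracle_sw <- function(a, b, match = 1, mismatch = -1, indel = -2) {
  if (is.character(a)) a <- dna_codes(a)
  if (is.character(b)) b <- dna_codes(b)
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    s <- if (a[i] == b[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + indel, H[i + 1, j] + indel)
    if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
  }
  best
}

# exhaustive mate scan: first 0-based position with Hamming distance <= M
oracle_mate_scan <- function(S, mate, M, from = 0L) {
  lm <- length(mate)
  last <- length(S) - lm
  if (last < from) return(NULL)
  for (p in from:last) {
    d <- sum(S[(p + 1):(p + lm)] != mate)
    if (d <= M) return(p)
  }
  NULL
}

# naive candidate scan: reads (character vector), both orientations, whose
# b-window at the orientation's fixed position matches the contig window
# character by character
oracle_candidates <- function(reads, S_codes, l, L, b) {
  nS <- length(S_codes)
  out <- list()
  for (id in seq_along(reads)) {
    codes <- dna_codes(reads[[id]])
    if (length(codes) < L) next
    for (rc in c(FALSE, TRUE)) {
      ori <- if (rc) revcomp_codes(codes) else codes
      x <- if (rc) L - b else 0L                # 0-based window start in read
      y <- nS - l + x                           # 0-based window start in contig
      if (y < 0 || y + b > nS) next
      if (all(ori[(x + 1):(x + b)] == S_codes[(y + 1):(y + b)]))
        out[[length(out) + 1L]] <- c(id, as.integer(rc))
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# naive all-pairs overlap scan implementing the selection definition
# directly: a (read, orientation) is eligible at l only if its b-window at
# the orientation's fixed position matches the contig character-exactly
# (the shortlist R(S, l) with k = 0); it is kept at its largest such l with
# Hamming distance of the l-prefix vs the contig l-suffix <= delta(l)
oracle_overlaps <- function(reads, S_codes, L, Delta, delta_fun, b) {
  nS <- length(S_codes)
  out <- list()
  for (id in seq_along(reads)) {
    codes <- dna_codes(reads[[id]])
    if (length(codes) < L) next
    for (rc in c(FALSE, TRUE)) {
      ori <- if (rc) revcomp_codes(codes) else codes
      x <- if (rc) L - b else 0L                # 0-based window start in read
      for (l in rev(seq(L, L + Delta))) {       # largest l first
        if (l > nS || l > length(ori)) next
        y <- nS - l + x                         # 0-based window start in contig
        if (y < 0 || y + b > nS) next
        if (!all(ori[(x + 1):(x + b)] == S_codes[(y + 1):(y + b)])) next
        d <- sum(ori[1:l] != S_codes[(nS - l + 1):nS])
        if (d <= delta_fun(l)) {
          out[[length(out) + 1L]] <- c(id, as.integer(rc), l, d)
          break
        }
      }
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), ncol = 4))
  m <- do.call(rbind, out)
  colnames(m) <- c("read_id", "is_rc", "l", "mism")
  m
}

# naive per-column counting oracle for the consensus
oracle_column <- function(seqs, Is, eff_lens, j) {
  counts <- integer(4)
  for (i in seq_along(seqs)) {
    if (Is[i] <= j && Is[i] + eff_lens[i] - 1 >= j)
      counts[seqs[[i]][j - Is[i] + 1] + 1] <- counts[seqs[[i]][j - Is[i] + 1] + 1] + 1L
  }
  counts
}

# naive interval-union coverage on a logical vector
oracle_coverage <- function(starts, lens, G, circular = FALSE) {
  covered <- logical(G)
  for (i in seq_along(starts)) {
    if (lens[i] <= 0) next
    pos <- starts[i] + seq_len(lens[i]) - 1
    pos <- if (circular) pos %% G else pos[pos >= 0 & pos < G]
    covered[pos + 1] <- TRUE
  }
  mean(covered)
}

# construct a minimal overlap_set by hand from oriented sequences + starts
make_ov <- function(seqs_chr, Is, S_len = NULL) {
  seqs <- lapply(seqs_chr, dna_codes)
  lens <- vapply(seqs, length, 0L)
  structure(list(n = length(seqs), read_id = seq_along(seqs),
                 is_rc = rep(FALSE, length(seqs)),
                 l = if (is.null(S_len)) rep(0L, length(seqs)) else S_len - Is,
                 I = as.integer(Is), len = lens, eff_len = lens,
                 mism = rep(0L, length(seqs)), seqs = seqs),
            class = "overlap_set")
}
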