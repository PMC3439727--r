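test_that("overlap positions follow I = |S| - l, F = I + |r| - 1", {
  expect_identical(overlap_positions(18, 8, 11), c(I = 10, F = 20))
  expect_identical(overlap_positions(60, 60, 80)[["I"]], 0)   # read spans whole contig
  expect_error(overlap_positions(10, 11, 20), "exceeds")
  set.seed(14)
  for (i in 1:20) {
    cl <- sample(50:500, 1); l <- sample(10:cl, 1); rl <- sample(30:120, 1)
    pos <- overlap_positions(cl, l, rl)
    expect_identical(pos[["F"]] - pos[["I"]] + 1, as.numeric(rl))
  }
})

test_that("extension parameter validation and the delta rule", {
  ep <- extension_params()
  expect_identical(ep$delta_fun(50L), 5)     # floor(10 * 50 / 100)
  expect_identical(ep$delta_fun(99L), 9)     # floor, not round
  expect_error(extension_params(T1 = 0.2), "0.25")
  expect_error(extension_params(T1 = 0.9, T2 = 0.6), "T1 < T2")
  epc <- extension_params(delta = 2)
  expect_identical(epc$delta_fun(77L), 2)
})

test_that("consensus bounds take the m-th largest end and respect the halt conditions", {
  # two identical overlaps, m = 2: F_C is their common end
  ov <- make_ov(c("ACGTACGT", "ACGTACGT"), c(0, 0))
  expect_identical(consensus_bounds(ov, 2)$F_C, 7L)
  # ends {20, 16, 19, 21}: the second largest is 20
  ov2 <- make_ov(c(strrep("A", 21), strrep("A", 17), strrep("A", 20), strrep("A", 22)),
                 c(0, 0, 0, 0))
  b2 <- consensus_bounds(ov2, 2)
  expect_identical(b2$F_C, 20L)
  expect_identical(b2$I_C, 0L)
  # a single overlap can never reach depth m = 2
  expect_null(consensus_bounds(make_ov("ACGT", 0), 2))
  # consensus not exceeding the contig end is a halt
  expect_null(consensus_bounds(ov, 2, S_len = 20))
})

test_that("consensus columns match a naive counting oracle", {
  # all reads agree: pi = 1, high-represented
  ov <- make_ov(c("ACGT", "ACGT", "ACGT"), c(0, 0, 0))
  cc <- build_consensus(ov, 0, 3, T1 = 0.6, T2 = 0.9)
  expect_identical(dna_string(cc$cons), "ACGT")
  expect_true(all(cc$pi == 1) && all(cc$klass == "high"))
  # four reads contributing A, C, G, T: pi hits its floor 0.25
  ov4 <- make_ov(c("A", "C", "G", "T"), c(0, 0, 0, 0))
  cc4 <- build_consensus(ov4, 0, 0, T1 = 0.6, T2 = 0.9)
  expect_identical(cc4$pi, 0.25)
  expect_identical(cc4$klass, "non")

  # randomized instances vs the per-column counting oracle
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    Is <- sample(0:5, n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), replace = TRUE),
            collapse = ""), "")
    ov <- make_ov(seqs, Is)
    IC <- min(Is); FC <- max(Is + nchar(seqs) - 1)
    cc <- build_consensus(ov, IC, FC, T1 = 0.6, T2 = 0.9)
    for (j in IC:FC) {
      counts <- oracle_column(ov$seqs, ov$I, ov$eff_len, j)
      jr <- j - IC + 1
      expect_identical(unname(cc$counts[, jr]), counts)
      expect_identical(cc$depth[jr], sum(counts))
      if (sum(counts) > 0) {
        expect_identical(cc$pi[jr], max(counts) / sum(counts))
        # the consensus character always attains the maximum count
        expect_identical(counts[cc$cons[jr] + 1], max(counts))
      }
    }
  }
})

test_that("consensus ties go to the character of the earliest read", {
  # at column 2 read 1 (I=0) says G, read 2 (I=1) says T, both count 1:
  # ascending I then input order elects read 1's G
  ov <- make_ov(c("AAG", "ATA"), c(0, 1))
  cc <- build_consensus(ov, 0, 3, T1 = 0.26, T2 = 0.5)
  expect_identical(cc$cons[3], dna_codes("G"))
  # same columns but read order swapped inside an equal-I pair
  ov2 <- make_ov(c("AG", "AT"), c(1, 1))
  cc2 <- build_consensus(ov2, 1, 2, T1 = 0.26, T2 = 0.5)
  expect_identical(cc2$cons[2], dna_codes("G"))
  ov3 <- make_ov(c("AT", "AG"), c(1, 1))
  cc3 <- build_consensus(ov3, 1, 2, T1 = 0.26, T2 = 0.5)
  expect_identical(cc3$cons[2], dna_codes("T"))
})

test_that("filtering drops low-represented mismatches and trims at non-represented columns", {
  # consensus over 4 reads; column 4 (0-based) is low-represented (pi = 0.5,
  # consensus C), column 5 non-represented (all four characters distinct)
  seqs <- c("AAAACA", "AAAACC", "AAAAGG", "AAAATT")
  ov <- make_ov(seqs, c(0, 0, 0, 0))
  cc <- build_consensus(ov, 0, 5, T1 = 0.3, T2 = 0.5)
  expect_identical(cc$klass[5], "low")
  expect_identical(cc$klass[6], "non")
  ft <- filter_and_trim(ov, cc)
  expect_identical(ft$dropped, c(3L, 4L))      # G/T mismatch the consensus C at col 4
  expect_identical(ft$trimmed, c(1L, 2L))      # survivors cut before the non column,
  expect_identical(ft$survivors$eff_len, c(5L, 5L))  # whether they match there or not
  # a read matching everywhere with all columns high-represented is untouched
  ovh <- make_ov(c("ACGT", "ACGT", "ACGT"), c(0, 0, 0))
  cch <- build_consensus(ovh, 0, 3, T1 = 0.3, T2 = 0.5)
  fth <- filter_and_trim(ovh, cch)
  expect_identical(fth$survivors$n, 3L)
  expect_identical(length(fth$dropped), 0L)
  expect_identical(length(fth$trimmed), 0L)
})

test_that("verified overlaps equal a naive all-pairs scan on planted instances", {
  L <- 20L; Delta <- 10L
  prm <- fingerprint_params(b = 10, w = 30)
  set.seed(55)
  n_checked <- 0L
  for (rep in 1:12) {
    g <- make_genome(600, rng_seed = 1000 + rep)
    gs <- g$seq
    S <- dna_codes(substr(gs, 201, 320))
    # plant reads overlapping the suffix with known mismatch loads, plus noise
    reads <- character(0)
    for (i in 1:30) {
      l <- sample(L:(L + Delta), 1)
      r <- paste0(substr(gs, 320 - l + 1, 320),
                  paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE), collapse = ""))
      nmut <- sample(0:4, 1)
      if (nmut > 0) {
        pos <- sample(nchar(r), nmut)
        for (p in pos)
          substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(r, p, p)), 1)
      }
      if (runif(1) < 0.3) r <- revcomp(r)
      reads <- c(reads, r)
    }
    reads <- c(reads, vapply(1:15, function(i)
      paste(sample(c("A", "C", "G", "T"), 35, replace = TRUE), collapse = ""), ""))
    ep <- extension_params(L = L, Delta = Delta, delta = 2, Lmax = 1000)
    idx <- build_read_index(reads, prm, L = L)
    got <- verify_overlaps(S, idx, ep)
    want <- oracle_overlaps(reads, S, L, Delta, ep$delta_fun, b = 10L)
    got_keys <- sort(paste(got$read_id, got$is_rc, got$l, got$mism))
    want_keys <- sort(paste(want[, "read_id"], want[, "is_rc"] == 1,
                            want[, "l"], want[, "mism"]))
    expect_identical(got_keys, want_keys)
    n_checked <- n_checked + nrow(want)
  }
  expect_gte(n_checked, 150L)
})

test_that("mate_check agrees with an exhaustive scan and honours M and from", {
  set.seed(66)
  S <- sample(0:3, 300, replace = TRUE)
  mate <- S[101:200]
  expect_identical(mate_check(S, mate, M = 0), 100L)
  # M = 0 with a single planted mismatch: not found
  mate1 <- mate; mate1[50] <- (mate1[50] + 1L) %% 4L
  expect_null(mate_check(S, mate1, M = 0))
  expect_identical(mate_check(S, mate1, M = 1), 100L)
  # random contig/mate pairs vs the brute-force oracle
  for (rep in 1:30) {
    S <- sample(0:3, sample(80:200, 1), replace = TRUE)
    mate <- sample(0:3, sample(20:60, 1), replace = TRUE)
    M <- sample(c(0, 5, 10, 25), 1)
    from <- sample(0:5, 1)
    got <- mate_check(S, mate, M, from)
    want <- oracle_mate_scan(S, mate, M, from)
    if (is.null(want)) expect_null(got) else expect_identical(got, want)
  }
  # mate longer than contig: none
  expect_null(mate_check(c(0L, 1L), c(0L, 1L, 2L), M = 10))
})

test_that("error-free extension reconstructs the genome and preserves the prefix", {
  w <- small_world()
  tr <- w$pairs$truth
  gs <- w$genome$seq
  picks <- which(tr$strand == "+" & tr$insert_start > 100 &
                 tr$insert_start + tr$insert_len < 4900)[1:8]
  for (i in picks) {
    seed <- w$pairs$reads1[[i]]
    ctg <- extend_seed(seed, revcomp(w$pairs$reads2[[i]]), w$index, w$ep, seed_id = i)
    expect_identical(ctg$label, "MATE_FOUND")
    # the contig is the genome substring starting at the seed's truth locus
    expect_identical(ctg$seq,
                     substr(gs, tr$insert_start[i] + 1,
                            tr$insert_start[i] + ctg$length))
    # the seed itself is never altered
    expect_identical(substr(ctg$seq, 1, nchar(seed)), seed)
    # the mate certificate is re-assertable post hoc
    mate_or <- dna_codes(revcomp(w$pairs$reads2[[i]]))
    S <- dna_codes(ctg$seq)
    d <- sum(S[ctg$mate_pos + seq_along(mate_or)] != mate_or)
    expect_lte(d, w$ep$M)
    # insert reconstruction: mate end sits at insert_len - 1
    expect_identical(ctg$mate_pos + length(mate_or), tr$insert_len[i])
  }
})

test_that("each extension step strictly grows the contig", {
  w <- small_world()
  tr <- w$pairs$truth
  i <- which(tr$strand == "+" & tr$insert_start > 200)[1]
  S <- dna_codes(w$pairs$reads1[[i]])
  for (step in 1:6) {
    st <- extend_step(S, w$index, w$ep)
    expect_identical(st$status, "extended")
    expect_gt(length(st$S_new), length(S))
    # prefix preservation up to the consensus revision point
    expect_identical(st$S_new[seq_len(st$I_C)], S[seq_len(st$I_C)])
    S <- st$S_new
  }
})

test_that("stop criteria label the contig correctly", {
  w <- small_world()
  tr <- w$pairs$truth
  i <- which(tr$strand == "+")[1]
  seed <- w$pairs$reads1[[i]]
  mate <- revcomp(w$pairs$reads2[[i]])
  # a seed that overlaps nothing: NO_MORE_EXTENSION with contig == seed
  set.seed(99)
  lone <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  ctg <- extend_seed(lone, mate, w$index, w$ep)
  expect_identical(ctg$label, "NO_MORE_EXTENSION")
  expect_identical(ctg$seq, lone)
  expect_identical(ctg$steps, 0L)
  # Lmax below the insert size on an extendable region: LENGTH_EXCEED
  ep_short <- extension_params(Lmax = 150)
  ctg2 <- extend_seed(seed, mate, w$index, ep_short, seed_id = i)
  expect_identical(ctg2$label, "LENGTH_EXCEED")
  expect_gt(ctg2$length, 150)
  # determinism: identical inputs give identical contigs
  a <- extend_seed(seed, mate, w$index, w$ep)
  b <- extend_seed(seed, mate, w$index, w$ep)
  expect_identical(a, b)
  expect_error(extend_seed(seed, mate, w$index, extension_params()), "Lmax")
})
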