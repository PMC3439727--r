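# The contig extension loop: select overlapping reads by fingerprint +
# Hamming verification, cluster them into a consensus policed by
# representation rates, filter/trim the cluster, extend, and stop with one
# of four labels. All contig coordinates exposed by these functions are
# 0-based, matching the I(r)/F(r) convention of the method.

#' Extension parameters
#'
#' Parameters of the contig extension phase. The per-overlap mismatch cap is
#' `delta(l) = floor(M * l / read_len)` unless a constant `delta` is given.
#' Representation-rate thresholds must satisfy `0.25 <= T1 < T2 < 1`: a
#' consensus column with rate `pi <= T1` is non-represented (every covering
#' read is cut just before it), `T1 < pi <= T2` is low-represented (reads
#' disagreeing with the consensus there are discarded), `pi > T2` is
#' high-represented.
#'
#' @param L Minimum overlap length (bases).
#' @param Delta Maximum shift; overlaps of length `l` in `[L, L + Delta]`
#'   are considered.
#' @param m Minimum number of reads required to compute a consensus.
#' @param T1,T2 Representation-rate thresholds (non/low/high-represented).
#' @param M Mismatch cap for the mate check, and numerator of the default
#'   overlap mismatch rule.
#' @param read_len Average read length, denominator of the delta rule.
#' @param delta Optional constant overlap mismatch cap overriding the rule.
#' @param Lmax Maximum contig length before the extension is abandoned
#'   (LENGTH_EXCEED); typically maximum insert size plus a tolerance.
#' @return A list of class `ext_params`.
#' @export
extension_params <- function(L = 50L, Delta = 40L, m = 2L, T1 = 0.6, T2 = 0.9,
                             M = 10L, read_len = 100L, delta = NULL, Lmax = NULL) {
  stopifnot(L >= 1L, Delta >= 0L, m >= 1L, M >= 0L, read_len >= 1L)
  if (!(T1 >= 0.25 && T1 < T2 && T2 < 1))
    stop("representation thresholds must satisfy 0.25 <= T1 < T2 < 1")
  if (!is.null(delta)) stopifnot(delta >= 0)
  delta_fun <- if (is.null(delta)) {
    force(M); force(read_len)
    function(l) floor(M * l / read_len)
  } else {
    force(delta)
    function(l) rep(delta, length(l))
  }
  structure(
    list(L = as.integer(L), Delta = as.integer(Delta), m = as.integer(m),
         T1 = T1, T2 = T2, M = as.integer(M), read_len = as.integer(read_len),
         delta = delta, delta_fun = delta_fun,
         Lmax = if (is.null(Lmax)) Inf else Lmax),
    class = "ext_params"
  )
}

#' Start and end position of an overlapping read on the contig
#'
#' A read whose prefix overlaps the `l`-suffix of a contig of length
#' `contig_len` is placed at `I = contig_len - l` and ends at
#' `F = I + read_len - 1` (0-based contig coordinates; `F` beyond the contig
#' end is the useful case, since that tail is the candidate extension).
#'
#' @param contig_len Contig length `|S|`.
#' @param l Overlap length, at most `contig_len`.
#' @param read_len Length of the overlapping read.
#' @return Named numeric vector `c(I = ..., F = ...)`.
#' @export
#' @examples
#' overlap_positions(18, 8, 11)  # I = 10, F = 20
overlap_positions <- function(contig_len, l, read_len) {
  if (l > contig_len) stop("overlap length l = ", l, " exceeds contig length ", contig_len)
  I <- contig_len - l
  c(I = I, F = I + read_len - 1)
}

# effective end positions of an overlap set
ov_end <- function(ov) ov$I + ov$eff_len - 1L

empty_overlaps <- function() {
  structure(list(n = 0L, read_id = integer(0), is_rc = logical(0), l = integer(0),
                 I = integer(0), len = integer(0), eff_len = integer(0),
                 mism = integer(0), seqs = list()),
            class = "overlap_set")
}

ov_subset <- function(ov, keep) {
  structure(list(n = length(keep), read_id = ov$read_id[keep], is_rc = ov$is_rc[keep],
                 l = ov$l[keep], I = ov$I[keep], len = ov$len[keep],
                 eff_len = ov$eff_len[keep], mism = ov$mism[keep],
                 seqs = ov$seqs[keep]),
            class = "overlap_set")
}

#' @export
print.overlap_set <- function(x, ...) {
  cat("overlap_set with", x$n, "reads\n")
  if (x$n > 0)
    print(data.frame(read_id = x$read_id, is_rc = x$is_rc, l = x$l, I = x$I,
                     F = ov_end(x), mism = x$mism, eff_len = x$eff_len))
  invisible(x)
}

#' Verified overlaps between a contig suffix and the indexed reads
#'
#' For every overlap length `l` in `[L, L + Delta]`, shortlists candidates
#' via the fingerprint index and keeps each read whose oriented `l`-prefix
#' matches the contig's `l`-suffix with at most `delta(l)` mismatches
#' (Hamming). A read qualifying at several lengths is kept once, at the
#' largest valid `l`.
#'
#' @param S_codes Contig as integer base codes.
#' @param index A `read_index` built with the same `L`.
#' @param params An `ext_params` object.
#' @param exclude Optional integer read ids never returned (e.g. the seed
#'   pair itself, when self-evidence is not wanted). Default none.
#' @return An `overlap_set`: parallel vectors `read_id`, `is_rc`, `l`, `I`
#'   (0-based start), `len`, `eff_len` (equal to `len` before trimming),
#'   `mism`, and the oriented code vectors in `seqs`.
#' @export
verify_overlaps <- function(S_codes, index, params, exclude = integer(0)) {
  stopifnot(inherits(index, "read_index"), inherits(params, "ext_params"))
  if (index$L != params$L)
    stop("index L (", index$L, ") and extension params L (", params$L, ") differ")
  n_S <- length(S_codes)
  ls <- params$L:(params$L + params$Delta)
  ls <- ls[ls <= n_S]
  if (length(ls) == 0L) return(empty_overlaps())

  per_l <- lapply(ls, function(l) query_entries(index, S_codes, l, params$Delta))
  nhits <- vapply(per_l, function(h) length(h$read_id), 0L)
  if (sum(nhits) == 0L) return(empty_overlaps())
  cand_id <- unlist(lapply(per_l, `[[`, "read_id"), use.names = FALSE)
  cand_rc <- unlist(lapply(per_l, `[[`, "is_rc"), use.names = FALSE)
  cand_l <- rep(ls, nhits)

  ord <- order(-cand_l)                      # largest overlap first
  cand_id <- cand_id[ord]; cand_rc <- cand_rc[ord]; cand_l <- cand_l[ord]
  caps <- params$delta_fun(cand_l)

  accepted <- new.env(hash = TRUE)
  keep <- integer(0); keep_mism <- integer(0)
  for (i in seq_along(cand_id)) {
    id <- cand_id[i]
    if (id %in% exclude) next
    l <- cand_l[i]
    if (l > index$lens[id]) next             # read too short for this overlap
    key <- as.character(2 * id + cand_rc[i])
    if (!is.null(accepted[[key]])) next
    ori <- oriented_codes(index, id, cand_rc[i])
    mism <- sum(ori[seq_len(l)] != S_codes[(n_S - l + 1L):n_S])
    if (mism <= caps[i]) {
      accepted[[key]] <- TRUE
      keep <- c(keep, i)
      keep_mism <- c(keep_mism, mism)
    }
  }
  if (length(keep) == 0L) return(empty_overlaps())

  id <- cand_id[keep]; rc <- cand_rc[keep]; l <- cand_l[keep]
  lens <- index$lens[id]
  structure(
    list(n = length(keep), read_id = id, is_rc = rc, l = l,
         I = as.integer(n_S - l), len = lens, eff_len = lens,
         mism = as.integer(keep_mism),
         seqs = lapply(seq_along(id), function(j) oriented_codes(index, id[j], rc[j]))),
    class = "overlap_set")
}

#' Consensus window bounds
#'
#' The consensus starts at the leftmost overlap start, `I_C = min I(r)`, and
#' ends at the rightmost position `F_C = F(r)` still supported by at least
#' `m` overlaps (`|{r': F(r') >= F(r)}| >= m`). Returns `NULL` (the halt
#' signal) when there are no overlaps, fewer than `m`, or when `F_C` does
#' not exceed the contig's last position `S_len - 1`.
#'
#' @param overlaps An `overlap_set` (effective, possibly trimmed, ends are
#'   used).
#' @param m Minimum read support.
#' @param S_len Current contig length; pass 0 to skip the
#'   must-exceed-contig check.
#' @return `list(I_C, F_C)` or `NULL`.
#' @export
consensus_bounds <- function(overlaps, m, S_len = 0L) {
  if (overlaps$n < m) return(NULL)
  ends <- sort(ov_end(overlaps), decreasing = TRUE)
  F_C <- ends[m]                             # m-th largest effective end
  if (F_C <= S_len - 1L) return(NULL)
  list(I_C = min(overlaps$I), F_C = as.integer(F_C))
}

#' Consensus columns over a window
#'
#' For every contig position `j` in `[I_C, F_C]` counts the characters
#' contributed by the overlapping reads (their oriented, effective
#' sequences), picks the majority character, and computes the
#' representation rate `pi = max count / depth`. Ties are broken by the
#' character contributed at `j` by the earliest read under the fixed
#' ordering (ascending `I(r)`, then position in the overlap set). Columns
#' with zero depth take `pi = 0` (non-represented) and fall back to the
#' contig's own character when `fallback` is supplied.
#'
#' @param overlaps An `overlap_set`.
#' @param I_C,F_C Window bounds (0-based contig coordinates).
#' @param T1,T2 Representation thresholds classifying each column as
#'   `"non"` (`pi <= T1`), `"low"` (`T1 < pi <= T2`) or `"high"`.
#' @param fallback Optional contig code vector used for zero-depth columns.
#' @return A list of class `consensus_cols`: `I_C`, `F_C`, `counts` (4 x
#'   ncol matrix), `cons` (consensus base codes), `depth`, `pi`, `klass`.
#' @export
build_consensus <- function(overlaps, I_C, F_C, T1 = 0.6, T2 = 0.9, fallback = NULL) {
  stopifnot(F_C >= I_C)
  k <- F_C - I_C + 1L
  counts <- matrix(0L, nrow = 4L, ncol = k)
  ends <- ov_end(overlaps)
  for (i in seq_len(overlaps$n)) {
    lo <- max(overlaps$I[i], I_C); hi <- min(ends[i], F_C)
    if (lo > hi) next
    rel <- (lo - I_C + 1L):(hi - I_C + 1L)               # column index in window
    off <- (lo - overlaps$I[i] + 1L):(hi - overlaps$I[i] + 1L)  # position in read
    ch <- overlaps$seqs[[i]][off]
    idx <- cbind(ch + 1L, rel)
    counts[idx] <- counts[idx] + 1L
  }
  depth <- as.integer(colSums(counts))
  mx <- pmax(counts[1L, ], counts[2L, ], counts[3L, ], counts[4L, ])
  cons <- max.col(t(counts), ties.method = "first") - 1L

  # read-based tie-break where several characters attain the max count
  ties <- which(depth > 0L & colSums(counts == rep(mx, each = 4L)) > 1L)
  if (length(ties) > 0L) {
    rank_order <- order(overlaps$I, seq_len(overlaps$n))
    for (jr in ties) {
      j_abs <- I_C + jr - 1L
      for (i in rank_order) {
        if (overlaps$I[i] <= j_abs && ends[i] >= j_abs) {
          ch <- overlaps$seqs[[i]][j_abs - overlaps$I[i] + 1L]
          if (counts[ch + 1L, jr] == mx[jr]) { cons[jr] <- ch; break }
        }
      }
    }
  }

  if (!is.null(fallback)) {
    z <- which(depth == 0L)
    z_in <- z[I_C + z - 1L <= length(fallback) - 1L]
    if (length(z_in) > 0L) cons[z_in] <- fallback[I_C + z_in]   # 0-based -> 1-based
  }

  pi <- ifelse(depth > 0L, mx / depth, 0)
  klass <- ifelse(pi <= T1, "non", ifelse(pi <= T2, "low", "high"))
  structure(list(I_C = as.integer(I_C), F_C = as.integer(F_C), counts = counts,
                 cons = cons, depth = depth, pi = pi, klass = klass),
            class = "consensus_cols")
}

#' @export
print.consensus_cols <- function(x, ...) {
  cat("consensus over contig columns [", x$I_C, ", ", x$F_C, "]: ",
      dna_string(x$cons), "\n", sep = "")
  invisible(x)
}

#' Filter and trim an overlap set against its consensus
#'
#' A read disagreeing with the consensus character at any low-represented
#' column it covers (`T1 < pi <= T2`) is discarded. Every surviving read
#' covering a non-represented column (`pi <= T1`) is cut just before its
#' first such column, regardless of whether it matches the consensus there;
#' reads trimmed to length zero are dropped.
#'
#' @param overlaps The `overlap_set` the consensus was built from.
#' @param cons A `consensus_cols` object.
#' @return A list: `survivors` (trimmed `overlap_set`), `dropped` and
#'   `trimmed` (indices into the input set).
#' @export
filter_and_trim <- function(overlaps, cons) {
  ends <- ov_end(overlaps)
  dropped <- logical(overlaps$n)
  trimmed <- logical(overlaps$n)
  eff <- overlaps$eff_len

  low_abs <- which(cons$klass == "low") + cons$I_C - 1L     # absolute columns
  non_abs <- which(cons$klass == "non") + cons$I_C - 1L

  for (i in seq_len(overlaps$n)) {
    lo <- max(overlaps$I[i], cons$I_C); hi <- min(ends[i], cons$F_C)
    if (lo > hi) next
    lows <- low_abs[low_abs >= lo & low_abs <= hi]
    if (length(lows) > 0L) {
      ch <- overlaps$seqs[[i]][lows - overlaps$I[i] + 1L]
      if (any(ch != cons$cons[lows - cons$I_C + 1L])) { dropped[i] <- TRUE; next }
    }
    nons <- non_abs[non_abs >= lo & non_abs <= hi]
    if (length(nons) > 0L) {
      j_not <- min(nons)
      new_len <- j_not - overlaps$I[i]
      if (new_len <= 0L) dropped[i] <- TRUE
      else if (new_len < eff[i]) { eff[i] <- as.integer(new_len); trimmed[i] <- TRUE }
    }
  }

  keep <- which(!dropped)
  out <- ov_subset(overlaps, keep)
  out$eff_len <- eff[keep]
  list(survivors = out, dropped = which(dropped), trimmed = which(trimmed & !dropped))
}

#' One extension of the contig from a filtered overlap set
#'
#' Recomputes the consensus bounds over the survivors (at least `m` reads
#' must support the rightmost kept position) and, if the new consensus
#' exceeds the contig's right end, replaces the contig suffix from
#' `I(C_new)` on with the consensus string. Returns the halt signal
#' otherwise.
#'
#' @param S_codes Current contig as base codes.
#' @param survivors The filtered, trimmed `overlap_set`.
#' @param params An `ext_params` object.
#' @return `list(status = "extended", S_new, I_C, F_C, cons)` or
#'   `list(status = "halt")`.
#' @export
extend_contig <- function(S_codes, survivors, params) {
  bounds <- consensus_bounds(survivors, params$m, length(S_codes))
  if (is.null(bounds)) return(list(status = "halt"))
  cons <- build_consensus(survivors, bounds$I_C, bounds$F_C,
                          params$T1, params$T2, fallback = S_codes)
  S_new <- c(S_codes[seq_len(bounds$I_C)], cons$cons)
  list(status = "extended", S_new = S_new, I_C = bounds$I_C, F_C = bounds$F_C,
       cons = cons)
}

#' Scan a contig for the seed's mate
#'
#' Slides the oriented mate along the contig from position `from` (0-based)
#' and returns the first position where the Hamming distance is at most
#' `M`, or `NULL`. Positions before `from` are assumed already checked (the
#' scan is performed on the fly during extension and never re-checks).
#'
#' @param S_codes Contig base codes.
#' @param mate_codes Mate base codes, already oriented as it must appear on
#'   the contig strand.
#' @param M Maximum mismatches.
#' @param from First position to check (0-based; default 0).
#' @return The 0-based match position, or `NULL` if absent.
#' @export
mate_check <- function(S_codes, mate_codes, M, from = 0L) {
  lm <- length(mate_codes)
  last <- length(S_codes) - lm
  if (last < from) return(NULL)
  for (p in from:last) {
    if (sum(S_codes[(p + 1L):(p + lm)] != mate_codes) <= M) return(p)
  }
  NULL
}

#' One full extension step (Steps 1-4)
#'
#' Runs overlap selection, consensus construction, filtering/trimming, and
#' the final consensus extension on the current contig. The status
#' distinguishes the two local stop criteria: `"no_more"` when the raw
#' overlap set already fails to extend the contig (stop criterion i), and
#' `"repeat"` when a viable raw set fails only after consensus-based
#' filtering (stop criterion ii, the repeat signature).
#'
#' @param S_codes Current contig base codes.
#' @param index A `read_index`.
#' @param params An `ext_params` object.
#' @param exclude Read ids excluded from overlaps (see [verify_overlaps()]).
#' @return A list with `status` (`"extended"`, `"no_more"`, `"repeat"`) and,
#'   when extended, `S_new`; the step ingredients (`overlaps`, `cons`,
#'   `dropped`, `trimmed`, `survivors`, `I_C`, `F_C`) are always returned
#'   for inspection.
#' @export
extend_step <- function(S_codes, index, params, exclude = integer(0)) {
  ov <- verify_overlaps(S_codes, index, params, exclude = exclude)
  bounds <- consensus_bounds(ov, params$m, length(S_codes))
  if (is.null(bounds))
    return(list(status = "no_more", overlaps = ov))
  cons <- build_consensus(ov, bounds$I_C, bounds$F_C, params$T1, params$T2,
                          fallback = S_codes)
  ft <- filter_and_trim(ov, cons)
  ext <- extend_contig(S_codes, ft$survivors, params)
  if (ext$status != "extended")
    return(list(status = "repeat", overlaps = ov, cons = cons,
                dropped = ft$dropped, trimmed = ft$trimmed, survivors = ft$survivors))
  list(status = "extended", S_new = ext$S_new, overlaps = ov, cons = cons,
       dropped = ft$dropped, trimmed = ft$trimmed, survivors = ft$survivors,
       I_C = ext$I_C, F_C = ext$F_C)
}

#' Extend a seed read until its mate is found
#'
#' The kernel loop: the contig is initialized with the seed and repeatedly
#' extended by [extend_step()]; after every extension the (oriented) mate is
#' searched in the newly exposed contig positions. The extension halts with
#' one of four labels: `MATE_FOUND` (the certificate of correctness),
#' `NO_MORE_EXTENSION` (overlap/coverage exhaustion), `REPEAT_FOUND`
#' (consensus collapse after filtering), or `LENGTH_EXCEED` (the contig
#' outgrew `Lmax` without meeting the mate).
#'
#' @param seed Seed read: DNA string or code vector.
#' @param mate Seed's mate, already oriented as it must appear on the contig
#'   strand: DNA string or code vector.
#' @param index A `read_index` over the extension library.
#' @param params An `ext_params` object with finite `Lmax`.
#' @param seed_id Optional identifier stored on the result.
#' @param exclude Read ids excluded from the overlap search.
#' @return An object of class `mf_contig`: list with `seq` (character),
#'   `seed_id`, `label`, `mate_pos` (0-based or `NA`), `steps`, `length`.
#' @export
extend_seed <- function(seed, mate, index, params, seed_id = NA, exclude = integer(0)) {
  if (is.character(seed)) seed <- dna_codes(seed)
  if (is.character(mate)) mate <- dna_codes(mate)
  if (!is.finite(params$Lmax))
    stop("extend_seed requires a finite Lmax (maximum contig length)")

  S <- seed
  steps <- 0L
  label <- NA_character_
  mate_pos <- NA_integer_
  checked_to <- -1L

  p <- mate_check(S, mate, params$M, from = 0L)
  if (!is.null(p)) {
    label <- "MATE_FOUND"; mate_pos <- p
  } else {
    checked_to <- length(S) - length(mate)   # may be < 0 when mate longer
    repeat {
      st <- extend_step(S, index, params, exclude = exclude)
      if (st$status == "no_more") { label <- "NO_MORE_EXTENSION"; break }
      if (st$status == "repeat") { label <- "REPEAT_FOUND"; break }
      S <- st$S_new
      steps <- steps + 1L
      p <- mate_check(S, mate, params$M, from = max(checked_to + 1L, 0L))
      checked_to <- length(S) - length(mate)
      if (!is.null(p)) { label <- "MATE_FOUND"; mate_pos <- p; break }
      if (length(S) > params$Lmax) { label <- "LENGTH_EXCEED"; break }
    }
  }

  structure(list(seq = dna_string(S), seed_id = seed_id, label = label,
                 mate_pos = mate_pos, steps = steps, length = length(S)),
            class = "mf_contig")
}

#' @export
print.mf_contig <- function(x, ...) {
  cat("contig [", x$label, "] len=", x$length, " steps=", x$steps,
      " mate_pos=", ifelse(is.na(x$mate_pos), "NA", x$mate_pos), "\n", sep = "")
  invisible(x)
}
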