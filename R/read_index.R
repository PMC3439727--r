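# Fingerprint-keyed index over a read set. Every usable read contributes two
# entries: one for its forward orientation (window at read position 0) and
# one for its reverse complement (window at position L - b, so that the
# window always falls inside the oriented read's L-prefix whatever the
# overlap length). Buckets live in an environment hashed on the fingerprint
# residue; each entry encodes (read id, orientation) as 2*id + is_rc.

#' Build a fingerprint index over a read library
#'
#' Indexes every read in both orientations for suffix-prefix overlap
#' candidate lookup. Reads shorter than the minimum overlap length `L`, or
#' containing non-ACGT characters, are excluded and counted in the returned
#' statistics.
#'
#' @param reads Character vector of read sequences.
#' @param params Fingerprint parameters from [fingerprint_params()]; requires
#'   `b <= L`.
#' @param L Minimum overlap length (bases). Window position for
#'   reverse-complemented entries is `L - b`.
#' @return An object of class `read_index`: a list with the bucket
#'   environment, per-read code vectors in both orientations, read lengths,
#'   and exclusion statistics.
#' @export
build_read_index <- function(reads, params = fingerprint_params(), L = 50L) {
  stopifnot(is.character(reads), inherits(params, "fp_params"))
  L <- as.integer(L)
  if (params$b > L) stop("fingerprint window b = ", params$b, " exceeds minimum overlap L = ", L)

  n <- length(reads)
  fwd <- vector("list", n)
  rc <- vector("list", n)
  lens <- integer(n)
  ok <- logical(n)
  n_nonacgt <- 0L
  for (i in seq_len(n)) {
    codes <- tryCatch(dna_codes(reads[[i]]), error = function(e) NULL)
    if (is.null(codes)) {
      n_nonacgt <- n_nonacgt + 1L
      next
    }
    lens[i] <- length(codes)
    if (lens[i] < L) next
    fwd[[i]] <- codes
    rc[[i]] <- revcomp_codes(codes)
    ok[i] <- TRUE
  }
  n_short <- n - sum(ok) - n_nonacgt

  idx <- which(ok)
  env <- new.env(hash = TRUE, size = max(2L * length(idx), 16L))
  if (length(idx) > 0L) {
    fp_f <- vapply(idx, function(i) fingerprint(fwd[[i]], 0L, params), numeric(1))
    fp_r <- vapply(idx, function(i) fingerprint(rc[[i]], L - params$b, params), numeric(1))
    entries <- c(2 * idx, 2 * idx + 1)        # even: forward, odd: reverse-complement
    keys <- as.character(c(fp_f, fp_r))
    grouped <- split(entries, keys)
    list2env(grouped, envir = env)
  }

  structure(
    list(env = env, params = params, L = L, n_reads = n, n_indexed = length(idx),
         n_short = n_short, n_nonacgt = n_nonacgt,
         fwd = fwd, rc = rc, lens = lens),
    class = "read_index"
  )
}

#' @export
print.read_index <- function(x, ...) {
  cat("read_index:", x$n_indexed, "reads indexed (2 entries each),",
      x$n_short, "too short,", x$n_nonacgt, "non-ACGT; L =", x$L,
      "b =", x$params$b, "\n")
  invisible(x)
}

# total number of index entries (2 per indexed read); used by invariants
index_entry_count <- function(index) {
  sum(vapply(ls(index$env, all.names = TRUE),
             function(k) length(get(k, envir = index$env)), numeric(1)))
}

#' Shortlist reads that may overlap a contig suffix
#'
#' Returns the candidate set R(S, l): reads whose oriented prefix may match
#' the contig's `l`-suffix, shortlisted by fingerprint equality on the
#' orientation-specific b-window. Forward-oriented reads are matched against
#' the contig window starting at `|S| - l`; reverse-complemented ones
#' against the window starting at `|S| - l + L - b`. The set is a superset
#' of all reads whose oriented l-prefix matches the suffix exactly on the
#' b-window; membership does not imply a true overlap.
#'
#' @param index A `read_index`.
#' @param S_codes Contig as an integer code vector.
#' @param l Overlap length, in `[L, L + Delta]`.
#' @param Delta Maximum shift (upper bound check); `Inf` to skip.
#' @return A data.frame with columns `read_id` and `is_rc`.
#' @export
query_candidates <- function(index, S_codes, l, Delta = Inf) {
  hits <- query_entries(index, S_codes, l, Delta)
  data.frame(read_id = hits$read_id, is_rc = hits$is_rc)
}

# fast internal form of query_candidates returning a plain list
query_entries <- function(index, S_codes, l, Delta = Inf) {
  L <- index$L
  if (l < L || l > L + Delta)
    stop("overlap length l = ", l, " outside [L, L + Delta] = [", L, ", ", L + Delta, "]")
  if (length(S_codes) < l)
    return(list(read_id = integer(0), is_rc = logical(0)))
  b <- index$params$b
  y_f <- length(S_codes) - l            # 0-based window starts
  y_r <- y_f + L - b
  keys <- as.character(fingerprint_windows(S_codes, c(y_f, y_r), index$params))
  hits_f <- index$env[[keys[1L]]]
  hits_r <- index$env[[keys[2L]]]
  fwd_ids <- if (is.null(hits_f)) integer(0) else hits_f[hits_f %% 2 == 0] / 2
  rc_ids <- if (is.null(hits_r)) integer(0) else (hits_r[hits_r %% 2 == 1] - 1) / 2
  list(read_id = as.integer(c(fwd_ids, rc_ids)),
       is_rc = rep(c(FALSE, TRUE), c(length(fwd_ids), length(rc_ids))))
}

# oriented code vector of a read as it would lie on the contig strand
oriented_codes <- function(index, read_id, is_rc) {
  if (is_rc) index$rc[[read_id]] else index$fwd[[read_id]]
}
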