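# Independent oracles: deliberately naive implementations used to freeze
# expected values. None of them share code paths with the package.

# per-pair energies, duplicated from the model definition on purpose
oracle_pair_e <- function(a, b) {
  key <- paste0(a, b)
  switch(key,
         GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1, NA_real_)
}

# exhaustive minimum energy over all non-crossing structures with hairpin
# loops >= 3 nt; plain recursion (decomposes on the 5'-most base, unlike
# the package DP which decomposes on the 3' end of the interval)
oracle_min_energy <- function(seq) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(s)
  memo <- new.env(hash = TRUE)
  best <- function(i, j) {
    if (j - i < 4) return(0)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    e <- best(i + 1, j)                      # i unpaired
    for (k in (i + 4):j) {
      pe <- oracle_pair_e(s[i], s[k])
      if (is.na(pe)) next
      inner <- best(i + 1, k - 1)
      outer <- if (k < j) best(k + 1, j) else 0
      e <- min(e, pe + inner + outer)
    }
    memo[[key]] <- e
    e
  }
  best(1, n)
}

# brute-force adapter locator mirroring the contract, written independently
oracle_adapter_pos <- function(read, adapter, max_mm, min_overlap = 6) {
  r <- strsplit(read, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  for (i in seq_along(r)) {
    cmp <- min(length(a), length(r) - i + 1)
    if (cmp < min_overlap) break
    mm <- sum(r[i:(i + cmp - 1)] != a[1:cmp])
    if (mm <= max_mm) return(i - 1L)   # insert length
  }
  -1L
}

# quadratic placement scan: every offset of `read` on `ref` with its
# mismatch count (both on the RNA alphabet)
oracle_placements <- function(read, ref) {
  nr <- nchar(read); nf <- nchar(ref)
  if (nr > nf) {
    return(data.frame(start = integer(0), mismatches = integer(0)))
  }
  r <- strsplit(read, "")[[1]]
  do.call(rbind, lapply(seq_len(nf - nr + 1), function(s) {
    w <- strsplit(substr(ref, s, s + nr - 1), "")[[1]]
    data.frame(start = s, mismatches = sum(r != w))
  }))
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGU", "UGCA", strsplit(s, "")[[1]])), collapse = "")
}

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
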