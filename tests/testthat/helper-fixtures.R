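# In-code fixtures shared across test files.

# A deterministic two-precursor reference with hand-placed matures.
# pre-A: 25 bp stem + 6 nt loop, annotated at 5p (3p arm free for novel
# candidates). pre-B: annotated at 3p.
tiny_reference <- function() {
  set.seed(421)
  mk <- function(stem_len, loop_len) {
    arm5 <- rand_rna(stem_len)
    loop <- rand_rna(loop_len)
    paste0(arm5, loop, oracle_revcomp(arm5))
  }
  pA <- mk(25, 6)
  pB <- mk(27, 8)
  precursors <- data.frame(id = c("pre-A", "pre-B"),
                           sequence = c(pA, pB), stringsAsFactors = FALSE)
  matures <- data.frame(
    precursor_id = c("pre-A", "pre-B"),
    mature_id = c("mirA-5p", "mirB-3p"),
    arm = c("5p", "3p"),
    start = c(2L, 27L + 8L + 3L),
    end = c(23L, 27L + 8L + 3L + 21L),
    stringsAsFactors = FALSE)
  precursor_reference(precursors, matures)
}

mature_seq <- function(ref, mid) {
  m <- ref$matures[ref$matures$mature_id == mid, ]
  p <- ref$precursors$sequence[ref$precursors$id == m$precursor_id]
  substr(p, m$start, m$end)
}

# substitute one base at `pos` with a different one, deterministically
substitute_base <- function(s, pos) {
  old <- substr(s, pos, pos)
  new <- setdiff(c("A", "C", "G", "U"), old)[1]
  substr(s, pos, pos) <- new
  s
}

# expand a unique table back to individual reads (for idempotence checks)
expand_table <- function(tab) {
  samples <- setdiff(names(tab), "sequence")
  out <- lapply(samples, function(s) rep(tab$sequence, tab[[s]]))
  names(out) <- samples
  out
}

TEST_ADAPTER <- "UGGAAUUCUCGGGUGCCAAGG"
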