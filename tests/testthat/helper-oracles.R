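# Independent oracles, deliberately naive: used to compute expected values,
# never sharing code with the implementation under test.

# apply a (pos, ref, alt) representation to a reference window -> haplotype
apply_to_window <- function(wseq, wstart, pos, ref, alt) {
  i <- pos - wstart + 1
  stopifnot(substr(wseq, i, i + nchar(ref) - 1) == ref)
  paste0(substr(wseq, 1, i - 1), alt,
         substr(wseq, i + nchar(ref), nchar(wseq)))
}

# enumerate every parsimonious representation inside the window that yields
# the same haplotype; return the one with the smallest pos
enumerate_leftmost <- function(wseq, wstart, pos, ref, alt) {
  hap <- apply_to_window(wseq, wstart, pos, ref, alt)
  Lw <- nchar(wseq); Lh <- nchar(hap)
  best <- NULL
  for (p in seq_len(Lw)) {
    for (q in p:Lw) {
      lr <- q - p + 1
      la <- Lh - Lw + lr
      if (la < 1) next
      r <- substr(wseq, p, q)
      a <- substr(hap, p, p + la - 1)
      cand <- paste0(substr(wseq, 1, p - 1), a, substr(wseq, q + 1, Lw))
      if (cand != hap) next
      if (r == a) next
      if (lr > 1 && la > 1 &&
          (substr(r, lr, lr) == substr(a, la, la) ||
           substr(r, 1, 1) == substr(a, 1, 1))) next
      if (is.null(best) || wstart + p - 1 < best$pos)
        best <- list(pos = wstart + p - 1, ref = r, alt = a)
    }
  }
  best
}

# random indel/SNV inside a random window, for property tests
random_windowed_variant <- function() {
  wseq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                collapse = "")
  wstart <- sample(1000:2000, 1)
  kind <- sample(c("snv", "del", "ins"), 1)
  pos <- sample(10:25, 1)
  if (kind == "snv") {
    ref <- substr(wseq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  } else if (kind == "del") {
    len <- sample(1:6, 1)
    ref <- substr(wseq, pos, pos + len)
    alt <- substr(wseq, pos, pos)
  } else {
    ref <- substr(wseq, pos, pos)
    alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                    sample(1:4, 1), replace = TRUE),
                             collapse = ""))
  }
  list(windows = data.frame(contig = "chrT", start = wstart, seq = wseq,
                            stringsAsFactors = FALSE),
       contig = "chrT", pos = wstart + pos - 1, ref = ref, alt = alt)
}

# brute-force allele-call conservation check for decompose: multiset of
# non-missing alt-allele calls per sample, input vs outputs
alt_calls_by_allele <- function(gt_string) {
  parts <- strsplit(gt_string, "[/|]")[[1]]
  parts[parts != "." & parts != "0"]
}
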