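#' Read reference windows
#'
#' A reference window is a contiguous stretch of reference sequence used to
#' left-normalize variants; the pipeline carries windows instead of a whole
#' genome FASTA. The TSV has columns `contig`, `start` (1-based position of
#' the first base) and `seq`.
#'
#' @param path path to a windows TSV.
#' @return data.frame of class `ref_windows`.
#' @export
read_ref_windows <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(contig = "character", start = "integer",
                                        seq = "character"))
  .check(all(c("contig", "start", "seq") %in% names(w)),
         "windows file needs contig/start/seq columns")
  .check(all(nchar(w$seq) > 0L), "empty reference window sequence")
  class(w) <- c("ref_windows", "data.frame")
  w
}

# find a window covering [pos, pos + reflen - 1]; NULL if none
.find_window <- function(windows, contig, pos, reflen) {
  hit <- windows$contig == contig & windows$start <= pos &
    windows$start + nchar(windows$seq) - 1L >= pos + reflen - 1L
  if (!any(hit)) return(NULL)
  windows[which(hit)[1], ]
}

.win_sub <- function(w, from, to) {
  substr(w$seq, from - w$start + 1L, to - w$start + 1L)
}

#' Decompose multiallelic records
#'
#' Splits every record with more than one ALT allele into one biallelic record
#' per ALT, in input ALT order. Genotype allele indices pointing at *other*
#' ALTs are recoded to missing (`.`) rather than to the reference: the sample
#' is known not to carry this ALT on that haplotype only in the sense that we
#' decline to assert a reference call.
#'
#' @param vs a [variant_set()], possibly multiallelic.
#' @return a biallelic [variant_set()].
#' @export
decompose_variants <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  symbolic <- grepl("[][<>]", vs$variants$alt)
  if (any(symbolic))
    stop(sprintf("symbolic allele unsupported: %s",
                 vs$variants$alt[which(symbolic)[1]]), call. = FALSE)
  out_var <- list(); out_gt <- list()
  for (i in seq_len(nrow(vs$variants))) {
    alts <- strsplit(vs$variants$alt[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      row <- vs$variants[i, ]
      row$alt <- alts[k]
      .check(row$ref != row$alt, "ref and alt identical at %s:%d",
             row$contig, row$pos)
      g <- vs$gt[i, , drop = TRUE]
      if (length(vs$samples) > 0L && length(alts) > 1L) {
        g <- vapply(g, function(s) {
          a <- gt_alleles(s)
          sep <- if (isTRUE(attr(a, "phased"))) "|" else "/"
          recoded <- vapply(a, function(ai) {
            if (is.na(ai)) "." else if (ai == 0L) "0"
            else if (ai == k) "1" else "."
          }, character(1))
          paste(recoded, collapse = sep)
        }, character(1), USE.NAMES = FALSE)
      }
      out_var[[length(out_var) + 1L]] <- row
      out_gt[[length(out_gt) + 1L]] <- g
    }
  }
  variants <- do.call(rbind, out_var)
  rownames(variants) <- NULL
  gt <- if (length(vs$samples) > 0L) do.call(rbind, out_gt)
        else matrix(character(), length(out_var), 0)
  variant_set(variants, gt, vs$samples)
}

#' Left-normalize one biallelic variant
#'
#' Produces the parsimonious, left-aligned representation (the vt algorithm):
#' shared trailing bases are trimmed, empty alleles are re-anchored by
#' extending left into the reference window, and shared leading bases are
#' trimmed while both alleles keep at least one base. `N` bases never match
#' anything, so normalization refuses to trim across them.
#'
#' @param contig,pos,ref,alt the variant, VCF-style 1-based.
#' @param windows a `ref_windows` data.frame from [read_ref_windows()].
#' @return list with elements `contig`, `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(contig, pos, ref, alt, windows) {
  pos <- as.integer(pos)
  w <- .find_window(windows, contig, pos, nchar(ref))
  .check(!is.null(w), "no reference window covers %s:%d", contig, pos)
  wref <- .win_sub(w, pos, pos + nchar(ref) - 1L)
  # N matches nothing, not even N
  .check(wref == ref && !grepl("N", ref, fixed = TRUE),
         "reference mismatch at %s:%d (window has %s, record has %s)",
         contig, pos, wref, ref)
  last <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    changed <- FALSE
    if (nchar(ref) > 0L && nchar(alt) > 0L &&
        last(ref) == last(alt) && last(ref) != "N") {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos <= w$start)
        stop(sprintf("window too small: left shift at %s:%d crosses window start",
                     contig, pos), call. = FALSE)
      b <- .win_sub(w, pos - 1L, pos - 1L)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1, 1) == substr(alt, 1, 1) && substr(ref, 1, 1) != "N") {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(contig = contig, pos = pos, ref = ref, alt = alt)
}

#' Left-normalize every record of a variant set
#'
#' @param vs a biallelic [variant_set()] (run [decompose_variants()] first).
#' @param windows a `ref_windows` data.frame.
#' @return a [variant_set()] with normalized coordinates and alleles.
#' @export
normalize_variants <- function(vs, windows) {
  stopifnot(inherits(vs, "variant_set"))
  v <- vs$variants
  for (i in seq_len(nrow(v))) {
    n <- left_normalize(v$contig[i], v$pos[i], v$ref[i], v$alt[i], windows)
    v$pos[i] <- n$pos; v$ref[i] <- n$ref; v$alt[i] <- n$alt
  }
  variant_set(v, vs$gt, vs$samples)
}
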