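#' Read a virtual gene panel
#'
#' The panel directory holds `panel_intervals.tsv` — BED-like, 0-based
#' half-open (`chrom`, `start`, `end`, `gene`) — and `gene_modes.tsv`
#' (`gene`, `modes` as a comma-separated subset of AD/AR/XL). Intervals are
#' merged per gene; every gene must declare at least one inheritance mode.
#' The bundled demo panel is a small stand-in for a full deafness panel (the
#' field maintains curated lists of >200 genes); substitute a full panel by
#' pointing `panel_dir` at your own pair of files.
#'
#' @param panel_dir directory containing the two panel files.
#' @return list of class `gene_panel` with elements `intervals` (data.frame,
#'   0-based half-open) and `modes` (named list gene -> character vector).
#' @export
read_panel <- function(panel_dir) {
  iv <- utils::read.delim(file.path(panel_dir, "panel_intervals.tsv"),
                          stringsAsFactors = FALSE)
  md <- utils::read.delim(file.path(panel_dir, "gene_modes.tsv"),
                          stringsAsFactors = FALSE)
  .check(all(c("chrom", "start", "end", "gene") %in% names(iv)),
         "panel_intervals.tsv needs chrom/start/end/gene")
  .check(all(iv$end > iv$start), "panel interval end must exceed start")
  modes <- lapply(strsplit(md$modes, ","), function(m) {
    m <- trimws(m)
    .check(all(m %in% c("AD", "AR", "XL")), "unknown inheritance mode: %s",
           paste(setdiff(m, c("AD", "AR", "XL")), collapse = ","))
    m
  })
  names(modes) <- md$gene
  .check(all(lengths(modes) >= 1L), "every panel gene needs >= 1 mode")
  # merge overlapping intervals per gene
  out <- do.call(rbind, lapply(split(seq_len(nrow(iv)), iv$gene), function(ix) {
    r <- GenomicRanges::reduce(GenomicRanges::GRanges(
      iv$chrom[ix], IRanges::IRanges(iv$start[ix] + 1L, iv$end[ix])))
    data.frame(chrom = as.character(GenomicRanges::seqnames(r)),
               start = GenomicRanges::start(r) - 1L,
               end = GenomicRanges::end(r),
               gene = iv$gene[ix][1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(list(intervals = out, modes = modes), class = "gene_panel")
}

#' Popmax allele-frequency filter
#'
#' Removes a variant iff its popmax frequency is `>= threshold` (the boundary
#' itself is removed: a variant seen at exactly 1% is common). Variants with
#' no frequency data at all are kept — absence of evidence of commonness.
#'
#' @param annotated data.frame from [attach_annotations()]`$annotated`.
#' @param threshold removal threshold in (0, 1\]; default 0.01.
#' @return list with `kept` and `removed` data.frames.
#' @export
frequency_filter <- function(annotated, threshold = 0.01) {
  .check(is.numeric(threshold) && threshold > 0 && threshold <= 1,
         "MAF threshold must lie in (0, 1]")
  pm <- annotated$popmax_af
  if (is.null(pm)) pm <- rep(0, nrow(annotated))
  drop <- !is.na(pm) & pm >= threshold
  list(kept = annotated[!drop, , drop = FALSE],
       removed = annotated[drop, , drop = FALSE])
}

#' Virtual gene-panel filter
#'
#' Keeps a variant iff its reference span intersects any panel interval
#' (intersection semantics: one overlapping base suffices). Disagreements
#' between the annotated gene symbol and the overlapped panel gene are
#' recorded in the `mismatches` attribute of `kept`, not dropped.
#'
#' @param annotated data.frame of annotated variants.
#' @param panel a `gene_panel` from [read_panel()].
#' @return list with `kept` and `removed` data.frames.
#' @export
panel_filter <- function(annotated, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  if (nrow(panel$intervals) == 0L) {
    warning("empty gene panel: all variants removed")
    return(list(kept = annotated[0, , drop = FALSE], removed = annotated))
  }
  if (nrow(annotated) == 0L)
    return(list(kept = annotated, removed = annotated))
  lev <- unique(c(panel$intervals$chrom, annotated$contig))
  pg <- GenomicRanges::GRanges(factor(panel$intervals$chrom, lev),
                               IRanges::IRanges(panel$intervals$start + 1L,
                                                panel$intervals$end))
  vg <- GenomicRanges::GRanges(factor(annotated$contig, lev),
                               IRanges::IRanges(annotated$pos,
                                                annotated$pos + nchar(annotated$ref) - 1L))
  ov <- GenomicRanges::findOverlaps(vg, pg)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  keep <- sort(unique(qh))
  kept <- annotated[keep, , drop = FALSE]
  mism <- vapply(keep, function(qi) {
    hit_genes <- panel$intervals$gene[sh[qh == qi]]
    if (annotated$gene[qi] %in% hit_genes) NA_character_
    else sprintf("%s annotated %s but overlaps panel gene(s) %s",
                 annotated$key[qi], annotated$gene[qi],
                 paste(unique(hit_genes), collapse = ","))
  }, character(1))
  attr(kept, "mismatches") <- mism[!is.na(mism)]
  list(kept = kept,
       removed = annotated[setdiff(seq_len(nrow(annotated)), keep), , drop = FALSE])
}

#' Two-pass candidate prioritization
#'
#' Pass 1 applies the popmax-frequency filter then the panel filter. If pass 1
#' leaves no candidate for the family, pass 2 falls back to the whole
#' "exome": the frequency-filtered variants genome-wide, flagged
#' `fallback_used`. The per-variant disposition report conserves every input
#' record exactly once.
#'
#' @param annotated data.frame of one family's annotated variants.
#' @param panel a `gene_panel`.
#' @param maf_threshold popmax removal threshold (default 0.01).
#' @return list with `candidates` (data.frame with `fallback` column),
#'   `fallback_used` (flag) and `report` (list of stage counts and
#'   per-variant dispositions).
#' @export
prioritize_two_pass <- function(annotated, panel, maf_threshold = 0.01) {
  ff <- frequency_filter(annotated, maf_threshold)
  pf <- panel_filter(ff$kept, panel)
  fallback <- nrow(pf$kept) == 0L && nrow(ff$kept) > 0L
  candidates <- if (fallback) ff$kept else pf$kept
  candidates$fallback <- rep(fallback, nrow(candidates))
  disposition <- data.frame(key = annotated$key,
                            stage = "kept", stringsAsFactors = FALSE)
  disposition$stage[annotated$key %in% ff$removed$key] <- "removed_maf"
  if (!fallback)
    disposition$stage[annotated$key %in% pf$removed$key] <- "removed_panel"
  report <- list(input = nrow(annotated),
                 after_maf = nrow(ff$kept),
                 after_panel = nrow(pf$kept),
                 fallback_used = fallback,
                 disposition = disposition,
                 gene_mismatches = attr(pf$kept, "mismatches"))
  list(candidates = candidates, fallback_used = fallback, report = report)
}
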