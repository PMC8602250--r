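#' Maximum population allele frequency (popmax)
#'
#' Returns the maximum over the global frequency and every per-population
#' frequency, with the arg-max population label. Absent (NA) entries are
#' distinct from observed zeros and are ignored; if everything is absent or
#' zero the result is `(0, "none")`.
#'
#' @param global_af global allele frequency in \[0, 1\], or NA if absent.
#' @param per_pop named numeric vector of per-population frequencies
#'   (NA allowed).
#' @return list with `af` (numeric) and `population` (label or `"none"`).
#' @export
max_frequency <- function(global_af = NA_real_, per_pop = numeric()) {
  all_f <- c(global = unname(global_af), per_pop)
  known <- all_f[!is.na(all_f)]
  .check(all(known >= 0 & known <= 1), "allele frequency outside [0,1]")
  if (length(known) == 0L || max(known) == 0) return(list(af = 0, population = "none"))
  i <- which.max(known)
  lab <- names(known)[i]
  list(af = unname(known[i]),
       population = if (identical(lab, "global")) "global" else lab)
}

# sidecar per-population column -> printed population label
.pop_labels <- c(af_afr = "African/African-American",
                 af_asj = "Ashkenazi Jewish",
                 af_eur_nf = "European (non-Finnish)",
                 af_amr = "Latino/Admixed American",
                 af_sas = "South Asian")

#' Read an annotation sidecar table
#'
#' The sidecar stands in for a live VEP/gnomAD annotation service: a TSV keyed
#' by the *normalized* representation (`chrom`, `pos`, `ref`, `alt`) carrying
#' gene, transcript, exon, HGVS strings, Sequence Ontology consequence,
#' per-population allele frequencies (`af_global` plus `af_*` columns; NA
#' means the population was not observed, 0 means observed absent), CADD and
#' REVEL scores, rsID, and a curated ACMG evidence string.
#'
#' @param path path to the sidecar TSV.
#' @return data.frame with a `key` column added.
#' @export
read_sidecar <- function(path) {
  sc <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "af_global")
  .check(all(need %in% names(sc)), "sidecar missing columns: %s",
         paste(setdiff(need, names(sc)), collapse = ", "))
  sc$key <- variant_key(sc$chrom, sc$pos, sc$ref, sc$alt)
  .check(!anyDuplicated(sc$key), "duplicate sidecar keys: %s",
         paste(sc$key[duplicated(sc$key)], collapse = ", "))
  sc
}

# popmax over the af_* columns of one sidecar row
.row_popmax <- function(row) {
  pops <- intersect(names(.pop_labels), names(row))
  per <- as.numeric(row[pops])
  names(per) <- .pop_labels[pops]
  max_frequency(as.numeric(row[["af_global"]]), per)
}

#' Attach sidecar annotations to normalized variants
#'
#' Total by construction: every input record lands either in `annotated` or
#' in `unannotated`; nothing is silently dropped. When reference windows are
#' supplied, every sidecar key touched is checked to be already normalized —
#' a right-aligned or non-parsimonious sidecar key is an error, forcing
#' normalization upstream rather than fuzzy matching here.
#'
#' @param vs a normalized biallelic [variant_set()].
#' @param sidecar data.frame from [read_sidecar()].
#' @param windows optional `ref_windows` for sidecar key validation.
#' @return list with `annotated` (data.frame: variant columns + annotations +
#'   `popmax_af`/`popmax_pop`), `unannotated` (data.frame of unmatched
#'   records), and the input `vs`.
#' @export
attach_annotations <- function(vs, sidecar, windows = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  v <- vs$variants
  v$key <- variant_key(v$contig, v$pos, v$ref, v$alt)
  idx <- match(v$key, sidecar$key)
  if (!is.null(windows)) {
    for (j in stats::na.omit(unique(idx))) {
      n <- left_normalize(sidecar$chrom[j], sidecar$pos[j],
                          sidecar$ref[j], sidecar$alt[j], windows)
      if (n$pos != sidecar$pos[j] || n$ref != sidecar$ref[j] ||
          n$alt != sidecar$alt[j])
        stop(sprintf("sidecar key not normalized: %s normalizes to %s",
                     sidecar$key[j],
                     variant_key(n$contig, n$pos, n$ref, n$alt)), call. = FALSE)
    }
  }
  ann <- v[!is.na(idx), , drop = FALSE]
  if (nrow(ann) > 0L) {
    sc <- sidecar[idx[!is.na(idx)], setdiff(names(sidecar),
                                            c("chrom", "pos", "ref", "alt", "key")),
                  drop = FALSE]
    ann <- cbind(ann, sc)
    pm <- lapply(seq_len(nrow(ann)),
                 function(i) .row_popmax(sidecar[idx[!is.na(idx)][i], ]))
    ann$popmax_af <- vapply(pm, `[[`, numeric(1), "af")
    ann$popmax_pop <- vapply(pm, `[[`, character(1), "population")
  }
  rownames(ann) <- NULL
  unann <- v[is.na(idx), , drop = FALSE]
  rownames(unann) <- NULL
  list(annotated = ann, unannotated = unann, vs = vs)
}
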