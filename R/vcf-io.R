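#' Variant set container
#'
#' A light container for biallelic (or not-yet-decomposed multiallelic)
#' variant records with per-sample genotype strings. VCF-facing coordinates
#' are 1-based inclusive throughout.
#'
#' @param variants data.frame with columns `contig`, `pos`, `id`, `ref`, `alt`.
#' @param gt character matrix of genotype strings (`"0/1"`, `"1"`, `"./."`),
#'   one row per variant, one column per sample. May have zero columns.
#' @param samples character vector of sample ids, matching `ncol(gt)`.
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(variants, gt = NULL, samples = character()) {
  stopifnot(is.data.frame(variants),
            all(c("contig", "pos", "ref", "alt") %in% names(variants)))
  if (is.null(variants$id)) variants$id <- NA_character_
  variants$pos <- as.integer(variants$pos)
  .check(all(variants$pos >= 1L), "variant pos must be >= 1")
  .check(all(nchar(variants$ref) > 0L) && all(nchar(variants$alt) > 0L),
         "ref and alt alleles must be non-empty")
  if (is.null(gt)) gt <- matrix(character(), nrow(variants), 0)
  gt <- as.matrix(gt)
  storage.mode(gt) <- "character"
  .check(nrow(gt) == nrow(variants), "gt rows must match variant rows")
  .check(ncol(gt) == length(samples), "gt columns must match samples")
  colnames(gt) <- samples
  structure(list(variants = variants[, c("contig", "pos", "id", "ref", "alt")],
                 gt = gt, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d record(s), %d sample(s)\n",
              nrow(x$variants), length(x$samples)))
  print(utils::head(cbind(x$variants, x$gt), 10))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$variants)

# split a genotype string into integer allele indices (NA for ".")
# attr "phased" records the | separator
gt_alleles <- function(g) {
  if (is.na(g) || g == "." || g == "") {
    return(structure(NA_integer_, phased = FALSE))
  }
  phased <- grepl("|", g, fixed = TRUE)
  parts <- strsplit(g, "[/|]")[[1]]
  structure(ifelse(parts == ".", NA_integer_, suppressWarnings(as.integer(parts))),
            phased = phased)
}

# alt-allele dosage of one genotype string for allele index 1; NA if fully missing
gt_dosage <- function(g) {
  a <- gt_alleles(g)
  if (all(is.na(a))) return(NA_integer_)
  sum(a == 1L, na.rm = TRUE)
}

#' Read a VCF file into a variant set
#'
#' Parsing is delegated to \pkg{vcfR}; a light pre-scan reports malformed body
#' lines by line number before handing off. Only the GT field is retained.
#'
#' @param path path to a VCF 4.x file (plain text).
#' @return a [variant_set()].
#' @export
read_vcf <- function(path) {
  .check(file.exists(path), "VCF not found: %s", path)
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  hdr <- grep("^#CHROM\t", lines)
  .check(length(hdr) == 1L, "VCF header line (#CHROM) missing in %s", path)
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[2]))))
      stop(sprintf("malformed VCF line %d in %s", i, path), call. = FALSE)
  }
  if (length(body_idx) == 0L) {
    samples <- setdiff(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]],
                       c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT"))
    return(variant_set(data.frame(contig = character(), pos = integer(),
                                  id = character(), ref = character(),
                                  alt = character(), stringsAsFactors = FALSE),
                       matrix(character(), 0, length(samples)), samples))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # matrix CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO
  variants <- data.frame(contig = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = ifelse(fix[, "ID"] %in% c(".", NA), NA_character_, fix[, "ID"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  if (ncol(v@gt) > 1L) {
    samples <- colnames(v@gt)[-1]
    fmt <- v@gt[, 1]
    gt <- v@gt[, -1, drop = FALSE]
    for (i in seq_len(nrow(gt))) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
      gi <- match("GT", keys)
      .check(!is.na(gi), "VCF record %d lacks GT in FORMAT", i)
      gt[i, ] <- vapply(strsplit(gt[i, ], ":", fixed = TRUE),
                        function(x) if (length(x) < gi) NA_character_ else x[gi],
                        character(1))
    }
    gt[is.na(gt)] <- "./."  # vcfR reads fully missing genotypes as NA
    variant_set(variants, gt, samples)
  } else {
    variant_set(variants)
  }
}

#' Write a variant set as a VCF 4.2 file
#'
#' Emits a minimal plain-text VCF (GT-only FORMAT) that round-trips through
#' [read_vcf()]. The header carries the package name and version but no
#' timestamp, so regeneration under one seed is byte-identical.
#'
#' @param vs a [variant_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=audiogene-",
                  as.character(utils::packageVersion("audiogene"))),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_samples <- length(vs$samples) > 0L
  if (has_samples) cols <- c(cols, "FORMAT", vs$samples)
  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(vs$variants) > 0L) {
    v <- vs$variants
    body <- paste(v$contig, v$pos, ifelse(is.na(v$id), ".", v$id),
                  v$ref, v$alt, ".", ".", ".", sep = "\t")
    if (has_samples) {
      gtcols <- apply(vs$gt, 1, paste, collapse = "\t")
      body <- paste(body, "GT", gtcols, sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
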