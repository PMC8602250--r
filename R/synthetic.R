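#' Load the transcribed clinical variant fixture
#'
#' The bundled fixture transcribes the 17 published variant observations (16
#' distinct variants across 15 carrier families; one TECTA missense recurs in
#' two families) with genomic coordinates, alleles, zygosities, population
#' frequencies, CADD/REVEL scores and curated strength-modified ACMG
#' evidence strings. Indel alleles carry synthetic flanking context (the
#' publication prints coordinates, not sequence); their windows live in
#' `ref_contexts.tsv`. Structural integrity is validated on every load:
#' wrong row/variant counts, an unparseable evidence string, or a printed
#' class that the rule engine cannot reproduce all raise an integrity error.
#'
#' @return data.frame of fixture rows.
#' @export
load_fixture <- function() {
  path <- system.file("extdata", "table2_variants.tsv", package = "audiogene")
  fx <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check(nrow(fx) == 17L, "fixture integrity: expected 17 rows, got %d", nrow(fx))
  fx$key <- variant_key(fx$contig, fx$pos, fx$ref, fx$alt)
  .check(length(unique(fx$key)) == 16L,
         "fixture integrity: expected 16 distinct variants")
  printed_map <- c("Pathogenic" = "Pathogenic",
                   "Likely pathogenic" = "LikelyPathogenic", "VUS" = "VUS")
  for (i in seq_len(nrow(fx))) {
    cls <- combine_rule_based(parse_evidence(fx$evidence[i]))$tier
    .check(identical(cls, unname(printed_map[fx$printed_class[i]])),
           "fixture integrity: row %d classifies %s but prints %s",
           i, cls, fx$printed_class[i])
  }
  fx
}

#' Bundled synthetic reference contexts
#'
#' @return `ref_windows` data.frame for the fixture variants.
#' @export
fixture_ref_windows <- function() {
  read_ref_windows(system.file("extdata", "ref_contexts.tsv",
                               package = "audiogene"))
}

# demo virtual panel: the nine implicated genes plus further deafness genes,
# and a few non-panel "decoy" gene spans used by the generator only
.panel_genes <- function() {
  data.frame(
    gene  = c("TECTA", "DIAPH1", "MYO7A", "TMC1", "COL4A5", "MYO15A", "OTOGL",
              "TMPRSS3", "TSPEAR", "KCNQ4", "EYA4", "POU4F3", "OTOA",
              "SLC26A4", "COL11A2", "CCDC50"),
    chrom = c("Chr11", "Chr5", "Chr11", "Chr9", "ChrX", "Chr17", "Chr12",
              "Chr21", "Chr21", "Chr1", "Chr6", "Chr5", "Chr16",
              "Chr7", "Chr6", "Chr3"),
    start = c(121100000L, 141500000L, 77128000L, 72720000L, 108550000L,
              18120000L, 80200000L, 42350000L, 44450000L, 40784000L,
              133240000L, 146339000L, 21689000L, 107660000L, 33160000L,
              191046000L),
    end   = c(121200000L, 141560000L, 77215000L, 73040000L, 108810000L,
              18190000L, 80340000L, 42420000L, 44520000L, 40817000L,
              133532000L, 146342000L, 21772000L, 107720000L, 33200000L,
              191116000L),
    modes = c("AD", "AD", "AD", "AD", "XL", "AR", "AR",
              "AR", "AR", "AD", "AD", "AD", "AR", "AR", "AD,AR", "AD"),
    stringsAsFactors = FALSE)
}

.offpanel_genes <- function() {
  data.frame(
    gene  = c("TTN", "OBSCN", "MUC16", "FLG", "PCLO"),
    chrom = c("Chr2", "Chr1", "Chr19", "Chr1", "Chr7"),
    start = c(178525000L, 228208000L, 8848000L, 152302000L, 82383000L),
    end   = c(178807000L, 228378000L, 8981000L, 152325000L, 82792000L),
    stringsAsFactors = FALSE)
}

#' Cohort generation specification
#'
#' Defaults emulate the study conditions: 30 families, the 15 carrier
#' families planted from the fixture, 15 families carrying only decoys; a
#' handful of decoy variants per family split between common (popmax >=
#' 0.01), rare off-panel, and rare on-panel benign-leaning; 2 dB audiogram
#' jitter around the published pure-tone-average anchors.
#'
#' @param seed integer seed; fully determines every generated byte.
#' @param n_families total families (>= 15; families beyond the 15 carriers
#'   receive decoys only).
#' @param decoys_per_family named counts `common` / `rare_off_panel` /
#'   `rare_on_panel`.
#' @param audiogram_jitter integer dB jitter half-width applied per frequency.
#' @param upstream upstream screening context written into the manifest.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(seed = 1L, n_families = 30L,
                        decoys_per_family = c(common = 2L, rare_off_panel = 2L,
                                              rare_on_panel = 2L),
                        audiogram_jitter = 2L,
                        upstream = c(total_probands = 851L, gjb2_solved = 245L)) {
  .check(n_families >= 15L, "cohort needs at least the 15 carrier families")
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 decoys_per_family = decoys_per_family,
                 audiogram_jitter = as.integer(audiogram_jitter),
                 upstream = upstream),
            class = "cohort_spec")
}

# audiogram shape templates: dB offsets from the target PTA; the four
# PTA frequencies' offsets average to zero so pta(curve) == target
.shape_offsets <- list(
  mid_frequency_typical = c(`250` = -25, `500` = -10, `1000` = 5,
                            `2000` = 10, `4000` = -5, `8000` = -22),
  mid_frequency_shallow = c(`250` = -10, `500` = -8, `1000` = 4,
                            `2000` = 8, `4000` = -4, `8000` = -6),
  flat = c(`250` = 0, `500` = 0, `1000` = 0, `2000` = 0, `4000` = 0, `8000` = 0),
  high_frequency = c(`250` = -20, `500` = -14, `1000` = -2, `2000` = 4,
                     `4000` = 12, `8000` = 20))

#' Generate one audiogram from a shape template
#'
#' Adds the template's offsets to the target PTA, applies integer jitter per
#' frequency, clips to \[-10, 120\] dB HL, and resamples (bounded retries)
#' until the curve both classifies as the requested template and lands
#' within `max(1, jitter)` dB of the target PTA.
#'
#' @param template one of `names(.shape_offsets)`:
#'   `mid_frequency_typical`, `mid_frequency_shallow`, `flat`,
#'   `high_frequency`.
#' @param target_pta target four-frequency PTA in \[0, 110\] dB HL.
#' @param jitter integer jitter half-width in dB (uniform on
#'   `-jitter:jitter`); 0 gives the deterministic template curve.
#' @param subject,ear,visit passed to [audiogram()].
#' @param max_tries resampling bound.
#' @return an [audiogram()] whose [classify_shape()] equals `template`.
#' @export
make_audiogram <- function(template, target_pta, jitter = 2L,
                           subject = NA_character_, ear = "right", visit = 1L,
                           max_tries = 100L) {
  .check(template %in% names(.shape_offsets), "unknown template: %s", template)
  .check(target_pta >= 0 && target_pta <= 110, "target PTA outside [0, 110]")
  off <- .shape_offsets[[template]]
  for (try in seq_len(max_tries)) {
    noise <- if (jitter > 0) sample(seq(-jitter, jitter), length(off),
                                    replace = TRUE) else rep(0L, length(off))
    th <- pmin(pmax(target_pta + off + noise, -10), 120)
    ag <- audiogram(stats::setNames(th, names(off)), subject, ear, visit)
    if (classify_shape(ag) == template &&
        abs(pta(ag) - target_pta) <= max(1, jitter))
      return(ag)
  }
  stop(sprintf("could not generate a %s audiogram at PTA %s within %d tries",
               template, target_pta, max_tries), call. = FALSE)
}

# carrier-family layouts: member roles, genotypes of the planted variants,
# audiometric anchors from the published phenotype table.
# gt values: character genotype per planted variant, in fixture row order.
.carrier_layout <- function() {
  list(
    FAM618 = list(members = c(fa = "unaff", mo = "carrier_het", pro = "aff",
                              sib = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 1, sib = 1),
                  gts = list(fa = "0", mo = "0/1", pro = "1", sib = "1"),
                  pta = c(46, 46), shape = "mid_frequency_typical"),
    FAM806 = list(members = c(fa = "aff_carrier", mo = "unaff", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 1),
                  gts = list(fa = "0/1", mo = "0/0", pro = "0/1"),
                  pta = c(57, 57), shape = "mid_frequency_typical"),
    FAM411 = list(members = c(fa = "aff_carrier", mo = "unaff", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 2),
                  gts = list(fa = "0/1", mo = "0/0", pro = "0/1"),
                  pta = c(25, 38), shape = "mid_frequency_typical"),
    FAM837 = list(members = c(fa = "nogt", mo = "nogt", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 2),
                  gts = list(fa = c("./.", "./."), mo = c("./.", "./."),
                             pro = c("0/1", "0/1")),
                  pta = c(109, 109), shape = "mid_frequency_typical"),
    FAM834 = list(members = c(fa = "nogt", mo = "nogt", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 1),
                  gts = list(fa = c("./.", "./."), mo = c("./.", "./."),
                             pro = c("0/1", "0/1")),
                  pta = c(48, 48), shape = "mid_frequency_typical"),
    FAM417 = list(members = c(fa = "nogt", mo = "nogt", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 2),
                  gts = list(fa = "./.", mo = "./.", pro = "0/1"),
                  pta = c(40, 40), shape = "mid_frequency_shallow"),
    FAM642 = list(members = c(fa = "aff_carrier", mo = "unaff", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 1),
                  gts = list(fa = "0/1", mo = "0/0", pro = "0/1"),
                  pta = c(49, 49), shape = "mid_frequency_typical"),
    FAM622 = list(members = c(fa = "aff_carrier", mo = "unaff", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 2),
                  gts = list(fa = "0/1", mo = "0/0", pro = "0/1"),
                  pta = c(81, 81), shape = "mid_frequency_typical"),
    FAM571 = list(members = c(fa = "aff_carrier", mo = "unaff", pro = "aff",
                              sib = "aff_carrier"),
                  sexes = c(fa = 1, mo = 2, pro = 2, sib = 1),
                  gts = list(fa = "0/1", mo = "0/0", pro = "0/1", sib = "0/1"),
                  pta = c(41, 41), shape = "mid_frequency_typical"),
    FAM623 = list(members = c(fa = "aff_carrier", mo = "unaff", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 1),
                  gts = list(fa = "0/1", mo = "0/0", pro = "0/1"),
                  pta = c(53, 53), shape = "mid_frequency_typical"),
    FAM090 = list(members = c(fa = "nogt", mo = "nogt", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 1),
                  gts = list(fa = "./.", mo = "./.", pro = "0/1"),
                  pta = c(26, 31), shape = "mid_frequency_typical"),
    FAM200 = list(members = c(fa = "nogt", mo = "nogt", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 2),
                  gts = list(fa = "./.", mo = "./.", pro = "0/1"),
                  pta = c(51, 66), shape = "mid_frequency_typical"),
    # proband is the affected parent; unaffected daughter carries the variant
    FAM416 = list(members = c(pro = "aff", sp = "unaff", dau = "unaff_carrier"),
                  sexes = c(pro = 1, sp = 2, dau = 2),
                  gts = list(pro = "0/1", sp = "0/0", dau = "0/1"),
                  pta = c(29, 29), shape = "mid_frequency_shallow",
                  child_of = c(dau = "pro_sp")),
    FAM253 = list(members = c(fa = "carrier_het", mo = "carrier_het", pro = "aff"),
                  sexes = c(fa = 1, mo = 2, pro = 1),
                  gts = list(fa = "0/1", mo = "0/1", pro = "1/1"),
                  pta = c(69, 69), shape = "mid_frequency_typical"),
    FAM174 = list(members = c(fa = "carrier_het", mo = "carrier_het", pro = "aff",
                              sib = "aff_het"),
                  sexes = c(fa = 1, mo = 2, pro = 2, sib = 2),
                  gts = list(fa = "0/1", mo = "0/1", pro = "1/1", sib = "0/1"),
                  pta = c(81, 81), shape = "mid_frequency_typical")
  )
}

.role_affected <- function(role) {
  if (role %in% c("aff", "aff_carrier", "aff_het")) 2L
  else if (role == "nogt") 0L
  else 1L
}

# draw a decoy SNV inside [start+1, end] avoiding taken positions
.draw_decoy <- function(gene_row, taken) {
  repeat {
    pos <- sample(seq(gene_row$start + 1L, gene_row$end), 1L)
    key0 <- paste(gene_row$chrom, pos)
    if (!(key0 %in% taken)) break
  }
  ref <- sample(c("A", "C", "G", "T"), 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  list(chrom = gene_row$chrom, pos = pos, ref = ref, alt = alt,
       gene = gene_row$gene)
}

#' Generate a complete synthetic cohort
#'
#' Writes, under `outdir`: per-family VCF 4.2 files (carrier families get
#' their fixture variants at the published zygosities — the two indels in a
#' deliberately non-parsimonious representation so normalization is
#' exercised — and every family gets seeded decoys), one merged annotation
#' sidecar, per-family PED files, a long audiogram table (probands anchored
#' to the published PTA/degrees, two visits; relatives flat), the demo panel
#' pair, reference windows covering every emitted variant, a family
#' manifest, and `truth.json` mapping each family to its expected resolution
#' status. A single seed drives every draw; regeneration is byte-identical.
#'
#' Decoys in the 15 decoy-only families are constrained to kinds the pipeline
#' must reject: common (popmax >= 0.01, includes one exactly at the 0.01
#' boundary), rare but off-panel, or rare on-panel carrying benign-direction
#' evidence — so no decoy ever classifies Pathogenic/Likely pathogenic or
#' counts as a warm VUS.
#'
#' @param spec a [cohort_spec()].
#' @param outdir output directory.
#' @param force overwrite an existing `outdir`.
#' @return invisibly, list with `dir`, `truth`, `manifest`.
#' @export
generate_cohort <- function(spec = cohort_spec(), outdir, force = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (dir.exists(outdir) && length(list.files(outdir)) > 0L && !force)
    stop(sprintf("output directory %s exists; use force = TRUE", outdir),
         call. = FALSE)
  dir.create(file.path(outdir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "ped"), showWarnings = FALSE)
  dir.create(file.path(outdir, "panel"), showWarnings = FALSE)
  set.seed(spec$seed)

  fx <- load_fixture()
  layouts <- .carrier_layout()
  panel <- .panel_genes()
  offp <- .offpanel_genes()
  decoy_fams <- sprintf("FAMD%02d", seq_len(spec$n_families - length(layouts)))
  families <- c(names(layouts), decoy_fams)

  # panel files
  utils::write.table(panel[, c("chrom", "start", "end", "gene")],
                     file.path(outdir, "panel", "panel_intervals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = panel$gene, modes = panel$modes),
                     file.path(outdir, "panel", "gene_modes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  taken <- paste(fx$contig, fx$pos)
  sidecar_rows <- list(); window_rows <- list()
  manifest <- list(); audio_rows <- list(); truth <- list()

  # fixture windows (frozen synthetic contexts)
  fw <- fixture_ref_windows()
  window_rows[[1]] <- fw[, c("contig", "start", "seq")]

  decoy_counter <- 0L
  boundary_planted <- FALSE
  for (fam in families) {
    is_carrier <- fam %in% names(layouts)
    lay <- if (is_carrier) layouts[[fam]] else
      list(members = c(fa = "nogt", mo = "nogt", pro = "aff"),
           sexes = c(fa = 1, mo = 2, pro = sample(1:2, 1)),
           gts = list(), pta = rep(sample(35:65, 1), 2),
           shape = "mid_frequency_typical")
    ids <- stats::setNames(paste0(fam, "_", names(lay$members)),
                           names(lay$members))
    pro_id <- ids[["pro"]]

    # --- variants: planted fixture rows then decoys
    rows <- list(); gts <- list()
    if (is_carrier) {
      frows <- fx[fx$family == fam, , drop = FALSE]
      for (k in seq_len(nrow(frows))) {
        r <- frows[k, ]
        ref <- r$ref; alt <- r$alt; pos <- r$pos
        if (nchar(ref) > 1L || nchar(alt) > 1L) {
          # pad with the next reference base: non-parsimonious on purpose
          w <- .find_window(fw, r$contig, pos, nchar(ref))
          nb <- .win_sub(w, pos + nchar(ref), pos + nchar(ref))
          ref <- paste0(ref, nb); alt <- paste0(alt, nb)
        }
        g <- vapply(names(lay$members), function(mem) {
          gv <- lay$gts[[mem]]
          if (length(gv) >= k) gv[k] else gv[1]
        }, character(1))
        rows[[length(rows) + 1L]] <-
          data.frame(contig = r$contig, pos = pos, id = r$rsid,
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
        gts[[length(gts) + 1L]] <- g
      }
    }

    dpf <- spec$decoys_per_family
    decoy_defs <- c(rep("common", dpf[["common"]]),
                    rep("rare_off_panel", dpf[["rare_off_panel"]]),
                    rep("rare_on_panel", dpf[["rare_on_panel"]]))
    for (kind in decoy_defs) {
      src <- if (kind == "rare_off_panel") offp else panel
      d <- .draw_decoy(src[sample(nrow(src), 1L), ], taken)
      taken <- c(taken, paste(d$chrom, d$pos))
      decoy_counter <- decoy_counter + 1L
      if (kind == "common") {
        af <- if (!boundary_planted) { boundary_planted <- TRUE; 0.01 }
              else round(stats::runif(1, 0.02, 0.2), 4)
        evidence <- "BA1"
      } else {
        af <- round(stats::runif(1, 0, 5e-5), 7)
        evidence <- "BP4"
      }
      sidecar_rows[[length(sidecar_rows) + 1L]] <- data.frame(
        chrom = d$chrom, pos = d$pos, ref = d$ref, alt = d$alt,
        gene = d$gene, transcript = sprintf("NM_%06d.1", decoy_counter),
        exon = "1/10", cdna = sprintf("c.%d%s>%s", decoy_counter, d$ref, d$alt),
        protein = "p.?", consequence = "missense_variant",
        af_global = af, af_afr = NA, af_asj = NA, af_eur_nf = af,
        af_amr = NA, af_sas = NA,
        cadd = round(stats::runif(1, 0, 15), 1),
        revel = round(stats::runif(1, 0.05, 0.3), 3),
        rsid = NA_character_, evidence = evidence, stringsAsFactors = FALSE)
      window_rows[[length(window_rows) + 1L]] <-
        data.frame(contig = d$chrom, start = d$pos, seq = d$ref,
                   stringsAsFactors = FALSE)
      g <- stats::setNames(rep("0/0", length(lay$members)), names(lay$members))
      g[lay$members == "nogt"] <- "./."
      g["pro"] <- "0/1"
      rows[[length(rows) + 1L]] <-
        data.frame(contig = d$chrom, pos = d$pos, id = NA_character_,
                   ref = d$ref, alt = d$alt, stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- g
    }

    variants <- do.call(rbind, rows)
    gt <- do.call(rbind, gts)
    colnames(gt) <- ids
    ord <- order(variants$contig, variants$pos)
    vs <- variant_set(variants[ord, , drop = FALSE], gt[ord, , drop = FALSE],
                      unname(ids))
    vcf_path <- file.path(outdir, "vcf", paste0(fam, ".vcf"))
    write_vcf(vs, vcf_path)

    # --- pedigree
    fa_id <- if ("fa" %in% names(ids)) ids[["fa"]] else "0"
    mo_id <- if ("mo" %in% names(ids)) ids[["mo"]] else "0"
    ped_df <- data.frame(family = fam, id = unname(ids),
                         father = "0", mother = "0",
                         sex = unname(lay$sexes),
                         phenotype = vapply(unname(lay$members), .role_affected,
                                            integer(1)),
                         stringsAsFactors = FALSE)
    rownames(ped_df) <- names(ids)
    if (all(c("fa", "mo", "pro") %in% names(ids))) {
      ped_df["pro", c("father", "mother")] <- c(fa_id, mo_id)
      if ("sib" %in% names(ids))
        ped_df["sib", c("father", "mother")] <- c(fa_id, mo_id)
    }
    if (!is.null(lay$child_of))  # FAM416: daughter of proband and spouse
      ped_df["dau", c("father", "mother")] <- c(ids[["pro"]], ids[["sp"]])
    utils::write.table(ped_df, file.path(outdir, "ped", paste0(fam, ".ped")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)

    # --- audiograms: proband two visits both ears; relatives one flat visit
    for (visit in 1:2) for (ear_i in 1:2) {
      ear <- c("right", "left")[ear_i]
      ag <- make_audiogram(lay$shape, lay$pta[ear_i], spec$audiogram_jitter,
                           subject = pro_id, ear = ear, visit = visit)
      audio_rows[[length(audio_rows) + 1L]] <-
        data.frame(subject = pro_id, ear = ear, visit = visit,
                   freq_hz = as.integer(names(ag$thresholds)),
                   db_hl = unname(ag$thresholds), stringsAsFactors = FALSE)
    }
    for (mem in setdiff(names(ids), "pro")) {
      target <- if (.role_affected(lay$members[[mem]]) == 2L)
        lay$pta[1] else 10
      shape <- if (.role_affected(lay$members[[mem]]) == 2L)
        lay$shape else "flat"
      ag <- make_audiogram(shape, target, spec$audiogram_jitter,
                           subject = ids[[mem]], ear = "right", visit = 1L)
      audio_rows[[length(audio_rows) + 1L]] <-
        data.frame(subject = ids[[mem]], ear = "right", visit = 1L,
                   freq_hz = as.integer(names(ag$thresholds)),
                   db_hl = unname(ag$thresholds), stringsAsFactors = FALSE)
    }

    manifest[[length(manifest) + 1L]] <-
      data.frame(family = fam, proband = pro_id,
                 vcf = file.path("vcf", paste0(fam, ".vcf")),
                 ped = file.path("ped", paste0(fam, ".ped")),
                 stringsAsFactors = FALSE)
    truth[[fam]] <- list(
      status = if (!is_carrier) "unsolved"
               else if (fam == "FAM837") "compound_P_plus_VUS"
               else if (fam %in% c("FAM618", "FAM834", "FAM622", "FAM571",
                                   "FAM623", "FAM253")) "solved"
               else "candidate_VUS",
      gene = if (is_carrier) fx$gene[fx$family == fam][1] else NA)
  }

  # --- merged sidecar: fixture rows (deduplicated by key) + decoys
  fxsc <- fx[!duplicated(fx$key),
             c("contig", "pos", "ref", "alt", "gene", "transcript", "exon",
               "cdna", "protein", "consequence", "af_global", "af_afr",
               "af_asj", "af_eur_nf", "af_amr", "af_sas", "cadd", "revel",
               "rsid", "evidence")]
  names(fxsc)[1] <- "chrom"
  sidecar <- rbind(fxsc, do.call(rbind, sidecar_rows))
  utils::write.table(sidecar, file.path(outdir, "sidecar.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")

  windows <- do.call(rbind, window_rows)
  utils::write.table(windows, file.path(outdir, "ref_windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  audio <- do.call(rbind, audio_rows)
  utils::write.table(audio, file.path(outdir, "audiograms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  man <- do.call(rbind, manifest)
  utils::write.table(man, file.path(outdir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_out <- list(
    statuses = truth,
    counts = as.list(table(vapply(truth, `[[`, character(1), "status"))),
    upstream = as.list(spec$upstream),
    metadata = list(
      note = paste("Pedigree structures are template approximations of the",
                   "published family-history flags; the affected X-linked",
                   "sister's zygosity is assumed heterozygous."),
      seed = spec$seed))
  jsonlite::write_json(truth_out, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = outdir, truth = truth_out, manifest = man))
}
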