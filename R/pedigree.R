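#' Read a 6-column (pre-makeped) PED file
#'
#' Columns: family, id, father, mother, sex (1 male / 2 female / 0 unknown),
#' phenotype (1 unaffected / 2 affected / 0 or -9 unknown). `0` parent ids
#' mean founder. Validates that parent references resolve, that fathers are
#' male and mothers female where sex is known, and that nobody is their own
#' ancestor.
#'
#' @param path path to the PED file.
#' @param proband optional proband id (the index patient).
#' @return object of class `pedigree`: data.frame `members` plus attributes.
#' @export
read_ped <- function(path, proband = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family", "id", "father", "mother",
                                        "sex", "phenotype"))
  pedigree(family = df$family[1], members = df, proband = proband)
}

#' Construct a pedigree
#'
#' @param family family id.
#' @param members data.frame with columns `id`, `father`, `mother`, `sex`,
#'   `phenotype` (PED conventions).
#' @param proband optional proband id; must be a member when given.
#' @return object of class `pedigree`.
#' @export
pedigree <- function(family, members, proband = NULL) {
  m <- members
  m$father <- as.character(m$father); m$mother <- as.character(m$mother)
  m$id <- as.character(m$id)
  .check(!anyDuplicated(m$id), "duplicate individual id in family %s", family)
  for (col in c("father", "mother")) {
    ref <- m[[col]][m[[col]] != "0"]
    .check(all(ref %in% m$id), "unresolved %s reference in family %s", col, family)
  }
  sex_of <- stats::setNames(m$sex, m$id)
  .check(all(sex_of[m$father[m$father != "0"]] %in% c(1, 0)),
         "father must be male in family %s", family)
  .check(all(sex_of[m$mother[m$mother != "0"]] %in% c(2, 0)),
         "mother must be female in family %s", family)
  # ancestry cycle check
  for (id in m$id) {
    seen <- character(); frontier <- id
    while (length(frontier) > 0L) {
      row <- m[m$id %in% frontier, , drop = FALSE]
      frontier <- setdiff(c(row$father, row$mother), c("0", seen))
      .check(!(id %in% frontier), "individual %s is its own ancestor", id)
      seen <- c(seen, frontier)
    }
  }
  if (!is.null(proband)) .check(proband %in% m$id,
                                "proband %s not in family %s", proband, family)
  structure(list(family = family, members = m, proband = proband),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> family %s, %d member(s), proband %s\n",
              x$family, nrow(x$members), x$proband %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.affected <- function(ped, id) {
  ph <- ped$members$phenotype[ped$members$id == id]
  if (ph == 2) TRUE else if (ph == 1) FALSE else NA
}

.sex <- function(ped, id) {
  sx <- ped$members$sex[ped$members$id == id]
  if (sx == 1) "male" else if (sx == 2) "female" else "unknown"
}

#' Genotype configuration of an individual under an inheritance mode
#'
#' Decides whether qualifying variants in one gene fill the causal dose for
#' the mode: `full` (dose complete), `half` (one allele of a recessive pair),
#' or `none`.
#'
#' * AD: full iff at least one qualifying variant is carried (het or hom).
#' * AR: full iff a qualifying variant is homozygous, or two distinct
#'   qualifying variants are heterozygous with pairwise phase trans or
#'   unknown (an all-cis pair does not fill the dose); half iff exactly one
#'   heterozygous qualifying variant.
#' * XL: full iff a male carries a hemizygous qualifying variant, or a female
#'   is homozygous — or heterozygous when `female_het_affected` (default on:
#'   manifesting X-linked heterozygotes are accepted).
#'
#' @param mode `"AD"`, `"AR"` or `"XL"`.
#' @param dosages named integer vector: qualifying variant key -> alt-allele
#'   dosage of this individual (0/1/2; a hemizygous alt call is dosage 1 and
#'   qualifies through the XL branch; NA = no call).
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param phase optional function(key_a, key_b) returning `"trans"`, `"cis"`
#'   or `"unknown"` for a heterozygous pair; default everything unknown.
#' @param female_het_affected logical, see above.
#' @return `"full"`, `"half"` or `"none"`.
#' @export
causal_configuration <- function(mode, dosages, sex = "unknown",
                                 phase = NULL,
                                 female_het_affected = TRUE) {
  .check(mode %in% c("AD", "AR", "XL"), "unknown inheritance mode: %s", mode)
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) return("none")
  if (mode == "AD") {
    return(if (any(d >= 1L)) "full" else "none")
  }
  if (mode == "XL") {
    if (any(d == 2L)) return("full")  # hemizygous alt or female hom
    if (any(d == 1L)) return(if (identical(sex, "female") && !female_het_affected)
                               "half" else "full")
    return("none")
  }
  # AR
  if (any(d == 2L)) return("full")
  het <- names(d)[d == 1L]
  if (length(het) >= 2L) {
    if (is.null(phase)) return("full")  # unknown phase kept as potentially trans
    for (i in seq_along(het)) for (j in seq_along(het)) {
      if (i < j && phase(het[i], het[j]) %in% c("trans", "unknown"))
        return("full")
    }
    return("half")
  }
  if (length(het) == 1L) return("half")
  "none"
}

#' Phase a compound-heterozygous pair through the parents
#'
#' `trans` when each parent carries exactly one of the two variants, `cis`
#' when one parent carries both and the other neither, `unknown` when a
#' parental genotype is unavailable or the configuration is uninformative.
#' Never returns cis/trans without both parental genotypes.
#'
#' @param ped a [pedigree()].
#' @param dosages_a,dosages_b named integer vectors: member id -> dosage for
#'   variant A and variant B (NA = no call).
#' @param carrier id of the doubly heterozygous individual.
#' @return `"trans"`, `"cis"` or `"unknown"`.
#' @export
phase_compound_het <- function(ped, dosages_a, dosages_b, carrier) {
  stopifnot(inherits(ped, "pedigree"))
  .check(identical(unname(dosages_a[carrier]), 1L) &&
           identical(unname(dosages_b[carrier]), 1L),
         "carrier %s must be heterozygous for both variants", carrier)
  row <- ped$members[ped$members$id == carrier, ]
  fa <- row$father; mo <- row$mother
  if (fa == "0" || mo == "0") return("unknown")
  da <- c(dosages_a[fa], dosages_a[mo]); db <- c(dosages_b[fa], dosages_b[mo])
  if (any(is.na(da)) || any(is.na(db))) return("unknown")
  carries_a <- da >= 1L; carries_b <- db >= 1L
  if (xor(carries_a[1], carries_a[2]) && xor(carries_b[1], carries_b[2]) &&
      !any(carries_a & carries_b))
    return("trans")
  if (any(carries_a & carries_b) && any(!carries_a & !carries_b))
    return("cis")
  "unknown"
}

# is (genotype dosage, affection) consistent with the mode's prediction?
.mode_consistent <- function(mode, dosage, affected, sex,
                             female_het_affected = TRUE) {
  if (is.na(dosage) || is.na(affected)) return(NA)
  carrier <- dosage >= 1L
  if (mode == "AD") {
    if (affected) carrier else !carrier
  } else if (mode == "AR") {
    if (affected) dosage == 2L else dosage < 2L
  } else {  # XL
    if (identical(sex, "male")) {
      if (affected) carrier else !carrier
    } else if (female_het_affected) {
      if (affected) carrier else !carrier
    } else {
      if (affected) dosage == 2L else dosage < 2L
    }
  }
}

#' Count informative meioses for co-segregation (PP1)
#'
#' An informative meiosis is a parent-to-child transmission where the parent
#' and child are genotyped and the child's affection status is known; it is
#' consistent when the child's carrier state co-varies with affection as the
#' mode predicts. The count is the number of consistent informative meioses
#' and resets to 0 on any contradiction (which is also flagged).
#'
#' @param ped a [pedigree()].
#' @param dosages named integer vector member id -> dosage.
#' @param mode inheritance mode.
#' @return list with `count` and `contradiction` (logical).
#' @export
count_informative_meioses <- function(ped, dosages, mode) {
  stopifnot(inherits(ped, "pedigree"))
  n <- 0L; contradiction <- FALSE
  for (i in seq_len(nrow(ped$members))) {
    child <- ped$members$id[i]
    for (par in c(ped$members$father[i], ped$members$mother[i])) {
      if (par == "0") next
      if (is.na(dosages[par]) || is.na(dosages[child])) next
      ok <- .mode_consistent(mode, unname(dosages[child]),
                             .affected(ped, child), .sex(ped, child))
      if (is.na(ok)) next
      if (ok) n <- n + 1L else contradiction <- TRUE
    }
  }
  list(count = if (contradiction) 0L else n, contradiction = contradiction)
}

#' Map an informative-meiosis count to a PP1 strength
#'
#' Thresholds default to >= 2 Supporting, >= 4 Moderate, >= 6 Strong; they
#' are a documented convention, configurable per lab.
#'
#' @param count consistent informative meioses.
#' @param thresholds named numeric vector `Supporting`/`Moderate`/`Strong`.
#' @return `"none"`, `"Supporting"`, `"Moderate"` or `"Strong"`.
#' @export
pp1_strength <- function(count, thresholds = c(Supporting = 2, Moderate = 4,
                                               Strong = 6)) {
  if (count >= thresholds[["Strong"]]) "Strong"
  else if (count >= thresholds[["Moderate"]]) "Moderate"
  else if (count >= thresholds[["Supporting"]]) "Supporting"
  else "none"
}

#' Detect genotype–phenotype inconsistencies in a family
#'
#' Reports (a) affected members whose configuration is half/none while the
#' proband's is full — the pattern of an affected sibling who is only a
#' heterozygous carrier of a recessive variant, pointing at a second,
#' unidentified cause; and (b) unaffected members with a full configuration —
#' non-penetrance candidates, relevant for late-onset dominant genes.
#'
#' @param ped a [pedigree()] with a proband.
#' @param dosage_matrix integer matrix: rows = variant keys, columns = member
#'   ids, entries = dosages (NA = no call).
#' @param mode inheritance mode for the gene under test.
#' @return data.frame of findings (`member`, `type`, `detail`).
#' @export
detect_inconsistencies <- function(ped, dosage_matrix, mode) {
  stopifnot(inherits(ped, "pedigree"))
  .check(!is.null(ped$proband), "pedigree needs a proband for inconsistency checks")
  config_of <- function(id) {
    causal_configuration(mode, stats::setNames(dosage_matrix[, id],
                                               rownames(dosage_matrix)),
                         sex = .sex(ped, id))
  }
  findings <- list()
  pro_cfg <- config_of(ped$proband)
  for (id in setdiff(colnames(dosage_matrix), ped$proband)) {
    if (!(id %in% ped$members$id)) next
    aff <- .affected(ped, id)
    if (is.na(aff)) next
    cfg <- config_of(id)
    if (aff && pro_cfg == "full" && cfg %in% c("half", "none"))
      findings[[length(findings) + 1L]] <-
        data.frame(member = id, type = "affected_underdosed",
                   detail = sprintf("affected %s has %s configuration under %s",
                                    id, cfg, mode), stringsAsFactors = FALSE)
    if (!aff && cfg == "full")
      findings[[length(findings) + 1L]] <-
        data.frame(member = id, type = "unaffected_carrier",
                   detail = sprintf("unaffected %s has full configuration under %s",
                                    id, mode), stringsAsFactors = FALSE)
  }
  if (length(findings) == 0L)
    return(data.frame(member = character(), type = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}
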