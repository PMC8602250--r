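.status_levels <- c("solved", "compound_P_plus_VUS", "candidate_VUS", "unsolved")

#' Resolve one family's diagnostic status
#'
#' Per gene and per supported inheritance mode, evaluates the proband's
#' genotype configuration over Pathogenic/Likely pathogenic candidates only:
#' any `full` dose makes the family `solved`. Failing that, under AR, one
#' P/LP heterozygote paired with one *warm* VUS heterozygote (phase not
#' proven cis) is `compound_P_plus_VUS`. Failing that, a full dose of warm
#' VUS alone is `candidate_VUS`; otherwise `unsolved`. A warm VUS is a VUS
#' whose evidence set carries no benign-direction item. Genes compete by best
#' achievable status; ties break by more P/LP variants, then lower popmax,
#' then gene symbol.
#'
#' @param family family id.
#' @param candidates data.frame of classified candidates for this family
#'   (columns `key`, `gene`, `class`, `warm`, `popmax_af`, optional
#'   `fallback`).
#' @param gt_dosages integer matrix rows = candidate keys, cols = member ids.
#' @param ped a [pedigree()] with proband set.
#' @param modes named list gene -> inheritance modes (from a `gene_panel`).
#' @param default_modes modes assumed for genes absent from `modes` (e.g. for
#'   whole-exome fallback candidates); `NULL` makes an absent gene an error.
#' @return object of class `family_call`: list with `family`, `status`,
#'   `gene`, `mode`, `variants` (supporting data.frame), `phase`,
#'   `fallback_used`, `inconsistencies`.
#' @export
resolve_family <- function(family, candidates, gt_dosages, ped, modes,
                           default_modes = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  pro <- ped$proband
  .check(!is.null(pro), "pedigree for %s needs a proband", family)
  empty_call <- function() {
    structure(list(family = family, status = "unsolved", gene = NA_character_,
                   mode = NA_character_, variants = candidates[0, , drop = FALSE],
                   phase = NA_character_, fallback_used = FALSE,
                   inconsistencies = data.frame()), class = "family_call")
  }
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty_call())
  fallback_used <- isTRUE(any(candidates$fallback))

  pro_dose <- function(keys) stats::setNames(gt_dosages[keys, pro], keys)
  phase_fn <- function(a, b) {
    phase_compound_het(ped, gt_dosages[a, ], gt_dosages[b, ], pro)
  }
  safe_phase <- function(a, b) {
    da <- gt_dosages[a, pro]; db <- gt_dosages[b, pro]
    if (is.na(da) || is.na(db) || da != 1L || db != 1L) return("unknown")
    phase_fn(a, b)
  }

  best <- NULL
  for (gene in unique(candidates$gene)) {
    gcand <- candidates[candidates$gene == gene, , drop = FALSE]
    gmodes <- modes[[gene]]
    if (is.null(gmodes)) {
      .check(!is.null(default_modes),
             "gene %s absent from the inheritance-mode table", gene)
      gmodes <- default_modes
    }
    plp <- gcand[gcand$class %in% c("Pathogenic", "LikelyPathogenic"), , drop = FALSE]
    warm <- gcand[gcand$class == "VUS" & gcand$warm, , drop = FALSE]
    for (mode in gmodes) {
      status <- "unsolved"; support <- gcand[0, , drop = FALSE]; ph <- NA_character_
      cfg_plp <- if (nrow(plp) > 0L)
        causal_configuration(mode, pro_dose(plp$key), .sex(ped, pro), safe_phase)
        else "none"
      if (cfg_plp == "full") {
        status <- "solved"; support <- plp
        if (mode == "AR" && nrow(plp) >= 2L &&
            all(gt_dosages[plp$key, pro] == 1L, na.rm = TRUE))
          ph <- safe_phase(plp$key[1], plp$key[2])
      } else if (mode == "AR" && nrow(plp) == 1L && nrow(warm) >= 1L &&
                 identical(unname(gt_dosages[plp$key, pro]), 1L)) {
        mates <- warm$key[!is.na(gt_dosages[warm$key, pro]) &
                            gt_dosages[warm$key, pro] == 1L]
        mates <- Filter(function(k) safe_phase(plp$key, k) != "cis", mates)
        if (length(mates) > 0L) {
          status <- "compound_P_plus_VUS"
          support <- gcand[gcand$key %in% c(plp$key, mates[1]), , drop = FALSE]
          ph <- safe_phase(plp$key, mates[1])
        }
      }
      if (status == "unsolved" && nrow(warm) > 0L) {
        cfg_w <- causal_configuration(mode, pro_dose(warm$key), .sex(ped, pro),
                                      safe_phase)
        if (cfg_w == "full") {
          status <- "candidate_VUS"; support <- warm
          if (mode == "AR" && nrow(warm) >= 2L &&
              all(gt_dosages[warm$key, pro] == 1L, na.rm = TRUE))
            ph <- safe_phase(warm$key[1], warm$key[2])
        }
      }
      if (status == "unsolved") next
      cand_call <- list(family = family, status = status, gene = gene,
                        mode = mode, variants = support, phase = ph,
                        fallback_used = fallback_used,
                        n_plp = nrow(plp),
                        min_popmax = suppressWarnings(min(support$popmax_af,
                                                          na.rm = TRUE)))
      if (is.null(best) || .call_beats(cand_call, best)) best <- cand_call
    }
  }
  if (is.null(best)) return(empty_call())
  dm <- gt_dosages[best$variants$key, , drop = FALSE]
  rownames(dm) <- best$variants$key
  best$inconsistencies <- detect_inconsistencies(ped, dm, best$mode)
  best$n_plp <- NULL; best$min_popmax <- NULL
  structure(best, class = "family_call")
}

# ordering: better status, then more P/LP, then lower popmax, then gene symbol
.call_beats <- function(a, b) {
  ra <- match(a$status, .status_levels); rb <- match(b$status, .status_levels)
  if (ra != rb) return(ra < rb)
  if (a$n_plp != b$n_plp) return(a$n_plp > b$n_plp)
  if (!identical(a$min_popmax, b$min_popmax)) {
    pa <- if (is.finite(a$min_popmax)) a$min_popmax else Inf
    pb <- if (is.finite(b$min_popmax)) b$min_popmax else Inf
    if (pa != pb) return(pa < pb)
  }
  a$gene < b$gene
}

#' @export
print.family_call <- function(x, ...) {
  cat(sprintf("<family_call> %s: %s%s%s\n", x$family, x$status,
              if (!is.na(x$gene)) paste0(" (", x$gene, ", ", x$mode, ")") else "",
              if (isTRUE(x$fallback_used)) " [whole-exome fallback]" else ""))
  invisible(x)
}

#' Summarize cohort yield
#'
#' Counts and percentages over the family calls; percentages are recomputed
#' from counts and rounded half-up to integers, except the cohort share of
#' the upstream screening population, reported at two decimals. Distinct
#' variants deduplicate by normalized key across families. Optional upstream
#' context (`total_probands` screened, `gjb2_solved` by first-line GJB2
#' testing) yields the GJB2 diagnostic rate and this cohort's share of the
#' GJB2-negative remainder.
#'
#' @param calls list of `family_call` objects.
#' @param upstream optional list/vector with `total_probands` and
#'   `gjb2_solved`.
#' @param classified optional data.frame of all classified candidates (for
#'   distinct-variant class tallies; must have `key` and `class`).
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(calls, upstream = NULL, classified = NULL) {
  .check(length(calls) >= 1L, "need at least one family call")
  status <- vapply(calls, `[[`, character(1), "status")
  gene <- vapply(calls, function(x) as.character(x$gene), character(1))
  n <- length(calls)
  counts <- stats::setNames(vapply(.status_levels,
                                   function(s) sum(status == s), integer(1)),
                            .status_levels)
  stopifnot(sum(counts) == n)
  pct <- function(k) round_half_up(100 * k / n)
  per_gene <- sort(table(gene[!is.na(gene) & status != "unsolved"]),
                   decreasing = TRUE)
  out <- list(n_families = n,
              n_solved = counts[["solved"]],
              pct_solved = pct(counts[["solved"]]),
              n_candidate = counts[["candidate_VUS"]],
              pct_candidate = pct(counts[["candidate_VUS"]]),
              n_compound = counts[["compound_P_plus_VUS"]],
              n_unsolved = counts[["unsolved"]],
              per_gene_families = as.list(per_gene),
              per_gene_pct = lapply(as.list(per_gene), pct))
  if (!is.null(classified) && nrow(classified) > 0L) {
    dd <- classified[!duplicated(classified$key), , drop = FALSE]
    out$variant_class_tally <- as.list(table(dd$class))
    out$n_distinct_variants <- nrow(dd)
  }
  if (!is.null(upstream)) {
    tot <- upstream[["total_probands"]]; gjb2 <- upstream[["gjb2_solved"]]
    .check(is.numeric(tot) && is.numeric(gjb2) && gjb2 <= tot && tot > 0,
           "inconsistent upstream counts")
    out$upstream <- list(
      total_probands = tot, gjb2_solved = gjb2,
      gjb2_yield_pct = round_half_up(100 * gjb2 / tot),
      non_gjb2_share_pct = round_half_up(100 * (1 - gjb2 / tot)),
      cohort_share_pct = round_half_up(100 * n / (tot - gjb2), 2))
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d families: %d solved (%d%%), %d candidate-VUS (%d%%), %d compound P+VUS, %d unsolved\n",
              x$n_families, x$n_solved, x$pct_solved, x$n_candidate,
              x$pct_candidate, x$n_compound, x$n_unsolved))
  if (!is.null(x$upstream))
    cat(sprintf("  upstream: GJB2 yield %d%%, cohort share %.2f%% of GJB2-negative probands\n",
                x$upstream$gjb2_yield_pct, x$upstream$cohort_share_pct))
  invisible(x)
}
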