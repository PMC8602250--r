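#' ACMG/AMP evidence code vocabulary
#'
#' The closed vocabulary of criterion codes with their direction and default
#' strength. Hearing-loss guideline practice modifies strengths per variant
#' with `_P`/`_M`/`_S`/`_VS` suffixes; the defaults here are the Richards
#' baseline (PVS1 very strong, PS strong, PM moderate, PP supporting, BA1
#' stand-alone, BS strong, BP supporting).
#'
#' @return data.frame with columns `code`, `direction`, `default_strength`.
#' @export
evidence_codes <- function() {
  path <- c(PVS1 = "VeryStrong",
            stats::setNames(rep("Strong", 4), paste0("PS", 1:4)),
            stats::setNames(rep("Moderate", 6), paste0("PM", 1:6)),
            stats::setNames(rep("Supporting", 5), paste0("PP", 1:5)))
  ben <- c(BA1 = "StandAlone",
           stats::setNames(rep("Strong", 4), paste0("BS", 1:4)),
           stats::setNames(rep("Supporting", 7), paste0("BP", 1:7)))
  data.frame(code = c(names(path), names(ben)),
             direction = c(rep("pathogenic", length(path)),
                           rep("benign", length(ben))),
             default_strength = c(unname(path), unname(ben)),
             stringsAsFactors = FALSE)
}

.strengths <- c("Supporting", "Moderate", "Strong", "VeryStrong", "StandAlone")
.suffix_map <- c("P" = "Supporting", "M" = "Moderate",
                 "S" = "Strong", "VS" = "VeryStrong")

#' Parse a strength-modified evidence string
#'
#' Accepts comma-separated tokens of the form `CODE` or `CODE_SUFFIX` with
#' suffix in `_P`, `_M`, `_S`, `_VS` (e.g. `"PM3_S, PP1_S, PP3, BS1_P"`).
#' Codes are case-insensitive and whitespace-tolerant; a suffix overrides the
#' code's default strength. Duplicate codes and unknown tokens are errors.
#'
#' @param spec evidence string.
#' @return data.frame of class `evidence_set` with columns `code`,
#'   `direction`, `strength`.
#' @export
parse_evidence <- function(spec) {
  codes <- evidence_codes()
  if (is.na(spec) || !nzchar(trimws(spec))) {
    out <- data.frame(code = character(), direction = character(),
                      strength = character(), stringsAsFactors = FALSE)
    class(out) <- c("evidence_set", "data.frame")
    return(out)
  }
  toks <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  parse_one <- function(tok) {
    m <- regmatches(toupper(tok), regexec("^([A-Z]+[0-9]+)(?:_(VS|S|M|P))?$",
                                          toupper(tok)))[[1]]
    if (length(m) == 0L || !(m[2] %in% codes$code))
      stop(sprintf("cannot parse evidence token '%s'", tok), call. = FALSE)
    row <- codes[codes$code == m[2], ]
    strength <- if (nzchar(m[3])) unname(.suffix_map[m[3]]) else row$default_strength
    data.frame(code = row$code, direction = row$direction,
               strength = strength, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(toks, parse_one))
  .check(!anyDuplicated(out$code), "duplicate evidence code in '%s'", spec)
  .check(all(out$strength != "StandAlone" | out$code == "BA1"),
         "StandAlone strength is reserved for BA1")
  class(out) <- c("evidence_set", "data.frame")
  out
}

# tally applied strengths by direction
.tally <- function(ev) {
  p <- ev[ev$direction == "pathogenic", ]
  b <- ev[ev$direction == "benign", ]
  list(nVS = sum(p$strength == "VeryStrong"),
       nS = sum(p$strength == "Strong"),
       nM = sum(p$strength == "Moderate"),
       nP = sum(p$strength == "Supporting"),
       ba = any(b$code == "BA1" & b$strength == "StandAlone"),
       # benign Moderate has no slot in the combining formulas; it is counted
       # with Supporting (conservative: never strengthens the benign call)
       nBS = sum(b$strength %in% c("Strong", "VeryStrong")),
       nBP = sum(b$strength %in% c("Supporting", "Moderate")))
}

.path_rules <- list(
  # two VeryStrong items combine to Pathogenic; without this the calculus is
  # non-monotone (upgrading a Strong partner of PVS1 would demote the call)
  P0 = function(t) t$nVS >= 2,
  P1 = function(t) t$nVS >= 1 && (t$nS >= 1 || t$nM >= 2 ||
                                    (t$nM >= 1 && t$nP >= 1) || t$nP >= 2),
  P2 = function(t) t$nS >= 2,
  P3 = function(t) t$nS == 1 && (t$nM >= 3 || (t$nM == 2 && t$nP >= 2) ||
                                   (t$nM == 1 && t$nP >= 4)),
  L1 = function(t) t$nVS >= 1 && t$nM >= 1,
  L2 = function(t) t$nS == 1 && t$nM >= 1 && t$nM <= 2,
  L3 = function(t) t$nS == 1 && t$nP >= 2,
  L4 = function(t) t$nM >= 3,
  L5 = function(t) t$nM == 2 && t$nP >= 2,
  L6 = function(t) t$nM == 1 && t$nP >= 4,
  L7 = function(t) t$nVS >= 1 && t$nP >= 1
)

#' Combine evidence under the categorical (rule-based) calculus
#'
#' The authoritative combining engine. Criteria are tallied at their
#' *applied* strengths — an upgraded PM3_S counts as Strong, which is the
#' entire point of strength modification. Pathogenic/Likely pathogenic fire
#' on the generalized Richards combinations over the tallies; Benign fires on
#' BA1 or two benign-Strong items, Likely benign on one Strong plus one
#' Supporting or two Supporting.
#'
#' Under the default `pathogenic_priority` policy, benign-direction evidence
#' in a set that also satisfies a pathogenic combination sets `conflict_flag`
#' but does not veto the call. Under `strict`, any two-direction conflict
#' yields VUS with the flag set.
#'
#' @param evidence an `evidence_set` from [parse_evidence()] (or a string,
#'   parsed on the fly).
#' @param conflict_policy `"pathogenic_priority"` (default) or `"strict"`.
#' @return list of class `acmg_class`: `tier`, `conflict_flag`, `rationale`
#'   (matched rule ids), `counts`.
#' @export
combine_rule_based <- function(evidence,
                               conflict_policy = c("pathogenic_priority", "strict")) {
  conflict_policy <- match.arg(conflict_policy)
  if (is.character(evidence)) evidence <- parse_evidence(evidence)
  t <- .tally(evidence)
  fired <- names(Filter(function(f) f(t), .path_rules))
  path_tier <- if (any(startsWith(fired, "P"))) "Pathogenic"
               else if (length(fired) > 0L) "LikelyPathogenic"
               else NA_character_
  benign_tier <- if (t$ba || t$nBS >= 2) "Benign"
                 else if ((t$nBS == 1 && t$nBP >= 1) || t$nBP >= 2) "LikelyBenign"
                 else NA_character_
  has_path <- (t$nVS + t$nS + t$nM + t$nP) > 0
  has_benign <- t$ba || (t$nBS + t$nBP) > 0
  conflict <- has_path && has_benign
  if (conflict_policy == "strict" && conflict) {
    tier <- "VUS"; rationale <- "conflict"
  } else if (!is.na(path_tier)) {
    tier <- path_tier
    rationale <- if (tier == "Pathogenic") fired[startsWith(fired, "P")] else fired
  } else if (!is.na(benign_tier)) {
    tier <- benign_tier
    rationale <- if (tier == "Benign") (if (t$ba) "BA1" else "BS>=2") else "LB"
  } else {
    tier <- "VUS"; rationale <- character()
  }
  structure(list(tier = tier, conflict_flag = conflict,
                 rationale = rationale, counts = t),
            class = "acmg_class")
}

#' @export
print.acmg_class <- function(x, ...) {
  cat(sprintf("<acmg_class> %s%s  [%s]\n", x$tier,
              if (x$conflict_flag) " (conflicting evidence)" else "",
              paste(x$rationale, collapse = ",")))
  invisible(x)
}

.point_weights <- c(Supporting = 1, Moderate = 2, Strong = 4,
                    VeryStrong = 8, StandAlone = 8)

#' Combine evidence under the Bayesian point system (advisory)
#'
#' Pathogenic items score +1/+2/+4/+8 for Supporting/Moderate/Strong/Very
#' strong; benign items score the negatives. Tiers: >= 10 Pathogenic, 6..9
#' Likely pathogenic, 0..5 VUS, -6..-1 Likely benign, <= -7 Benign. BA1 is
#' Benign outright. The engine is advisory: the categorical calculus above is
#' what the pipeline reports, and the two are expected to disagree on exactly
#' one of the transcribed clinical evidence sets (a double-Strong upgrade
#' worth 9 points).
#'
#' @inheritParams combine_rule_based
#' @return list with `points` (integer) and `tier`.
#' @export
combine_points <- function(evidence) {
  if (is.character(evidence)) evidence <- parse_evidence(evidence)
  if (any(evidence$code == "BA1"))
    return(list(points = -8L, tier = "Benign"))
  w <- .point_weights[evidence$strength]
  pts <- sum(ifelse(evidence$direction == "pathogenic", w, -w))
  tier <- if (pts >= 10) "Pathogenic"
          else if (pts >= 6) "LikelyPathogenic"
          else if (pts >= 0) "VUS"
          else if (pts >= -6) "LikelyBenign"
          else "Benign"
  list(points = as.integer(pts), tier = tier)
}

#' PVS1 decision tree for loss-of-function variants
#'
#' Maps a loss-of-function consequence plus minimal transcript context to the
#' applied PVS1 strength, following the hearing-loss adaptation of the LoF
#' decision tree: a truncation predicted to trigger nonsense-mediated decay
#' in an established LoF gene earns full VeryStrong; a splice-region change
#' whose exon skip preserves reading frame outside a critical region earns
#' Strong; a last-exon truncation replacing only a short terminal segment
#' earns Moderate. Node outcomes are overridable via `outcomes`.
#'
#' @param consequence Sequence Ontology term.
#' @param nmd_escape logical: does the truncation escape nonsense-mediated
#'   decay (e.g. last exon)? Required for truncating consequences.
#' @param frame_preserved logical: does the predicted exon skip preserve
#'   frame? Required for splice consequences.
#' @param critical_region logical: does the lost/altered region hit a region
#'   critical to protein function? Default FALSE.
#' @param terminal_short logical: for NMD-escaping truncations, is the
#'   replaced terminal segment short? Default TRUE.
#' @param outcomes named list overriding tree-leaf strengths
#'   (`nmd`, `frame_preserving_splice`, `disruptive_splice`,
#'   `last_exon_short`, `last_exon_long`).
#' @return applied strength string, `"not_applicable"`, or an error condition
#'   `"insufficient context"` when a required flag is missing.
#' @export
pvs1_strength <- function(consequence, nmd_escape = NA, frame_preserved = NA,
                          critical_region = FALSE, terminal_short = TRUE,
                          outcomes = list()) {
  leaf <- utils::modifyList(list(nmd = "VeryStrong",
                                 frame_preserving_splice = "Strong",
                                 disruptive_splice = "VeryStrong",
                                 last_exon_short = "Moderate",
                                 last_exon_long = "Strong"), outcomes)
  truncating <- c("stop_gained", "frameshift_variant")
  splicing <- c("splice_region_deletion", "splice_acceptor_variant",
                "splice_donor_variant")
  if (!(consequence %in% c(truncating, splicing))) return("not_applicable")
  if (consequence %in% splicing) {
    if (is.na(frame_preserved))
      stop("insufficient context: frame_preserved required for splice variants",
           call. = FALSE)
    if (frame_preserved && !isTRUE(critical_region))
      return(leaf$frame_preserving_splice)
    return(leaf$disruptive_splice)
  }
  if (is.na(nmd_escape))
    stop("insufficient context: nmd_escape required for truncating variants",
         call. = FALSE)
  if (!nmd_escape) return(leaf$nmd)
  if (isTRUE(terminal_short) && !isTRUE(critical_region))
    return(leaf$last_exon_short)
  leaf$last_exon_long
}

#' Suggest frequency- and score-based evidence (advisory)
#'
#' Mechanical suggestions calibrated against the transcribed clinical set:
#' PP3 for missense with REVEL at or above `revel_pp3`; PM2 at full Moderate
#' when the variant is absent from every population (popmax 0); PM2 at
#' Supporting when popmax is positive but at or below `rare_threshold`;
#' BS1 at Supporting when popmax exceeds the inheritance-mode-dependent
#' `bs1_threshold`. Suggestions never override curated evidence strings.
#'
#' @param consequence Sequence Ontology term.
#' @param revel REVEL score (missense only) or NA.
#' @param popmax_af popmax allele frequency.
#' @param mode inheritance mode `"AD"`, `"AR"` or `"XL"` (for the BS1 bound).
#' @param config list of thresholds: `revel_pp3` (0.7), `rare_threshold`
#'   (1e-4), `bs1_threshold` (AD 2e-4, AR 1e-3, XL 2e-4).
#' @return character vector of suggested evidence tokens.
#' @export
suggest_score_evidence <- function(consequence, revel = NA, popmax_af = 0,
                                   mode = "AD", config = list()) {
  cfg <- utils::modifyList(list(revel_pp3 = 0.7, rare_threshold = 1e-4,
                                bs1_threshold = c(AD = 2e-4, AR = 1e-3, XL = 2e-4)),
                           config)
  out <- character()
  if (identical(consequence, "missense_variant") && !is.na(revel) &&
      revel >= cfg$revel_pp3)
    out <- c(out, "PP3")
  if (!is.na(popmax_af)) {
    if (popmax_af == 0) out <- c(out, "PM2")
    else if (popmax_af <= cfg$rare_threshold) out <- c(out, "PM2_P")
    bs1 <- cfg$bs1_threshold[[mode]]
    if (popmax_af > bs1) out <- c(out, "BS1_P")
  }
  out
}

#' Classify a table of candidates
#'
#' Applies [combine_rule_based()] (authoritative) and [combine_points()]
#' (advisory) to each row's curated `evidence` string and adds a `warm`
#' column: a warm VUS is a VUS whose set carries no benign-direction item,
#' i.e. an uncontradicted candidate that can fill a causal dose slot.
#'
#' @param candidates data.frame with an `evidence` column.
#' @param conflict_policy passed to [combine_rule_based()].
#' @return `candidates` with `class`, `conflict`, `points`, `points_tier`,
#'   `warm` columns appended.
#' @export
classify_variants <- function(candidates,
                              conflict_policy = "pathogenic_priority") {
  if (nrow(candidates) == 0L) {
    for (col in c("class", "conflict", "points", "points_tier", "warm"))
      candidates[[col]] <- logical(0)
    return(candidates)
  }
  res <- lapply(candidates$evidence, function(e) {
    ev <- parse_evidence(e)
    rb <- combine_rule_based(ev, conflict_policy)
    pt <- combine_points(ev)
    list(class = rb$tier, conflict = rb$conflict_flag,
         points = pt$points, points_tier = pt$tier,
         warm = rb$tier == "VUS" && !any(ev$direction == "benign"))
  })
  candidates$class <- vapply(res, `[[`, character(1), "class")
  candidates$conflict <- vapply(res, `[[`, logical(1), "conflict")
  candidates$points <- vapply(res, `[[`, integer(1), "points")
  candidates$points_tier <- vapply(res, `[[`, character(1), "points_tier")
  candidates$warm <- vapply(res, `[[`, logical(1), "warm")
  candidates
}
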