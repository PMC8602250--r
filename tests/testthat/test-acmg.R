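test_that("evidence strings parse with suffix overrides and strict validation", {
  ev <- parse_evidence("PVS1, PM3, PM2_P")
  expect_equal(ev$code, c("PVS1", "PM3", "PM2"))
  expect_equal(ev$strength, c("VeryStrong", "Moderate", "Supporting"))
  ev <- parse_evidence("pm2")  # case-insensitive
  expect_equal(ev$strength, "Moderate")
  ev <- parse_evidence(" PM3_S ,PP1_S,  PP3, BS1_P")
  expect_equal(ev$direction, c(rep("pathogenic", 3), "benign"))
  expect_equal(ev$strength, c("Strong", "Strong", "Supporting", "Supporting"))
  expect_error(parse_evidence("PM2_Q"), "PM2_Q")
  expect_error(parse_evidence("PZ9"), "PZ9")
  expect_error(parse_evidence("PM2, PM2_P"), "duplicate")
  expect_equal(nrow(parse_evidence("")), 0L)
})

test_that("the rule-based engine reproduces the printed class for all 16 golden sets", {
  fx <- load_fixture()
  golden <- fx[!duplicated(fx$key), ]
  expect_equal(nrow(golden), 16L)
  map <- c(Pathogenic = "Pathogenic", `Likely pathogenic` = "LikelyPathogenic",
           VUS = "VUS")
  got <- vapply(golden$evidence,
                function(e) combine_rule_based(e)$tier, character(1),
                USE.NAMES = FALSE)
  expect_equal(got, unname(map[golden$printed_class]))
  expect_equal(sum(got == "Pathogenic"), 4L)
  expect_equal(sum(got == "LikelyPathogenic"), 3L)
  expect_equal(sum(got == "VUS"), 9L)
})

test_that("specific combinations hit the intended rules and policies", {
  r <- combine_rule_based("PM1, PM2, PM5, PP1, PP3, PP4")
  expect_equal(r$tier, "LikelyPathogenic")
  expect_true("L4" %in% r$rationale)
  r <- combine_rule_based("PVS1, PM3, PM2_P")
  expect_equal(r$tier, "Pathogenic")
  expect_true("P1" %in% r$rationale)
  r <- combine_rule_based("PM3_S, PP1_S, PP3, BS1_P")
  expect_equal(r$tier, "Pathogenic")  # two upgraded Strongs
  expect_true(r$conflict_flag)
  expect_true("P2" %in% r$rationale)
  r <- combine_rule_based("PP1_S, PM2, PS2_M, PS4_M, PP3")
  expect_equal(r$tier, "Pathogenic")
  expect_true("P3" %in% r$rationale)
  r <- combine_rule_based("PVS1_S, PM2, PM3_P")
  expect_equal(r$tier, "LikelyPathogenic")
  expect_true("L2" %in% r$rationale)
  expect_equal(combine_rule_based("PVS1_M, PM2_P, PM3_P")$tier, "VUS")
  expect_equal(combine_rule_based("PM2, PM4")$tier, "VUS")
  expect_equal(combine_rule_based("")$tier, "VUS")
  expect_equal(combine_rule_based("")$rationale, character())
  # PVS1 + a single Supporting reaches Likely pathogenic (L7)
  expect_equal(combine_rule_based("PVS1, PP3")$tier, "LikelyPathogenic")
  # strict policy turns any two-direction conflict into VUS
  s <- combine_rule_based("PM3_S, PP1_S, PP3, BS1_P", "strict")
  expect_equal(s$tier, "VUS")
  expect_true(s$conflict_flag)
  # benign side
  expect_equal(combine_rule_based("BA1, PM2")$conflict_flag, TRUE)
  expect_equal(combine_rule_based("BA1")$tier, "Benign")
  expect_equal(combine_rule_based("BS1, BS2")$tier, "Benign")
  expect_equal(combine_rule_based("BS1, BP4")$tier, "LikelyBenign")
  expect_equal(combine_rule_based("BP4, BP7")$tier, "LikelyBenign")
  expect_equal(combine_rule_based("BP4")$tier, "VUS")
})

test_that("the point system scores and tiers as specified", {
  # expected points computed by hand: 3x2 + 3x1 = 9
  p <- combine_points("PM1, PM2, PM5, PP1, PP3, PP4")
  expect_equal(p$points, 9L)
  expect_equal(p$tier, "LikelyPathogenic")
  expect_equal(combine_points("")$points, 0L)
  expect_equal(combine_points("")$tier, "VUS")
  # 4 + 4 + 1 - 1 = 8
  p <- combine_points("PM3_S, PP1_S, PP3, BS1_P")
  expect_equal(p$points, 8L)
  expect_equal(p$tier, "LikelyPathogenic")
  expect_equal(combine_points("BA1")$tier, "Benign")
  expect_equal(combine_points("BS1, BS2")$points, -8L)
})

test_that("rules and points agree on 15 of the 16 golden sets with the one documented exception", {
  fx <- load_fixture()
  golden <- fx[!duplicated(fx$key), ]
  map <- c(Pathogenic = "Pathogenic", `Likely pathogenic` = "LikelyPathogenic",
           VUS = "VUS")
  agree <- vapply(seq_len(nrow(golden)), function(i) {
    combine_rule_based(golden$evidence[i])$tier ==
      combine_points(golden$evidence[i])$tier
  }, logical(1))
  expect_equal(sum(agree), 15L)
  disagreeing <- golden[!agree, ]
  expect_equal(disagreeing$evidence, "PM3_S, PP1_S, PP3, BS1_P")
  expect_equal(combine_rule_based(disagreeing$evidence)$tier, "Pathogenic")
  expect_equal(combine_points(disagreeing$evidence)$points, 8L)
})

test_that("classification is monotone under evidence addition and upgrade", {
  tiers <- c(Benign = 1, LikelyBenign = 2, VUS = 3,
             LikelyPathogenic = 4, Pathogenic = 5)
  strengths <- c("Supporting", "Moderate", "Strong", "VeryStrong")
  suffix <- c(Supporting = "_P", Moderate = "_M", Strong = "_S",
              VeryStrong = "_VS")
  path_codes <- c("PVS1", "PS1", "PS4", "PM1", "PM2", "PM3", "PP1", "PP3")
  set.seed(13)
  for (i in 1:80) {
    n <- sample(0:4, 1)
    codes <- sample(path_codes, n)
    st <- sample(strengths, n, replace = TRUE)
    spec <- paste0(codes, suffix[st], collapse = ", ")
    base <- combine_rule_based(spec)$tier
    # add one pathogenic item
    extra <- sample(setdiff(path_codes, codes), 1)
    spec_add <- paste(c(if (nzchar(spec)) spec, paste0(extra, "_P")),
                      collapse = ", ")
    expect_gte(tiers[combine_rule_based(spec_add)$tier], tiers[base])
    # upgrade one item's strength
    if (n > 0) {
      j <- sample(n, 1)
      cur <- match(st[j], strengths)
      if (cur < 4) {
        st2 <- st; st2[j] <- strengths[cur + 1]
        spec_up <- paste0(codes, suffix[st2], collapse = ", ")
        expect_gte(tiers[combine_rule_based(spec_up)$tier], tiers[base])
      }
    }
  }
})

test_that("the LoF decision tree maps the published truncating variants correctly", {
  # NMD-predicted nonsense in an established LoF gene -> full VeryStrong
  expect_equal(pvs1_strength("stop_gained", nmd_escape = FALSE), "VeryStrong")
  # frame-preserving exon skip outside a critical region -> Strong
  expect_equal(pvs1_strength("splice_region_deletion", frame_preserved = TRUE),
               "Strong")
  # last-exon truncation replacing a short terminal segment -> Moderate
  expect_equal(pvs1_strength("stop_gained", nmd_escape = TRUE), "Moderate")
  expect_equal(pvs1_strength("missense_variant"), "not_applicable")
  expect_error(pvs1_strength("stop_gained"), "insufficient context")
  expect_error(pvs1_strength("splice_region_deletion"), "insufficient context")
  # frame-disrupting splice stays VeryStrong; critical region blocks Moderate
  expect_equal(pvs1_strength("splice_acceptor_variant", frame_preserved = FALSE),
               "VeryStrong")
  expect_equal(pvs1_strength("stop_gained", nmd_escape = TRUE,
                             critical_region = TRUE), "Strong")
  # leaf outcomes are configurable
  expect_equal(pvs1_strength("stop_gained", nmd_escape = FALSE,
                             outcomes = list(nmd = "Strong")), "Strong")
})

test_that("score/frequency suggestions calibrate against every missense fixture row", {
  fx <- load_fixture()
  mis <- fx[fx$consequence == "missense_variant", ]
  for (i in seq_len(nrow(mis))) {
    sug <- suggest_score_evidence("missense_variant", mis$revel[i],
                                  mis$popmax_af[i])
    has_pp3 <- grepl("PP3", mis$evidence[i])
    expect_equal("PP3" %in% sug, has_pp3,
                 label = sprintf("PP3 suggestion for %s (REVEL %.3f)",
                                 mis$protein[i], mis$revel[i]))
  }
  expect_true("PM2" %in% suggest_score_evidence("stop_gained", NA, 0))
  expect_true("PM2_P" %in% suggest_score_evidence("missense_variant", 0.2, 5e-5))
  expect_true("BS1_P" %in%
                suggest_score_evidence("missense_variant", 0.2, 0.002, "AR"))
  expect_false("BS1_P" %in%
                 suggest_score_evidence("missense_variant", 0.2, 5e-4, "AR"))
})

test_that("classify_variants marks warm VUS and carries both engines", {
  df <- data.frame(key = c("a", "b", "c", "d"),
                   evidence = c("PM2", "PM2, BP4", "PVS1, PM3, PM2_P", ""),
                   stringsAsFactors = FALSE)
  out <- classify_variants(df)
  expect_equal(out$class, c("VUS", "VUS", "Pathogenic", "VUS"))
  expect_equal(out$warm, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$points, c(2L, 1L, 11L, 0L))
})
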