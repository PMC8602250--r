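# a 10-member three-generation pedigree used across segregation tests
big_ped <- function() {
  pedigree("FAMT", data.frame(
    id = c("gf", "gm", "fa", "mo", "un", "pro", "sib1", "sib2", "sp", "ch"),
    father = c("0", "0", "gf", "0", "gf", "fa", "fa", "fa", "0", "pro"),
    mother = c("0", "0", "gm", "0", "gm", "mo", "mo", "mo", "0", "sp"),
    sex = c(1, 2, 1, 2, 1, 1, 2, 1, 2, 2),
    phenotype = c(2, 1, 2, 1, 1, 2, 2, 1, 1, 2)), proband = "pro")
}

test_that("pedigree validation catches structural errors", {
  expect_error(pedigree("F", data.frame(id = c("a", "a"), father = "0",
                                        mother = "0", sex = 1, phenotype = 1)),
               "duplicate")
  expect_error(pedigree("F", data.frame(id = "a", father = "zz", mother = "0",
                                        sex = 1, phenotype = 1)), "unresolved")
  expect_error(pedigree("F", data.frame(id = c("a", "b"),
                                        father = c("0", "a"),
                                        mother = c("0", "0"),
                                        sex = c(2, 1),
                                        phenotype = c(1, 2))),
               "father must be male")
  # cycle: a's father is b, b's father is a
  expect_error(pedigree("F", data.frame(id = c("a", "b"),
                                        father = c("b", "a"),
                                        mother = c("0", "0"),
                                        sex = c(1, 1),
                                        phenotype = c(1, 1))),
               "own ancestor")
  expect_error(pedigree("F", data.frame(id = "a", father = "0", mother = "0",
                                        sex = 1, phenotype = 2),
                        proband = "x"), "proband")
})

test_that("PED files round-trip through read_ped", {
  p <- tempfile(fileext = ".ped")
  writeLines(c("FAM1\tpro\tfa\tmo\t1\t2",
               "FAM1\tfa\t0\t0\t1\t1",
               "FAM1\tmo\t0\t0\t2\t1"), p)
  ped <- read_ped(p, proband = "pro")
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped$members), 3L)
  expect_equal(ped$proband, "pro")
})

test_that("genotype configurations follow the inheritance-mode dose rules", {
  # published homozygote: AR full
  expect_equal(causal_configuration("AR", c(v1 = 2L)), "full")
  # published compound het, phase unknown: AR full
  expect_equal(causal_configuration("AR", c(v1 = 1L, v2 = 1L)), "full")
  expect_equal(causal_configuration("AR", c(v1 = 1L, v2 = 1L),
                                    phase = function(a, b) "unknown"), "full")
  expect_equal(causal_configuration("AR", c(v1 = 1L, v2 = 1L),
                                    phase = function(a, b) "cis"), "half")
  expect_equal(causal_configuration("AR", c(v1 = 1L)), "half")
  expect_equal(causal_configuration("AR", c(v1 = 0L)), "none")
  expect_equal(causal_configuration("AD", c(v1 = 1L)), "full")
  expect_equal(causal_configuration("AD", c(v1 = 0L, v2 = NA)), "none")
  # X-linked: hemizygous male, het female (default on), config off
  expect_equal(causal_configuration("XL", c(v1 = 1L), sex = "male"), "full")
  expect_equal(causal_configuration("XL", c(v1 = 1L), sex = "female"), "full")
  expect_equal(causal_configuration("XL", c(v1 = 1L), sex = "female",
                                    female_het_affected = FALSE), "half")
  expect_equal(causal_configuration("XL", c(v1 = 2L), sex = "female",
                                    female_het_affected = FALSE), "full")
  expect_error(causal_configuration("YL", c(v1 = 1L)), "unknown inheritance")
})

test_that("AD configuration is monotone in added qualifying variants", {
  set.seed(31)
  rank <- c(none = 0, half = 1, full = 2)
  for (i in 1:25) {
    n <- sample(1:4, 1)
    d <- setNames(sample(c(0L, 1L, 2L, NA), n, replace = TRUE),
                  paste0("v", seq_len(n)))
    base <- causal_configuration("AD", d)
    d2 <- c(d, extra = sample(1:2, 1))
    expect_gte(rank[causal_configuration("AD", d2)], rank[base])
  }
})

test_that("compound-het phasing requires both parents and is forced by transmission", {
  p <- pedigree("F", data.frame(
    id = c("fa", "mo", "pro"), father = c("0", "0", "fa"),
    mother = c("0", "0", "mo"), sex = c(1, 2, 1), phenotype = c(1, 1, 2)),
    proband = "pro")
  # each parent carries exactly one variant -> trans
  expect_equal(phase_compound_het(p, c(fa = 1L, mo = 0L, pro = 1L),
                                  c(fa = 0L, mo = 1L, pro = 1L), "pro"),
               "trans")
  # one parent carries both, the other neither -> cis
  expect_equal(phase_compound_het(p, c(fa = 1L, mo = 0L, pro = 1L),
                                  c(fa = 1L, mo = 0L, pro = 1L), "pro"),
               "cis")
  # missing parental genotypes -> unknown, never cis/trans
  expect_equal(phase_compound_het(p, c(fa = NA, mo = NA, pro = 1L),
                                  c(fa = NA, mo = NA, pro = 1L), "pro"),
               "unknown")
  # both parents carry both -> uninformative
  expect_equal(phase_compound_het(p, c(fa = 1L, mo = 1L, pro = 1L),
                                  c(fa = 1L, mo = 1L, pro = 1L), "pro"),
               "unknown")
  expect_error(phase_compound_het(p, c(fa = 1L, mo = 0L, pro = 2L),
                                  c(fa = 0L, mo = 1L, pro = 1L), "pro"),
               "heterozygous")
  # founder carrier: parents outside the pedigree -> unknown
  p2 <- pedigree("F", data.frame(id = "solo", father = "0", mother = "0",
                                 sex = 1, phenotype = 2), proband = "solo")
  expect_equal(phase_compound_het(p2, c(solo = 1L), c(solo = 1L), "solo"),
               "unknown")
})

test_that("informative meioses match brute-force edge enumeration", {
  ped <- big_ped()
  # AD variant tracking affection perfectly
  dos <- c(gf = 1L, gm = 0L, fa = 1L, mo = 0L, un = 0L, pro = 1L,
           sib1 = 1L, sib2 = 0L, sp = 0L, ch = 1L)
  # brute force over parent-child edges with genotyped parent+child and
  # known child affection: count consistency
  m <- ped$members
  expected <- 0L
  for (i in seq_len(nrow(m))) {
    for (par in c(m$father[i], m$mother[i])) {
      if (par == "0" || is.na(dos[par]) || is.na(dos[m$id[i]])) next
      aff <- m$phenotype[i] == 2
      if (m$phenotype[i] == 0) next
      if ((aff && dos[m$id[i]] >= 1) || (!aff && dos[m$id[i]] == 0))
        expected <- expected + 1L
    }
  }
  out <- count_informative_meioses(ped, dos, "AD")
  expect_equal(out$count, expected)
  expect_false(out$contradiction)
  expect_gte(out$count, 4L)  # enough transmissions for Moderate
})

test_that("a contradicting relative resets the meiosis count and flags", {
  ped <- big_ped()
  dos <- c(gf = 1L, gm = 0L, fa = 1L, mo = 0L, un = 0L, pro = 1L,
           sib1 = 0L,  # affected sister without the variant
           sib2 = 0L, sp = 0L, ch = 1L)
  out <- count_informative_meioses(ped, dos, "AD")
  expect_equal(out$count, 0L)
  expect_true(out$contradiction)
})

test_that("no genotyped relatives means zero informative meioses", {
  ped <- big_ped()
  dos <- c(gf = NA, gm = NA, fa = NA, mo = NA, un = NA, pro = 1L,
           sib1 = NA, sib2 = NA, sp = NA, ch = NA)
  out <- count_informative_meioses(ped, dos, "AD")
  expect_equal(out$count, 0L)
  expect_equal(pp1_strength(out$count), "none")
})

test_that("PP1 strength thresholds map counts as configured", {
  expect_equal(pp1_strength(0), "none")
  expect_equal(pp1_strength(2), "Supporting")
  expect_equal(pp1_strength(4), "Moderate")
  expect_equal(pp1_strength(6), "Strong")
  expect_equal(pp1_strength(3, c(Supporting = 1, Moderate = 3, Strong = 9)),
               "Moderate")
})

test_that("inconsistency detection finds under-dosed affected and unaffected carriers", {
  # affected sister only heterozygous for a homozygous recessive variant
  ped <- pedigree("F", data.frame(
    id = c("fa", "mo", "pro", "sis"), father = c("0", "0", "fa", "fa"),
    mother = c("0", "0", "mo", "mo"), sex = c(1, 2, 2, 2),
    phenotype = c(1, 1, 2, 2)), proband = "pro")
  dm <- matrix(c(1L, 1L, 2L, 1L), 1, 4,
               dimnames = list("v1", c("fa", "mo", "pro", "sis")))
  f <- detect_inconsistencies(ped, dm, "AR")
  expect_equal(f$member, "sis")
  expect_equal(f$type, "affected_underdosed")
  # unaffected daughter carrying a dominant candidate
  ped2 <- pedigree("F", data.frame(
    id = c("pro", "sp", "dau"), father = c("0", "0", "pro"),
    mother = c("0", "0", "sp"), sex = c(1, 2, 2), phenotype = c(2, 1, 1)),
    proband = "pro")
  dm2 <- matrix(c(1L, 0L, 1L), 1, 3,
                dimnames = list("v1", c("pro", "sp", "dau")))
  f2 <- detect_inconsistencies(ped2, dm2, "AD")
  expect_equal(f2$member, "dau")
  expect_equal(f2$type, "unaffected_carrier")
  # fully consistent nuclear family -> empty
  dm3 <- matrix(c(1L, 1L, 2L, 2L), 1, 4,
                dimnames = list("v1", c("fa", "mo", "pro", "sis")))
  expect_equal(nrow(detect_inconsistencies(ped, dm3, "AR")), 0L)
})
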