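# Frequency classification and the 12 gene-level Boolean representations.

test_that("frequency classification honours the class thresholds", {
  expect_equal(classify_frequency(0.0005, FALSE, 1L), "ultra_rare")
  expect_equal(classify_frequency(NA, TRUE, 3L), "discarded")
  expect_equal(classify_frequency(NA, TRUE, 1L), "ultra_rare")
  expect_equal(classify_frequency(NA, FALSE, 5L), "ultra_rare")
  # boundary reading: left-closed under the default convention
  expect_equal(classify_frequency(0.001, FALSE, 1L), "rare")
  expect_equal(classify_frequency(0.01, FALSE, 1L), "low_frequency")
  expect_equal(classify_frequency(0.05, FALSE, 1L), "common")
  # the alternative closure flips exact boundaries down a class
  expect_equal(classify_frequency(0.001, FALSE, 1L, boundary = "results"), "ultra_rare")
  expect_equal(classify_frequency(0.01, FALSE, 1L, boundary = "results"), "rare")
  expect_error(classify_frequency(-0.1, FALSE, 1L), class = "ipgs_domain_error")
  expect_error(classify_frequency(1.5, FALSE, 1L), class = "ipgs_domain_error")
  expect_error(classify_frequency(NA, FALSE, NA), class = "ipgs_domain_error")
})

test_that("classification agrees with a direct threshold oracle on fuzzed input", {
  withr::with_seed(31, {
    for (i in 1:200) {
      maf <- if (runif(1) < 0.2) NA else runif(1)
      indel <- runif(1) < 0.3
      cnt <- sample(1:4, 1)
      expect_equal(classify_frequency(maf, indel, cnt),
                   oracle_class(maf, indel, cnt))
    }
  })
})

test_that("collapsed representations implement the 1-variant / 2-allele rules", {
  v <- tibble::tibble(
    sample_id = "s1", gene = "G", chrom = "7", pos = 100L, ref = "A", alt = "G",
    protein_impacting = TRUE, ref_maf = 0.0002, zygosity = "heterozygous"
  )
  ad <- build_collapsed_representation(v, "ultra_rare", "AD", samples = c("s1", "s2"))
  ar <- build_collapsed_representation(v, "ultra_rare", "AR", samples = c("s1", "s2"))
  expect_equal(unname(ad$matrix["s1", "UR_AD:G"]), 1L)
  expect_equal(unname(ar$matrix["s1", "UR_AR:G"]), 0L)
  # a sample without qualifying variants is an all-zero row
  expect_equal(unname(ad$matrix["s2", ]), 0L)
  # a homozygous call counts two alleles toward the recessive rule
  v$zygosity <- "homozygous_alt"
  ar2 <- build_collapsed_representation(v, "ultra_rare", "AR", samples = "s1")
  expect_equal(unname(ar2$matrix["s1", "UR_AR:G"]), 1L)
  # wrong-class input violates the contract
  v$ref_maf <- 0.3
  expect_error(build_collapsed_representation(v, "ultra_rare", "AD"),
               class = "ipgs_contract_error")
})

test_that("a two-variant gene yields the A, B, AB combinations plus absence", {
  toy <- make_toy_fixture()
  common <- toy$variants[toy$variants$gene == "GD", ]
  rep_ad <- build_common_representation(common, "AD",
                                        samples = toy$phenotypes$sample_id)
  combos <- rep_ad$features[rep_ad$features$members != "absence", ]
  expect_equal(nrow(combos), 3L)
  expect_setequal(combos$members,
                  c("2:2000:C:T", "2:2100:G:A", "2:2000:C:T+2:2100:G:A"))
  expect_equal(sum(rep_ad$features$members == "absence"), 1L)
  # carrying A and B heterozygously activates A, B and AB and kills absence
  s02 <- rep_ad$matrix["s02", ]
  expect_equal(unname(s02[combos$feature_id]), c(1L, 1L, 1L))
  expect_equal(unname(s02["C_AD:GD:absence"]), 0L)
  # no common variant: absence on, combinations off
  s08 <- rep_ad$matrix["s08", ]
  expect_equal(unname(s08["C_AD:GD:absence"]), 1L)
  expect_true(all(s08[combos$feature_id] == 0L))
  # AR: only the homozygous B carrier activates the {B} combination
  rep_ar <- build_common_representation(common, "AR",
                                        samples = toy$phenotypes$sample_id)
  expect_equal(unname(rep_ar$matrix["s04", "C_AR:GD:2:2100:G:A"]), 1L)
  expect_equal(unname(rep_ar$matrix["s02", "C_AR:GD:2:2100:G:A"]), 0L)
})

test_that("the combination cap falls back to observed genotype patterns", {
  n_var <- 8
  v <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = n_var),
    gene = "BIG", chrom = "2", pos = rep(100L + seq_len(n_var), 2), ref = "A", alt = "G",
    protein_impacting = TRUE, ref_maf = 0.2, zygosity = "heterozygous"
  )
  expect_warning(
    rep_ad <- build_common_representation(v, "AD", cap = 6),
    class = "ipgs_cap_warning"
  )
  # both samples carry all 8: one observed pattern + absence
  expect_equal(nrow(rep_ad$features), 2L)
})

test_that("the toy fixture encodes to 12 representations matching hand counts", {
  toy <- make_toy_fixture()
  reps <- encode_cohort(toy$variants, toy$phenotypes)
  expect_named(reps, c("UR_AD", "UR_AR", "UR_X", "R_AD", "R_AR", "R_X",
                       "LF_AD", "LF_AR", "LF_X", "C_AD", "C_AR", "C_X"))
  # hand-computed expectations for the fixture
  expect_equal(unname(reps$UR_AD$matrix[, "UR_AD:GA"]),
               c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(unname(reps$UR_AR$matrix[, "UR_AR:GA"]),
               c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))  # only the homozygote
  expect_equal(unname(reps$R_AR$matrix[, "R_AR:GB"]),
               c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))  # compound heterozygote
  expect_equal(unname(reps$UR_X$matrix[, "UR_X:GE"]),
               c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L))  # hemizygous male + het female
  expect_equal(ncol(reps$R_X$matrix), 0L)          # no rare X variants: empty but emitted
  # the non-protein-impacting call in s07 contributes nowhere
  expect_true(all(reps$UR_AD$matrix["s07", ] == 0L))
  expect_error(encode_cohort(toy$variants[0, ], toy$phenotypes),
               class = "ipgs_domain_error")
})

test_that("every matrix cell is reproduced by the brute-force recount oracle", {
  withr::with_seed(91, {
    for (round in 1:3) {
      sim <- small_sim(n = 40, seed = 100 + round)
      reps <- encode_cohort(sim$variants, sim$phenotypes)
      # the oracle sees only protein-impacting, PAR-free variants of kept classes
      expect_true(isTRUE(oracle_check_representations(reps, sim$variants)))
    }
  })
})

test_that("sample order never affects the encoded matrices", {
  sim <- small_sim(n = 30, seed = 17)
  reps1 <- encode_cohort(sim$variants, sim$phenotypes)
  shuffled <- sim$variants[sample(nrow(sim$variants)), ]
  reps2 <- encode_cohort(as_variant_table(shuffled),
                         sim$phenotypes[sample(nrow(sim$phenotypes)), ])
  for (nm in names(reps1)) expect_identical(reps1[[nm]]$matrix, reps2[[nm]]$matrix)
})

test_that("AR implies AD and absence mirrors the combinations on fuzzed cohorts", {
  for (round in 1:3) {
    sim <- small_sim(n = 50, seed = 200 + round)
    reps <- encode_cohort(sim$variants, sim$phenotypes)
    for (cls in c("UR", "R", "LF")) {
      ad <- reps[[paste0(cls, "_AD")]]; ar <- reps[[paste0(cls, "_AR")]]
      shared <- intersect(ad$features$gene, ar$features$gene)
      for (g in shared) {
        ad_col <- ad$matrix[, ad$features$feature_id[ad$features$gene == g]]
        ar_col <- ar$matrix[, ar$features$feature_id[ar$features$gene == g]]
        expect_true(all(ad_col >= ar_col))  # >=2 variants implies >=1
      }
    }
    for (nm in c("C_AD", "C_AR", "C_X")) {
      r <- reps[[nm]]
      for (g in unique(r$features$gene)) {
        f <- r$features[r$features$gene == g, ]
        absence <- r$matrix[, f$feature_id[f$members == "absence"]]
        combos <- r$matrix[, f$feature_id[f$members != "absence"], drop = FALSE]
        expect_equal(unname(absence), as.integer(rowSums(combos) == 0L))
      }
    }
  }
})

test_that("Y, MT and pseudo-autosomal variants are excluded from encoding", {
  v <- tibble::tibble(
    sample_id = "s1",
    gene = c("GY", "GMT", "GPAR", "GOK"),
    chrom = c("Y", "MT", "X", "X"),
    pos = c(100L, 200L, 100100L, 5000000L),
    ref = "A", alt = "G", protein_impacting = TRUE, ref_maf = 0.0002,
    zygosity = c("hemizygous", "heterozygous", "hemizygous", "hemizygous")
  )
  reps <- encode_cohort(v, c(s1 = "M"))
  genes <- unlist(lapply(reps, function(r) r$features$gene))
  expect_equal(unname(genes), "GOK")
})
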