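# Codon bias statistics against hand-computed values and brute-force
# oracles.

test_that("count_codons tallies sense and stop codons separately", {
  cc <- count_codons(c("ATG", "TAA"))
  expect_equal(unname(cc$counts[c("ATG", "TAA")]), c(1L, 1L))
  expect_equal(cc$sense_total, 1L)
  expect_equal(cc$stop_total, 1L)
  cc2 <- count_codons(rep("GCT", 100))
  expect_equal(unname(cc2$counts["GCT"]), 100L)
  expect_equal(cc2$sense_total, 100L)
  cc3 <- count_codons(rep(genetic_code_table()$sense_codons, 2))
  expect_equal(cc3$sense_total, 122L)
  expect_error(count_codons(c("ATG", "AXG")), "AXG.*position 2")
})

test_that("RSCU matches hand-computed values and distinguishes 0 from NA", {
  # Phe 3:1 -> 1.5 / 0.5
  rs <- rscu(count_codons(c(rep("TTT", 3), "TTC")))
  phe <- rs[rs$amino_acid == "F", ]
  expect_equal(phe$rscu[phe$codon == "TTT"], 1.5)
  expect_equal(phe$rscu[phe$codon == "TTC"], 0.5)
  # uniform four-fold family -> all 1.0
  rs2 <- rscu(count_codons(c("GCT", "GCC", "GCA", "GCG")))
  expect_equal(rs2$rscu[rs2$amino_acid == "A"], rep(1, 4))
  # Leu only CTG (count 5) -> 6.0, siblings 0.0
  rs3 <- rscu(count_codons(rep("CTG", 5)))
  leu <- rs3[rs3$amino_acid == "L", ]
  expect_equal(leu$rscu[leu$codon == "CTG"], 6)
  expect_equal(leu$rscu[leu$codon != "CTG"], rep(0, 5))
  # absent amino acids are NA, not 0
  expect_true(all(is.na(rs3$rscu[rs3$amino_acid == "K"])))
})

test_that("RSCU sums to the degeneracy within each observed amino acid", {
  set.seed(42)
  for (i in 1:1000) {
    rs <- rscu(count_codons(random_codons(sample(5:120, 1))))
    sums <- tapply(rs$rscu, rs$amino_acid, sum)
    deg <- genetic_code_table()$degeneracy[names(sums)]
    ok <- !is.na(sums)
    expect_equal(as.numeric(sums[ok]), as.numeric(deg[ok]), tolerance = 1e-12)
  }
})

test_that("ENC hits its boundary values", {
  code <- genetic_code_table()
  # one codon per amino acid, each count >= 2 -> exactly 20
  one_per_aa <- unlist(lapply(code$families, function(f) rep(f[1], 3)),
                       use.names = FALSE)
  expect_equal(enc(count_codons(one_per_aa))$value, 20)
  # every sense codon twice -> raw 102, capped at 61
  e <- enc(count_codons(rep(code$sense_codons, 2)))
  expect_equal(e$raw, 102)
  expect_equal(e$value, 61)
  # uniform synthetic genes of >= 3000 codons land near the top
  cfg <- simulation_config(n_genes = 3, length_range = c(3000, 3000),
                           profile = make_profile(beta = 0), seed = 99)
  for (s in generate_cds_set(cfg)$sequence) {
    v <- enc(count_codons(split_codons(s)))$value
    expect_gt(v, 58)
    expect_lte(v, 61)
  }
})

test_that("ENC flags too-few-observation genes instead of returning 0", {
  e <- enc(count_codons(c("ATG", "TTT"))) # single Phe observation
  expect_false(e$computable)
  expect_true(is.na(e$value))
})

test_that("ENC imputes the Ile class mean from the 2- and 4-fold classes", {
  code <- genetic_code_table()
  no_ile <- setdiff(code$sense_codons, code$families[["I"]])
  e <- enc(count_codons(rep(no_ile, 2)))
  expect_true(e$computable)
  expect_equal(unname(e$class_means["F3"]),
               unname((e$class_means["F2"] + e$class_means["F4"]) / 2))
})

test_that("ENC and RSCU match brute-force oracles on short random genes", {
  set.seed(2024)
  for (i in 1:500) {
    codons <- random_codons(sample(3:30, 1))
    cc <- count_codons(codons)
    # RSCU
    rs <- rscu(cc)
    oracle <- oracle_rscu(codons)
    got <- stats::setNames(rs$rscu, rs$codon)[names(oracle)]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
    # ENC (both sides NA, or both equal)
    e <- enc(cc)
    o <- oracle_enc(codons)
    if (is.na(o)) {
      expect_true(is.na(e$value))
    } else {
      expect_equal(e$value, o, tolerance = 1e-10)
    }
  }
})

test_that("CAI is the geometric mean of reference weights", {
  w <- cai_weights()
  w[] <- 1
  expect_equal(cai(count_codons(c("TTT", "AAA", "GGG")), w), 1)
  w2 <- w; w2["TTT"] <- 0.25
  expect_equal(cai(count_codons(c("TTT", "TTC")), w2), 0.5) # sqrt(0.25)
  # Met/Trp and stops are excluded
  expect_equal(cai(count_codons(c("ATG", "TGG", "TAA", "TTC")), w2), 1)
  # no eligible codons -> NA
  expect_true(is.na(cai(count_codons(c("ATG", "TGG")), w2)))
})

test_that("CAI never decreases when a codon is swapped for a higher-w synonym", {
  set.seed(5)
  w <- cai_weights()
  for (i in 1:50) {
    codons <- random_codons(30)
    base <- cai(count_codons(codons), w)
    code <- genetic_code_table()
    j <- sample(30, 1)
    aa <- code$aa[[codons[j]]]
    fam <- code$families[[aa]]
    best <- fam[which.max(w[fam])]
    codons[j] <- best
    expect_gte(cai(count_codons(codons), w) + 1e-12, base)
  }
})

test_that("CBI and Fop follow the optimal-codon accounting", {
  # all optimal
  r <- cbi_fop(count_codons(rep("TTC", 10)), optimal = "TTC")
  expect_equal(r$cbi, 1)
  expect_equal(r$fop, 1)
  # 2-fold amino acid, half optimal: random usage
  r2 <- cbi_fop(count_codons(c(rep("TTC", 5), rep("TTT", 5))),
                optimal = "TTC")
  expect_equal(r2$cbi, 0)
  expect_equal(r2$fop, 0.5)
  # none optimal
  r3 <- cbi_fop(count_codons(rep("TTT", 10)), optimal = "TTC")
  expect_equal(r3$cbi, -1)
  expect_equal(r3$fop, 0)
  # RNA spelling accepted
  expect_equal(cbi_fop(count_codons(rep("TTC", 4)), optimal = "UUC")$fop, 1)
})

test_that("third-position composition follows the silent-site conventions", {
  # all-GCC gene: every synonymous third position is C
  cc <- count_codons(rep("GCC", 100))
  comp <- third_position_composition(cc, strrep("GCC", 100))
  expect_equal(comp$gc3s, 1)
  expect_equal(comp$c3s, 1)
  expect_equal(comp$t3s, 0)
  # 50 GCT + 50 GCA: no G/C third bases
  comp2 <- third_position_composition(
    count_codons(c(rep("GCT", 50), rep("GCA", 50))))
  expect_equal(comp2$gc3s, 0)
  # X3s denominator restricted to amino acids that can accept the base:
  # Phe (TTT/TTC) cannot end in A, so A3s over a Phe+Lys gene counts only Lys
  comp3 <- third_position_composition(
    count_codons(c("TTT", "TTC", "AAA", "AAA")))
  expect_equal(comp3$a3s, 1) # both Lys codons end in A; Phe not in denominator
  expect_equal(comp3$t3s, 0.5) # only Phe accepts T at pos 3: TTT of TTT+TTC
  # GC over the full sequence, Met/Trp/stops excluded from GC3s only
  s <- paste0("ATG", strrep("GGC", 9), "TAA")
  comp4 <- third_position_composition(count_codons(split_codons(s)), s)
  expect_equal(comp4$gc, 28 / 33)
  expect_equal(comp4$gc3s, 1)
})

test_that("usage_table rows equal the individual statistics", {
  recs <- generate_cds_set(simulation_config(n_genes = 4, seed = 12))
  w <- cai_weights()
  opt <- optimal_codons_default(w)
  tab <- usage_table(recs, w, opt)
  expect_equal(names(tab), c("gene", "T3s", "C3s", "A3s", "G3s", "CAI",
                             "CBI", "Fop", "ENC", "GC3s", "GC"))
  i <- 2
  cc <- count_codons(split_codons(recs$sequence[i]))
  expect_equal(tab$ENC[i], enc(cc)$value)
  expect_equal(tab$CAI[i], cai(cc, w))
  expect_equal(tab$Fop[i], cbi_fop(cc, opt)$fop)
  comp <- third_position_composition(cc, recs$sequence[i])
  expect_equal(tab$GC3s[i], comp$gc3s)
  expect_equal(tab$GC[i], comp$gc)
  # empty input -> empty table
  expect_equal(nrow(usage_table(cds_set(character(0), character(0)))), 0)
  # summary rows
  s <- attr(tab, "summary")
  expect_equal(unname(s$average["ENC"]), mean(tab$ENC))
})

test_that("GC3s of generated genes recovers the profile target", {
  for (target in c(0.35, 0.5, 0.7)) {
    prof <- make_profile(beta = 0.2, target_gc3s = target)
    cfg <- simulation_config(n_genes = 10, length_range = c(500, 500),
                             profile = prof, seed = round(1000 * target))
    recs <- generate_cds_set(cfg)
    pooled <- pool_codon_counts(recs)
    comp <- third_position_composition(pooled)
    n_syn <- sum(pooled$counts[unlist(
      genetic_code_table()$families[genetic_code_table()$synonymous_aa])])
    sigma <- sqrt(target * (1 - target) / n_syn)
    expect_lt(abs(comp$gc3s - target), 3 * sigma + 1e-9)
  }
})

test_that("weights are validated on load", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(codon = names(cai_weights()), value = unname(cai_weights()))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_weights_tsv(path), cai_weights())
  bad <- df[-1, ]
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_weights_tsv(path), "missing")
})
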