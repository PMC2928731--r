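test_that("per-site Fitch steps match hand-checked columns", {
  tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  aln <- alignment(c(a = "AAAA", b = "ACAN", c = "AGCA", d = "ATCA"))
  prof <- fitch_site_steps(aln, tr)
  expect_equal(prof$min_steps[1], 0)   # constant
  expect_equal(prof$min_steps[2], 3)   # A,C,G,T needs 3 changes
  expect_equal(prof$min_steps[3], 1)   # (A,A,C,C) on matching split
  expect_equal(prof$min_steps[4], 0)   # N never forces a change
  # site 4 sits in a trailing partial codon: not annotated
  expect_equal(prof$codon_position, c(1, 2, 3, NA))
})

test_that("Fitch equals the exhaustive minimum over internal labelings", {
  set.seed(40)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    tr <- simulate_tree(n, seed = 600 + rep)
    m <- matrix(sample(c("A", "C", "G", "T", "N"), n * 12, TRUE,
                       prob = c(.23, .23, .23, .23, .08)),
                n, 12, dimnames = list(tr$tip.label, NULL))
    aln <- alignment(m)
    prof <- fitch_site_steps(aln, tr)
    oracle <- sapply(seq_len(ncol(m)), function(j) {
      col <- m[, j]; names(col) <- rownames(m)
      brute_force_steps(tr, col)
    })
    expect_equal(prof$min_steps, oracle)
  }
})

test_that("total parsimony steps ignore leaf input order", {
  tr <- simulate_tree(6, seed = 41)
  aln <- random_dna(6, 50, seed = 42, ids = tr$tip.label)
  s1 <- sum(fitch_site_steps(aln, tr)$min_steps)
  s2 <- sum(fitch_site_steps(aln[sample(rownames(aln)), ], tr)$min_steps)
  expect_equal(s1, s2)
})

test_that("amino-acid-change flagging distinguishes silent from replacement sites", {
  tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  # codon 1: GGA/GGC (Gly/Gly, silent at position 3)
  # codon 2: CCA/ACA (Pro/Thr, replacement at position 1)
  # codon 3: constant ATG
  aln <- alignment(c(a = "GGACCAATG", b = "GGAACAATG",
                     c = "GGCCCAATG", d = "GGCACAATG"))
  prof <- fitch_site_steps(aln, tr)
  cls <- classify_recurrent_aa_changes(prof, aln)
  expect_false(cls$aa_change[3])          # Gly <-> Gly
  expect_true(cls$aa_change[4])           # Pro <-> Thr
  expect_false(any(cls$aa_change[7:9]))   # constant codon never flagged
  # position 4 varies on both sides of the split: recurrent replacement
  expect_equal(prof$min_steps[4], 2)
  expect_true(cls$recurrent_aa[4])
})

test_that("synonymous and non-synonymous differences are classified per codon", {
  expect_equal(count_synonymous_diffs("GGAATG", "GGAATG"),
               list(syn = 0L, nonsyn = 0L, ambiguous = 0L))
  expect_equal(count_synonymous_diffs("GGAATG", "GGGATG")$syn, 1L)   # Gly=Gly
  expect_equal(count_synonymous_diffs("GGAATG", "GGAATA")$nonsyn, 1L) # Met->Ile
  # two hits in one codon are ambiguous, never silently assigned
  r <- count_synonymous_diffs("GGAATG", "GCCATG")
  expect_equal(r$ambiguous, 2L)
  expect_equal(r$syn + r$nonsyn, 0L)
  # missing context also goes to ambiguous
  r2 <- count_synonymous_diffs("GGA", "GNG")
  expect_equal(r2$ambiguous, 1L)
  expect_error(count_synonymous_diffs("GGA", "GG"), "equal length")
})

test_that("the mutation-rate bound is s_syn / (length x years)", {
  expect_equal(signif(mutation_rate(3, 500, 11)$rate, 2), 5.5e-4)
  expect_equal(signif(mutation_rate(10, 500, 11)$rate, 2), 1.8e-3)
  expect_equal(mutation_rate(0, 500, 11)$rate, 0)
  # linear in the count, inverse in length and time
  set.seed(43)
  for (i in 1:5) {
    s <- sample(1:20, 1); l <- sample(100:900, 1); y <- runif(1, 1, 30)
    expect_equal(mutation_rate(2 * s, l, y)$rate,
                 2 * mutation_rate(s, l, y)$rate)
    expect_equal(mutation_rate(s, 2 * l, y)$rate,
                 mutation_rate(s, l, 2 * y)$rate)
  }
  expect_error(mutation_rate(3, 500, 0), "years")
})

test_that("haplotype grouping honours the identity policy", {
  aln <- alignment(c(x1 = "AAA", x2 = "AAA", x3 = "AAC"))
  g <- distinct_haplotypes(aln)
  expect_equal(g$n_distinct, 2)
  expect_setequal(g$groups[[1]], c("x1", "x2"))

  aln2 <- alignment(c(p = "AAN", q = "AAA"))
  expect_equal(distinct_haplotypes(aln2, "missing-tolerant")$n_distinct, 1)
  expect_equal(distinct_haplotypes(aln2, "strict")$n_distinct, 2)

  # two timepoints with identical sequences fall in one group
  aln3 <- alignment(c(t0 = "ACGTACGT", t3mo = "ACGTACGT"))
  expect_equal(distinct_haplotypes(aln3)$n_distinct, 1)
})

test_that("label-tree association test detects clade-aligned labels", {
  tr <- parse_newick(paste0("(((a1:.1,a2:.1):.1,(a3:.1,a4:.1):.1):.1,",
                            "((b1:.1,b2:.1):.1,(b3:.1,b4:.1):.1):.1);"))
  labs <- setNames(rep(c("A", "B"), each = 4), tr$tip.label)
  r <- label_association_test(tr, labs, n_perm = 999, seed = 1)
  expect_equal(r$statistic, 1)
  expect_lte(r$p_value, 0.05)

  r2 <- label_association_test(tr, labs, n_perm = 999, seed = 1)
  expect_identical(r$p_value, r2$p_value)

  bad <- setNames(c(rep("A", 7), "B"), tr$tip.label)
  expect_error(label_association_test(tr, bad, n_perm = 99), "degenerate")
})

test_that("label permutation p-values are roughly uniform under the null", {
  tr <- simulate_tree(10, seed = 44)
  ids <- tr$tip.label
  set.seed(45)
  pvals <- replicate(60, {
    labs <- setNames(sample(rep(c("A", "B"), 5)), ids)
    label_association_test(tr, labs, n_perm = 99,
                           seed = sample.int(1e6, 1))$p_value
  })
  # the parsimony statistic is heavily discrete, so the permutation p is
  # super-uniform: calibrated or conservative, never anti-conservative
  expect_lte(mean(pvals <= 0.05), 0.12)
  expect_lte(mean(pvals <= 0.25), 0.37)
  expect_gte(mean(pvals), 0.45)
})
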