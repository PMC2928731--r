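test_that("JC distances follow the closed form and flag saturation", {
  aln <- alignment(c(a = strrep("A", 100), b = strrep("A", 100)))
  expect_equal(jc_distance_matrix(aln)$d["a", "b"], 0)

  # p = 0.1 -> d = -(3/4) ln(1 - 4*0.1/3) = 0.107326
  s <- c(strrep("A", 90), strrep("C", 10))
  aln2 <- alignment(c(a = strrep("A", 100), b = paste(s, collapse = "")))
  expect_equal(jc_distance_matrix(aln2)$d["a", "b"],
               -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)

  # p = 0.8: beyond the JC saturation point
  s3 <- paste0(strrep("A", 20), strrep("C", 80))
  aln3 <- alignment(c(a = strrep("A", 100), b = s3))
  dm <- jc_distance_matrix(aln3, cap = 5)
  expect_true(dm$flagged["a", "b"])
  expect_equal(dm$d["a", "b"], 5)

  # positions with N are excluded pairwise
  aln4 <- alignment(c(a = "AANA", b = "AACA"))
  expect_equal(jc_distance_matrix(aln4)$d["a", "b"], 0)
  expect_error(jc_distance_matrix(alignment(c(a = "NNN", b = "ACG"))),
               "record 'a'")
})

test_that("neighbor joining recovers additive metrics exactly", {
  # additive distances on ((a,b),(c,d)) with internal branch 0.3
  lab <- c("a", "b", "c", "d")
  bl <- c(a = 0.1, b = 0.2, c = 0.15, d = 0.25)
  d <- matrix(0, 4, 4, dimnames = list(lab, lab))
  for (i in 1:3) for (j in (i + 1):4) {
    x <- lab[i]; y <- lab[j]
    extra <- if (setequal(c(x, y), c("a", "b")) ||
                 setequal(c(x, y), c("c", "d"))) 0 else 0.3
    d[i, j] <- d[j, i] <- bl[x] + bl[y] + extra
  }
  tr <- nj_tree(d)
  expect_equal(phangorn::RF.dist(tr, parse_newick("((a,b),(c,d));")), 0)
  # path distances reproduce the metric
  cd <- ape::cophenetic.phylo(tr)[lab, lab]
  expect_equal(cd, d, tolerance = 1e-10)

  # two taxa: a single split of length d12
  tr2 <- nj_tree(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                        dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(sum(tr2$edge.length), 0.4)

  # label order must not change the unrooted topology
  aln <- random_dna(6, 200, seed = 30)  # i.i.d. columns: near-saturated pairs
  t1 <- suppressWarnings(nj_tree(jc_distance_matrix(aln)))
  t2 <- suppressWarnings(nj_tree(jc_distance_matrix(aln[rev(rownames(aln)), ])))
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
})

test_that("NJ on random additive metrics reproduces the generating tree", {
  for (s in 1:5) {
    tr <- simulate_tree(sample(5:8, 1), seed = 500 + s, mean_branch = 0.2)
    tr$edge.length <- tr$edge.length + 0.05   # safely positive
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d[tr$tip.label, tr$tip.label])
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(rec)), 0)
  }
})

test_that("NNI search improves on the NJ start and is reproducible", {
  tr <- simulate_tree(6, seed = 31, mean_branch = 0.15)
  tr$edge.length <- pmax(tr$edge.length, 0.1)
  aln <- evolve_sequences(tr, subst_model(), 800, seed = 32)

  njfit <- phylo_ml(aln, model = "JC", search = "fixed")
  fit <- phylo_ml(aln, model = "JC", search = "nni")
  expect_gte(fit$lnL, njfit$lnL - 1e-9)

  fit2 <- phylo_ml(aln, model = "JC", search = "nni")
  expect_equal(fit$lnL, fit2$lnL)
  expect_equal(phangorn::RF.dist(fit$tree, fit2$tree), 0)
})

test_that("NNI search recovers well-separated topologies", {
  hits <- 0
  for (s in 1:5) {
    tr <- simulate_tree(6, seed = s * 100, mean_branch = 0.15)
    tr$edge.length <- pmax(tr$edge.length, 0.1)
    aln <- evolve_sequences(tr, subst_model(), 1000, seed = s * 100 + 1)
    fit <- phylo_ml(aln, model = "JC", search = "nni")
    hits <- hits + (phangorn::RF.dist(ape::unroot(tr),
                                      ape::unroot(fit$tree)) == 0)
  }
  expect_gte(hits, 4)
})

test_that("chi-squared upper-tail quantiles invert the tail probability", {
  expect_equal(round(chi2_quantile(0.001, 1), 2), 10.83)
  expect_equal(chi2_quantile(1, 1), 0)
  expect_equal(round(chi2_quantile(0.05, 1), 2), 3.84)
  for (p in c(0.001, 0.01, 0.5)) {
    for (df in c(1, 3)) {
      expect_equal(pchisq(chi2_quantile(p, df), df, lower.tail = FALSE), p,
                   tolerance = 1e-8)
    }
  }
  expect_error(chi2_quantile(0, 1), "tail_prob")
  expect_error(chi2_quantile(0.05, 0), "df")
})

test_that("the likelihood ratio test applies the chi-squared decision rule", {
  null <- list(lnL = -1000, n_free_params = 30)
  alt <- list(lnL = -1000 + 27.2504 / 2, n_free_params = 31)
  r <- lrt(null, alt, level = 0.001)
  expect_equal(r$stat, 27.2504)
  expect_equal(r$df, 1)
  expect_true(r$reject)
  expect_lt(r$p_value, 0.001)

  r0 <- lrt(list(lnL = -50, n_free_params = 5),
            list(lnL = -50, n_free_params = 6))
  expect_equal(r0$stat, 0)
  expect_equal(r0$p_value, 1)
  expect_false(r0$reject)

  expect_error(lrt(list(lnL = -50, n_free_params = 6),
                   list(lnL = -49, n_free_params = 6)), "not nested")
  expect_error(lrt(list(lnL = -49, n_free_params = 5),
                   list(lnL = -50, n_free_params = 6)), "contract")
})

test_that("AIC ranking prefers the generating model class", {
  tr <- simulate_tree(6, seed = 33, mean_branch = 0.1)
  gen <- subst_model(alpha = 0.1, k = 4)
  aln <- evolve_sequences(tr, gen, 2000, seed = 34)
  tab <- select_model(aln, c("JC", "JC+G"), k = 4)
  expect_equal(tab$model[1], "JC+G")
  expect_true(all(diff(tab$AIC) >= 0))

  single <- select_model(aln, "JC", k = 4)
  expect_equal(nrow(single), 1)

  # without heterogeneity the simpler model stays competitive
  aln2 <- evolve_sequences(tr, subst_model(), 2000, seed = 35)
  tab2 <- select_model(aln2, c("JC", "JC+G"), k = 4)
  expect_lt(tab2$AIC[tab2$model == "JC"] - min(tab2$AIC), 2 + 1e-9)
})
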