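# Evidence-union TF annotation: alignment scoring, candidate streams,
# family rules, and the family-size ratio test.

test_that("local alignment score matches hand-derived values", {
  # BLOSUM62 diagonal for A,C,D,E is 4+9+6+5
  expect_equal(local_align_score("ACDE", "ACDE"), 24)
  expect_equal(local_align_score("", "ACDE"), 0)
  expect_equal(local_align_score("ACDE", ""), 0)
  # all pair scores negative -> empty local alignment
  expect_equal(local_align_score("AAAA", "CCCC"), 0)
  expect_error(local_align_score("AB1", "ACDE"), "invalid residue")
})

test_that("local alignment equals the brute-force DP oracle on short peptides", {
  set.seed(42)
  mat <- blosum62_oracle()
  alph <- c("A", "C", "D", "E")
  seqs <- c("", replicate(24, paste(sample(alph, sample(1:8, 1),
                                           replace = TRUE),
                                    collapse = "")))
  for (i in seq_along(seqs)) {
    for (j in seq(i, length(seqs))) {
      expect_equal(local_align_score(seqs[i], seqs[j]),
                   sw_oracle(seqs[i], seqs[j], mat),
                   info = paste(seqs[i], seqs[j]))
      # symmetry under a symmetric matrix
      expect_equal(local_align_score(seqs[i], seqs[j]),
                   local_align_score(seqs[j], seqs[i]))
    }
  }
})

test_that("similarity candidates are ranked, capped, and deduplicated", {
  targets <- c(t1 = "ACDEFGHIKL", t2 = "ACDEFGHIKL", t3 = "MNPQRSTVWY")
  res <- similarity_candidates(c(q1 = "ACDEFGHIKL"), targets,
                               max_targets = 10)
  expect_setequal(res$genes, c("t1", "t2", "t3"))
  expect_equal(res$hits$gene[1:2], c("t1", "t2"))  # ties lexicographic

  # 12 targets with distinct scores, cap 10: two lowest excluded
  set.seed(1)
  q <- paste(sample(AA <- c("A","C","D","E","F","G","H","I","K","L"),
                    30, replace = TRUE), collapse = "")
  tg <- vapply(1:12, function(i) {
    # increasingly corrupted copies of the query -> decreasing scores
    ch <- strsplit(q, "")[[1]]
    idx <- seq_len(2 * i)
    ch[idx] <- rev(c("W", "Y"))[idx %% 2 + 1]
    paste(ch, collapse = "")
  }, "")
  names(tg) <- sprintf("t%02d", 1:12)
  sc <- vapply(tg, function(s) local_align_score(q, s), 0)
  worst2 <- names(sort(sc))[1:2]
  res <- similarity_candidates(c(q = q), tg, max_targets = 10)
  expect_length(res$genes, 10)
  expect_false(any(worst2 %in% res$genes))
})

test_that("ortholog candidates deduplicate and report malformed rows", {
  tab <- data.frame(src = c("r1", "r2", "r2", "r3", "r4"),
                    poly = c("g1", "g1", "g2", "g3", "g3"))
  expect_equal(ortholog_candidates(tab), c("g1", "g2", "g3"))
  expect_equal(ortholog_candidates(tab[0, ]), character())
  bad <- data.frame(src = c("r1", "r2"), poly = c("g1", ""))
  expect_error(ortholog_candidates(bad), "line 3")
})

test_that("domain rules assign, reject forbidden combos, and flag ambiguity", {
  rules <- default_family_rules()
  tab <- data.frame(
    gene = c("g1", "g2", "g2", "g3", "g3"),
    domain = c("DOM_NAC", "DOM_NAC", "DOM_FORBID", "DOM_NAC", "DOM_MYB"))
  dc <- domain_candidates(tab, rules)
  expect_equal(dc$family[dc$gene == "g1"], "NAC")
  expect_equal(dc$status[dc$gene == "g2"], "rejected")
  expect_equal(dc$status[dc$gene == "g3"], "ambiguous")
  expect_equal(dc$family[dc$gene == "g3"], "MYB;NAC")
  # gene with no relevant domains is not a candidate at all
  none <- domain_candidates(data.frame(gene = "g9", domain = "DOM_OTHER"),
                            rules)
  expect_equal(nrow(none), 0)
})

test_that("union records evidence, enforces rules, and recovers the truth set", {
  clean <- simulate_dataset(small_config(false_positive_rate = 0))
  poly <- clean$truth$genes[clean$truth$genes$species == "polyploid", ]
  truth_tf <- poly$gene[!is.na(poly$family)]
  orth <- clean$truth$orthologs
  orth_tf <- orth$poly_gene[orth$poly_gene %in% truth_tf]
  calls <- union_and_classify(similarity = truth_tf[1:5],
                              orthologs = unique(orth_tf),
                              domain_table = clean$domains,
                              proteome_info = poly)
  expect_setequal(calls$gene, truth_tf)   # recall and precision 1
  ev <- strsplit(calls$evidence[calls$gene == truth_tf[1]], ";")[[1]]
  expect_setequal(ev, c("similarity", "ortholog", "domain"))
  # a similarity-only candidate failing the rules is excluded
  nontf <- setdiff(poly$gene, truth_tf)[1]
  calls2 <- union_and_classify(similarity = nontf, orthologs = character(),
                               domain_table = clean$domains,
                               proteome_info = poly)
  expect_false(nontf %in% calls2$gene)
  # union is order-independent across streams
  calls3 <- union_and_classify(similarity = unique(orth_tf),
                               orthologs = truth_tf[1:5],
                               domain_table = clean$domains,
                               proteome_info = poly)
  expect_setequal(calls3$gene, calls$gene)
})

test_that("family ratio test matches closed-form chi-square arithmetic", {
  exact <- family_ratio_test(30, 10, 3)
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)
  ft <- family_ratio_test(13, 10, 3)
  expect_equal(ft$chi2, (13 - 17.25)^2 / 17.25 + (10 - 5.75)^2 / 5.75,
               tolerance = 1e-12)
  expect_equal(ft$p, pchisq(ft$chi2, 1, lower.tail = FALSE))
  expect_equal(round(ft$chi2, 3), 4.188)
  expect_equal(round(ft$p, 4), 0.0407)
  zero <- family_ratio_test(0, 10, 3)
  expect_equal(zero$chi2, 30)
  expect_lt(zero$p, 1e-7)
  for (n in c(1, 7, 123)) {
    expect_equal(family_ratio_test(3 * n, n, 3)$p, 1)
  }
  expect_error(family_ratio_test(0, 0), "zero")
})

test_that("chromosome distribution tallies agree with an independent recount", {
  sim <- fx$sim
  poly <- fx$poly_info
  calls <- union_and_classify(character(), character(), sim$domains, poly)
  dist <- chromosome_distribution(calls)
  expect_equal(sum(dist$counts$n),
               sum(calls$status == "assigned" & !is.na(calls$chrom_group)))
  # spot-check one cell against a direct tally of the truth
  nac2a <- sum(poly$family %in% "NAC" & poly$chrom_group == 2 &
                 poly$subgenome == "A")
  cell <- dist$counts$n[dist$counts$chrom_group == 2 &
                          dist$counts$subgenome == "A" &
                          dist$counts$family == "NAC"]
  expect_equal(sum(cell), nac2a)
  empty <- chromosome_distribution(calls[0, ])
  expect_equal(nrow(empty$counts), 0)
})
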