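# Expression collation, filtering, normalization, and the signed-hybrid
# coexpression network machinery.

test_that("transcript aggregation sums to gene level and warns on unmapped", {
  tx <- matrix(c(1, 2.5, 4, 1, 2.5, 4), nrow = 3,
               dimnames = list(c("g1.1", "g1.2", "g2.1"), c("s1", "s2")))
  map <- data.frame(transcript = c("g1.1", "g1.2", "g2.1"),
                    gene = c("g1", "g1", "g2"))
  out <- aggregate_to_genes(tx, map)
  expect_equal(out["g1", ], c(s1 = 3.5, s2 = 3.5))
  expect_equal(out["g2", ], c(s1 = 4, s2 = 4))
  expect_warning(out2 <- aggregate_to_genes(tx, map[1:2, ]),
                 "excluded")
  expect_equal(rownames(out2), "g1")
  expect_error(aggregate_to_genes(tx, rbind(map, map[1, ])), "exactly one")
})

test_that("the expression filter is strict and idempotent", {
  x <- rbind(kept = c(0.6, 0.6, 0.6, 0),
             boundary = c(0.5, 0.5, 0.5, 0.5),
             burst = c(5, 0, 0, 0))
  colnames(x) <- paste0("s", 1:4)
  out <- filter_expressed(x)
  expect_equal(rownames(out), "kept")
  expect_identical(filter_expressed(out), out)
  expect_error(filter_expressed(x[, 1:2]), "fewer samples")
})

test_that("min-max normalization maps rows into [0,1] and zeros constants", {
  x <- rbind(a = c(2, 4, 6), b = c(5, 5, 5))
  out <- minmax_normalize(x)
  expect_equal(unname(out["a", ]), c(0, 0.5, 1))
  expect_equal(unname(out["b", ]), c(0, 0, 0))
  expect_true(all(out >= 0 & out <= 1))
  set.seed(5)
  y <- matrix(rexp(50), 5)
  ny <- minmax_normalize(y)
  expect_true(all(apply(ny, 1, max) == 1))
  expect_true(all(apply(ny, 1, min) == 0))
})

test_that("expressed fraction per group is a straight recount", {
  ga <- data.frame(gene = paste0("g", 1:6),
                   group = c("a", "a", "a", "a", "b", NA))
  out <- expressed_fraction_by_group(c("g1", "g2", "g5"), ga)
  expect_equal(out$fraction[out$group == "a"], 0.5)
  expect_equal(out$fraction[out$group == "b"], 1.0)
  expect_false(any(is.na(out$group)))
})

test_that("bicor approximates Pearson on clean Gaussian data", {
  set.seed(100)
  n <- 100
  z <- rnorm(n)
  x <- cbind(g1 = z + rnorm(n, sd = 0.5),
             g2 = z + rnorm(n, sd = 0.5),
             g3 = rnorm(n),
             g4 = -z + rnorm(n, sd = 0.5))
  pc <- cor(x)
  bc <- bicor_matrix(x)
  expect_lt(max(abs(pc - bc)), 0.05)
  expect_true(isSymmetric(bc))
  expect_equal(unname(diag(bc)), rep(1, 4))

  expr <- t(x)
  expect_warning(cm <- correlation_matrix(rbind(expr, flat = rep(1, n))),
                 "zero-variance")
  expect_equal(unname(cm["flat", "g1"]), 0)
  expect_equal(unname(cm["flat", "flat"]), 1)
  # perfectly anti-correlated pair
  anti <- rbind(u = c(1, 2, 3, 4, 5), v = c(5, 4, 3, 2, 1))
  expect_equal(correlation_matrix(anti)["u", "v"], -1)
})

test_that("soft-threshold selection: connectivity decreases with power", {
  set.seed(3)
  sim <- simulate_dataset(small_config(seed = 3))
  expr <- aggregate_to_genes(sim$expression$tx_tpm, sim$expression$tx2gene)
  expr <- filter_expressed(expr)
  cm <- suppressWarnings(correlation_matrix(log2(expr + 1)))
  st <- pick_soft_threshold(cm, powers = c(1, 2, 4, 6, 8))
  expect_true(all(diff(st$fit$mean_k) < 0))
  expect_true(st$beta %in% st$fit$power)
  # deterministic: rerun gives the same pick
  expect_equal(pick_soft_threshold(cm, powers = c(1, 2, 4, 6, 8))$beta,
               st$beta)
})

test_that("topological overlap matches its closed forms", {
  # 2-gene network: TOM_12 = a
  for (a in c(0.2, 0.7, 1)) {
    adj <- matrix(c(0, a, a, 0), 2, 2,
                  dimnames = list(c("g1", "g2"), c("g1", "g2")))
    expect_equal(tom_similarity(adj)["g1", "g2"], a)
  }
  # empty graph -> identity
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(tom_similarity(z), diag(3), ignore_attr = TRUE)
  # complete graph with unit weights -> all ones
  k <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(k) <- 0
  expect_true(all(tom_similarity(k) == 1))
  # range and symmetry on a random adjacency
  set.seed(2)
  r <- matrix(runif(36), 6)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  dimnames(r) <- list(paste0("g", 1:6), paste0("g", 1:6))
  tom <- tom_similarity(r)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_true(isSymmetric(tom))
})

test_that("noiseless planted blocks are recovered exactly and merged when identical", {
  set.seed(9)
  ns <- 20
  f <- matrix(rnorm(3 * ns), 3)
  expr_log <- rbind(
    f[rep(1, 35), ] + 3,
    f[rep(2, 35), ] + 3,
    f[rep(3, 35), ] + 3)
  rownames(expr_log) <- sprintf("g%03d", seq_len(nrow(expr_log)))
  colnames(expr_log) <- paste0("s", seq_len(ns))
  truth <- rep(1:3, each = 35)
  cm <- suppressWarnings(correlation_matrix(expr_log))
  tom <- tom_similarity(signed_hybrid_adjacency(cm, 6))
  res <- detect_modules(tom, expr_log, min_size = 30)
  expect_equal(length(setdiff(unique(res$modules), 0L)), 3)
  expect_equal(ari(res$modules[rownames(expr_log)], truth), 1)

  # two identical planted modules merge into one
  expr2 <- rbind(f[rep(1, 35), ], f[rep(1, 35), ] + 5)
  rownames(expr2) <- sprintf("h%03d", seq_len(70))
  colnames(expr2) <- paste0("s", seq_len(ns))
  cm2 <- suppressWarnings(correlation_matrix(expr2))
  # force two clusters at cut, then let the eigengene merge unify them
  tom2 <- tom_similarity(signed_hybrid_adjacency(cm2, 6))
  res2 <- detect_modules(tom2, expr2, min_size = 30, cut_height = 0.99)
  expect_equal(length(setdiff(unique(res2$modules), 0L)), 1)
})

test_that("planted modules are recovered at SNR 3 with ARI above 0.8", {
  cfg <- sim_config(seed = 3, n_triads = 600, n_nac_triads = 0,
                    nac_groups = integer(), other_tf_families = c(),
                    n_samples = 60, n_modules = 5, module_snr = 3)
  sim <- simulate_dataset(cfg)
  expr <- aggregate_to_genes(sim$expression$tx_tpm, sim$expression$tx2gene)
  expr <- filter_expressed(expr)
  res <- coexpression_modules(expr)
  truthmod <- setNames(sim$truth$modules$module, sim$truth$modules$gene)
  common <- intersect(names(res$modules), names(truthmod)[truthmod > 0])
  expect_gt(ari(res$modules[common], truthmod[common]), 0.8)
  # module sizes respect the minimum except for module 0
  sizes <- table(res$modules[res$modules > 0])
  expect_true(all(sizes >= 30))
})

test_that("module composition chi-square matches hand arithmetic", {
  modules <- setNames(rep(1L, 20), paste0("g", 1:20))
  tf <- paste0("g", 1:10)
  nac <- paste0("g", 1:3)
  out <- module_composition(modules, tf, nac, global_nac_fraction = 0.08)
  expect_equal(out$n_tf, 10)
  expect_equal(out$pct_nac_of_tf, 30)
  chi2_hand <- (3 - 0.8)^2 / 0.8 + (7 - 9.2)^2 / 9.2
  expect_equal(out$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(out$p, pchisq(chi2_hand, 1, lower.tail = FALSE))
  # module matching the global fraction exactly gives p = 1
  m2 <- setNames(rep(1L, 100), paste0("h", 1:100))
  out2 <- module_composition(m2, paste0("h", 1:50), paste0("h", 1:5),
                             global_nac_fraction = 0.1)
  expect_equal(out2$p, 1)
  # module with no NACs reports zero percent
  out3 <- module_composition(m2, paste0("h", 1:50), character(),
                             global_nac_fraction = 0.1)
  expect_equal(out3$pct_nac_of_tf, 0)
})

test_that("planted NAC overrepresentation is detected with high power", {
  set.seed(17)
  n_tf <- 60
  detected <- vapply(seq_len(200), function(i) {
    k <- rbinom(1, n_tf, 0.30)
    modules <- setNames(rep(1L, n_tf), paste0("g", seq_len(n_tf)))
    out <- module_composition(modules, names(modules),
                              head(names(modules), k),
                              global_nac_fraction = 0.08)
    out$p < 0.05
  }, TRUE)
  expect_gte(mean(detected), 0.9)
})
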