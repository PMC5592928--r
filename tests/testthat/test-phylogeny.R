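# Domain extraction, occupancy trimming, p-distances, neighbor joining,
# and group-label propagation.

test_that("domain extraction honors 1-based inclusive boundaries", {
  expect_equal(extract_nac_domain("MKDEF", c(2, 4)), "KDE")
  expect_equal(extract_nac_domain("MKDEF", c(1, 5)), "MKDEF")
  expect_error(extract_nac_domain("MKDEF", c(0, 4)), "out of range")
  expect_error(extract_nac_domain("MKDEF", c(2, 9)), "out of range")
})

test_that("occupancy trimming keeps >= 10% columns and is idempotent", {
  # 20 rows; col1 has 1 residue (5%) -> dropped, col2 has 2 (10%) -> kept
  rows <- c(paste0("A", "A", "CC"), rep("--CC", 18), "-ACC")
  names(rows) <- paste0("s", 1:20)
  out <- trim_alignment(rows)
  expect_equal(unique(nchar(out)), 3)
  expect_equal(unname(out[1]), "ACC")
  expect_identical(trim_alignment(out), out)
  gapfree <- c(a = "ACDE", b = "ACDE")
  expect_identical(trim_alignment(gapfree), gapfree)
})

test_that("all-gap rows are removed and counted", {
  msa <- c(a = "AC-E", b = "----", c = "ACDE", d = "----")
  out <- drop_empty_sequences(msa)
  expect_setequal(names(out), c("a", "c"))
  expect_identical(drop_empty_sequences(out), out)
  expect_error(drop_empty_sequences(c(x = "---")), "empty")
})

test_that("p-distances use pairwise gap deletion", {
  expect_equal(pairwise_distances(c(a = "ACDE", b = "ACDE"))["a", "b"], 0)
  expect_equal(pairwise_distances(c(a = "ACDE", b = "CDEA"))["a", "b"], 1)
  # two shared columns, both identical
  d <- pairwise_distances(c(a = "AC-E", b = "ACD-"))
  expect_equal(d["a", "b"], 0)
  # disjoint coverage -> distance 1 with a warning
  expect_warning(d2 <- pairwise_distances(c(a = "AC--", b = "--DE")),
                 "no aligned columns")
  expect_equal(d2["a", "b"], 1)
  m <- pairwise_distances(c(a = "ACDE", b = "ACDF", c = "AAAA"))
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
})

test_that("neighbor joining solves the 3-taxon closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 1)
  expect_equal(bl[["b"]], 1)
  expect_equal(bl[["c"]], 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  expect_true(all(neighbor_joining(matrix(1, 4, 4,
    dimnames = list(letters[1:4], letters[1:4])) -
      diag(4))$edge.length >= 0))
})

test_that("NJ exactly recovers additive trees up to 6 taxa, all topologies", {
  for (ntip in 4:6) {
    tops <- phangorn::allTrees(ntip, rooted = FALSE)
    set.seed(ntip)
    for (ti in seq_along(tops)) {
      tr <- tops[[ti]]  # [[ restores tip labels from the multiPhylo
      tr$edge.length <- runif(nrow(tr$edge), 0.2, 1.5)
      d <- cophenetic(tr)
      est <- neighbor_joining(d[tr$tip.label, tr$tip.label])
      expect_equal(phangorn::RF.dist(est, tr), 0)
      expect_equal(sort(est$edge.length), sort(tr$edge.length),
                   tolerance = 1e-8)
    }
  }
})

test_that("group propagation assigns unanimous clades and flags conflicts", {
  # unanimous clades
  tr <- ape::read.tree(text = "((w1:1,r1:1):1,(w2:1,(r2:1,r3:1):1):1);")
  asg <- propagate_groups(tr, labels = c(r1 = "a", r2 = "b", r3 = "b"))
  expect_equal(asg$group[asg$gene == "w1"], "a")
  expect_equal(asg$group[asg$gene == "w2"], "b")

  # reference discordant with the rest of its clade -> query unassigned
  txt <- paste0("(((((w:0.1,r1:0.1):0.1,x1:0.1):0.1,x2:0.1):0.1,",
                "x3:0.1):0.5,(y1:0.1,y2:0.1):0.5);")
  tr2 <- ape::read.tree(text = txt)
  asg2 <- propagate_groups(tr2,
                           labels = c(r1 = "a", x1 = "b", x2 = "b",
                                      x3 = "b", y1 = "c", y2 = "c"))
  expect_true(is.na(asg2$group[asg2$gene == "w"]))

  # no polyploid leaves -> empty assignment
  asg3 <- propagate_groups(tr, labels = c(w1 = "a", r1 = "a", w2 = "b",
                                          r2 = "b", r3 = "b"))
  expect_equal(nrow(asg3), 0)
  expect_error(propagate_groups(tr, labels = character()), "no labeled")
})

test_that("label suffixes round-trip through Newick files", {
  tr <- ape::read.tree(text = "((w1:1,r1:1):1,(w2:1,(r2:1,r3:1):0.123456):1);")
  labels <- c(r1 = "a", r2 = "b", r3 = "b")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick_labeled(tr, path, labels)
  back <- read_newick_labeled(path)
  expect_setequal(back$tree$tip.label, tr$tip.label)
  expect_equal(back$labels[names(labels)], labels)
  expect_equal(phangorn::RF.dist(back$tree, tr), 0)
  expect_equal(sort(back$tree$edge.length), sort(tr$edge.length),
               tolerance = 1e-6)
  # propagate_groups can consume the suffix encoding directly
  raw <- ape::read.tree(path)
  asg <- propagate_groups(raw)
  expect_equal(asg$group[asg$gene == "w2"], "b")
  suppressWarnings(
    expect_error(read_newick_labeled(withr::local_tempfile(fileext = ".nwk")),
                 "malformed Newick"))
})

test_that("synthetic pipeline assigns every NAC to its true group", {
  cfg <- small_config(seed = 11, domain_truncation_rate = 0)
  sim <- generate_proteomes(cfg)
  msa <- drop_empty_sequences(trim_alignment(sim$msa))
  tr <- neighbor_joining(pairwise_distances(msa))
  g <- sim$truth$genes
  refs <- g[g$species != "polyploid" & !is.na(g$nac_group), ]
  labels <- setNames(refs$nac_group, refs$gene)
  asg <- propagate_groups(tr, labels = labels)
  truth_grp <- setNames(g$nac_group, g$gene)
  expect_true(all(!is.na(asg$group)))
  expect_equal(unname(truth_grp[asg$gene]), asg$group)

  # leaf-order invariance
  perm <- sample(seq_along(msa))
  tr2 <- neighbor_joining(pairwise_distances(msa[perm]))
  asg2 <- propagate_groups(tr2, labels = labels)
  expect_equal(asg2[order(asg2$gene), ], asg[order(asg$gene), ],
               ignore_attr = TRUE)

  # planting one mislabeled reference inside another group's clade makes
  # its polyploid sisters unassigned
  bad <- labels
  agene <- refs$gene[refs$nac_group == "a"][1]
  bad[agene] <- "h"
  asg3 <- propagate_groups(tr, labels = bad)
  tid <- g$triad_id[g$gene == agene]
  sisters <- g$gene[g$species == "polyploid" & g$triad_id == tid]
  sisters <- intersect(sisters, asg3$gene)
  expect_true(any(is.na(asg3$group[asg3$gene %in% sisters])))
})
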