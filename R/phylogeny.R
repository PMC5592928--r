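# NAC-domain phylogeny: domain extraction, occupancy-based alignment
# trimming, neighbor-joining tree estimation, and propagation of the
# a-h phylogenetic group labels from labeled reference leaves onto
# polyploid leaves with a conflict rule.

# An MSA is represented as a named character vector of equal-length
# aligned rows, gap = "-".

check_msa <- function(msa) {
  fail_if(length(msa) == 0, "empty alignment")
  fail_if(anyDuplicated(names(msa)) > 0, "alignment ids must be unique")
  w <- unique(nchar(msa))
  fail_if(length(w) != 1, "alignment rows must have equal length")
  invisible(w)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa, "", fixed = TRUE))
}

#' Extract the NAC domain from a protein
#'
#' Returns the subsequence spanning the given 1-based inclusive
#' boundaries, i.e. from the start of subdomain A to the end of
#' subdomain E.
#'
#' @param protein Peptide string.
#' @param boundaries Integer vector `c(start, end)`, 1-based inclusive.
#' @return The domain peptide, of length `end - start + 1`.
#' @export
extract_nac_domain <- function(protein, boundaries) {
  start <- boundaries[1]
  end <- boundaries[2]
  fail_if(start < 1 || end < start || end > nchar(protein),
          "domain boundaries out of range")
  substr(protein, start, end)
}

#' Trim alignment columns by occupancy
#'
#' Keeps a column iff its fraction of non-gap residues is at least
#' `min_occupancy` (inclusive, so with 20 rows a column with exactly 2
#' residues at the default 10 percent survives). Row order is preserved
#' and the operation is idempotent.
#'
#' @param msa Named character vector of aligned rows.
#' @param min_occupancy Minimum non-gap fraction (default 0.10).
#' @return The trimmed alignment.
#' @export
trim_alignment <- function(msa, min_occupancy = 0.10) {
  check_msa(msa)
  m <- msa_matrix(msa)
  occ <- colMeans(m != "-")
  keep <- occ >= min_occupancy
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  setNames(out, names(msa))
}

#' Remove all-gap rows from an alignment
#'
#' @param msa Named character vector of aligned rows.
#' @return The alignment without rows consisting entirely of gaps.
#' @export
drop_empty_sequences <- function(msa) {
  check_msa(msa)
  m <- msa_matrix(msa)
  keep <- rowSums(m != "-") > 0
  fail_if(!any(keep), "all sequences are empty after domain extraction")
  msa[keep]
}

#' Pairwise p-distances with pairwise gap deletion
#'
#' For each pair of rows the distance is the fraction of differing
#' residues over the columns where both rows are non-gap. Pairs sharing no
#' columns get distance 1 with a warning.
#'
#' @param msa Named character vector of aligned rows (at least 2).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(msa) {
  check_msa(msa)
  fail_if(length(msa) < 2, "need at least two sequences")
  m <- msa_matrix(msa)
  n <- nrow(m)
  code <- matrix(match(m, c(AA20, "X")), n, ncol(m))
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  n_disjoint <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(code[i, ]) & !is.na(code[j, ])
      ns <- sum(shared)
      if (ns == 0) {
        d[i, j] <- d[j, i] <- 1
        n_disjoint <- n_disjoint + 1L
      } else {
        pd <- sum(code[i, shared] != code[j, shared]) / ns
        d[i, j] <- d[j, i] <- pd
      }
    }
  }
  if (n_disjoint > 0) {
    warning(n_disjoint, " sequence pair(s) share no aligned columns; ",
            "their distance was set to 1", call. = FALSE)
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric
#' non-negative distance matrix; negative branch-length estimates are
#' clamped to zero. Deterministic given the input order.
#'
#' @param d Symmetric distance matrix with at least three taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  fail_if(nrow(d) < 3, "neighbor joining needs at least 3 taxa")
  fail_if(!isSymmetric(unname(d), tol = 1e-8), "distance matrix must be symmetric")
  fail_if(any(d < 0), "distances must be non-negative")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Propagate phylogenetic group labels onto unlabeled leaves
#'
#' The tree is midpoint rooted, then each query leaf is assigned the group
#' of the smallest enclosing clade that contains at least one labeled
#' reference leaf, provided the labels in that clade are unanimous. A
#' conflict rule guards against mislabeled or misplaced references: if the
#' next enclosing clade (below the root) that adds further labeled leaves
#' is unanimously labeled with a *different* group, and carries at least
#' as many labeled leaves as the inner clade, the reference is treated as
#' discordant with the rest of the clade and the query is left unassigned.
#'
#' @param tree A `phylo` tree. Leaves may carry label suffixes of the form
#'   `"|group=a"`, which are parsed when `labels` is `NULL`.
#' @param labels Named character vector mapping reference leaf names to
#'   groups; overrides any suffix encoding.
#' @param queries Leaf names to assign; defaults to all unlabeled leaves.
#' @return A data.frame with columns `gene`, `group` (`NA` when
#'   unassigned).
#' @export
propagate_groups <- function(tree, labels = NULL, queries = NULL) {
  if (is.null(labels)) {
    parsed <- parse_leaf_labels(tree$tip.label)
    tree$tip.label <- parsed$leaf
    labels <- parsed$labels
  }
  fail_if(length(labels) == 0, "tree has no labeled reference leaves")
  fail_if(!all(names(labels) %in% tree$tip.label),
          "labels refer to unknown leaves")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree <- phangorn::midpoint(tree)
  if (is.null(queries)) {
    queries <- setdiff(tree$tip.label, names(labels))
  }
  if (length(queries) == 0) {
    return(data.frame(gene = character(), group = character(),
                      stringsAsFactors = FALSE))
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  labeled_tip <- match(names(labels), tree$tip.label)
  tip_group <- setNames(unname(labels), labeled_tip)

  assign_one <- function(leaf_name) {
    tip <- match(leaf_name, tree$tip.label)
    anc <- phangorn::Ancestors(tree, tip, type = "all")
    prev_labeled <- integer()
    candidate <- NA_character_
    for (nd in anc) {
      tips <- phangorn::Descendants(tree, nd, type = "tips")[[1]]
      lab <- intersect(tips, labeled_tip)
      if (length(lab) == 0) next
      if (is.na(candidate)) {
        # innermost clade with labeled references
        grps <- unique(tip_group[as.character(lab)])
        if (length(grps) > 1) return(NA_character_)
        candidate <- grps
        prev_labeled <- lab
        if (length(lab) == length(labeled_tip)) return(candidate)
        next
      }
      extra <- setdiff(lab, prev_labeled)
      if (length(extra) == 0) next
      if (nd == root) return(candidate)  # no outer context beyond the root
      out_grps <- unique(tip_group[as.character(extra)])
      if (length(out_grps) == 1 && out_grps != candidate &&
          length(extra) >= length(prev_labeled)) {
        return(NA_character_)  # reference discordant with rest of clade
      }
      return(candidate)
    }
    candidate
  }

  grp <- vapply(sort(queries), assign_one, "")
  data.frame(gene = sort(queries), group = unname(grp),
             stringsAsFactors = FALSE)
}

# Split "name|group=a" leaf names into bare names plus a label map.
parse_leaf_labels <- function(tip_labels) {
  has <- grepl("|group=", tip_labels, fixed = TRUE)
  leaf <- sub("\\|group=.*$", "", tip_labels)
  labels <- sub("^.*\\|group=", "", tip_labels[has])
  names(labels) <- leaf[has]
  list(leaf = leaf, labels = labels)
}

#' Read a Newick tree with optional group-label suffixes
#'
#' Leaf names of the form `"gene|group=a"` are split into the bare leaf
#' name and an entry of the returned label map.
#'
#' @param path Newick file path.
#' @return A list with `tree` (a `phylo` with bare leaf names) and
#'   `labels` (named character vector, possibly empty).
#' @export
read_newick_labeled <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick in '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  fail_if(is.null(tr), paste0("malformed Newick in '", path, "'"))
  parsed <- parse_leaf_labels(tr$tip.label)
  tr$tip.label <- parsed$leaf
  list(tree = tr, labels = parsed$labels)
}

#' Write a Newick tree with group-label suffixes
#'
#' Branch lengths are rounded to six decimals; labels are encoded on leaf
#' names as `"|group=a"` so the file round-trips through
#' [read_newick_labeled()].
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @param labels Optional named character vector leaf -> group.
#' @return Invisibly, `path`.
#' @export
write_newick_labeled <- function(tree, path, labels = NULL) {
  if (!is.null(labels) && length(labels) > 0) {
    idx <- match(names(labels), tree$tip.label)
    fail_if(anyNA(idx), "labels refer to unknown leaves")
    tree$tip.label[idx] <- paste0(tree$tip.label[idx], "|group=",
                                  unname(labels))
  }
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
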