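# Reciprocal-best-hit orthology, homeolog triad construction, and
# retention-class accounting.

#' Reciprocal best hits between two proteomes
#'
#' A pair (x, y) is reported iff y is x's unique best-scoring hit in
#' proteome Y and x is y's unique best-scoring hit in proteome X. A gene
#' whose best score is tied between two or more partners has no unique best
#' hit and is excluded; the result is therefore a matching (each gene in at
#' most one pair).
#'
#' @param proteome_x,proteome_y Named character vectors of peptides.
#' @param scorer Pairwise scoring function `(a, b) -> numeric`; defaults to
#'   [local_align_score()]. Ignored when `scores` is supplied.
#' @param scores Optional precomputed score matrix (rows = X genes,
#'   columns = Y genes); symmetric scorers make `score_ab == score_ba`.
#' @return A data.frame with columns `gene_x`, `gene_y`, `score_xy`,
#'   `score_yx`.
#' @export
reciprocal_best_hits <- function(proteome_x, proteome_y,
                                 scorer = local_align_score,
                                 scores = NULL) {
  fail_if(length(proteome_x) == 0 || length(proteome_y) == 0,
          "both proteomes must be non-empty")
  if (is.null(scores)) {
    mat <- blosum62()
    scores <- t(vapply(proteome_x,
                       function(q) score_against(q, proteome_y, mat),
                       numeric(length(proteome_y))))
    rownames(scores) <- names(proteome_x)
    colnames(scores) <- names(proteome_y)
  }
  best_unique <- function(v) {
    m <- max(v)
    idx <- which(v == m)
    if (length(idx) == 1) idx else NA_integer_
  }
  bx <- apply(scores, 1, best_unique)  # best Y partner per X gene
  by <- apply(scores, 2, best_unique)  # best X partner per Y gene
  pairs <- list()
  for (i in seq_along(bx)) {
    j <- bx[i]
    if (is.na(j)) next
    if (!is.na(by[j]) && by[j] == i) {
      pairs[[length(pairs) + 1]] <- data.frame(
        gene_x = rownames(scores)[i], gene_y = colnames(scores)[j],
        score_xy = scores[i, j], score_yx = scores[i, j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(gene_x = character(), gene_y = character(),
                      score_xy = numeric(), score_yx = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Build homeolog triads from cross-subgenome gene pairs
#'
#' Triads are the connected components of the homeolog graph whose vertices
#' are polyploid genes and whose edges are the supplied pairs. Slots are
#' filled by subgenome; a component carrying two genes of the same
#' subgenome stays in one triad (its retention class will be `other`).
#' Genes listed in `all_genes` but absent from any pair become singleton
#' triads.
#'
#' @param pairs A data.frame with columns `gene_x`, `gene_y` (as from
#'   [reciprocal_best_hits()] run between subgenomes).
#' @param subgenome_of Named character vector mapping gene id to `A`, `B`
#'   or `D`.
#' @param all_genes Optional character vector of genes that must appear in
#'   the output even if unpaired.
#' @return A data.frame with columns `triad_id`, `gene_A`, `gene_B`,
#'   `gene_D` (comma-joined lists, `-` when empty), `n_A`, `n_B`, `n_D`,
#'   `retention`.
#' @export
build_triads <- function(pairs, subgenome_of, all_genes = NULL) {
  genes <- unique(c(pairs$gene_x, pairs$gene_y, all_genes))
  fail_if(length(genes) == 0, "no genes to group")
  fail_if(!all(genes %in% names(subgenome_of)),
          "every gene needs a subgenome assignment")
  g <- igraph::graph_from_data_frame(
    d = pairs[, c("gene_x", "gene_y"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  rows <- lapply(sort(unique(comp)), function(cid) {
    members <- sort(names(comp)[comp == cid])
    sg <- subgenome_of[members]
    slot <- function(s) {
      m <- members[sg == s]
      if (length(m) == 0) "-" else paste(m, collapse = ",")
    }
    nA <- sum(sg == "A"); nB <- sum(sg == "B"); nD <- sum(sg == "D")
    data.frame(triad_id = cid, gene_A = slot("A"), gene_B = slot("B"),
               gene_D = slot("D"), n_A = nA, n_B = nB, n_D = nD,
               retention = classify_counts(nA, nB, nD),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$triad_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Retention class from per-subgenome copy counts.
classify_counts <- function(nA, nB, nD) {
  counts <- c(nA, nB, nD)
  fail_if(sum(counts) == 0, "triad with all slots empty is invalid")
  ones <- sum(counts == 1)
  zeros <- sum(counts == 0)
  if (ones == 3) "complete"
  else if (ones == 2 && zeros == 1) "single_loss"
  else "other"
}

#' Classify the homeolog retention state of a triad
#'
#' `complete` when every subgenome slot holds exactly one gene,
#' `single_loss` when exactly two slots hold one gene and one slot is
#' empty, `other` for every remaining configuration (duplications or loss
#' of two homeologs).
#'
#' @param triad A single row of the [build_triads()] output, or any list
#'   with elements `n_A`, `n_B`, `n_D`.
#' @return One of `"complete"`, `"single_loss"`, `"other"`.
#' @export
classify_retention <- function(triad) {
  classify_counts(triad$n_A, triad$n_B, triad$n_D)
}

#' Summarize retention classes over a triad table
#'
#' @param triads A [build_triads()] output (needs a `retention` column).
#' @return A list with `n_triads`, `fractions` (named, summing to 1) and
#'   `percent` (fractions rounded to the nearest integer percent).
#' @export
retention_summary <- function(triads) {
  fail_if(nrow(triads) == 0, "need at least one triad")
  lev <- c("complete", "single_loss", "other")
  tab <- table(factor(triads$retention, levels = lev))
  frac <- as.numeric(tab) / nrow(triads)
  names(frac) <- lev
  list(n_triads = nrow(triads), fractions = frac,
       percent = round(100 * frac))
}

#' Homeolog pairs implied by a truth triad table
#'
#' Expands each truth triad into the within-triad gene pairs joining
#' distinct genes, the form consumed by [build_triads()]. Useful for
#' running triad construction at scales where all-vs-all alignment is not
#' needed.
#'
#' @param truth Ground truth from [generate_proteomes()].
#' @return A data.frame with columns `gene_x`, `gene_y`.
#' @export
truth_homeolog_pairs <- function(truth) {
  g <- truth$genes
  poly <- g[g$species == "polyploid", , drop = FALSE]
  rows <- lapply(split(poly$gene, poly$triad_id), function(members) {
    if (length(members) < 2) return(NULL)
    cmb <- utils::combn(sort(members), 2)
    data.frame(gene_x = cmb[1, ], gene_y = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(gene_x = character(), gene_y = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
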