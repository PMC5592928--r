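# Functional-term (GO) overrepresentation within coexpression modules:
# one-sided hypergeometric tests with Benjamini-Hochberg control per
# module.

#' Hypergeometric term enrichment for one module
#'
#' For every term annotating at least one universe gene, computes
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' universe size, `K` the term's universe genes, `n` the module size and
#' `k` the term's module genes. Equivalent to a one-sided Fisher exact
#' test on the 2x2 table.
#'
#' @param module_genes Character vector, a subset of `universe`.
#' @param annotation Data.frame with columns `gene`, `term` (optionally
#'   `description`).
#' @param universe Character vector: the gene universe (e.g. all
#'   module-assigned genes).
#' @return A data.frame with columns `term`, `k`, `n`, `K`, `N`, `p`
#'   (and `description` when available), sorted by ascending `p`.
#' @export
hypergeometric_enrichment <- function(module_genes, annotation, universe) {
  fail_if(length(universe) == 0, "empty universe")
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  fail_if(!all(module_genes %in% universe),
          "module genes must be contained in the universe")
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  if (nrow(ann) == 0) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(module_genes)
  terms <- split(unique(ann[, c("gene", "term")])$gene,
                 unique(ann[, c("gene", "term")])$term)
  rows <- lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- sum(terms[[tm]] %in% module_genes)
    # upper tail including k itself
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("description" %in% names(annotation)) {
    d <- unique(annotation[, c("term", "description")])
    out$description <- d$description[match(out$term, d$term)]
  }
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter enrichment results to significant terms
#'
#' Benjamini-Hochberg adjustment across the terms of each module; terms
#' with adjusted p strictly below `alpha` are kept, sorted ascending.
#'
#' @param results A data.frame as returned by
#'   [hypergeometric_enrichment()], optionally with a `module` column when
#'   several modules are stacked.
#' @param alpha Adjusted-p threshold (default 0.05, strict `<`).
#' @return The filtered data.frame with an added `p_adj` column.
#' @export
significant_terms <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) {
    results$p_adj <- numeric(0)
    return(results)
  }
  if ("module" %in% names(results)) {
    parts <- split(results, results$module)
  } else {
    parts <- list(results)
  }
  out <- lapply(parts, function(df) {
    df$p_adj <- bh_qvalues(df$p)
    df[df$p_adj < alpha, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(out$p_adj, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment across all modules
#'
#' Runs [hypergeometric_enrichment()] for every module (id > 0) against a
#' common universe (by default all module-assigned genes) and stacks the
#' results with a `module` column.
#'
#' @param modules Named integer vector gene -> module (0 = unassigned).
#' @param annotation Data.frame with columns `gene`, `term`.
#' @param universe Gene universe; defaults to all module-assigned genes.
#' @return Stacked enrichment data.frame.
#' @export
enrich_modules <- function(modules, annotation, universe = NULL) {
  if (is.null(universe)) universe <- names(modules)[modules > 0]
  ids <- setdiff(sort(unique(modules)), 0L)
  out <- lapply(ids, function(m) {
    res <- hypergeometric_enrichment(names(modules)[modules == m],
                                     annotation, universe)
    if (nrow(res) > 0) cbind(module = m, res) else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(data.frame(module = integer(), term = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
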