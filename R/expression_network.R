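# Expression collation, filtering and normalization, and a signed-hybrid
# weighted coexpression network: soft-threshold selection by scale-free
# fit, topological overlap, average-linkage module detection with
# eigengene merging, and module composition statistics.

#' Collate transcript-level tpm to gene level
#'
#' Gene tpm is the per-sample sum of its transcripts' tpm. Transcripts
#' missing from the map are excluded with a warning.
#'
#' @param tx_tpm Transcript x sample numeric matrix.
#' @param tx2gene Data.frame with columns `transcript`, `gene`.
#' @return Gene x sample numeric matrix.
#' @export
aggregate_to_genes <- function(tx_tpm, tx2gene) {
  fail_if(anyDuplicated(tx2gene$transcript) > 0,
          "each transcript must map to exactly one gene")
  unmapped <- setdiff(rownames(tx_tpm), tx2gene$transcript)
  if (length(unmapped) > 0) {
    warning(length(unmapped), " transcript(s) missing from tx2gene were ",
            "excluded", call. = FALSE)
    tx_tpm <- tx_tpm[setdiff(rownames(tx_tpm), unmapped), , drop = FALSE]
  }
  genes <- tx2gene$gene[match(rownames(tx_tpm), tx2gene$transcript)]
  rowsum(tx_tpm, group = genes, reorder = TRUE)
}

#' Filter to expressed genes
#'
#' Keeps a gene iff its tpm exceeds `min_tpm` (strictly) in at least
#' `min_samples` samples. Idempotent.
#'
#' @param expr Gene x sample tpm matrix.
#' @param min_tpm Expression threshold (default 0.5 tpm, strict `>`).
#' @param min_samples Minimum qualifying samples (default 3).
#' @return The filtered matrix.
#' @export
filter_expressed <- function(expr, min_tpm = 0.5, min_samples = 3) {
  fail_if(ncol(expr) < min_samples,
          "fewer samples than min_samples; filter undefined")
  keep <- rowSums(expr > min_tpm) >= min_samples
  expr[keep, , drop = FALSE]
}

#' Per-gene min-max normalization to [0, 1]
#'
#' Each gene is rescaled as `(x - min) / (max - min)`; constant genes map
#' to all zeros.
#'
#' @param expr Gene x sample matrix.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(expr) {
  lo <- apply(expr, 1, min)
  hi <- apply(expr, 1, max)
  rng <- hi - lo
  out <- (expr - lo) / ifelse(rng == 0, 1, rng)
  out[rng == 0, ] <- 0
  out
}

#' Fraction of expressed genes per phylogenetic group
#'
#' @param expressed_genes Character vector of genes passing
#'   [filter_expressed()].
#' @param group_assignment Data.frame with columns `gene`, `group`.
#' @return A data.frame with columns `group`, `n`, `n_expressed`,
#'   `fraction` (`NA` rows are genes without a group and are dropped;
#'   empty groups are absent).
#' @export
expressed_fraction_by_group <- function(expressed_genes,
                                        group_assignment) {
  ga <- group_assignment[!is.na(group_assignment$group), , drop = FALSE]
  if (nrow(ga) == 0) {
    return(data.frame(group = character(), n = integer(),
                      n_expressed = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(ga$gene, ga$group)
  data.frame(
    group = names(sp),
    n = lengths(sp),
    n_expressed = vapply(sp, function(g) sum(g %in% expressed_genes), 0L),
    fraction = vapply(sp, function(g) mean(g %in% expressed_genes), 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Biweight midcorrelation
#'
#' Median/MAD-based robust correlation (standard definition, without
#' outlier-fraction capping). Zero-MAD columns fall back to Pearson
#' centering for that column.
#'
#' @param x Sample x variable numeric matrix.
#' @return Variable x variable correlation matrix.
#' @export
bicor_matrix <- function(x) {
  n <- nrow(x)
  w <- matrix(0, n, ncol(x))
  xc <- x
  for (j in seq_len(ncol(x))) {
    med <- median(x[, j])
    m <- mad(x[, j], constant = 1)
    if (m == 0) {
      # degenerate spread: fall back to mean-centering, unit weights
      xc[, j] <- x[, j] - mean(x[, j])
      w[, j] <- 1
    } else {
      u <- (x[, j] - med) / (9 * m)
      wi <- (1 - u^2)^2 * (abs(u) < 1)
      xc[, j] <- x[, j] - med
      w[, j] <- wi
    }
  }
  a <- xc * w
  denom <- sqrt(colSums(a^2))
  denom[denom == 0] <- 1
  s <- crossprod(a) / tcrossprod(denom)
  s <- pmin(pmax(s, -1), 1)
  diag(s) <- 1
  s
}

#' Gene-gene correlation matrix
#'
#' Pearson (default) or biweight midcorrelation of genes across samples,
#' computed on the supplied matrix (callers typically pass
#' `log2(tpm + 1)`). Zero-variance genes get correlation 0 with a warning.
#'
#' @param expr Gene x sample matrix.
#' @param kind `"pearson"` or `"bicor"`.
#' @return Gene x gene correlation matrix (diagonal 1).
#' @export
correlation_matrix <- function(expr, kind = c("pearson", "bicor")) {
  kind <- match.arg(kind)
  fail_if(ncol(expr) < 4, "need at least 4 samples")
  x <- t(expr)
  const <- apply(x, 2, function(v) all(v == v[1]))
  if (any(const)) {
    warning(sum(const), " zero-variance gene(s); their correlations were ",
            "set to 0", call. = FALSE)
  }
  if (kind == "pearson") {
    cm <- suppressWarnings(cor(x))
    cm[is.na(cm)] <- 0
  } else {
    cm <- bicor_matrix(x)
    cm[, const] <- 0
    cm[const, ] <- 0
  }
  diag(cm) <- 1
  cm
}

#' Signed-hybrid adjacency
#'
#' `a_ij = max(cor_ij, 0)^beta`, zero diagonal.
#'
#' @param cor_mat Correlation matrix.
#' @param beta Soft-threshold power.
#' @return Adjacency matrix in `[0, 1]`.
#' @export
signed_hybrid_adjacency <- function(cor_mat, beta) {
  a <- pmax(cor_mat, 0)^beta
  diag(a) <- 0
  a
}

#' Pick a soft-threshold power by scale-free fit
#'
#' For each candidate power the signed-hybrid adjacency is formed, the
#' connectivity `k_i = sum_j a_ij` computed, and the scale-free fit R^2
#' taken as the squared correlation of `log10(freq)` vs `log10(mean k)`
#' over 10 connectivity bins. Returns the smallest power reaching
#' `target_r2`, or the power maximizing R^2 if none does.
#'
#' @param cor_mat Gene-gene correlation matrix.
#' @param powers Candidate powers (default 1:12).
#' @param target_r2 Scale-free fit target (default 0.8).
#' @return A list with `beta`, and `fit` (data.frame power, r2, mean_k).
#' @export
pick_soft_threshold <- function(cor_mat, powers = 1:12, target_r2 = 0.8) {
  fail_if(length(powers) < 2, "need at least two candidate powers")
  fit <- lapply(powers, function(b) {
    a <- signed_hybrid_adjacency(cor_mat, b)
    k <- rowSums(a)
    data.frame(power = b, r2 = scale_free_r2(k), mean_k = mean(k))
  })
  fit <- do.call(rbind, fit)
  ok <- which(fit$r2 >= target_r2)
  beta <- if (length(ok) > 0) fit$power[ok[1]] else
    fit$power[which.max(fit$r2)]
  list(beta = beta, fit = fit)
}

# Scale-free topology fit index over 10 connectivity bins.
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(0)
  cuts <- cut(k, breaks = n_bins)
  freq <- tabulate(cuts, nbins = n_bins)
  meank <- tapply(k, cuts, mean)
  keep <- freq > 0 & !is.na(meank)
  if (sum(keep) < 3) return(0)
  suppressWarnings(cor(log10(freq[keep]), log10(meank[keep]))^2)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; the standard unsigned topological overlap of a
#' non-negative adjacency.
#'
#' @param adjacency Symmetric adjacency in `[0, 1]` with zero diagonal.
#' @return Symmetric TOM matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adjacency) {
  fail_if(any(adjacency < 0 | adjacency > 1), "adjacency must be in [0,1]")
  fail_if(any(diag(adjacency) != 0), "adjacency diagonal must be zero")
  k <- rowSums(adjacency)
  shared <- adjacency %*% adjacency
  minimum_k <- outer(k, k, pmin)
  tom <- (shared + adjacency) / (minimum_k + 1 - adjacency)
  diag(tom) <- 1
  pmin(pmax(tom, 0), 1)
}

# First-principal-component eigengene of a module, sign-aligned to the
# module's mean standardized profile.
module_eigengene <- function(expr_log, genes) {
  x <- t(expr_log[genes, , drop = FALSE])  # samples x genes
  x <- scale(x)
  x[is.na(x)] <- 0
  sv <- svd(x, nu = 1, nv = 0)
  eg <- sv$u[, 1]
  avg <- rowMeans(x)
  if (sum(eg * avg) < 0) eg <- -eg
  eg
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static cut at
#' `cut_height`, removal of clusters below `min_size` (to module 0), and
#' iterative merging of modules whose eigengenes correlate above
#' `1 - merge_threshold`. Modules are renumbered by decreasing size, ties
#' broken by smallest member gene id.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param expr_log Gene x sample expression on the correlation scale
#'   (e.g. `log2(tpm + 1)`), used for eigengenes.
#' @param min_size Minimum module size (default 30).
#' @param merge_threshold Eigengene dissimilarity below which modules are
#'   merged (default 0.15).
#' @param cut_height Static tree-cut height on `1 - TOM` (default 0.99).
#' @return A list with `modules` (named integer vector gene -> module,
#'   0 = unassigned) and `eigengenes` (sample x module matrix).
#' @export
detect_modules <- function(tom, expr_log, min_size = 30,
                           merge_threshold = 0.15, cut_height = 0.99) {
  genes <- rownames(tom)
  fail_if(is.null(genes), "TOM must carry gene ids as dimnames")
  if (length(genes) < min_size) {
    return(list(modules = setNames(rep(0L, length(genes)), genes),
                eigengenes = NULL))
  }
  hc <- hclust(stats::as.dist(1 - tom), method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < min_size])] <- 0L

  # iterative eigengene merge
  repeat {
    ids <- setdiff(unique(cl), 0L)
    if (length(ids) < 2) break
    eg <- vapply(ids, function(m) module_eigengene(expr_log,
                                                   genes[cl == m]),
                 numeric(ncol(expr_log)))
    colnames(eg) <- ids
    ec <- cor(eg)
    diag(ec) <- -Inf
    top <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (max(ec) <= 1 - merge_threshold) break
    a <- ids[top[1]]
    b <- ids[top[2]]
    cl[cl == b] <- a
  }

  # renumber by decreasing size; ties by smallest member gene id
  ids <- setdiff(unique(cl), 0L)
  if (length(ids) > 0) {
    size <- vapply(ids, function(m) sum(cl == m), 0L)
    first <- vapply(ids, function(m) min(genes[cl == m]), "")
    ord <- ids[order(-size, first)]
    new <- setNames(seq_along(ord), ord)
    cl <- ifelse(cl == 0L, 0L, new[as.character(cl)])
  }
  modules <- setNames(as.integer(cl), genes)
  ids <- setdiff(sort(unique(modules)), 0L)
  eigengenes <- if (length(ids) > 0) {
    m <- vapply(ids, function(mm) module_eigengene(expr_log,
                                                   genes[modules == mm]),
                numeric(ncol(expr_log)))
    colnames(m) <- ids
    rownames(m) <- colnames(expr_log)
    m
  } else NULL
  list(modules = modules, eigengenes = eigengenes)
}

#' Run the signed-hybrid coexpression pipeline
#'
#' Convenience chain: correlation, soft-threshold pick, adjacency, TOM,
#' module detection.
#'
#' @param expr Gene x sample tpm matrix (already filtered); correlations
#'   are computed on `log2(tpm + 1)`.
#' @param kind Correlation kind (see [correlation_matrix()]).
#' @param powers,target_r2 Passed to [pick_soft_threshold()].
#' @param ... Passed to [detect_modules()].
#' @return The [detect_modules()] result plus `beta` and `fit`.
#' @export
coexpression_modules <- function(expr, kind = "pearson", powers = 1:12,
                                 target_r2 = 0.8, ...) {
  expr_log <- log2(expr + 1)
  cm <- correlation_matrix(expr_log, kind)
  st <- pick_soft_threshold(cm, powers, target_r2)
  adj <- signed_hybrid_adjacency(cm, st$beta)
  tom <- tom_similarity(adj)
  res <- detect_modules(tom, expr_log, ...)
  res$beta <- st$beta
  res$fit <- st$fit
  res
}

#' Module composition and NAC overrepresentation
#'
#' Per module: size, percent TFs, percent NACs among TFs, NAC counts per
#' phylogenetic group, and a 1-df chi-square test (no continuity
#' correction) of the module's (NAC, non-NAC TF) split against the global
#' NAC fraction among module-assigned TFs, Benjamini-Hochberg adjusted
#' across modules. Modules without TFs are skipped in the test (p = NA).
#'
#' @param modules Named integer vector gene -> module (0 = unassigned).
#' @param tf_genes Character vector of TF gene ids.
#' @param nac_genes Character vector of NAC gene ids (subset of
#'   `tf_genes`).
#' @param nac_group_of Optional named character vector gene -> group a-h.
#' @param global_nac_fraction Override for the null NAC fraction; by
#'   default the observed NAC share among all module-assigned TFs.
#' @return A data.frame with one row per module (columns `module`, `n`,
#'   `n_tf`, `pct_tf`, `n_nac`, `pct_nac_of_tf`, per-group counts,
#'   `chi2`, `p`, `q`).
#' @export
module_composition <- function(modules, tf_genes, nac_genes,
                               nac_group_of = NULL,
                               global_nac_fraction = NULL) {
  ids <- setdiff(sort(unique(modules)), 0L)
  fail_if(length(ids) == 0, "no modules to summarize")
  assigned <- names(modules)[modules > 0]
  tf_assigned <- intersect(assigned, tf_genes)
  nac_assigned <- intersect(assigned, nac_genes)
  p0 <- if (is.null(global_nac_fraction)) {
    fail_if(length(tf_assigned) == 0, "no module-assigned TFs")
    length(nac_assigned) / length(tf_assigned)
  } else global_nac_fraction
  groups <- letters[1:8]
  rows <- lapply(ids, function(m) {
    genes <- names(modules)[modules == m]
    tf <- intersect(genes, tf_genes)
    nac <- intersect(genes, nac_genes)
    row <- data.frame(module = m, n = length(genes), n_tf = length(tf),
                      pct_tf = 100 * length(tf) / length(genes),
                      n_nac = length(nac),
                      pct_nac_of_tf = if (length(tf) > 0)
                        100 * length(nac) / length(tf) else NA_real_,
                      stringsAsFactors = FALSE)
    for (g in groups) {
      row[[paste0("n_group_", g)]] <- if (is.null(nac_group_of)) NA_integer_
        else sum(nac_group_of[nac] == g, na.rm = TRUE)
    }
    if (length(tf) > 0 && p0 > 0 && p0 < 1) {
      expected <- c(length(tf) * p0, length(tf) * (1 - p0))
      observed <- c(length(nac), length(tf) - length(nac))
      chi2 <- sum((observed - expected)^2 / expected)
      row$chi2 <- chi2
      row$p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    } else {
      row$chi2 <- NA_real_
      row$p <- NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  has_p <- !is.na(out$p)
  out$q[has_p] <- bh_qvalues(out$p[has_p])
  out$global_nac_fraction <- p0
  rownames(out) <- NULL
  out
}
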