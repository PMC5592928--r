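# C-terminal-domain motif scanning: IUPAC motifs -> position weight
# matrices scored in bits against proteome background frequencies, exact
# per-window p-values by dynamic-programming convolution of the discretized
# position score distributions (the FIMO approach), Benjamini-Hochberg
# q-values, presence calls at p < 0.05 and q < 0.05, and per-group motif
# combination rules.

# Score discretization: 1/1000 bit per bin.
PWM_BIN <- 0.001

#' Amino-acid background frequencies of a proteome
#'
#' Counts every residue over all sequences (`X` ignored), adds a
#' pseudocount of 1 per amino acid, and normalizes.
#'
#' @param proteome Named character vector of peptides, or a FASTA path.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
background_frequencies <- function(proteome) {
  if (is.character(proteome) && length(proteome) == 1 &&
      file.exists(proteome)) {
    proteome <- read_protein_fasta(proteome)
  }
  fail_if(length(proteome) == 0, "empty proteome")
  tab <- table(factor(unlist(strsplit(proteome, "", fixed = TRUE)),
                      levels = AA20))
  counts <- as.numeric(tab) + 1
  setNames(counts / sum(counts), AA20)
}

#' Convert an IUPAC motif to a position weight matrix
#'
#' Each position's allowed residues share probability `1 - epsilon`
#' equally; disallowed residues share the `epsilon` leakage (avoiding
#' minus-infinity log-odds). Scores are log2 odds against the background.
#'
#' @param pattern IUPAC-style pattern, e.g. `"A[ST]Q"` (`X` = any).
#' @param bg Background frequencies from [background_frequencies()].
#' @param motif_id Identifier carried along with the matrix.
#' @param epsilon Leakage probability for disallowed residues.
#' @return A list of class `pwm` with `probs` and `scores` (width x 20
#'   matrices), `width`, and `motif_id`.
#' @export
iupac_to_pwm <- function(pattern, bg, motif_id = pattern, epsilon = 0.01) {
  positions <- parse_iupac_pattern(pattern)
  w <- length(positions)
  probs <- matrix(0, w, 20, dimnames = list(NULL, AA20))
  for (i in seq_len(w)) {
    k <- length(positions[[i]])
    if (k >= 20) {
      probs[i, ] <- 1 / 20
    } else {
      probs[i, ] <- epsilon / (20 - k)
      probs[i, positions[[i]]] <- (1 - epsilon) / k
    }
  }
  scores <- log2(sweep(probs, 2, bg[AA20], "/"))
  structure(list(probs = probs, scores = scores, width = w,
                 motif_id = motif_id),
            class = "pwm")
}

# Integer-discretized score matrix (bins of PWM_BIN bits).
pwm_int_scores <- function(pwm) {
  round(pwm$scores / PWM_BIN)
}

# Exact null distribution of the integer window score under i.i.d.
# background: returns list(offset, probs) where probs[k] is the
# probability of integer score offset + k - 1.
pwm_null_distribution <- function(pwm, bg) {
  si <- pwm_int_scores(pwm)
  bgv <- bg[AA20]
  lo <- sum(apply(si, 1, min))
  hi <- sum(apply(si, 1, max))
  probs <- numeric(hi - lo + 1)
  # start with an empty-prefix point mass; track the running support
  cur <- 1
  cur_lo <- 0
  for (i in seq_len(pwm$width)) {
    row <- si[i, ]
    rlo <- min(row)
    rhi <- max(row)
    new <- numeric(length(cur) + (rhi - rlo))
    for (a in seq_len(20)) {
      sh <- row[a] - rlo
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * bgv[a]
    }
    cur <- new
    cur_lo <- cur_lo + rlo
  }
  # cumulative upper tail, summed from the top for numerical stability
  tail <- rev(cumsum(rev(cur)))
  list(offset = cur_lo, probs = cur, tail = pmin(tail, 1))
}

# P(window score >= s_int) from a null distribution; vectorized in s_int.
pwm_tail_p <- function(null_dist, s_int) {
  idx <- s_int - null_dist$offset + 1
  p <- rep(1, length(s_int))
  p[idx > length(null_dist$tail)] <- 0
  inside <- idx >= 1 & idx <= length(null_dist$tail)
  p[inside] <- null_dist$tail[idx[inside]]
  p
}

# Integer scores of every window of ctd under the pwm; numeric(0) when the
# sequence is shorter than the motif.
window_scores_int <- function(ctd, pwm) {
  chars <- pep_chars(ctd)
  n <- length(chars)
  w <- pwm$width
  if (n < w) return(integer(0))
  si <- pwm_int_scores(pwm)
  col <- match(chars, AA20)  # X and unknowns -> NA
  # score X against the background-weighted average, i.e. 0 bits
  per_pos <- matrix(0L, w, n - w + 1L)
  for (i in seq_len(w)) {
    v <- si[i, col[i:(i + n - w)]]
    v[is.na(v)] <- 0
    per_pos[i, ] <- v
  }
  as.integer(colSums(per_pos))
}

#' Best motif hit in a single C-terminal domain
#'
#' Scores every window of `ctd` with the PWM and reports the best
#' (leftmost on ties) window with its exact per-window p-value
#' `P(score >= observed)` under i.i.d. background, computed by
#' dynamic-programming convolution of the discretized position score
#' distributions. Sequences shorter than the motif get `score = NA`,
#' `p = 1`.
#'
#' @param ctd Peptide string (the C-terminal domain).
#' @param pwm A [iupac_to_pwm()] object.
#' @param bg Background frequencies.
#' @return A list with `score` (bits), `p`, `position` (1-based in `ctd`).
#' @export
scan_best_hit <- function(ctd, pwm, bg) {
  ws <- window_scores_int(ctd, pwm)
  if (length(ws) == 0) {
    return(list(score = NA_real_, p = 1, position = NA_integer_))
  }
  nd <- pwm_null_distribution(pwm, bg)
  best <- which.max(ws)  # leftmost maximum
  list(score = ws[best] * PWM_BIN,
       p = pwm_tail_p(nd, ws[best]),
       position = best)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values `q_(i) = min_(j>=i) p_(j) m / j`, clipped to
#' 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_qvalues <- function(p) {
  fail_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Scan a set of C-terminal domains for a motif table
#'
#' For each motif and each gene the best window hit is computed with
#' [scan_best_hit()]; q-values are then computed per motif by
#' Benjamini-Hochberg either over all scanned windows of all genes (the
#' FIMO-style default, `q_universe = "windows"`, in which a gene inherits
#' the q-value of its best window) or over the per-gene best-hit p-values
#' (`q_universe = "genes"`). Presence requires `p < 0.05` and `q < 0.05`
#' (both strict).
#'
#' @param ctds Named character vector of C-terminal domain peptides.
#' @param motif_table Data.frame with columns `motif_id`, `pattern` (see
#'   [nac_ctd_motifs()]).
#' @param bg Background frequencies from [background_frequencies()].
#' @param q_universe `"windows"` (default) or `"genes"`.
#' @param p_threshold,q_threshold Presence thresholds (default 0.05).
#' @return A data.frame with columns `gene`, `motif_id`, `position`,
#'   `score`, `p`, `q`, `present`.
#' @export
scan_ctd_motifs <- function(ctds, motif_table, bg,
                            q_universe = c("windows", "genes"),
                            p_threshold = 0.05, q_threshold = 0.05) {
  q_universe <- match.arg(q_universe)
  out <- list()
  for (r in seq_len(nrow(motif_table))) {
    pwm <- iupac_to_pwm(motif_table$pattern[r], bg,
                        motif_id = motif_table$motif_id[r])
    nd <- pwm_null_distribution(pwm, bg)
    win <- lapply(ctds, window_scores_int, pwm = pwm)
    best <- lapply(win, function(ws) {
      if (length(ws) == 0) {
        return(c(score = NA_real_, p = 1, position = NA_real_))
      }
      b <- which.max(ws)
      c(score = ws[b] * PWM_BIN, p = pwm_tail_p(nd, ws[b]), position = b)
    })
    bm <- do.call(rbind, best)
    df <- data.frame(gene = names(ctds), motif_id = pwm$motif_id,
                     position = as.integer(bm[, "position"]),
                     score = bm[, "score"], p = bm[, "p"],
                     stringsAsFactors = FALSE)
    if (q_universe == "windows") {
      all_p <- unlist(lapply(win, function(ws) {
        if (length(ws) == 0) return(numeric(0))
        pwm_tail_p(nd, ws)
      }))
      if (length(all_p) > 0) {
        all_q <- bh_qvalues(all_p)
        # a gene's q is the q of its best (minimum-p) window
        gene_of <- rep(names(ctds),
                       vapply(win, length, 0L))
        qbest <- tapply(seq_along(all_p), gene_of, function(ix) {
          all_q[ix[which.min(all_p[ix])]]
        })
        df$q <- as.numeric(qbest[df$gene])
        df$q[is.na(df$q)] <- 1
      } else {
        df$q <- rep(1, nrow(df))
      }
    } else {
      df$q <- bh_qvalues(df$p)
    }
    df$present <- !is.na(df$p) & df$p < p_threshold & df$q < q_threshold
    out[[r]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract C-terminal domains from NAC proteins
#'
#' The CTD is everything strictly after the NAC domain end.
#'
#' @param proteome Named character vector of peptides.
#' @param domain_end Named integer vector: last NAC-domain position per
#'   gene (genes absent from this vector are skipped).
#' @return Named character vector of CTD peptides (possibly empty
#'   strings).
#' @export
extract_ctds <- function(proteome, domain_end) {
  genes <- intersect(names(proteome), names(domain_end))
  out <- vapply(genes, function(gn) {
    e <- domain_end[[gn]]
    s <- proteome[[gn]]
    if (e >= nchar(s)) "" else substr(s, e + 1, nchar(s))
  }, "")
  setNames(out, genes)
}

#' Apply per-group motif combination rules
#'
#' Each motif group is declared `any_of` (at least one of its motifs
#' present) or `all_of` (every motif present); single-motif groups are
#' trivially `any_of`.
#'
#' @param presence Data.frame from [scan_ctd_motifs()] (columns `gene`,
#'   `motif_id`, `present`).
#' @param motif_table Data.frame with `motif_id`, `ooka_group`,
#'   `combinator`.
#' @return A data.frame with columns `gene`, `ooka_group`, one row per
#'   satisfied (gene, group) combination.
#' @export
apply_group_rules <- function(presence, motif_table) {
  unknown <- setdiff(presence$motif_id, motif_table$motif_id)
  fail_if(length(unknown) > 0,
          paste0("presence table references unknown motif id(s): ",
                 paste(unknown, collapse = ", ")))
  groups <- unique(motif_table$ooka_group)
  rows <- list()
  for (g in groups) {
    ids <- motif_table$motif_id[motif_table$ooka_group == g]
    comb <- unique(motif_table$combinator[motif_table$ooka_group == g])
    fail_if(length(comb) != 1,
            paste0("conflicting combinators for group ", g))
    sub <- presence[presence$motif_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) next
    hit <- tapply(sub$present, sub$gene, if (comb == "all_of") all else any)
    # all_of additionally requires every motif of the group to be scanned
    if (comb == "all_of") {
      nmot <- tapply(sub$motif_id, sub$gene,
                     function(x) length(unique(x)))
      hit <- hit & (nmot[names(hit)] == length(ids))
    }
    got <- names(hit)[which(hit)]
    if (length(got) > 0) {
      rows[[length(rows) + 1]] <- data.frame(gene = got, ooka_group = g,
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(), ooka_group = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$ooka_group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
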