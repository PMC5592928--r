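# TF candidate identification by the union of three evidence streams
# (sequence similarity to known TFs, orthology, and protein-domain rules),
# family assignment via a rule table, and family-size statistics.

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two peptides under a substitution
#' matrix with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`, the BLAST convention). Defaults are the
#' classical blastp settings: BLOSUM62, open 11, extend 1.
#'
#' @param a,b Peptide strings over the 20 amino acids plus `X`.
#' @param matrix Substitution matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @return Integer local alignment score (>= 0); 0 if either sequence is
#'   empty.
#' @export
local_align_score <- function(a, b, matrix = NULL, gap_open = 11,
                              gap_extend = 1) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  check_peptide(a, "sequence 'a'")
  check_peptide(b, "sequence 'b'")
  if (is.null(matrix)) matrix <- blosum62()
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local", scoreOnly = TRUE)
  max(0, s)
}

# BLOSUM62, loaded once per session.
blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Score one query against every target; vectorized over targets.
score_against <- function(query, targets, matrix, gap_open = 11,
                          gap_extend = 1) {
  if (nchar(query) == 0 || length(targets) == 0) {
    return(setNames(numeric(length(targets)), names(targets)))
  }
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(targets), Biostrings::AAString(query),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local", scoreOnly = TRUE)
  setNames(pmax(0, s), names(targets))
}

#' Similarity-based TF candidates
#'
#' For each known-TF query peptide, ranks all target proteome genes by
#' Smith-Waterman score and keeps the top `max_targets` (ties at the cutoff
#' broken by lexicographic gene id, for determinism). The union over all
#' queries is returned deduplicated.
#'
#' @param queries Named character vector of known TF peptides.
#' @param targets Named character vector: the polyploid proteome.
#' @param max_targets Hits retained per query (default 10).
#' @return A list with `genes` (sorted unique candidate gene ids) and
#'   `hits` (data.frame query, gene, score, rank).
#' @export
similarity_candidates <- function(queries, targets, max_targets = 10) {
  fail_if(length(targets) == 0, "target proteome is empty")
  mat <- blosum62()
  hits <- list()
  for (qn in names(queries)) {
    sc <- score_against(queries[[qn]], targets, mat)
    ord <- order(-sc, names(sc))
    keep <- ord[seq_len(min(max_targets, length(ord)))]
    hits[[qn]] <- data.frame(query = qn, gene = names(sc)[keep],
                             score = unname(sc[keep]),
                             rank = seq_along(keep),
                             stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query = character(), gene = character(), score = numeric(),
               rank = integer(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  list(genes = sort(unique(hits$gene)), hits = hits)
}

#' Ortholog-based TF candidates
#'
#' Reads a two-column ortholog table (source gene, polyploid gene) and
#' returns the deduplicated polyploid gene set.
#'
#' @param ortholog_table A data.frame whose first two columns are source
#'   gene and polyploid gene, or a path to such a TSV.
#' @return Sorted character vector of unique polyploid gene ids.
#' @export
ortholog_candidates <- function(ortholog_table) {
  if (is.character(ortholog_table) && length(ortholog_table) == 1) {
    ortholog_table <- read_tsv_file(ortholog_table)
  }
  fail_if(ncol(ortholog_table) < 2,
          "ortholog table needs at least two columns")
  poly <- ortholog_table[[2]]
  bad <- which(is.na(poly) | !nzchar(poly))
  if (length(bad) > 0) {
    stop("malformed ortholog table row(s): line ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  sort(unique(poly))
}

# Parse the `required` rule syntax: alternatives separated by "|", domains
# within an alternative joined by "+".
parse_required <- function(x) {
  lapply(strsplit(x, "|", fixed = TRUE)[[1]],
         function(alt) trimws(strsplit(alt, "+", fixed = TRUE)[[1]]))
}

parse_forbidden <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Domain-rule TF candidates and family assignment
#'
#' Assigns each gene in the domain table to the TF family whose required
#' domain set it satisfies, provided none of the family's forbidden domains
#' are present. Genes satisfying more than one family are flagged
#' ambiguous.
#'
#' @param domain_table A data.frame with columns `gene`, `domain` (a path
#'   to such a TSV is also accepted).
#' @param rules A family rule table as in [default_family_rules()].
#' @return A data.frame with columns `gene`, `family`, `status`
#'   (`assigned`, `ambiguous`, or `rejected`); `family` for ambiguous genes
#'   lists all candidates joined by `;`, and is `NA` for rejected genes.
#' @export
domain_candidates <- function(domain_table, rules = default_family_rules()) {
  if (is.character(domain_table) && length(domain_table) == 1) {
    domain_table <- read_tsv_file(domain_table)
  }
  fail_if(anyDuplicated(rules$family) > 0, "family names must be unique")
  doms <- split(domain_table$domain, domain_table$gene)
  req <- lapply(rules$required, parse_required)
  forb <- lapply(rules$forbidden, parse_forbidden)
  out <- lapply(names(doms), function(gn) {
    d <- unique(doms[[gn]])
    fams <- character()
    blocked <- FALSE
    for (i in seq_len(nrow(rules))) {
      sat <- any(vapply(req[[i]], function(alt) all(alt %in% d), TRUE))
      if (!sat) next
      if (any(forb[[i]] %in% d)) {
        blocked <- TRUE
        next
      }
      fams <- c(fams, rules$family[i])
    }
    if (length(fams) == 1) {
      data.frame(gene = gn, family = fams, status = "assigned",
                 stringsAsFactors = FALSE)
    } else if (length(fams) > 1) {
      data.frame(gene = gn, family = paste(sort(fams), collapse = ";"),
                 status = "ambiguous", stringsAsFactors = FALSE)
    } else if (blocked) {
      data.frame(gene = gn, family = NA_character_, status = "rejected",
                 stringsAsFactors = FALSE)
    } else {
      NULL
    }
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(data.frame(gene = character(), family = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene), , drop = FALSE]
}

#' Combine evidence streams into a final TF call list
#'
#' Takes the union of the similarity, ortholog and domain candidate sets,
#' then applies the family rule check to every gene in the union: a gene is
#' called a TF only if its domain content assigns it to exactly one family.
#' Candidates proposed by similarity or orthology that fail the rule check
#' are dropped (mirroring a final prediction-server-style filter);
#' ambiguous multi-family genes are reported but flagged and excluded from
#' family counts.
#'
#' @param similarity Character vector of similarity candidate gene ids.
#' @param orthologs Character vector of ortholog candidate gene ids.
#' @param domain_table Domain annotation data.frame (`gene`, `domain`).
#' @param proteome_info A data.frame with at least `gene`, `confidence`,
#'   `subgenome`, `chrom_group` for the polyploid proteome (e.g.
#'   `truth$genes` restricted to the polyploid).
#' @param rules Family rule table.
#' @return A data.frame of TF calls: `gene`, `family`, `status`,
#'   `evidence` (semicolon-joined subset of similarity/ortholog/domain),
#'   `confidence`, `subgenome`, `chrom_group`.
#' @export
union_and_classify <- function(similarity, orthologs, domain_table,
                               proteome_info,
                               rules = default_family_rules()) {
  dc <- domain_candidates(domain_table, rules)
  dc_genes <- dc$gene[dc$status != "rejected"]
  all_genes <- sort(unique(c(similarity, orthologs, dc_genes)))
  fail_if(!all(all_genes %in% proteome_info$gene),
          "candidate gene ids missing from the proteome")
  keep <- dc[match(all_genes, dc$gene), , drop = FALSE]
  ok <- !is.na(keep$status) & keep$status %in% c("assigned", "ambiguous")
  genes <- all_genes[ok]
  if (length(genes) == 0) {
    return(data.frame(gene = character(), family = character(),
                      status = character(), evidence = character(),
                      confidence = character(), subgenome = character(),
                      chrom_group = integer(), stringsAsFactors = FALSE))
  }
  ev <- vapply(genes, function(gn) {
    e <- c("similarity", "ortholog", "domain")[c(gn %in% similarity,
                                                 gn %in% orthologs,
                                                 gn %in% dc_genes)]
    paste(e, collapse = ";")
  }, "")
  info <- proteome_info[match(genes, proteome_info$gene), , drop = FALSE]
  out <- data.frame(gene = genes,
                    family = keep$family[ok],
                    status = keep$status[ok],
                    evidence = unname(ev),
                    confidence = info$confidence,
                    subgenome = info$subgenome,
                    chrom_group = info$chrom_group,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Average TF-count fold changes of a polyploid versus reference species
#'
#' Given a per-species TF census (as in the bundled
#' `extdata/table1_tf_counts.tsv`), computes the mean ratio of the focal
#' polyploid high-confidence TF gene count to each comparison group's
#' per-species gene counts.
#'
#' @param counts A data.frame with columns `genes` and `group`, or a path
#'   to such a TSV. The focal count is the `polyploid_tgac` row.
#' @param focal_group,comparison_groups Group labels selecting the focal
#'   species and the denominators.
#' @return Named numeric vector of mean fold changes, one per comparison
#'   group.
#' @export
tf_abundance_ratios <- function(counts,
                                focal_group = "polyploid_tgac",
                                comparison_groups = c("diploid_triticeae",
                                                      "rice")) {
  if (is.character(counts) && length(counts) == 1) {
    counts <- read_tsv_file(counts)
  }
  focal <- counts$genes[counts$group == focal_group]
  fail_if(length(focal) != 1, "need exactly one focal species row")
  vapply(setNames(comparison_groups, comparison_groups), function(g) {
    denom <- counts$genes[counts$group == g]
    fail_if(length(denom) == 0, paste0("no rows for group ", g))
    mean(focal / denom)
  }, 0)
}

#' Chi-square test of a family-size ratio against a fixed expectation
#'
#' One-degree-of-freedom goodness-of-fit of observed polyploid and diploid
#' gene counts against the proportions `r/(r+1)` and `1/(r+1)` implied by
#' an expected ratio `r` (default 3:1 for a hexaploid vs a diploid), with
#' no continuity correction.
#'
#' @param count_poly,count_diploid Non-negative gene counts.
#' @param expected_ratio Expected polyploid:diploid ratio (default 3).
#' @return A list with `chi2` and `p`.
#' @export
family_ratio_test <- function(count_poly, count_diploid,
                              expected_ratio = 3) {
  fail_if(count_poly < 0 || count_diploid < 0, "counts must be >= 0")
  fail_if(count_poly + count_diploid == 0,
          "both counts are zero; test undefined")
  r <- expected_ratio
  ht <- suppressWarnings(
    stats::chisq.test(c(count_poly, count_diploid),
                      p = c(r / (r + 1), 1 / (r + 1))))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Tally TF calls by chromosome group, subgenome and family
#'
#' @param tf_calls Output of [union_and_classify()]; ambiguous calls are
#'   excluded.
#' @param per_homeolog If `TRUE`, also return per-family averages per
#'   homeolog (mean count over the three subgenomes per chromosome group).
#' @return A list with `counts` (data.frame chrom_group, subgenome, family,
#'   n) and, if requested, `per_homeolog` (data.frame chrom_group, family,
#'   mean_n).
#' @export
chromosome_distribution <- function(tf_calls, per_homeolog = TRUE) {
  calls <- tf_calls[tf_calls$status == "assigned" &
                      !is.na(tf_calls$chrom_group), , drop = FALSE]
  if (nrow(calls) == 0) {
    counts <- data.frame(chrom_group = integer(), subgenome = character(),
                         family = character(), n = integer(),
                         stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(table(chrom_group = calls$chrom_group,
                               subgenome = calls$subgenome,
                               family = calls$family),
                         stringsAsFactors = FALSE)
    names(tab)[4] <- "n"
    tab$chrom_group <- as.integer(tab$chrom_group)
    counts <- tab[order(tab$chrom_group, tab$subgenome, tab$family), ,
                  drop = FALSE]
    rownames(counts) <- NULL
  }
  out <- list(counts = counts)
  if (per_homeolog && nrow(counts) > 0) {
    agg <- stats::aggregate(n ~ chrom_group + family, data = counts,
                            FUN = function(v) sum(v) / 3)
    names(agg)[3] <- "mean_n"
    out$per_homeolog <- agg[order(agg$chrom_group, agg$family), ,
                            drop = FALSE]
    rownames(out$per_homeolog) <- NULL
  }
  out
}
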