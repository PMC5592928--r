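# Synthetic hexaploid-genome generator.
#
# Emits a toy "hexaploid + two diploid relatives" dataset in which every
# downstream quantity (TF families, homeolog triads, NAC phylogenetic
# groups, planted C-terminal motifs, coexpression modules, enriched GO
# terms) is known exactly, so each pipeline stage can be validated against
# ground truth without any external resource.

# ---------------------------------------------------------------------------
# Built-in sequence material
# ---------------------------------------------------------------------------

#' Built-in NAC domain consensus
#'
#' A fixed 150-residue consensus standing in for the conserved N-terminal
#' NAC DNA-binding domain (subdomains A-E). The sequence is synthetic: it is
#' an arbitrary but fixed peptide, not derived from any real gene, and is
#' used only as the common ancestor from which the generator derives group-
#' and gene-level NAC domains by point substitution.
#'
#' @return A single 150-character peptide string.
#' @export
nac_domain_consensus <- function() {
  paste0(
    "MGLRELDPLAQVNEFLSRHWKELPAGVKFDPSDQELVGHYLKRKVAEGKP",
    "LPVEVIREVDLYKFDPWDLPAKATFGEQEWYFFSPRDRKYPNGSRPNRAT",
    "ATSGYWKATGTDKAIYSGSKTVGVKKALVFYKGRPPKGVKTDWIMHEYRL"
  )
}

#' Built-in C-terminal-domain motif table
#'
#' Sixteen short IUPAC-style protein motifs organized into thirteen motif
#' groups (i-xiii), mirroring the classical NAC C-terminal-domain motif
#' catalog in structure: groups ii, iv and ix contain two motifs each, the
#' rest one. Groups ii and iv are satisfied by either of their motifs
#' (`any_of`); group ix requires both (`all_of`). The patterns themselves
#' are synthetic stand-ins with realistic widths (6-7 residues), not the
#' published motifs.
#'
#' @return A data.frame with columns `motif_id`, `pattern`, `ooka_group`,
#'   `combinator`.
#' @export
nac_ctd_motifs <- function() {
  m <- rbind(
    c("i",    "ETLPS[ED]",  "i",    "any_of"),
    c("ii-1", "[ST]PSH[ST]R", "ii", "any_of"),
    c("ii-2", "NPS[ST]HD",  "ii",   "any_of"),
    c("iii",  "FWGQ[KR]D",  "iii",  "any_of"),
    c("iv-1", "EVQS[EG]PK", "iv",   "any_of"),
    c("iv-2", "Q[ND]EVWSE", "iv",   "any_of"),
    c("v",    "S[FY]LDLP",  "v",    "any_of"),
    c("vi",   "LDYM[DE]F",  "vi",   "any_of"),
    c("vii",  "WNP[AV]AQ",  "vii",  "any_of"),
    c("viii", "PQM[ND]SP",  "viii", "any_of"),
    c("ix-1", "KGSNSGY",    "ix",   "all_of"),
    c("ix-2", "MPFGSR",     "ix",   "all_of"),
    c("x",    "NQ[FY]GNE",  "x",    "any_of"),
    c("xi",   "SG[FY]WGE",  "xi",   "any_of"),
    c("xii",  "QLNHL[ST]",  "xii",  "any_of"),
    c("xiii", "DF[ST]RPL",  "xiii", "any_of")
  )
  data.frame(motif_id = m[, 1], pattern = m[, 2], ooka_group = m[, 3],
             combinator = m[, 4], stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Configuration
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic dataset.
#' Defaults encode the study conditions the generator emulates: a 58/33/9
#' percent split of homeolog triads into complete / single-loss / other
#' retention classes, and an 8 percent average NAC share among module TFs.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param n_triads Number of homeolog triads to simulate.
#' @param retention_probs Length-3 numeric (complete, single_loss, other);
#'   must sum to 1.
#' @param n_nac_triads Number of triads belonging to the NAC family; must
#'   equal `sum(nac_groups)`.
#' @param nac_groups Named integer vector of NAC triad counts per
#'   phylogenetic group `a`-`h`.
#' @param ctd_motif_plan Named list mapping each NAC group to the motif ids
#'   (rows of `motif_table`) planted in its members' C-terminal domains.
#' @param other_tf_families Named integer vector of triad counts for
#'   additional (non-NAC) TF families.
#' @param diploid_divergence Per-site substitution rate separating diploid
#'   orthologs from the polyploid triad ancestor.
#' @param within_divergence Per-site substitution rate between homeologs.
#' @param group_divergence Per-site rate separating each NAC group ancestor
#'   from the built-in domain consensus.
#' @param within_group_divergence Per-site rate separating NAC triads within
#'   a group from the group ancestor.
#' @param domain_truncation_rate Probability that a NAC gene's domain is
#'   N-terminally truncated (creating leading gaps in the truth alignment).
#' @param low_confidence_rate Fraction of polyploid genes annotated as
#'   low-confidence gene models.
#' @param false_positive_rate Fraction of non-TF genes that receive a decoy
#'   TF domain paired with a forbidden domain in the domain table.
#' @param protein_length Length of non-NAC proteins.
#' @param ctd_length Length of the C-terminal domain of NAC proteins.
#' @param n_samples Number of expression samples (at least 3).
#' @param n_studies Number of studies the samples are grouped into.
#' @param n_modules Number of planted coexpression modules.
#' @param module_snr Ratio of module-factor to noise standard deviation on
#'   the log2 expression scale; `Inf` gives noiseless profiles.
#' @param assigned_fraction Fraction of genes assigned to a module.
#' @param nac_module_enrichment Target fraction of module-assigned TFs that
#'   are NACs.
#' @param low_expr_fraction Fraction of genes emitted below the
#'   0.5-tpm-in-3-samples expression filter.
#' @param go_module_fraction Fraction of a module's genes annotated with the
#'   module's planted GO term.
#' @param go_background_rate Annotation rate of each planted GO term among
#'   genes outside its module.
#' @param nac_consensus,motif_table Overrides for the built-in NAC domain
#'   consensus and motif table.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_triads = 150,
                       retention_probs = c(complete = 0.58,
                                           single_loss = 0.33,
                                           other = 0.09),
                       n_nac_triads = 40,
                       nac_groups = c(a = 8, b = 6, c = 6, d = 6,
                                      e = 4, f = 4, g = 3, h = 3),
                       ctd_motif_plan = list(
                         a = c("ii-1", "v", "vi"),
                         b = c("vii", "viii"),
                         c = c("iii", "xiii"),
                         d = c("i", "xiii", "ix-1", "ix-2"),
                         e = c("xiii"),
                         f = c("iv-1", "iv-2"),
                         g = c("vii"),
                         h = c("ix-1")
                       ),
                       other_tf_families = c(MYB = 15, WRKY = 15),
                       diploid_divergence = 0.05,
                       within_divergence = 0.02,
                       group_divergence = 0.15,
                       within_group_divergence = 0.03,
                       domain_truncation_rate = 0.05,
                       low_confidence_rate = 0.2,
                       false_positive_rate = 0.02,
                       protein_length = 250,
                       ctd_length = 120,
                       n_samples = 308,
                       n_studies = 15,
                       n_modules = 5,
                       module_snr = 3,
                       assigned_fraction = 0.67,
                       nac_module_enrichment = 0.08,
                       low_expr_fraction = 0.10,
                       go_module_fraction = 0.6,
                       go_background_rate = 0.05,
                       nac_consensus = nac_domain_consensus(),
                       motif_table = nac_ctd_motifs()) {
  fail_if(abs(sum(retention_probs) - 1) > 1e-9,
          "retention_probs must sum to 1")
  fail_if(length(retention_probs) != 3, "retention_probs must have length 3")
  fail_if(any(retention_probs < 0), "retention_probs must be non-negative")
  fail_if(n_triads < 0 || n_nac_triads < 0, "counts must be >= 0")
  if (n_nac_triads > 0) {
    fail_if(sum(nac_groups) != n_nac_triads,
            "sum(nac_groups) must equal n_nac_triads")
    fail_if(!all(names(nac_groups) %in% letters[1:8]),
            "nac_groups names must be among a-h")
  }
  fail_if(n_nac_triads + sum(other_tf_families) > n_triads,
          "TF triads exceed n_triads")
  fail_if(nchar(nac_consensus) < 1, "nac_consensus must be non-empty")
  cfg <- list(
    seed = as.integer(seed), n_triads = n_triads,
    retention_probs = retention_probs, n_nac_triads = n_nac_triads,
    nac_groups = nac_groups, ctd_motif_plan = ctd_motif_plan,
    other_tf_families = other_tf_families,
    diploid_divergence = diploid_divergence,
    within_divergence = within_divergence,
    group_divergence = group_divergence,
    within_group_divergence = within_group_divergence,
    domain_truncation_rate = domain_truncation_rate,
    low_confidence_rate = low_confidence_rate,
    false_positive_rate = false_positive_rate,
    protein_length = protein_length, ctd_length = ctd_length,
    n_samples = n_samples, n_studies = n_studies, n_modules = n_modules,
    module_snr = module_snr, assigned_fraction = assigned_fraction,
    nac_module_enrichment = nac_module_enrichment,
    low_expr_fraction = low_expr_fraction,
    go_module_fraction = go_module_fraction,
    go_background_rate = go_background_rate,
    nac_consensus = nac_consensus, motif_table = motif_table
  )
  structure(cfg, class = "sim_config")
}

# ---------------------------------------------------------------------------
# Sequence-level primitives
# ---------------------------------------------------------------------------

rand_peptide_chars <- function(n) sample(AA20, n, replace = TRUE)

# Point-substitute each site with probability `rate`, always to a different
# residue, so `rate` is the realized per-site divergence in expectation.
mutate_chars <- function(chars, rate) {
  if (rate <= 0 || length(chars) == 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  chars
}

# Parse an IUPAC-style protein pattern ("A[ST]Q", X = any residue) into a
# list of allowed-residue sets, one per position.
parse_iupac_pattern <- function(pattern) {
  out <- list()
  i <- 1
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      fail_if(j < 0, paste0("unclosed '[' in pattern: ", pattern))
      set <- pep_chars(substr(pattern, i + 1, i + j - 2))
      fail_if(length(set) == 0, paste0("empty residue set in: ", pattern))
      out[[length(out) + 1]] <- set
      i <- i + j
    } else if (ch == "X") {
      out[[length(out) + 1]] <- AA20
      i <- i + 1
    } else {
      fail_if(!ch %in% AA20, paste0("invalid residue '", ch,
                                    "' in pattern: ", pattern))
      out[[length(out) + 1]] <- ch
      i <- i + 1
    }
  }
  fail_if(length(out) == 0, "empty motif pattern")
  out
}

# One concrete word matching a parsed pattern.
realize_motif_word <- function(positions) {
  paste(vapply(positions, function(s) s[sample.int(length(s), 1)], ""),
        collapse = "")
}

# ---------------------------------------------------------------------------
# Proteome generation
# ---------------------------------------------------------------------------

#' Generate synthetic polyploid and diploid proteomes with ground truth
#'
#' Simulates `n_triads` homeolog triads on a hexaploid A/B/D genome plus one
#' ortholog per triad in each of two diploid relatives (`REF1`, `REF2`).
#' Triad retention follows `retention_probs`; the "other" class is realized
#' half as a tandem duplication in one subgenome and half as loss of two
#' homeologs. NAC genes are built as an N-terminal NAC domain (a mutated
#' copy of the group ancestor, itself derived from the built-in consensus)
#' followed by a C-terminal domain carrying the group's planted motifs
#' verbatim at recorded positions. Polyploid gene ids follow the pattern
#' `SYN<chromosome group><subgenome>G<number>`.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{polyploid}{Named character vector of polyploid peptides.}
#'     \item{diploids}{List of two named character vectors (`REF1`, `REF2`).}
#'     \item{msa}{Named character vector: the truth alignment of all NAC
#'       domains (equal-length rows, `-` for truncated positions).}
#'     \item{truth}{Ground-truth list with `genes`, `triads`, `motifs`,
#'       `orthologs` data.frames and the `config`.}
#'   }
#' @export
generate_proteomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_triads
  empty_truth <- list(
    genes = data.frame(gene = character(), species = character(),
                       subgenome = character(), chrom_group = integer(),
                       triad_id = integer(), family = character(),
                       nac_group = character(), confidence = character(),
                       nac_domain_start = integer(),
                       nac_domain_end = integer(),
                       stringsAsFactors = FALSE),
    triads = data.frame(triad_id = integer(), n_A = integer(),
                        n_B = integer(), n_D = integer(),
                        retention = character(), stringsAsFactors = FALSE),
    motifs = data.frame(gene = character(), motif_id = character(),
                        word = character(), start = integer(),
                        stringsAsFactors = FALSE),
    orthologs = data.frame(ref_gene = character(), poly_gene = character(),
                           species = character(), stringsAsFactors = FALSE),
    config = config
  )
  if (n == 0) {
    return(list(polyploid = setNames(character(), character()),
                diploids = list(REF1 = setNames(character(), character()),
                                REF2 = setNames(character(), character())),
                msa = setNames(character(), character()),
                truth = empty_truth))
  }

  dom_len <- nchar(config$nac_consensus)
  consensus <- pep_chars(config$nac_consensus)

  # family plan per triad: NAC triads first, then the other TF families
  family <- rep(NA_character_, n)
  if (config$n_nac_triads > 0) family[seq_len(config$n_nac_triads)] <- "NAC"
  pos <- config$n_nac_triads
  for (fam in names(config$other_tf_families)) {
    k <- config$other_tf_families[[fam]]
    if (k > 0) family[pos + seq_len(k)] <- fam
    pos <- pos + k
  }
  nac_group <- rep(NA_character_, n)
  if (config$n_nac_triads > 0) {
    nac_group[seq_len(config$n_nac_triads)] <-
      rep(names(config$nac_groups), config$nac_groups)
  }

  # one ancestor domain per NAC group
  groups_used <- unique(nac_group[!is.na(nac_group)])
  ancestors <- lapply(setNames(groups_used, groups_used), function(g) {
    mutate_chars(consensus, config$group_divergence)
  })

  retention_planted <- sample(c("complete", "single_loss", "other"), n,
                              replace = TRUE, prob = config$retention_probs)

  motif_positions <- lapply(setNames(config$motif_table$pattern,
                                     config$motif_table$motif_id),
                            parse_iupac_pattern)

  genes <- vector("list", n * 6)
  seqs <- vector("list", n * 6)
  motif_rows <- list()
  ortholog_rows <- vector("list", n)
  triad_rows <- vector("list", n)
  msa_rows <- list()
  gi <- 0L  # running gene counter
  rec <- 0L # rows used in genes/seqs

  plant_motifs <- function(ctd, words, starts) {
    for (k in seq_along(words)) {
      w <- pep_chars(words[k])
      ctd[starts[k] + seq_along(w) - 1L] <- w
    }
    ctd
  }

  for (i in seq_len(n)) {
    chrom <- (i - 1L) %% 7L + 1L
    fam <- family[i]
    grp <- nac_group[i]
    is_nac <- identical(fam, "NAC")

    # per-triad ancestral sequence material
    if (is_nac) {
      dom_base <- mutate_chars(ancestors[[grp]],
                               config$within_group_divergence)
      ctd_base <- rand_peptide_chars(config$ctd_length)
      plan_ids <- config$ctd_motif_plan[[grp]]
      if (is.null(plan_ids)) plan_ids <- character()
      words <- vapply(plan_ids,
                      function(id) realize_motif_word(motif_positions[[id]]),
                      "")
      # non-overlapping starts: one slot per motif across the CTD
      if (length(plan_ids) > 0) {
        slot <- floor(config$ctd_length / length(plan_ids))
        widths <- nchar(words)
        fail_if(any(widths > slot), "ctd_length too short for motif plan")
        starts <- vapply(seq_along(plan_ids), function(k) {
          lo <- (k - 1L) * slot + 1L
          hi <- k * slot - widths[k] + 1L
          as.integer(lo + sample.int(hi - lo + 1L, 1) - 1L)
        }, integer(1))
      } else {
        starts <- integer()
      }
    } else {
      base <- rand_peptide_chars(config$protein_length)
    }

    # realized slot plan
    retn <- retention_planted[i]
    if (retn == "complete") {
      copies <- c(A = 1L, B = 1L, D = 1L)
    } else if (retn == "single_loss") {
      copies <- c(A = 1L, B = 1L, D = 1L)
      copies[sample(c("A", "B", "D"), 1)] <- 0L
    } else if (runif(1) < 0.5) {  # other: tandem duplication
      copies <- c(A = 1L, B = 1L, D = 1L)
      copies[sample(c("A", "B", "D"), 1)] <- 2L
    } else {                      # other: loss of two homeologs
      copies <- c(A = 0L, B = 0L, D = 0L)
      copies[sample(c("A", "B", "D"), 1)] <- 1L
    }

    make_nac_seq <- function(dom, ctd) {
      # optional N-terminal truncation of the domain
      trunc <- 0L
      if (runif(1) < config$domain_truncation_rate) {
        trunc <- sample.int(floor(dom_len * 0.4), 1)
      }
      dom_kept <- if (trunc > 0) dom[-seq_len(trunc)] else dom
      ctd <- plant_motifs(ctd, words, starts)
      list(seq = paste(c(dom_kept, ctd), collapse = ""),
           dom_end = dom_len - trunc,
           msa = paste(c(rep("-", trunc), dom_kept), collapse = ""),
           words = words,
           starts_protein = (dom_len - trunc) + starts)
    }

    emit <- function(id, species, subg, seq_info, confidence) {
      rec <<- rec + 1L
      genes[[rec]] <<- data.frame(
        gene = id, species = species, subgenome = subg,
        chrom_group = if (species == "polyploid") chrom else NA_integer_,
        triad_id = i, family = fam, nac_group = grp,
        confidence = confidence,
        nac_domain_start = if (is_nac) 1L else NA_integer_,
        nac_domain_end = if (is_nac) seq_info$dom_end else NA_integer_,
        stringsAsFactors = FALSE)
      seqs[[rec]] <<- seq_info$seq
      names(seqs)[rec] <<- id
      if (is_nac) {
        msa_rows[[id]] <<- seq_info$msa
        if (length(seq_info$words) > 0) {
          motif_rows[[length(motif_rows) + 1L]] <<- data.frame(
            gene = id, motif_id = names(seq_info$words),
            word = unname(seq_info$words),
            start = seq_info$starts_protein, stringsAsFactors = FALSE)
        }
      }
    }

    poly_ids <- character()
    for (subg in c("A", "B", "D")) {
      for (cp in seq_len(copies[[subg]])) {
        gi <- gi + 1L
        id <- sprintf("SYN%d%sG%04d", chrom, subg, gi)
        conf <- if (runif(1) < config$low_confidence_rate) "low" else "high"
        if (is_nac) {
          info <- make_nac_seq(mutate_chars(dom_base,
                                            config$within_divergence),
                               mutate_chars(ctd_base,
                                            config$within_divergence))
        } else {
          info <- list(seq = paste(mutate_chars(base,
                                                config$within_divergence),
                                   collapse = ""))
        }
        if (is_nac) names(info$words) <- plan_ids
        emit(id, "polyploid", subg, info, conf)
        poly_ids <- c(poly_ids, id)
      }
    }

    for (sp in c("REF1", "REF2")) {
      id <- sprintf("%sG%04d", sp, i)
      if (is_nac) {
        info <- make_nac_seq(mutate_chars(dom_base,
                                          config$diploid_divergence),
                             mutate_chars(ctd_base,
                                          config$diploid_divergence))
        names(info$words) <- plan_ids
      } else {
        info <- list(seq = paste(mutate_chars(base,
                                              config$diploid_divergence),
                                 collapse = ""))
      }
      emit(id, sp, "none", info, "high")
      if (length(poly_ids) > 0) {
        ortholog_rows[[i]] <- rbind(
          ortholog_rows[[i]],
          data.frame(ref_gene = id, poly_gene = poly_ids, species = sp,
                     stringsAsFactors = FALSE))
      }
    }

    triad_rows[[i]] <- data.frame(
      triad_id = i, n_A = copies[["A"]], n_B = copies[["B"]],
      n_D = copies[["D"]],
      retention = classify_counts(copies[["A"]], copies[["B"]],
                                  copies[["D"]]),
      stringsAsFactors = FALSE)
  }

  genes_df <- do.call(rbind, genes[seq_len(rec)])
  all_seqs <- unlist(seqs[seq_len(rec)])
  truth <- empty_truth
  truth$genes <- genes_df
  truth$triads <- do.call(rbind, triad_rows)
  if (length(motif_rows) > 0) truth$motifs <- do.call(rbind, motif_rows)
  ortho <- do.call(rbind, ortholog_rows[!vapply(ortholog_rows, is.null,
                                                TRUE)])
  if (!is.null(ortho)) truth$orthologs <- ortho

  poly_mask <- genes_df$species == "polyploid"
  list(
    polyploid = all_seqs[genes_df$gene[poly_mask]],
    diploids = list(
      REF1 = all_seqs[genes_df$gene[genes_df$species == "REF1"]],
      REF2 = all_seqs[genes_df$gene[genes_df$species == "REF2"]]),
    msa = unlist(msa_rows),
    truth = truth
  )
}

# ---------------------------------------------------------------------------
# Domain table
# ---------------------------------------------------------------------------

#' Generate a synthetic domain-annotation table
#'
#' Every true TF gene receives its family's required domain accession
#' (`DOM_<family>`). Additionally, a configurable fraction of non-TF genes
#' receives a decoy `DOM_NAC` row paired with `DOM_FORBID`, emulating
#' domain combinations known not to act as TFs; a correct downstream
#' classifier must reject these.
#'
#' @param truth Ground truth from [generate_proteomes()].
#' @param config The same [sim_config()].
#' @return A data.frame with columns `gene`, `domain`, `score`.
#' @export
generate_domain_table <- function(truth, config) {
  set.seed(config$seed + 1L)
  g <- truth$genes
  poly <- g[g$species == "polyploid", , drop = FALSE]
  tf <- poly[!is.na(poly$family), , drop = FALSE]
  rows <- list()
  if (nrow(tf) > 0) {
    rows[[1]] <- data.frame(gene = tf$gene,
                            domain = paste0("DOM_", tf$family),
                            score = round(runif(nrow(tf), 30, 100), 1),
                            stringsAsFactors = FALSE)
  }
  nontf <- poly$gene[is.na(poly$family)]
  if (config$false_positive_rate > 0 && length(nontf) > 0) {
    k <- rbinom(1, length(nontf), config$false_positive_rate)
    if (k > 0) {
      decoy <- sample(nontf, k)
      rows[[length(rows) + 1]] <- data.frame(
        gene = rep(decoy, each = 2),
        domain = rep(c("DOM_NAC", "DOM_FORBID"), times = k),
        score = round(runif(2 * k, 20, 60), 1),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(), domain = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default family rule table matching the synthetic domain vocabulary
#'
#' @return A data.frame with columns `family`, `required`, `forbidden`.
#'   `required` lists alternative domain sets separated by `|`, domains
#'   within a set joined by `+`; `forbidden` is comma-separated.
#' @export
default_family_rules <- function() {
  data.frame(
    family = c("NAC", "MYB", "WRKY"),
    required = c("DOM_NAC", "DOM_MYB", "DOM_WRKY"),
    forbidden = c("DOM_FORBID", "DOM_FORBID", "DOM_FORBID"),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Expression
# ---------------------------------------------------------------------------

#' Generate a synthetic transcript-level expression compendium
#'
#' Gene-level log2 expression is `mu + loading * factor + noise` where each
#' module has an i.i.d. standard-normal latent factor per sample and
#' `loading / sd(noise) = module_snr`; values are exponentiated to strictly
#' positive tpm-like values (log-normal noise model). Genes are split into
#' 1-3 transcripts with flat-Dirichlet proportions so transcript tpms sum
#' exactly to the gene tpm. A `low_expr_fraction` of genes is emitted below
#' the 0.5-tpm-in-3-samples expression filter. Module membership is sampled
#' so that the expected NAC share among module-assigned TFs matches
#' `nac_module_enrichment`.
#'
#' @param truth Ground truth from [generate_proteomes()].
#' @param config The same [sim_config()].
#' @return A list with `tx_tpm` (transcript x sample matrix), `tx2gene`
#'   (data.frame transcript, gene), `samples` (data.frame sample, study,
#'   tissue), and `truth`: the input truth augmented with `modules`
#'   (data.frame gene, module; module 0 = unassigned) and `factors`
#'   (module x sample latent factors).
#' @export
generate_expression <- function(truth, config) {
  fail_if(config$n_samples < 3,
          "n_samples must be >= 3 (expression filter would be untestable)")
  set.seed(config$seed + 2L)
  g <- truth$genes
  poly <- g[g$species == "polyploid", , drop = FALSE]
  genes <- poly$gene
  ng <- length(genes)
  ns <- config$n_samples
  nm <- config$n_modules

  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(ns)),
    study = sprintf("study%02d",
                    sort(rep_len(seq_len(max(config$n_studies, 1)), ns))),
    tissue = sample(c("leaf", "root", "spike", "grain", "seedling", "stem",
                      "endosperm"), ns, replace = TRUE),
    stringsAsFactors = FALSE)

  if (ng == 0) {
    tx <- matrix(numeric(), 0, ns,
                 dimnames = list(character(), samples$sample))
    truth$modules <- data.frame(gene = character(), module = integer(),
                                stringsAsFactors = FALSE)
    truth$factors <- matrix(numeric(), nm, ns)
    return(list(tx_tpm = tx,
                tx2gene = data.frame(transcript = character(),
                                     gene = character(),
                                     stringsAsFactors = FALSE),
                samples = samples, truth = truth))
  }

  # module membership with NAC share control among TFs
  is_nac <- !is.na(poly$family) & poly$family == "NAC"
  is_tf <- !is.na(poly$family)
  p_assign <- rep(config$assigned_fraction, ng)
  n_other_tf <- sum(is_tf & !is_nac)
  n_nac <- sum(is_nac)
  if (n_nac > 0 && n_other_tf > 0 && config$nac_module_enrichment < 1) {
    tgt <- config$nac_module_enrichment
    p_nac <- tgt * config$assigned_fraction * n_other_tf /
      (n_nac * (1 - tgt))
    p_assign[is_nac] <- min(1, p_nac)
  }
  low <- runif(ng) < config$low_expr_fraction
  # genes planted below the expression filter carry no module signal
  assigned <- runif(ng) < p_assign & !low
  module <- integer(ng)
  module[assigned] <- sample.int(nm, sum(assigned), replace = TRUE)

  factors <- matrix(rnorm(nm * ns), nm, ns,
                    dimnames = list(NULL, samples$sample))

  sigma <- 0.5
  noiseless <- is.infinite(config$module_snr)
  loading <- if (noiseless) rep(1, ng) else
    config$module_snr * sigma * runif(ng, 0.8, 1.2)
  mu <- rnorm(ng, mean = 3, sd = 1)
  mu[low] <- -4

  x <- matrix(mu, ng, ns)
  inmod <- module > 0
  if (any(inmod)) {
    x[inmod, ] <- x[inmod, , drop = FALSE] +
      loading[inmod] * factors[module[inmod], , drop = FALSE]
  }
  if (!noiseless) x <- x + matrix(rnorm(ng * ns, sd = sigma), ng, ns)
  gene_tpm <- 2^x
  rownames(gene_tpm) <- genes
  colnames(gene_tpm) <- samples$sample

  # split into transcripts, flat-Dirichlet proportions
  ntx <- sample.int(3, ng, replace = TRUE)
  tx_gene <- rep(genes, ntx)
  tx_id <- paste0(tx_gene, ".", unlist(lapply(ntx, seq_len)))
  w <- rexp(length(tx_id))
  w <- w / rep(vapply(split(w, rep(seq_len(ng), ntx)), sum, 0), ntx)
  tx_tpm <- gene_tpm[tx_gene, , drop = FALSE] * w
  rownames(tx_tpm) <- tx_id

  truth$modules <- data.frame(gene = genes, module = module,
                              stringsAsFactors = FALSE)
  truth$factors <- factors
  list(tx_tpm = tx_tpm,
       tx2gene = data.frame(transcript = tx_id, gene = tx_gene,
                            stringsAsFactors = FALSE),
       samples = samples, truth = truth)
}

# ---------------------------------------------------------------------------
# GO annotation
# ---------------------------------------------------------------------------

#' Generate a synthetic GO annotation table
#'
#' One GO term is planted per coexpression module: it annotates
#' `go_module_fraction` of the module's genes and `go_background_rate` of
#' all other genes, so each planted term should be recovered as the top
#' enriched term of its module downstream.
#'
#' @param truth Ground truth augmented by [generate_expression()] (must
#'   contain `modules`).
#' @param config The same [sim_config()].
#' @return A data.frame with columns `gene`, `term`, `description`.
#' @export
generate_go_annotation <- function(truth, config) {
  fail_if(is.null(truth$modules),
          "truth lacks module assignments; run generate_expression() first")
  set.seed(config$seed + 3L)
  mods <- truth$modules
  out <- list()
  for (m in seq_len(config$n_modules)) {
    term <- sprintf("GO:SYN%04d", m)
    descr <- sprintf("synthetic process %d", m)
    ingenes <- mods$gene[mods$module == m]
    outgenes <- mods$gene[mods$module != m]
    pick_in <- ingenes[runif(length(ingenes)) < config$go_module_fraction]
    pick_out <- outgenes[runif(length(outgenes)) < config$go_background_rate]
    picked <- c(pick_in, pick_out)
    if (length(picked) > 0) {
      out[[length(out) + 1]] <- data.frame(
        gene = picked, term = term, description = descr,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(), term = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---------------------------------------------------------------------------
# One-call driver
# ---------------------------------------------------------------------------

#' Generate the full synthetic dataset
#'
#' Convenience wrapper chaining [generate_proteomes()],
#' [generate_domain_table()], [generate_expression()] and
#' [generate_go_annotation()].
#'
#' @param config A [sim_config()].
#' @return A list with `proteomes`, `domains`, `expression`, `go`, and the
#'   fully augmented `truth`.
#' @export
simulate_dataset <- function(config) {
  prot <- generate_proteomes(config)
  dom <- generate_domain_table(prot$truth, config)
  expr <- generate_expression(prot$truth, config)
  go <- generate_go_annotation(expr$truth, config)
  list(proteomes = prot, domains = dom, expression = expr, go = go,
       truth = expr$truth)
}

#' Write synthetic proteomes as FASTA
#'
#' @param seqs Named character vector of peptides.
#' @param path Output path; sequences are wrapped at 60 columns.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Read a protein FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of peptides.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
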