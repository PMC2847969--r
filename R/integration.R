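# Cross-dataset integration: one master record per UCE merging microarray,
# RNA-Seq, enhancer-assay, human-expression and genomic-context evidence,
# plus the headline overlap, concordance and term-enrichment summaries.

check_unique_ids <- function(df, source) {
  if (anyDuplicated(df$uce_id))
    stopf("duplicate uce_id in %s: %s", source,
          paste(unique(df$uce_id[duplicated(df$uce_id)]), collapse = ", "))
  invisible(df)
}

lookup <- function(master_ids, df, column, default, source) {
  check_unique_ids(df, source)
  unknown <- setdiff(df$uce_id, master_ids)
  if (length(unknown) > 0)
    stopf("unknown uce_id in %s: %s", source,
          paste(utils::head(unknown, 5), collapse = ", "))
  out <- rep(default, length(master_ids))
  m <- match(master_ids, df$uce_id)
  hit <- !is.na(m)
  out[hit] <- df[[column]][m[hit]]
  out
}

#' Build the master per-UCE integration table
#'
#' Merges every evidence stream onto the master UCE list. Sources missing a
#' UCE are marked `not_tested` / `not_assessed`, never dropped; duplicate
#' or unknown ids in any source are rejected.
#'
#' @param uce_ids Master UCE id vector.
#' @param contexts Named context-class vector (from [classify_context()]).
#' @param profile Per-UCE array profile (from [expression_profile()]).
#' @param stability Stability table (from [stability_summary()]); optional.
#' @param rnaseq Data.frame `uce_id`, `expressed` (logical) for RNA-Seq
#'   calls; optional.
#' @param enhancer Data.frame `uce_id`, `status`
#'   (positive/negative/not_tested); optional.
#' @param human Data.frame `uce_id`, `status`
#'   (expressed/not_expressed/not_tested); optional.
#' @param flanking Data.frame `uce_id`, `status` (flanking classes);
#'   optional.
#' @return Data.frame of class `integration_table`, one row per master UCE.
#' @export
build_integration_table <- function(uce_ids, contexts, profile,
                                    stability = NULL, rnaseq = NULL,
                                    enhancer = NULL, human = NULL,
                                    flanking = NULL) {
  if (anyDuplicated(uce_ids)) stopf("duplicate ids in master UCE list")
  out <- data.frame(uce_id = uce_ids, stringsAsFactors = FALSE)
  out$context <- lookup(uce_ids,
                        data.frame(uce_id = names(contexts),
                                   context = unname(contexts),
                                   stringsAsFactors = FALSE),
                        "context", NA_character_, "contexts")
  check_unique_ids(profile, "array profile")
  m <- match(uce_ids, profile$uce_id)
  stage_cols <- grep("^status_", names(profile), value = TRUE)
  for (sc in stage_cols) {
    st <- sub("^status_", "", sc)
    out[[paste0("array_", st)]] <-
      ifelse(is.na(m), "not_tested",
             ifelse(profile[[sc]][m] == "none", "not_expressed", "expressed"))
  }
  out$array_any <- !is.na(m) & profile$any_stage[m]
  out$array_all <- !is.na(m) & profile$all_stages[m]
  out$strandedness <- ifelse(is.na(m), "none", profile$strandedness[m])
  out$constitutive <- if (is.null(stability)) FALSE else
    lookup(uce_ids, stability, "constitutive", FALSE, "stability")
  out$rnaseq_expressed <- if (is.null(rnaseq)) "not_assessed" else
    ifelse(lookup(uce_ids, transform(rnaseq, s = ifelse(expressed, "expressed",
                                                        "not_expressed")),
                  "s", "not_assessed", "rnaseq") == "expressed",
           "expressed",
           ifelse(uce_ids %in% rnaseq$uce_id, "not_expressed", "not_assessed"))
  out$enhancer <- if (is.null(enhancer)) "not_tested" else
    lookup(uce_ids, enhancer, "status", "not_tested", "enhancer")
  out$human_expressed <- if (is.null(human)) "not_tested" else
    lookup(uce_ids, human, "status", "not_tested", "human")
  out$flanking <- if (is.null(flanking)) "not_assessable" else
    lookup(uce_ids, flanking, "status", "not_assessable", "flanking")
  class(out) <- c("integration_table", "data.frame")
  out
}

#' Venn-style overlap summary across evidence sources
#'
#' Counts and fractions over an explicit universe for every membership
#' combination of the four sources (array, RNA-Seq, enhancer, human), plus
#' the dual-function breakdown: "transcribed in mouse" (array any-stage OR
#' RNA-Seq expressed) crossed with enhancer activity.
#'
#' @param table An `integration_table`.
#' @param universe UCE ids defining the universe (default: all rows).
#'   Universes are always explicit because headline fractions depend on
#'   them (all UCEs, those on the array, those tested for enhancer
#'   activity).
#' @return List: `n`, `subset_counts` (16-row data.frame), `fractions`
#'   (per-source positive fractions), `dual` (fractions transcribed_and_
#'   enhancer / transcribed_only / enhancer_only / neither, summing to 1),
#'   and `transcribed_mouse_fraction`.
#' @export
overlap_summary <- function(table, universe = table$uce_id) {
  if (length(universe) == 0L) stopf("empty universe")
  miss <- setdiff(universe, table$uce_id)
  if (length(miss) > 0) stopf("universe ids absent from table: %s",
                              paste(utils::head(miss, 5), collapse = ", "))
  t <- table[match(universe, table$uce_id), ]
  flags <- data.frame(
    array = t$array_any,
    rnaseq = t$rnaseq_expressed == "expressed",
    enhancer = t$enhancer == "positive",
    human = t$human_expressed == "expressed")
  combos <- expand.grid(array = c(FALSE, TRUE), rnaseq = c(FALSE, TRUE),
                        enhancer = c(FALSE, TRUE), human = c(FALSE, TRUE))
  combos$count <- apply(combos, 1, function(cmb)
    sum(flags$array == cmb["array"] & flags$rnaseq == cmb["rnaseq"] &
          flags$enhancer == cmb["enhancer"] & flags$human == cmb["human"]))
  transcribed <- flags$array | flags$rnaseq
  n <- nrow(t)
  dual <- c(transcribed_and_enhancer = sum(transcribed & flags$enhancer),
            transcribed_only = sum(transcribed & !flags$enhancer),
            enhancer_only = sum(!transcribed & flags$enhancer),
            neither = sum(!transcribed & !flags$enhancer)) / n
  list(n = n, subset_counts = combos,
       fractions = colMeans(flags), dual = dual,
       transcribed_mouse_fraction = mean(transcribed))
}

#' Concordance between two binary call sets
#'
#' Per-UCE agreement over an explicit tested universe, with the agreement
#' fraction and its Wald 95% confidence interval.
#'
#' @param calls_a,calls_b Named logical vectors covering the universe.
#' @param universe UCE ids over which both sets are defined.
#' @param level Confidence level (default 0.95).
#' @return List: `agree_pos`, `agree_neg`, `disagree` (id vectors),
#'   `fraction`, `ci`.
#' @export
concordance <- function(calls_a, calls_b, universe, level = 0.95) {
  for (nm in list(calls_a, calls_b)) {
    miss <- setdiff(universe, names(nm))
    if (length(miss) > 0)
      stopf("universe member(s) missing from a call set: %s",
            paste(utils::head(miss, 5), collapse = ", "))
  }
  a <- calls_a[universe]; b <- calls_b[universe]
  agree_pos <- universe[a & b]
  agree_neg <- universe[!a & !b]
  disagree <- universe[a != b]
  n_agree <- length(agree_pos) + length(agree_neg)
  list(agree_pos = agree_pos, agree_neg = agree_neg, disagree = disagree,
       fraction = n_agree / length(universe),
       ci = proportion_ci(n_agree, length(universe), level))
}

#' Assign each UCE to its nearest gene
#'
#' Genic UCEs map to their host gene; intergenic UCEs map to the nearest
#' gene body by gap distance on the same chromosome. Ties map to all tied
#' genes (one row each).
#'
#' @param uces Interval table with `name` = UCE id.
#' @param gene_bodies Interval table with `name` = gene id.
#' @return Data.frame `uce_id`, `gene`, `distance` (bp gap; 0 when inside).
#' @export
nearest_genes <- function(uces, gene_bodies) {
  if (nrow(gene_bodies) == 0L)
    return(data.frame(uce_id = character(), gene = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  rows <- list()
  for (ch in unique(uces$chrom)) {
    ui <- which(uces$chrom == ch)
    gi <- which(gene_bodies$chrom == ch)
    if (length(gi) == 0L) next
    for (i in ui) {
      gap <- pmax(0, pmax(gene_bodies$start[gi] - uces$end[i],
                          uces$start[i] - gene_bodies$end[gi]))
      best <- which(gap == min(gap))
      rows[[length(rows) + 1L]] <- data.frame(
        uce_id = uces$name[i], gene = gene_bodies$name[gi][best],
        distance = gap[best], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(uce_id = character(), gene = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Term enrichment of a UCE subset via associated genes
#'
#' Maps UCEs to genes and genes to flat annotation terms, then tests each
#' term by the upper-tail hypergeometric test on gene counts (subset genes
#' drawn from universe genes), with Benjamini-Hochberg adjustment across
#' terms; both raw and adjusted p-values are reported.
#'
#' @param uce_to_gene Data.frame `uce_id`, `gene`.
#' @param gene_to_terms Data.frame `gene`, `term`.
#' @param subset_uces,universe_uces UCE id vectors, subset within universe.
#' @return Data.frame per term: `term`, `k`, `K`, `n`, `N`, `p`, `p_bh`.
#' @export
term_enrichment <- function(uce_to_gene, gene_to_terms, subset_uces,
                            universe_uces) {
  if (!all(subset_uces %in% universe_uces))
    stopf("subset must be within the universe")
  uni_genes <- unique(uce_to_gene$gene[uce_to_gene$uce_id %in% universe_uces])
  sub_genes <- unique(uce_to_gene$gene[uce_to_gene$uce_id %in% subset_uces])
  N <- length(uni_genes); n <- length(sub_genes)
  if (N == 0L) stopf("no genes mapped for the universe")
  g2t <- gene_to_terms[gene_to_terms$gene %in% uni_genes, , drop = FALSE]
  terms <- sort(unique(g2t$term))
  rows <- lapply(terms, function(tm) {
    tg <- unique(g2t$gene[g2t$term == tm])
    K <- length(tg); k <- sum(sub_genes %in% tg)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = hypergeometric_tail(k, K, n, N)$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_bh <- bh_adjust(out$p) else
    out <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_bh = numeric(), stringsAsFactors = FALSE)
  out
}
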