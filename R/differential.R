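#' Pooled-variance two-sample t test on log2 values
#'
#' Classical Student's t test (equal-variance, two-sided) via
#' `stats::t.test(var.equal = TRUE)`, with the degenerate constant-data
#' cases resolved deterministically: zero variance in both groups with
#' equal means gives t = 0, p = 1; with unequal means t = +/-Inf, p = 0.
#' The fold change is `mean(x) - mean(y)` (callers pass log2 quantities).
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @return list with `t`, `p`, `log2fc`, `df`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >=2 values")
  }
  lfc <- mean(x) - mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (lfc == 0) return(list(t = 0, p = 1, log2fc = 0,
                              df = length(x) + length(y) - 2L))
    return(list(t = sign(lfc) * Inf, p = 0, log2fc = lfc,
                df = length(x) + length(y) - 2L))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, log2fc = lfc,
       df = unname(tt$parameter))
}

#' Pairwise differential calls across stages
#'
#' Runs [two_sample_t()] per row (peak or gene) for every ordered stage
#' pair A vs B, and labels each row `higher_A` (log2FC > 0, p < alpha),
#' `higher_B` (log2FC < 0, p < alpha) or `ns`.
#'
#' @param values Matrix rows x replicate columns of log2 quantities.
#' @param groups Stage label per column.
#' @param alpha Significance level, default 0.05.
#' @return data.frame of class `differential_calls`: id, stage_a, stage_b,
#'   log2fc, t, p, n_a, n_b, category.
#' @export
pairwise_differential <- function(values, groups, alpha = 0.05) {
  stages <- unique(groups)
  pairs <- utils::combn(stages, 2, simplify = FALSE)
  ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  rows <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    xa <- values[, groups == a, drop = FALSE]
    xb <- values[, groups == b, drop = FALSE]
    res <- lapply(seq_len(nrow(values)), function(i) {
      two_sample_t(xa[i, !is.na(xa[i, ])], xb[i, !is.na(xb[i, ])])
    })
    lfc <- vapply(res, `[[`, numeric(1), "log2fc")
    p <- vapply(res, `[[`, numeric(1), "p")
    tstat <- vapply(res, `[[`, numeric(1), "t")
    data.frame(id = ids, stage_a = a, stage_b = b,
               log2fc = lfc, t = tstat, p = p,
               n_a = ncol(xa), n_b = ncol(xb),
               category = ifelse(p < alpha & lfc > 0, "higher_a",
                                 ifelse(p < alpha & lfc < 0, "higher_b",
                                        "ns")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("differential_calls", "data.frame")
  out
}

# Internal: is `id` higher in `stage` than in BOTH other stages per calls
higher_in_stage <- function(calls, stage, ids) {
  other <- setdiff(unique(c(calls$stage_a, calls$stage_b)), stage)
  ok <- rep(TRUE, length(ids))
  for (o in other) {
    sub_a <- calls[calls$stage_a == stage & calls$stage_b == o, ]
    sub_b <- calls[calls$stage_a == o & calls$stage_b == stage, ]
    hit <- union(sub_a$id[sub_a$category == "higher_a"],
                 sub_b$id[sub_b$category == "higher_b"])
    ok <- ok & ids %in% hit
  }
  ok
}

#' Stage-higher peak sets (t test plus stage-unique peaks)
#'
#' A peak entity is "higher" in stage S when its replicate log2 enrichments
#' are significantly above BOTH other stages (pooled t test, log2FC > 0,
#' p < alpha against each), or when it was detected in S's consensus set
#' only (`stage_unique`). Requires exactly >= 3 stages; the resulting sets
#' are pairwise disjoint.
#'
#' @param rep_log2 Matrix entities x replicate columns of log2 enrichment
#'   (NA where the entity is absent from that stage's consensus set).
#' @param groups Stage per column.
#' @param presence Logical matrix entities x stages: consensus membership.
#' @param alpha Default 0.05.
#' @return Named list (per stage) of data.frames `id`, `provenance`
#'   ("t_test" or "stage_unique").
#' @export
call_stage_higher <- function(rep_log2, groups, presence, alpha = 0.05) {
  stages <- colnames(presence)
  if (length(unique(groups)) < 3L || length(stages) < 3L) {
    stop("stage-higher sets need >=3 stages")
  }
  ids <- rownames(rep_log2)
  complete <- rowSums(!presence) == 0L
  calls <- if (any(complete)) {
    pairwise_differential(rep_log2[complete, , drop = FALSE], groups, alpha)
  } else NULL
  out <- lapply(stages, function(s) {
    t_ids <- character(0)
    if (!is.null(calls)) {
      cid <- ids[complete]
      hit <- higher_in_stage(calls, s, cid)
      t_ids <- cid[hit]
    }
    uniq <- ids[presence[, s] & rowSums(presence) == 1L]
    data.frame(id = c(t_ids, uniq),
               provenance = c(rep("t_test", length(t_ids)),
                              rep("stage_unique", length(uniq))),
               stringsAsFactors = FALSE)
  })
  stats::setNames(out, stages)
}

#' Stage-higher (and lower) expression gene sets
#'
#' As [call_stage_higher()] on log2(FPKM + eps) without a stage-unique
#' clause; also returns the symmetric "lower in S vs both others" sets used
#' for the methylation/expression intersection.
#'
#' @param fpkm Matrix genes x input libraries (raw FPKM).
#' @param groups Stage per column.
#' @param alpha Default 0.05.
#' @param eps Pseudo-FPKM inside the log, default 0.01.
#' @return list with `higher` and `lower`: named lists (per stage) of gene
#'   id vectors, plus `calls` (the pairwise table).
#' @export
call_expression <- function(fpkm, groups, alpha = 0.05, eps = 0.01) {
  lg <- log2(fpkm + eps)
  stages <- unique(groups)
  if (length(stages) < 3L) stop("expression sets need >=3 stages")
  calls <- pairwise_differential(lg, groups, alpha)
  ids <- rownames(lg)
  higher <- lapply(stages, function(s) ids[higher_in_stage(calls, s, ids)])
  # "lower in S" = higher in each other stage over S, i.e. S significantly
  # below both others
  lower <- lapply(stages, function(s) {
    other <- setdiff(stages, s)
    ok <- rep(TRUE, length(ids))
    for (o in other) {
      sub_a <- calls[calls$stage_a == s & calls$stage_b == o, ]
      sub_b <- calls[calls$stage_a == o & calls$stage_b == s, ]
      hit <- union(sub_a$id[sub_a$category == "higher_b"],
                   sub_b$id[sub_b$category == "higher_a"])
      ok <- ok & ids %in% hit
    }
    ids[ok]
  })
  list(higher = stats::setNames(higher, stages),
       lower = stats::setNames(lower, stages),
       calls = calls)
}

#' Genes with higher methylation and lower expression per stage
#'
#' Intersects, per stage, the genes carrying at least one higher-methylation
#' peak with the genes whose expression is lower than in both other stages.
#'
#' @param meth_sets Output of [call_stage_higher()] (peak entities).
#' @param lower_expr Named list (per stage) of gene ids (see
#'   [call_expression()]`$lower`).
#' @param peak_genes Named character vector: entity/peak id -> gene_id.
#' @return Named list (per stage) of gene id vectors.
#' @export
higher_meth_lower_expr <- function(meth_sets, lower_expr, peak_genes) {
  stages <- names(meth_sets)
  out <- lapply(stages, function(s) {
    genes <- unique(peak_genes[meth_sets[[s]]$id])
    genes <- genes[!is.na(genes) & genes != "intergenic"]
    sort(intersect(genes, lower_expr[[s]]))
  })
  stats::setNames(out, stages)
}

#' Gene-level differential summary per pairwise comparison
#'
#' Collapses per-peak methylation calls to genes (a gene is differentially
#' methylated in a direction when it carries >= 1 such peak) and tabulates,
#' per stage pair, how many genes are higher in each stage for methylation
#' and for expression, with proportions over the modified / expressed gene
#' universe.
#'
#' @param meth_calls `differential_calls` on peak entities.
#' @param expr_calls `differential_calls` on genes.
#' @param peak_genes Named character vector: entity id -> gene_id.
#' @param n_modified_genes Denominator for methylation proportions.
#' @param n_expressed_genes Denominator for expression proportions.
#' @return data.frame: comparison, measure, higher_in_a, higher_in_b,
#'   prop_a, prop_b, total.
#' @export
summarize_differential <- function(meth_calls, expr_calls, peak_genes,
                                   n_modified_genes, n_expressed_genes) {
  pair_key <- function(df) paste(df$stage_a, "vs", df$stage_b)
  rows <- list()
  for (k in unique(pair_key(meth_calls))) {
    sub <- meth_calls[pair_key(meth_calls) == k, ]
    ga <- unique(peak_genes[sub$id[sub$category == "higher_a"]])
    gb <- unique(peak_genes[sub$id[sub$category == "higher_b"]])
    ga <- ga[!is.na(ga) & ga != "intergenic"]
    gb <- gb[!is.na(gb) & gb != "intergenic"]
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = k, measure = "methylation",
      higher_in_a = length(ga), higher_in_b = length(gb),
      prop_a = length(ga) / n_modified_genes,
      prop_b = length(gb) / n_modified_genes,
      total = length(ga) + length(gb), stringsAsFactors = FALSE)
  }
  for (k in unique(pair_key(expr_calls))) {
    sub <- expr_calls[pair_key(expr_calls) == k, ]
    na_ <- sum(sub$category == "higher_a")
    nb_ <- sum(sub$category == "higher_b")
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = k, measure = "expression",
      higher_in_a = na_, higher_in_b = nb_,
      prop_a = na_ / n_expressed_genes,
      prop_b = nb_ / n_expressed_genes,
      total = na_ + nb_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
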