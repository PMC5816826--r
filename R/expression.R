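#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (library_size * length_bp)`, where the library size is the
#' per-sample column sum of raw counts.
#'
#' @param counts Integer matrix, genes x samples, with rownames = gene ids.
#' @param lengths Numeric vector of gene lengths in bp, aligned with rows
#'   (or named by gene id).
#'
#' @return Numeric matrix of FPKM values, same dimensions as `counts`.
#' @export
compute_fpkm <- function(counts, lengths) {
  counts <- .as_count_matrix(counts)
  lengths <- .aligned_lengths(counts, lengths)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero-count sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  sweep(counts / lengths, 2, lib, "/") * 1e9
}

#' TPM normalization
#'
#' Transcripts per million: per-sample length-normalized rates rescaled so
#' each sample sums to one million.
#'
#' @inheritParams compute_fpkm
#' @return Numeric matrix of TPM values.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- .as_count_matrix(counts)
  lengths <- .aligned_lengths(counts, lengths)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero-count sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

.as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  counts
}

.aligned_lengths <- function(counts, lengths) {
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("'lengths' must align with the rows of 'counts'")
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive and known for every gene")
  lengths
}

#' Call genes expressed per condition
#'
#' A gene counts as expressed in a condition when its replicate-mean FPKM
#' strictly exceeds the expression threshold (default FPKM > 1).
#'
#' @param fpkm Numeric matrix, genes x samples.
#' @param conditions Character/factor vector naming the condition of each
#'   sample (aligned with columns).
#' @param thresholds A [missp_thresholds()] object or `NULL`.
#'
#' @return Logical matrix, genes x conditions.
#' @export
call_expressed <- function(fpkm, conditions, thresholds = NULL) {
  th <- .as_thresholds(thresholds)
  stopifnot(length(conditions) == ncol(fpkm))
  conditions <- as.factor(conditions)
  means <- sapply(levels(conditions), function(cc)
    rowMeans(fpkm[, conditions == cc, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(fpkm),
                                           dimnames = list(rownames(fpkm),
                                                           levels(conditions)))
  means > th$expressed_fpkm
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with the usual monotonicity enforcement. Inputs are
#' validated to lie in [0, 1].
#'
#' @param pvalues Numeric vector of p-values.
#' @return Numeric vector of BH-adjusted values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues))
    stop("p-values must be numeric")
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok))
    stop("p-values outside [0, 1] at positions: ",
         paste(which(!ok), collapse = ", "))
  stats::p.adjust(pvalues, method = "BH")
}

#' Threshold-based regulation calls
#'
#' Applies the study's differential-expression rule: `up` when
#' log2FC > `reg_lfc` and FDR < `reg_fdr`; `down` when log2FC < -`reg_lfc`
#' and FDR < `reg_fdr`; otherwise `ns`.
#'
#' @param de A data.frame with columns `gene_id`, `log2fc`, `fdr` and
#'   optionally `contrast`.
#' @param thresholds A [missp_thresholds()] object or `NULL`.
#'
#' @return The input with an added `status` factor (`up`, `down`, `ns`).
#' @export
call_regulation <- function(de, thresholds = NULL) {
  th <- .as_thresholds(thresholds)
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(de)))
  status <- rep("ns", nrow(de))
  sig <- !is.na(de$fdr) & de$fdr < th$reg_fdr & !is.na(de$log2fc)
  status[sig & de$log2fc > th$reg_lfc] <- "up"
  status[sig & de$log2fc < -th$reg_lfc] <- "down"
  de$status <- factor(status, levels = c("up", "down", "ns"))
  de
}

#' Host-preference call from per-host mean expression
#'
#' Compares a gene's mean FPKM between two host interactions. A transcript is
#' `specific_a`/`specific_b` when the other host shows exactly zero
#' expression, `prefer_a`/`prefer_b` when the larger-to-smaller ratio
#' strictly exceeds the host-fold threshold (default 5), and `shared`
#' otherwise (including both zero).
#'
#' @param mean_a,mean_b Non-negative numeric vectors of condition-mean FPKM.
#' @param thresholds A [missp_thresholds()] object or `NULL`.
#'
#' @return Factor with levels shared, prefer_a, prefer_b, specific_a,
#'   specific_b.
#' @export
host_preference <- function(mean_a, mean_b, thresholds = NULL) {
  th <- .as_thresholds(thresholds)
  stopifnot(length(mean_a) == length(mean_b),
            all(mean_a >= 0), all(mean_b >= 0))
  out <- rep("shared", length(mean_a))
  out[mean_b == 0 & mean_a > 0] <- "specific_a"
  out[mean_a == 0 & mean_b > 0] <- "specific_b"
  both <- mean_a > 0 & mean_b > 0
  ratio <- pmax(mean_a, mean_b) / pmin(mean_a, mean_b)
  out[both & ratio > th$host_fold & mean_a > mean_b] <- "prefer_a"
  out[both & ratio > th$host_fold & mean_b > mean_a] <- "prefer_b"
  factor(out, levels = c("shared", "prefer_a", "prefer_b",
                         "specific_a", "specific_b"))
}

#' Secreted-protein class enrichment among regulated genes
#'
#' For each class and each regulation direction, tests over-representation of
#' the class among regulated genes with the one-sided hypergeometric tail
#' `P(X >= k)` (the one-sided Fisher enrichment test), where the universe is
#' the classified secretome.
#'
#' @param calls Output of [call_regulation()] restricted to one contrast.
#' @param catalog Output of [classify_secretome()].
#'
#' @return A data.frame with columns `sp_class`, `direction`, `k` (class
#'   members regulated), `K` (class size), `n` (regulated genes), `N`
#'   (secretome size) and `p_enrich`.
#' @export
class_enrichment <- function(calls, catalog) {
  stopifnot(all(c("gene_id", "status") %in% names(calls)),
            all(c("protein_id", "sp_class") %in% names(catalog)))
  missing_class <- setdiff(calls$gene_id, catalog$protein_id)
  if (length(missing_class))
    stop("regulated genes absent from the secretome catalog: ",
         paste(utils::head(missing_class, 5), collapse = ", "))
  N <- nrow(catalog)
  cls <- as.character(catalog$sp_class)
  res <- list()
  for (dir in c("up", "down")) {
    reg_ids <- calls$gene_id[calls$status == dir]
    n <- length(reg_ids)
    in_reg <- catalog$protein_id %in% reg_ids
    for (cc in sp_class_levels()) {
      K <- sum(cls == cc)
      k <- sum(cls == cc & in_reg)
      p <- if (n == 0 || k == 0) 1 else
        stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        sp_class = cc, direction = dir, k = k, K = K, n = n, N = N,
        p_enrich = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Venn-region counts across gene sets
#'
#' Counts every intersection region of two or more named gene-id sets
#' (e.g. up-regulated sets per synthesis system). Region labels join member
#' set names with `&`; region counts sum to the size of the union.
#'
#' @param sets Named list of character vectors (>= 2 sets).
#' @return A data.frame with columns `region` and `count`.
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  ids <- unique(unlist(sets))
  member <- sapply(sets, function(s) ids %in% s)
  if (length(ids) == 1L) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  regions <- unlist(lapply(seq_along(sets), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = TRUE)))
  counts <- table(factor(key, levels = regions))
  data.frame(region = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Lightweight differential-expression test for synthetic counts
#'
#' A deliberately simple stand-in used to evaluate synthetic data: library
#' sizes are estimated with median-of-ratios size factors (geometric-mean
#' reference; genes with a zero geometric mean are excluded from the
#' median), log2 fold changes are computed from normalized group means with
#' a pseudocount of 1, significance comes from a two-sided Welch t-test on
#' `log2(normalized + 1)`, and p-values are BH-adjusted. It makes no claim
#' to the shrinkage or filtering behaviour of a full RNA-seq engine.
#'
#' @param counts Integer matrix, genes x samples.
#' @param condition Factor/character vector of sample conditions.
#' @param treatment,reference Condition labels to contrast.
#'
#' @return A data.frame with columns `gene_id`, `contrast`, `log2fc`,
#'   `pvalue`, `fdr`.
#' @export
simple_de_test <- function(counts, condition, treatment, reference) {
  counts <- .as_count_matrix(counts)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(counts))
  ti <- which(condition == treatment)
  ri <- which(condition == reference)
  if (length(ti) < 2 || length(ri) < 2)
    stop("need at least 2 replicates per group")
  sub <- counts[, c(ri, ti), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  grp <- rep(c("ref", "trt"), c(length(ri), length(ti)))
  mu_r <- rowMeans(norm[, grp == "ref", drop = FALSE])
  mu_t <- rowMeans(norm[, grp == "trt", drop = FALSE])
  lfc <- log2((mu_t + 1) / (mu_r + 1))
  lx <- log2(norm + 1)
  pv <- vapply(seq_len(nrow(lx)), function(i) {
    a <- lx[i, grp == "trt"]; b <- lx[i, grp == "ref"]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  data.frame(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    contrast = paste(treatment, "vs", reference),
    log2fc = lfc, pvalue = pv, fdr = bh_adjust(pv),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Median-of-ratios size factors
#'
#' @param counts Integer matrix, genes x samples.
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- .as_count_matrix(counts)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("every gene has a zero count; size factors undefined")
  apply(counts, 2, function(cnt)
    exp(stats::median((log(cnt) - loggeo)[use])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
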