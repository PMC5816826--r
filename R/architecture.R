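#' Flanking intergenic regions (FIRs) for every gene
#'
#' For each gene the distance to its neighbouring gene is measured on both
#' sides as the number of bases strictly between the two gene spans
#' (`start_next - end_prev - 1`), then assigned to the gene's 5' or 3' side
#' according to its strand: for a `+` gene the upstream (left) gap is the 5'
#' FIR; for a `-` gene the assignment is swapped. The first and last gene on
#' a contig have an undefined FIR on the contig-edge side. Overlapping
#' adjacent genes yield a distance clamped to 0 (with a warning); duplicate
#' gene ids are an error.
#'
#' @param genes A data.frame with columns `gene_id`, `contig`, `start`,
#'   `end` (1-based inclusive) and `strand` (`+`/`-`).
#'
#' @return A data.frame with columns `gene_id`, `contig`, `strand`,
#'   `fir5_bp`, `fir3_bp` (`NA` at contig edges), in the input row order.
#' @export
#' @examples
#' g <- data.frame(gene_id = c("a", "b", "c"), contig = "tig1",
#'                 start = c(101, 501, 2001), end = c(200, 700, 2100),
#'                 strand = "+")
#' compute_firs(g)
compute_firs <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "contig", "start", "end", "strand") %in%
                  names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  if (any(genes$start > genes$end))
    stop("gene with start > end")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")

  fir5 <- rep(NA_real_, nrow(genes))
  fir3 <- rep(NA_real_, nrow(genes))
  n_clamped <- 0L
  for (ctg in unique(genes$contig)) {
    idx <- which(genes$contig == ctg)
    ord <- idx[order(genes$start[idx], genes$end[idx])]
    k <- length(ord)
    gap_left <- rep(NA_real_, k)
    if (k > 1) {
      g <- genes$start[ord][-1] - genes$end[ord][-k] - 1
      n_clamped <- n_clamped + sum(g < 0)
      gap_left[-1] <- pmax(g, 0)
    }
    gap_right <- c(gap_left[-1], NA_real_)
    plus <- genes$strand[ord] == "+"
    fir5[ord] <- ifelse(plus, gap_left, gap_right)
    fir3[ord] <- ifelse(plus, gap_right, gap_left)
  }
  if (n_clamped > 0)
    warning(n_clamped, " overlapping adjacent gene pair(s); ",
            "distances clamped to 0")
  data.frame(
    gene_id = as.character(genes$gene_id),
    contig = as.character(genes$contig),
    strand = as.character(genes$strand),
    fir5_bp = fir5, fir3_bp = fir3,
    stringsAsFactors = FALSE
  )
}

#' Classify genes into GDR/GSR genome compartments
#'
#' A gene belongs to the gene-sparse repeat-rich (GSR) compartment when its
#' 5' and/or 3' FIR strictly exceeds the cutoff (default 6,495 bp); to the
#' gene-dense repeat-poor (GDR) compartment when every defined FIR is at or
#' below the cutoff; and is `unassigned` when neither FIR is defined
#' (single gene on its contig).
#'
#' @param firs Output of [compute_firs()].
#' @param thresholds A [missp_thresholds()] object or `NULL`.
#'
#' @return The input data.frame with an added `region` factor
#'   (`GDR`, `GSR`, `unassigned`).
#' @export
classify_region <- function(firs, thresholds = NULL) {
  th <- .as_thresholds(thresholds)
  stopifnot(all(c("fir5_bp", "fir3_bp") %in% names(firs)))
  long5 <- !is.na(firs$fir5_bp) & firs$fir5_bp > th$gsr_cutoff_bp
  long3 <- !is.na(firs$fir3_bp) & firs$fir3_bp > th$gsr_cutoff_bp
  none <- is.na(firs$fir5_bp) & is.na(firs$fir3_bp)
  region <- ifelse(none, "unassigned", ifelse(long5 | long3, "GSR", "GDR"))
  firs$region <- factor(region, levels = c("GDR", "GSR", "unassigned"))
  firs
}

#' 2D log-binned FIR density heatmap
#'
#' Bins genes by `log10` of their 5' (x) and 3' (y) FIR lengths, with a
#' fixed bin width on the log scale (default 0.1). Zero-length FIRs fall in
#' the first bin. Genes lacking either FIR are excluded from the matrix and
#' reported in `n_excluded`. Optional per-gene overlays (e.g. log2 fold
#' change or FPKM) are averaged per occupied bin.
#'
#' @param firs Output of [compute_firs()].
#' @param bin_width_log10 Bin width on the log10(bp) scale.
#' @param overlay Optional named list of numeric vectors (named by gene id)
#'   to average per bin.
#'
#' @return A list with `breaks` (log10 bin edges, shared by both axes),
#'   `counts` (matrix, 5' bins x 3' bins), `overlays` (list of mean
#'   matrices) and `n_excluded`.
#' @export
bin_heatmap <- function(firs, bin_width_log10 = 0.1, overlay = NULL) {
  stopifnot(all(c("gene_id", "fir5_bp", "fir3_bp") %in% names(firs)))
  keep <- !is.na(firs$fir5_bp) & !is.na(firs$fir3_bp)
  x <- firs$fir5_bp[keep]; y <- firs$fir3_bp[keep]
  ids <- firs$gene_id[keep]
  if (!length(x)) {
    return(list(breaks = numeric(0),
                counts = matrix(0L, 0, 0),
                overlays = list(), n_excluded = sum(!keep)))
  }
  pos <- c(x[x > 0], y[y > 0])
  w <- bin_width_log10
  lo <- if (length(pos)) floor(min(log10(pos)) / w) * w else 0
  hi <- if (length(pos)) ceiling(max(log10(pos)) / w) * w else w
  if (hi <= lo) hi <- lo + w
  breaks <- seq(lo, hi + w / 2, by = w)
  bin_of <- function(v) {
    b <- findInterval(log10(pmax(v, 10^lo)), breaks,
                      rightmost.closed = TRUE, all.inside = TRUE)
    b
  }
  bx <- bin_of(x); by <- bin_of(y)
  nb <- length(breaks) - 1L
  counts <- matrix(0L, nb, nb)
  for (i in seq_along(bx)) counts[bx[i], by[i]] <- counts[bx[i], by[i]] + 1L
  overlays <- list()
  if (!is.null(overlay)) {
    for (nm in names(overlay)) {
      v <- overlay[[nm]][ids]
      s <- matrix(0, nb, nb); m <- matrix(NA_real_, nb, nb)
      for (i in seq_along(bx)) {
        if (is.na(v[i])) next
        s[bx[i], by[i]] <- s[bx[i], by[i]] + v[i]
      }
      occ <- counts > 0
      m[occ] <- s[occ] / counts[occ]
      overlays[[nm]] <- m
    }
  }
  list(breaks = breaks, counts = counts, overlays = overlays,
       n_excluded = sum(!keep))
}

#' Compartment composition per secreted-protein class
#'
#' For every class of the secretome catalog (and for the whole gene
#' complement as background) reports the fraction of region-assigned genes
#' lying in the GSR compartment, plus a one-sided hypergeometric
#' over-representation p-value of the class among GSR genes.
#'
#' @param catalog Output of [classify_secretome()] (or any data.frame with
#'   `protein_id` and `sp_class`).
#' @param regions Output of [classify_region()] covering at least the
#'   catalogued genes (gene ids matched to protein ids).
#'
#' @return A data.frame with columns `category`, `n_assigned`, `n_gsr`,
#'   `gsr_fraction` (`NA` when no gene of the category is assigned) and
#'   `p_enrich`.
#' @export
region_composition <- function(catalog, regions) {
  stopifnot(all(c("protein_id", "sp_class") %in% names(catalog)),
            all(c("gene_id", "region") %in% names(regions)))
  reg <- regions[regions$region %in% c("GDR", "GSR"), ]
  missing_reg <- setdiff(catalog$protein_id, regions$gene_id)
  if (length(missing_reg))
    stop("catalogued genes with no computed region: ",
         paste(utils::head(missing_reg, 5), collapse = ", "))
  N <- nrow(reg)
  K <- sum(reg$region == "GSR")
  rows <- list()
  add <- function(category, ids) {
    sub <- reg[reg$gene_id %in% ids, ]
    n <- nrow(sub); k <- sum(sub$region == "GSR")
    frac <- if (n > 0) k / n else NA_real_
    p <- if (n == 0 || k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, n_assigned = n, n_gsr = k,
      gsr_fraction = frac, p_enrich = p, stringsAsFactors = FALSE)
  }
  add("genome", reg$gene_id)
  add("secretome", catalog$protein_id)
  for (cc in sp_class_levels())
    add(cc, catalog$protein_id[catalog$sp_class == cc])
  do.call(rbind, rows)
}

#' Expression level by genome compartment
#'
#' Compares per-gene expression (e.g. FPKM) between the GDR and GSR
#' compartments: per-region medians plus a two-sided Mann-Whitney rank-sum
#' test (exact for small untied samples, otherwise normal approximation
#' with tie correction, as provided by [stats::wilcox.test()]).
#'
#' @param values Named numeric vector of per-gene expression values.
#' @param regions Output of [classify_region()].
#'
#' @return A list with `median_gdr`, `median_gsr`, `p_value` and `n` per
#'   region; when one region is empty the comparison is skipped
#'   (`p_value = NA`) with a message.
#' @export
expression_by_region <- function(values, regions) {
  stopifnot(!is.null(names(values)),
            all(c("gene_id", "region") %in% names(regions)))
  reg <- regions[regions$gene_id %in% names(values), ]
  gdr <- values[reg$gene_id[reg$region == "GDR"]]
  gsr <- values[reg$gene_id[reg$region == "GSR"]]
  out <- list(
    median_gdr = if (length(gdr)) stats::median(gdr) else NA_real_,
    median_gsr = if (length(gsr)) stats::median(gsr) else NA_real_,
    n_gdr = length(gdr), n_gsr = length(gsr), p_value = NA_real_)
  if (!length(gdr) || !length(gsr)) {
    message("one compartment has no genes; rank-sum comparison skipped")
    return(out)
  }
  out$p_value <- suppressWarnings(
    stats::wilcox.test(gsr, gdr, alternative = "two.sided")$p.value)
  out
}
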