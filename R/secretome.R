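#' Partition a secretome into disjoint secreted-protein classes
#'
#' Every protein carrying a signal peptide is assigned to exactly one of five
#' classes: `CAZyme`, `lipase`, `protease`, `SSP` (small secreted protein,
#' shorter than the SSP size limit) or `otherSP`. Enzymatic annotations take
#' precedence over the size rule (precedence CAZyme > lipase > protease >
#' SSP > otherSP), so the five class counts always sum to the secretome size.
#'
#' @param proteins A data.frame with columns `protein_id`, `length_aa`,
#'   `has_signal_peptide`, and optionally `cazy_families` (character; empty
#'   string or `NA` when none), `is_lipase`, `is_protease`.
#' @param thresholds A [missp_thresholds()] object (default thresholds used
#'   when `NULL`).
#'
#' @return A data.frame with columns `protein_id` and `sp_class` (factor with
#'   levels SSP, CAZyme, lipase, protease, otherSP).
#' @export
#' @examples
#' p <- data.frame(protein_id = c("a", "b"), length_aa = c(250, 320),
#'                 has_signal_peptide = TRUE)
#' classify_secretome(p)
classify_secretome <- function(proteins, thresholds = NULL) {
  th <- .as_thresholds(thresholds)
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "length_aa", "has_signal_peptide") %in%
                  names(proteins)))
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein ids in secretome input")
  no_sp <- !proteins$has_signal_peptide
  if (any(no_sp))
    stop("proteins without a signal peptide are not part of the secretome: ",
         paste(proteins$protein_id[no_sp], collapse = ", "))

  n <- nrow(proteins)
  cazy <- .flag_column(proteins, "cazy_families")
  lipase <- .logical_column(proteins, "is_lipase", n)
  protease <- .logical_column(proteins, "is_protease", n)

  cls <- rep("otherSP", n)
  is_ssp <- proteins$length_aa < th$ssp_max_len
  cls[is_ssp] <- "SSP"
  cls[protease] <- "protease"
  cls[lipase] <- "lipase"
  cls[cazy] <- "CAZyme"

  data.frame(
    protein_id = as.character(proteins$protein_id),
    sp_class = factor(cls, levels = sp_class_levels()),
    stringsAsFactors = FALSE
  )
}

#' Secreted-protein class levels
#'
#' @return Character vector of the five class labels in canonical order.
#' @export
sp_class_levels <- function() {
  c("SSP", "CAZyme", "lipase", "protease", "otherSP")
}

.flag_column <- function(df, col) {
  if (!col %in% names(df)) return(rep(FALSE, nrow(df)))
  v <- df[[col]]
  if (is.logical(v)) return(!is.na(v) & v)
  v <- as.character(v)
  !is.na(v) & nzchar(trimws(v))
}

.logical_column <- function(df, col, n) {
  if (!col %in% names(df)) return(rep(FALSE, n))
  v <- df[[col]]
  !is.na(v) & as.logical(v)
}

#' Per-protein summary statistics
#'
#' Computes, for each protein, its length, signal-peptide length and cysteine
#' content as a percentage of total length (two decimals), matching the
#' columns of a MiSSP candidate table. The cysteine percentage is only
#' reported when a sequence is available.
#'
#' @param proteins A data.frame with columns `protein_id`, `length_aa` and
#'   optionally `sp_length_aa` and `sequence` (one-letter amino-acid codes).
#'
#' @return A data.frame with columns `protein_id`, `length_aa`,
#'   `sp_length_aa` and `cysteine_percent` (`NA` when no sequence given).
#' @export
#' @examples
#' protein_stats(data.frame(protein_id = "x", length_aa = 4, sequence = "CCAA"))
protein_stats <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "length_aa") %in% names(proteins)))
  n <- nrow(proteins)
  sp_len <- if ("sp_length_aa" %in% names(proteins))
    proteins$sp_length_aa else rep(NA_real_, n)
  seqs <- if ("sequence" %in% names(proteins))
    as.character(proteins$sequence) else rep(NA_character_, n)

  bad_sp <- !is.na(sp_len) &
    (sp_len <= 0 | sp_len >= proteins$length_aa)
  if (any(bad_sp))
    stop("signal-peptide length must satisfy 0 < sp_length_aa < length_aa ",
         "for: ", paste(proteins$protein_id[bad_sp], collapse = ", "))

  cys <- rep(NA_real_, n)
  has_seq <- !is.na(seqs) & nzchar(seqs)
  if (any(has_seq)) {
    aa <- "ACDEFGHIKLMNPQRSTVWY"
    for (i in which(has_seq)) {
      s <- toupper(seqs[i])
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      bad <- setdiff(unique(chars), strsplit(aa, "")[[1]])
      if (length(bad))
        stop("non-amino-acid characters in sequence of ",
             proteins$protein_id[i], ": ", paste(bad, collapse = ", "))
      if (nchar(s) != proteins$length_aa[i])
        stop("sequence length of ", proteins$protein_id[i],
             " does not match length_aa")
      cys[i] <- round(100 * sum(chars == "C") / proteins$length_aa[i], 2)
    }
  }
  data.frame(
    protein_id = as.character(proteins$protein_id),
    length_aa = proteins$length_aa,
    sp_length_aa = sp_len,
    cysteine_percent = cys,
    stringsAsFactors = FALSE
  )
}

#' Select mycorrhiza-induced SSP (MiSSP) candidates
#'
#' From a differential-expression table for the reference symbiosis contrast
#' (ECM root tips versus free-living mycelium), selects the SSPs whose linear
#' fold change `2^log2fc` strictly exceeds the MiSSP induction threshold
#' (default 2.5-fold). Only genes classified as `SSP` are eligible.
#'
#' @param de A data.frame with columns `gene_id` and `log2fc`.
#' @param secretome Output of [classify_secretome()].
#' @param thresholds A [missp_thresholds()] object or `NULL`.
#'
#' @return A data.frame of selected candidates (`gene_id`, `log2fc`,
#'   `fold_change`) ordered by descending fold change. Rows with missing
#'   `log2fc` are skipped with a warning giving their count.
#' @export
select_missps <- function(de, secretome, thresholds = NULL) {
  th <- .as_thresholds(thresholds)
  stopifnot(all(c("gene_id", "log2fc") %in% names(de)),
            all(c("protein_id", "sp_class") %in% names(secretome)))
  ssp_ids <- secretome$protein_id[secretome$sp_class == "SSP"]
  de <- de[de$gene_id %in% ssp_ids, , drop = FALSE]
  n_missing <- sum(is.na(de$log2fc))
  if (n_missing > 0) {
    warning(n_missing, " SSP row(s) lacked a log2 fold change and were skipped")
    de <- de[!is.na(de$log2fc), , drop = FALSE]
  }
  fold <- 2^de$log2fc
  sel <- de[fold > th$missp_fold, , drop = FALSE]
  sel$fold_change <- 2^sel$log2fc
  sel <- sel[order(-sel$log2fc), , drop = FALSE]
  rownames(sel) <- NULL
  sel[, c("gene_id", "log2fc", "fold_change")]
}

#' Resolve annotated duplication pairs
#'
#' Reciprocal `duplication_partner` annotations (a points to b and b to a)
#' collapse into a single unordered pair. One-way annotations are reported as
#' dangling, not paired; a protein naming itself as partner is an error.
#'
#' @param proteins A data.frame with columns `protein_id` and
#'   `duplication_partner` (empty string or `NA` when none).
#'
#' @return A data.frame with columns `id1`, `id2` (lexicographically ordered
#'   within each pair, rows sorted), carrying a `dangling` attribute listing
#'   unreciprocated ids.
#' @export
duplication_pairs <- function(proteins) {
  stopifnot(all(c("protein_id", "duplication_partner") %in% names(proteins)))
  id <- as.character(proteins$protein_id)
  partner <- as.character(proteins$duplication_partner)
  partner[is.na(partner) | !nzchar(trimws(partner))] <- NA_character_
  if (any(!is.na(partner) & partner == id))
    stop("protein annotated as its own duplication partner: ",
         paste(id[!is.na(partner) & partner == id], collapse = ", "))
  unresolved <- !is.na(partner) & !(partner %in% id)
  if (any(unresolved))
    stop("duplication partner not found in input set: ",
         paste(partner[unresolved], collapse = ", "))

  has <- which(!is.na(partner))
  pairs <- list(); dangling <- character(0)
  seen <- character(0)
  for (i in has) {
    a <- id[i]; b <- partner[i]
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% seen) next
    back <- partner[match(b, id)]
    if (!is.na(back) && back == a) {
      pairs[[length(pairs) + 1L]] <- sort(c(a, b))
      seen <- c(seen, key)
    } else {
      dangling <- c(dangling, a)
    }
  }
  out <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    df <- data.frame(id1 = m[, 1], id2 = m[, 2], stringsAsFactors = FALSE)
    df[order(df$id1, df$id2), , drop = FALSE]
  } else {
    data.frame(id1 = character(0), id2 = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "dangling") <- dangling
  out
}
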