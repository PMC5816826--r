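#' Load the packaged in-text fixtures
#'
#' Loads and validates the fixtures shipped with the package: the 22-row
#' MiSSP candidate table, the five secretome class counts, the 22 x 18
#' presence-absence statement matrix (16 isolates plus the outgroups
#' *Glonium stellatum* and *Lepidopterella palustris*) and the synthetic
#' isolate metadata. Structural checksums (row/column counts, class-count
#' total) are verified and a mismatch is an error.
#'
#' @return A list with `table1` (data.frame), `class_counts` (named integer
#'   vector over the five classes), `presence` (a `pav_matrix`-style list
#'   with `calls` and `is_outgroup`) and `strain_metadata` (data.frame).
#' @export
#' @examples
#' fx <- load_fixtures()
#' nrow(fx$table1)
load_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "misspR",
                                  mustWork = TRUE)
  table1 <- utils::read.delim(path("missp_table1.tsv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(protein_id = "character",
                                             duplication_partner = "character"))
  if (nrow(table1) != 22)
    stop("fixture checksum mismatch: candidate table must have 22 rows")
  need <- c("protein_id", "size_aa", "sp_length", "cysteine_pct",
            "in_dothideomycetes", "lfc_semisterile_pine",
            "duplication_partner")
  if (!all(need %in% names(table1)))
    stop("fixture checksum mismatch: candidate table columns")

  cc <- utils::read.delim(path("secretome_class_counts.tsv"),
                          stringsAsFactors = FALSE)
  if (!identical(sort(cc$sp_class), sort(sp_class_levels())) ||
      nrow(cc) != 5)
    stop("fixture checksum mismatch: class counts must cover 5 classes")
  class_counts <- stats::setNames(as.integer(cc$count), cc$sp_class)
  class_counts <- class_counts[sp_class_levels()]

  pm <- utils::read.delim(path("missp_presence_statements.tsv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character"))
  calls <- as.matrix(pm[, -1])
  rownames(calls) <- pm$gene_id
  storage.mode(calls) <- "integer"
  if (nrow(calls) != 22 || ncol(calls) != 18 ||
      !all(calls %in% c(0L, 1L)))
    stop("fixture checksum mismatch: presence matrix must be 22 x 18 binary")
  outg <- c("G_stellatum", "L_palustris")
  presence <- structure(list(
    calls = calls,
    is_outgroup = stats::setNames(colnames(calls) %in% outg,
                                  colnames(calls)),
    evidence = NULL), class = "pav_matrix")

  meta <- utils::read.delim(path("strain_metadata_synthetic.tsv"),
                            stringsAsFactors = FALSE)
  if (nrow(meta) != 16 ||
      !all(c("strain_id", "clade", "country", "forest_type") %in%
             names(meta)))
    stop("fixture checksum mismatch: strain metadata")

  list(table1 = table1, class_counts = class_counts,
       presence = presence, strain_metadata = meta)
}

#' Summary statistics of the packaged MiSSP candidate table
#'
#' Recomputes the headline quantities of the candidate table: number of
#' candidates, protein size range, maximum cysteine percentage, number of
#' candidates absent from other Dothideomycetes, and the number of
#' reciprocal duplication pairs (via [duplication_pairs()]).
#'
#' @param table1 The `table1` element of [load_fixtures()].
#' @return A named list of numbers.
#' @export
table1_stats <- function(table1) {
  pairs <- duplication_pairs(data.frame(
    protein_id = table1$protein_id,
    duplication_partner = table1$duplication_partner,
    stringsAsFactors = FALSE))
  list(
    n_candidates = nrow(table1),
    size_min_aa = min(table1$size_aa),
    size_max_aa = max(table1$size_aa),
    max_cysteine_pct = max(table1$cysteine_pct),
    n_dothideomycete_specific = sum(table1$in_dothideomycetes == "No"),
    n_duplication_pairs = nrow(pairs)
  )
}
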