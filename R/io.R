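#' Read gene models from a GFF3 file
#'
#' Imports a GFF3 annotation and returns its `gene` features as a
#' data.frame of 1-based inclusive coordinates, taking the `ID` attribute
#' as the gene id.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) stop("no 'gene' features in ", path)
  data.frame(
    gene_id = as.character(gr$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write gene models to a GFF3 file
#'
#' @param genes A data.frame with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$source <- "misspR"
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a hit table in 12-column tabular format (no header)
#'
#' @param hits A data.frame with the canonical 12 hit columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
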