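# small in-code builders shared across tests

toy_genes <- function() {
  data.frame(
    gene_id = c("a", "b", "c"),
    contig = "tig1",
    start = c(101, 501, 2001),
    end = c(200, 700, 2100),
    strand = "+",
    stringsAsFactors = FALSE
  )
}

toy_hits <- function(qstart, qend, evalue = 1e-50, len = NULL, id = "g1") {
  n <- length(qstart)
  data.frame(
    qseqid = rep(id, n), sseqid = "ctg", pident = 99,
    length = if (is.null(len)) qend - qstart + 1 else len,
    mismatch = 0L, gapopen = 0L,
    qstart = qstart, qend = qend, sstart = qstart, send = qend,
    evalue = rep_len(evalue, n), bitscore = 100,
    stringsAsFactors = FALSE
  )
}

# independent BH oracle: literal step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m))
    q[i] <- min(sorted[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# independent hypergeometric upper-tail oracle by term enumeration
hyper_tail_oracle <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# independent PERMANOVA pseudo-F from first principles (explicit loops)
permanova_f_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  ss_t <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng < 2) next
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
    ss_w <- ss_w + s / ng
  }
  a <- length(unique(groups))
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

tempfile_empty_file <- function() {
  f <- tempfile(fileext = ".tsv")
  file.create(f)
  f
}

random_binary_matrix <- function(n_genes, n_strains, p = 0.6) {
  matrix(as.integer(stats::runif(n_genes * n_strains) < p),
         n_genes, n_strains,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_strains))))
}
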