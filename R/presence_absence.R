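#' Read a 12-column tabular hit file
#'
#' Parses the standard 12-column tabular alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bit score). Query coordinates are normalized so
#' `qstart <= qend`.
#'
#' @param path Path to a tab-separated hit file without header.
#' @return A data.frame with the canonical column names.
#' @export
read_hit_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0)
    return(stats::setNames(
      data.frame(character(0), character(0), numeric(0), integer(0),
                 integer(0), integer(0), integer(0), integer(0), integer(0),
                 integer(0), numeric(0), numeric(0)), cols))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12)
    stop("hit table must have 12 columns, found ", ncol(df), ": ", path)
  names(df) <- cols
  flip <- df$qstart > df$qend
  if (any(flip)) {
    tmp <- df$qstart[flip]
    df$qstart[flip] <- df$qend[flip]
    df$qend[flip] <- tmp
  }
  df
}

#' Best hit by the lowest-E-value / greatest-HSP-length rule
#'
#' Selects the hit with the minimal e-value; ties are broken by the maximal
#' alignment length, remaining ties by input order (stable).
#'
#' @param hits A data.frame of hit records (possibly empty).
#' @return A single-row data.frame, or `NULL` for an empty input.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  ord <- order(hits$evalue, -hits$length)
  hits[ord[1], , drop = FALSE]
}

#' Fraction of a gene covered by merged hit intervals
#'
#' Merges the query intervals `[qstart, qend]` of all hits and reports the
#' union length divided by the gene length. Intervals extending outside
#' `[1, gene_length]` are clipped with a warning.
#'
#' @param gene_length Gene length in bp (> 0).
#' @param hits A data.frame of hit records (possibly empty).
#' @return Covered fraction in [0, 1].
#' @export
covered_fraction <- function(gene_length, hits) {
  stopifnot(gene_length > 0)
  if (is.null(hits) || nrow(hits) == 0) return(0)
  s <- pmin(pmax(hits$qstart, 1), gene_length)
  e <- pmin(pmax(hits$qend, 1), gene_length)
  if (any(hits$qstart < 1 | hits$qend > gene_length))
    warning("hit interval(s) outside [1, gene_length]; clipped")
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]
  total <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e + 1) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  total <- total + (cur_e - cur_s + 1)
  total / gene_length
}

#' Presence/absence call for one gene in one strain
#'
#' A gene is called absent when the deletion (the uncovered complement of
#' the merged hit intervals) spans strictly more than the deletion fraction
#' of the gene (default > 90\%), i.e. covered fraction < 0.10; otherwise
#' present. Evidence from the best hit is retained.
#'
#' @param gene_length Gene length in bp.
#' @param hits Hit records for this gene x strain (possibly empty).
#' @param thresholds A [missp_thresholds()] object or `NULL`.
#'
#' @return A list with `present` (logical), `covered`, `best_evalue`,
#'   `best_hsp_length`.
#' @export
call_presence <- function(gene_length, hits, thresholds = NULL) {
  th <- .as_thresholds(thresholds)
  cov <- covered_fraction(gene_length, hits)
  bh <- best_hit(hits)
  list(
    present = !((1 - cov) > th$absence_deletion_frac),
    covered = cov,
    best_evalue = if (is.null(bh)) NA_real_ else bh$evalue,
    best_hsp_length = if (is.null(bh)) NA_integer_ else bh$length
  )
}

#' Build a genes x strains presence-absence matrix from hit tables
#'
#' @param hit_tables Named list of hit-table data.frames, one per strain or
#'   outgroup (names become column names).
#' @param gene_lengths Named numeric vector of gene lengths in bp; its names
#'   define the gene rows.
#' @param outgroups Character vector of column names to flag as outgroups.
#' @param thresholds A [missp_thresholds()] object or `NULL`.
#'
#' @return A list of class `"pav_matrix"` with `calls` (0/1 integer matrix,
#'   genes x columns), `is_outgroup` (named logical), and `evidence`
#'   (long data.frame with per-call covered fraction and best-hit fields).
#' @export
build_pav_matrix <- function(hit_tables, gene_lengths, outgroups = character(0),
                             thresholds = NULL) {
  th <- .as_thresholds(thresholds)
  stopifnot(is.list(hit_tables), !is.null(names(hit_tables)),
            !is.null(names(gene_lengths)))
  if (!all(outgroups %in% names(hit_tables)))
    stop("outgroup name(s) absent from hit tables: ",
         paste(setdiff(outgroups, names(hit_tables)), collapse = ", "))
  genes <- names(gene_lengths)
  cols <- names(hit_tables)
  calls <- matrix(0L, length(genes), length(cols),
                  dimnames = list(genes, cols))
  ev <- list()
  for (cn in cols) {
    tab <- hit_tables[[cn]]
    split_hits <- if (nrow(tab)) split(tab, tab$qseqid) else list()
    for (g in genes) {
      res <- call_presence(gene_lengths[[g]], split_hits[[g]], th)
      calls[g, cn] <- as.integer(res$present)
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = g, column = cn, present = res$present,
        covered = res$covered, best_evalue = res$best_evalue,
        best_hsp_length = res$best_hsp_length, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    calls = calls,
    is_outgroup = stats::setNames(cols %in% outgroups, cols),
    evidence = do.call(rbind, ev)
  ), class = "pav_matrix")
}

#' Jaccard distances between strain presence profiles
#'
#' `d(x, y) = 1 - |x AND y| / |x OR y|` over gene rows. A pair of columns
#' with an empty union (both all-absent) is assigned distance 0: two
#' strains missing every gene are indistinguishable on this data.
#'
#' @param calls Binary matrix, genes x strains (a `pav_matrix$calls`, with
#'   outgroup columns removed by the caller if desired).
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
jaccard_distances <- function(calls) {
  calls <- as.matrix(calls)
  if (ncol(calls) < 2) stop("need at least 2 columns")
  if (!all(calls %in% c(0, 1))) stop("calls must be binary")
  inter <- crossprod(calls)
  tot <- colSums(calls)
  uni <- outer(tot, tot, "+") - inter
  d <- 1 - inter / uni
  empty <- uni == 0
  if (any(empty[upper.tri(empty)]))
    message("column pair(s) with empty union assigned distance 0")
  d[empty] <- 0
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centers `-D^2/2` and eigendecomposes the result. Axes with
#' eigenvalues above the tolerance are kept, scaled by the square root of
#' their eigenvalue; negative eigenvalues are reported and their axes
#' dropped (no Lingoes/Cailliez correction).
#'
#' @param d Square symmetric distance matrix with zero diagonal.
#' @param eig_tol Positive-eigenvalue tolerance (default `1e-10`).
#'
#' @return A list of class `"pco"` with `eigenvalues` (all, descending),
#'   `points` (samples x retained axes), `prop_var` (share of the positive
#'   eigenvalue total per retained axis) and `negative_eigenvalues`.
#' @export
pco <- function(d, eig_tol = 1e-10) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix asymmetric beyond 1e-8")
  n <- nrow(d)
  d2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  keep <- e$values > eig_tol
  pts <- if (any(keep))
    e$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(e$values[keep]), sum(keep)) else
    matrix(0, n, 0)
  rownames(pts) <- rownames(d)
  pos_sum <- sum(e$values[e$values > eig_tol])
  structure(list(
    eigenvalues = e$values,
    points = pts,
    prop_var = if (pos_sum > 0) e$values[keep] / pos_sum else numeric(0),
    negative_eigenvalues = e$values[e$values < -eig_tol]
  ), class = "pco")
}

#' One-way PERMANOVA on a distance matrix
#'
#' Computes the pseudo-F statistic of Anderson's permutational multivariate
#' ANOVA for a single factor: `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, and
#' `F = ((SS_total - SS_within)/(a-1)) / (SS_within/(N-a))`. The p-value
#' comes from unrestricted permutation of the factor labels: every distinct
#' assignment is enumerated when there are at most `exhaustive_limit` of
#' them, otherwise `n_perm` random permutations are drawn and the
#' `(1 + b) / (1 + n_perm)` estimator is used.
#'
#' @param d Square symmetric distance matrix.
#' @param groups Factor (or coercible) of group labels, one per sample;
#'   at least 2 levels, each non-empty, N >= 4.
#' @param n_perm Number of random permutations (ignored when exhaustive).
#' @param seed Optional integer seed for the permutation RNG.
#' @param exhaustive_limit Enumerate all distinct assignments when their
#'   count does not exceed this.
#'
#' @return A list of class `"permanova"` with `factor_name`, `F`, `df`
#'   (between, within), `p`, `n_perm`, `method` (`"exhaustive"` or
#'   `"sampled"`) and `seed`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL,
                      exhaustive_limit = 10000) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stop("PERMANOVA needs at least 4 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix asymmetric")
  groups <- factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  tab <- table(groups)
  a <- length(tab)
  if (a < 2) stop("factor needs at least 2 levels with members")
  if (any(tab == n)) stop("a level contains all samples; no residual df")
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  f_stat <- function(lab) {
    ss_w <- 0
    for (lv in levels(groups)) {
      m <- lab == lv
      ng <- sum(m)
      if (ng > 1) ss_w <- ss_w + sum(d2[m, m]) / (2 * ng)
    }
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_stat(groups)
  n_distinct <- exp(lfactorial(n) - sum(lfactorial(tab)))
  eps <- 1e-12
  if (n_distinct <= exhaustive_limit) {
    perms <- .multiset_permutations(as.character(groups))
    fs <- apply(perms, 1, f_stat)
    p <- mean(fs >= f_obs - eps)
    method <- "exhaustive"
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    b <- 0L
    for (i in seq_len(n_perm)) {
      if (f_stat(sample(groups)) >= f_obs - eps) b <- b + 1L
    }
    p <- (1 + b) / (1 + n_perm)
    method <- "sampled"
    n_used <- n_perm
  }
  structure(list(
    factor_name = deparse(substitute(groups)),
    F = f_obs, df = c(between = a - 1, within = n - a),
    p = p, n_perm = n_used, method = method, seed = seed
  ), class = "permanova")
}

# all distinct permutations of a label multiset, one per row
.multiset_permutations <- function(labels) {
  recurse <- function(remaining) {
    if (length(remaining) == 1L) return(matrix(remaining, 1, 1))
    out <- list()
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      sub <- recurse(rest)
      out[[length(out) + 1L]] <- cbind(u, sub, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  recurse(labels)
}

#' Gene conservation classes against strains and outgroups
#'
#' Classifies each gene by its presence pattern: `core` (present in every
#' strain and every outgroup), `genus_conserved` (present in every strain
#' but missing in at least one outgroup) and `dispersed` (missing in at
#' least one strain). Without an outgroup column the genus-conserved class
#' is undefined and a two-class fallback (`conserved`/`dispersed`) is
#' returned with a message.
#'
#' @param pav A `"pav_matrix"` from [build_pav_matrix()], or a list with
#'   `calls` and `is_outgroup`.
#' @return A list with `classes` (named factor per gene) and `counts`.
#' @export
conservation_classes <- function(pav) {
  calls <- pav$calls
  og <- pav$is_outgroup
  stopifnot(!is.null(calls), !is.null(og))
  strains <- calls[, !og, drop = FALSE]
  outs <- calls[, og, drop = FALSE]
  all_strains <- rowSums(strains) == ncol(strains)
  if (ncol(outs) == 0) {
    message("no outgroup column; genus_conserved undefined, ",
            "two-class fallback used")
    cls <- ifelse(all_strains, "conserved", "dispersed")
    cls <- factor(cls, levels = c("conserved", "dispersed"))
  } else {
    all_outs <- rowSums(outs) == ncol(outs)
    cls <- ifelse(!all_strains, "dispersed",
                  ifelse(all_outs, "core", "genus_conserved"))
    cls <- factor(cls, levels = c("core", "genus_conserved", "dispersed"))
  }
  names(cls) <- rownames(calls)
  list(classes = cls, counts = table(cls))
}
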