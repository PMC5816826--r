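#' Configuration for the synthetic study generator
#'
#' Bundles and validates every parameter of the synthetic data emulating the
#' study design: a genome whose intergenic gaps are a two-component
#' log-normal mixture (gene-dense vs repeat-rich blocks), a secretome with
#' the five secreted-protein classes in the published genome proportions,
#' negative-binomial counts with class-structured planted fold changes
#' between free-living mycelium and two ectomycorrhiza conditions, and a
#' strain panel with clade-structured gene deletions expressed as
#' 12-column hit tables.
#'
#' @param seed Integer master seed; each generator derives its own stream
#'   by a fixed offset, so partial runs stay reproducible.
#' @param n_contigs,n_genes Genome size in contigs and genes.
#' @param frac_gsr Fraction of genes planted in repeat-rich blocks.
#' @param intergenic_dense_mean,intergenic_sparse_mean Median intergenic
#'   gap (bp) of the dense and sparse mixture components (log-normal
#'   location parameters on the natural scale).
#' @param intergenic_sdlog Log-normal shape parameter shared by both
#'   components.
#' @param gene_len_range Uniform gene-length range in bp.
#' @param n_secreted Number of secreted proteins.
#' @param class_proportions Named 5-vector of class proportions over
#'   SSP, CAZyme, lipase, protease, otherSP; must sum to 1 within 1e-9.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param n_replicates Replicates per condition.
#' @param planted_lfc Log2 fold-change magnitude planted in induced genes.
#' @param de_fraction Fraction of genes per class planted as induced in the
#'   ectomycorrhiza contrasts.
#' @param n_strains,n_outgroups Panel size.
#' @param deletion_rate Per-gene per-clade deletion probability; either a
#'   single rate or a named vector with one rate per clade.
#' @param outgroup_deletion_rate Per-gene per-outgroup deletion probability.
#' @param strain_noise_rate Per-gene per-strain probability of flipping the
#'   clade-level call (strain-private gain/loss).
#' @param clade_assignment Character vector mapping each strain to a clade;
#'   recycled defaults split strains over clades 5a/5b/6.
#' @param max_contig_bp Optional capacity per contig; exceeding it is a
#'   sizing error naming the contig.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 10L,
                       n_genes = 2000L,
                       frac_gsr = 0.30,
                       intergenic_dense_mean = 200,
                       intergenic_sparse_mean = 20000,
                       intergenic_sdlog = 0.5,
                       gene_len_range = c(300, 3000),
                       n_secreted = 300L,
                       class_proportions = c(SSP = 227, CAZyme = 120,
                                             lipase = 13, protease = 27,
                                             otherSP = 208) / 595,
                       nb_dispersion = 0.1,
                       n_replicates = 3L,
                       planted_lfc = 2,
                       de_fraction = 0.1,
                       n_strains = 16L,
                       n_outgroups = 2L,
                       deletion_rate = 0.15,
                       outgroup_deletion_rate = 0.30,
                       strain_noise_rate = 0.02,
                       clade_assignment = NULL,
                       max_contig_bp = Inf) {
  if (is.null(clade_assignment))
    clade_assignment <- rep(c("5a", "5b", "6"),
                            times = .split_sizes(n_strains, 3))
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              n_genes = as.integer(n_genes), frac_gsr = frac_gsr,
              intergenic_dense_mean = intergenic_dense_mean,
              intergenic_sparse_mean = intergenic_sparse_mean,
              intergenic_sdlog = intergenic_sdlog,
              gene_len_range = gene_len_range,
              n_secreted = as.integer(n_secreted),
              class_proportions = class_proportions,
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              planted_lfc = planted_lfc, de_fraction = de_fraction,
              n_strains = as.integer(n_strains),
              n_outgroups = as.integer(n_outgroups),
              deletion_rate = deletion_rate,
              outgroup_deletion_rate = outgroup_deletion_rate,
              strain_noise_rate = strain_noise_rate,
              clade_assignment = clade_assignment,
              max_contig_bp = max_contig_bp)
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.split_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

.validate_sim_config <- function(cfg) {
  counts <- c("n_contigs", "n_genes", "n_secreted", "n_replicates",
              "n_strains", "n_outgroups")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop("'", nm, "' must be a positive count")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1 within 1e-9")
  if (!setequal(names(cfg$class_proportions), sp_class_levels()))
    stop("class_proportions must be named over the five SP classes")
  for (nm in c("deletion_rate", "outgroup_deletion_rate",
               "strain_noise_rate", "frac_gsr", "de_fraction"))
    if (any(cfg[[nm]] < 0) || any(cfg[[nm]] > 1))
      stop("'", nm, "' must lie in [0, 1]")
  if (length(cfg$deletion_rate) > 1 &&
      !all(unique(cfg$clade_assignment) %in% names(cfg$deletion_rate)))
    stop("per-clade 'deletion_rate' must name every clade")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$n_secreted > cfg$n_genes)
    stop("n_secreted cannot exceed n_genes")
  if (length(cfg$clade_assignment) != cfg$n_strains)
    stop("clade_assignment must name a clade for every strain")
  invisible(cfg)
}

# fixed sub-seed offsets: one RNG stream per generator
.SEED_GENOME <- 101L
.SEED_SECRETOME <- 202L
.SEED_COUNTS <- 303L
.SEED_PANEL <- 404L

#' Simulate a bipartite genome annotation
#'
#' Lays non-overlapping genes along contigs. Each contig carries one
#' repeat-rich block (at its 3' end) holding approximately `frac_gsr` of
#' its genes; gaps between two repeat-block genes are drawn from the sparse
#' log-normal component, all other gaps from the dense component. Repeat
#' blocks hold at least two genes so that every planted-GSR gene exposes at
#' least one sparse flank. The planted compartment label of every gene is
#' exported as truth.
#'
#' @param config A [sim_config()] object.
#' @return A list with `genes` (data.frame: gene_id, contig, start, end,
#'   strand, length_bp) and `truth_region` (data.frame: gene_id, region).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .SEED_GENOME)
  per_contig <- .split_sizes(config$n_genes, config$n_contigs)
  rows <- list()
  gid <- 0L
  for (ci in seq_len(config$n_contigs)) {
    nc <- per_contig[ci]
    n_gsr <- round(config$frac_gsr * nc)
    if (n_gsr == 1L && nc >= 2L) n_gsr <- 2L
    labels <- c(rep("GDR", nc - n_gsr), rep("GSR", n_gsr))
    lens <- round(stats::runif(nc, config$gene_len_range[1],
                               config$gene_len_range[2]))
    strands <- sample(c("+", "-"), nc, replace = TRUE)
    # gap before gene i: sparse only between two repeat-block genes
    gaps <- numeric(nc)
    gaps[1] <- round(stats::rlnorm(1, log(config$intergenic_dense_mean),
                                   config$intergenic_sdlog))
    if (nc > 1) {
      sparse_gap <- labels[-nc] == "GSR" & labels[-1] == "GSR"
      mu <- ifelse(sparse_gap, log(config$intergenic_sparse_mean),
                   log(config$intergenic_dense_mean))
      gaps[-1] <- round(stats::rlnorm(nc - 1, mu, config$intergenic_sdlog))
    }
    start <- cumsum(gaps + c(0, lens[-nc])) + 1
    end <- start + lens - 1
    if (end[nc] > config$max_contig_bp)
      stop("contig capacity exceeded on contig_", ci, ": needs ",
           end[nc], " bp, capacity ", config$max_contig_bp, " bp")
    rows[[ci]] <- data.frame(
      gene_id = sprintf("gene_%05d", gid + seq_len(nc)),
      contig = sprintf("contig_%02d", ci),
      start = start, end = end, strand = strands,
      length_bp = lens, region = labels,
      stringsAsFactors = FALSE)
    gid <- gid + nc
  }
  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  list(
    genes = all[, c("gene_id", "contig", "start", "end", "strand",
                    "length_bp")],
    truth_region = data.frame(gene_id = all$gene_id, region = all$region,
                              stringsAsFactors = FALSE)
  )
}

#' Simulate a secretome annotation over simulated genes
#'
#' Marks `n_secreted` genes as secreted and assigns the five
#' secreted-protein classes in the configured proportions. Protein lengths
#' are uniform on 50-500 aa with SSPs forced below 300 aa; CAZyme, lipase
#' and protease flags are set consistently with the class so that
#' [classify_secretome()] recovers the planted class exactly.
#'
#' @param config A [sim_config()] object.
#' @param genes The `genes` data.frame from [simulate_genome()].
#' @return A list with `proteins` (classify_secretome()-ready data.frame)
#'   and `truth_class` (data.frame: protein_id, sp_class).
#' @export
simulate_secretome <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .SEED_SECRETOME)
  ids <- sort(sample(genes$gene_id, config$n_secreted))
  n <- length(ids)
  classes <- sample(sp_class_levels(), n, replace = TRUE,
                    prob = config$class_proportions)
  len <- round(stats::runif(n, 50, 500))
  is_ssp <- classes == "SSP"
  len[is_ssp] <- round(stats::runif(sum(is_ssp), 50, 299))
  len[!is_ssp & classes == "otherSP"] <-
    round(stats::runif(sum(!is_ssp & classes == "otherSP"), 300, 500))
  proteins <- data.frame(
    protein_id = ids,
    length_aa = len,
    has_signal_peptide = TRUE,
    sp_length_aa = round(stats::runif(n, 15, 25)),
    cazy_families = ifelse(classes == "CAZyme", "GH5", ""),
    is_lipase = classes == "lipase",
    is_protease = classes == "protease",
    stringsAsFactors = FALSE)
  list(proteins = proteins,
       truth_class = data.frame(protein_id = ids, sp_class = classes,
                                stringsAsFactors = FALSE))
}

#' Simulate negative-binomial counts with planted fold changes
#'
#' Draws counts for three conditions (free-living mycelium `FLM` and two
#' ectomycorrhiza conditions `ECM_pine`, `ECM_poplar`) with `n_replicates`
#' each. A `de_fraction` of genes per secretome class (and of the
#' unclassified background) is planted as induced by `planted_lfc` log2
#' units in both ECM conditions; the truth table records per-contrast DE
#' status.
#'
#' @param config A [sim_config()] object.
#' @param genes The `genes` data.frame from [simulate_genome()].
#' @param classes Optional data.frame (`protein_id`, `sp_class`) from
#'   [simulate_secretome()]; used to stratify the planted genes by class.
#' @return A list with `counts` (integer matrix), `conditions` (per-sample
#'   labels), `lengths` (named vector) and `truth_de` (data.frame:
#'   gene_id, contrast, is_de, true_lfc).
#' @export
simulate_counts <- function(config, genes, classes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  set.seed(config$seed + .SEED_COUNTS)
  gids <- genes$gene_id
  ng <- length(gids)
  base_mu <- stats::rlnorm(ng, log(100), 1)
  cls <- stats::setNames(rep("background", ng), gids)
  if (!is.null(classes))
    cls[classes$protein_id] <- as.character(classes$sp_class)
  de_flag <- logical(ng)
  for (cc in unique(cls)) {
    idx <- which(cls == cc)
    n_de <- round(config$de_fraction * length(idx))
    if (n_de > 0) de_flag[sample(idx, n_de)] <- TRUE
  }
  true_lfc <- ifelse(de_flag, config$planted_lfc, 0)
  conds <- c("FLM", "ECM_pine", "ECM_poplar")
  cond_vec <- rep(conds, each = config$n_replicates)
  sample_ids <- paste(cond_vec, rep(seq_len(config$n_replicates),
                                    times = length(conds)), sep = "_r")
  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, ng, length(sample_ids),
                   dimnames = list(gids, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- if (cond_vec[j] == "FLM") base_mu else base_mu * 2^true_lfc
    counts[, j] <- stats::rnbinom(ng, mu = mu, size = size)
  }
  truth <- do.call(rbind, lapply(c("ECM_pine", "ECM_poplar"), function(cc)
    data.frame(gene_id = gids, contrast = paste(cc, "vs FLM"),
               is_de = de_flag, true_lfc = true_lfc,
               stringsAsFactors = FALSE)))
  list(counts = counts, conditions = cond_vec,
       lengths = stats::setNames(genes$length_bp, gids), truth_de = truth)
}

#' Simulate a strain panel with clade-structured deletions
#'
#' Deletions are drawn at the clade level (each gene deleted in an entire
#' clade with probability `deletion_rate`), then perturbed per strain with
#' probability `strain_noise_rate`; outgroups lose genes independently at
#' `outgroup_deletion_rate`. Retained genes receive one hit spanning the
#' whole gene at high identity and low e-value; deleted genes receive
#' either no hit or a short residual hit covering well under 10\% of the
#' gene, so coverage-based presence calls can recover the truth exactly.
#'
#' @param config A [sim_config()] object.
#' @param genes A data.frame with `gene_id` and `length_bp` (subset the
#'   genes of interest, e.g. MiSSP candidates).
#' @return A list with `hit_tables` (named list of 12-column data.frames,
#'   strains then outgroups), `truth_deleted` (logical matrix genes x
#'   columns), `metadata` (strain_id, clade, country, forest_type) and
#'   `outgroups` (column names flagged as outgroups).
#' @export
simulate_strain_panel <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"),
            all(c("gene_id", "length_bp") %in% names(genes)))
  set.seed(config$seed + .SEED_PANEL)
  gids <- genes$gene_id
  lens <- stats::setNames(genes$length_bp, gids)
  strains <- sprintf("strain_%02d", seq_len(config$n_strains))
  outs <- if (config$n_outgroups > 0)
    sprintf("outgroup_%d", seq_len(config$n_outgroups)) else character(0)
  clades <- config$clade_assignment
  deleted <- matrix(FALSE, length(gids), length(strains) + length(outs),
                    dimnames = list(gids, c(strains, outs)))
  rate_of <- function(cl) {
    if (length(config$deletion_rate) > 1) config$deletion_rate[[cl]]
    else config$deletion_rate
  }
  for (cl in unique(clades)) {
    clade_del <- stats::runif(length(gids)) < rate_of(cl)
    for (s in strains[clades == cl]) {
      flip <- stats::runif(length(gids)) < config$strain_noise_rate
      deleted[, s] <- xor(clade_del, flip)
    }
  }
  for (o in outs)
    deleted[, o] <- stats::runif(length(gids)) < config$outgroup_deletion_rate

  countries <- c("Switzerland", "France", "Poland", "Finland")
  forests <- c("Pa", "Ps", "Fs", "Mx")
  metadata <- data.frame(
    strain_id = strains,
    clade = clades,
    country = sample(countries, length(strains), replace = TRUE),
    forest_type = sample(forests, length(strains), replace = TRUE),
    stringsAsFactors = FALSE)

  hit_tables <- lapply(colnames(deleted), function(cn) {
    rows <- list()
    for (g in gids) {
      len <- lens[[g]]
      if (!deleted[g, cn]) {
        rows[[length(rows) + 1L]] <- data.frame(
          qseqid = g, sseqid = paste0(cn, "_ctg1"),
          pident = round(stats::runif(1, 96, 100), 2), length = len,
          mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
          sstart = 1000L, send = 1000L + len - 1L,
          evalue = 1e-180, bitscore = round(1.8 * len, 1),
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < 0.5) {
        span <- max(1L, as.integer(floor(0.08 * len)))
        rows[[length(rows) + 1L]] <- data.frame(
          qseqid = g, sseqid = paste0(cn, "_ctg9"),
          pident = round(stats::runif(1, 80, 95), 2), length = span,
          mismatch = 2L, gapopen = 1L, qstart = 1L, qend = span,
          sstart = 5000L, send = 5000L + span - 1L,
          evalue = 1e-5, bitscore = round(1.2 * span, 1),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      read_hit_table(tempfile_empty())
  })
  names(hit_tables) <- colnames(deleted)
  list(hit_tables = hit_tables, truth_deleted = deleted,
       metadata = metadata, outgroups = outs)
}

tempfile_empty <- function() {
  f <- tempfile(fileext = ".tsv")
  file.create(f)
  f
}
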