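#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the stages end-to-end from one configuration: synthetic
#' data generation, secretome classification, expression calls
#' (normalization, stand-in DE test, regulation calls, class enrichment),
#' genome-architecture classification (FIRs, GDR/GSR, compartment
#' composition) and presence-absence analysis (coverage calls, Jaccard,
#' PCO, PERMANOVA, conservation classes), then writes stage outputs under
#' `outdir` and returns a consolidated report. Identical configuration and
#' seed give identical outputs.
#'
#' @param config Either a list or the path to a YAML file. Recognized keys:
#'   `seed` (integer), `outdir` (directory; created), `stages` (character
#'   subset of `c("simulate", "secretome", "expression", "architecture",
#'   "pav")`; later stages require the earlier ones), `sim` (named list of
#'   [sim_config()] overrides) and `thresholds` (named list of
#'   [missp_thresholds()] overrides).
#'
#' @return A list of class `"missp_report"` with per-stage summaries and
#'   run metadata; stages that were not run are `NULL`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% tempfile("missp_run_")
  all_stages <- c("simulate", "secretome", "expression", "architecture",
                  "pav")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- do.call(missp_thresholds, config$thresholds %||% list())
  scfg <- do.call(sim_config, c(list(seed = seed), config$sim %||% list()))

  report <- list(seed = seed, outdir = outdir, stages = stages,
                 simulate = NULL, secretome = NULL, expression = NULL,
                 architecture = NULL, pav = NULL)
  class(report) <- "missp_report"
  if (!length(stages)) return(report)
  run_stage <- function(name, fn) {
    message("[", name, "] running")
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genome <- NULL; secretome <- NULL; sec <- NULL; cnt <- NULL
  if ("simulate" %in% stages) {
    report$simulate <- run_stage("simulate", function() {
      genome <<- simulate_genome(scfg)
      sec <<- simulate_secretome(scfg, genome$genes)
      cnt <<- simulate_counts(scfg, genome$genes, sec$truth_class)
      write_genes_gff3(genome$genes, file.path(outdir, "genome.gff3"))
      write_tsv_file(genome$truth_region,
                     file.path(outdir, "truth_region.tsv"))
      write_tsv_file(data.frame(gene_id = rownames(cnt$counts),
                                cnt$counts, check.names = FALSE),
                     file.path(outdir, "counts.tsv"))
      list(n_genes = nrow(genome$genes),
           n_secreted = nrow(sec$proteins),
           n_samples = ncol(cnt$counts))
    })
  }
  if ("secretome" %in% stages) {
    if (is.null(sec)) stop("stage 'secretome' requires stage 'simulate'")
    report$secretome <- run_stage("secretome", function() {
      secretome <<- classify_secretome(sec$proteins, th)
      write_tsv_file(secretome, file.path(outdir, "secretome_catalog.tsv"))
      cls <- table(secretome$sp_class)
      list(class_counts = cls,
           agreement = mean(as.character(secretome$sp_class) ==
                              sec$truth_class$sp_class))
    })
  }
  de_calls <- NULL
  if ("expression" %in% stages) {
    if (is.null(cnt) || is.null(secretome))
      stop("stage 'expression' requires stages 'simulate' and 'secretome'")
    report$expression <- run_stage("expression", function() {
      fpkm <- compute_fpkm(cnt$counts, cnt$lengths)
      expressed <- call_expressed(fpkm, cnt$conditions, th)
      de <- simple_de_test(cnt$counts, cnt$conditions, "ECM_pine", "FLM")
      de_calls <<- call_regulation(de, th)
      enr <- class_enrichment(
        de_calls[de_calls$gene_id %in% secretome$protein_id, ],
        secretome)
      write_tsv_file(de_calls, file.path(outdir, "regulation_calls.tsv"))
      write_tsv_file(enr, file.path(outdir, "class_enrichment.tsv"))
      list(n_up = sum(de_calls$status == "up"),
           n_down = sum(de_calls$status == "down"),
           n_expressed_flm = sum(expressed[, "FLM"]))
    })
  }
  if ("architecture" %in% stages) {
    if (is.null(genome)) stop("stage 'architecture' requires 'simulate'")
    report$architecture <- run_stage("architecture", function() {
      firs <- classify_region(compute_firs(genome$genes), th)
      write_tsv_file(firs, file.path(outdir, "fir_records.tsv"))
      truth <- stats::setNames(genome$truth_region$region,
                               genome$truth_region$gene_id)
      assigned <- firs$region != "unassigned"
      agreement <- mean(as.character(firs$region[assigned]) ==
                          truth[firs$gene_id[assigned]])
      comp <- if (!is.null(secretome))
        region_composition(secretome, firs) else NULL
      if (!is.null(comp))
        write_tsv_file(comp, file.path(outdir, "region_composition.tsv"))
      list(n_gsr = sum(firs$region == "GSR"),
           n_gdr = sum(firs$region == "GDR"),
           truth_agreement = agreement)
    })
  }
  if ("pav" %in% stages) {
    if (is.null(genome) || is.null(sec))
      stop("stage 'pav' requires 'simulate'")
    report$pav <- run_stage("pav", function() {
      cand <- genome$genes[genome$genes$gene_id %in%
                             utils::head(sec$proteins$protein_id, 22), ]
      panel <- simulate_strain_panel(scfg, cand)
      pav <- build_pav_matrix(panel$hit_tables,
                              stats::setNames(cand$length_bp, cand$gene_id),
                              outgroups = panel$outgroups, thresholds = th)
      strains <- pav$calls[, !pav$is_outgroup, drop = FALSE]
      d <- jaccard_distances(strains)
      ord <- pco(d)
      perm <- permanova(d, panel$metadata$clade,
                        n_perm = min(th$n_permutations, 999),
                        seed = seed)
      cons <- conservation_classes(pav)
      write_tsv_file(data.frame(gene_id = rownames(pav$calls), pav$calls,
                                check.names = FALSE),
                     file.path(outdir, "pav_matrix.tsv"))
      jsonlite::write_json(
        list(factor = "clade", F = perm$F, df = as.list(perm$df),
             p = perm$p, n_perm = perm$n_perm, seed = seed),
        file.path(outdir, "permanova.json"), auto_unbox = TRUE,
        digits = NA)
      accuracy <- mean((pav$calls == 0) == panel$truth_deleted)
      list(deletion_call_accuracy = accuracy,
           permanova_clade_p = perm$p,
           pco_eigen1 = ord$eigenvalues[1],
           conservation = cons$counts)
    })
  }
  jsonlite::write_json(.report_summary(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

.report_summary <- function(report) {
  clean <- function(x) {
    if (is.null(x)) return(NULL)
    lapply(x, function(v) if (inherits(v, "table"))
      as.list(stats::setNames(as.integer(v), names(v))) else v)
  }
  list(seed = report$seed, stages = report$stages,
       simulate = clean(report$simulate),
       secretome = clean(report$secretome),
       expression = clean(report$expression),
       architecture = clean(report$architecture),
       pav = clean(report$pav))
}

#' @export
print.missp_report <- function(x, ...) {
  cat("misspR pipeline report (seed ", x$seed, ")\n", sep = "")
  for (st in c("simulate", "secretome", "expression", "architecture",
               "pav")) {
    if (is.null(x[[st]])) next
    cat("* ", st, ":\n", sep = "")
    s <- x[[st]]
    for (nm in names(s)) {
      v <- s[[nm]]
      if (inherits(v, "table"))
        v <- paste(names(v), as.integer(v), sep = "=", collapse = ", ")
      else v <- paste(signif(unlist(v), 4), collapse = ", ")
      cat("    ", nm, ": ", v, "\n", sep = "")
    }
  }
  invisible(x)
}
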