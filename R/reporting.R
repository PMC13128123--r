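# Config-driven pipeline stages and report generation.
#
# A single base seed expands deterministically (base + stage offset) so any
# stage can be replayed in isolation; every stage writes its artifacts plus
# a manifest (parameters, seeds, input hashes) into an append-only output
# directory.

.stage_offsets <- c(simulate = 0L, prepare = 0L, split = 100L,
                    permute = 200L, diversity = 300L, sweep = 400L,
                    mechanism = 500L, analyze = 600L, report = 0L)

.default_pipeline_config <- function() {
  list(mode = "synthetic",
       sim = list(),                     # simConfig() overrides
       model = list(),                   # modelConfigSynthetic() overrides
       meta = list(),                    # metaConfig() overrides
       permute = list(replicates = 3L),
       diversity = list(k_grid = c(10, 40, 120), modes = "mixed",
                        replicates = 3L),
       sweep = list(design = "partial_blind", n_runs = 150L),
       mechanism = list(mechanisms = NULL),
       paths = list())                   # real mode input tables
}

.read_pipeline_config <- function(config) {
  cfg <- .default_pipeline_config()
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(config)
  } else config
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(user[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
  }
  if (!cfg$mode %in% c("synthetic", "real"))
    stop("mode must be synthetic or real")
  if (cfg$mode == "real") {
    need <- c("response", "expression", "smiles", "annotations")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      stop("real mode config must name input paths: ",
           paste(miss, collapse = ", "))
    absent <- unlist(cfg$paths[need])[!file.exists(unlist(cfg$paths[need]))]
    if (length(absent))
      stop("input file does not exist: ", paste(absent, collapse = ", "))
  }
  cfg
}

.write_manifest <- function(outdir, stage, info) {
  jsonlite::write_json(info, file.path(outdir,
                                       sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
}

.load_inputs <- function(cfg, outdir, seed) {
  if (cfg$mode == "synthetic") {
    sim <- generatePanel(do.call(simConfig, c(cfg$sim, list(seed = seed))))
    sim
  } else {
    panel <- do.call(readResponseTable,
                     c(list(path = cfg$paths$response),
                       cfg$response %||% list()))
    smiles <- readSmilesTable(cfg$paths$smiles)
    drugs <- featurizeDrugs(smiles)
    expr <- readExpressionMatrix(cfg$paths$expression)
    genes <- cfg$paths$reference_genes
    cells <- if (!is.null(genes))
      intersectGeneFeatures(expr, readLines(genes))
    else CellFeatureSet(expr, encoding = "expression")
    ann <- readAnnotations(cfg$paths$annotations)
    keep <- panel@tuples$drug_id %in% drugIds(drugs) &
      panel@tuples$cell_id %in% cellIds(cells)
    if (!all(keep))
      message(sprintf("dropping %d tuples without features", sum(!keep)))
    list(panel = ResponsePanel(panel@tuples[keep, , drop = FALSE],
                               panel@metric),
         drugs = drugs, cells = cells, annotations = ann, truth = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run pipeline stages into an output directory
#'
#' Executes the requested stages in order.  Available stages: `simulate`
#' (synthetic mode: generate and write the panel), `prepare` (real mode:
#' read and featurize the input tables), `split` (write an example split
#' JSON), `permute` (permutation suite), `diversity` (cells-per-drug
#' sweep), `sweep` (composition sweep -> run records), `mechanism`
#' (isolated-vs-all comparisons), `analyze` (meta-regression, clustering,
#' relationship statistics), `report` (render `report.md`).  Each stage
#' writes a manifest with its parameters and seeds; rerunning with an
#' identical config and seed reproduces all numeric outputs exactly.
#'
#' @param config a config list or path to a YAML file; see
#'   `inst/extdata/pipeline-default.yaml` for the fully commented default.
#' @param stages character vector of stage names, run in the given order.
#' @param outdir output directory (created if needed).
#' @param seed global base seed; stage s uses `seed +` a fixed offset.
#' @return invisibly, a list of stage results.
#' @export
runPipeline <- function(config = list(),
                        stages = c("simulate", "permute", "sweep",
                                   "analyze", "report"),
                        outdir = "drpaudit_out", seed = 1L) {
  cfg <- .read_pipeline_config(config)
  unknown <- setdiff(stages, names(.stage_offsets))
  if (length(unknown)) stop("unknown stage: ", paste(unknown, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  model_cfg <- do.call(modelConfigSynthetic, cfg$model)
  meta_cfg <- do.call(metaConfig, cfg$meta)
  state <- list()
  results <- list()

  get_inputs <- function() {
    if (is.null(state$inputs))
      state$inputs <<- .load_inputs(cfg, outdir, seed)
    state$inputs
  }

  for (stage in stages) {
    s <- seed + .stage_offsets[[stage]]
    res <- switch(stage,
      simulate = , prepare = {
        inputs <- get_inputs()
        ddir <- file.path(outdir, "data")
        if (cfg$mode == "synthetic") writeSyntheticData(inputs, ddir)
        .write_manifest(outdir, stage,
                        list(stage = stage, seed = seed, mode = cfg$mode,
                             n_tuples = nTuples(inputs$panel),
                             n_drugs = length(drugIds(inputs$panel)),
                             n_cells = length(cellIds(inputs$panel))))
        inputs$panel
      },
      split = {
        inputs <- get_inputs()
        sp <- splitMixed(inputs$panel, seed = s)
        writeSplit(sp, file.path(outdir, "split_mixed.json"))
        .write_manifest(outdir, stage, list(stage = stage, seed = s,
                                            mode = "mixed"))
        sp
      },
      permute = {
        inputs <- get_inputs()
        tab <- do.call(runPermutationSuite,
                       c(list(panel = inputs$panel, drugs = inputs$drugs,
                              cells = inputs$cells, config = model_cfg,
                              seed = s), cfg$permute))
        write.csv(tab, file.path(outdir, "permutation.csv"),
                  row.names = FALSE)
        .write_manifest(outdir, stage,
                        c(list(stage = stage, seed = s), cfg$permute))
        tab
      },
      diversity = {
        inputs <- get_inputs()
        div <- do.call(runDiversitySweep,
                       c(list(panel = inputs$panel, drugs = inputs$drugs,
                              cells = inputs$cells, config = model_cfg,
                              annotations = inputs$annotations, seed = s),
                         cfg$diversity))
        write.csv(div$runs, file.path(outdir, "diversity_runs.csv"),
                  row.names = FALSE)
        write.csv(div$summary, file.path(outdir, "diversity_summary.csv"),
                  row.names = FALSE)
        .write_manifest(outdir, stage,
                        c(list(stage = stage, seed = s), cfg$diversity))
        div
      },
      sweep = {
        inputs <- get_inputs()
        rec <- do.call(runCompositionSweep,
                       c(list(panel = inputs$panel, drugs = inputs$drugs,
                              cells = inputs$cells, config = model_cfg,
                              base_seed = s), cfg$sweep))
        writeRunRecords(rec, file.path(outdir, "run_records.jsonl"))
        .write_manifest(outdir, stage,
                        c(list(stage = stage, base_seed = s,
                               n_failed = sum(vapply(rec, function(r)
                                 r$failed, logical(1)))), cfg$sweep))
        rec
      },
      mechanism = {
        inputs <- get_inputs()
        targets <- drugTargets(inputs$annotations)
        mechs <- cfg$mechanism$mechanisms %||%
          names(which(table(targets) >= 2))
        rows <- do.call(rbind, lapply(mechs, function(m)
          runMechanismSpecific(inputs$panel, inputs$drugs, inputs$cells,
                               inputs$annotations, m, config = model_cfg,
                               seed = s)))
        write.csv(rows, file.path(outdir, "mechanism.csv"),
                  row.names = FALSE)
        .write_manifest(outdir, stage, list(stage = stage, seed = s,
                                            mechanisms = mechs))
        rows
      },
      analyze = {
        inputs <- get_inputs()
        rec_path <- file.path(outdir, "run_records.jsonl")
        if (!file.exists(rec_path))
          stop("analyze requires the sweep stage artifact run_records.jsonl")
        rec <- readRunRecords(rec_path)
        design <- rec[[1L]]$design
        out <- list(design = design)
        if (design == "fixed_test") {
          gm <- fitGlobalMeta(rec, meta_cfg)
          write.csv(gm$oof, file.path(outdir, "global_meta_oof.csv"),
                    row.names = FALSE)
          write.csv(data.frame(drug_id = names(gm$coefficients),
                               coefficient = gm$coefficients),
                    file.path(outdir, "global_meta_coefficients.csv"),
                    row.names = FALSE)
          out$global <- gm
        } else {
          cm <- fitPerDrugMeta(rec, meta_cfg)
          v <- coefValues(cm)
          write.csv(cbind(data.frame(predictor = rownames(v)),
                          as.data.frame(v)),
                    file.path(outdir, "coefficient_matrix.csv"),
                    row.names = FALSE)
          cl <- clusterMatrix(cm)
          targets <- drugTargets(inputs$annotations)
          sbr <- selfBestRate(cm)
          stats <- list(
            self_best_rate = sbr$rate,
            self_best_exceptions = sbr$exceptions,
            one_to_one = as.list(oneToOne(cm)),
            many_to_one = as.list(manyToOne(cm)),
            class_to_class = classToClass(cm, targets),
            leaf_order = cl$order)
          jsonlite::write_json(stats,
                               file.path(outdir, "relationship_stats.json"),
                               auto_unbox = TRUE, digits = NA,
                               dataframe = "rows", na = "null")
          out$matrix <- cm
          out$cluster <- cl
          out$stats <- stats
        }
        .write_manifest(outdir, stage,
                        list(stage = stage, design = design,
                             meta = unclass(meta_cfg)))
        out
      },
      report = writeReport(outdir))
    results[[stage]] <- res
  }
  invisible(results)
}

.md_table <- function(df, digits = 3) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, digits = digits,
                                                format = "g") else x
  df[] <- lapply(df, fmt)
  paste(c(paste0("| ", paste(names(df), collapse = " | "), " |"),
          paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
          vapply(seq_len(nrow(df)), function(i)
            paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |"),
            character(1))),
        collapse = "\n")
}

#' Render a markdown report from pipeline artifacts
#'
#' Collects whatever stage artifacts exist in `outdir` into a single
#' `report.md` (plus heatmap/scatter figures when ggplot2/pheatmap are
#' available), naming for every table the artifact file it was computed
#' from.  All statistics are sourced from uncapped values; only the heatmap
#' color scale is clipped to \[-1, 1\], and is annotated as such.  The report
#' regenerates byte-identically from unchanged artifacts.
#'
#' @param outdir a directory populated by [runPipeline()].
#' @return invisibly, the report path.
#' @export
writeReport <- function(outdir) {
  have <- function(f) file.exists(file.path(outdir, f))
  if (!have("manifest_simulate.json") && !have("manifest_prepare.json") &&
      !have("run_records.jsonl"))
    stop("no pipeline artifacts found in ", outdir,
         " (run the simulate/prepare stage first)")
  md <- c("# Drug-blind composition audit report", "")
  warn <- character()

  if (have("permutation.csv")) {
    tab <- utils::read.csv(file.path(outdir, "permutation.csv"))
    agg <- aggregate(cbind(pearson, rel_drop) ~ condition, tab, mean)
    md <- c(md, "## Permutation conditions (from permutation.csv)", "",
            "Mean test Pearson and relative drop vs control over replicates:",
            "", .md_table(agg), "")
  }
  if (have("diversity_summary.csv")) {
    md <- c(md, "## Cells-per-drug diversity sweep (from diversity_summary.csv)",
            "", .md_table(utils::read.csv(
              file.path(outdir, "diversity_summary.csv"))), "")
  }
  if (have("global_meta_oof.csv")) {
    oof <- utils::read.csv(file.path(outdir, "global_meta_oof.csv"))
    r <- cor(oof$observed, oof$predicted)
    md <- c(md, "## Composition predicts performance (from global_meta_oof.csv)",
            "",
            sprintf("Out-of-fold prediction of run performance from training-set composition: Pearson %.3f over %d runs.",
                    r, nrow(oof)), "")
    .plot_oof(oof, outdir)
    if (file.exists(file.path(outdir, "fig_global_meta.png")))
      md <- c(md, "![predicted vs observed](fig_global_meta.png)", "")
  }
  if (have("relationship_stats.json")) {
    st <- jsonlite::read_json(file.path(outdir, "relationship_stats.json"),
                              simplifyVector = TRUE)
    md <- c(md, "## Drug-to-drug information sharing (from relationship_stats.json)",
            "", sprintf("Self-best rate: %.3f", st$self_best_rate), "")
    exc <- st$self_best_exceptions
    if (is.data.frame(exc) && nrow(exc))
      md <- c(md, "Targets better predicted by another drug:", "",
              .md_table(exc), "")
    else md <- c(md, "No target had a stronger non-self predictor.", "")
    m2o <- sort(unlist(st$many_to_one))
    m2o_df <- data.frame(target = names(m2o), many_to_one = unname(m2o))
    md <- c(md, "Most negative many-to-one targets:", "",
            .md_table(head(m2o_df, 5)), "")
    if (is.data.frame(st$class_to_class) && nrow(st$class_to_class))
      md <- c(md, "Class-to-class sharing:", "",
              .md_table(st$class_to_class), "")
  }
  if (have("coefficient_matrix.csv")) {
    .plot_heatmap(outdir)
    if (file.exists(file.path(outdir, "fig_coefficient_heatmap.png")))
      md <- c(md,
              "![coefficient heatmap, color scale clipped to [-1, 1] for contrast; statistics use uncapped values](fig_coefficient_heatmap.png)",
              "")
  }
  if (have("mechanism.csv")) {
    md <- c(md, "## Mechanism-isolated training (from mechanism.csv)", "",
            .md_table(utils::read.csv(file.path(outdir, "mechanism.csv"))),
            "")
  }
  path <- file.path(outdir, "report.md")
  writeLines(md, path)
  invisible(path)
}

.plot_oof <- function(oof, outdir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(invisible())
  p <- ggplot2::ggplot(oof, ggplot2::aes(x = observed, y = predicted)) +
    ggplot2::geom_abline(linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "observed test Pearson",
                  y = "out-of-fold predicted Pearson") +
    ggplot2::theme_bw()
  suppressMessages(ggplot2::ggsave(file.path(outdir, "fig_global_meta.png"),
                                   p, width = 4, height = 4, dpi = 150))
  invisible()
}

.plot_heatmap <- function(outdir) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) return(invisible())
  raw <- utils::read.csv(file.path(outdir, "coefficient_matrix.csv"),
                         check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  disp <- pmin(pmax(m, -1), 1)  # display clipping only
  ann <- NULL
  ann_path <- file.path(outdir, "data", "annotations.csv")
  if (file.exists(ann_path)) {
    a <- utils::read.csv(ann_path)
    ann <- data.frame(row.names = a$drug_id, mechanism = a$putative_target)
    ann <- ann[rownames(disp), , drop = FALSE]
  }
  grDevices::png(file.path(outdir, "fig_coefficient_heatmap.png"),
                 width = 900, height = 800, res = 120)
  pheatmap::pheatmap(disp, cluster_rows = TRUE, cluster_cols = TRUE,
                     clustering_method = "average",
                     annotation_col = ann, annotation_row = ann,
                     main = "predictor (rows) x target (cols); clipped [-1,1]")
  grDevices::dev.off()
  invisible()
}
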