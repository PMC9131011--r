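# End-to-end pipeline: simulate or ingest, filter, aggregate, diversity,
# PERMANOVA, differential abundance, correlations, prediction — driven by a
# plain-text key = value configuration, with a JSON run manifest recording
# config, seeds, input digests and per-stage outputs.

#' Read a plain-text pipeline configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values that parse
#' as numbers become numeric, `true`/`false` become logical, comma-separated
#' values become vectors.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", l)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(tolower(parts) %in% c("true", "false"))) tolower(parts) == "true"
      else parts
  }
  out
}

.pipeline_defaults <- function() list(
  seed = 1, out_dir = "pipeline_out",
  rank = "genus", prevalence_fraction = 0.10,
  permanova_permutations = 999, mc_samples = 128,
  nutrient = "carbohydrate_g",
  covariates = c("age", "bmi", "carbohydrate_g"),
  stages = c("filter", "aggregate", "alpha", "beta", "diffabund",
             "association", "prediction"),
  simulate = TRUE, n_pd = 60, n_hc = 60, n_asv = 150,
  effect_log2 = 2, n_differential = 8, stratum_effect = FALSE,
  num_trees = 500)

#' Run the full analysis pipeline
#'
#' Executes the analysis stages in dependency order on either a synthetic
#' cohort (`simulate = true`) or the three input TSVs (+ optional Newick
#' tree) named in the config, writes every stage's output under `out_dir`,
#' and finishes with a JSON run manifest (config echo, seeds, input
#' digests, stage outputs, package version, timestamps). Stages may be
#' skipped via the `stages` key; UniFrac is skipped with a logged reason
#' when no tree is available, while Bray-Curtis is always produced.
#'
#' @param config Path to a `key = value` config file, or an equivalent
#'   named list.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message("[pipeline] ", msg)
    log_lines <<- c(log_lines, msg)
  }
  outputs <- list()
  digests <- list()
  t0 <- Sys.time()

  # ingest or simulate
  if (isTRUE(cfg$simulate)) {
    note("simulating cohort (seed %d)", as.integer(cfg$seed))
    cohort <- generate_cohort(cohort_config(
      n_group_a = cfg$n_pd, n_group_b = cfg$n_hc, n_asv = cfg$n_asv,
      effect_log2 = cfg$effect_log2, n_differential = cfg$n_differential,
      stratum_effect = cfg$stratum_effect, seed = as.integer(cfg$seed)))
    counts <- cohort$counts; tax <- cohort$taxonomy
    meta <- cohort$metadata; tree <- cohort$tree
  } else {
    for (f in c("counts_tsv", "taxonomy_tsv", "metadata_tsv"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("missing input: ", f)
    counts <- read_counts(cfg$counts_tsv)
    tax <- read_taxonomy(cfg$taxonomy_tsv)
    meta <- read_metadata(cfg$metadata_tsv)
    tree <- if (!is.null(cfg$tree_newick) && file.exists(cfg$tree_newick))
      ape::read.tree(cfg$tree_newick) else NULL
    digests <- lapply(cfg[c("counts_tsv", "taxonomy_tsv", "metadata_tsv")],
                      function(p) unname(tools::md5sum(p)))
  }

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) { note("stage %s skipped by config", name); return(NULL) }
    path <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    tryCatch(fun(path), error = function(e) {
      file.create(paste0(path, ".partial"))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    outputs[[name]] <<- path
    note("stage %s -> %s", name, path)
    path
  }

  filtered <- counts
  run_stage("filter", function(path) {
    filtered <<- filter_by_prevalence(counts, cfg$prevalence_fraction)
    write_counts(filtered, path)
  })
  ranked <- filtered
  run_stage("aggregate", function(path) {
    ranked <<- aggregate_to_rank(filtered, tax, cfg$rank)
    write_counts(ranked, path)
  })
  run_stage("alpha", function(path) {
    utils::write.table(alpha_diversity(ranked), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  run_stage("beta", function(path) {
    bc <- bray_curtis(ranked)
    utils::write.table(data.frame(sample_id = rownames(bc), bc,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tree)) {
      uf <- unifrac(filtered, tree, weighted = TRUE)
      ufp <- file.path(cfg$out_dir, "beta_wunifrac.tsv")
      utils::write.table(data.frame(sample_id = rownames(uf), uf,
                                    check.names = FALSE),
                         ufp, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs$beta_wunifrac <<- ufp
    } else note("unifrac skipped: no tree provided")
    pv <- permanova(bc, meta, terms = "group",
                    n_permutations = cfg$permanova_permutations,
                    seed = as.integer(cfg$seed) + 11L)
    pvp <- file.path(cfg$out_dir, "permanova.tsv")
    utils::write.table(data.frame(term = pv$terms, F = pv$F, R2 = pv$R2,
                                  p = pv$p, permutations = pv$n_permutations),
                       pvp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$permanova <<- pvp
  })
  run_stage("diffabund", function(path) {
    da <- test_features(ranked, meta, n_mc = cfg$mc_samples,
                        seed = as.integer(cfg$seed) + 23L)
    utils::write.table(da, path, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  run_stage("association", function(path) {
    sc <- spearman_screen(ranked, meta, covariates = cfg$covariates,
                          adjust_for = intersect(c("age", "sex", "bmi"),
                                                 names(meta)))
    utils::write.table(sc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  run_stage("prediction", function(path) {
    X <- t(relative_abundance(ranked))
    labels <- meta$group[match(rownames(X), meta$sample_id)]
    sv <- survey_macronutrients(X, meta, labels,
                                candidates = cfg$nutrient,
                                seed = as.integer(cfg$seed) + 31L,
                                num_trees = cfg$num_trees)
    utils::write.table(sv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  manifest <- list(
    config = cfg,
    seed = as.integer(cfg$seed),
    input_digests = digests,
    stage_outputs = outputs,
    log = log_lines,
    package_version = as.character(utils::packageVersion("pdbiome")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
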