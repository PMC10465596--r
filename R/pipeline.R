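PIPELINE_STAGES <- c("simulate", "validate", "filter", "glom_metrics",
                     "arbor_metrics", "clones", "imaging", "report")

#' Map a neuron's synapse sites to its skeleton nodes
#'
#' Inputs use the postsynaptic site, outputs the presynaptic site; each site
#' is mapped to the nearest skeleton node (the per-node granularity flow
#' centrality operates on).
#'
#' @param conn an `al_connectome`.
#' @param neuron neuron id (must have a skeleton).
#' @return list with integer vectors `input_nodes` and `output_nodes`.
#' @export
map_synapses_to_nodes <- function(conn, neuron) {
  sk <- conn$skeletons[[neuron]]
  al_assert(!is.null(sk), "al_input_error", "no skeleton for neuron %s", neuron)
  cx <- conn$connections
  nearest <- function(sites) {
    if (nrow(sites) == 0L) return(integer(0))
    nd <- as.matrix(sk$nodes[, c("x", "y", "z")])
    d2 <- outer(rowSums(sites^2), rowSums(nd^2), `+`) - 2 * sites %*% t(nd)
    sk$nodes$node_id[max.col(-d2, ties.method = "first")]
  }
  ins <- as.matrix(cx[cx$post_neuron == neuron,
                      c("post_x", "post_y", "post_z"), drop = FALSE])
  outs <- as.matrix(cx[cx$pre_neuron == neuron,
                       c("pre_x", "pre_y", "pre_z"), drop = FALSE])
  list(input_nodes = nearest(ins), output_nodes = nearest(outs))
}

#' Load and check a pipeline run configuration
#'
#' The configuration is a YAML file (or equivalent list) with blocks
#' `out_dir`, `population`, `clones`, `traces`, `filter` and `toggles`.
#' Unknown keys are rejected, and every stochastic block must carry an
#' explicit `seed`.
#'
#' @param config path to a YAML file, or a list.
#' @return the validated configuration list with attribute `"hash"` (MD5 of
#'   its canonical YAML serialization).
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    al_assert(file.exists(config), "al_load_error", "missing file: %s", config)
    config <- yaml::read_yaml(config)
  }
  known <- c("out_dir", "population", "clones", "traces", "filter", "toggles")
  bad <- setdiff(names(config), known)
  al_assert(length(bad) == 0, "al_config_error",
            "unknown config key(s): %s", paste(bad, collapse = ", "))
  al_assert(!is.null(config$out_dir), "al_config_error",
            "config must set out_dir")
  for (blk in c("population", "clones", "traces")) {
    if (!is.null(config[[blk]])) {
      al_assert(!is.null(config[[blk]]$seed), "al_config_error",
                "config block '%s' is missing its seed", blk)
    }
  }
  # hash the scientific configuration only, so a run is identifiable
  # independently of where its artifacts land
  hashed <- config[setdiff(names(config), "out_dir")]
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hashed[order(names(hashed))], tf)
  attr(config, "hash") <- unname(tools::md5sum(tf))
  unlink(tf)
  config
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> validate -> filter -> glomerular metrics -> arbor
#' metrics -> clone statistics -> imaging -> report as a reproducible run:
#' idempotent for a fixed config (all randomness flows from the config
#' seeds), every output file stamped with the config hash, and partial stage
#' lists reusing the artifacts already on disk.
#'
#' @param config path to a YAML config or a list; see [load_run_config()].
#' @param stages character vector of stage names to run (default: all, in
#'   canonical order). Unknown names are a usage error.
#' @return invisibly, a run-report list (also written to
#'   `out_dir/run_report.json` by the report stage).
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  cfg <- load_run_config(config)
  bad <- setdiff(stages, PIPELINE_STAGES)
  al_assert(length(bad) == 0, "al_usage_error",
            "unknown stage name(s): %s", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- attr(cfg, "hash")
  stamp <- sprintf("config_hash=%s", hash)
  tg <- cfg$toggles
  artifacts <- character(0)
  log_lines <- c(sprintf("run: %s", stamp),
                 sprintf("stages: %s", paste(stages, collapse = ",")))
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  if ("simulate" %in% stages) {
    sim <- make_connectome(do.call(population_spec, cfg$population))
    write_connectome(sim$connectome, file.path(out, "connectome"))
    dir.create(file.path(out, "references"), showWarnings = FALSE)
    for (r in sim$references) {
      write_swc(r, file.path(out, "references", paste0(r$neuron_id, ".swc")))
    }
    jsonlite::write_json(
      list(config_hash = hash, patchy = sim$ground_truth$patchy),
      file.path(out, "ground_truth.json"), auto_unbox = FALSE)
    write_tsv(sim$ground_truth$counts, file.path(out, "planted_counts.tsv"),
              comment = stamp)
    if (!is.null(cfg$clones)) {
      cm <- make_clone_matrix(do.call(clone_matrix_spec, cfg$clones))
      write_innervation_matrix(cm, file.path(out, "clone_matrix.tsv"))
    }
    if (!is.null(cfg$traces)) {
      tr_cfg <- cfg$traces
      n_trials <- tr_cfg$n_trials %||% 4L
      tr_cfg$n_trials <- NULL
      traces <- lapply(seq_len(n_trials), function(i) {
        a <- tr_cfg
        a$seed <- substream_seed(tr_cfg$seed, paste0("trial", i))
        make_trace(do.call(trace_spec, a))
      })
      write_traces(traces, file.path(out, "traces.tsv"))
    }
    artifacts <- c(artifacts, "connectome", "ground_truth.json")
    note("simulate: %d neurons, %d connection rows",
         nrow(sim$connectome$annotations), nrow(sim$connectome$connections))
  }

  conn <- NULL
  need_conn <- function() {
    if (is.null(conn)) conn <<- load_connectome(file.path(out, "connectome"))
    conn
  }

  if ("validate" %in% stages) {
    rep <- validate_connectome(load_connectome(file.path(out, "connectome"),
                                               validate = FALSE))
    checks <- rep$checks
    jsonlite::write_json(
      list(config_hash = hash, n_failed = rep$n_failed, checks = checks),
      file.path(out, "validation.json"), auto_unbox = TRUE, digits = NA)
    al_assert(rep$n_failed == 0 || isTRUE(tg$force), "al_validation_error",
              "validation failed (%d checks); set toggles$force to continue",
              rep$n_failed)
    artifacts <- c(artifacts, "validation.json")
    note("validate: %d checks, %d failed", nrow(checks), rep$n_failed)
  }

  if ("filter" %in% stages) {
    cn <- need_conn()
    refs <- lapply(list.files(file.path(out, "references"),
                              full.names = TRUE, pattern = "\\.swc$"),
                   read_swc)
    crit <- do.call(filter_criteria, cfg$filter %||% list())
    led <- filter_candidates(cn, refs, crit)
    write_tsv(led$stages, file.path(out, "filter_ledger.tsv"), comment = stamp)
    write_tsv(data.frame(neuron_id = led$candidates),
              file.path(out, "candidates.tsv"), comment = stamp)
    artifacts <- c(artifacts, "filter_ledger.tsv", "candidates.tsv")
    note("filter: %d candidates", length(led$candidates))
  }

  if ("glom_metrics" %in% stages) {
    cn <- need_conn()
    cand <- read_tsv(file.path(out, "candidates.tsv"))$neuron_id
    assigned <- assign_synapses(cn)
    tab <- io_ratio_table(cn, assigned, neurons = cand)
    write_tsv(tab, file.path(out, "glomerular_metrics.tsv"), comment = stamp)
    rm_ <- ratio_matrix(tab)
    write_tsv(data.frame(neuron_id = rownames(rm_),
                         as.data.frame(rm_, check.names = FALSE),
                         check.names = FALSE),
              file.path(out, "ratio_matrix.tsv"), comment = stamp)
    pol <- do.call(rbind, lapply(cand, function(id) {
      polarity_breakdown(cn, id, assigned)
    }))
    write_tsv(pol, file.path(out, "polarity.tsv"), comment = stamp)
    dem <- do.call(rbind, lapply(cand, function(id) {
      rbind(partner_demographics(cn, id, "upstream"),
            partner_demographics(cn, id, "downstream"))
    }))
    write_tsv(dem, file.path(out, "demographics.tsv"), comment = stamp)
    artifacts <- c(artifacts, "glomerular_metrics.tsv", "ratio_matrix.tsv",
                   "polarity.tsv", "demographics.tsv")
    note("glom_metrics: %d (neuron, glomerulus) rows", nrow(tab))
  }

  if ("arbor_metrics" %in% stages) {
    cn <- need_conn()
    cand <- read_tsv(file.path(out, "candidates.tsv"))$neuron_id
    rows <- lapply(cand, function(id) {
      sites <- map_synapses_to_nodes(cn, id)
      fc <- flow_centrality(cn$skeletons[[id]], sites$input_nodes,
                            sites$output_nodes)
      data.frame(neuron_id = id, split_node = fc$split_node,
                 segregation_index = fc$segregation_index,
                 degenerate = fc$degenerate)
    })
    write_tsv(do.call(rbind, rows), file.path(out, "arbor_metrics.tsv"),
              comment = stamp)
    artifacts <- c(artifacts, "arbor_metrics.tsv")
    note("arbor_metrics: %d neurons", length(cand))
  }

  if ("clones" %in% stages) {
    cm <- read_innervation_matrix(file.path(out, "clone_matrix.tsv"))
    adj <- if (isTRUE(tg$holm)) "holm" else "none"
    cres <- innervation_correlations(cm, adjust = adj)
    write_corr <- function(m, path) {
      write_tsv(data.frame(glomerulus = rownames(m),
                           as.data.frame(m, check.names = FALSE),
                           check.names = FALSE), path, comment = stamp)
    }
    write_corr(cres$r, file.path(out, "clone_correlations_r.tsv"))
    write_corr(cres$p, file.path(out, "clone_correlations_p.tsv"))
    cn <- need_conn()
    vols <- vapply(cn$meshes, mesh_volume, numeric(1))
    common <- intersect(colnames(cm), names(vols))
    freq <- if (length(common) >= 3) {
      innervation_frequency(cm[, common, drop = FALSE], vols)
    } else NULL
    ord <- ward_order(cm, "rows")
    write_tsv(data.frame(position = seq_along(ord),
                         clone = rownames(cm)[ord]),
              file.path(out, "clone_leaf_order.tsv"), comment = stamp)
    if (!is.null(freq)) {
      write_tsv(data.frame(glomerulus = names(freq$frequency),
                           frequency = freq$frequency,
                           r_volume = freq$r, p_volume = freq$p),
                file.path(out, "innervation_frequency.tsv"), comment = stamp)
    }
    artifacts <- c(artifacts, "clone_correlations_r.tsv",
                   "clone_correlations_p.tsv", "clone_leaf_order.tsv")
    note("clones: %d x %d matrix", nrow(cm), ncol(cm))
  }

  if ("imaging" %in% stages) {
    traces <- read_traces(file.path(out, "traces.tsv"))
    origin <- tg$auc_origin %||% "onset"
    rows <- lapply(names(traces), function(nm) {
      resp <- compute_dff(traces[[nm]], sigma = tg$smoothing_sigma %||% 1,
                          bleach_correct = isTRUE(tg$bleach_correct))
      met <- response_metrics(resp, origin = origin)
      data.frame(trial = nm, f0 = resp$f0, peak = met$peak, auc = met$auc)
    })
    met <- do.call(rbind, rows)
    met <- rbind(met, data.frame(trial = "mean", f0 = mean(met$f0),
                                 peak = mean(met$peak), auc = mean(met$auc)))
    write_tsv(met, file.path(out, "imaging_metrics.tsv"), comment = stamp)
    artifacts <- c(artifacts, "imaging_metrics.tsv")
    note("imaging: %d trials averaged", length(traces))
  }

  report <- list(
    config_hash = hash,
    package_version = as.character(utils::packageVersion("alcircuit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages_run = stages,
    artifacts = artifacts,
    log = log_lines
  )
  if ("report" %in% stages) {
    jsonlite::write_json(report, file.path(out, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(out, "run.log"))
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
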