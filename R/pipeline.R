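# End-to-end pipeline: load and group replicates, align all same-K pairs,
# detect modes, build consensus memberships, score, align modes across K,
# lay out and draw the multipartite figure, and write all text outputs.

#' Pipeline configuration
#'
#' @param input_dir directory of replicate files.
#' @param output_dir directory for all outputs.
#' @param input_format replicate file dialect; see [load_collection()].
#' @param resolution Louvain resolution (> 0, default 1).
#' @param consensus_method `"mean"` (default) or `"representative"`.
#' @param acrossk_method `"direct"` (default) or `"merge"`.
#' @param community_test_significance significance of the mode-structure
#'   gate, in (0, 1); default 0.01.
#' @param seed seed for every stochastic step (default 0).
#' @param plot draw the multipartite figure and within-mode histograms.
#' @param plot_format `"png"`, `"svg"`, or `"pdf"`.
#' @param fig_width,fig_height,dpi figure parameters.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            input_format = "auto",
                            resolution = 1,
                            consensus_method = "mean",
                            acrossk_method = "direct",
                            community_test_significance = 0.01,
                            seed = 0L,
                            plot = TRUE,
                            plot_format = "png",
                            fig_width = 9, fig_height = 6, dpi = 150) {
  stopifnot(resolution > 0,
            community_test_significance > 0,
            community_test_significance < 1)
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         input_format = match.arg(input_format, c("auto", "q", "structure")),
         resolution = resolution,
         consensus_method = match.arg(consensus_method,
                                      c("mean", "representative")),
         acrossk_method = match.arg(acrossk_method, c("direct", "merge")),
         community_test_significance = community_test_significance,
         seed = as.integer(seed), plot = isTRUE(plot),
         plot_format = match.arg(plot_format, c("png", "svg", "pdf")),
         fig_width = fig_width, fig_height = fig_height, dpi = dpi),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `input_dir` and
#' `output_dir` may also be given as arguments, overriding the file.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

log_stage <- function(log_path, ...) {
  msg <- paste0(...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  invisible(NULL)
}

#' Run the full replicate-alignment pipeline
#'
#' Stages: (1) load and group replicates by K; (2a) optimal pairwise
#' alignment of all same-K pairs; (2b) mode detection; (2c) mode
#' consensus and within-mode scores; (3) across-K mode alignment; then
#' layout, figures, and text outputs. Identical inputs, configuration and
#' seed produce byte-identical text outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run manifest (also written as
#'   `manifest.json` in the output directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  cat("", file = log_path)

  log_stage(log_path, "step 1: loading replicates from ", config$input_dir)
  collection <- load_collection(config$input_dir, config$input_format)
  log_stage(log_path, "  N = ", collection$N, "; K groups: ",
            paste(sprintf("K=%s (R=%d)", names(collection$groups),
                          collection$R_K), collapse = ", "))

  modes <- list()
  for (k in names(collection$groups)) {
    reps <- collection$groups[[k]]
    log_stage(log_path, "step 2a: aligning ",
              length(reps) * (length(reps) - 1L) / 2L,
              " replicate pairs at K = ", k)
    graph <- build_replicate_graph(reps)
    log_stage(log_path, "step 2b: mode detection at K = ", k)
    mode_set <- detect_modes(graph, resolution = config$resolution,
                             seed = config$seed,
                             significance = config$community_test_significance)
    log_stage(log_path, "  m = ", mode_set$m, " mode(s), s = ", mode_set$s,
              " singleton(s)")
    log_stage(log_path, "step 2c: consensus memberships at K = ", k)
    consensus <- lapply(mode_set$modes, function(m) {
      build_consensus(graph, m, reps)
    })
    scores <- compute_scores(graph, mode_set)
    modes[[k]] <- list(graph = graph, mode_set = mode_set,
                       consensus = consensus, scores = scores)
  }

  layers <- lapply(modes, `[[`, "consensus")
  across <- NULL
  layout <- NULL
  if (length(layers) >= 1L) {
    log_stage(log_path, "step 3: across-K alignment (",
              config$acrossk_method, ")")
    across <- build_across_k_graph(layers, method = config$acrossk_method,
                                   consensus_method = config$consensus_method)
    log_stage(log_path, "  ",
              sum(vapply(across$edges, length, 0L)), " mode-pair edge(s)")
    layout <- compute_global_layout(across)
  }

  log_stage(log_path, "writing outputs to ", config$output_dir)
  files <- write_aligned_outputs(collection, modes, across, config$output_dir)
  scores_path <- file.path(config$output_dir, "scores.tsv")
  write_scores_tsv(modes, scores_path)
  files <- c(files, scores_path)

  if (config$plot) {
    log_stage(log_path, "rendering figures")
    fig <- render_modes(layout, across,
                        file.path(config$output_dir, "modes_multipartite"),
                        format = config$plot_format,
                        width = config$fig_width, height = config$fig_height,
                        dpi = config$dpi)
    files <- c(files, fig)
    for (k in names(modes)) {
      h <- plot_mode_histograms(modes[[k]]$graph, modes[[k]]$mode_set)
      if (!is.null(h)) {
        hp <- file.path(config$output_dir,
                        sprintf("K%s_mode_dissimilarity.%s", k,
                                config$plot_format))
        dev <- switch(config$plot_format, png = grDevices::png,
                      svg = grDevices::svg, pdf = grDevices::pdf)
        ggplot2::ggsave(hp, h, device = dev, width = config$fig_width,
                        height = config$fig_height, dpi = config$dpi)
        files <- c(files, hp)
      }
    }
  }

  manifest <- list(
    N = collection$N,
    K_values = as.integer(names(collection$groups)),
    seed = config$seed,
    resolution = config$resolution,
    consensus_method = config$consensus_method,
    acrossk_method = config$acrossk_method,
    per_K = lapply(modes, function(mk) {
      list(R = sum(lengths(mk$mode_set$modes)),
           m = mk$mode_set$m,
           s = mk$mode_set$s,
           mode_sizes = lengths(mk$mode_set$modes),
           H_bar = mk$scores$weighted_H,
           H_tilde = mk$scores$singleton_excluded_H)
    }),
    across_K_edges = if (is.null(across)) 0L else
      sum(vapply(across$edges, length, 0L)),
    files = sort(basename(files))
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")
  log_stage(log_path, "done")
  invisible(manifest)
}
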