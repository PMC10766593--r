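# Text outputs of a pipeline run. All files are plain text, written
# deterministically in 6-decimal precision.

#' Write aligned replicates, consensus matrices, mode lists and across-K
#' alignments
#'
#' Per K, writes each mode member permuted into its mode's common frame
#' (Q dialect, `<id>_aligned.Q`), the mode consensus matrices
#' (`K<k>_M<l>_mean.Q`, `K<k>_M<l>_rep.Q`), and a mode list file with one
#' replicate id per line under `# mode <K>-M<l>` headers. A single
#' across-K file lists one line per aligned mode pair: the two K values
#' and mode indices, the optimal cost, and the mapping as comma-separated
#' target indices.
#'
#' @param collection the loaded `replicate_collection`.
#' @param modes named list (by K) of lists with elements `mode_set` and
#'   `consensus` (list of [build_consensus()] results, one per mode).
#' @param across a [build_across_k_graph()] result (or `NULL` with a
#'   single K; the across-K file then has no data lines).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the written file paths.
#' @export
write_aligned_outputs <- function(collection, modes, across, out_dir) {
  if (!length(modes)) stop("no mode results to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- character()

  for (k in names(modes)) {
    kdir <- file.path(out_dir, paste0("K", k))
    dir.create(kdir, showWarnings = FALSE)
    ms <- modes[[k]]$mode_set
    cons <- modes[[k]]$consensus
    reps <- collection$groups[[k]]
    by_id <- stats::setNames(reps, vapply(reps, `[[`, "", "id"))

    mode_lines <- character()
    for (l in seq_along(ms$modes)) {
      cn <- cons[[l]]
      mode_lines <- c(mode_lines, sprintf("# mode %s-M%d", k, l),
                      cn$member_ids)
      for (id in cn$member_ids) {
        p <- file.path(kdir, paste0(id, "_aligned.Q"))
        write_q_file(apply_alignment(by_id[[id]], cn$member_permutations[[id]]), p)
        paths <- c(paths, p)
      }
      p_mean <- file.path(kdir, sprintf("K%s_M%d_mean.Q", k, l))
      write_q_file(cn$mean_matrix, p_mean)
      p_rep <- file.path(kdir, sprintf("K%s_M%d_rep.Q", k, l))
      write_q_file(cn$representative_matrix, p_rep)
      paths <- c(paths, p_mean, p_rep)
    }
    p_modes <- file.path(kdir, sprintf("K%s_modes.txt", k))
    writeLines(mode_lines, p_modes)
    paths <- c(paths, p_modes)
  }

  across_lines <- character()
  if (!is.null(across) && length(across$edges)) {
    ks <- across$k_values
    for (p in seq_along(across$edges)) {
      for (e in across$edges[[p]]) {
        across_lines <- c(across_lines, sprintf(
          "%d\t%d\t%d\t%d\t%.6f\t%s",
          ks[p], e$hi_mode, ks[p + 1L], e$lo_mode, e$cost,
          paste(alignment_mapping(e$alignment), collapse = ",")))
      }
    }
  }
  p_across <- file.path(out_dir, "acrossK_alignments.txt")
  writeLines(c("# K_i\tmode_i\tK_j\tmode_j\tcost\tmapping", across_lines),
             p_across)
  paths <- c(paths, p_across)
  invisible(paths)
}

# scores summary: one row per mode plus one per-K summary row
write_scores_tsv <- function(modes, path) {
  lines <- "K\tmode\tsize\tH_prime\tH_bar\tH_tilde\tsingletons"
  for (k in names(modes)) {
    sc <- modes[[k]]$scores
    sizes <- lengths(modes[[k]]$mode_set$modes)
    for (l in seq_along(sizes)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%.6f\t\t\t", k, l, sizes[l],
                                sc$per_mode_H[l]))
    }
    lines <- c(lines, sprintf(
      "%s\tall\t%d\t\t%.6f\t%s\t%d", k, sum(sizes), sc$weighted_H,
      if (is.na(sc$singleton_excluded_H)) "NA"
      else sprintf("%.6f", sc$singleton_excluded_H),
      sc$singleton_count))
  }
  writeLines(lines, path)
  invisible(path)
}
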