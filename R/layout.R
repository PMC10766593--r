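# Global cluster ordering for visualization. Colors propagate from the
# largest-K layer's anchor mode: within each layer every other mode is
# aligned to the layer's anchor, and each lower layer inherits its frame
# through the anchor-pair alignment. Composition of these permutations
# gives each mode one final display permutation and one color per cluster.

#' Compute the global display layout of an across-K mode graph
#'
#' Each mode receives a display permutation (`perm`, a bijection on its
#' own clusters giving the stacking slot of each column) and a `colors`
#' vector (the global palette index of each column). The largest-K
#' anchor's columns define the palette order; anchor-pair alignments carry
#' it downward, each smaller-K cluster taking the color of the
#' smallest-slot source cluster mapped onto it.
#'
#' @param graph a [build_across_k_graph()] result.
#' @return a `global_layout`: `k_values`, per-layer lists `perms` and
#'   `colors` (one entry per mode), `anchor_modes` (per layer), and the
#'   graph's anchors and edges for annotation.
#' @export
compute_global_layout <- function(graph) {
  ks <- graph$k_values
  n_layer <- length(ks)
  perms <- vector("list", n_layer)
  colors <- vector("list", n_layer)
  anchor_modes <- integer(n_layer)

  cons_method <- graph$consensus_method
  layer_anchor_idx <- function(p) {
    # layer p's anchor mode: from the pair above it, or the pair below for
    # the top layer; single layers anchor on their first (largest) mode
    if (n_layer == 1L) return(1L)
    if (p == 1L) graph$anchors[[1L]]$hi_mode else {
      graph$anchors[[p - 1L]]$lo_mode
    }
  }

  for (p in seq_len(n_layer)) {
    modes <- graph$layers[[p]]
    a <- layer_anchor_idx(p)
    anchor_modes[p] <- a
    K <- modes[[a]]$K

    if (p == 1L) {
      anchor_perm <- seq_len(K)
      anchor_cols <- seq_len(K)
    } else {
      # inherit the frame through the anchor-pair alignment
      up <- p - 1L
      pair <- graph$anchors[[up]]
      map <- alignment_mapping(pair$alignment)      # upper clusters -> lower
      up_perm <- perms[[up]][[pair$hi_mode]]
      up_cols <- colors[[up]][[pair$hi_mode]]
      anchor_perm <- integer(K)
      anchor_cols <- integer(K)
      rep_slot <- numeric(K)
      for (j in seq_len(K)) {
        pre <- which(map == j)
        lead <- pre[which.min(up_perm[pre])]
        anchor_cols[j] <- up_cols[lead]
        rep_slot[j] <- up_perm[lead]
      }
      anchor_perm <- rank(rep_slot)
    }

    perms[[p]] <- vector("list", length(modes))
    colors[[p]] <- vector("list", length(modes))
    perms[[p]][[a]] <- anchor_perm
    colors[[p]][[a]] <- anchor_cols
    for (m in seq_along(modes)) {
      if (m == a) next
      al <- align_pair(as_matrix(consensus_matrix(modes[[m]], cons_method)),
                       as_matrix(consensus_matrix(modes[[a]], cons_method)))
      pi_map <- al$mapping                          # mode clusters -> anchor
      perms[[p]][[m]] <- anchor_perm[pi_map]
      colors[[p]][[m]] <- anchor_cols[pi_map]
    }
  }
  structure(
    list(k_values = ks, perms = perms, colors = colors,
         anchor_modes = anchor_modes, anchors = graph$anchors,
         edges = graph$edges),
    class = "global_layout"
  )
}

#' @export
print.global_layout <- function(x, ...) {
  cat("global layout: layers K = ", paste(x$k_values, collapse = ", "),
      "; anchors M", paste(x$anchor_modes, collapse = ", M"), "\n", sep = "")
  invisible(x)
}
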