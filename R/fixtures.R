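# Synthetic replicate collections with known ground truth. Replicates are
# modeled as noise-perturbed, label-permuted copies of per-mode base
# matrices: bases have symmetric-Dirichlet rows (realistic admixed
# profiles), noise is additive uniform with clipping at zero and row
# renormalization, and every replicate's cluster labels are scrambled by a
# planted permutation. The construction emulates the statistical structure
# the pipeline assumes — it does not simulate genotypes or MCMC.

#' Specification of a synthetic replicate collection
#'
#' @param N number of individuals.
#' @param K_values integer vector of cluster counts to generate.
#' @param replicates_per_mode named list (names = K values) of integer
#'   vectors, one count per planted mode; or a single vector recycled for
#'   every K.
#' @param base_concentration concentration of the symmetric Dirichlet
#'   generating base membership rows (default 1: uniform over the
#'   simplex).
#' @param noise_scale half-width of the additive uniform per-entry
#'   perturbation applied before clipping and renormalization; must be
#'   below 1. Default 0.05, comparable to run-to-run MCMC variation.
#' @param seed RNG seed.
#' @param bases optional explicit base matrices: named list (by K) of
#'   lists of membership matrices, one per planted mode, overriding the
#'   Dirichlet draw.
#' @export
fixture_spec <- function(N, K_values, replicates_per_mode,
                         base_concentration = 1, noise_scale = 0.05,
                         seed = 0L, bases = NULL) {
  stopifnot(N >= 1L, all(K_values >= 1L), base_concentration > 0,
            noise_scale >= 0, noise_scale < 1)
  if (!is.list(replicates_per_mode)) {
    replicates_per_mode <- stats::setNames(
      rep(list(as.integer(replicates_per_mode)), length(K_values)),
      K_values)
  }
  if (!all(as.character(K_values) %in% names(replicates_per_mode))) {
    stop("replicates_per_mode must name every K value")
  }
  if (any(unlist(replicates_per_mode) < 1L)) stop("mode replicate counts must be positive")
  structure(
    list(N = as.integer(N), K_values = as.integer(K_values),
         replicates_per_mode = replicates_per_mode,
         base_concentration = base_concentration,
         noise_scale = noise_scale, seed = as.integer(seed), bases = bases),
    class = "fixture_spec"
  )
}

dirichlet_rows <- function(N, K, concentration) {
  g <- matrix(stats::rgamma(N * K, shape = concentration), N, K)
  g / rowSums(g)
}

# additive uniform noise, clipped at zero, rows renormalized; degenerate
# all-zero rows (only possible at extreme noise) fall back to uniform
perturb_membership <- function(base, noise_scale) {
  m <- base + matrix(stats::runif(length(base), -noise_scale, noise_scale),
                     nrow(base), ncol(base))
  m[m < 0] <- 0
  rs <- rowSums(m)
  zero <- rs <= 0
  if (any(zero)) {
    m[zero, ] <- 1 / ncol(m)
    rs[zero] <- 1
  }
  m / rs
}

#' Generate a synthetic replicate collection with ground truth
#'
#' For each K, draws one base matrix per planted mode, then produces each
#' replicate by perturbing its mode's base and permuting the columns by a
#' random planted permutation (replicate column `k` is base column
#' `perm[k]`). Fully reproducible from the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `collection` (a `replicate_collection`) and `truth`:
#'   per-replicate planted `mode` labels and `permutation`s, plus the
#'   per-mode `bases`.
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    groups <- list()
    truth_mode <- character()
    truth_perm <- list()
    bases_out <- list()
    for (K in spec$K_values) {
      counts <- spec$replicates_per_mode[[as.character(K)]]
      bases <- if (!is.null(spec$bases)) {
        lapply(spec$bases[[as.character(K)]], as_matrix)
      } else {
        lapply(seq_along(counts), function(m) {
          dirichlet_rows(spec$N, K, spec$base_concentration)
        })
      }
      if (length(bases) != length(counts)) {
        stop("need one base matrix per planted mode at K = ", K)
      }
      reps <- list()
      r_idx <- 0L
      for (m in seq_along(counts)) {
        for (r in seq_len(counts[m])) {
          r_idx <- r_idx + 1L
          noisy <- perturb_membership(bases[[m]], spec$noise_scale)
          perm <- sample.int(K)
          id <- sprintf("K%d_R%03d", K, r_idx)
          reps[[r_idx]] <- q_replicate(id, noisy[, perm, drop = FALSE])
          truth_mode[id] <- sprintf("K%d_M%d", K, m)
          truth_perm[[id]] <- perm
        }
      }
      groups[[as.character(K)]] <- reps
      bases_out[[as.character(K)]] <- bases
    }
    collection <- structure(
      list(groups = groups, N = spec$N,
           R_K = vapply(groups, length, 0L)),
      class = "replicate_collection"
    )
    list(collection = collection,
         truth = list(mode = truth_mode, permutation = truth_perm,
                      bases = bases_out))
  })
}

#' Write a collection as a directory of Q files
#'
#' One file per replicate, named `<id>.Q`, in the whitespace-delimited Q
#' dialect.
#'
#' @param collection a `replicate_collection`.
#' @param dir destination directory (created if absent).
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (grp in collection$groups) {
    for (rep in grp) {
      p <- file.path(dir, paste0(rep$id, ".Q"))
      write_q_file(rep$matrix, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Split one cluster of a base matrix into two
#'
#' Produces a (K+1)-column matrix whose optimal many-to-one alignment to
#' the base is known by construction: the chosen column is divided
#' row-wise into two columns in the given proportions (the second placed
#' last), so summing the two split columns reproduces the base exactly.
#' With `jitter > 0` the proportions are perturbed per row (seeded),
#' keeping the reconstruction exact while making the split columns
#' unequal across individuals.
#'
#' @param base membership matrix with K columns.
#' @param cluster index of the column to split.
#' @param fractions two positive-or-zero reals summing to 1.
#' @param seed RNG seed (used only when `jitter > 0`).
#' @param jitter half-width of a per-row uniform perturbation of
#'   `fractions[1]`, truncated to \[0, 1\].
#' @export
split_cluster_fixture <- function(base, cluster, fractions = c(0.5, 0.5),
                                  seed = 0L, jitter = 0) {
  base <- as_matrix(base)
  K <- ncol(base)
  stopifnot(cluster >= 1L, cluster <= K)
  if (length(fractions) != 2L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be two non-negative values summing to 1")
  }
  f1 <- rep(fractions[1L], nrow(base))
  if (jitter > 0) {
    f1 <- withr::with_seed(seed, {
      pmin(1, pmax(0, f1 + stats::runif(nrow(base), -jitter, jitter)))
    })
  }
  out <- cbind(base, base[, cluster] * (1 - f1))
  out[, cluster] <- base[, cluster] * f1
  membership_matrix(out, tol = 1e-9)
}
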