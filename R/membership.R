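#' Construct a membership matrix
#'
#' A membership matrix holds the inferred cluster memberships of one
#' clustering replicate: one row per individual, one column per cluster,
#' entries non-negative, rows summing to one. Mixed-membership programs
#' print rounded coefficients, so rows are accepted when they sum to one
#' within `tol` and are then renormalized to exact unit sum.
#'
#' @param x numeric matrix (or object coercible to one), N rows by K columns.
#' @param tol permitted deviation of a raw row sum from 1 before the row is
#'   rejected; default `1e-4`, matching the rounding of published Q files.
#' @param renormalize rescale each accepted row to exact unit sum.
#' @return a numeric matrix of class `membership_matrix`.
#' @export
membership_matrix <- function(x, tol = 1e-4, renormalize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("membership matrix must have at least one row and one column")
  }
  if (anyNA(x)) stop("membership matrix contains non-numeric or missing entries")
  if (any(x < 0)) {
    bad <- which(apply(x, 1L, function(r) any(r < 0)))[1L]
    stop("negative membership coefficient in row ", bad)
  }
  rs <- rowSums(x)
  off <- which(abs(rs - 1) > tol)
  if (length(off)) {
    stop("row ", off[1L], " sums to ", format(rs[off[1L]]),
         ", outside 1 +/- ", tol)
  }
  if (renormalize) x <- x / rs
  dimnames(x) <- NULL
  class(x) <- c("membership_matrix", class(x))
  x
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat("membership matrix: ", nrow(x), " individuals x ", ncol(x),
      " clusters\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE], digits = 4)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

# strip class/attrs for internal arithmetic
as_matrix <- function(x) {
  if (inherits(x, "q_replicate")) x <- x$matrix
  x <- unclass(as.matrix(x))
  storage.mode(x) <- "double"
  x
}

#' A single clustering replicate
#'
#' Bundles a membership matrix with the identifier and provenance used by
#' the rest of the pipeline.
#'
#' @param id unique string identifier (typically the source filename stem).
#' @param matrix a [membership_matrix()] or coercible numeric matrix.
#' @param source_path optional path of the file the replicate was read from.
#' @export
q_replicate <- function(id, matrix, source_path = NA_character_) {
  m <- if (inherits(matrix, "membership_matrix")) matrix else membership_matrix(matrix)
  structure(
    list(id = as.character(id), K = ncol(m), N = nrow(m), matrix = m,
         source_path = source_path),
    class = "q_replicate"
  )
}

#' @export
print.q_replicate <- function(x, ...) {
  cat("replicate ", x$id, ": N = ", x$N, ", K = ", x$K, "\n", sep = "")
  invisible(x)
}

#' Read an Admixture-style Q file
#'
#' Plain whitespace-delimited text, one individual per row, one column per
#' cluster, no header. The number of clusters is inferred from the first
#' line.
#'
#' @param path file path.
#' @inheritParams membership_matrix
#' @return a [membership_matrix()].
#' @export
read_q_file <- function(path, tol = 1e-4) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty Q file: ", path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nc <- lengths(toks)
  if (any(nc != nc[1L])) {
    bad <- which(nc != nc[1L])[1L]
    stop("ragged Q file ", path, ": line ", bad, " has ", nc[bad],
         " fields, expected ", nc[1L])
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1L] / nc[1L])
    stop("non-numeric field in ", path, " at line ", bad)
  }
  m <- matrix(vals, nrow = length(lines), ncol = nc[1L], byrow = TRUE)
  membership_matrix(m, tol = tol)
}

#' Read the inferred-ancestry block of a Structure run report
#'
#' Consumes only the block headed by "Inferred ancestry of individuals";
#' membership coefficients are the numeric tokens following the `:`
#' separator on each individual's line. Allele-frequency and likelihood
#' sections are ignored.
#'
#' @inheritParams read_q_file
#' @return a [membership_matrix()].
#' @export
read_structure_file <- function(path, tol = 1e-4) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("Inferred ancestry of individuals", lines, fixed = TRUE)
  if (!length(hdr)) {
    stop("no 'Inferred ancestry of individuals' block in ", path)
  }
  rows <- list()
  for (ln in lines[(hdr[1L] + 1L):length(lines)]) {
    if (!nzchar(trimws(ln))) {
      if (length(rows)) break else next
    }
    if (!grepl(":", ln, fixed = TRUE)) {
      if (length(rows)) break else next
    }
    tail_part <- sub("^[^:]*:", "", ln)
    toks <- strsplit(trimws(tail_part), "[[:space:]]+")[[1L]]
    # tokens may include per-population probability intervals like (0.883,1.000)
    toks <- toks[!grepl("[(]", toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (!length(vals) || anyNA(vals)) {
      if (length(rows)) break else next  # column-header line before data
    }
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) {
    stop("inferred-ancestry block of ", path, " contains no parseable rows")
  }
  nc <- lengths(rows)
  if (any(nc != nc[1L])) {
    bad <- which(nc != nc[1L])[1L]
    stop("inconsistent coefficient counts in ", path, ": individual ", bad,
         " has ", nc[bad], " coefficients, expected ", nc[1L])
  }
  membership_matrix(do.call(rbind, rows), tol = tol)
}

#' Load a directory of replicates and group them by K
#'
#' Reads every regular file in `input_dir`, groups the replicates by their
#' number of clusters, and checks that all replicates describe the same
#' individuals. Files are processed in sorted filename order, which fixes
#' the within-group replicate order.
#'
#' @param input_dir directory of replicate files.
#' @param format `"q"`, `"structure"`, or `"auto"` (try the Structure
#'   run-report dialect first, fall back to the Q dialect).
#' @return a `replicate_collection`: list with `groups` (named by K, each an
#'   ordered list of [q_replicate()]s), `N`, and per-K counts `R_K`.
#' @export
load_collection <- function(input_dir, format = c("auto", "q", "structure")) {
  format <- match.arg(format)
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  files <- list.files(input_dir, full.names = TRUE)
  files <- sort(files[file.exists(files) & !dir.exists(files)])
  if (!length(files)) stop("no replicate files in ", input_dir)

  reps <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    m <- switch(format,
      q = read_q_file(f),
      structure = read_structure_file(f),
      auto = tryCatch(read_structure_file(f), error = function(e) read_q_file(f))
    )
    reps[[i]] <- q_replicate(tools::file_path_sans_ext(basename(f)), m,
                             source_path = f)
  }
  ids <- vapply(reps, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate replicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  Ns <- vapply(reps, `[[`, 0L, "N")
  if (length(unique(Ns)) > 1L) {
    tab <- table(Ns)
    majority <- as.integer(names(tab)[which.max(tab)])
    bad <- ids[Ns != majority]
    stop("replicates disagree on the number of individuals; offending files: ",
         paste(bad, collapse = ", "))
  }
  Ks <- vapply(reps, `[[`, 0L, "K")
  groups <- lapply(sort(unique(Ks)), function(k) reps[Ks == k])
  names(groups) <- sort(unique(Ks))
  structure(
    list(groups = groups, N = Ns[1L],
         R_K = vapply(groups, length, 0L)),
    class = "replicate_collection"
  )
}

#' @export
print.replicate_collection <- function(x, ...) {
  cat("replicate collection: N = ", x$N, "\n", sep = "")
  for (k in names(x$groups)) {
    cat("  K = ", k, ": ", length(x$groups[[k]]), " replicates\n", sep = "")
  }
  invisible(x)
}

#' Write a membership matrix in the Q dialect
#'
#' @param m matrix to write.
#' @param path destination file.
#' @param digits decimal places (6 matches common Admixture output).
#' @export
write_q_file <- function(m, path, digits = 6L) {
  m <- as_matrix(m)
  lines <- apply(m, 1L, function(r) {
    paste(sprintf(paste0("%.", digits, "f"), r), collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}
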