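# Plain-text readers and writers: paths, trajectories, profiles,
# configurations.  All formats are whitespace-delimited with '#'
# comments so runs can be inspected with standard command-line tools.

#' Read and write path files
#'
#' A path file holds one node per line (whitespace-separated reals).
#' Snapshot files append blocks separated by header lines of the form
#' `# snapshot <index> time_fs <t>`.
#'
#' @param path a [cv_path()] (or list of paths for snapshots).
#' @param file file path.
#' @param times snapshot times in fs (for snapshot files).
#' @return `read_path()` returns a [cv_path()]; `read_path_snapshots()`
#'   a list with `paths` and `times`.
#' @export
write_path <- function(path, file) {
  P <- unclass(cv_path(unclass(path)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# path: %d nodes, dimension %d", nrow(P), ncol(P)), con)
  write.table(format(P, digits = 12), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_path
#' @export
read_path <- function(file) {
  cv_path(as.matrix(read.table(file, comment.char = "#")))
}

#' @rdname write_path
#' @param paths list of node matrices.
#' @export
write_path_snapshots <- function(paths, times, file) {
  stopifnot(length(paths) == length(times))
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(paths)) {
    writeLines(sprintf("# snapshot %d time_fs %.6g", i, times[i]), con)
    write.table(format(as.matrix(paths[[i]]), digits = 12), con,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname write_path
#' @export
read_path_snapshots <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# snapshot", lines)
  times <- as.numeric(sub(".*time_fs ", "", lines[hdr]))
  bounds <- c(hdr, length(lines) + 1)
  paths <- lapply(seq_along(hdr), function(i) {
    block <- lines[(bounds[i] + 1):(bounds[i + 1] - 1)]
    block <- block[!grepl("^#", block) & nzchar(block)]
    as.matrix(read.table(text = block))
  })
  list(paths = paths, times = times)
}

#' Read and write trajectory files
#'
#' Whitespace-delimited table with a commented header line naming the
#' columns (`step time_fs x [y] s d lambda epot ebias temp epoch`).
#'
#' @param sim a `"path_sim"` (or a data frame of frames).
#' @param file file path.
#' @return `read_trajectory()` returns the data frame of frames.
#' @export
write_trajectory <- function(sim, file) {
  tr <- if (inherits(sim, "path_sim")) sim$trajectory else sim
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("#", paste(names(tr), collapse = " ")), con)
  write.table(format(tr, digits = 10, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  hdr <- readLines(file, n = 1)
  cols <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  out <- read.table(file, comment.char = "#")
  names(out) <- cols
  out
}

#' Read and write free-energy profile files
#'
#' Columns `bin_center free_energy_kJmol count ci95`, '#' comments.
#'
#' @param profile a [fep()].
#' @param file file path.
#' @return `read_pmf()` returns the [fep()].
#' @export
write_pmf <- function(profile, file) {
  stopifnot(inherits(profile, "fep"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# bin_center free_energy_kJmol count ci95", con)
  df <- data.frame(profile$center, profile$energy, profile$count,
                   profile$ci95)
  write.table(format(df, digits = 10, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(file) {
  df <- read.table(file, comment.char = "#",
                   na.strings = c("NA", "nan"))
  fep(df[[1]], df[[2]], count = df[[3]], ci95 = df[[4]])
}

#' Read and write sampler configurations
#'
#' Key-value text format, one `key = value` per line under a
#' `[sampling]` section header; unknown keys are errors so typos fail
#' loudly.
#'
#' @param config a [sampler_config()].
#' @param file file path.
#' @return `read_config()` returns the [sampler_config()].
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "sampler_config"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("[sampling]", con)
  for (k in names(config)) {
    v <- config[[k]]
    writeLines(sprintf("%s = %s", k, format(v, digits = 12)), con)
  }
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#\\[]", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  proto <- sampler_config()
  unknown <- setdiff(keys, names(proto))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    args[[k]] <- if (k == "bias") vals[i]
                 else if (is.logical(proto[[k]])) as.logical(vals[i])
                 else as.numeric(vals[i])
  }
  do.call(sampler_config, args)
}
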