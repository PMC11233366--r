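#' @title Trajectory and result-table IO
#' @description
#' The interchange trajectory format is extended-XYZ-style text: per
#' snapshot a particle-count line, a comment line
#' `step=<n> time=<t> box=<L> model=<m>`, and one row per particle with
#' columns `species x y radius vesicle_id dimer_id` (coordinates printed
#' with 9 significant digits). A compact full-precision binary container
#' (RDS) is used when the output path ends in `.rds`.
#' @name trajectory-io
NULL

#' Write a trajectory
#'
#' @param trajectory a `vc_trajectory`.
#' @param path output path; `.rds` selects the binary container, anything
#'   else the XYZ-style text format.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "vc_trajectory"))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(trajectory, path)
    return(invisible(path))
  }
  n <- length(trajectory$species)
  con <- file(path, open = "wt")
  on.exit(close(con))
  dim_col <- ifelse(is.na(trajectory$dimer_id), -1L, trajectory$dimer_id)
  static <- sprintf("%s %%s %%s %.9g %d %d", trajectory$species,
                    trajectory$radius, trajectory$vesicle_id, dim_col)
  for (i in seq_len(n_snapshots(trajectory))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("step=%d time=%.9g box=%.9g model=%s",
                       trajectory$steps[i], trajectory$times[i],
                       trajectory$box_length, trajectory$model), con)
    writeLines(sprintf(static,
                       formatC(trajectory$x[, i], format = "g", digits = 9),
                       formatC(trajectory$y[, i], format = "g", digits = 9)),
               con)
  }
  invisible(path)
}

.parse_comment <- function(line, i) {
  kv <- regmatches(line, gregexpr("[A-Za-z_]+=[^ ]+", line))[[1]]
  if (!length(kv)) stop(sprintf("snapshot %d: malformed comment line", i))
  vals <- sub("^[A-Za-z_]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  vals
}

#' Read a trajectory
#'
#' Inverse of [write_trajectory()]; species, ids and radii round-trip
#' exactly, coordinates to the printed precision. Velocities are not part
#' of the text format and read back as zero.
#'
#' @param path trajectory file.
#' @return a `vc_trajectory` (with `config = NULL` for text files).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    tr <- readRDS(path)
    if (!inherits(tr, "vc_trajectory")) stop("not a trajectory container")
    return(tr)
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trajectory file: at least one snapshot required")
  pos <- 1L
  snaps <- list()
  i <- 0L
  n <- NA_integer_
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    i <- i + 1L
    n_i <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n_i)) stop(sprintf("snapshot %d: bad particle-count line", i))
    if (!is.na(n) && n_i != n)
      stop(sprintf("snapshot %d: inconsistent particle count (%d vs %d)",
                   i, n_i, n))
    n <- n_i
    if (pos + 1L + n > length(lines))
      stop(sprintf("snapshot %d: truncated block", i))
    hdr <- .parse_comment(lines[pos + 1L], i)
    body <- lines[(pos + 2L):(pos + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    if (any(lengths(fields) != 6))
      stop(sprintf("snapshot %d: expected 6 columns per particle row", i))
    m <- do.call(rbind, fields)
    if (!all(m[, 1] %in% .species_levels))
      stop(sprintf("snapshot %d: unknown species token '%s'", i,
                   setdiff(m[, 1], .species_levels)[1]))
    snaps[[i]] <- list(step = as.integer(hdr[["step"]]),
                       time = as.numeric(hdr[["time"]]),
                       box = as.numeric(hdr[["box"]]),
                       model = hdr[["model"]],
                       species = m[, 1],
                       x = as.numeric(m[, 2]), y = as.numeric(m[, 3]),
                       radius = as.numeric(m[, 4]),
                       vesicle_id = as.integer(m[, 5]),
                       dimer_id = as.integer(m[, 6]))
    pos <- pos + 2L + n
  }
  s1 <- snaps[[1]]
  dimid <- ifelse(s1$dimer_id < 0, NA_integer_, s1$dimer_id)
  structure(list(config = NULL, model = s1$model, box_length = s1$box,
                 species = s1$species, radius = s1$radius,
                 vesicle_id = s1$vesicle_id, dimer_id = dimid,
                 steps = vapply(snaps, `[[`, integer(1), "step"),
                 times = vapply(snaps, `[[`, numeric(1), "time"),
                 x = matrix(unlist(lapply(snaps, `[[`, "x")), nrow = n),
                 y = matrix(unlist(lapply(snaps, `[[`, "y")), nrow = n),
                 vx = matrix(0, n, length(snaps)),
                 vy = matrix(0, n, length(snaps)),
                 potential_energy = rep(NA_real_, length(snaps)),
                 kinetic_energy = rep(NA_real_, length(snaps))),
            class = "vc_trajectory")
}

#' Write the growth curve of a trajectory as CSV
#'
#' Columns `snapshot`, `time`, `n_clusters`, `mean_size`, `max_size`.
#'
#' @param curve a `vc_growth_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(curve, path) {
  stopifnot(inherits(curve, "vc_growth_curve"))
  df <- data.frame(snapshot = seq_along(curve$times), time = curve$times,
                   n_clusters = curve$n_clusters,
                   mean_size = curve$mean_size, max_size = curve$max_size)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest next to a simulation output
#'
#' JSON record of the resolved configuration, package version, seed, step
#' range, output paths and wall time: enough to reproduce the run
#' bit-for-bit. Written atomically (temp file + rename).
#'
#' @param config the resolved `vc_config` of the run.
#' @param output_paths character vector of files the run produced.
#' @param wall_time_s elapsed seconds (informational).
#' @param path manifest path (default: first output path + `.manifest.json`).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, output_paths, wall_time_s = NA_real_,
                               path = paste0(output_paths[1],
                                             ".manifest.json")) {
  stopifnot(inherits(config, "vc_config"))
  manifest <- list(
    package = "vesicond",
    version = as.character(utils::packageVersion("vesicond")),
    seed = config$seed,
    start_step = 0,
    end_step = config$n_steps,
    config = unclass(config),
    outputs = output_paths,
    wall_time_s = wall_time_s)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
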