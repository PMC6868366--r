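#' Write a labeled frame to a plain-text coordinate file
#'
#' Minimal fixed-column text format (format tag `pathsampler-frame v1`):
#' one whitespace-separated row per atom with columns `residue_id`,
#' `atom_name`, `x`, `y`, `z` (nm). Water oxygens are written as residue
#' `SOL` with atom name `OW` and recovered into the `water_oxygens` slot on
#' reading. Not a PDB dialect; just enough structure for fixtures and
#' interchange.
#'
#' @param frame A [labeled_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pathsampler-frame v1", con)
  df <- frame$atoms
  if (nrow(frame$water_oxygens)) {
    w <- as.data.frame(frame$water_oxygens)
    names(w) <- c("x", "y", "z")
    w <- cbind(residue_id = "SOL", atom_name = "OW", w)
    df <- rbind(df, w)
  }
  write.table(format(df, digits = 12, trim = TRUE), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a labeled frame from a plain-text coordinate file
#'
#' @param path File written by [write_frame()] (or any whitespace table
#'   with columns residue_id, atom_name, x, y, z).
#' @return A [labeled_frame()].
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("read_frame: no such file: ", path)
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("residue_id", "atom_name", "x", "y", "z"),
                   colClasses = c("character", "character", "numeric",
                                  "numeric", "numeric"))
  wat <- df$residue_id == "SOL"
  labeled_frame(df[!wat, , drop = FALSE],
                water_oxygens = if (any(wat))
                  as.matrix(df[wat, c("x", "y", "z")]) else NULL)
}

#' Write a toy trajectory to a delimited text store
#'
#' Self-describing tab-separated container (format tag
#' `pathsampler-traj v1`): `# key: value` metadata header lines carrying
#' the model parameters and the seed, followed by a header row and one row
#' per saved frame (time, x, y, vx, vy).
#'
#' @param traj A `toy_traj` (from [propagate_until()]) or a frame matrix.
#' @param path Output file path.
#' @param params The [toy_params()] used to generate it (stored as
#'   metadata), or NULL.
#' @param seed Seed recorded in the metadata, or NULL.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, params = NULL, seed = NULL) {
  frames <- if (inherits(traj, "toy_traj")) traj$frames else traj
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# format: pathsampler-traj v1", con)
  if (!is.null(params))
    for (nm in setdiff(names(params), "save_interval"))
      writeLines(sprintf("# %s: %.17g", nm, params[[nm]]), con)
  if (!is.null(params))
    writeLines(sprintf("# save_interval: %d", params$save_interval), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  writeLines(paste(colnames(frames), collapse = "\t"), con)
  write.table(format(frames, digits = 17, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a toy trajectory store
#'
#' @param path File written by [write_trajectory()].
#' @return List with `frames` (numeric matrix) and `meta` (named list of
#'   metadata values, possibly empty).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("read_trajectory: no such file: ", path)
  lines <- readLines(path)
  metal <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in metal) {
    kv <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(kv) == 3L) {
      v <- suppressWarnings(as.numeric(kv[3]))
      meta[[trimws(kv[2])]] <- if (is.na(v)) trimws(kv[3]) else v
    }
  }
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t")[[1]]
  dat <- read.table(text = body[-1], sep = "\t")
  frames <- as.matrix(dat)
  colnames(frames) <- header
  list(frames = frames, meta = meta)
}
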