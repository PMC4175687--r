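#' Read a plasmid size in base pairs
#'
#' Accepts either a positive integer (passed through) or a FASTA file
#' path, in which case the length of the record is returned: only the
#' closed-circular length matters to the skeleton, never the sequence
#' content (lowercase and ambiguity codes all count).
#'
#' @param x Integer base-pair count or FASTA path.
#' @param id Record identifier, required when the file holds several
#'   records.
#' @return Integer base-pair count.
#' @export
read_bp_count <- function(x, id = NULL) {
  if (is.numeric(x)) {
    n <- as.integer(x)
    if (n <= 0) stop("base-pair count must be positive")
    return(n)
  }
  if (!file.exists(x)) stop("FASTA file not found: ", x)
  lens <- Biostrings::fasta.seqlengths(x)
  if (length(lens) == 0L) stop("empty FASTA file: ", x)
  if (length(lens) > 1L) {
    if (is.null(id)) {
      stop("FASTA has ", length(lens), " records; supply a record id")
    }
    hit <- which(sub("\\s.*$", "", names(lens)) == id | names(lens) == id)
    if (length(hit) != 1L) stop("record id not found: ", id)
    lens <- lens[hit]
  }
  as.integer(lens[[1L]])
}

#' Write skeleton(s) to an XYZ file
#'
#' One frame per skeleton: an atom-count line, a comment line carrying the
#' step index and segment length, then one `C x y z` line per vertex with
#' nine-decimal coordinates (Angstrom).
#'
#' @param x A `dna_skeleton`, or a list of them (trajectory).
#' @param path Output file.
#' @param steps Step index per frame (for the comment line).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, steps = NULL) {
  if (inherits(x, "dna_skeleton")) x <- list(x)
  if (is.null(steps)) steps <- seq_along(x) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(x)) {
    sk <- x[[k]]
    writeLines(as.character(sk$s), con)
    writeLines(sprintf("step=%d l=%.9f", steps[k], sk$l), con)
    writeLines(sprintf("C %.9f %.9f %.9f", sk$vertices[, 1], sk$vertices[, 2],
                       sk$vertices[, 3]), con)
  }
  invisible(path)
}

#' Read skeleton(s) from an XYZ file
#'
#' @param path XYZ file written by [write_xyz()].
#' @param frame Which frame to return; `NULL` returns all frames as a
#'   list.
#' @return A `dna_skeleton` (single frame) or list of them.
#' @export
read_xyz <- function(path, frame = 1L) {
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    s <- as.integer(lines[pos])
    comment <- lines[pos + 1L]
    l <- as.numeric(sub(".*l=([0-9.eE+-]+).*", "\\1", comment))
    atoms <- lines[(pos + 2L):(pos + 1L + s)]
    parts <- do.call(rbind, strsplit(trimws(atoms), "\\s+"))
    v <- matrix(as.numeric(parts[, 2:4]), ncol = 3L)
    frames[[length(frames) + 1L]] <- skeleton(v, l = if (is.na(l)) NULL else l,
                                              validate = FALSE)
    pos <- pos + 2L + s
  }
  if (is.null(frame)) frames else frames[[frame]]
}

#' Write simulation metrics to CSV
#'
#' Per-step metrics with a provenance header (`#`-prefixed lines: package
#' version, move, steps, seed, key parameters) followed by the CSV table
#' `step,E,E_b,E_t,Wr,T,accepted,knot_rejected,avg_disp`.
#'
#' @param sim An `mc_simulation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(sim, path) {
  cfg <- sim$config
  hdr <- c(sprintf("# plasmidmc %s", as.character(utils::packageVersion("plasmidmc"))),
           sprintf("# move=%s steps=%d seed=%s", cfg$move_name,
                   nrow(sim$metrics),
                   if (is.null(cfg$seed)) "NA" else as.character(cfg$seed)),
           sprintf("# n_bp=%s T0=%g anneal=%s dLk=%.6f r=%g l=%g",
                   as.character(cfg$n_bp), cfg$T0, cfg$anneal, cfg$dLk,
                   cfg$r, cfg$l))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(sim$metrics, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics()]
#'
#' @param path Metrics file.
#' @return The metrics data frame.
#' @export
read_metrics <- function(path) {
  read.csv(path, comment.char = "#")
}
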