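AGP_COLS <- c("object", "object_beg", "object_end", "part_number",
              "component_type", "col6", "col7", "col8", "col9")

#' Read an AGP v2.1 file
#'
#' Parses the nine-column AGP format describing how components (contigs) and
#' gaps are laid out within assembly objects. Only `W` (WGS contig) components
#' and `N`/`U` gap lines are interpreted; comment lines (`#`) are skipped.
#'
#' @param path Path to an AGP file.
#' @return A data.frame with one row per line: `object`, `object_beg`,
#'   `object_end` (1-based, inclusive, as in the file), `part_number`,
#'   `component_type`, and the type-dependent columns 6-9 as character.
#' @seealso [contig_track_from_agp()], [write_agp()]
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(object = character(), object_beg = integer(),
                      object_end = integer(), part_number = integer(),
                      component_type = character(), col6 = character(),
                      col7 = character(), col8 = character(), col9 = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L)
    stop(sprintf("AGP format error: line %d does not have 9 columns", bad[1L]),
         call. = FALSE)
  m <- do.call(rbind, fields)
  out <- data.frame(object = m[, 1L],
                    object_beg = as.integer(m[, 2L]),
                    object_end = as.integer(m[, 3L]),
                    part_number = as.integer(m[, 4L]),
                    component_type = m[, 5L],
                    col6 = m[, 6L], col7 = m[, 7L], col8 = m[, 8L],
                    col9 = m[, 9L], stringsAsFactors = FALSE)
  if (any(is.na(out$object_beg)) || any(is.na(out$object_end)))
    stop("AGP format error: non-numeric object coordinates", call. = FALSE)
  out
}

#' Write an AGP v2.1 file
#'
#' @param agp A data.frame as returned by [read_agp()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (nrow(agp) > 0L) {
    lines <- do.call(paste, c(unname(as.list(agp[AGP_COLS])), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

# Build AGP rows for one object laid out as alternating contigs and N gaps.
# contigs: data.frame(start, end) 0-based half-open in object coordinates.
agp_rows_for_object <- function(object, contigs, component_ids) {
  n <- nrow(contigs)
  rows <- vector("list", 2L * n)
  part <- 0L
  prev_end <- 0L
  k <- 0L
  for (i in seq_len(n)) {
    if (contigs$start[i] > prev_end) {
      part <- part + 1L
      k <- k + 1L
      rows[[k]] <- data.frame(
        object = object, object_beg = prev_end + 1L,
        object_end = contigs$start[i], part_number = part,
        component_type = "N",
        col6 = as.character(contigs$start[i] - prev_end),
        col7 = "contig", col8 = "no", col9 = "na",
        stringsAsFactors = FALSE)
    }
    part <- part + 1L
    k <- k + 1L
    rows[[k]] <- data.frame(
      object = object, object_beg = contigs$start[i] + 1L,
      object_end = contigs$end[i], part_number = part,
      component_type = "W", col6 = component_ids[i], col7 = "1",
      col8 = as.character(contigs$end[i] - contigs$start[i]), col9 = "+",
      stringsAsFactors = FALSE)
    prev_end <- contigs$end[i]
  }
  do.call(rbind, rows[seq_len(k)])
}
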