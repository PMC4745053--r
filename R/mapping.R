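#' Positional records for accepted primers
#'
#' Converts a primer table to track intervals: a forward primer at 5' start
#' `s` with length `l` occupies `(s, s+l-1, +)`; a reverse primer named `n`
#' occupies `(n-l+1, n, -)` on the plus strand.
#'
#' @param primers Accepted primer table (see [apply_filters()]).
#' @return Data frame: `source_id`, `name`, `start`, `end`, `strand`,
#'   `sequence` with one row per primer.
#' @export
positional_records <- function(primers) {
  if (nrow(primers) == 0L) {
    return(data.frame(source_id = character(0), name = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  fwd <- primers$orientation == "forward"
  data.frame(source_id = primers$source_id, name = primers$name,
             start = ifelse(fwd, primers$start,
                            primers$start - primers$length + 1L),
             end = ifelse(fwd, primers$start + primers$length - 1L,
                          primers$start),
             strand = ifelse(fwd, "+", "-"), sequence = primers$sequence,
             stringsAsFactors = FALSE)
}

#' Write / read positional records as TSV
#'
#' The TSV round-trips byte-identically (write, read, write gives the same
#' file).
#'
#' @param positions Data frame from [positional_records()].
#' @param path File path.
#' @return `write_positions_tsv()` returns `path` invisibly;
#'   `read_positions_tsv()` returns the data frame.
#' @export
write_positions_tsv <- function(positions, path) {
  utils::write.table(positions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions_tsv
#' @export
read_positions_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(source_id = "character",
                                   name = "character", start = "integer",
                                   end = "integer", strand = "character",
                                   sequence = "character"),
                    stringsAsFactors = FALSE)
}

# greedy lane assignment: first lane whose last occupant ends before this
# interval starts (with a 1-base gutter); intervals must be sorted by start
assign_lanes <- function(start, end) {
  lanes <- integer(length(start))
  lane_end <- numeric(0)
  for (i in order(start, end)) {
    free <- which(lane_end < start[i] - 1L)
    lane <- if (length(free)) free[1L] else length(lane_end) + 1L
    lanes[i] <- lane
    lane_end[lane] <- end[i]
  }
  lanes
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.2f", x))

# an arrowed primer glyph: rectangular body plus a triangular head pointing
# 3'-ward (right on +, left on -)
primer_glyph <- function(x1, x2, y, name, strand, colour) {
  h <- 8
  head <- min(6, x2 - x1)
  pts <- if (strand == "+") {
    sprintf("%s,%s %s,%s %s,%s %s,%s %s,%s",
            fmt_num(x1), fmt_num(y - h / 2), fmt_num(x2 - head),
            fmt_num(y - h / 2), fmt_num(x2), fmt_num(y),
            fmt_num(x2 - head), fmt_num(y + h / 2), fmt_num(x1),
            fmt_num(y + h / 2))
  } else {
    sprintf("%s,%s %s,%s %s,%s %s,%s %s,%s",
            fmt_num(x2), fmt_num(y - h / 2), fmt_num(x1 + head),
            fmt_num(y - h / 2), fmt_num(x1), fmt_num(y),
            fmt_num(x1 + head), fmt_num(y + h / 2), fmt_num(x2),
            fmt_num(y + h / 2))
  }
  c(sprintf('<polygon class="primer" points="%s" fill="%s"><title>%s</title></polygon>',
            pts, colour, svg_escape(name)),
    sprintf('<text class="primer-label" x="%s" y="%s" font-size="7" fill="%s">%s</text>',
            fmt_num(x1), fmt_num(y - h / 2 - 2), colour, svg_escape(name)))
}

ruler_svg <- function(offset_x, y, length_bp, ppb, label_from = 0L) {
  step <- max(10L, 10^floor(log10(max(length_bp, 10L))) / 2)
  ticks <- seq(0L, length_bp, by = step)
  out <- sprintf('<line class="ruler" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
                 fmt_num(offset_x), fmt_num(y),
                 fmt_num(offset_x + length_bp * ppb), fmt_num(y))
  for (t in ticks) {
    x <- offset_x + t * ppb
    out <- c(out,
             sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
                     fmt_num(x), fmt_num(y), fmt_num(x), fmt_num(y + 4)),
             sprintf('<text x="%s" y="%s" font-size="8">%s</text>',
                     fmt_num(x), fmt_num(y + 14), label_from + t))
  }
  out
}

#' Render a per-sequence primer map as SVG
#'
#' A scaled base-pair ruler with one arrowed glyph per primer (arrowhead
#' pointing in the direction of synthesis), each labelled with the primer
#' name, the record header as title and, for SNP records, a distinct
#' marker at the SNP coordinate. Pure function: identical inputs give
#' byte-identical SVG.
#'
#' @param record One record row (`id`, `residues`, optional `description`).
#' @param positions Positional records belonging to this record.
#' @param snp_position Optional 1-based SNP coordinate to mark.
#' @param pixels_per_base Horizontal scale (default chosen so the map is
#'   about 900 px wide).
#' @param primer_colour,snp_colour Glyph colours (defaults: blue primers,
#'   green SNP marker).
#' @return A single character string containing the SVG document.
#' @export
render_sequence_map <- function(record, positions, snp_position = NULL,
                                pixels_per_base = NULL,
                                primer_colour = "#1f4fd8",
                                snp_colour = "#1fa83c") {
  L <- nchar(record$residues[[1L]])
  if (nrow(positions) > 0L &&
      (any(positions$start < 1L) || any(positions$end > L))) {
    stop("positional record out of range for record '", record$id[[1L]], "'",
         call. = FALSE)
  }
  ppb <- if (is.null(pixels_per_base)) 900 / L else pixels_per_base
  margin <- 30
  ruler_y <- 40
  lanes <- if (nrow(positions)) assign_lanes(positions$start, positions$end)
           else integer(0)
  n_lanes <- if (length(lanes)) max(lanes) else 0L
  height <- ruler_y + 30 + n_lanes * 22 + 20
  width <- L * ppb + 2 * margin
  title <- svg_escape(trimws(paste(record$id[[1L]],
                                   if ("description" %in% names(record))
                                     record$description[[1L]] else "")))
  body <- c(sprintf('<text class="map-title" x="%s" y="16" font-size="11">%s</text>',
                    fmt_num(margin), title),
            ruler_svg(margin, ruler_y, L, ppb))
  if (!is.null(snp_position)) {
    x <- margin + (snp_position - 0.5) * ppb
    body <- c(body,
              sprintf('<polygon class="snp" points="%s,%s %s,%s %s,%s" fill="%s"/>',
                      fmt_num(x - 4), fmt_num(ruler_y - 12), fmt_num(x + 4),
                      fmt_num(ruler_y - 12), fmt_num(x), fmt_num(ruler_y - 4),
                      snp_colour),
              sprintf('<text class="snp-label" x="%s" y="%s" font-size="8" fill="%s">SNP %d</text>',
                      fmt_num(x + 6), fmt_num(ruler_y - 8), snp_colour,
                      snp_position))
  }
  if (nrow(positions)) {
    for (i in seq_len(nrow(positions))) {
      y <- ruler_y + 30 + (lanes[i] - 1L) * 22 + 8
      body <- c(body, primer_glyph(margin + (positions$start[i] - 1L) * ppb,
                                   margin + positions$end[i] * ppb, y,
                                   positions$name[i], positions$strand[i],
                                   primer_colour))
    }
  }
  paste(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
                  fmt_num(width), fmt_num(height), fmt_num(width),
                  fmt_num(height)),
          body, "</svg>"), collapse = "\n")
}

#' Global offsets for the concatenated map
#'
#' Records are laid end-to-end with zero gap, in input order; the offset of
#' record i is the summed length of records 1..i-1.
#'
#' @param records Record data frame.
#' @return Named integer vector of offsets.
#' @export
global_offsets <- function(records) {
  lens <- nchar(records$residues)
  stats::setNames(c(0L, cumsum(lens))[seq_len(nrow(records))], records$id)
}

#' Render the single concatenated all-sequence primer map
#'
#' All records are assembled end-to-end (zero gap, input-file order) on one
#' ruler; a primer at local start `s` of record `i` appears at global
#' coordinate `offset(i) + s`. Record boundaries are ticked and labelled.
#'
#' @param records Record data frame in input order.
#' @param positions Positional records for all records.
#' @param snp_positions Optional named vector (by record id) of SNP
#'   coordinates to mark.
#' @inheritParams render_sequence_map
#' @return SVG document as a character string.
#' @export
render_concatenated_map <- function(records, positions, snp_positions = NULL,
                                    pixels_per_base = NULL,
                                    primer_colour = "#1f4fd8",
                                    snp_colour = "#1fa83c") {
  offsets <- global_offsets(records)
  total <- sum(nchar(records$residues))
  ppb <- if (is.null(pixels_per_base)) 1100 / total else pixels_per_base
  margin <- 30
  ruler_y <- 46
  glob <- positions
  if (nrow(glob)) {
    off <- offsets[glob$source_id]
    glob$start <- glob$start + off
    glob$end <- glob$end + off
    lanes <- assign_lanes(glob$start, glob$end)
  } else lanes <- integer(0)
  n_lanes <- if (length(lanes)) max(lanes) else 0L
  height <- ruler_y + 30 + n_lanes * 22 + 20
  width <- total * ppb + 2 * margin
  body <- c(sprintf('<text class="map-title" x="%s" y="16" font-size="11">concatenated primer map (%d sequences, %d bp)</text>',
                    fmt_num(margin), nrow(records), total),
            ruler_svg(margin, ruler_y, total, ppb))
  for (id in records$id) {
    x <- margin + offsets[[id]] * ppb
    body <- c(body,
              sprintf('<line class="boundary" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888" stroke-dasharray="3,2"/>',
                      fmt_num(x), fmt_num(ruler_y - 18), fmt_num(x),
                      fmt_num(height - 10)),
              sprintf('<text class="boundary-label" x="%s" y="%s" font-size="9" fill="#555">%s</text>',
                      fmt_num(x + 2), fmt_num(ruler_y - 20), svg_escape(id)))
  }
  if (!is.null(snp_positions)) {
    for (id in names(snp_positions)) {
      x <- margin + (offsets[[id]] + snp_positions[[id]] - 0.5) * ppb
      body <- c(body,
                sprintf('<polygon class="snp" points="%s,%s %s,%s %s,%s" fill="%s"/>',
                        fmt_num(x - 4), fmt_num(ruler_y - 12), fmt_num(x + 4),
                        fmt_num(ruler_y - 12), fmt_num(x),
                        fmt_num(ruler_y - 4), snp_colour))
    }
  }
  if (nrow(glob)) {
    for (i in seq_len(nrow(glob))) {
      y <- ruler_y + 30 + (lanes[i] - 1L) * 22 + 8
      body <- c(body, primer_glyph(margin + (glob$start[i] - 1L) * ppb,
                                   margin + glob$end[i] * ppb, y,
                                   glob$name[i], glob$strand[i],
                                   primer_colour))
    }
  }
  paste(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
                  fmt_num(width), fmt_num(height), fmt_num(width),
                  fmt_num(height)),
          body, "</svg>"), collapse = "\n")
}

#' Derive a primer from two template coordinates
#'
#' The map-drawing rule: coordinates given left-to-right (`a < b`) return
#' the forward substring `[a..b]`; right-to-left (`a > b`) return the
#' reverse complement of `[b..a]`. GC% and Tm are computed on the returned
#' 5'->3' sequence.
#'
#' @param record One record row (`id`, `residues`).
#' @param a,b 1-based template coordinates, `a != b`; the span must be at
#'   least 8 nt.
#' @param conditions A [thermo_conditions()] object.
#' @return List with `sequence`, `gc_percent`, `tm`, `orientation`.
#' @export
primer_from_coordinates <- function(record, a, b,
                                    conditions = thermo_conditions()) {
  L <- nchar(record$residues[[1L]])
  if (a < 1L || b < 1L || a > L || b > L) {
    stop("coordinates out of range [1, ", L, "]", call. = FALSE)
  }
  if (a == b) stop("coordinates must differ", call. = FALSE)
  lo <- min(a, b); hi <- max(a, b)
  if (hi - lo + 1L < 8L) {
    stop("span shorter than 8 nt: too short for a primer", call. = FALSE)
  }
  seqc <- substring(record$residues[[1L]], lo, hi)
  orientation <- if (a < b) "forward" else "reverse"
  if (orientation == "reverse") seqc <- reverse_complement(seqc)
  list(sequence = seqc, gc_percent = gc_percent(seqc),
       tm = tm_calc(seqc, conditions), orientation = orientation)
}

#' Export primers as JSON lines
#'
#' One JSON object per primer (`source_id`, `name`, `start`, `end`,
#' `strand`), a viewer-agnostic companion to the positional TSV.
#'
#' @param positions Data frame from [positional_records()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_primers_json <- function(positions, path) {
  lines <- vapply(seq_len(nrow(positions)), function(i) {
    as.character(jsonlite::toJSON(list(source_id = positions$source_id[i],
                                       name = positions$name[i],
                                       start = positions$start[i],
                                       end = positions$end[i],
                                       strand = positions$strand[i]),
                                  auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
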