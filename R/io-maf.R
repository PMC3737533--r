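# MAF (multiple alignment format) reader/writer. Only 'a' and 's' lines are
# interpreted; the first 's' line of each block is the reference row. Blocks
# whose reference row is on the '-' strand are flipped into '+' coordinates
# with every row reverse-complemented, so downstream code sees a single
# orientation.

revcomp <- function(x) {
  # keeps gaps and case; alignment rows may contain '-'
  vapply(x, function(s) {
    chartr("ACGTacgtNn", "TGCAtgcaNn",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# Split a MAF src field into species and sequence id at the first dot.
maf_split_src <- function(src) {
  sp <- sub("\\..*$", "", src)
  sid <- ifelse(grepl(".", src, fixed = TRUE), sub("^[^.]*\\.", "", src), src)
  list(species = sp, seq_id = sid)
}

#' Read a MAF multiple alignment
#'
#' @param path Path to a MAF file.
#' @return Tibble with one row per alignment block: `seq_id`, `start`, `end`
#'   (reference coordinates, 0-based half-open, '+' strand), `ref_species`,
#'   and a `rows` list-column of `(species, text)` tibbles whose first row is
#'   the reference. Blocks are sorted by reference position.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL
  flush_block <- function(cur) {
    if (is.null(cur) || length(cur$species) == 0) return(NULL)
    widths <- nchar(cur$text)
    if (length(unique(widths)) != 1) {
      abort(sprintf("%s: block starting at line %d has rows of unequal gapped length",
                    path, cur$line))
    }
    ungapped <- nchar(gsub("-", "", cur$text[1], fixed = TRUE))
    if (ungapped != cur$size[1]) {
      abort(sprintf("%s: block at line %d: reference ungapped length %d != declared size %d",
                    path, cur$line, ungapped, cur$size[1]))
    }
    if (cur$strand[1] == "-") {
      # flip to '+' reference coordinates; reverse-complement all rows
      cur$text <- revcomp(cur$text)
      cur$start[1] <- cur$src_size[1] - (cur$start[1] + cur$size[1])
    }
    src <- maf_split_src(cur$src[1])
    tibble(
      seq_id = src$seq_id,
      start = cur$start[1],
      end = cur$start[1] + cur$size[1],
      ref_species = src$species,
      rows = list(tibble(species = maf_split_src(cur$src)$species,
                         text = cur$text))
    )
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "a")) {
      blocks <- c(blocks, list(flush_block(cur)))
      cur <- list(line = i, src = character(), species = character(),
                  start = integer(), size = integer(), strand = character(),
                  src_size = integer(), text = character())
    } else if (startsWith(ln, "s ")) {
      if (is.null(cur)) abort(sprintf("%s line %d: 's' line outside a block", path, i))
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 7) abort(sprintf("%s line %d: malformed 's' line", path, i))
      cur$src <- c(cur$src, f[2])
      cur$species <- c(cur$species, maf_split_src(f[2])$species)
      cur$start <- c(cur$start, as.integer(f[3]))
      cur$size <- c(cur$size, as.integer(f[4]))
      cur$strand <- c(cur$strand, f[5])
      cur$src_size <- c(cur$src_size, as.integer(f[6]))
      cur$text <- c(cur$text, chartr("Uu", "Tt", f[7]))
    }
  }
  blocks <- c(blocks, list(flush_block(cur)))
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (length(blocks) == 0) abort(sprintf("%s: no alignment blocks", path))
  bind_rows(blocks) |> arrange(.data$seq_id, .data$start)
}

#' Write alignment blocks to MAF
#'
#' @param maf Tibble as returned by [read_maf()].
#' @param path Output path.
#' @param src_sizes Optional named vector of source sequence lengths per
#'   `seq_id` (defaults to the block end, which is only correct for blocks
#'   covering whole sequences).
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path, src_sizes = NULL) {
  con <- file(path, open = "wb")
  writeLines("##maf version=1", con, sep = "\n")
  for (i in seq_len(nrow(maf))) {
    rows <- maf$rows[[i]]
    size <- nchar(gsub("-", "", rows$text[1], fixed = TRUE))
    src_size <- if (!is.null(src_sizes)) unname(src_sizes[maf$seq_id[i]]) else
      maf$end[i]
    writeLines("", con, sep = "\n")
    writeLines("a score=0", con, sep = "\n")
    for (j in seq_len(nrow(rows))) {
      src <- if (j == 1) paste0(rows$species[j], ".", maf$seq_id[i]) else
        paste0(rows$species[j], ".", maf$seq_id[i])
      sz <- nchar(gsub("-", "", rows$text[j], fixed = TRUE))
      writeLines(paste("s", src, if (j == 1) maf$start[i] else 0L,
                       if (j == 1) size else sz, "+", src_size,
                       rows$text[j], sep = " "), con, sep = "\n")
    }
  }
  close(con)
  invisible(path)
}
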