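#' Create a protein region
#'
#' A `protein_region` is a named subsequence of a parent protein with 1-based
#' inclusive residue numbering, the unit on which all sequence-level disorder
#' statistics are computed.
#'
#' @param sequence Character scalar, amino acids in the canonical 20-letter
#'   one-letter alphabet. Ambiguity codes (B, Z, X) and anything else are
#'   rejected.
#' @param name Label for the region (e.g. `"CTD2A"`).
#' @param start 1-based residue number of the first residue in the parent
#'   protein.
#' @param end 1-based residue number of the last residue; defaults to
#'   `start + nchar(sequence) - 1` and must equal it.
#' @return An object of class `protein_region` with fields `name`, `sequence`,
#'   `start`, `end`.
#' @examples
#' protein_region("MKTAYIA", name = "toy")
#' @export
protein_region <- function(sequence, name = "region", start = 1L,
                           end = start + nchar(sequence) - 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("protein_region(): empty sequence")
  if (start < 1L)
    stop("protein_region(): 'start' must be >= 1")
  if (end - start + 1L != nchar(sequence))
    stop("protein_region(): end - start + 1 (", end - start + 1L,
         ") does not match sequence length (", nchar(sequence), ")")
  letters <- region_letters_check(sequence)
  structure(
    list(name = name, sequence = sequence,
         start = as.integer(start), end = as.integer(end)),
    class = "protein_region"
  )
}

# Validate the alphabet, reporting offending positions.
region_letters_check <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  bad <- which(!ch %in% AA_CANONICAL)
  if (length(bad))
    stop("non-canonical amino-acid letter(s) ",
         paste0(ch[bad], " at position ", bad, collapse = ", "))
  invisible(ch)
}

#' @export
print.protein_region <- function(x, ...) {
  cat(sprintf("<protein_region> %s [%d-%d], %d aa\n",
              x$name, x$start, x$end, region_length(x)))
  seq <- x$sequence
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat(" ", seq, "\n")
  invisible(x)
}

#' @rdname protein_region
#' @param x A `protein_region`.
#' @export
region_length <- function(x) nchar(x$sequence)

# Residues of a region as a character vector.
region_chars <- function(region) strsplit(region$sequence, "")[[1]]

#' Read a numbered region from a FASTA file
#'
#' Extracts the inclusive subsequence `start..end` (numbered along the FASTA
#' record, 1-based) from a single- or multi-record FASTA file.
#'
#' @param path Path to a FASTA file.
#' @param start,end 1-based inclusive residue numbers within the record.
#' @param name Region label; defaults to the record name with the boundaries
#'   appended.
#' @param record Record index or name when the file holds several sequences.
#' @return A [protein_region()].
#' @export
read_fasta_region <- function(path, start, end, name = NULL, record = 1L) {
  if (!file.exists(path))
    stop("read_fasta_region(): no such file: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("read_fasta_region(): malformed FASTA (",
                             conditionMessage(e), ")")
  )
  if (length(set) == 0L)
    stop("read_fasta_region(): FASTA file contains no records")
  if (is.character(record)) {
    hit <- grep(record, names(set), fixed = TRUE)
    if (length(hit) == 0L)
      stop("read_fasta_region(): no record matching '", record, "'")
    record <- hit[1L]
  }
  full <- as.character(set[[record]])
  L <- nchar(full)
  if (start < 1L || end > L || start > end)
    stop("read_fasta_region(): boundaries [", start, ", ", end,
         "] out of range for record of length ", L)
  if (is.null(name))
    name <- sprintf("%s_%d-%d", sub("\\s.*$", "", names(set)[record]),
                    start, end)
  protein_region(substr(full, start, end), name = name,
                 start = start, end = end)
}

#' Read a region-definition table
#'
#' A plain CSV with columns `name`, `source` (FASTA path, relative paths are
#' resolved against the config file's directory), `record` (optional record
#' index or name), `start`, `end`.
#'
#' @param path Path to the CSV config.
#' @return A list of [protein_region()] objects.
#' @export
read_region_config <- function(path) {
  cfg <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "source", "start", "end")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("read_region_config(): missing column(s): ",
         paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(cfg)), function(i) {
    src <- cfg$source[i]
    if (!file.exists(src)) src <- file.path(base, cfg$source[i])
    rec <- if ("record" %in% names(cfg) && !is.na(cfg$record[i]) &&
               nzchar(cfg$record[i])) cfg$record[i] else 1L
    read_fasta_region(src, cfg$start[i], cfg$end[i],
                      name = cfg$name[i], record = rec)
  })
}

#' Write regions to a FASTA file
#'
#' @param regions A `protein_region` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_regions <- function(regions, path) {
  if (inherits(regions, "protein_region")) regions <- list(regions)
  seqs <- Biostrings::AAStringSet(vapply(regions, `[[`, "", "sequence"))
  names(seqs) <- vapply(regions, function(r)
    sprintf("%s %d-%d", r$name, r$start, r$end), "")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
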